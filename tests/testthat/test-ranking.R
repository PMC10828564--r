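test_that("cosine similarity closed forms and degenerate inputs", {
  expect_equal(cosine_similarity(c(3, 4), c(3, 4)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 2)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("predicted ranking sorts by cosine with id tie-breaks", {
  q <- c(1, 0)
  E <- rbind(self = c(2, 0), ortho = c(0, 1), mid = c(1, 1))
  expect_equal(predict_ranking(q, E), c("self", "mid", "ortho"))
  # all candidates identical: pure id order
  E2 <- rbind(zz = c(1, 1), aa = c(1, 1), mm = c(1, 1))
  expect_equal(predict_ranking(q, E2), c("aa", "mm", "zz"))
  # random case against an explicit sort oracle
  set.seed(22)
  E3 <- matrix(rnorm(40), 20, 2,
               dimnames = list(sprintf("c%02d", 1:20), NULL))
  got <- predict_ranking(q, E3)
  sims <- apply(E3, 1, function(r) cosine_similarity(q, r))
  expect_equal(got, names(sort(-sims)))
})

test_that("NDCG identities and extremal permutations (enumeration)", {
  ids <- letters[1:3]
  expect_equal(ndcg(ranking_comparison(ids, ids)), 1)
  expect_equal(ndcg(ranking_comparison("a", "a")), 1)  # single item
  for (n in 3:5) {
    ids <- letters[seq_len(n)]
    vals <- vapply(all_perms(n), function(p)
      ndcg(ranking_comparison(ids, ids[p])), numeric(1))
    expect_equal(max(vals), 1)  # attained by the identity permutation
    # reversal minimises NDCG among all permutations
    rev_val <- ndcg(ranking_comparison(ids, rev(ids)))
    expect_equal(min(vals), rev_val)
    expect_true(all(vals > 0 & vals <= 1))
  }
  expect_error(ranking_comparison(letters[1:3], letters[2:4]),
               "permutations")
})

test_that("one adjacent transposition towards the truth never lowers NDCG", {
  set.seed(24)
  ids <- letters[1:6]
  for (rep in 1:20) {
    p <- sample(6)
    i <- sample(5, 1)
    if (p[i] > p[i + 1]) {  # out of order: swapping moves towards truth
      q <- p; q[c(i, i + 1)] <- q[c(i + 1, i)]
      expect_gte(ndcg(ranking_comparison(ids, ids[q])),
                 ndcg(ranking_comparison(ids, ids[p])))
    }
  }
})

test_that("positional rank score has the stated closed forms", {
  ids <- letters[1:5]
  perfect <- lapply(1:4, function(i) ranking_comparison(ids, ids))
  expect_equal(positional_rank_score(perfect, 1), 1)
  # uniformly off by one rank: swap neighbouring pairs
  off1 <- lapply(1:4, function(i)
    ranking_comparison(ids, ids[c(2, 1, 4, 3, 5)]))
  expect_equal(positional_rank_score(off1, 1), exp(-1))
  # mixed case equals a term-by-term oracle
  set.seed(26)
  cmps <- lapply(1:10, function(i) ranking_comparison(ids, ids[sample(5)]))
  p <- 2
  oracle <- mean(vapply(cmps, function(cmp)
    exp(-abs(p - match(cmp$predicted_order[p], cmp$true_order))),
    numeric(1)))
  expect_equal(positional_rank_score(cmps, p), oracle)
  expect_error(positional_rank_score(cmps, 9), "p <= ")
})

test_that("rank_scores aggregates per-anchor values faithfully", {
  ranked <- toy_ranked(3)
  d <- generate_dataset(toy_spec(3))
  im <- cgr_images(d, 16)
  E <- embed_dataset(im, "fcgr")
  rs <- rank_scores(E, ranked)
  expect_equal(rs$mean_ndcg, mean(rs$per_anchor$ndcg))
  expect_equal(rs$sd_ndcg, sd(rs$per_anchor$ndcg))
  # forcing predictions equal to truth gives NDCG exactly 1 (plumbing)
  perfect <- lapply(names(ranked), function(a)
    ranking_comparison(ranked[[a]]$neighbor_id, ranked[[a]]$neighbor_id))
  expect_true(all(vapply(perfect, ndcg, numeric(1)) == 1))
  # subsetting anchors restricts the evaluation
  sub <- rank_scores(E, ranked, anchors = names(ranked)[1:4])
  expect_equal(nrow(sub$per_anchor), 4)
  # shuffled floor sits below the informative embedding
  expect_lt(shuffled_ndcg(ranked, seed = 1), rs$mean_ndcg)
})

test_that("cosine index retrieval matches a brute-force scan", {
  set.seed(28)
  E <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(sprintf("v%03d", 1:100), NULL))
  idx <- index_build(E)
  q <- E[37, ]
  top <- index_query(idx, q, 5)
  expect_equal(top$id[1], "v037")
  expect_equal(top$score[1], 1)
  # brute-force oracle over the whole index
  sims <- apply(E, 1, function(r) cosine_similarity(q, r))
  oracle <- names(sort(-sims))[1:5]
  expect_equal(top$id, oracle)
  # top_k = index size reproduces predict_ranking
  expect_warning(all_hits <- index_query(idx, q, 200), "exceeds")
  expect_equal(all_hits$id, predict_ranking(q, E))
  # persistence round-trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_index(idx, f)
  idx2 <- read_index(f)
  expect_equal(index_query(idx2, q, 5)$id, top$id)
})
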