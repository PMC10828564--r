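make_record <- function(ids, scores, anchor = "q") {
  ord <- order(-scores, ids)
  structure(list(anchor_id = anchor, neighbor_id = ids[ord],
                 score = as.integer(scores[ord]), n = length(ids)),
            class = "ranked_record")
}

test_that("triplet enumeration counts strict pairs only", {
  r3 <- make_record(c("a", "b", "c"), c(9, 5, 1))
  expect_equal(nrow(make_triplets(r3)), 3)  # C(3,2), all distinct
  r_tied <- make_record(c("a", "b", "c"), c(4, 4, 4))
  expect_equal(nrow(make_triplets(r_tied)), 0)
  # brute-force double-loop oracle with ties present
  set.seed(31)
  s <- sample(1:5, 10, replace = TRUE)
  r10 <- make_record(sprintf("n%02d", 1:10), s)
  oracle <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    if (r10$score[i] > r10$score[j]) oracle <- oracle + 1
  }
  tt <- make_triplets(r10)
  expect_equal(nrow(tt), oracle)
  # positives strictly more similar than negatives in every triplet
  sc <- stats::setNames(r10$score, r10$neighbor_id)
  expect_true(all(sc[tt$pos] > sc[tt$neg]))
  # a cap draws a seeded subsample
  expect_equal(nrow(make_triplets(r10, cap = 5, seed = 1)), 5)
})

test_that("triplet loss satisfies its closed-form identities", {
  a <- c(1, 0, 0)
  # positive equal to anchor, negative at squared distance alpha: loss 0
  neg <- c(1, sqrt(0.3), 0)
  expect_equal(triplet_loss(a, a, neg, margin = 0.3), 0)
  # positive == negative: distances cancel, loss = margin
  p <- c(0, 1, 1)
  expect_equal(triplet_loss(a, p, p, margin = 0.25), 0.25)
  expect_error(triplet_loss(a, c(1, 2), c(0, 0, 1)), "mismatch")
  # batch equals a term-by-term scalar oracle
  set.seed(41)
  A <- matrix(rnorm(15), 5, 3); P <- matrix(rnorm(15), 5, 3)
  N <- matrix(rnorm(15), 5, 3)
  oracle <- sum(vapply(1:5, function(i) {
    max(sum((A[i, ] - P[i, ])^2) - sum((A[i, ] - N[i, ])^2) + 0.4, 0)
  }, numeric(1)))
  expect_equal(triplet_loss(A, P, N, margin = 0.4), oracle)
  # invariance under a common translation
  sh <- matrix(rnorm(3), 5, 3, byrow = TRUE)
  expect_equal(triplet_loss(A + sh, P + sh, N + sh, margin = 0.4), oracle)
})

test_that("ladder groups split near-equally and never straddle ties", {
  r9 <- make_record(sprintf("n%d", 1:9), 9:1)
  expect_equal(lengths(make_ladder_groups(r9, 3)$groups), c(3, 3, 3))
  r10 <- make_record(sprintf("n%02d", 1:10), 10:1)
  expect_equal(lengths(make_ladder_groups(r10, 3)$groups), c(4, 3, 3))
  expect_error(make_ladder_groups(r9, 10), "at least")
  # tie block across the natural boundary is pulled into the earlier group
  r_tie <- make_record(sprintf("n%d", 1:6), c(9, 8, 7, 7, 7, 1))
  gr <- make_ladder_groups(r_tie, 3)
  sc <- stats::setNames(r_tie$score, r_tie$neighbor_id)
  for (i in 1:2) {
    hi <- sc[gr$groups[[i]]]
    lo <- sc[unlist(gr$groups[(i + 1):3])]
    if (length(hi) && length(lo)) expect_gte(min(hi), max(lo))
  }
  # pairwise audit on random records
  set.seed(13)
  for (rep in 1:10) {
    s <- sample(1:6, 12, replace = TRUE)
    rr <- make_record(sprintf("m%02d", 1:12), s)
    gr <- make_ladder_groups(rr, 4)
    sc <- stats::setNames(rr$score, rr$neighbor_id)
    expect_setequal(unlist(gr$groups), rr$neighbor_id)
    for (i in 1:3) {
      hi <- sc[gr$groups[[i]]]
      lo <- sc[unlist(gr$groups[(i + 1):4])]
      if (length(hi) && length(lo)) expect_gte(min(hi), max(lo))
    }
  }
})

test_that("ladder tier losses satisfy their identities", {
  q <- c(1, 0)
  # embeddings placed so every margin is met: positives at cosine 1,
  # negatives at cosine <= 1 - alpha
  g1 <- rbind(c(2, 0))                 # cosine 1
  g2 <- rbind(c(0, 1), c(0, 3))        # cosine 0
  expect_equal(ladder_group_loss(q, list(g1, g2), 2, alpha_i = 0.5), 0)
  # all candidates identical to q: tier-1 loss is n * alpha_1
  gsame <- list(rbind(q, q), rbind(q))
  expect_equal(ladder_group_loss(q, gsame, 1, alpha_i = 0.2), 3 * 0.2)
  # random case equals a double-loop scalar oracle
  set.seed(51)
  groups <- list(matrix(rnorm(6), 3, 2), matrix(rnorm(4), 2, 2),
                 matrix(rnorm(4), 2, 2))
  for (i in 2:3) {
    alpha <- 0.3
    oracle <- 0
    pos <- groups[[i - 1]]
    negs <- do.call(rbind, groups[i:3])
    for (a in seq_len(nrow(pos))) for (b in seq_len(nrow(negs))) {
      oracle <- oracle + max(alpha - cosine_similarity(q, pos[a, ]) +
                               cosine_similarity(q, negs[b, ]), 0)
    }
    expect_equal(ladder_group_loss(q, groups, i, alpha), oracle)
  }
})

test_that("full ladder loss is the weighted sum of tier losses", {
  set.seed(61)
  q <- rnorm(4)
  groups <- list(matrix(rnorm(8), 2), matrix(rnorm(8), 2),
                 matrix(rnorm(4), 1))
  cfg <- ladder_config(M = 3, alphas = c(0.1, 0.2, 0.3),
                       betas = c(1, 0.5, 2))
  oracle <- sum(vapply(1:3, function(i) {
    cfg$betas[i] * ladder_group_loss(q, groups, i, cfg$alphas[i])
  }, numeric(1)))
  expect_equal(ladder_loss(q, groups, cfg), oracle)
  # all-zero weights: zero loss
  cfg0 <- ladder_config(M = 3, alphas = c(0.1, 0.2, 0.3), betas = rep(0, 3))
  expect_equal(ladder_loss(q, groups, cfg0), 0)
  # M = 2 with beta = (0, 1) reduces to the single boundary term
  cfg2 <- ladder_config(M = 2, alphas = c(0.1, 0.25), betas = c(0, 1))
  g2 <- list(matrix(rnorm(8), 2), matrix(rnorm(8), 2))
  expect_equal(ladder_loss(q, g2, cfg2),
               ladder_group_loss(q, g2, 2, 0.25))
})

test_that("ladder loss falls when a positive moves towards the anchor", {
  # monotonicity in the positive direction: with the tier-1 repulsion term
  # inactive (alpha_1 = 0), raising a tier-1 member's cosine to q can only
  # relax the tier-2 hinges it appears in as a positive
  q <- c(1, 0, 0)
  groups <- list(rbind(c(0.5, 0.8, 0)), rbind(c(-0.3, 1, 0)),
                 rbind(c(-1, 0.2, 0)))
  cfg <- ladder_config(M = 3, alphas = c(0, 0.9, 0.9), betas = c(1, 1, 1))
  base <- ladder_loss(q, groups, cfg)
  groups2 <- groups
  groups2[[1]] <- rbind(c(0.9, 0.3, 0))  # higher cosine to q
  expect_lt(ladder_loss(q, groups2, cfg), base)
  # conversely, with alpha_1 > 0 the anchor-repulsion tier is active for
  # candidates nearly identical to q
  cfg1 <- ladder_config(M = 3, alphas = c(0.2, 0.4, 0.6), betas = c(1, 0, 0))
  near_q <- list(rbind(c(1, 0.01, 0)), groups[[2]], groups[[3]])
  expect_gt(ladder_loss(q, near_q, cfg1), 0)
})

test_that("training objectives agree with the exported loss functions", {
  set.seed(71)
  E <- matrix(rnorm(8 * 5), 8, 5)
  # ladder: rows 2..8 in three tiers
  gidx <- list(2:4, 5:6, 7:8)
  cfg <- ladder_config(M = 3, alphas = c(0.1, 0.2, 0.3), betas = c(1, 2, 3))
  internal <- dnaembed:::ladder_objective(E, gidx, cfg$alphas, cfg$betas,
                                          want_grad = FALSE)$loss
  exported <- ladder_loss(E[1, ], lapply(gidx, function(i)
    E[i, , drop = FALSE]), cfg)
  expect_equal(internal, exported)
  # triplet: sampled index pairs
  pos <- c(2L, 3L, 4L); neg <- c(5L, 6L, 8L)
  internal_t <- dnaembed:::triplet_objective(E, pos, neg, 0.3,
                                             want_grad = FALSE)$loss
  exported_t <- triplet_loss(E[rep(1, 3), ], E[pos, ], E[neg, ],
                             margin = 0.3)
  expect_equal(internal_t, exported_t)
})
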