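#' Cosine similarity of two embedding vectors
#'
#' @param a,b numeric vectors of equal dimension; both must be nonzero.
#' @return `a . b / (||a|| ||b||)` in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("dimension mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

# cosine of q against rows of E; zero rows get similarity 0 with a warning
cosine_scores <- function(q_emb, E) {
  en <- sqrt(rowSums(E^2))
  qn <- sqrt(sum(q_emb^2))
  if (qn == 0) stop("cosine similarity undefined: zero query embedding")
  sims <- as.numeric(E %*% q_emb) / (qn * pmax(en, .Machine$double.eps))
  if (any(en == 0)) {
    warning(sum(en == 0), " zero candidate embedding(s); similarity set to 0")
    sims[en == 0] <- 0
  }
  sims
}

#' Predicted ranking of candidates by embedding similarity
#'
#' Orders candidate ids by descending cosine similarity to the query
#' embedding, ties broken by ascending id — the same deterministic rule the
#' ground-truth ranking uses.
#'
#' @param q_emb query embedding vector.
#' @param candidate_embs matrix of candidate embeddings (ids as rownames).
#' @return Character vector of candidate ids, best first.
#' @export
predict_ranking <- function(q_emb, candidate_embs) {
  stopifnot(!is.null(rownames(candidate_embs)))
  sims <- cosine_scores(q_emb, candidate_embs)
  rownames(candidate_embs)[order(-sims, rownames(candidate_embs))]
}

#' Pair a true and a predicted ranking for scoring
#'
#' Relevance of an item is its reversed true rank, `n - i + 1`, so the top
#' true neighbor carries relevance `n`.
#'
#' @param true_order ids by descending ground-truth similarity.
#' @param predicted_order permutation of the same ids by predicted
#'   similarity.
#' @return List of class `ranking_comparison`: `true_order`,
#'   `predicted_order`, `n`, `rel` (relevance at each *predicted* position),
#'   `true_pos` (true rank of each predicted item).
#' @export
ranking_comparison <- function(true_order, predicted_order) {
  n <- length(true_order)
  if (n == 0) stop("empty ranking")
  if (!setequal(true_order, predicted_order) ||
      length(predicted_order) != n) {
    stop("true and predicted orders must be permutations of the same ids")
  }
  true_pos <- match(predicted_order, true_order)
  structure(list(true_order = true_order, predicted_order = predicted_order,
                 n = n, rel = n - true_pos + 1, true_pos = true_pos),
            class = "ranking_comparison")
}

#' Discounted cumulative gain of a predicted ranking
#'
#' `DCG = sum_i rel_i / log(i + 1)` over predicted positions, with
#' relevance the reversed true rank. Log base 2 by default.
#'
#' @param comparison a [ranking_comparison].
#' @param log_base logarithm base of the positional discount.
#' @return Scalar DCG.
#' @export
dcg <- function(comparison, log_base = 2) {
  stopifnot(inherits(comparison, "ranking_comparison"))
  i <- seq_len(comparison$n)
  sum(comparison$rel / log(i + 1, base = log_base))
}

#' Normalized discounted cumulative gain
#'
#' DCG of the predicted order divided by the DCG of the ideal (true) order;
#' 1 exactly when the predicted ranking matches the true one.
#'
#' @inheritParams dcg
#' @return Scalar in `(0, 1]`.
#' @export
ndcg <- function(comparison, log_base = 2) {
  stopifnot(inherits(comparison, "ranking_comparison"))
  i <- seq_len(comparison$n)
  ideal <- sum((comparison$n - i + 1) / log(i + 1, base = log_base))
  dcg(comparison, log_base) / ideal
}

#' Positional rank score at position p
#'
#' `score_p = mean_i exp(-|p - truep_i|)` over dataset entries, where
#' `truep_i` is the true rank of the item predicted at position `p` for
#' entry `i`. Equals 1 only when every entry's position-p prediction is
#' exactly right; an exponential penalty on rank displacement.
#'
#' @param comparisons list of [ranking_comparison]s.
#' @param p 1-based rank position to score.
#' @return Scalar in `(0, 1]`.
#' @export
positional_rank_score <- function(comparisons, p) {
  stopifnot(length(comparisons) >= 1)
  devs <- vapply(comparisons, function(cmp) {
    stopifnot(inherits(cmp, "ranking_comparison"), p <= cmp$n)
    abs(p - cmp$true_pos[p])
  }, numeric(1))
  mean(exp(-devs))
}

#' Score an embedding matrix against ground-truth rankings
#'
#' For each anchor, ranks all other embedded sequences by cosine similarity
#' and compares with the alignment-derived true ranking.
#'
#' @param embeddings numeric matrix, one row per sequence, ids as rownames.
#' @param ranked a `ranked_records` ground-truth dataset.
#' @param anchors anchor ids to evaluate (default: all).
#' @param positions positions for the positional rank score.
#' @return List: `per_anchor` (data.frame of anchor, ndcg), `mean_ndcg`,
#'   `sd_ndcg`, `positional` (named vector over `positions`), `comparisons`.
#' @export
rank_scores <- function(embeddings, ranked, anchors = names(ranked),
                        positions = 1:3) {
  stopifnot(inherits(ranked, "ranked_records"),
            all(anchors %in% names(ranked)),
            all(anchors %in% rownames(embeddings)))
  comparisons <- lapply(anchors, function(a) {
    rec <- ranked[[a]]
    cand <- embeddings[rec$neighbor_id, , drop = FALSE]
    pred <- predict_ranking(embeddings[a, ], cand)
    ranking_comparison(rec$neighbor_id, pred)
  })
  names(comparisons) <- anchors
  nd <- vapply(comparisons, ndcg, numeric(1))
  pos <- vapply(positions, function(p)
    positional_rank_score(comparisons, p), numeric(1))
  names(pos) <- paste0("p", positions)
  list(per_anchor = data.frame(anchor = anchors, ndcg = unname(nd),
                               stringsAsFactors = FALSE),
       mean_ndcg = mean(nd), sd_ndcg = stats::sd(nd),
       positional = pos, comparisons = comparisons)
}

#' NDCG of uniformly shuffled rankings (noise floor)
#'
#' Replaces every predicted ranking by a uniform random permutation and
#' averages NDCG over anchors — the no-information baseline a weak embedder
#' should approach.
#'
#' @param ranked a `ranked_records` dataset.
#' @param anchors anchor ids (default all).
#' @param n_shuffles random permutations averaged per anchor.
#' @param seed RNG seed.
#' @return Mean NDCG of shuffled rankings.
#' @export
shuffled_ndcg <- function(ranked, anchors = names(ranked), n_shuffles = 5L,
                          seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vals <- vapply(anchors, function(a) {
    rec <- ranked[[a]]
    mean(vapply(seq_len(n_shuffles), function(k) {
      ndcg(ranking_comparison(rec$neighbor_id, sample(rec$neighbor_id)))
    }, numeric(1)))
  }, numeric(1))
  mean(vals)
}

#' Exact cosine retrieval index
#'
#' A small in-memory index over an embedding matrix; queries return the
#' top-k ids by cosine similarity with the same deterministic tie rule as
#' [predict_ranking()].
#'
#' @param embeddings numeric matrix with ids as rownames.
#' @return List of class `cosine_index`.
#' @export
index_build <- function(embeddings) {
  stopifnot(is.matrix(embeddings), nrow(embeddings) >= 1,
            !is.null(rownames(embeddings)))
  structure(list(embeddings = embeddings), class = "cosine_index")
}

#' Query a cosine index
#'
#' @param index a [index_build()] result.
#' @param q_emb query embedding.
#' @param top_k number of hits; truncated to the index size with a warning.
#' @return `data.frame` with columns `id`, `score`, best first.
#' @export
index_query <- function(index, q_emb, top_k = 10L) {
  stopifnot(inherits(index, "cosine_index"))
  E <- index$embeddings
  if (top_k > nrow(E)) {
    warning("top_k exceeds index size; returning all ", nrow(E), " entries")
    top_k <- nrow(E)
  }
  sims <- cosine_scores(q_emb, E)
  ord <- order(-sims, rownames(E))[seq_len(top_k)]
  data.frame(id = rownames(E)[ord], score = unname(sims[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Persist / load a cosine index as TSV
#'
#' @param index a `cosine_index`.
#' @param path file path.
#' @return `write_index` returns `path` invisibly; `read_index` the index.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "cosine_index"))
  df <- data.frame(id = rownames(index$embeddings), index$embeddings,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  E <- as.matrix(df[, -1, drop = FALSE])
  rownames(E) <- df$id
  index_build(E)
}
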