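#' Triplet training configuration
#'
#' The recorded reference configuration follows the published architecture
#' settings (learning rate 6e-7, dropout 0.2); the benchmark preset used in
#' this package's scaled-down experiments raises the learning rate, which is
#' reported loudly when it happens.
#'
#' @param margin non-negative hinge margin `alpha`.
#' @param cap per-anchor cap on sampled triplets (full enumeration is
#'   O(n^2) per anchor); `NULL` for all.
#' @param epochs epoch cap.
#' @param learning_rate optimizer step size.
#' @param dropout dropout probability of the hidden dense layer.
#' @param patience early-stopping patience (epochs of rising validation
#'   loss tolerated).
#' @return List of class `triplet_config`.
#' @export
triplet_config <- function(margin = 0.2, cap = 64L, epochs = 10L,
                           learning_rate = 6e-7, dropout = 0.2,
                           patience = 5L) {
  stopifnot(margin >= 0, epochs >= 1, learning_rate >= 0)
  structure(list(margin = margin, cap = cap, epochs = as.integer(epochs),
                 learning_rate = learning_rate, dropout = dropout,
                 patience = as.integer(patience)),
            class = "triplet_config")
}

#' Ladder training configuration
#'
#' `M` similarity tiers per anchor, with per-tier margins `alphas` and
#' weights `betas` (all tunable; defaults `alpha_i = 0.1 * i`, `beta_i = 1`).
#'
#' @param M number of tiers (>= 2).
#' @param alphas non-negative, non-decreasing margins, length `M`.
#' @param betas non-negative tier weights, length `M`.
#' @inheritParams triplet_config
#' @return List of class `ladder_config`.
#' @export
ladder_config <- function(M = 4L, alphas = 0.1 * seq_len(M),
                          betas = rep(1, M), epochs = 10L,
                          learning_rate = 6e-7, dropout = 0.2,
                          patience = 5L) {
  stopifnot(M >= 2, length(alphas) == M, length(betas) == M,
            all(alphas >= 0), all(betas >= 0), epochs >= 1,
            learning_rate >= 0)
  if (any(diff(alphas) < 0)) stop("alphas must be non-decreasing")
  structure(list(M = as.integer(M), alphas = alphas, betas = betas,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 dropout = dropout, patience = as.integer(patience)),
            class = "ladder_config")
}

#' Enumerate (or sample) training triplets for one anchor
#'
#' Every ordered pair of candidates `(i, j)` with a strictly higher
#' ground-truth score for `i` yields the triplet `(q, a_i, a_j)`; tied pairs
#' are never triplets. With `cap` set, a seeded uniform subsample is drawn.
#'
#' @param record a `ranked_record`.
#' @param cap optional maximum number of triplets.
#' @param seed optional seed for the subsample.
#' @return `data.frame` with columns `anchor`, `pos`, `neg` (sequence ids).
#' @export
make_triplets <- function(record, cap = NULL, seed = NULL) {
  stopifnot(inherits(record, "ranked_record"), record$n >= 2)
  s <- record$score
  pair <- which(outer(s, s, ">"), arr.ind = TRUE)  # s[row] > s[col]
  out <- data.frame(anchor = rep(record$anchor_id, nrow(pair)),
                    pos = record$neighbor_id[pair[, 1]],
                    neg = record$neighbor_id[pair[, 2]],
                    stringsAsFactors = FALSE)
  if (!is.null(cap) && nrow(out) > cap) {
    if (!is.null(seed)) set.seed(seed)
    out <- out[sample.int(nrow(out), cap), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Triplet loss over a batch of embeddings
#'
#' `sum_i [ ||f(x_i) - f(x_i^+)||^2 - ||f(x_i) - f(x_i^-)||^2 + alpha ]_+`
#' — the squared Euclidean hinge pulling positives within `alpha` closer
#' than negatives. Accepts single vectors or row-matched matrices.
#'
#' @param anchor,positive,negative embedding vectors, or matrices with one
#'   triplet per row.
#' @param margin non-negative margin `alpha`.
#' @return Non-negative scalar loss (sum over the batch).
#' @export
triplet_loss <- function(anchor, positive, negative, margin = 0.2) {
  if (is.null(dim(anchor))) anchor <- matrix(anchor, nrow = 1)
  if (is.null(dim(positive))) positive <- matrix(positive, nrow = 1)
  if (is.null(dim(negative))) negative <- matrix(negative, nrow = 1)
  if (!all(dim(anchor) == dim(positive)) ||
      !all(dim(anchor) == dim(negative))) {
    stop("embedding dimension mismatch across the triplet")
  }
  d_pos <- rowSums((anchor - positive)^2)
  d_neg <- rowSums((anchor - negative)^2)
  sum(pmax(d_pos - d_neg + margin, 0))
}

#' Partition a ranked neighbor list into M similarity tiers
#'
#' Contiguous slices of the descending-ranked list into `M` near-equal
#' groups (remainder spread over the leading groups), with boundaries
#' shifted forward so that tied scores never straddle a tier boundary:
#' every member of tier `i` has score >= every member of tier `j > i`.
#'
#' @param record a `ranked_record` with `n >= M` neighbors.
#' @param M number of tiers.
#' @return List of class `ladder_groups`: `anchor_id`, `groups` (list of id
#'   vectors, possibly empty after tie shifting), `M`.
#' @export
make_ladder_groups <- function(record, M) {
  stopifnot(inherits(record, "ranked_record"))
  n <- record$n
  if (n < M) stop("need at least M = ", M, " neighbors, have ", n)
  base <- n %/% M
  sizes <- rep(base, M)
  rem <- n - base * M
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- cumsum(sizes)
  s <- record$score
  for (i in seq_len(M - 1L)) {
    e <- max(ends[i], if (i > 1) ends[i - 1] else 0L)
    while (e > 0 && e < n && s[e] == s[e + 1]) e <- e + 1L
    ends[i] <- e
  }
  ends[M] <- n
  starts <- c(1L, head(ends, -1L) + 1L)
  groups <- lapply(seq_len(M), function(i) {
    if (starts[i] > ends[i]) character(0)
    else record$neighbor_id[starts[i]:ends[i]]
  })
  structure(list(anchor_id = record$anchor_id, groups = groups,
                 M = as.integer(M)),
            class = "ladder_groups")
}

cosine_to_anchor <- function(q_emb, E) {
  qn <- sqrt(sum(q_emb^2))
  en <- sqrt(rowSums(E^2))
  if (qn == 0 || any(en == 0)) stop("cosine undefined for zero embeddings")
  as.numeric(E %*% q_emb) / (qn * en)
}

#' Ladder loss of one tier
#'
#' For tier `i >= 2`: `sum_{x+ in N_{i-1}} sum_{x- in N_{i..M}}
#' [alpha_i - s(q, x+) + s(q, x-)]_+` where `s` is embedding-space cosine
#' similarity. For `i = 1` the only positive is the anchor itself, with
#' `s(q, q) = 1` substituted, and the sum runs over all negatives in
#' `N_{1..M}`. Empty tiers contribute 0.
#'
#' @param q_emb anchor embedding vector.
#' @param group_embeddings list of `M` matrices (tier members as rows; may
#'   have zero rows).
#' @param i tier index in `1..M`.
#' @param alpha_i margin for this tier.
#' @return Non-negative scalar loss.
#' @export
ladder_group_loss <- function(q_emb, group_embeddings, i, alpha_i) {
  M <- length(group_embeddings)
  stopifnot(i >= 1, i <= M, alpha_i >= 0)
  sims <- lapply(group_embeddings, function(E) {
    if (is.null(E) || NROW(E) == 0) numeric(0) else cosine_to_anchor(q_emb, E)
  })
  if (i == 1L) {
    s_neg <- unlist(sims[1:M])
    return(sum(pmax(alpha_i - 1 + s_neg, 0)))
  }
  s_pos <- sims[[i - 1L]]
  s_neg <- unlist(sims[i:M])
  if (length(s_pos) == 0 || length(s_neg) == 0) return(0)
  sum(pmax(outer(-s_pos, s_neg, "+") + alpha_i, 0))
}

#' Full ladder loss for one anchor
#'
#' Weighted sum of the per-tier losses:
#' `L(q) = sum_{i=1}^{M} beta_i * L_i(q)`.
#'
#' @inheritParams ladder_group_loss
#' @param config a [ladder_config] supplying `alphas` and `betas`.
#' @return Non-negative scalar loss.
#' @export
ladder_loss <- function(q_emb, group_embeddings, config) {
  stopifnot(inherits(config, "ladder_config"),
            length(group_embeddings) == config$M)
  sum(vapply(seq_len(config$M), function(i) {
    config$betas[i] *
      ladder_group_loss(q_emb, group_embeddings, i, config$alphas[i])
  }, numeric(1)))
}
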