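#' Run the scaled embedding benchmark
#'
#' End-to-end study on synthetic graded families: generate the dataset,
#' compute the full Needleman-Wunsch ground truth, split anchors 80/20,
#' build CGR images, embed with the requested methods, and score every
#' method by mean NDCG (over all anchors and over held-out test anchors
#' separately) plus positional rank scores at positions 1-3.
#'
#' Neural embedders are trained on training anchors only with the
#' desk-scale preset (small network, Adam, raised learning rate — messaged
#' as a deviation from the recorded reference configuration). `"shuffled"`
#' adds the random-permutation noise floor as a pseudo-method.
#'
#' @param seeds integer vector; the whole pipeline is repeated per seed
#'   (dataset, split, weights, sampling).
#' @param spec a [family_spec()] describing the synthetic data conditions;
#'   its `seed` field is replaced by each run seed.
#' @param resolution CGR image resolution.
#' @param methods methods to run; any of `"fcgr"`, `"pca"`, `"ahash"`,
#'   `"phash"`, `"whash"`, `"cnn_ladder"`, `"cnn_triplet"`, `"fcn_ladder"`,
#'   `"fcn_triplet"`, `"shuffled"`.
#' @param pca_dims PCA target dimensions to sweep.
#' @param hash_dims hash dimensions (perfect squares) to sweep.
#' @param neural_dim embedding dimension of the neural models.
#' @param epochs epoch cap for neural training.
#' @param learning_rate Adam step size for neural training.
#' @param filters,hidden network size of the desk-scale preset.
#' @param candidates_per_anchor per-step candidate sample size.
#' @param verbose print progress.
#' @return `data.frame` with one row per (method, dim, seed): columns
#'   `method`, `dim`, `seed`, `ndcg_full`, `ndcg_test`, `sd_ndcg_full`,
#'   `p1`, `p2`, `p3` (positional scores over all anchors) and
#'   `sec_per_item`.
#' @export
run_benchmark <- function(seeds = 1:3, spec = family_spec(),
                          resolution = 16L,
                          methods = c("fcgr", "pca", "ahash", "phash",
                                      "whash", "cnn_ladder", "cnn_triplet",
                                      "shuffled"),
                          pca_dims = c(16L, 256L), hash_dims = 16L,
                          neural_dim = 64L, epochs = 10L,
                          learning_rate = 2e-3, filters = 8L, hidden = 64L,
                          candidates_per_anchor = 24L, verbose = FALSE) {
  known <- c("fcgr", "pca", "ahash", "phash", "whash", "cnn_ladder",
             "cnn_triplet", "fcn_ladder", "fcn_triplet", "shuffled")
  stopifnot(all(methods %in% known))
  rows <- list()
  say <- function(...) if (verbose) message(...)
  for (seed in seeds) {
    spec$seed <- as.integer(seed)
    say("seed ", seed, ": generating data and ground truth")
    records <- generate_dataset(spec)
    ranked <- build_ranked_dataset(records)
    split <- split_anchors(ranked, 0.8, seed = seed)
    images <- cgr_images(records, resolution, normalize = TRUE)

    score_method <- function(method, dim, E, sec) {
      full <- rank_scores(E, ranked)
      test <- rank_scores(E, ranked, anchors = split$test, positions = 1)
      rows[[length(rows) + 1L]] <<- data.frame(
        method = method, dim = dim, seed = seed,
        ndcg_full = full$mean_ndcg, ndcg_test = test$mean_ndcg,
        sd_ndcg_full = full$sd_ndcg,
        p1 = full$positional[["p1"]], p2 = full$positional[["p2"]],
        p3 = full$positional[["p3"]], sec_per_item = sec,
        stringsAsFactors = FALSE)
    }

    if ("fcgr" %in% methods) {
      E <- embed_dataset(images, "fcgr")
      score_method("fcgr", resolution^2, E, attr(E, "sec_per_item"))
    }
    if ("pca" %in% methods) {
      for (dd in pca_dims) {
        model <- withCallingHandlers(
          pca_fit(images[, , split$train, drop = FALSE], dd),
          warning = function(w) invokeRestart("muffleWarning"))
        E <- embed_dataset(images, "pca", pca_model = model)
        score_method("pca", dd, E, attr(E, "sec_per_item"))
      }
    }
    for (h in intersect(methods, c("ahash", "phash", "whash"))) {
      for (dd in hash_dims) {
        E <- embed_dataset(images, h, d = dd)
        score_method(h, dd, E, attr(E, "sec_per_item"))
      }
    }
    for (nm in intersect(methods, c("cnn_ladder", "cnn_triplet",
                                    "fcn_ladder", "fcn_triplet"))) {
      arch <- sub("_.*", "", nm)
      lss <- sub(".*_", "", nm)
      say("seed ", seed, ": training ", nm)
      fit <- neural_embedder(ranked, images, loss = lss,
                             architecture = arch, d = neural_dim,
                             anchors = split$train, epochs = epochs,
                             learning_rate = learning_rate,
                             filters = filters, hidden = hidden,
                             candidates_per_anchor = candidates_per_anchor,
                             seed = seed)
      E <- predict(fit, images)
      score_method(nm, neural_dim, E, attr(E, "sec_per_item"))
    }
    if ("shuffled" %in% methods) {
      base_full <- shuffled_ndcg(ranked, seed = seed)
      base_test <- shuffled_ndcg(ranked, anchors = split$test, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "shuffled", dim = NA_integer_, seed = seed,
        ndcg_full = base_full, ndcg_test = base_test,
        sd_ndcg_full = NA_real_, p1 = NA_real_, p2 = NA_real_,
        p3 = NA_real_, sec_per_item = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
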