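# row-major flattening: image row 1 first, matching the documented
# fcgr_embed contract ([[1,2],[3,4]] -> 1,2,3,4)
flatten_image <- function(img) as.vector(t(img))

# area-mean block pooling from resolution R down to s (R divisible by s)
block_mean <- function(img, s) {
  R <- nrow(img)
  if (R %% s != 0) stop("image side ", R, " not divisible by target ", s)
  f <- R %/% s
  A <- matrix(0, s, R)
  A[cbind(rep(seq_len(s), each = f), seq_len(R))] <- 1 / f
  A %*% img %*% t(A)
}

hash_side <- function(d) {
  s <- as.integer(round(sqrt(d)))
  if (s * s != d) stop("hash dimension d must be a perfect square, got ", d)
  s
}

#' Flattened-CGR baseline embedding
#'
#' Row-major flattening of the pixel grid: the information-free baseline
#' embedder (`d = resolution^2`, invertible back to the image).
#'
#' @param image a `cgr_image` matrix (or any numeric matrix).
#' @return Numeric vector of length `length(image)`. An all-zero image
#'   yields a zero vector with a warning (its cosine similarity is
#'   undefined).
#' @export
fcgr_embed <- function(image) {
  v <- flatten_image(unclass(image))
  if (all(v == 0)) warning("all-zero image: zero embedding (degenerate)")
  v
}

#' Average-hash embedding
#'
#' The image is downscaled to a `sqrt(d) x sqrt(d)` grid by area-mean block
#' pooling; each cell becomes +1 if it exceeds the mean of all cells and -1
#' otherwise (ties are -1). Emitting signs rather than 0/1 bits keeps
#' cosine similarity centred: `cos = 1 - 2 * hamming / d`.
#'
#' @param image square numeric matrix (side a power of two).
#' @param d embedding dimension; a perfect square dividing the image grid.
#' @return `+1/-1` vector of length `d` (row-major).
#' @export
ahash_embed <- function(image, d) {
  s <- hash_side(d)
  sm <- block_mean(unclass(image), s)
  ifelse(flatten_image(sm) > mean(sm), 1, -1)
}

# orthonormal type-II DCT matrix of size n
dct_matrix <- function(n) {
  C <- outer(0:(n - 1), 0:(n - 1), function(u, x)
    cos(pi * (2 * x + 1) * u / (2 * n)))
  C * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
}

#' Perceptual-hash embedding
#'
#' The image is area-mean downscaled to a working grid (4x the hash side,
#' capped at the image size), transformed with the 2D orthonormal type-II
#' DCT, and the top-left `sqrt(d) x sqrt(d)` low-frequency block retained.
#' Bits are +1 where a coefficient exceeds the median of the retained block
#' computed without the DC term; the DC position itself always reads -1,
#' since it carries only overall intensity. Near-zero coefficients (relative
#' magnitude below 1e-10) are treated as exact zeros so that a constant
#' image yields the all-ties hash. The hash is invariant to uniform
#' brightness scaling.
#'
#' @inheritParams ahash_embed
#' @return `+1/-1` vector of length `d` (row-major).
#' @export
phash_embed <- function(image, d) {
  s <- hash_side(d)
  img <- unclass(image)
  work <- min(nrow(img), 4L * s)
  if (work < s) stop("image too small for hash side ", s)
  sm <- block_mean(img, work)
  C <- dct_matrix(work)
  D <- C %*% sm %*% t(C)
  v <- flatten_image(D[seq_len(s), seq_len(s), drop = FALSE])
  v[abs(v) < 1e-10 * max(abs(v))] <- 0       # zap numerical DCT noise
  med <- stats::median(v[-1])                # exclude DC term
  bits <- ifelse(v > med, 1, -1)
  bits[1] <- -1                              # DC = intensity only
  bits
}

# orthonormal Haar approximation band after `levels` decompositions
haar_approx <- function(img, levels) {
  for (l in seq_len(levels)) {
    n <- nrow(img)
    odd <- seq(1, n, by = 2); even <- odd + 1
    img <- (img[odd, , drop = FALSE] + img[even, , drop = FALSE]) / sqrt(2)
    img <- (img[, odd, drop = FALSE] + img[, even, drop = FALSE]) / sqrt(2)
  }
  img
}

#' Wavelet-hash embedding
#'
#' Multi-level orthonormal Haar decomposition down to a
#' `sqrt(d) x sqrt(d)` approximation band, thresholded at the band median.
#'
#' @inheritParams ahash_embed
#' @return `+1/-1` vector of length `d` (row-major).
#' @export
whash_embed <- function(image, d) {
  s <- hash_side(d)
  img <- unclass(image)
  R <- nrow(img)
  if (R < s) stop("image too small for hash side ", s)
  levels <- as.integer(round(log2(R / s)))
  if (s * 2^levels != R) stop("hash side must relate to image side by a power of two")
  approx <- haar_approx(img, levels)
  med <- stats::median(approx)
  ifelse(flatten_image(approx) > med, 1, -1)
}

#' Fit a PCA embedder on training images
#'
#' Mean-centred projection onto the leading `d` principal axes of the
#' flattened images, with a deterministic sign convention: each component's
#' largest-magnitude loading is made positive. When `d` exceeds the rank of
#' the (centred) training data, the surplus axes carry no variance; their
#' scores are zero and a warning is emitted — rankings are unaffected
#' beyond the rank.
#'
#' @param images 3D array `(R, R, n)` as from [cgr_images()], or an
#'   `n x p` matrix of flattened images with ids as rownames.
#' @param d target dimension, at most the number of pixels.
#' @return List of class `pca_model`: `center`, `rotation` (`p x d`), `d`,
#'   `sdev`.
#' @export
pca_fit <- function(images, d) {
  X <- images_as_matrix(images)
  p <- ncol(X)
  if (d > p) stop("d (", d, ") exceeds the number of pixels (", p, ")")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  avail <- ncol(fit$rotation)
  rot <- fit$rotation[, seq_len(min(d, avail)), drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(rot))) {
    m <- which.max(abs(rot[, j]))
    if (rot[m, j] < 0) rot[, j] <- -rot[, j]
  }
  sdev <- fit$sdev[seq_len(min(d, avail))]
  if (d > avail) {
    warning("requested d = ", d, " exceeds data rank (", avail,
            "); surplus components have zero variance")
    rot <- cbind(rot, matrix(0, p, d - avail))
    sdev <- c(sdev, rep(0, d - avail))
  }
  structure(list(center = fit$center, rotation = rot, d = d, sdev = sdev),
            class = "pca_model")
}

#' Embed an image with a fitted PCA model
#'
#' @param model a [pca_fit()] result.
#' @param image a `cgr_image` (same resolution as the training images).
#' @return Numeric vector of length `model$d`.
#' @export
pca_embed <- function(model, image) {
  stopifnot(inherits(model, "pca_model"))
  v <- flatten_image(unclass(image))
  if (length(v) != length(model$center)) stop("image resolution mismatch")
  as.numeric((v - model$center) %*% model$rotation)
}

# images: 3D array (R, R, n) or n x p matrix -> n x p matrix (row-major rows)
images_as_matrix <- function(images) {
  if (is.matrix(images)) return(images)
  stopifnot(length(dim(images)) == 3)
  n <- dim(images)[3]
  X <- t(apply(images, 3, function(m) flatten_image(m)))
  rownames(X) <- dimnames(images)[[3]]
  X
}

#' Embed a whole image set with one method
#'
#' Dispatcher over the classical embedders; neural embedders are applied
#' through [predict.neural_embedder()].
#'
#' @param images 3D array `(R, R, n)` with ids as third dimnames.
#' @param method one of `"fcgr"`, `"pca"`, `"ahash"`, `"phash"`, `"whash"`.
#' @param d embedding dimension (ignored for `"fcgr"`, which uses all
#'   pixels).
#' @param pca_model a fitted [pca_fit()] model (required for `"pca"`).
#' @return `n x d` matrix with ids as rownames and per-sequence embedding
#'   time (seconds) in attribute `"sec_per_item"`.
#' @export
embed_dataset <- function(images, method = c("fcgr", "pca", "ahash",
                                             "phash", "whash"),
                          d = NULL, pca_model = NULL) {
  method <- match.arg(method)
  stopifnot(length(dim(images)) == 3)
  n <- dim(images)[3]
  f <- switch(method,
    fcgr = function(img) fcgr_embed(img),
    pca = {
      if (is.null(pca_model)) stop("pca requires a fitted pca_model")
      function(img) pca_embed(pca_model, img)
    },
    ahash = function(img) ahash_embed(img, d),
    phash = function(img) phash_embed(img, d),
    whash = function(img) whash_embed(img, d))
  t0 <- proc.time()[["elapsed"]]
  rows <- lapply(seq_len(n), function(i) f(images[, , i]))
  elapsed <- proc.time()[["elapsed"]] - t0
  E <- do.call(rbind, rows)
  rownames(E) <- dimnames(images)[[3]]
  attr(E, "sec_per_item") <- elapsed / n
  E
}
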