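#' Construct a Siamese branch network
#'
#' Builds the (single, weight-shared) embedding branch of the Siamese
#' model. Two architectures are supported:
#' \describe{
#'   \item{cnn}{convolution (`filters` kernels of size `kernel`, ReLU) ->
#'     2x2 max-pool with stride 1, padding 0 -> flatten -> dense `hidden`
#'     ReLU with dropout -> dense `d` with tanh output.}
#'   \item{fcn}{flatten -> dense `hidden` ReLU with dropout -> dense `d`
#'     with ReLU output.}
#' }
#' The reference configuration records the published layout (kernel 5,
#' 512 dense neurons, dropout 0.2, tanh/ReLU outputs, 1024 convolution
#' filters); the default `filters = 32` is the desk-scale setting.
#' Initialization is Glorot-uniform and fully seeded.
#'
#' @param architecture `"cnn"` or `"fcn"`.
#' @param resolution input image side length.
#' @param d embedding dimension.
#' @param filters convolution filter count (cnn only).
#' @param kernel convolution kernel size (cnn only).
#' @param hidden dense hidden width.
#' @param dropout dropout probability on the hidden layer (training only).
#' @param seed integer seed for the initial weights.
#' @return List of class `embedder_net`.
#' @export
build_network <- function(architecture = c("cnn", "fcn"), resolution, d,
                          filters = 32L, kernel = 5L, hidden = 512L,
                          dropout = 0.2, seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(resolution >= kernel + 1, d >= 1, hidden >= 1,
            dropout >= 0, dropout < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  R <- as.integer(resolution)
  net <- list(arch = architecture, resolution = R, d = as.integer(d),
              hidden = as.integer(hidden), dropout = dropout, seed = seed)
  if (architecture == "cnn") {
    s <- R - kernel + 1L          # conv output side
    t_side <- s - 1L              # after 2x2 stride-1 max-pool
    k2 <- kernel^2
    # patch index matrix: rows = conv positions (column-major), cols = patch
    pos <- expand.grid(i = seq_len(s), j = seq_len(s))
    off <- expand.grid(di = 0:(kernel - 1L), dj = 0:(kernel - 1L))
    idx <- matrix(0L, s * s, k2)
    for (q in seq_len(k2)) {
      idx[, q] <- (pos$i + off$di[q]) + (pos$j + off$dj[q] - 1L) * R
    }
    feat <- t_side^2 * filters
    net <- c(net, list(kernel = as.integer(kernel),
                       filters = as.integer(filters),
                       conv_side = s, pool_side = t_side, idx = idx,
                       params = list(Wc = glorot(k2, filters),
                                     bc = numeric(filters),
                                     W1 = glorot(feat, hidden),
                                     b1 = numeric(hidden),
                                     W2 = glorot(hidden, d),
                                     b2 = numeric(d))))
  } else {
    net <- c(net, list(params = list(W1 = glorot(R^2, hidden),
                                     b1 = numeric(hidden),
                                     W2 = glorot(hidden, d),
                                     b2 = numeric(d))))
  }
  class(net) <- "embedder_net"
  net
}

#' Number of learned parameters of a network
#'
#' @param net an `embedder_net`.
#' @return Integer parameter count.
#' @export
n_params <- function(net) {
  stopifnot(inherits(net, "embedder_net"))
  sum(vapply(net$params, length, integer(1)))
}

as_image_batch <- function(images, R) {
  if (is.matrix(images) && nrow(images) == R && ncol(images) == R) {
    images <- array(images, c(R, R, 1))
  }
  stopifnot(length(dim(images)) == 3, dim(images)[1] == R,
            dim(images)[2] == R)
  images
}

# forward pass; train = TRUE applies (seeded by caller's RNG) dropout and
# keeps the caches needed by net_backward
net_forward <- function(net, images, train = FALSE) {
  R <- net$resolution
  images <- as_image_batch(images, R)
  B <- dim(images)[3]
  pr <- net$params
  cache <- list(B = B)
  if (net$arch == "cnn") {
    s <- net$conv_side; t_side <- net$pool_side
    nf <- net$filters; k2 <- net$kernel^2
    IM <- matrix(images, R * R, B)
    patch <- IM[as.vector(net$idx), , drop = FALSE]
    P <- matrix(aperm(array(patch, c(s * s, k2, B)), c(1, 3, 2)),
                s * s * B, k2)
    Z <- P %*% pr$Wc
    Z <- Z + rep(pr$bc, each = nrow(Z))
    A1 <- pmax(Z, 0)
    A <- array(A1, c(s, s, B, nf))
    p11 <- A[seq_len(t_side), seq_len(t_side), , , drop = FALSE]
    p21 <- A[2:s, seq_len(t_side), , , drop = FALSE]
    p12 <- A[seq_len(t_side), 2:s, , , drop = FALSE]
    p22 <- A[2:s, 2:s, , , drop = FALSE]
    PL <- pmax(p11, p21, p12, p22)
    X1 <- t(matrix(aperm(PL, c(1, 2, 4, 3)), t_side^2 * nf, B))
    if (train) {
      cache$P <- P; cache$A <- A
      cache$m11 <- p11 == PL
      cache$m21 <- (p21 == PL) & !cache$m11
      cache$m12 <- (p12 == PL) & !(cache$m11 | cache$m21)
      cache$m22 <- !(cache$m11 | cache$m21 | cache$m12)
    }
  } else {
    X1 <- t(matrix(images, R * R, B))
  }
  H <- X1 %*% pr$W1
  H <- H + rep(pr$b1, each = B)
  Ha <- pmax(H, 0)
  if (train && net$dropout > 0) {
    keep <- 1 - net$dropout
    Mk <- matrix(stats::rbinom(length(Ha), 1L, keep), nrow(Ha)) / keep
    Hd <- Ha * Mk
    cache$Mk <- Mk
  } else {
    Hd <- Ha
  }
  Z2 <- Hd %*% pr$W2
  Z2 <- Z2 + rep(pr$b2, each = B)
  out <- if (net$arch == "cnn") tanh(Z2) else pmax(Z2, 0)
  if (train) {
    cache$X1 <- X1; cache$H <- H; cache$Hd <- Hd
    cache$Z2 <- Z2; cache$out <- out
  }
  list(out = out, cache = cache)
}

# gradients of all parameters given d(loss)/d(out); uses forward caches
net_backward <- function(net, cache, dout) {
  pr <- net$params
  B <- cache$B
  dZ2 <- if (net$arch == "cnn") dout * (1 - cache$out^2) else
    dout * (cache$Z2 > 0)
  grads <- list(W2 = crossprod(cache$Hd, dZ2), b2 = colSums(dZ2))
  dHd <- tcrossprod(dZ2, pr$W2)
  dHa <- if (!is.null(cache$Mk)) dHd * cache$Mk else dHd
  dH <- dHa * (cache$H > 0)
  grads$W1 <- crossprod(cache$X1, dH)
  grads$b1 <- colSums(dH)
  if (net$arch == "cnn") {
    s <- net$conv_side; t_side <- net$pool_side; nf <- net$filters
    dX1 <- tcrossprod(dH, pr$W1)
    dPL <- aperm(array(t(dX1), c(t_side, t_side, nf, B)), c(1, 2, 4, 3))
    dA <- array(0, c(s, s, B, nf))
    i1 <- seq_len(t_side); i2 <- 2:s
    dA[i1, i1, , ] <- dA[i1, i1, , ] + dPL * cache$m11
    dA[i2, i1, , ] <- dA[i2, i1, , ] + dPL * cache$m21
    dA[i1, i2, , ] <- dA[i1, i2, , ] + dPL * cache$m12
    dA[i2, i2, , ] <- dA[i2, i2, , ] + dPL * cache$m22
    dZ <- matrix(dA, s * s * B, nf) * (matrix(cache$A, s * s * B, nf) > 0)
    grads$Wc <- crossprod(cache$P, dZ)
    grads$bc <- colSums(dZ)
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}

#' Embed images with a (trained or untrained) network
#'
#' Deterministic forward pass with dropout disabled, batched; the mean
#' per-sequence wall-clock time is attached for the timing benchmark.
#'
#' @param net an `embedder_net`.
#' @param images 3D array `(R, R, n)` (ids as third dimnames) or a single
#'   image matrix.
#' @param batch_size forward-pass batch size.
#' @return `n x d` matrix of embeddings with ids as rownames and attribute
#'   `"sec_per_item"`.
#' @export
embed_images <- function(net, images, batch_size = 256L) {
  stopifnot(inherits(net, "embedder_net"))
  images <- as_image_batch(images, net$resolution)
  n <- dim(images)[3]
  t0 <- proc.time()[["elapsed"]]
  out <- matrix(0, n, net$d)
  for (start in seq(1L, n, by = batch_size)) {
    end <- min(start + batch_size - 1L, n)
    out[start:end, ] <-
      net_forward(net, images[, , start:end, drop = FALSE])$out
  }
  rownames(out) <- dimnames(images)[[3]]
  attr(out, "sec_per_item") <- (proc.time()[["elapsed"]] - t0) / n
  out
}
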