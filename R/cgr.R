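#' Default CGR vertex assignment
#'
#' Corner coordinates of the unit square assigned to each base. The map is a
#' free convention (any fixed assignment yields an equivalent representation
#' up to symmetry); it is fixed here because every downstream embedder
#' depends on it. With this choice the x-bit of a cell index encodes
#' `base %in% c(G, T)` and the y-bit encodes `base %in% c(C, G)`.
#'
#' @return Named list of `(x, y)` corners for A, C, G, T.
#' @export
cgr_vertices <- function() {
  list(A = c(0, 0), C = c(0, 1), G = c(1, 1), T = c(1, 0))
}

#' Chaos game trajectory of a DNA sequence
#'
#' Starting at the centre `(0.5, 0.5)` of the unit square, the marker moves
#' halfway towards the corner of each successive base:
#' `p_i = (p_{i-1} + V(base_i)) / 2`. The returned trajectory holds
#' `p_1 .. p_L` (the start point is not included).
#'
#' @param sequence a DNA string over `{A,C,G,T}`, or a single-row
#'   [dna_records] data frame.
#' @param vertex_map corner assignment, as from [cgr_vertices()].
#' @return A list of class `cgr_trajectory`: `points` (L x 2 matrix of x, y),
#'   `vertex_map`, `sequence_id`.
#' @export
cgr_trajectory <- function(sequence, vertex_map = cgr_vertices()) {
  seq_id <- NA_character_
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    seq_id <- sequence$id
    sequence <- sequence$sequence
  }
  bases <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(bases, names(vertex_map))
  if (anyNA(idx)) {
    stop("sequence contains characters outside the vertex map: ",
         paste(unique(bases[is.na(idx)]), collapse = ", "))
  }
  vm <- do.call(rbind, vertex_map)
  vx <- vm[idx, 1]; vy <- vm[idx, 2]
  # linear recursion p_i = p_{i-1}/2 + v_i/2, p_0 = 1/2
  x <- as.numeric(stats::filter(vx / 2, 0.5, "recursive", init = 0.5))
  y <- as.numeric(stats::filter(vy / 2, 0.5, "recursive", init = 0.5))
  structure(list(points = cbind(x = x, y = y), vertex_map = vertex_map,
                 sequence_id = seq_id),
            class = "cgr_trajectory")
}

#' Rasterize a CGR trajectory into a square count image
#'
#' The unit square is divided into `resolution^2` half-open cells
#' `[i/R, (i+1)/R)` (the top/right edge closed so boundary points are
#' unambiguous); each trajectory point increments the count of its cell.
#' Row index of the returned matrix corresponds to y, column index to x,
#' both increasing with the coordinate.
#'
#' @param trajectory a [cgr_trajectory].
#' @param resolution image side length; a power of two.
#' @param normalize if `TRUE`, counts are divided by the maximum count so
#'   pixels lie in `[0, 1]`.
#' @return A `resolution x resolution` matrix of class `cgr_image` with
#'   attributes `resolution`, `sequence_id`, `normalized`.
#' @export
rasterize <- function(trajectory, resolution, normalize = FALSE) {
  stopifnot(inherits(trajectory, "cgr_trajectory"))
  check_power_of_two(resolution)
  p <- trajectory$points
  jx <- pmin(floor(p[, 1] * resolution), resolution - 1) + 1L
  iy <- pmin(floor(p[, 2] * resolution), resolution - 1) + 1L
  img <- matrix(0, resolution, resolution)
  counts <- table(factor(iy + (jx - 1L) * resolution,
                         levels = seq_len(resolution^2)))
  img[] <- as.numeric(counts)
  if (normalize && max(img) > 0) img <- img / max(img)
  structure(img, class = "cgr_image", resolution = resolution,
            sequence_id = trajectory$sequence_id, normalized = normalize)
}

check_power_of_two <- function(r) {
  if (r < 1 || bitwAnd(as.integer(r), as.integer(r) - 1L) != 0L) {
    stop("resolution must be a positive power of two, got ", r)
  }
  invisible(r)
}

#' CGR image of a sequence (trajectory + rasterization)
#'
#' @inheritParams cgr_trajectory
#' @inheritParams rasterize
#' @return A `cgr_image` matrix.
#' @export
cgr_image <- function(sequence, resolution = 64L, normalize = FALSE,
                      vertex_map = cgr_vertices()) {
  rasterize(cgr_trajectory(sequence, vertex_map), resolution, normalize)
}

#' Frequency-matrix CGR (k-mer count grid)
#'
#' The `2^k x 2^k` grid whose cells count occurrences of each k-mer;
#' equivalently, the rasterized CGR trajectory at resolution `2^k` with the
#' first `k - 1` warm-up points skipped, since the cell of point `i` at that
#' resolution is determined exactly by the last `k` bases.
#'
#' @inheritParams cgr_trajectory
#' @param k k-mer length; must not exceed the sequence length.
#' @param normalize divide by the maximum count.
#' @return A `2^k x 2^k` `cgr_image` whose total mass is `L - k + 1`.
#' @export
fcgr_matrix <- function(sequence, k, normalize = FALSE,
                        vertex_map = cgr_vertices()) {
  traj <- cgr_trajectory(sequence, vertex_map)
  L <- nrow(traj$points)
  if (k > L) stop("k (", k, ") exceeds sequence length (", L, ")")
  traj$points <- traj$points[k:L, , drop = FALSE]
  rasterize(traj, 2^k, normalize)
}

#' Batch CGR images as a 3D array
#'
#' Convenience encoder for a whole dataset: one normalized (by default) CGR
#' image per record, stacked into an array for the embedders.
#'
#' @param records a [dna_records] data frame.
#' @inheritParams rasterize
#' @return Array of dim `c(resolution, resolution, nrow(records))` with the
#'   record ids as the third dimnames.
#' @export
cgr_images <- function(records, resolution = 64L, normalize = TRUE) {
  check_power_of_two(resolution)
  arr <- array(0, c(resolution, resolution, nrow(records)),
               dimnames = list(NULL, NULL, records$id))
  for (i in seq_len(nrow(records))) {
    arr[, , i] <- rasterize(cgr_trajectory(records$sequence[i]),
                            resolution, normalize)
  }
  arr
}
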