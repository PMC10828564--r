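# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (no dynamic programming, no matrix DCT,
# no Haar filter bank) so that agreement is meaningful.

# exhaustive global-alignment maximum by plain recursion over all
# alignment paths (no memoisation): the enumeration oracle for nw_score
enum_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      best <- max(best, rec(i - 1L, j - 1L) +
                    if (A[i] == B[j]) match else mismatch)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(A), length(B))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# brute-force k-mer counting by substring scan
kmer_count_oracle <- function(sequence, k) {
  L <- nchar(sequence)
  kmers <- vapply(seq_len(L - k + 1), function(i)
    substr(sequence, i, i + k - 1), character(1))
  table(kmers)
}

# expected CGR cell (1-based row, col) of the point after the last base of
# `kmer` at resolution 2^k, from the bit construction: column bits come from
# base %in% {G,T}, row bits from base %in% {C,G}, most recent base most
# significant
kmer_cell_oracle <- function(kmer) {
  b <- rev(strsplit(kmer, "")[[1]])  # most recent first
  k <- length(b)
  xb <- as.integer(b %in% c("G", "T"))
  yb <- as.integer(b %in% c("C", "G"))
  w <- 2^((k - 1):0)
  c(row = sum(yb * w) + 1L, col = sum(xb * w) + 1L)
}

# naive O(n^4) orthonormal type-II DCT
dct2_oracle <- function(X) {
  n <- nrow(X)
  a <- function(u) if (u == 0) sqrt(1 / n) else sqrt(2 / n)
  D <- matrix(0, n, n)
  for (u in 0:(n - 1)) for (v in 0:(n - 1)) {
    s <- 0
    for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
      s <- s + X[x + 1, y + 1] *
        cos(pi * (2 * x + 1) * u / (2 * n)) *
        cos(pi * (2 * y + 1) * v / (2 * n))
    }
    D[u + 1, v + 1] <- a(u) * a(v) * s
  }
  D
}

# two-pass average-hash oracle: explicit block means, then mean threshold
ahash_oracle <- function(img, s) {
  R <- nrow(img)
  f <- R / s
  sm <- matrix(0, s, s)
  for (i in seq_len(s)) for (j in seq_len(s)) {
    sm[i, j] <- mean(img[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  }
  bits <- ifelse(sm > mean(sm), 1, -1)
  as.vector(t(bits))
}

# recursive pairwise-averaging oracle for the Haar approximation band
# (unscaled block means; the median threshold is scale-invariant)
whash_oracle <- function(img, s) {
  while (nrow(img) > s) {
    n <- nrow(img)
    odd <- seq(1, n, 2)
    img <- (img[odd, , drop = FALSE] + img[odd + 1, , drop = FALSE]) / 2
    img <- (img[, odd, drop = FALSE] + img[, odd + 1, drop = FALSE]) / 2
  }
  bits <- ifelse(img > median(img), 1, -1)
  as.vector(t(bits))
}

# all permutations of 1..n
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# small deterministic test fixtures
toy_spec <- function(seed = 1L) {
  family_spec(n_families = 3L, members_per_family = 5L,
              ancestor_length = 120L,
              mutation_tiers = c(0, 0.05, 0.1, 0.18, 0.25), seed = seed)
}

toy_ranked <- function(seed = 1L) {
  build_ranked_dataset(generate_dataset(toy_spec(seed)))
}
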