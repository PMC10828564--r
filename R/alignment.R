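#' Needleman-Wunsch scoring parameters
#'
#' Linear gap model: every gap position costs `gap`, opening and extension
#' alike. Defaults are the similarity scheme used for the ground truth:
#' +1 match, 0 mismatch, -1 per gap position.
#'
#' @param match,mismatch,gap integer scores with `match > mismatch >= gap`.
#' @return List of class `nw_params`.
#' @export
nw_params <- function(match = 1L, mismatch = 0L, gap = -1L) {
  if (!(match > mismatch && mismatch >= gap)) {
    stop("require match > mismatch >= gap")
  }
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap)), class = "nw_params")
}

substitution_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch)
}

#' Optimal global alignment score of two DNA sequences
#'
#' Needleman-Wunsch dynamic programming via [Biostrings::pairwiseAlignment()]
#' with a linear gap penalty. Symmetric in its arguments. An empty sequence
#' is scored as an all-gap alignment, `gap * nchar(other)`, with a warning
#' rather than an error.
#'
#' @param a,b DNA strings over `{A,C,G,T}`.
#' @param params an [nw_params] scoring scheme.
#' @return Integer alignment score.
#' @examples
#' nw_score("ACGT", "ACGT")  # 4
#' nw_score("ACGT", "AGGT")  # 3
#' @export
nw_score <- function(a, b, params = nw_params()) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    warning("empty sequence: score is the gap-only alignment")
    return(as.integer(params$gap * (nchar(a) + nchar(b))))
  }
  s <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = substitution_matrix(params),
    gapOpening = 0, gapExtension = -params$gap, scoreOnly = TRUE)
  as.integer(round(s))
}

#' All pairwise global-alignment scores of a dataset
#'
#' Scores each unordered pair once and mirrors the result; the diagonal is
#' the self-score `match * length`.
#'
#' @param records a [dna_records] data frame.
#' @inheritParams nw_score
#' @return Symmetric integer matrix with record ids as dimnames.
#' @export
nw_pairwise <- function(records, params = nw_params()) {
  n <- nrow(records)
  stopifnot(n >= 1)
  ids <- records$id
  S <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(S) <- as.integer(params$match * nchar(records$sequence))
  if (n == 1L) return(S)
  subs <- substitution_matrix(params)
  set <- Biostrings::DNAStringSet(records$sequence)
  for (i in seq_len(n - 1L)) {
    s <- Biostrings::pairwiseAlignment(
      set[(i + 1L):n], set[[i]], type = "global",
      substitutionMatrix = subs, gapOpening = 0, gapExtension = -params$gap,
      scoreOnly = TRUE)
    S[i, (i + 1L):n] <- as.integer(round(s))
    S[(i + 1L):n, i] <- S[i, (i + 1L):n]
  }
  S
}

#' Ranked record: an anchor with candidates ordered by similarity
#'
#' Orders `candidates` by descending alignment score to the anchor `q`,
#' ties broken by ascending id (a deterministic rule so downstream ranking
#' metrics are reproducible).
#'
#' @param q single-row [dna_records] anchor.
#' @param candidates [dna_records] excluding the anchor.
#' @param params an [nw_params].
#' @param scores optional precomputed named score vector (one per candidate
#'   id); if supplied no alignment is run.
#' @return List of class `ranked_record`: `anchor_id`, `neighbor_id`
#'   (ordered), `score` (descending), `n`.
#' @export
build_ranked_record <- function(q, candidates, params = nw_params(),
                                scores = NULL) {
  stopifnot(nrow(q) == 1L)
  if (q$id %in% candidates$id) stop("candidates must exclude the anchor")
  if (is.null(scores)) {
    scores <- vapply(candidates$sequence, function(s)
      nw_score(q$sequence, s, params), integer(1))
    names(scores) <- candidates$id
  }
  scores <- scores[candidates$id]
  ord <- order(-scores, candidates$id)
  structure(list(anchor_id = q$id,
                 neighbor_id = candidates$id[ord],
                 score = unname(as.integer(scores[ord])),
                 n = length(ord)),
            class = "ranked_record")
}

#' Ground-truth ranking dataset: every sequence as anchor once
#'
#' Computes the full pairwise alignment matrix (each unordered pair once)
#' and builds one [build_ranked_record()] per record, with all other
#' records as candidates.
#'
#' @param records a [dna_records] data frame (>= 2 rows).
#' @inheritParams nw_score
#' @return Named list of `ranked_record`s, class `ranked_records`, with the
#'   pairwise score matrix in attribute `"scores"`.
#' @export
build_ranked_dataset <- function(records, params = nw_params()) {
  stopifnot(nrow(records) >= 2L)
  S <- nw_pairwise(records, params)
  out <- lapply(seq_len(nrow(records)), function(i) {
    build_ranked_record(records[i, , drop = FALSE],
                        records[-i, , drop = FALSE],
                        scores = S[records$id[-i], records$id[i]])
  })
  names(out) <- records$id
  structure(out, class = "ranked_records", scores = S)
}

#' Split anchors into training and test sets
#'
#' The split concerns anchors only: a test anchor's candidate list still
#' spans the whole dataset, mirroring retrieval against a full database.
#'
#' @param dataset a `ranked_records` list (or a character vector of ids).
#' @param train_fraction fraction of anchors assigned to training.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return List with character vectors `train` and `test` (disjoint, union =
#'   all anchors).
#' @export
split_anchors <- function(dataset, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  ids <- if (is.character(dataset)) dataset else names(dataset)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_train <- round(length(ids) * train_fraction)
  n_train <- max(1L, min(length(ids) - 1L, n_train))
  train <- sort(sample(ids, n_train))
  list(train = train, test = sort(setdiff(ids, train)))
}
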