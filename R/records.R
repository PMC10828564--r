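#' DNA sequence records
#'
#' A `dna_records` object is a plain `data.frame` with columns `id`,
#' `group` and `sequence`, one row per sequence. Ids must be unique and
#' sequences are upper-case strings over `{A,C,G,T}` (non-ACGT symbols are
#' handled by the ambiguity policy of [read_fasta()] / [dna_records()]).
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of DNA sequences (any case; cleaned).
#' @param group character vector of group labels (e.g. pathogen or family).
#' @param ambiguity how to treat characters outside `{A,C,G,T}`:
#'   `"drop-character"` removes them (with a warning counting removals),
#'   `"drop-record"` removes the whole record.
#' @return A `data.frame` of class `dna_records` with columns
#'   `id`, `group`, `sequence`.
#' @examples
#' dna_records(c("s1", "s2"), c("acgt", "AANCG"), c("gA", "gA"))
#' @export
dna_records <- function(id, sequence, group,
                        ambiguity = c("drop-character", "drop-record")) {
  ambiguity <- match.arg(ambiguity)
  id <- as.character(id)
  group <- as.character(group)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence) || length(id) != length(group)) {
    stop("id, sequence and group must have equal length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  n_bad <- nchar(sequence) - nchar(gsub("[^ACGT]", "", sequence))
  if (any(n_bad > 0)) {
    if (ambiguity == "drop-character") {
      warning(sum(n_bad), " non-ACGT character(s) removed from ",
              sum(n_bad > 0), " record(s)")
      sequence <- gsub("[^ACGT]", "", sequence)
    } else {
      warning(sum(n_bad > 0), " record(s) with non-ACGT characters dropped")
      keep <- n_bad == 0
      id <- id[keep]; group <- group[keep]; sequence <- sequence[keep]
    }
  }
  empty <- nchar(sequence) == 0
  if (any(empty)) {
    warning(sum(empty), " empty record(s) dropped after cleaning")
    id <- id[!empty]; group <- group[!empty]; sequence <- sequence[!empty]
  }
  out <- data.frame(id = id, group = group, sequence = sequence,
                    stringsAsFactors = FALSE)
  class(out) <- c("dna_records", "data.frame")
  out
}

#' Read labelled DNA sequences from a FASTA file
#'
#' Headers follow the convention `id<delim>group` (default delimiter `"|"`);
#' the part before the first delimiter is the id, the rest the group label.
#' Sequences are upper-cased and non-ACGT characters are handled by the
#' ambiguity policy.
#'
#' @param path path to a FASTA file.
#' @param delim single character separating id and group in headers.
#' @inheritParams dna_records
#' @return A [dna_records] data frame in file order.
#' @export
read_fasta <- function(path, delim = "|",
                       ambiguity = c("drop-character", "drop-record")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) stop("empty dataset: no FASTA records in '", path, "'")
  headers <- names(set)
  has_delim <- grepl(delim, headers, fixed = TRUE)
  if (!all(has_delim)) {
    warning(sum(!has_delim), " header(s) without '", delim,
            "' delimiter; group set to NA")
  }
  pos <- regexpr(delim, headers, fixed = TRUE)
  id <- ifelse(has_delim, substr(headers, 1L, pos - 1L), headers)
  group <- ifelse(has_delim, substr(headers, pos + nchar(delim), nchar(headers)),
                  NA_character_)
  dna_records(id, as.character(set), group, ambiguity = ambiguity)
}

#' Write DNA records to a FASTA file
#'
#' Headers are written as `id<delim>group`, so
#' `read_fasta(write_fasta(x, f))` round-trips exactly.
#'
#' @param records a [dna_records] data frame.
#' @param path output file path.
#' @param delim header delimiter between id and group.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, delim = "|", width = 80L) {
  stopifnot(is.data.frame(records))
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- paste(records$id, records$group, sep = delim)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Drop records from under-represented groups
#'
#' Keeps exactly the records whose group has strictly more than `min_count`
#' members, mirroring the outlier filter that removes labels with too few
#' sequences to learn from. Record order is preserved and sequence content
#' untouched; the operation is idempotent.
#'
#' @param records a [dna_records] data frame.
#' @param min_count groups with `min_count` or fewer members are removed
#'   (default 10).
#' @return Filtered [dna_records] (possibly empty).
#' @export
filter_small_groups <- function(records, min_count = 10L) {
  stopifnot(is.data.frame(records), min_count >= 0)
  sizes <- table(records$group)
  keep_groups <- names(sizes)[sizes > min_count]
  out <- records[records$group %in% keep_groups, , drop = FALSE]
  rownames(out) <- NULL
  out
}
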