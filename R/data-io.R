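# Reading, validating and writing labelled uridine-centred RNA fragments
# and feature tables. A labelled sequence set is a tibble with columns
# id (chr), sequence (chr over A/C/G/U), label (int 0/1).

#' Normalize a raw nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U, so that benchmark files written in the
#' DNA alphabet can be used directly. Any character outside
#' `A/C/G/U/T` (either case) is an error naming the first offending
#' position. Idempotent.
#'
#' @param raw non-empty character scalar.
#' @return The normalized sequence over `{A,C,G,U}`.
#' @export
#' @examples
#' normalize_sequence("acgt")
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1, nzchar(raw))
  up <- chartr("acgut", "ACGUT", raw)
  up <- gsub("T", "U", up, fixed = TRUE)
  bad <- regexpr("[^ACGU]", up)
  if (bad > 0) {
    stop(sprintf("invalid character '%s' at position %d (alphabet is A/C/G/U/T)",
                 substr(up, bad, bad), bad), call. = FALSE)
  }
  up
}

new_sequence_set <- function(id, sequence, label) {
  tibble::tibble(id = as.character(id),
                 sequence = as.character(sequence),
                 label = as.integer(label))
}

#' Read a FASTA file of equal-length RNA fragments
#'
#' Each entry becomes one record with the given class label (1 = positive
#' \eqn{\Psi} site, 0 = negative). Sequences are normalized with
#' [normalize_sequence()]; entry order is preserved. If `label` is `NULL`
#' the label is parsed from a `|label=0/1` suffix in each header.
#'
#' @param path FASTA file path.
#' @param label 0, 1, or `NULL` to read labels from headers.
#' @return A tibble with columns `id`, `sequence`, `label`.
#' @export
read_fasta_set <- function(path, label = NULL) {
  fas <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  if (length(fas) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(fas, function(x) attr(x, "Annot"), character(1))
  ids <- sub("^>", "", ids)
  seqs <- vapply(fas, function(x) normalize_sequence(as.character(x)),
                 character(1))
  lens <- unique(nchar(seqs))
  if (length(lens) > 1) {
    stop("sequences must share one length; found lengths: ",
         paste(sort(lens), collapse = ", "), call. = FALSE)
  }
  if (is.null(label)) {
    m <- regmatches(ids, regexpr("\\|label=[01]", ids))
    if (length(m) != length(ids)) {
      stop("`label` not given and some headers lack a |label=0/1 suffix",
           call. = FALSE)
    }
    lab <- as.integer(sub("\\|label=", "", m))
    ids <- sub("\\|label=[01]", "", ids)
  } else {
    stopifnot(label %in% c(0L, 1L))
    lab <- rep(as.integer(label), length(ids))
  }
  new_sequence_set(ids, unname(seqs), lab)
}

#' Read positive and negative FASTA files into one labelled set
#'
#' @param pos,neg FASTA paths for the positive (label 1) and negative
#'   (label 0) fragments.
#' @return A tibble with columns `id`, `sequence`, `label`.
#' @export
read_fasta_pair <- function(pos, neg) {
  ds <- dplyr::bind_rows(read_fasta_set(pos, label = 1L),
                         read_fasta_set(neg, label = 0L))
  if (length(unique(nchar(ds$sequence))) > 1) {
    stop("positive and negative files have different sequence lengths",
         call. = FALSE)
  }
  ds
}

#' Write a labelled sequence set to FASTA
#'
#' Headers carry a `|label=` suffix so [read_fasta_set()] round-trips the
#' labels.
#'
#' @param data tibble with `id`, `sequence`, `label`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_set <- function(data, path) {
  stopifnot(nrow(data) > 0)
  seqinr::write.fasta(as.list(data$sequence),
                      names = paste0(data$id, "|label=", data$label),
                      file.out = path, as.string = TRUE)
  invisible(path)
}

#' Validate a labelled sequence set
#'
#' Checks the structural contract of a \eqn{\Psi}-site dataset: a single odd
#' fragment length and uridine at the centre position `(L+1)/2` of every
#' record. Report-only: violations are listed, not raised.
#'
#' @param data tibble with `id`, `sequence`, `label`.
#' @return A tibble of violations (columns `id`, `problem`) with attribute
#'   `pass` (`TRUE` iff empty); also available via [validation_passed()].
#' @export
validate_sequence_set <- function(data) {
  stopifnot(nrow(data) > 0)
  lens <- nchar(data$sequence)
  L <- as.integer(stats::median(lens))
  problems <- list()
  if (length(unique(lens)) > 1) {
    off <- data$id[lens != L]
    problems <- c(problems, lapply(off, function(i)
      tibble::tibble(id = i, problem = "length differs from majority length")))
  }
  odd <- lens %% 2L == 1L
  if (any(!odd)) {
    problems <- c(problems, lapply(data$id[!odd], function(i)
      tibble::tibble(id = i, problem = "even length (must be odd)")))
  }
  centre_ok <- rep(FALSE, nrow(data))
  centre_ok[odd] <- substr(data$sequence[odd], (lens[odd] + 1L) %/% 2L,
                           (lens[odd] + 1L) %/% 2L) == "U"
  if (any(odd & !centre_ok)) {
    problems <- c(problems, lapply(data$id[odd & !centre_ok], function(i)
      tibble::tibble(id = i, problem = "centre nucleotide is not U")))
  }
  report <- if (length(problems)) dplyr::bind_rows(problems) else
    tibble::tibble(id = character(), problem = character())
  attr(report, "pass") <- nrow(report) == 0
  report
}

#' Did a validation report pass?
#' @param report result of [validate_sequence_set()].
#' @return `TRUE` iff the report lists no violations.
#' @export
validation_passed <- function(report) isTRUE(attr(report, "pass"))

#' Write a feature table to CSV
#'
#' Header row of scheme-qualified feature names, one row per sample, `label`
#' as the final column. Round-trips losslessly through
#' [read_feature_table()].
#'
#' @param ft feature table (tibble, `label` last).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  assert_feature_table(ft)
  ft <- dplyr::relocate(ft, "label", .after = dplyr::last_col())
  readr::write_csv(ft, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return Feature-table tibble.
#' @export
read_feature_table <- function(path) {
  ft <- readr::read_csv(path, show_col_types = FALSE,
                        name_repair = "minimal")
  ft$label <- as.integer(ft$label)
  assert_feature_table(tibble::as_tibble(ft, .name_repair = "minimal"))
}
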