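# Shared low-level helpers: alphabet, k-mer indexing, fold assignment,
# feature-table accessors. Alphabet order A < C < G < U everywhere.

RNA_BASES <- c("A", "C", "G", "U")

#' All RNA k-mers in lexicographic order (A < C < G < U)
#'
#' @param k word length.
#' @return Character vector of length `4^k`, e.g. `AAA, AAC, ..., UUU` for
#'   `k = 3`.
#' @export
#' @examples
#' rna_kmers(2)[1:4]
rna_kmers <- function(k) {
  stopifnot(k >= 1)
  grid <- expand.grid(rep(list(RNA_BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic
  apply(grid[rev(seq_len(k))], 1L, paste0, collapse = "")
}

# 1-based lexicographic index of each k-mer in a vector of k-mer strings
kmer_index <- function(kmers, k) {
  base_val <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  chars <- strsplit(kmers, "", fixed = TRUE)
  vapply(chars, function(ch) {
    as.integer(sum(base_val[ch] * 4^((k - 1):0)) + 1)
  }, integer(1))
}

# split a sequence into its overlapping k-mers (length L - k + 1)
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k", call. = FALSE)
  substring(seq, 1:(L - k + 1L), k:L)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `folds` cross-validation folds so that both
#' classes are spread as evenly as possible across folds. Reproducible from
#' `seed`.
#'
#' @param labels binary 0/1 vector.
#' @param folds number of folds (>= 2).
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1:folds`, aligned to `labels`.
#' @export
make_folds <- function(labels, folds = 5, seed = 1) {
  stopifnot(folds >= 2)
  if (any(table(labels) < folds)) {
    stop("each class needs at least `folds` samples for stratified CV",
         call. = FALSE)
  }
  fold_id <- integer(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

# feature-table accessors: a feature table is a tibble whose final column
# is `label`; everything else is a numeric feature column.
ft_feature_names <- function(ft) names(ft)[names(ft) != "label"]

ft_matrix <- function(ft, features = ft_feature_names(ft)) {
  as.matrix(ft[features])
}

ft_labels <- function(ft) {
  if (!"label" %in% names(ft)) stop("feature table has no `label` column",
                                    call. = FALSE)
  as.integer(ft[["label"]])
}

assert_feature_table <- function(ft) {
  if (!is.data.frame(ft) || nrow(ft) == 0) {
    stop("feature table must be a non-empty data frame", call. = FALSE)
  }
  feats <- ft_feature_names(ft)
  if (anyDuplicated(feats)) {
    stop("duplicate feature names: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(ft)
}

assert_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("both classes (0 and 1) must be present", call. = FALSE)
  }
  invisible(labels)
}
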