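# Synthetic uridine-centred fragment generator. Emulates the structure of
# the Psi-site benchmark sets: balanced positive/negative classes, odd
# fragment length (21 or 31 nt typical), U pinned at the centre, and a
# class difference realised as position-specific trinucleotide enrichment
# in the positives -- the statistical structure the propensity encoder and
# the positional trinucleotide one-hot are designed to detect. No attempt
# is made to imitate real Psi-site biology.

default_signal_positions <- function(L) {
  centre <- (L + 1L) %/% 2L
  # three trinucleotide start positions clear of the centre window
  cand <- c(centre - 8L, centre - 5L, centre + 3L)
  cand[cand >= 1L & cand <= L - 2L]
}

#' Generate a labelled synthetic fragment dataset
#'
#' Every record is `L` nt with U at the centre. Negatives draw each
#' non-centre base independently from `background`. Positives do the same,
#' except that at each signal position the designated trinucleotide is
#' planted with probability `delta` (otherwise that window stays
#' background), so `delta = 0` makes the two classes identically
#' distributed and larger `delta` gives a stronger, PSTNPss/PS3-detectable
#' class difference.
#'
#' @param n_pos,n_neg class sizes (default 200 each; benchmark-style sets
#'   are balanced).
#' @param L odd fragment length (default 21).
#' @param signal_positions trinucleotide start positions (1-based, in
#'   `1..L-2`) carrying signal; default three positions clear of the
#'   centre. Windows must not overlap each other, and a window covering
#'   the centre must plant U there.
#' @param signal_kmers designated trinucleotides, one per signal position.
#' @param delta planting probability in `[0, 1]` (effect size).
#' @param background nucleotide probabilities, order A, C, G, U (default
#'   uniform).
#' @param seed integer seed; output is fully reproducible.
#' @return Tibble `id`, `sequence`, `label` (positives first); simulation
#'   settings kept in attribute `sim_config`.
#' @export
#' @examples
#' simulate_psi_dataset(n_pos = 5, n_neg = 5, L = 21, seed = 1)
simulate_psi_dataset <- function(n_pos = 200, n_neg = 200, L = 21,
                                 signal_positions = NULL,
                                 signal_kmers = NULL,
                                 delta = 0.5,
                                 background = c(A = 0.25, C = 0.25,
                                                G = 0.25, U = 0.25),
                                 seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1, L >= 3, L %% 2 == 1,
            delta >= 0, delta <= 1,
            length(background) == 4, all(background >= 0),
            abs(sum(background) - 1) < 1e-8)
  centre <- (L + 1L) %/% 2L
  if (is.null(signal_positions)) signal_positions <- default_signal_positions(L)
  if (is.null(signal_kmers)) {
    signal_kmers <- rep_len(c("GAC", "CGA", "UCG"), length(signal_positions))
  }
  stopifnot(length(signal_kmers) == length(signal_positions),
            all(signal_positions >= 1), all(signal_positions <= L - 2),
            all(nchar(signal_kmers) == 3))
  if (length(signal_positions) > 1) {
    gaps <- diff(sort(signal_positions))
    if (any(gaps < 3)) stop("signal windows must not overlap", call. = FALSE)
  }
  for (i in seq_along(signal_positions)) {
    j <- signal_positions[i]
    if (centre >= j && centre <= j + 2L &&
        substr(signal_kmers[i], centre - j + 1L, centre - j + 1L) != "U") {
      stop("signal k-mer at position ", j,
           " would overwrite the centre U", call. = FALSE)
    }
  }
  set.seed(seed)
  draw <- function(n, planted) {
    vapply(seq_len(n), function(i) {
      s <- sample(RNA_BASES, L, replace = TRUE, prob = background)
      s[centre] <- "U"
      if (planted) {
        for (k in seq_along(signal_positions)) {
          if (stats::runif(1) < delta) {
            j <- signal_positions[k]
            s[j:(j + 2L)] <- strsplit(signal_kmers[k], "")[[1]]
            s[centre] <- "U"
          }
        }
      }
      paste0(s, collapse = "")
    }, character(1))
  }
  out <- new_sequence_set(
    id = c(paste0("pos_", seq_len(n_pos)), paste0("neg_", seq_len(n_neg))),
    sequence = c(draw(n_pos, TRUE), draw(n_neg, FALSE)),
    label = c(rep(1L, n_pos), rep(0L, n_neg)))
  attr(out, "sim_config") <- list(
    n_pos = n_pos, n_neg = n_neg, L = L,
    signal_positions = signal_positions, signal_kmers = signal_kmers,
    delta = delta, background = background, seed = seed)
  out
}

#' Permute the labels of a labelled sequence set
#'
#' Sequences stay in place; labels are permuted uniformly at random, so
#' class counts are preserved while any sequence-label association is
#' destroyed. A negative control for the whole pipeline.
#'
#' @param data labelled sequence tibble.
#' @param seed integer seed.
#' @return The same tibble with permuted `label`.
#' @export
shuffle_labels <- function(data, seed = 1) {
  stopifnot(nrow(data) > 0)
  set.seed(seed)
  data$label <- sample(data$label)
  data
}
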