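# Fixture builders and independent brute-force oracles shared across the
# suite. Oracles are deliberately naive (loops, all-pairs counts) and never
# call the implementation paths they check.

# random labelled feature table with balanced classes
rand_feature_table <- function(n = 30, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::runif(n * p), nrow = n,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  ft <- tibble::as_tibble(X)
  ft$label <- rep_len(c(0L, 1L), n)[sample(n)]
  ft
}

# tiny labelled sequence set with fixed sequences (odd L, centre U)
toy_sequences <- function() {
  tibble::tibble(
    id = c("p1", "p2", "n1", "n2"),
    sequence = c("ACUGA", "GCUCA", "AAUAA", "CGUGC"),
    label = c(1L, 1L, 0L, 0L))
}

# brute-force chi-square oracle: explicit per-feature contingency of
# min-max-scaled per-class sums vs expectation under class proportions
oracle_chi2 <- function(ft) {
  y <- ft$label
  feats <- setdiff(names(ft), "label")
  vapply(feats, function(f) {
    x <- ft[[f]]
    if (max(x) > min(x)) x <- (x - min(x)) / (max(x) - min(x)) else x <- x * 0
    total <- sum(x)
    if (total == 0) return(0)
    stat <- 0
    for (cl in c(0, 1)) {
      obs <- sum(x[y == cl])
      expd <- total * mean(y == cl)
      stat <- stat + (obs - expd)^2 / expd
    }
    stat
  }, numeric(1))
}

# brute-force AUC oracle: all (positive, negative) pairs, ties as 1/2
oracle_auc <- function(truth, score) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# trinucleotide start position parsed from a scheme-qualified feature name
feature_position <- function(feature) {
  as.integer(sub(".*:pos(\\d+).*", "\\1", feature))
}
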