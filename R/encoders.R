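# Sequence encoders. Five stateless schemes (one-hot "binary", nucleotide
# chemical property NCP, sliding-window composition ENAC, and the
# position-specific di-/trinucleotide one-hots PS2/PS3) plus the fitted,
# label-dependent PSTNPss propensity encoder. All per-position blocks use
# alphabet order A < C < G < U; k-mers are indexed lexicographically.

ENCODING_SCHEMES <- c("ENAC", "binary", "NCP", "PSTNPss", "PS2", "PS3")

#' One-hot (binary) encoding
#'
#' Each position becomes a 4-bit indicator block in order A, C, G, U:
#' A = (1,0,0,0), C = (0,1,0,0), G = (0,0,1,0), U = (0,0,0,1).
#'
#' @param seq normalized sequence (see [normalize_sequence()]).
#' @return Named numeric vector of length `4 * nchar(seq)`; sums to `L`.
#' @export
#' @examples
#' encode_binary("AC")
encode_binary <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  m <- matrix(0, nrow = 4L, ncol = L, dimnames = list(RNA_BASES, NULL))
  m[cbind(match(chars, RNA_BASES), seq_len(L))] <- 1
  v <- as.numeric(m)
  names(v) <- paste0("binary:pos", rep(seq_len(L), each = 4L), ":",
                     rep(RNA_BASES, L))
  v
}

# chemical-property triples: c1 = weak hydrogen bond {A,U},
# c2 = purine ring {A,G}, c3 = amino group {A,C}
NCP_MAP <- matrix(c(1, 1, 1,   # A
                    0, 0, 1,   # C
                    0, 1, 0,   # G
                    1, 0, 0),  # U
                  nrow = 4L, byrow = TRUE,
                  dimnames = list(RNA_BASES, c("hbond", "ring", "amino")))

#' Nucleotide chemical property (NCP) encoding
#'
#' Each nucleotide becomes a 3-coordinate code built from its chemical
#' classes (hydrogen-bond strength, ring structure, functional group):
#' A = (1,1,1), C = (0,0,1), G = (0,1,0), U = (1,0,0).
#'
#' @inheritParams encode_binary
#' @return Named numeric vector of length `3 * nchar(seq)`.
#' @export
encode_ncp <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  v <- as.numeric(t(NCP_MAP[match(chars, RNA_BASES), , drop = FALSE]))
  names(v) <- paste0("NCP:pos", rep(seq_len(L), each = 3L), ":",
                     rep(colnames(NCP_MAP), L))
  v
}

#' Enhanced nucleic acid composition (ENAC)
#'
#' Slides a fixed-length window 5' to 3' and records the within-window
#' nucleotide frequencies (count / window) in order A, C, G, U, so each
#' window block sums to 1. The default window of 2 yields the feature-space
#' sizes used throughout (e.g. 80 features for 21-nt fragments).
#'
#' @inheritParams encode_binary
#' @param window window width, `1 <= window <= nchar(seq)`.
#' @return Named numeric vector of length `4 * (L - window + 1)`.
#' @export
encode_enac <- function(seq, window = 2) {
  L <- nchar(seq)
  if (window < 1 || window > L) stop("window must be in 1..L", call. = FALSE)
  starts <- seq_len(L - window + 1L)
  blocks <- vapply(starts, function(s) {
    ch <- strsplit(substr(seq, s, s + window - 1L), "", fixed = TRUE)[[1]]
    tabulate(match(ch, RNA_BASES), nbins = 4L) / window
  }, numeric(4))
  v <- as.numeric(blocks)
  names(v) <- paste0("ENAC:win", window, ":pos",
                     rep(starts, each = 4L), ":", rep(RNA_BASES, length(starts)))
  v
}

# shared worker for the positional k-mer one-hots (PS2: k=2, PS3: k=3)
encode_ps_k <- function(seq, k, scheme) {
  L <- nchar(seq)
  if (L < k) stop(sprintf("%s needs sequences of length >= %d", scheme, k),
                  call. = FALSE)
  n_pos <- L - k + 1L
  n_words <- 4L^k
  idx <- kmer_index(seq_kmers(seq, k), k)
  m <- matrix(0, nrow = n_words, ncol = n_pos)
  m[cbind(idx, seq_len(n_pos))] <- 1
  v <- as.numeric(m)
  names(v) <- paste0(scheme, ":pos", rep(seq_len(n_pos), each = n_words),
                     ":", rep(rna_kmers(k), n_pos))
  v
}

#' Position-specific dinucleotide one-hot (PS2)
#'
#' Each adjacent nucleotide pair becomes a 16-bit one-hot block in
#' lexicographic order AA, AC, ..., UU (so AA = 1000000000000000).
#'
#' @inheritParams encode_binary
#' @return Named numeric vector of length `16 * (L - 1)`; sums to `L - 1`.
#' @export
encode_ps2 <- function(seq) encode_ps_k(seq, 2L, "PS2")

#' Position-specific trinucleotide one-hot (PS3)
#'
#' Each adjacent nucleotide triple becomes a 64-bit one-hot block in
#' lexicographic order AAA, AAC, ..., UUU.
#'
#' @inheritParams encode_binary
#' @return Named numeric vector of length `64 * (L - 2)`; sums to `L - 2`.
#' @export
encode_ps3 <- function(seq) encode_ps_k(seq, 3L, "PS3")

# per-class trinucleotide frequency matrix, 64 x (L-2)
trinuc_freq_matrix <- function(seqs, L) {
  n_pos <- L - 2L
  counts <- matrix(0, nrow = 64L, ncol = n_pos,
                   dimnames = list(rna_kmers(3), paste0("pos", seq_len(n_pos))))
  for (s in seqs) {
    idx <- kmer_index(seq_kmers(s, 3L), 3L)
    counts[cbind(idx, seq_len(n_pos))] <-
      counts[cbind(idx, seq_len(n_pos))] + 1
  }
  counts / length(seqs)
}

#' Fit the position-specific trinucleotide propensity (PSTNPss) model
#'
#' For each of the 64 trinucleotides i and each start position
#' j = 1..L-2, the propensity is the difference of relative occurrence
#' frequencies between the positive and negative training subsets:
#' `Z[i, j] = F+(3mer_i | j) - F-(3mer_i | j)`. Plain relative frequencies,
#' no smoothing. This is a fitted, label-dependent encoder: fit it on
#' training data only and apply it to held-out data via
#' [encode_pstnpss()].
#'
#' @param data labelled sequence tibble (`id`, `sequence`, `label`) with at
#'   least one record of each class and a single sequence length.
#' @return An object of class `pstnpss_model` with fields `L`, `Z`
#'   (64 x (L-2) matrix, rows named by trinucleotide), `n_pos`, `n_neg`.
#' @export
fit_pstnpss <- function(data) {
  assert_two_classes(data$label)
  lens <- unique(nchar(data$sequence))
  if (length(lens) > 1) stop("sequences must share one length", call. = FALSE)
  L <- lens
  if (L < 3) stop("sequences must be at least 3 nt", call. = FALSE)
  pos <- data$sequence[data$label == 1L]
  neg <- data$sequence[data$label == 0L]
  Z <- trinuc_freq_matrix(pos, L) - trinuc_freq_matrix(neg, L)
  structure(list(L = L, Z = Z, n_pos = length(pos), n_neg = length(neg)),
            class = "pstnpss_model")
}

#' @export
print.pstnpss_model <- function(x, ...) {
  cat(sprintf("PSTNPss propensity model: L = %d (%d positions), fitted on %d+/%d- sequences\n",
              x$L, x$L - 2L, x$n_pos, x$n_neg))
  cat(sprintf("propensity range [%.3f, %.3f]\n", min(x$Z), max(x$Z)))
  invisible(x)
}

#' @describeIn fit_pstnpss tidy the fitted propensity matrix into a tibble
#'   with columns `trinucleotide`, `position`, `propensity`.
#' @param x fitted `pstnpss_model`.
#' @param ... unused.
#' @method tidy pstnpss_model
#' @export
tidy.pstnpss_model <- function(x, ...) {
  tibble::tibble(
    trinucleotide = rep(rownames(x$Z), ncol(x$Z)),
    position = rep(seq_len(ncol(x$Z)), each = nrow(x$Z)),
    propensity = as.numeric(x$Z)
  )
}

#' Encode a sequence with a fitted PSTNPss model
#'
#' Position u of the output is the propensity of the trinucleotide starting
#' at u, i.e. `Z[3mer at u, u]`.
#'
#' @param seq normalized sequence of length `model$L`.
#' @param model a [fit_pstnpss()] fit.
#' @return Named numeric vector of length `L - 2`.
#' @export
encode_pstnpss <- function(seq, model) {
  stopifnot(inherits(model, "pstnpss_model"))
  if (nchar(seq) != model$L) {
    stop(sprintf("sequence length %d does not match model length %d",
                 nchar(seq), model$L), call. = FALSE)
  }
  idx <- kmer_index(seq_kmers(seq, 3L), 3L)
  n_pos <- model$L - 2L
  v <- model$Z[cbind(idx, seq_len(n_pos))]
  names(v) <- paste0("PSTNPss:pos", seq_len(n_pos))
  v
}

#' Save / load a PSTNPss model as JSON text
#'
#' @param model a `pstnpss_model`.
#' @param path JSON file path.
#' @return `path` invisibly / the restored model.
#' @export
write_pstnpss <- function(model, path) {
  stopifnot(inherits(model, "pstnpss_model"))
  jsonlite::write_json(
    list(L = model$L, n_pos = model$n_pos, n_neg = model$n_neg,
         trinucleotides = rownames(model$Z), Z = unname(model$Z)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pstnpss
#' @export
read_pstnpss <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Z <- matrix(obj$Z, nrow = 64L,
              dimnames = list(obj$trinucleotides,
                              paste0("pos", seq_len(obj$L - 2L))))
  structure(list(L = obj$L, Z = Z, n_pos = obj$n_pos, n_neg = obj$n_neg),
            class = "pstnpss_model")
}

#' Encode a labelled sequence set into a feature table
#'
#' Applies the requested encoding schemes in order and concatenates the
#' per-scheme vectors; feature names are scheme-qualified (e.g.
#' `PSTNPss:pos7`, `PS3:pos1:AAA`). Labels are carried through as the final
#' `label` column.
#'
#' Because PSTNPss is fitted on class labels, by default a pre-fitted model
#' must be supplied so that held-out data are never used for fitting; set
#' `fit_pstnpss_on_data = TRUE` to fit on `data` itself (appropriate for a
#' training set).
#'
#' @param data labelled sequence tibble (`id`, `sequence`, `label`).
#' @param schemes character vector from
#'   `c("ENAC", "binary", "NCP", "PSTNPss", "PS2", "PS3")`, applied in the
#'   given order.
#' @param pstnpss_model optional [fit_pstnpss()] fit, required when
#'   `"PSTNPss" %in% schemes` unless `fit_pstnpss_on_data = TRUE`.
#' @param fit_pstnpss_on_data fit the PSTNPss model on `data` itself.
#' @param enac_window ENAC window width (default 2).
#' @return A feature-table tibble (samples x features, `label` last). The
#'   PSTNPss model used, if any, is attached as attribute `pstnpss_model`.
#' @export
encode_sequences <- function(data,
                             schemes = c("PSTNPss", "PS3"),
                             pstnpss_model = NULL,
                             fit_pstnpss_on_data = FALSE,
                             enac_window = 2) {
  stopifnot(nrow(data) > 0)
  hit <- match(toupper(schemes), toupper(ENCODING_SCHEMES))
  if (anyNA(hit)) {
    stop("unknown scheme(s): ", paste(schemes[is.na(hit)], collapse = ", "),
         "; choose from ", paste(ENCODING_SCHEMES, collapse = ", "),
         call. = FALSE)
  }
  schemes <- ENCODING_SCHEMES[hit]
  if ("PSTNPss" %in% schemes && is.null(pstnpss_model)) {
    if (!fit_pstnpss_on_data) {
      stop("PSTNPss needs a fitted model: pass `pstnpss_model` (fit on ",
           "training data) or set `fit_pstnpss_on_data = TRUE`",
           call. = FALSE)
    }
    pstnpss_model <- fit_pstnpss(data)
  }
  encode_one <- function(seq) {
    unlist(lapply(schemes, function(sc) {
      switch(sc,
             ENAC = encode_enac(seq, window = enac_window),
             binary = encode_binary(seq),
             NCP = encode_ncp(seq),
             PSTNPss = encode_pstnpss(seq, pstnpss_model),
             PS2 = encode_ps2(seq),
             PS3 = encode_ps3(seq))
    }))
  }
  first <- encode_one(data$sequence[[1]])
  mat <- t(vapply(data$sequence, encode_one, first))
  ft <- tibble::as_tibble(mat, .name_repair = "minimal")
  ft$label <- as.integer(data$label)
  attr(ft, "pstnpss_model") <- pstnpss_model
  assert_feature_table(ft)
}
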