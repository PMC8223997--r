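# Independent brute-force oracles and small fixture builders used across
# the suite.

rand_seq <- function(len) paste(sample(AA_ALPHABET20, len, replace = TRUE),
                                collapse = "")

# naive conjoint-triad counter: walk every window with substr()
ct_oracle_counts <- function(seq, class_map) {
  counts <- numeric(343)
  L <- nchar(seq)
  for (i in seq_len(max(L - 2, 0))) {
    w <- strsplit(substr(seq, i, i + 2), "")[[1]]
    cls <- class_map[w]
    idx <- (cls[1] - 1) * 49 + (cls[2] - 1) * 7 + cls[3]
    counts[idx] <- counts[idx] + 1
  }
  counts
}

# naive autocovariance: explicit double loop over positions
ac_oracle <- function(seq, property_table, lag) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  mu <- rowMeans(property_table)
  sdv <- apply(property_table, 1, sd)
  out <- numeric(nrow(property_table) * lag)
  for (j in seq_len(nrow(property_table))) {
    x <- (property_table[j, chars] - mu[j]) / sdv[j]
    xb <- mean(x)
    for (d in seq_len(lag)) {
      s <- 0
      for (i in seq_len(L - d)) s <- s + (x[i] - xb) * (x[i + d] - xb)
      out[(j - 1) * lag + d] <- s / (L - d)
    }
  }
  out
}

# descriptor config over the first m bundled property scales
tiny_dconfig <- function(m = 2, lag = 3, ...) {
  descriptor_config(lag = lag,
                    property_table = read_property_table()[seq_len(m), ,
                                                           drop = FALSE],
                    ...)
}

# brute-force motif-co-occurrence classifier over a labeled pair set
motif_oracle_accuracy <- function(proteins, pairs, motifs) {
  has <- function(id, motif)
    grepl(motif, proteins[[id]]$sequence, fixed = TRUE)
  call_pos <- function(df) mapply(function(a, b)
    has(a, motifs[1]) && has(b, motifs[2]), df$id_a, df$id_b)
  correct <- sum(call_pos(pairs$positives)) +
    sum(!call_pos(pairs$negatives))
  correct / (nrow(pairs$positives) + nrow(pairs$negatives))
}

# cheap deterministic engine for cross-validation harness tests
threshold_engine <- function() {
  list(fit = function(train_pos, train_neg, fold_seed) {
    # midpoint of the class means of the first feature
    list(cut = (mean(train_pos[, 1]) + mean(train_neg[, 1])) / 2,
         pos_high = mean(train_pos[, 1]) > mean(train_neg[, 1]))
  }, predict = function(fit, X) {
    hi <- X[, 1] > fit$cut
    ifelse(xor(hi, !fit$pos_high), "positive", "negative")
  })
}

always_positive_engine <- function() {
  list(fit = function(train_pos, train_neg, fold_seed) NULL,
       predict = function(fit, X) rep("positive", nrow(X)))
}

# small planted-signal data set for classifier smoke tests
tiny_ppi_data <- function(seed = 11, n_proteins = 60, n_pos = 80,
                          n_neg = 80) {
  cfg <- synthesis_config(n_proteins = n_proteins,
                          length_range = c(40L, 80L),
                          n_pos = n_pos, n_neg = n_neg,
                          signal_strength = 1, lag = 3L, seed = seed)
  generate_ppi_dataset(cfg)
}
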