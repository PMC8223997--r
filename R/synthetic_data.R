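# Seeded synthetic proteomes and labeled pair sets with a planted,
# learnable interaction signal.
#
# The signal mechanism is motif co-occurrence, mimicking interface motifs:
# "bait" proteins carry copies of the first library motif, "prey" proteins
# carry the second, and interacting pairs are formed between baits and
# preys. Non-interacting pairs are drawn among motif-free background
# proteins. The default motifs are 12-mers over the two rarest conjoint
# classes (C alone; R/K), so the planted signal lands directly on a few
# conjoint-triad coordinates while perturbing the autocovariance channel
# only weakly.

#' Configuration for synthetic interaction data
#'
#' @param n_proteins Number of proteins to simulate.
#' @param length_range `c(min, max)` sequence lengths (uniform); `min` must
#'   exceed `lag` and accommodate the planted motifs.
#' @param n_pos,n_neg Number of interacting / non-interacting pairs.
#' @param motif_library Character vector of two motifs (bait motif, prey
#'   motif) over the standard alphabet.
#' @param signal_strength Probability in `[0, 1]` that a positive-pair
#'   partner actually carries its motif; 0 plants nothing (null data).
#' @param motif_copies Copies of the motif planted per carrier protein.
#' @param background Named length-20 probability vector for residue
#'   sampling; default uniform. `skewed_background()` gives a
#'   composition-biased preset.
#' @param role_fractions Named fractions `c(bait, prey, background)`
#'   partitioning the proteome.
#' @param lag The descriptor lag the data must support (`min length > lag`).
#' @param seed Integer seed.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(n_proteins = 400L,
                             length_range = c(50L, 300L),
                             n_pos = 1000L, n_neg = 1000L,
                             motif_library = c("CCCCCCCCCCCC",
                                               "RKRKRKRKRKRK"),
                             signal_strength = 1,
                             motif_copies = 2L,
                             background = NULL,
                             role_fractions = c(bait = 0.3, prey = 0.3,
                                                background = 0.4),
                             lag = 30L, seed = 1L) {
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
  stopifnot(n_proteins >= 3, length(length_range) == 2L,
            length_range[1] <= length_range[2],
            n_pos >= 0, n_neg >= 0,
            length(motif_library) == 2L,
            signal_strength >= 0, signal_strength <= 1,
            motif_copies >= 1,
            abs(sum(role_fractions) - 1) < 1e-8)
  if (length_range[1] <= lag)
    stop("minimum sequence length (", length_range[1],
         ") must exceed lag (", lag, ")", call. = FALSE)
  if (!setequal(names(background), AA_ALPHABET20) ||
      abs(sum(background) - 1) > 1e-8)
    stop("background must be a probability vector over the 20 residues",
         call. = FALSE)
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")),
               motif_library)
  if (any(bad))
    stop("motif(s) contain non-standard residues: ",
         paste(motif_library[bad], collapse = ", "), call. = FALSE)
  if (length_range[1] < motif_copies * max(nchar(motif_library)))
    stop("minimum length too short for ", motif_copies, " motif copies",
         call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 motif_library = motif_library,
                 signal_strength = signal_strength,
                 motif_copies = as.integer(motif_copies),
                 background = background[AA_ALPHABET20],
                 role_fractions = role_fractions,
                 lag = as.integer(lag), seed = as.integer(seed)),
            class = "synthesis_config")
}

#' Composition-skewed background preset
#'
#' Residue probabilities proportional to `rank + 5` in alphabet order —
#' a mild but systematic compositional bias used to stress descriptor
#' normalization.
#'
#' @return Named probability vector over the 20 residues.
#' @export
skewed_background <- function() {
  w <- seq_len(20) + 5
  stats::setNames(w / sum(w), AA_ALPHABET20)
}

# overwrite `copies` non-overlapping occurrences of motif into chars
plant_motif <- function(chars, motif, copies) {
  mlen <- nchar(motif)
  mchars <- strsplit(motif, "")[[1L]]
  # divide the sequence into `copies` blocks and place one copy per block,
  # guaranteeing non-overlap
  L <- length(chars)
  block <- L %/% copies
  for (c_i in seq_len(copies)) {
    lo <- (c_i - 1L) * block + 1L
    hi <- min(c_i * block, L) - mlen + 1L
    start <- if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    chars[start:(start + mlen - 1L)] <- mchars
  }
  chars
}

#' Generate a synthetic proteome
#'
#' Samples `n_proteins` sequences with uniform lengths in `length_range`
#' and residues drawn from the background distribution, then assigns roles
#' (bait / prey / background per `role_fractions`) and plants the library
#' motifs into bait and prey proteins with probability `signal_strength`.
#'
#' @param config A [synthesis_config()].
#' @return Named list of protein records; the role of each protein is in
#'   attribute `"roles"`, motif carriage in attribute `"carries_motif"`.
#' @export
generate_proteome <- function(config) {
  n <- config$n_proteins
  n_bait <- floor(config$role_fractions[["bait"]] * n)
  n_prey <- floor(config$role_fractions[["prey"]] * n)
  roles <- rep(c("bait", "prey", "background"),
               c(n_bait, n_prey, n - n_bait - n_prey))
  with_seed(derive_seed(config$seed, 41L), {
    lens <- sample(config$length_range[1]:config$length_range[2], n,
                   replace = TRUE)
    carries <- logical(n)
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      chars <- sample(AA_ALPHABET20, lens[i], replace = TRUE,
                      prob = config$background)
      motif <- switch(roles[i], bait = config$motif_library[1L],
                      prey = config$motif_library[2L], NULL)
      if (!is.null(motif) && stats::runif(1) < config$signal_strength) {
        chars <- plant_motif(chars, motif, config$motif_copies)
        carries[i] <- TRUE
      }
      recs[[i]] <- protein_record(sprintf("prot%04d", i),
                                  paste(chars, collapse = ""))
    }
    names(recs) <- vapply(recs, `[[`, character(1), "id")
    attr(recs, "roles") <- stats::setNames(roles, names(recs))
    attr(recs, "carries_motif") <- stats::setNames(carries, names(recs))
    recs
  })
}

# sample `n` distinct ordered pairs (i from A, j from B); A and B disjoint
sample_cross_pairs <- function(a_ids, b_ids, n) {
  total <- length(a_ids) * length(b_ids)
  if (n > total)
    stop("requested ", n, " pairs but only ", total, " are available",
         call. = FALSE)
  idx <- sample.int(total, n)
  data.frame(id_a = a_ids[(idx - 1L) %/% length(b_ids) + 1L],
             id_b = b_ids[(idx - 1L) %% length(b_ids) + 1L])
}

# sample `n` distinct ordered pairs (i, j), i != j, within one id set
sample_within_pairs <- function(ids, n) {
  m <- length(ids)
  total <- m * (m - 1L)
  if (n > total)
    stop("requested ", n, " pairs but only ", total, " are available",
         call. = FALSE)
  idx <- sample.int(total, n)
  i <- (idx - 1L) %/% (m - 1L) + 1L
  j <- (idx - 1L) %% (m - 1L) + 1L
  j <- j + (j >= i)
  data.frame(id_a = ids[i], id_b = ids[j])
}

#' Generate labeled interaction pairs over a synthetic proteome
#'
#' Interacting pairs are ordered (bait, prey) pairs — proteins into which
#' complementary motifs were planted (with probability `signal_strength`
#' each). Non-interacting pairs are sampled among motif-free background
#' proteins. No ordered pair is duplicated within or across classes.
#'
#' @param proteome Result of [generate_proteome()] (role attributes
#'   required).
#' @param config The same [synthesis_config()].
#' @return A [labeled_pair_set()].
#' @export
generate_pairs <- function(proteome, config) {
  if (length(proteome) == 0L) stop("empty proteome", call. = FALSE)
  roles <- attr(proteome, "roles")
  if (is.null(roles))
    stop("proteome lacks role annotations; use generate_proteome()",
         call. = FALSE)
  ids <- names(proteome)
  with_seed(derive_seed(config$seed, 42L), {
    pos <- sample_cross_pairs(ids[roles == "bait"], ids[roles == "prey"],
                              config$n_pos)
    neg <- sample_within_pairs(ids[roles == "background"], config$n_neg)
    labeled_pair_set(pos, neg)
  })
}

#' Generate a complete synthetic data set
#'
#' @param config A [synthesis_config()].
#' @return List with `proteins` and `pairs`.
#' @export
generate_ppi_dataset <- function(config = synthesis_config()) {
  proteins <- generate_proteome(config)
  list(proteins = proteins, pairs = generate_pairs(proteins, config))
}
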