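# Conjoint Triad (CT) and Autocovariance (AC) sequence descriptors.
#
# A protein of cleaned length L is represented by the concatenation
# [AC | CT]: m*lag lagged autocovariances of standardized physico-chemical
# property scales followed by 343 normalized frequencies of ordered triples
# of the seven conjoint amino-acid classes.

# Seven-class grouping of Shen et al.: dipole / side-chain-volume clusters.
SHEN_CLASSES <- list(
  c("A", "G", "V"),
  c("I", "L", "F", "P"),
  c("Y", "M", "T", "S"),
  c("H", "N", "Q", "W"),
  c("R", "K"),
  c("D", "E"),
  c("C")
)

default_class_map <- function() {
  map <- integer(20)
  names(map) <- AA_ALPHABET20
  for (k in seq_along(SHEN_CLASSES)) map[SHEN_CLASSES[[k]]] <- k
  map
}

#' Load an amino-acid property table
#'
#' Reads a tab-separated table with a `property` name column and one column
#' per standard residue. The bundled default carries 14 published scales:
#' two hydrophobicity scales, hydrophilicity, net side-chain charge, two
#' polarity scales, polarizability, solvent-accessible surface area,
#' side-chain volume, flexibility, accessibility, exposed surface, turn
#' propensity and antigenic propensity. Any m x 20 table is accepted.
#'
#' @param path Path to a property TSV; default is the bundled 14-scale table.
#' @return Numeric matrix (m scales x 20 residues, columns in standard order).
#' @export
read_property_table <- function(path = system.file("extdata",
                                                   "aa_properties_14.tsv",
                                                   package = "aeppi")) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"property" %in% names(df))
    stop("property table needs a 'property' name column", call. = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), "property"), drop = FALSE])
  rownames(mat) <- df$property
  if (!setequal(colnames(mat), AA_ALPHABET20))
    stop("property table must have exactly the 20 standard residue columns",
         call. = FALSE)
  storage.mode(mat) <- "double"
  mat[, AA_ALPHABET20, drop = FALSE]
}

#' Descriptor configuration
#'
#' Fixes everything the featurization depends on: the AC lag, the property
#' scales, the CT normalization mode and the seven-class residue grouping.
#' Two feature vectors are only comparable when they share the configuration
#' fingerprint.
#'
#' @param lag Maximum position offset for the autocovariance; must be smaller
#'   than every sequence length that will be featurized.
#' @param property_table m x 20 numeric matrix of property scales (columns
#'   named by residue); default is the bundled 14-scale table.
#' @param ct_normalization `"minmax"` (per-protein `(f - min f) / max f`,
#'   matching the common descriptor-toolkit convention) or
#'   `"relative_frequency"` (`f / (L - 2)`).
#' @param class_map Named integer vector mapping each of the 20 residues to a
#'   class in 1..7; default is the Shen grouping.
#' @return A `descriptor_config` with a precomputed `fingerprint`.
#' @export
descriptor_config <- function(lag = 30L,
                              property_table = read_property_table(),
                              ct_normalization = c("minmax",
                                                   "relative_frequency"),
                              class_map = default_class_map()) {
  ct_normalization <- match.arg(ct_normalization)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1", call. = FALSE)
  property_table <- as.matrix(property_table)
  if (ncol(property_table) != 20L || nrow(property_table) < 1L)
    stop("property_table must be an m x 20 matrix (m >= 1)", call. = FALSE)
  if (!setequal(colnames(property_table), AA_ALPHABET20))
    stop("property_table columns must be the 20 standard residues",
         call. = FALSE)
  property_table <- property_table[, AA_ALPHABET20, drop = FALSE]
  if (!setequal(names(class_map), AA_ALPHABET20) ||
      !setequal(unique(class_map), 1:7))
    stop("class_map must cover the 20 residues with exactly 7 classes",
         call. = FALSE)
  class_map <- class_map[AA_ALPHABET20]
  cfg <- structure(list(lag = lag,
                        property_table = property_table,
                        ct_normalization = ct_normalization,
                        class_map = class_map),
                   class = "descriptor_config")
  cfg$fingerprint <- rlang::hash(list(lag, unname(property_table),
                                      rownames(property_table),
                                      ct_normalization, unname(class_map)))
  cfg
}

#' @export
print.descriptor_config <- function(x, ...) {
  cat("<descriptor_config> lag=", x$lag, ", m=", nrow(x$property_table),
      " scales, ct_normalization=", x$ct_normalization,
      ", k=", feature_length(x), "\n  fingerprint ", x$fingerprint, "\n",
      sep = "")
  invisible(x)
}

#' Per-protein feature length k = 343 + m*lag
#' @param config A [descriptor_config()].
#' @return Integer feature length.
#' @export
feature_length <- function(config) {
  343L + nrow(config$property_table) * config$lag
}

seq_to_ints <- function(seq) {
  idx <- match(strsplit(seq, "")[[1L]], AA_ALPHABET20)
  if (anyNA(idx))
    stop("sequence contains non-standard residues; clean_sequence() first",
         call. = FALSE)
  idx
}

#' Conjoint Triad features
#'
#' Maps residues to the seven conjoint classes, slides a window of size 3
#' over the sequence and counts each of the 7^3 = 343 ordered class triples,
#' linearized class-1-major: index `(c1-1)*49 + (c2-1)*7 + c3`. Counts are
#' normalized per `config$ct_normalization`.
#'
#' @param seq Cleaned sequence of length >= 3.
#' @param config A [descriptor_config()].
#' @return Numeric vector of length 343.
#' @export
ct_features <- function(seq, config) {
  counts <- ct_counts(seq, config)
  if (config$ct_normalization == "minmax") {
    (counts - min(counts)) / max(counts)
  } else {
    counts / sum(counts)
  }
}

# Raw triad counts (length 343); sum(ct_counts) == L - 2.
ct_counts <- function(seq, config) {
  cls <- unname(config$class_map)[seq_to_ints(seq)]
  L <- length(cls)
  if (L < 3L)
    stop("conjoint-triad features need at least 3 residues (got ", L, ")",
         call. = FALSE)
  idx <- (cls[1:(L - 2L)] - 1L) * 49L + (cls[2:(L - 1L)] - 1L) * 7L +
    cls[3:L]
  tabulate(idx, nbins = 343L)
}

#' Autocovariance features
#'
#' Each property scale is standardized to zero mean and unit (sample)
#' standard deviation over the 20 residues, then for each scale j and each
#' offset d in 1..lag the lagged autocovariance along the sequence is
#' computed:
#' `AC(j, d) = sum_i (x_i - xbar)(x_{i+d} - xbar) / (L - d)`,
#' where x is the standardized property evaluated at each residue and xbar
#' its mean over the whole sequence. Output is property-major: scale 1 lags
#' 1..lag, then scale 2, etc.
#'
#' @param seq Cleaned sequence of length > `config$lag`.
#' @param config A [descriptor_config()].
#' @return Numeric vector of length `m * lag`.
#' @export
ac_features <- function(seq, config) {
  ints <- seq_to_ints(seq)
  L <- length(ints)
  lag <- config$lag
  if (L <= lag)
    stop("autocovariance needs sequence length > lag (length ", L,
         ", lag ", lag, ")", call. = FALSE)
  pt <- standardize_properties(config$property_table)
  m <- nrow(pt)
  out <- numeric(m * lag)
  for (j in seq_len(m)) {
    x <- pt[j, ints]
    xc <- x - mean(x)
    for (d in seq_len(lag)) {
      out[(j - 1L) * lag + d] <-
        sum(xc[1:(L - d)] * xc[(1L + d):L]) / (L - d)
    }
  }
  out
}

standardize_properties <- function(pt) {
  mu <- rowMeans(pt)
  sdv <- apply(pt, 1L, stats::sd)
  if (any(sdv == 0))
    stop("constant property scale cannot be standardized", call. = FALSE)
  (pt - mu) / sdv
}

#' Featurize one protein
#'
#' Cleans the sequence and concatenates autocovariance then conjoint-triad
#' features into the length-k protein representation.
#'
#' @param record A [protein_record()].
#' @param config A [descriptor_config()].
#' @return A `feature_vector`: list with `protein_id`, numeric `values` of
#'   length `feature_length(config)` and the config `fingerprint`.
#' @export
protein_features <- function(record, config) {
  seq <- clean_sequence(record$sequence)
  values <- c(ac_features(seq, config), ct_features(seq, config))
  if (!all(is.finite(values)))
    stop("non-finite feature values for protein ", record$id, call. = FALSE)
  structure(list(protein_id = record$id, values = values,
                 config_fingerprint = config$fingerprint),
            class = "feature_vector")
}

#' Featurize a set of proteins into a matrix
#'
#' @param records Named list of protein records.
#' @param config A [descriptor_config()].
#' @return Numeric matrix (one row per protein, rownames are ids) with the
#'   config fingerprint in attribute `"fingerprint"`.
#' @export
feature_matrix <- function(records, config) {
  k <- feature_length(config)
  out <- matrix(0, nrow = length(records), ncol = k)
  for (i in seq_along(records)) {
    fv <- tryCatch(protein_features(records[[i]], config), error = function(e)
      stop("featurization failed for protein '", records[[i]]$id, "': ",
           conditionMessage(e), call. = FALSE))
    out[i, ] <- fv$values
  }
  rownames(out) <- unname(vapply(records, `[[`, character(1), "id"))
  attr(out, "fingerprint") <- config$fingerprint
  out
}

#' Concatenate two protein feature vectors into a pair vector
#'
#' @param fa,fb `feature_vector` objects sharing the same configuration
#'   fingerprint.
#' @return Numeric vector of length 2k: `c(fa$values, fb$values)`.
#' @export
pair_vector <- function(fa, fb) {
  if (!identical(fa$config_fingerprint, fb$config_fingerprint))
    stop("feature vectors come from different descriptor configurations",
         call. = FALSE)
  c(fa$values, fb$values)
}

# Pair feature matrix for a data.frame of (id_a, id_b) against a feature
# matrix with rownames; rows are [features(a) | features(b)].
pair_matrix <- function(pairs_df, fmat) {
  ia <- match(pairs_df$id_a, rownames(fmat))
  ib <- match(pairs_df$id_b, rownames(fmat))
  if (anyNA(ia) || anyNA(ib))
    stop("pair references protein id(s) missing from the feature matrix",
         call. = FALSE)
  out <- cbind(fmat[ia, , drop = FALSE], fmat[ib, , drop = FALSE])
  rownames(out) <- NULL  # protein ids may repeat across pairs
  out
}

#' Export a feature matrix as TSV
#'
#' @param fmat Matrix from [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fmat, path) {
  df <- data.frame(protein_id = rownames(fmat), fmat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
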