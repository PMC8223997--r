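# Confusion-matrix metrics, k-fold cross-validation and confidence
# intervals.

#' Confusion matrix for binary interaction labels
#'
#' "Positive" means interacting.
#'
#' @param preds,truth Vectors of `"positive"`/`"negative"` labels (factors
#'   or characters) of equal length.
#' @return A `confusion_matrix` list with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(preds, truth) {
  preds <- as.character(preds)
  truth <- as.character(truth)
  if (length(preds) != length(truth))
    stop("preds and truth differ in length", call. = FALSE)
  ok <- c("positive", "negative")
  if (!all(preds %in% ok) || !all(truth %in% ok))
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  structure(list(tp = sum(preds == "positive" & truth == "positive"),
                 fp = sum(preds == "positive" & truth == "negative"),
                 tn = sum(preds == "negative" & truth == "negative"),
                 fn = sum(preds == "negative" & truth == "positive")),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> tp=", x$tp, " fp=", x$fp, " tn=", x$tn,
      " fn=", x$fn, "\n", sep = "")
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' `accuracy = (TP+TN)/total`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `specificity = TN/(TN+FP)`, F1 is the harmonic
#' mean of precision and recall, and `auc_balanced = (specificity +
#' recall)/2` — the balanced accuracy, reported here under the name the
#' evaluation protocol uses for it. A degenerate denominator yields 0 with
#' a warning rather than NaN.
#'
#' @param cm A [confusion()] result, or a list with `tp`, `fp`, `tn`, `fn`.
#' @return Named list of the six metrics, class `metrics_report`.
#' @export
ppi_metrics <- function(cm) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("degenerate denominator for ", what, "; reporting 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  precision <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  recall <- safe_div(cm$tp, cm$tp + cm$fn, "recall")
  specificity <- safe_div(cm$tn, cm$tn + cm$fp, "specificity")
  f1 <- if (precision + recall == 0) {
    warning("degenerate denominator for f1; reporting 0", call. = FALSE)
    0
  } else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = safe_div(cm$tp + cm$tn, total, "accuracy"),
                 precision = precision, recall = recall,
                 specificity = specificity, f1 = f1,
                 auc_balanced = (specificity + recall) / 2),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  vals <- unlist(x)
  cat("<metrics_report>\n")
  for (nm in names(vals))
    cat(sprintf("  %-12s %.4f\n", nm, vals[nm]))
  invisible(x)
}

#' Rank-based ROC AUC (diagnostic only)
#'
#' Conventional area under the ROC curve over interaction scores. Provided
#' for diagnostics; the evaluation protocol's "AUC" is the balanced
#' accuracy `(specificity + recall)/2` computed by [ppi_metrics()].
#'
#' @param scores Numeric interaction scores (higher = more likely positive).
#' @param truth `"positive"`/`"negative"` labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  if (!requireNamespace("pROC", quietly = TRUE))
    stop("the pROC package is required for roc_auc()", call. = FALSE)
  as.numeric(pROC::auc(pROC::roc(
    response = factor(as.character(truth), levels = c("negative", "positive")),
    predictor = scores, quiet = TRUE, direction = "<")))
}

#' Student-t confidence interval of a mean
#'
#' `mean +/- t_{(1+level)/2, n-1} * s / sqrt(n)` with `s` the sample
#' standard deviation.
#'
#' @param values At least two numeric values (e.g. per-fold metrics).
#' @param level Confidence level, default 0.95.
#' @return List with `mean` and `half_width`.
#' @export
confidence_interval <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a confidence interval",
                   call. = FALSE)
  hw <- stats::qt((1 + level) / 2, df = n - 1L) * stats::sd(values) / sqrt(n)
  list(mean = mean(values), half_width = hw)
}

# Seeded per-class fold assignment: shuffle indices, deal them round-robin
# into k folds. Returns an integer vector of fold ids.
fold_assignments <- function(n, k, seed) {
  with_seed(seed, {
    folds <- integer(n)
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
    folds
  })
}

# Default model engine: fit the two-autoencoder classifier, predict labels.
# An engine is a list(fit = function(train_pos, train_neg, fold_seed),
# predict = function(fit, X) -> factor labels or data.frame with $label).
aeppi_engine <- function(arch, tconfig, widths = c(600L, 600L, 300L)) {
  list(
    fit = function(train_pos, train_neg, fold_seed) {
      cfg <- tconfig
      cfg$seed <- fold_seed
      aeppi_fit(train_pos, train_neg, arch = arch, tconfig = cfg,
                widths = widths)
    },
    predict = function(fit, X) aeppi_predict(fit, X)$label
  )
}

#' k-fold cross-validation of the interaction classifier
#'
#' Each class is shuffled (seeded) and partitioned into k folds
#' independently, preserving the per-class train/test proportions. For each
#' fold the model is fitted on the remaining k-1 folds of both classes and
#' evaluated on the held-out fold; per-fold metrics are averaged and a 95%
#' Student-t confidence interval of each mean is reported.
#'
#' @param proteins Named list of protein records.
#' @param pairs A [labeled_pair_set()].
#' @param k Number of folds (>= 2; each class must have >= k pairs).
#' @param arch Architecture tag.
#' @param tconfig A [training_config()].
#' @param dconfig A [descriptor_config()].
#' @param seed Seed controlling fold assignment and per-fold training.
#' @param widths Encoder widths (see [build_autoencoder()]).
#' @param engine Optional custom fit/predict engine (used e.g. for harness
#'   tests); defaults to the two-autoencoder classifier.
#' @return A `cv_report`: list with `folds` (data frame of per-fold
#'   metrics), `mean` and `ci_half_width` (named numeric vectors), `k`.
#' @export
cross_validate <- function(proteins, pairs, k = 5L, arch = "siamese_siamese",
                           tconfig = desk_training_config(),
                           dconfig = descriptor_config(),
                           seed = 1L, widths = c(600L, 600L, 300L),
                           engine = NULL) {
  k <- as.integer(k)
  npos <- nrow(pairs$positives)
  nneg <- nrow(pairs$negatives)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (npos < k || nneg < k)
    stop("each class needs at least k pairs (have ", npos, " positives, ",
         nneg, " negatives, k = ", k, ")", call. = FALSE)
  if (is.null(engine)) engine <- aeppi_engine(arch, tconfig)

  ids <- unique(c(pairs$positives$id_a, pairs$positives$id_b,
                  pairs$negatives$id_a, pairs$negatives$id_b))
  missing <- setdiff(ids, names(proteins))
  if (length(missing) > 0L)
    stop("pairs reference unknown protein id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  fmat <- feature_matrix(proteins[ids], dconfig)
  Xpos <- pair_matrix(pairs$positives, fmat)
  Xneg <- pair_matrix(pairs$negatives, fmat)

  fold_pos <- fold_assignments(npos, k, derive_seed(seed, 31L))
  fold_neg <- fold_assignments(nneg, k, derive_seed(seed, 32L))

  metric_names <- c("accuracy", "precision", "recall", "specificity", "f1",
                    "auc_balanced")
  folds <- as.data.frame(matrix(NA_real_, nrow = k,
                                ncol = length(metric_names),
                                dimnames = list(NULL, metric_names)))
  for (fold in seq_len(k)) {
    tr_pos <- Xpos[fold_pos != fold, , drop = FALSE]
    tr_neg <- Xneg[fold_neg != fold, , drop = FALSE]
    te <- rbind(Xpos[fold_pos == fold, , drop = FALSE],
                Xneg[fold_neg == fold, , drop = FALSE])
    truth <- rep(c("positive", "negative"),
                 c(sum(fold_pos == fold), sum(fold_neg == fold)))
    fit <- engine$fit(tr_pos, tr_neg, derive_seed(seed, 100L + fold))
    preds <- engine$predict(fit, te)
    if (is.data.frame(preds)) preds <- preds$label
    m <- ppi_metrics(confusion(preds, truth))
    folds[fold, ] <- unlist(m)
  }
  folds <- cbind(fold = seq_len(k), folds)
  cis <- lapply(metric_names, function(nm) confidence_interval(folds[[nm]]))
  structure(list(folds = folds,
                 mean = stats::setNames(vapply(cis, `[[`, numeric(1),
                                               "mean"), metric_names),
                 ci_half_width = stats::setNames(vapply(cis, `[[`,
                                                        numeric(1),
                                                        "half_width"),
                                                 metric_names),
                 k = k, architecture = arch, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  cat("<cv_report> ", x$k, "-fold, architecture ", x$architecture, "\n",
      sep = "")
  for (nm in names(x$mean))
    cat(sprintf("  %-12s %s ± %s\n", nm,
                format(round(x$mean[nm], digits), nsmall = digits),
                format(round(x$ci_half_width[nm], digits),
                       nsmall = digits)))
  invisible(x)
}

#' Write a cross-validation report to TSV and JSON
#'
#' The TSV has one row per fold plus a summary row formatted
#' `mean ± half_width` per metric.
#'
#' @param report A `cv_report`.
#' @param path_tsv,path_json Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_cv_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    df <- report$folds
    df[] <- lapply(df, function(col) if (is.numeric(col))
      format(round(col, 4), nsmall = 0) else col)
    summary_row <- c(fold = "mean",
                     vapply(names(report$mean), function(nm)
                       sprintf("%.4f ± %.4f", report$mean[nm],
                               report$ci_half_width[nm]), character(1)))
    utils::write.table(rbind(df, summary_row), path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(k = report$k,
                              architecture = report$architecture,
                              folds = report$folds,
                              mean = as.list(report$mean),
                              ci_half_width = as.list(report$ci_half_width)),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
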