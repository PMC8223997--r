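# Two-autoencoder interaction classifier.
#
# One autoencoder is trained on interacting pairs (C+), one on
# non-interacting pairs (C-). A new pair is scored by both reconstruction
# losses; the probability of non-interaction is
#   pr- = 0.5 + (L+ - L-) / (2 * (L+ + L-)),    pr+ = 1 - pr-,
# so the pair is called interacting exactly when L+ < L-.

#' Convert a pair of reconstruction losses into class probabilities
#'
#' Vectorized over loss pairs. The degenerate case `L+ = L- = 0` is defined
#' as `pr- = 0.5` (by the symmetry of the formula); ties classify as
#' negative (the positive call requires strictly `L+ < L-`).
#'
#' @param loss_pos,loss_neg Non-negative reconstruction losses under the
#'   positive-class and negative-class autoencoder.
#' @return Data frame with columns `loss_pos`, `loss_neg`, `pr_pos`,
#'   `pr_neg`, `label` (factor positive/negative).
#' @export
interaction_probability <- function(loss_pos, loss_neg) {
  if (length(loss_pos) == 1L) loss_pos <- rep(loss_pos, length(loss_neg))
  if (length(loss_neg) == 1L) loss_neg <- rep(loss_neg, length(loss_pos))
  stopifnot(length(loss_pos) == length(loss_neg),
            all(loss_pos >= 0), all(loss_neg >= 0))
  tot <- loss_pos + loss_neg
  pr_neg <- ifelse(tot > 0, 0.5 + (loss_pos - loss_neg) / (2 * tot), 0.5)
  pr_pos <- 1 - pr_neg
  label <- factor(ifelse(pr_pos > 0.5, "positive", "negative"),
                  levels = c("positive", "negative"))
  data.frame(loss_pos = loss_pos, loss_neg = loss_neg,
             pr_pos = pr_pos, pr_neg = pr_neg, label = label)
}

#' Fit the two-autoencoder interaction model
#'
#' Trains one autoencoder on the positive-class pair vectors and one on the
#' negative-class pair vectors, independently but with identical
#' hyperparameters (each with its own seeded validation split).
#'
#' @param train_pos,train_neg Matrices of pair vectors (rows are pairs, 2k
#'   columns) for C+ and C-.
#' @param arch Architecture tag (see [build_autoencoder()]).
#' @param tconfig A [training_config()].
#' @param widths Encoder widths passed to [build_autoencoder()].
#' @param fingerprint Optional descriptor-config fingerprint recorded on the
#'   model and checked at prediction time.
#' @return An `aeppi_model` with components `ae_pos`, `ae_neg`, the
#'   training logs and the fingerprint.
#' @export
aeppi_fit <- function(train_pos, train_neg, arch = "siamese_siamese",
                      tconfig = training_config(),
                      widths = c(600L, 600L, 300L), fingerprint = NULL) {
  if (is.list(train_pos) && !is.matrix(train_pos))
    train_pos <- do.call(rbind, train_pos)
  if (is.list(train_neg) && !is.matrix(train_neg))
    train_neg <- do.call(rbind, train_neg)
  if (!is.matrix(train_pos) || nrow(train_pos) == 0L)
    stop("positive class is empty", call. = FALSE)
  if (!is.matrix(train_neg) || nrow(train_neg) == 0L)
    stop("negative class is empty", call. = FALSE)
  if (ncol(train_pos) != ncol(train_neg))
    stop("positive and negative pair vectors differ in length",
         call. = FALSE)
  if (ncol(train_pos) %% 2L != 0L)
    stop("pair vectors must have even length 2k", call. = FALSE)
  k <- ncol(train_pos) %/% 2L

  cfg_pos <- tconfig; cfg_pos$seed <- derive_seed(tconfig$seed, 11L)
  cfg_neg <- tconfig; cfg_neg$seed <- derive_seed(tconfig$seed, 12L)
  ae_pos <- build_autoencoder(arch, k, seed = derive_seed(tconfig$seed, 21L),
                              widths = widths)
  ae_neg <- build_autoencoder(arch, k, seed = derive_seed(tconfig$seed, 22L),
                              widths = widths)
  fit_pos <- train_autoencoder(ae_pos, train_pos, cfg_pos)
  fit_neg <- train_autoencoder(ae_neg, train_neg, cfg_neg)

  structure(list(ae_pos = fit_pos$model, ae_neg = fit_neg$model,
                 architecture = arch, k = k,
                 fingerprint = fingerprint,
                 log_pos = fit_pos$log, log_neg = fit_neg$log),
            class = "aeppi_model")
}

#' @export
print.aeppi_model <- function(x, ...) {
  cat("<aeppi_model> ", x$architecture, ", k=", x$k,
      "\n  final val loss: AE+ ",
      format(utils::tail(x$log_pos$val_loss, 1), digits = 4),
      ", AE- ", format(utils::tail(x$log_neg$val_loss, 1), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Score featurized pairs with a fitted model
#'
#' Computes both reconstruction losses for each pair and converts them into
#' interaction probabilities via [interaction_probability()].
#'
#' @param model An `aeppi_model`.
#' @param pairs Matrix of pair vectors (2k columns), or a single pair
#'   vector.
#' @param fingerprint Optional descriptor fingerprint of `pairs`; if both
#'   this and the model's fingerprint are non-NULL they must match.
#' @return Data frame as from [interaction_probability()], one row per
#'   pair (rownames preserved from `pairs`).
#' @export
aeppi_predict <- function(model, pairs, fingerprint = NULL) {
  if (!is.null(fingerprint) && !is.null(model$fingerprint) &&
      !identical(fingerprint, model$fingerprint))
    stop("descriptor fingerprint mismatch between model and features",
         call. = FALSE)
  X <- as_pair_matrix(model$ae_pos, pairs)
  res <- interaction_probability(reconstruction_loss(model$ae_pos, X),
                                 reconstruction_loss(model$ae_neg, X))
  rownames(res) <- rownames(pairs)
  res
}

#' Predict a list of protein-id pairs
#'
#' Featurizes each referenced protein once, assembles the ordered pair
#' vectors and scores them; row order follows the input.
#'
#' @param model An `aeppi_model`.
#' @param pairs_df Data frame with columns `id_a`, `id_b`.
#' @param proteins Named list of protein records.
#' @param dconfig The [descriptor_config()] the model was trained under.
#' @return Data frame with `id_a`, `id_b`, losses, probabilities and label.
#' @export
aeppi_predict_pairs <- function(model, pairs_df, proteins, dconfig) {
  if (nrow(pairs_df) == 0L)
    return(cbind(pairs_df[, c("id_a", "id_b")],
                 interaction_probability(numeric(0), numeric(0))))
  ids <- unique(c(pairs_df$id_a, pairs_df$id_b))
  missing <- setdiff(ids, names(proteins))
  if (length(missing) > 0L)
    stop("pairs reference unknown protein id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  fmat <- feature_matrix(proteins[ids], dconfig)
  res <- aeppi_predict(model, pair_matrix(pairs_df, fmat),
                       fingerprint = attr(fmat, "fingerprint"))
  cbind(pairs_df[, c("id_a", "id_b")], res, row.names = NULL)
}

#' Save / load a fitted interaction model
#'
#' Single-file bundle with a versioned header; the descriptor configuration
#' may be embedded so that prediction can re-featurize new sequences
#' consistently (it is attached as attribute `"dconfig"` on load).
#'
#' @param model An `aeppi_model`.
#' @param path Bundle file path.
#' @param dconfig Optional [descriptor_config()] to embed.
#' @return `path` invisibly (save); the model (load).
#' @export
save_aeppi <- function(model, path, dconfig = NULL) {
  saveRDS(list(format = "aeppi-model", version = 1L, model = model,
               dconfig = dconfig), path)
  invisible(path)
}

#' @rdname save_aeppi
#' @export
load_aeppi <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "aeppi-model"))
    stop("not an aeppi model bundle: ", path, call. = FALSE)
  model <- obj$model
  attr(model, "dconfig") <- obj$dconfig
  model
}
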