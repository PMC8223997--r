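# Fully connected autoencoders over pair feature vectors.
#
# Three architectures share the same layer recipe (encoder 600-600-300,
# mirrored decoder, SELU activations, linear output):
#   joint_joint     : one network on the concatenated 2k pair vector.
#   siamese_joint   : a weight-shared per-protein encoder produces codes
#                     z, z'; a joint decoder reconstructs the 2k pair from
#                     concat(z, z').
#   siamese_siamese : shared encoder; combined code zhat = z * z'
#                     (element-wise); a shared decoder maps concat(z, zhat)
#                     to a reconstruction of p and concat(z', zhat) to a
#                     reconstruction of p'.
# Training minimizes mean squared reconstruction error with Adam and a
# reduce-on-plateau learning-rate schedule.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(z) SELU_LAMBDA * (pmax(z, 0) + SELU_ALPHA * expm1(pmin(z, 0)))

# derivative of selu wrt its pre-activation
selu_grad <- function(z) {
  SELU_LAMBDA * ((z > 0) + SELU_ALPHA * exp(pmin(z, 0)) * (z <= 0))
}

# Evaluate expr with a private, seeded RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic fan-out of one seed into component seeds (kept < 2^31)
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6) * 2039 + 1000003 * i) %% 2147483647L
}

## ---- minimal MLP ---------------------------------------------------------

# dims: layer widths input..output; SELU on every layer except the last
# (linear output). LeCun-normal init (sd = 1/sqrt(fan_in)), the standard
# companion of SELU; biases zero. Caller provides RNG state.
mlp_new <- function(dims, act_last = FALSE) {
  nl <- length(dims) - 1L
  W <- vector("list", nl)
  b <- vector("list", nl)
  for (l in seq_len(nl)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                  sd = 1 / sqrt(dims[l])),
                     nrow = dims[l], ncol = dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(dims = dims, W = W, b = b, act_last = act_last)
}

mlp_fwd <- function(net, X, cache = FALSE) {
  nl <- length(net$W)
  A <- X
  Zs <- if (cache) vector("list", nl) else NULL
  As <- if (cache) vector("list", nl + 1L) else NULL
  if (cache) As[[1L]] <- X
  for (l in seq_len(nl)) {
    Z <- A %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))
    A <- if (l < nl || isTRUE(net$act_last)) selu(Z) else Z
    if (cache) {
      Zs[[l]] <- Z
      As[[l + 1L]] <- A
    }
  }
  list(out = A, Zs = Zs, As = As)
}

# dOut: gradient wrt the network output. Returns weight/bias grads and the
# gradient wrt the input.
mlp_bwd <- function(net, fw, dOut) {
  nl <- length(net$W)
  dW <- vector("list", nl)
  db <- vector("list", nl)
  dA <- dOut
  for (l in rev(seq_len(nl))) {
    dZ <- if (l < nl || isTRUE(net$act_last)) dA * selu_grad(fw$Zs[[l]])
          else dA
    dW[[l]] <- crossprod(fw$As[[l]], dZ)
    db[[l]] <- colSums(dZ)
    dA <- tcrossprod(dZ, net$W[[l]])
  }
  list(dW = dW, db = db, dX = dA)
}

mlp_params <- function(net) c(net$W, net$b)

mlp_copy <- function(net) {
  net$W <- lapply(net$W, function(w) w + 0)
  net$b <- lapply(net$b, function(b) b + 0)
  net
}

## ---- architectures -------------------------------------------------------

ARCHITECTURES <- c("joint_joint", "siamese_joint", "siamese_siamese")

#' Build an untrained pair autoencoder
#'
#' @param arch One of `"joint_joint"`, `"siamese_joint"`,
#'   `"siamese_siamese"`.
#' @param k Per-protein feature length; the pair vector has length 2k.
#' @param seed Integer seed for the (LeCun-normal) weight initialization.
#' @param widths Encoder layer widths `c(hidden1, hidden2, bottleneck)`;
#'   default `c(600, 600, 300)`. The decoder mirrors the hidden widths and
#'   ends in a linear layer sized to the reconstruction target.
#' @return A `ppi_autoencoder` object.
#' @export
build_autoencoder <- function(arch, k, seed = 1L, widths = c(600L, 600L, 300L)) {
  if (length(arch) != 1L || !arch %in% ARCHITECTURES)
    stop("unknown architecture: ", paste(arch, collapse = ","),
         " (expected one of ", paste(ARCHITECTURES, collapse = ", "), ")",
         call. = FALSE)
  stopifnot(k >= 1, length(widths) == 3L, all(widths >= 1))
  k <- as.integer(k)
  w1 <- widths[1L]; w2 <- widths[2L]; wb <- widths[3L]
  nets <- with_seed(seed, {
    if (arch == "joint_joint") {
      list(net = mlp_new(c(2L * k, w1, w2, wb, w2, w1, 2L * k)))
    } else if (arch == "siamese_joint") {
      list(encoder = mlp_new(c(k, w1, w2, wb), act_last = TRUE),
           decoder = mlp_new(c(2L * wb, w2, w1, 2L * k)))
    } else {
      list(encoder = mlp_new(c(k, w1, w2, wb), act_last = TRUE),
           decoder = mlp_new(c(2L * wb, w2, w1, k)))
    }
  })
  structure(c(list(architecture = arch, k = k, widths = as.integer(widths),
                   trained = FALSE), nets),
            class = "ppi_autoencoder")
}

#' @export
print.ppi_autoencoder <- function(x, ...) {
  cat("<ppi_autoencoder> ", x$architecture, ", k=", x$k,
      ", widths=", paste(x$widths, collapse = "-"),
      if (isTRUE(x$trained)) ", trained" else ", untrained", "\n", sep = "")
  invisible(x)
}

as_pair_matrix <- function(model, pair) {
  X <- if (is.matrix(pair)) pair else matrix(pair, nrow = 1L)
  if (ncol(X) != 2L * model$k)
    stop("pair vector length ", ncol(X), " does not match model (2k = ",
         2L * model$k, ")", call. = FALSE)
  X
}

# Forward pass; returns reconstruction of the full 2k vector plus caches
# needed for backprop.
ae_fwd <- function(model, X, cache = FALSE) {
  k <- model$k
  if (model$architecture == "joint_joint") {
    f <- mlp_fwd(model$net, X, cache)
    list(out = f$out, f = f)
  } else {
    n <- nrow(X)
    # run both twins of the weight-shared encoder as one stacked batch;
    # crossprod over the stack then sums the shared-weight gradients
    Xstack <- rbind(X[, 1:k, drop = FALSE],
                    X[, (k + 1L):(2L * k), drop = FALSE])
    fe <- mlp_fwd(model$encoder, Xstack, cache)
    z <- fe$out[seq_len(n), , drop = FALSE]
    zp <- fe$out[n + seq_len(n), , drop = FALSE]
    if (model$architecture == "siamese_joint") {
      fd <- mlp_fwd(model$decoder, cbind(z, zp), cache)
      list(out = fd$out, fe = fe, fd = fd, z = z, zp = zp)
    } else {
      zh <- z * zp
      fd <- mlp_fwd(model$decoder,
                    rbind(cbind(z, zh), cbind(zp, zh)), cache)
      list(out = cbind(fd$out[seq_len(n), , drop = FALSE],
                       fd$out[n + seq_len(n), , drop = FALSE]),
           fe = fe, fd = fd, z = z, zp = zp, zh = zh)
    }
  }
}

# Gradients of mean((out - X)^2) (mean over all n*2k entries) wrt every
# parameter, as a flat list aligned with ae_params().
ae_bwd <- function(model, X, fw) {
  n <- nrow(X)
  dOut <- 2 * (fw$out - X) / (n * ncol(X))
  k <- model$k
  wb <- model$widths[3L]
  if (model$architecture == "joint_joint") {
    g <- mlp_bwd(model$net, fw$f, dOut)
    c(g$dW, g$db)
  } else if (model$architecture == "siamese_joint") {
    gd <- mlp_bwd(model$decoder, fw$fd, dOut)
    dz <- gd$dX[, 1:wb, drop = FALSE]
    dzp <- gd$dX[, (wb + 1L):(2L * wb), drop = FALSE]
    ge <- mlp_bwd(model$encoder, fw$fe, rbind(dz, dzp))
    c(ge$dW, ge$db, gd$dW, gd$db)
  } else {
    gd <- mlp_bwd(model$decoder, fw$fd,
                  rbind(dOut[, 1:k, drop = FALSE],
                        dOut[, (k + 1L):(2L * k), drop = FALSE]))
    da <- gd$dX[seq_len(n), , drop = FALSE]
    db_ <- gd$dX[n + seq_len(n), , drop = FALSE]
    dzh <- da[, (wb + 1L):(2L * wb), drop = FALSE] +
      db_[, (wb + 1L):(2L * wb), drop = FALSE]
    dz <- da[, 1:wb, drop = FALSE] + dzh * fw$zp
    dzp <- db_[, 1:wb, drop = FALSE] + dzh * fw$z
    ge <- mlp_bwd(model$encoder, fw$fe, rbind(dz, dzp))
    c(ge$dW, ge$db, gd$dW, gd$db)
  }
}

ae_params <- function(model) {
  if (model$architecture == "joint_joint") mlp_params(model$net)
  else c(mlp_params(model$encoder), mlp_params(model$decoder))
}

ae_copy_weights <- function(model) {
  if (model$architecture == "joint_joint") model$net <- mlp_copy(model$net)
  else {
    model$encoder <- mlp_copy(model$encoder)
    model$decoder <- mlp_copy(model$decoder)
  }
  model
}

#' Per-pair reconstruction loss
#'
#' Mean squared error between the 2k pair vector and its reconstruction. For
#' the Siamese-Siamese architecture this equals the mean of the two
#' per-protein MSEs.
#'
#' @param model A `ppi_autoencoder`.
#' @param pair Numeric vector of length 2k, or a matrix with one pair per
#'   row.
#' @return Non-negative numeric vector, one loss per pair.
#' @export
reconstruction_loss <- function(model, pair) {
  X <- as_pair_matrix(model, pair)
  out <- ae_fwd(model, X)$out
  unname(rowMeans((out - X)^2))
}

## ---- training ------------------------------------------------------------

#' Training configuration
#'
#' Defaults are the reference training recipe: Adam, initial learning rate
#' 5e-4, batch size 64, 2000 epochs, learning rate halved after 5 epochs
#' without validation-loss improvement down to 1e-5, with 10% of the
#' training pairs held out (seeded) for validation.
#'
#' @param epochs,batch_size,initial_learning_rate,plateau_patience,lr_reduction_factor,min_learning_rate,validation_fraction,seed
#'   See description; `validation_fraction` must lie in (0, 1).
#' @param keep_best If `TRUE`, return the weights with the best validation
#'   loss rather than the final-epoch weights (off by default).
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 2000L, batch_size = 64L,
                            initial_learning_rate = 5e-4,
                            plateau_patience = 5L,
                            lr_reduction_factor = 2,
                            min_learning_rate = 1e-5,
                            validation_fraction = 0.10,
                            seed = 1L, keep_best = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, initial_learning_rate > 0,
            plateau_patience >= 1, lr_reduction_factor >= 1,
            min_learning_rate > 0,
            min_learning_rate <= initial_learning_rate,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_learning_rate = initial_learning_rate,
                 plateau_patience = as.integer(plateau_patience),
                 lr_reduction_factor = lr_reduction_factor,
                 min_learning_rate = min_learning_rate,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), keep_best = keep_best),
            class = "training_config")
}

#' Desk-scale training preset
#'
#' The reference recipe with the epoch budget cut to 50, keeping the full
#' 600-600-300 layer widths. Intended for synthetic-data experiments and
#' continuous testing on a single CPU.
#'
#' @param ... Overrides passed on to [training_config()].
#' @return A `training_config`.
#' @export
desk_training_config <- function(...) {
  args <- list(...)
  defaults <- list(epochs = 50L)
  do.call(training_config, utils::modifyList(defaults, args))
}

#' Train an autoencoder on pair vectors
#'
#' Splits off a seeded validation fraction, then runs minibatch Adam on the
#' mean-squared reconstruction error with a reduce-on-plateau schedule: the
#' learning rate is divided by `lr_reduction_factor` whenever
#' `plateau_patience` consecutive epochs pass without a strictly better
#' validation loss, never dropping below `min_learning_rate`.
#'
#' @param model An untrained (or previously trained) `ppi_autoencoder`.
#' @param data Matrix of pair vectors (one per row, 2k columns), or a list
#'   of numeric vectors.
#' @param config A [training_config()].
#' @return List with `model` (trained) and `log` (data frame of epoch,
#'   train_loss, val_loss, lr).
#' @export
train_autoencoder <- function(model, data, config = training_config()) {
  if (is.list(data) && !is.matrix(data)) data <- do.call(rbind, data)
  if (!is.matrix(data) || nrow(data) == 0L)
    stop("training data must be a non-empty matrix of pair vectors",
         call. = FALSE)
  X <- as_pair_matrix(model, data)
  model <- ae_copy_weights(model)

  n <- nrow(X)
  split <- with_seed(derive_seed(config$seed, 1L), {
    if (n >= 2L) {
      nv <- max(1L, floor(config$validation_fraction * n))
      val_idx <- sample.int(n, nv)
      list(train = X[-val_idx, , drop = FALSE],
           val = X[val_idx, , drop = FALSE])
    } else list(train = X, val = X)
  })
  Xtr <- split$train; Xval <- split$val
  ntr <- nrow(Xtr)

  params <- ae_params(model)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)

  lr <- config$initial_learning_rate
  best_val <- Inf
  wait <- 0L
  tstep <- 0L
  best_model <- NULL
  log <- data.frame(epoch = integer(config$epochs),
                    train_loss = numeric(config$epochs),
                    val_loss = numeric(config$epochs),
                    lr = numeric(config$epochs))

  with_seed(derive_seed(config$seed, 2L), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      starts <- seq.int(1L, ntr, by = config$batch_size)
      tot_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, ntr)]
        B <- Xtr[idx, , drop = FALSE]
        fw <- ae_fwd(model, B, cache = TRUE)
        loss <- mean((fw$out - B)^2)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch, call. = FALSE)
        tot_loss <- tot_loss + loss * length(idx)
        grads <- ae_bwd(model, B, fw)
        tstep <- tstep + 1L
        adam_step_impl(params, grads, mstate, vstate, lr, 0.9, 0.999,
                       1e-8, tstep)
      }
      val_loss <- mean((ae_fwd(model, Xval)$out - Xval)^2)
      if (!is.finite(val_loss))
        stop("non-finite validation loss at epoch ", epoch, call. = FALSE)
      log$epoch[epoch] <- epoch
      log$train_loss[epoch] <- tot_loss / ntr
      log$val_loss[epoch] <- val_loss
      log$lr[epoch] <- lr
      if (val_loss < best_val) {
        best_val <- val_loss
        wait <- 0L
        if (isTRUE(config$keep_best)) best_model <- ae_copy_weights(model)
      } else {
        wait <- wait + 1L
        if (wait >= config$plateau_patience) {
          lr <- max(lr / config$lr_reduction_factor,
                    config$min_learning_rate)
          wait <- 0L
        }
      }
    }
  })

  out <- if (isTRUE(config$keep_best) && !is.null(best_model)) best_model
         else model
  out$trained <- TRUE
  list(model = out, log = log)
}

#' Save / load an autoencoder checkpoint
#'
#' Single-file archive holding a format version, the architecture tag, k,
#' widths, an optional descriptor fingerprint and the weights.
#'
#' @param model A `ppi_autoencoder`.
#' @param path Checkpoint path.
#' @param fingerprint Optional descriptor-config fingerprint to embed.
#' @return `path` invisibly (save); the model (load).
#' @export
save_autoencoder <- function(model, path, fingerprint = NULL) {
  saveRDS(list(format = "aeppi-checkpoint", version = 1L,
               fingerprint = fingerprint, model = model), path)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "aeppi-checkpoint"))
    stop("not an autoencoder checkpoint: ", path, call. = FALSE)
  structure(obj$model, fingerprint = obj$fingerprint)
}
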