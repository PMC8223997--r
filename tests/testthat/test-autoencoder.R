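test_that("architectures have the contracted shapes", {
  k <- 5
  jj <- build_autoencoder("joint_joint", k, seed = 1)
  expect_equal(jj$net$dims, c(10, 600, 600, 300, 600, 600, 10))
  sj <- build_autoencoder("siamese_joint", k, seed = 1)
  expect_equal(sj$encoder$dims, c(5, 600, 600, 300))
  expect_equal(sj$decoder$dims, c(600, 600, 600, 10))
  ss <- build_autoencoder("siamese_siamese", k, seed = 1)
  expect_equal(ss$encoder$dims, c(5, 600, 600, 300))
  expect_equal(ss$decoder$dims, c(600, 600, 600, 5))
  expect_error(build_autoencoder("deep_joint", k), "unknown architecture")
  # weight sharing: one encoder parameter set serves both proteins
  expect_length(asNamespace("aeppi")$ae_params(ss), 12)
})

test_that("initialization is seed-deterministic", {
  a <- build_autoencoder("siamese_joint", 7, seed = 99, widths = c(8, 6, 4))
  b <- build_autoencoder("siamese_joint", 7, seed = 99, widths = c(8, 6, 4))
  d <- build_autoencoder("siamese_joint", 7, seed = 100, widths = c(8, 6, 4))
  expect_identical(a, b)
  expect_false(identical(a$encoder$W[[1]], d$encoder$W[[1]]))
})

test_that("reconstruction loss is the MSE of the pair vector", {
  set.seed(21)
  m <- build_autoencoder("joint_joint", 3, seed = 2, widths = c(5, 4, 3))
  x <- rnorm(6)
  expect_gte(reconstruction_loss(m, x), 0)

  # zero weights reconstruct zero, so the loss is mean(x^2)
  m$net$W <- lapply(m$net$W, function(w) w * 0)
  expect_equal(reconstruction_loss(m, x), mean(x^2))

  # an identity-behaving model has zero loss: bypass with input 0
  expect_equal(reconstruction_loss(m, rep(0, 6)), 0)

  expect_error(reconstruction_loss(m, rnorm(5)), "does not match")
})

test_that("siamese-siamese loss is swap-invariant; joint variants are not", {
  set.seed(31)
  k <- 12
  ss <- build_autoencoder("siamese_siamese", k, seed = 5,
                          widths = c(16, 12, 6))
  for (i in 1:10) {
    a <- rnorm(k); b <- rnorm(k)
    expect_equal(reconstruction_loss(ss, c(a, b)),
                 reconstruction_loss(ss, c(b, a)), tolerance = 1e-12)
  }
  found_jj <- found_sj <- FALSE
  jj <- build_autoencoder("joint_joint", k, seed = 5, widths = c(16, 12, 6))
  sj <- build_autoencoder("siamese_joint", k, seed = 5, widths = c(16, 12, 6))
  for (i in 1:10) {
    a <- rnorm(k); b <- rnorm(k)
    if (abs(reconstruction_loss(jj, c(a, b)) -
            reconstruction_loss(jj, c(b, a))) > 1e-8) found_jj <- TRUE
    if (abs(reconstruction_loss(sj, c(a, b)) -
            reconstruction_loss(sj, c(b, a))) > 1e-8) found_sj <- TRUE
  }
  expect_true(found_jj)
  expect_true(found_sj)
})

test_that("training reconstructs a constant data set", {
  set.seed(41)
  k <- 6
  X <- matrix(rep(rnorm(2 * k), each = 40), 40)
  for (arch in c("joint_joint", "siamese_joint", "siamese_siamese")) {
    m <- build_autoencoder(arch, k, seed = 3, widths = c(16, 16, 8))
    fit <- train_autoencoder(m, X, training_config(epochs = 300,
                                                   batch_size = 16,
                                                   seed = 7))
    expect_lt(tail(fit$log$train_loss, 1), 1e-3)
  }
})

test_that("training is deterministic and leaves the input model untouched", {
  set.seed(51)
  k <- 5
  X <- matrix(rnorm(30 * 2 * k), 30)
  m <- build_autoencoder("siamese_siamese", k, seed = 3, widths = c(8, 8, 4))
  snapshot <- m$encoder$W[[1]] + 0
  cfg <- training_config(epochs = 20, batch_size = 8, seed = 13)
  f1 <- train_autoencoder(m, X, cfg)
  f2 <- train_autoencoder(m, X, cfg)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$log$val_loss, f2$log$val_loss)
  expect_identical(m$encoder$W[[1]], snapshot)
  expect_error(train_autoencoder(m, X[0, , drop = FALSE]), "non-empty")
})

test_that("the learning-rate schedule is non-increasing, bounded, and
           waits out the patience window", {
  set.seed(61)
  k <- 4
  X <- matrix(rnorm(20 * 2 * k), 20)
  m <- build_autoencoder("joint_joint", k, seed = 2, widths = c(6, 6, 3))
  # learning rate too small to change the loss in double precision:
  # no strict improvement after epoch 1, so the plateau logic must fire
  # exactly every `patience` epochs afterwards
  cfg <- training_config(epochs = 12, batch_size = 8, seed = 3,
                         initial_learning_rate = 1e-30,
                         min_learning_rate = 1e-40,
                         plateau_patience = 3)
  fit <- train_autoencoder(m, X, cfg)
  lr <- fit$log$lr
  expect_true(all(diff(lr) <= 0))
  expect_true(all(lr >= cfg$min_learning_rate))
  expect_equal(lr[1:4], rep(1e-30, 4))      # no cut before patience elapses
  expect_equal(lr[5:7], rep(5e-31, 3))
  expect_equal(lr[8:10], rep(2.5e-31, 3))

  # normal training never raises the rate and respects the floor
  m2 <- build_autoencoder("joint_joint", k, seed = 2, widths = c(6, 6, 3))
  fit2 <- train_autoencoder(m2, X, training_config(
    epochs = 40, batch_size = 8, seed = 3, plateau_patience = 2,
    min_learning_rate = 2e-4))
  expect_true(all(diff(fit2$log$lr) <= 0))
  expect_gte(min(fit2$log$lr), 2e-4)
})

test_that("checkpoints round-trip", {
  m <- build_autoencoder("siamese_joint", 4, seed = 9, widths = c(6, 5, 3))
  f <- withr::local_tempfile(fileext = ".rds")
  save_autoencoder(m, f, fingerprint = "abc")
  back <- load_autoencoder(f)
  expect_equal(attr(back, "fingerprint"), "abc")
  attr(back, "fingerprint") <- NULL
  expect_identical(back, m)
  saveRDS(list(format = "other"), f)
  expect_error(load_autoencoder(f), "not an autoencoder checkpoint")
})
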