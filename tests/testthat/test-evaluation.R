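test_that("confusion counts match hand counts", {
  cm <- confusion(c("positive", "positive", "negative", "negative"),
                  c("positive", "positive", "negative", "negative"))
  expect_equal(unclass(cm)[c("tp", "fp", "tn", "fn")],
               list(tp = 2, fp = 0, tn = 2, fn = 0))
  cm <- confusion(rep("positive", 5), rep("negative", 5))
  expect_equal(cm$fp, 5)
  expect_equal(cm$tp + cm$tn + cm$fn, 0)
  preds <- c("+", "+", "+", "-", "-", "-", "+", "-", "-", "+")
  truth <- c("+", "-", "+", "-", "+", "-", "+", "-", "+", "-")
  to_lab <- function(x) ifelse(x == "+", "positive", "negative")
  cm <- confusion(to_lab(preds), to_lab(truth))
  expect_equal(unclass(cm)[c("tp", "fp", "tn", "fn")],
               list(tp = 3, fp = 2, tn = 3, fn = 2))
  expect_error(confusion("positive", c("positive", "negative")), "length")
  expect_error(confusion("yes", "positive"), "labels")
})

test_that("metric formulas match the hand-computed example", {
  m <- ppi_metrics(list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$auc_balanced, 0.7)

  perfect <- ppi_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_true(all(unlist(perfect) == 1))

  w <- capture_warnings(z <- ppi_metrics(list(tp = 0, fp = 0, tn = 4,
                                              fn = 2)))
  expect_match(w, "precision", all = FALSE)
  expect_match(w, "f1", all = FALSE)
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(81)
  for (i in 1:50) {
    cm <- list(tp = sample(0:50, 1), fp = sample(0:50, 1),
               tn = sample(0:50, 1), fn = sample(0:50, 1))
    if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0 || cm$tp + cm$fp == 0)
      next
    m <- suppressWarnings(ppi_metrics(cm))
    expect_equal(m$auc_balanced, (m$specificity + m$recall) / 2)
    P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
    expect_equal(m$accuracy,
                 (m$recall * P + m$specificity * N) / (P + N))
  }
})

test_that("the confidence interval is the Student-t interval on fold means", {
  ci <- confidence_interval(rep(0.9, 5))
  expect_equal(ci$half_width, 0)
  expect_equal(ci$mean, 0.9)

  # n = 2, values {0, 1}: t_{0.975,1} * sd / sqrt(2) = 12.7062 * 0.5
  ci <- confidence_interval(c(0, 1))
  expect_equal(ci$mean, 0.5)
  expect_equal(ci$half_width, qt(0.975, 1) * sd(c(0, 1)) / sqrt(2))
  expect_equal(ci$half_width, 6.3531, tolerance = 1e-4)

  # fixed-variance samples shrink like 1/sqrt(n)
  v5 <- rep(c(0, 1), length.out = 40)
  hw_small <- confidence_interval(v5[1:10])$half_width
  hw_big <- confidence_interval(v5)$half_width
  expect_lt(hw_big, hw_small / 1.5)

  expect_error(confidence_interval(0.5), "at least 2")
})

test_that("rank-based ROC AUC behaves as a diagnostic", {
  truth <- rep(c("positive", "negative"), each = 10)
  expect_equal(roc_auc(c(rep(0.9, 10), rep(0.1, 10)), truth), 1)
  expect_equal(roc_auc(c(rep(0.1, 10), rep(0.9, 10)), truth), 0)
})

make_cv_fixture <- function(seed = 91, n_proteins = 40, n_pos = 24,
                            n_neg = 24) {
  cfg <- synthesis_config(n_proteins = n_proteins,
                          length_range = c(40L, 60L), n_pos = n_pos,
                          n_neg = n_neg, signal_strength = 1, lag = 3L,
                          seed = seed)
  generate_ppi_dataset(cfg)
}

test_that("cross-validation with an always-positive stub gives the harness
           oracle values", {
  ds <- make_cv_fixture()
  rep <- suppressWarnings(
    cross_validate(ds$proteins, ds$pairs, k = 4,
                   dconfig = tiny_dconfig(m = 2, lag = 3), seed = 5,
                   engine = always_positive_engine()))
  expect_equal(unname(rep$mean["recall"]), 1)
  expect_equal(unname(rep$mean["specificity"]), 0)
  expect_equal(unname(rep$mean["auc_balanced"]), 0.5)
  expect_equal(nrow(rep$folds), 4)
})

test_that("fold assignment partitions each class, preserves proportions and
           is seed-stable", {
  fold_assignments <- asNamespace("aeppi")$fold_assignments
  f1 <- fold_assignments(50, 5, seed = 3)
  f2 <- fold_assignments(50, 5, seed = 3)
  f3 <- fold_assignments(50, 5, seed = 4)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_equal(sort(unique(f1)), 1:5)
  expect_equal(as.vector(table(f1)), rep(10L, 5))   # 20% test per fold at k=5
  expect_equal(as.vector(table(fold_assignments(30, 10, seed = 1))),
               rep(3L, 10))                      # 10% test per fold at k=10

  ds <- make_cv_fixture()
  r1 <- cross_validate(ds$proteins, ds$pairs, k = 3,
                       dconfig = tiny_dconfig(m = 2, lag = 3), seed = 9,
                       engine = threshold_engine())
  r2 <- cross_validate(ds$proteins, ds$pairs, k = 3,
                       dconfig = tiny_dconfig(m = 2, lag = 3), seed = 9,
                       engine = threshold_engine())
  expect_identical(r1$folds, r2$folds)

  expect_error(cross_validate(ds$proteins, ds$pairs, k = 30,
                              dconfig = tiny_dconfig(m = 2, lag = 3)),
               "at least k")
  expect_error(cross_validate(ds$proteins, ds$pairs, k = 1,
                              dconfig = tiny_dconfig(m = 2, lag = 3)),
               "k must be >= 2")
})

test_that("cv reports serialize with per-fold rows and a summary row", {
  ds <- make_cv_fixture()
  rep <- cross_validate(ds$proteins, ds$pairs, k = 3,
                        dconfig = tiny_dconfig(m = 2, lag = 3), seed = 9,
                        engine = threshold_engine())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep, tsv, js)
  lines <- readLines(tsv)
  expect_length(lines, 5)            # header + 3 folds + summary
  expect_match(lines[5], "mean\t")
  expect_match(lines[5], "±")
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$k, 3)
  expect_length(parsed$folds, 3)
  expect_equal(parsed$mean$accuracy, unname(rep$mean["accuracy"]))
})
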