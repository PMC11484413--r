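test_that("confusion counts treat the anomalous class as positive", {
  truth <- c("anomalous", "anomalous", "regular", "regular", "regular")
  pred <- c("anomalous", "anomalous", "anomalous", "regular", "regular")
  cc <- confusion_counts(truth, pred)
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 1L, tn = 2L, fn = 0L))
  all_ok <- confusion_counts(rep(c("regular", "anomalous"), 5),
                             rep(c("regular", "anomalous"), 5))
  expect_equal(all_ok$fp + all_ok$fn, 0L)
  expect_error(confusion_counts(character(0), character(0)), "no labels")
  expect_error(confusion_counts("regular", c("regular", "regular")),
               "length")
  expect_error(confusion_counts("odd", "regular"), "labels")
})

test_that("metrics reproduce the textbook formulas, with undefined ratios
           reported as missing", {
  m <- metrics_from_confusion(
    structure(list(tp = 2, fp = 1, tn = 7, fn = 0),
              class = "confusion_counts"))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$fpr, 0.125)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 0.8)
  expect_equal(m$fnr, 0)

  perf <- metrics_from_confusion(
    structure(list(tp = 3, fp = 0, tn = 9, fn = 0),
              class = "confusion_counts"))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$f1, 1)

  none <- metrics_from_confusion(
    structure(list(tp = 0, fp = 0, tn = 5, fn = 2),
              class = "confusion_counts"))
  expect_true(is.na(none$precision))
  expect_error(metrics_from_confusion(
    structure(list(tp = 0, fp = 0, tn = 0, fn = 0),
              class = "confusion_counts")), "zero")

  # accuracy identity on fuzzed counts
  set.seed(2)
  for (i in 1:30) {
    cc <- structure(as.list(setNames(rpois(4, 4), c("tp", "fp", "tn",
                                                    "fn"))),
                    class = "confusion_counts")
    total <- cc$tp + cc$fp + cc$tn + cc$fn
    if (total == 0) next
    expect_equal(metrics_from_confusion(cc)$accuracy,
                 (cc$tp + cc$tn) / total)
  }
})

test_that("rank AUC matches the pairwise oracle, handles ties, and equals
           the trapezoidal curve integral", {
  r <- roc_auc(c(1, 2, 3, 2.5, 4),
               c("regular", "regular", "regular", "anomalous", "anomalous"))
  expect_equal(r$auc, 5 / 6, tolerance = 1e-12)
  expect_equal(roc_auc(c(5, 6, 1, 2), c("anomalous", "anomalous",
                                        "regular", "regular"))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("anomalous", "regular"), 3))$auc,
               0.5)

  set.seed(99)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    s <- sample(round(runif(n, 0, 5), 1))  # coarse grid forces ties
    l <- sample(c("regular", "anomalous"), n, replace = TRUE)
    if (!any(l == "anomalous")) l[1] <- "anomalous"
    if (!any(l == "regular")) l[2] <- "regular"
    r <- roc_auc(s, l)
    expect_equal(r$auc, oracle_auc(s, l), tolerance = 1e-12)
    expect_equal(vmatqa:::trapezoid_auc(r$curve), r$auc,
                 tolerance = 1e-12)
    expect_equal(tail(r$curve$tpr, 1), 1)
    expect_equal(tail(r$curve$fpr, 1), 1)
  }
  expect_error(roc_auc(1:3, rep("regular", 3)), "both classes")
})

test_that("rank AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- rnorm(40)
  l <- sample(c("regular", "anomalous"), 40, replace = TRUE)
  got <- roc_auc(s, l)$auc
  want <- as.numeric(pROC::auc(pROC::roc(
    response = factor(l, levels = c("regular", "anomalous")),
    predictor = s, direction = "<", quiet = TRUE)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("cross-validation partitions regular plans, reuses anomalies in
           every fold, and achieves zero FNR under the oracle policy", {
  cfg <- tiny_sim_config(n_regular = 10L, n_anomalous = 2L)
  plans <- make_dataset(cfg)
  mcfg <- ae_config(kind = "multitask", input_shape = c(16, 16),
                    latent_dim = 4, channels = c(2, 3, 4, 5), epochs = 1,
                    batch_size = 32)
  grid <- build_grid(cfg$machine, 0.5)  # 80x80 -> 16x16
  cv <- crossvalidate(plans, mcfg, threshold_policy("oracle_fnr0"),
                      seed = 4, grid = grid, target_shape = c(16, 16))
  expect_length(cv$folds, 5L)
  reg_ids <- sprintf("reg_%04d", 1:10)
  test_reg <- unlist(lapply(cv$folds, function(f)
    setdiff(f$test_ids, c("anom_0001", "anom_0002"))))
  expect_setequal(test_reg, reg_ids)
  expect_equal(anyDuplicated(test_reg), 0L)  # partition
  for (f in cv$folds) {
    expect_true(all(c("anom_0001", "anom_0002") %in% f$test_ids))
    expect_false(any(grepl("anom", f$train_ids)))
    expect_equal(f$counts$fn, 0L)
    expect_equal(f$metrics$recall, 1)
  }

  cv2 <- crossvalidate(plans, mcfg, threshold_policy("oracle_fnr0"),
                       seed = 4, grid = grid, target_shape = c(16, 16))
  expect_equal(cv$mean_metrics, cv2$mean_metrics)
  expect_equal(cv$scores, cv2$scores)

  expect_error(crossvalidate(plans[1:10], mcfg), "no anomalies")
  expect_error(crossvalidate(plans[c(1:3, 11:12)], mcfg,
                             grid = grid, target_shape = c(16, 16)),
               "fewer than")
})
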