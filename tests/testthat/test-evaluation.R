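test_that("confusion metrics follow the three printed formulas", {
  m <- confusion_metrics(tibble::tibble(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_equal(unlist(m), c(accuracy = 1, sensitivity = 1, specificity = 1))
  expect_warning(
    m2 <- confusion_metrics(tibble::tibble(TP = 3, TN = 0, FP = 0, FN = 1)),
    "specificity undefined")
  expect_equal(m2$sensitivity, 0.75)
  expect_true(is.na(m2$specificity))
  m3 <- confusion_metrics(tibble::tibble(TP = 50, TN = 50, FP = 25, FN = 25))
  expect_equal(m3$accuracy, 100 / 150)
})

test_that("confusion counts tabulate calls against truth", {
  truth <- c("amyloid", "amyloid", "non_amyloid", "non_amyloid")
  call <- c("amyloid", "non_amyloid", "amyloid", "non_amyloid")
  cc <- confusion_counts(truth, call)
  expect_equal(unlist(cc), c(TP = 1, TN = 1, FP = 1, FN = 1))
  expect_error(confusion_counts(truth, call[1:2]), "equal length")
})

test_that("ROC handles separation, ties and the worked pairwise example", {
  lab <- c(rep("amyloid", 3), rep("non_amyloid", 3))
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), lab), 1)
  expect_equal(roc_auc(rep(0.5, 6), lab), 0.5)
  expect_equal(
    roc_auc(c(0.9, 0.4, 0.5, 0.1),
            c("amyloid", "amyloid", "non_amyloid", "non_amyloid")),
    0.75)
  expect_error(roc_auc(runif(4), rep("amyloid", 4)), "both classes")
  pts <- roc_points(c(0.9, 0.4, 0.5, 0.1),
                    c("amyloid", "amyloid", "non_amyloid", "non_amyloid"))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
})

test_that("trapezoidal AUC equals brute-force pairwise probability", {
  set.seed(71)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    lab <- c(rep("amyloid", max(1, rbinom(1, n - 2, 0.4) + 1)))
    lab <- c(lab, rep("non_amyloid", n - length(lab)))
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # induce ties sometimes
    expect_equal(roc_auc(scores, lab), oracle_pairwise_auc(scores, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  set.seed(72)
  scores <- runif(60)
  lab <- sample(c("amyloid", "non_amyloid"), 60, replace = TRUE,
                prob = c(0.3, 0.7))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = scores, levels = c("non_amyloid", "amyloid"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, lab), ref, tolerance = 1e-12)
})

test_that("LOOCV recovers trivially separable data perfectly", {
  d <- tibble::tibble(x = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                      label = rep(c("non_amyloid", "amyloid"), each = 3))
  # majority threshold: with leaves this small, Laplace smoothing keeps
  # every P(amyloid) above the 0.15 operating point by construction
  ev <- vl_cross_validate(d, "loocv", threshold = 0.5, seed = 1)
  expect_equal(ev$metrics$accuracy, 100)
  expect_equal(ev$metrics$auc, 1)
  expect_s3_class(autoplot(ev), "ggplot")
})

test_that("evaluation protocols are reproducible under a fixed seed", {
  sim <- simulate_vl(25, 25, seed = 73)
  f <- vl_features(sim)
  r1 <- vl_cross_validate(f, "resampling", n_iter = 2, seed = 5)
  r2 <- vl_cross_validate(f, "resampling", n_iter = 2, seed = 5)
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_identical(r1$metrics, r2$metrics)
  k1 <- vl_cross_validate(f, "kfold", k = 5, seed = 5)
  k2 <- vl_cross_validate(f, "kfold", k = 5, seed = 5)
  expect_identical(k1$metrics, k2$metrics)
})

test_that("label-shuffled data cross-validates to chance-level AUC", {
  sim <- simulate_vl(60, 60, seed = 74)
  f <- vl_features(sim)
  set.seed(99)
  f$label <- sample(f$label) # destroy the feature-label association
  ev <- vl_cross_validate(f, "kfold", k = 5, seed = 6)
  expect_gt(ev$metrics$auc, 0.35)
  expect_lt(ev$metrics$auc, 0.65)
})

test_that("stratified protocols refuse degenerate class layouts", {
  d <- tibble::tibble(x = runif(10),
                      label = c(rep("amyloid", 2), rep("non_amyloid", 8)))
  expect_error(vl_cross_validate(d, "kfold", k = 20), "exceeds")
  d1 <- tibble::tibble(x = runif(5), label = rep("amyloid", 5))
  expect_error(vl_cross_validate(d1, "loocv"), "each class")
})

test_that("resampling aggregates per-iteration metrics as mean and sd", {
  sim <- simulate_vl(30, 30, seed = 75)
  f <- vl_features(sim)
  ev <- vl_cross_validate(f, "resampling", n_iter = 20, seed = 7)
  expect_equal(nrow(ev$per_iteration), 20)
  expect_equal(ev$metrics$accuracy,
               round(100 * mean(ev$per_iteration$accuracy), 1))
  expect_equal(ev$metrics$accuracy_sd,
               round(100 * sd(ev$per_iteration$accuracy), 1))
  expect_true(ev$metrics$auc >= 0 && ev$metrics$auc <= 1)
  # train/test split proportions: 90% of each class trains, the rest tests
  expect_equal(ev$n, 60)
})

test_that("feature ablation ranks a planted signal above pure noise", {
  set.seed(76)
  n <- 120
  signal <- c(rnorm(n / 2, 0), rnorm(n / 2, 1.6))
  d <- tibble::tibble(
    signal = signal,
    noise = rnorm(n),
    label = rep(c("non_amyloid", "amyloid"), each = n / 2))
  ab <- vl_feature_ablation(d, protocol = "kfold", k = 5, seed = 3)
  expect_equal(ab$feature, c("signal", "noise"))
  expect_true(all(ab$auc_without >= 0 & ab$auc_without <= 1))
  expect_true(all(ab$auc_only >= 0 & ab$auc_only <= 1))
  full <- vl_cross_validate(d, "kfold", k = 5, seed = 3)$metrics$auc
  drop_signal <- abs(full - ab$auc_without[ab$feature == "signal"])
  drop_noise <- abs(full - ab$auc_without[ab$feature == "noise"])
  expect_gt(drop_signal, drop_noise)
  expect_error(vl_feature_ablation(d, feature_cols = "signal"),
               "at least two")
})
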