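part_data <- function(x, y, more = NULL) {
  d <- tibble::tibble(x = x, label = ifelse(y == 1, "amyloid", "non_amyloid"))
  if (!is.null(more)) d <- dplyr::bind_cols(d, more)
  d
}

test_that("separable 1-D data yields a single-condition first rule", {
  set.seed(51)
  x <- c(runif(10, 0, 0.45), runif(10, 0.55, 1))
  y <- rep(c(0, 1), each = 10)
  d <- part_data(x, y)
  fit <- part_fit(d)
  expect_equal(length(fit$rules[[1]]$conditions), 1)
  expect_equal(fit$rules[[1]]$conditions[[1]]$feature, "x")
  acc <- mean(predict(fit, d, type = "class") == d$label)
  expect_equal(acc, 1)

  # the chosen root split maximizes gain ratio over all midpoint candidates
  oracle <- oracle_best_split(matrix(x, ncol = 1), y)
  expect_equal(fit$rules[[1]]$conditions[[1]]$threshold, oracle$threshold)
})

test_that("the root split agrees with exhaustive gain-ratio search", {
  set.seed(52)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    p <- sample(1:2, 1)
    X <- matrix(runif(n * p), ncol = p)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    # the root split of the first partial tree, as the learner computes it
    root <- vlamy:::best_split_cpp(X, as.integer(y), seq_len(n) - 1L, TRUE)
    oracle <- oracle_best_split(X, y)
    expect_equal(root$feature, oracle$feature)
    expect_equal(root$threshold, oracle$threshold, tolerance = 1e-12)
  }
})

test_that("XOR-style clusters are learned exactly by multiple rules", {
  set.seed(53)
  centers <- list(c(0.2, 0.2), c(0.8, 0.8), c(0.2, 0.8), c(0.8, 0.2))
  sizes <- c(4, 5, 5, 6) # unequal so that root splits carry information
  lab <- c(1, 1, 0, 0)
  pts <- purrr::map2_dfr(centers, seq_along(centers), function(cc, i) {
    tibble::tibble(f1 = cc[1] + runif(sizes[i], -0.05, 0.05),
                   f2 = cc[2] + runif(sizes[i], -0.05, 0.05),
                   label = ifelse(lab[i] == 1, "amyloid", "non_amyloid"))
  })
  fit <- part_fit(pts)
  expect_gte(length(fit$rules), 2)
  expect_equal(mean(predict(fit, pts, type = "class") == pts$label), 1)
  # every training instance's first matching rule is pure
  td <- tidy(fit)
  matched <- td[td$conditions != "<default>", ]
  expect_true(all(matched$n_pos == 0 | matched$n_neg == 0))
})

test_that("single-class input yields no rules and a class-pure default", {
  d <- part_data(runif(8), rep(1, 8))
  fit <- part_fit(d)
  expect_length(fit$rules, 0)
  expect_equal(as.integer(fit$default_counts), c(8L, 0L))
  expect_true(all(predict(fit, d, type = "class") == "amyloid"))
})

test_that("probabilities are Laplace-smoothed leaf fractions", {
  model <- structure(list(
    rules = list(list(conditions = list(list(feature = "x", op = "<=",
                                             threshold = 0.5)),
                      n_covered = 9, n_pos = 9, n_neg = 0),
                 list(conditions = list(list(feature = "x", op = ">",
                                             threshold = 0.7)),
                      n_covered = 8, n_pos = 0, n_neg = 8)),
    default_counts = c(n_pos = 0L, n_neg = 0L),
    feature_names = "x", positive = "amyloid",
    meta = list(n_train = 17)), class = "vlamy_part")
  d <- tibble::tibble(x = c(0.3, 0.9, 0.6))
  p <- predict(model, d)
  expect_equal(p, c(10 / 11, 1 / 10, 0.5))
})

test_that("classification applies the >= threshold convention", {
  model <- structure(list(
    rules = list(), default_counts = c(n_pos = 0L, n_neg = 0L),
    feature_names = "x", positive = "amyloid", meta = list()),
    class = "vlamy_part")
  expect_equal(vlamy:::classify_prob(c(0.16, 0.15, 0.14), 0.15),
               c("amyloid", "amyloid", "non_amyloid"))
  expect_error(vlamy:::classify_prob(0.5, 0), "threshold")
  expect_error(vlamy:::classify_prob(0.5, 1), "threshold")
})

test_that("threshold selection sweeps candidates and favors sensitivity", {
  expect_equal(select_threshold(runif(10), rep(c("amyloid", "non_amyloid"),
                                               5)), 0.15)
  # perfectly separated scores: the smallest maximizing candidate is chosen
  sc <- c(0.1, 0.2, 0.8, 0.9)
  lab <- c("non_amyloid", "non_amyloid", "amyloid", "amyloid")
  expect_equal(select_threshold(sc, lab, "max_balanced_accuracy"), 0.8)
  expect_equal(select_threshold(sc, lab, "max_youden"), 0.8)
  expect_error(select_threshold(sc, rep("amyloid", 4),
                                "max_balanced_accuracy"), "both classes")
  # labels independent of scores: the optimized criterion stays near chance
  set.seed(54)
  sc2 <- runif(2000)
  lab2 <- sample(c("amyloid", "non_amyloid"), 2000, replace = TRUE)
  t_star <- select_threshold(sc2, lab2, "max_balanced_accuracy")
  call_pos <- sc2 >= t_star
  yy <- lab2 == "amyloid"
  bal <- (mean(call_pos[yy]) + mean(!call_pos[!yy])) / 2
  expect_lt(abs(bal - 0.5), 0.06)
})

test_that("coverage is conserved across rules and the default", {
  set.seed(55)
  for (i in 1:8) {
    n <- sample(30:120, 1)
    p <- sample(2:5, 1)
    X <- matrix(runif(n * p), ncol = p)
    d <- tibble::as_tibble(as.data.frame(X))
    names(d) <- paste0("f", seq_len(p))
    d$label <- ifelse(rbinom(n, 1, 0.4) == 1, "amyloid", "non_amyloid")
    fit <- part_fit(d)
    covered <- sum(vapply(fit$rules, `[[`, numeric(1), "n_covered"))
    expect_equal(covered + sum(fit$default_counts), n)
  }
})

test_that("training is deterministic and models serialize losslessly", {
  sim <- simulate_vl(30, 30, seed = 61)
  f <- vl_features(sim)
  fit1 <- part_fit(f, seed = 9)
  fit2 <- part_fit(f, seed = 9)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_part_model(fit1, p1)
  write_part_model(fit2, p2)
  expect_identical(readLines(p1), readLines(p2))

  back <- read_part_model(p1)
  expect_equal(back$rules, fit1$rules, tolerance = 0)
  expect_equal(back$default_counts, fit1$default_counts)
  expect_equal(back$feature_names, fit1$feature_names)
  expect_equal(predict(back, f), predict(fit1, f))
  expect_error(read_part_model(system.file("extdata",
                                           "aaindex_sample.txt",
                                           package = "vlamy")),
               "not a vlamy_part")
})

test_that("degenerate inputs are refused or handled as specified", {
  d <- part_data(runif(6), rep(c(0, 1), 3))
  expect_error(part_fit(d, unpruned = FALSE), "unpruned")
  expect_error(part_fit(d, outcome = "nope"), "not found")
  expect_error(part_fit(d["label"]), "no feature columns")
  dd <- d; dd$x[2] <- NA
  expect_error(part_fit(dd), "missing feature values")
  # constant features are skippable, not fatal
  d$flat <- 1
  expect_s3_class(part_fit(d), "vlamy_part")
  fit <- part_fit(d)
  expect_error(predict(fit, tibble::tibble(x = 0.5)), "lacks feature")
})
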