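#' Confusion counts and derived metrics
#'
#' `confusion_counts()` tabulates calls against truth with the amyloid class
#' as positive. `confusion_metrics()` applies the three standard formulas:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). A metric whose denominator is zero is returned
#' as `NA` with a warning rather than silently as 0.
#'
#' @param truth True labels (character or logical).
#' @param call Predicted labels (character or logical).
#' @param positive Positive label. Default `"amyloid"`.
#' @return `confusion_counts()`: one-row tibble `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, call, positive = "amyloid") {
  yt <- as_positive(truth, positive)
  yc <- as_positive(call, positive)
  if (length(yt) != length(yc)) {
    stop("truth and call must have equal length", call. = FALSE)
  }
  tibble::tibble(
    TP = sum(yt & yc), TN = sum(!yt & !yc),
    FP = sum(!yt & yc), FN = sum(yt & !yc)
  )
}

#' @rdname confusion_counts
#' @param counts One-row tibble / named list with `TP`, `TN`, `FP`, `FN`.
#' @return `confusion_metrics()`: one-row tibble `accuracy`, `sensitivity`,
#'   `specificity` (proportions in \[0, 1\]).
#' @export
confusion_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  sens <- if (TP + FN == 0) {
    warning("sensitivity undefined: no positive instances"); NA_real_
  } else TP / (TP + FN)
  spec <- if (TN + FP == 0) {
    warning("specificity undefined: no negative instances"); NA_real_
  } else TN / (TN + FP)
  tibble::tibble(
    accuracy = (TP + TN) / (TP + TN + FP + FN),
    sensitivity = sens,
    specificity = spec
  )
}

#' ROC curve and AUC
#'
#' `roc_points()` sweeps every distinct score as a decision threshold (calls
#' positive at score >= threshold) and returns the (FPR, TPR) staircase from
#' (0,0) to (1,1); `roc_auc()` integrates it by the trapezoidal rule, which
#' equals the pairwise probability P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores Numeric scores (higher = more amyloid-like).
#' @param labels True labels.
#' @param positive Positive label.
#' @return `roc_points()`: tibble `threshold`, `fpr`, `tpr` (the leading
#'   (0,0) point carries threshold `Inf`). `roc_auc()`: a single number.
#' @export
roc_points <- function(scores, labels, positive = "amyloid") {
  y <- as_positive(labels, positive)
  if (all(y) || !any(y)) {
    stop("both classes are required for a ROC curve", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  np <- sum(y); nn <- sum(!y)
  tibble::tibble(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(!y & scores >= t), numeric(1)) / nn,
    tpr = vapply(thr, function(t) sum(y & scores >= t), numeric(1)) / np
  )
}

#' @rdname roc_points
#' @export
roc_auc <- function(scores, labels, positive = "amyloid") {
  pts <- roc_points(scores, labels, positive)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}

# fold assignment: stratified, shuffled within class, round-robin
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    if (length(i) < k && length(i) < 1) next
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Cross-validate the amyloidogenicity pipeline
#'
#' Retrains the rule classifier per split and evaluates it under one of the
#' method's protocols: `"self"` (resubstitution on the full data), `"loocv"`
#' (leave-one-out: n models, each record predicted by a model trained on the
#' others), `"kfold"` (stratified k-fold, predictions pooled across folds)
#' and `"resampling"` (repeated stratified subsampling without replacement:
#' each iteration trains on `frac_train` of every class and tests on the
#' rest; metrics are aggregated as mean and sd over iterations). The fixed
#' decision threshold is applied to every split.
#'
#' @param features Feature tibble with a label column (see [vl_features()]).
#' @param protocol `"self"`, `"loocv"`, `"kfold"` or `"resampling"`.
#' @param k Folds for `"kfold"` (default 10).
#' @param n_iter Iterations for `"resampling"` (default 5000).
#' @param frac_train Training fraction per class for `"resampling"` (0.9).
#' @param threshold Decision threshold (default 0.15).
#' @param min_leaf Passed to [part_fit()].
#' @param seed Integer seed; the whole protocol is reproducible.
#' @param outcome,positive Outcome column and positive level.
#' @param feature_cols Optional character vector restricting the features.
#' @return An object of class `vl_eval`: list with `protocol`, `metrics`
#'   (one-row tibble with accuracy/sensitivity/specificity as percentages
#'   and `auc`), `counts`, `roc` (pooled ROC points; `NULL` for
#'   resampling), `per_iteration` (resampling only) and `threshold`.
#' @export
vl_cross_validate <- function(features,
                              protocol = c("self", "loocv", "kfold",
                                           "resampling"),
                              k = 10, n_iter = 5000, frac_train = 0.9,
                              threshold = 0.15, min_leaf = 2, seed = 1,
                              outcome = "label", positive = "amyloid",
                              feature_cols = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(
      names(features)[vapply(features, is.numeric, logical(1))], outcome)
  }
  y <- as_positive(features[[outcome]], positive)
  n <- nrow(features)
  if (protocol != "self" && (sum(y) < 2 || sum(!y) < 2)) {
    stop("at least two instances of each class are required", call. = FALSE)
  }
  fit_on <- function(i) {
    part_fit(features[i, ], outcome = outcome, features = feature_cols,
             positive = positive, min_leaf = min_leaf, seed = seed)
  }
  truth <- ifelse(y, positive, paste0("non_", positive))

  pooled_report <- function(prob) {
    calls <- classify_prob(prob, threshold)
    cc <- confusion_counts(truth, calls, positive)
    structure(list(
      protocol = protocol,
      metrics = dplyr::mutate(
        confusion_metrics(cc),
        dplyr::across(dplyr::everything(), ~ round(100 * .x, 1)),
        auc = roc_auc(prob, truth, positive)),
      counts = cc,
      roc = roc_points(prob, truth, positive),
      per_iteration = NULL,
      threshold = threshold,
      n = n
    ), class = "vl_eval")
  }

  set.seed(seed)
  if (protocol == "self") {
    model <- fit_on(seq_len(n))
    return(pooled_report(predict(model, features)))
  }
  if (protocol == "loocv") {
    prob <- vapply(seq_len(n), function(i) {
      predict(fit_on(setdiff(seq_len(n), i)), features[i, ])
    }, numeric(1))
    return(pooled_report(prob))
  }
  if (protocol == "kfold") {
    if (k > n) stop("k exceeds the number of records", call. = FALSE)
    if (k > min(sum(y), sum(!y))) {
      stop("k exceeds the size of the smaller class; stratified folds ",
           "would leave training splits without one class", call. = FALSE)
    }
    fold <- stratified_folds(y, k)
    prob <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      te <- which(fold == f)
      prob[te] <- predict(fit_on(which(fold != f)), features[te, ])
    }
    return(pooled_report(prob))
  }
  # resampling: stratified train subsample without replacement per iteration
  iters <- purrr::map_dfr(seq_len(n_iter), function(it) {
    tr <- unlist(lapply(c(TRUE, FALSE), function(cls) {
      i <- which(y == cls)
      sample(i, round(frac_train * length(i)))
    }))
    te <- setdiff(seq_len(n), tr)
    prob <- predict(fit_on(tr), features[te, ])
    cc <- confusion_counts(truth[te], classify_prob(prob, threshold),
                           positive)
    met <- suppressWarnings(confusion_metrics(cc))
    met$auc <- if (length(unique(y[te])) == 2) {
      roc_auc(prob, truth[te], positive)
    } else NA_real_
    met$iteration <- it
    met
  })
  agg <- dplyr::summarise(iters, dplyr::across(
    c("accuracy", "sensitivity", "specificity"),
    list(mean = ~ round(100 * mean(.x, na.rm = TRUE), 1),
         sd = ~ round(100 * sd(.x, na.rm = TRUE), 1))),
    auc = mean(.data$auc, na.rm = TRUE),
    auc_sd = sd(.data$auc, na.rm = TRUE))
  structure(list(
    protocol = protocol,
    metrics = dplyr::rename(agg, accuracy = "accuracy_mean",
                            sensitivity = "sensitivity_mean",
                            specificity = "specificity_mean"),
    counts = NULL,
    roc = NULL,
    per_iteration = iters,
    threshold = threshold,
    n = n
  ), class = "vl_eval")
}

#' @export
print.vl_eval <- function(x, ...) {
  cat("<vl_eval> protocol:", x$protocol, " n =", x$n,
      " threshold =", x$threshold, "\n")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.vl_eval <- function(x, ...) {
  dplyr::mutate(x$metrics, protocol = x$protocol, .before = 1)
}

#' @export
glance.vl_eval <- function(x, ...) {
  tibble::tibble(protocol = x$protocol, n = x$n, threshold = x$threshold,
                 auc = x$metrics$auc)
}

#' ROC curve plot for an evaluation
#'
#' @param object A `vl_eval` with pooled ROC points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vl_eval <- function(object, ...) {
  if (is.null(object$roc)) {
    stop("this evaluation has no pooled ROC points (resampling protocol)",
         call. = FALSE)
  }
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (%s), AUC = %.3f", object$protocol,
                      object$metrics$auc)) +
    ggplot2::theme_minimal()
}

#' Feature ablation analysis
#'
#' Re-evaluates the pipeline with each feature removed (`auc_without`) and
#' with each feature alone (`auc_only`), under the same protocol and seed
#' throughout, quantifying how much each feature carries.
#'
#' @inheritParams vl_cross_validate
#' @return Tibble `feature`, `auc_without`, `auc_only`.
#' @export
vl_feature_ablation <- function(features, protocol = "kfold", k = 10,
                                n_iter = 100, frac_train = 0.9,
                                threshold = 0.15, min_leaf = 2, seed = 1,
                                outcome = "label", positive = "amyloid",
                                feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(
      names(features)[vapply(features, is.numeric, logical(1))], outcome)
  }
  if (length(feature_cols) < 2) {
    stop("feature ablation needs at least two features", call. = FALSE)
  }
  one_auc <- function(cols) {
    ev <- vl_cross_validate(features, protocol = protocol, k = k,
                            n_iter = n_iter, frac_train = frac_train,
                            threshold = threshold, min_leaf = min_leaf,
                            seed = seed, outcome = outcome,
                            positive = positive, feature_cols = cols)
    ev$metrics$auc
  }
  purrr::map_dfr(feature_cols, function(f) {
    tibble::tibble(
      feature = f,
      auc_without = one_auc(setdiff(feature_cols, f)),
      auc_only = one_auc(f)
    )
  })
}
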