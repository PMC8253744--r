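#' Train a PART-style rule list
#'
#' Separate-and-conquer rule induction in the style of PART: in each
#' iteration an unpruned partial C4.5-style decision tree is grown on the
#' instances not yet covered (binary numeric splits at midpoints between
#' consecutive distinct values, chosen by information gain ratio with the
#' C4.5 average-gain admissibility screen), the leaf covering the most
#' instances is extracted as an ordered rule, the instances it covers are
#' removed, and the loop repeats until no instances remain or the partial
#' tree collapses to a single leaf (whose class counts then become the
#' default). Leaf class counts are retained on every rule so that prediction
#' can emit Laplace-smoothed class probabilities.
#'
#' @param data Feature tibble (e.g. from [vl_features()]) with an outcome
#'   column; non-numeric columns other than the outcome are ignored.
#' @param outcome Name of the outcome column. Default `"label"`.
#' @param features Optional character vector of feature columns; defaults to
#'   every numeric column.
#' @param positive Level of `outcome` treated as the positive (amyloid)
#'   class.
#' @param min_leaf Nodes with fewer instances are never split (default 2).
#' @param unpruned Must be `TRUE`; pruning is intentionally not implemented.
#' @param seed Recorded in the model metadata. Training itself is
#'   deterministic given the data and parameters.
#' @return An object of class `vlamy_part`: a list with elements `rules`
#'   (ordered list of rules, each with `conditions`, `n_covered`, `n_pos`,
#'   `n_neg`), `default_counts`, `feature_names`, `positive` and `meta`.
#' @examples
#' d <- tibble::tibble(x = c(0.1, 0.2, 0.8, 0.9),
#'                     label = c("non_amyloid", "non_amyloid",
#'                               "amyloid", "amyloid"))
#' fit <- part_fit(d)
#' predict(fit, d)
#' @export
part_fit <- function(data, outcome = "label", features = NULL,
                     positive = "amyloid", min_leaf = 2, unpruned = TRUE,
                     seed = 0L) {
  if (!isTRUE(unpruned)) {
    stop("pruned trees are not supported; the rule learner is unpruned by design",
         call. = FALSE)
  }
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(features, outcome)
  }
  if (length(features) == 0) stop("no feature columns", call. = FALSE)
  X <- as.matrix(data[features])
  if (anyNA(X)) stop("missing feature values are not supported", call. = FALSE)
  y <- as.integer(data[[outcome]] == positive)
  n <- nrow(X)

  # the separate-and-conquer loop (partial-tree growth, largest-leaf
  # extraction, instance removal) runs compiled; see src/split.cpp
  fit <- part_fit_cpp(X, y, min_leaf)
  rules <- lapply(fit$rules, function(r) {
    conds <- purrr::pmap(
      list(r$feature, r$le, r$threshold),
      function(f, le, thr) {
        list(feature = features[f + 1], op = if (le) "<=" else ">",
             threshold = thr)
      })
    list(conditions = simplify_conditions(conds),
         n_covered = r$n_covered, n_pos = r$n_pos, n_neg = r$n_neg)
  })
  default_counts <- c(n_pos = fit$default_pos, n_neg = fit$default_neg)

  structure(list(
    rules = rules,
    default_counts = default_counts,
    feature_names = features,
    positive = positive,
    meta = list(n_train = n, n_pos = sum(y), n_neg = n - sum(y),
                min_leaf = min_leaf, unpruned = TRUE, seed = seed,
                outcome = outcome)
  ), class = "vlamy_part")
}

# keep only the tightest bound per (feature, op) along a root-to-leaf path
simplify_conditions <- function(conds) {
  if (length(conds) == 0) return(conds)
  key <- vapply(conds, function(cn) paste(cn$feature, cn$op), character(1))
  out <- list()
  for (k in unique(key)) {
    grp <- conds[key == k]
    thr <- vapply(grp, `[[`, numeric(1), "threshold")
    pick <- grp[[1]]
    pick$threshold <- if (pick$op == "<=") min(thr) else max(thr)
    out[[length(out) + 1]] <- pick
  }
  out
}

rule_matches <- function(rule, X) {
  m <- rep(TRUE, nrow(X))
  for (cn in rule$conditions) {
    xv <- X[, cn$feature]
    m <- m & (if (cn$op == "<=") xv <= cn$threshold else xv > cn$threshold)
  }
  m
}

#' Predict from a PART-style rule list
#'
#' Each row is scored by the first rule (in training order) whose conditions
#' it satisfies; its P(amyloid) is the Laplace-smoothed positive fraction
#' `(n_pos + 1) / (n_covered + 2)` of that rule's leaf, or of the default
#' counts when no rule matches. Class calls are positive iff
#' `P(amyloid) >= threshold` (ties classify positive).
#'
#' @param object A `vlamy_part` model.
#' @param newdata Tibble containing the model's feature columns.
#' @param type `"prob"` for P(amyloid), `"class"` for calls.
#' @param threshold Decision threshold in (0, 1); default 0.15, the
#'   imbalance-aware operating point of the method.
#' @param ... Unused.
#' @return Numeric vector of probabilities, or character vector of
#'   `"amyloid"` / `"non_amyloid"` calls.
#' @export
predict.vlamy_part <- function(object, newdata, type = c("prob", "class"),
                               threshold = 0.15, ...) {
  type <- match.arg(type)
  missing_f <- setdiff(object$feature_names, names(newdata))
  if (length(missing_f)) {
    stop("newdata lacks feature column(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[object$feature_names])
  if (anyNA(X)) stop("missing feature values are not supported", call. = FALSE)
  p <- rep(NA_real_, nrow(X))
  open <- seq_len(nrow(X))
  for (rule in object$rules) {
    if (length(open) == 0) break
    hit <- rule_matches(rule, X[open, , drop = FALSE])
    p[open[hit]] <- (rule$n_pos + 1) / (rule$n_covered + 2)
    open <- open[!hit]
  }
  if (length(open)) {
    dc <- object$default_counts
    p[open] <- (dc[["n_pos"]] + 1) / (dc[["n_pos"]] + dc[["n_neg"]] + 2)
  }
  if (type == "prob") return(p)
  classify_prob(p, threshold)
}

classify_prob <- function(p, threshold) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  ifelse(p >= threshold, "amyloid", "non_amyloid")
}

#' Select a decision threshold
#'
#' With `criterion = "fixed"` returns the method's operating point (default
#' 0.15), chosen to balance sensitivity against specificity under the ~1:4
#' class imbalance of the reference dataset. The data-driven criteria sweep
#' every distinct predicted probability as a candidate threshold and return
#' the maximizer; ties break toward the smaller threshold, favoring
#' sensitivity.
#'
#' @param probabilities Numeric vector of P(amyloid).
#' @param labels Character/logical vector of true labels.
#' @param criterion `"fixed"`, `"max_balanced_accuracy"` or `"max_youden"`.
#' @param fixed Threshold returned by the fixed criterion.
#' @param positive Positive label.
#' @return A single numeric threshold.
#' @export
select_threshold <- function(probabilities, labels,
                             criterion = c("fixed", "max_balanced_accuracy",
                                           "max_youden"),
                             fixed = 0.15, positive = "amyloid") {
  criterion <- match.arg(criterion)
  if (criterion == "fixed") return(fixed)
  y <- as_positive(labels, positive)
  if (length(unique(y)) < 2) {
    stop("both classes are required for a data-driven threshold",
         call. = FALSE)
  }
  cands <- sort(unique(probabilities))
  vals <- vapply(cands, function(t) {
    call_pos <- probabilities >= t
    sens <- mean(call_pos[y])
    spec <- mean(!call_pos[!y])
    switch(criterion,
           max_balanced_accuracy = (sens + spec) / 2,
           max_youden = sens + spec - 1)
  }, numeric(1))
  cands[which.max(vals)] # which.max takes the first, i.e. smallest, maximizer
}

as_positive <- function(labels, positive) {
  if (is.logical(labels)) labels else labels == positive
}

#' @export
print.vlamy_part <- function(x, ...) {
  cat("<vlamy_part> rule list:", length(x$rules), "rules over",
      length(x$feature_names), "features; trained on", x$meta$n_train,
      "instances (", x$meta$n_pos, "pos /", x$meta$n_neg, "neg )\n")
  td <- tidy(x)
  print(td, n = min(nrow(td), 10))
  invisible(x)
}

#' Tidy a PART-style rule list
#'
#' @param x A `vlamy_part` model.
#' @param ... Unused.
#' @return One row per rule (plus the default), with columns `rule`,
#'   `conditions` (human-readable), `n_covered`, `n_pos`, `n_neg` and
#'   `p_amyloid` (the Laplace-smoothed leaf probability).
#' @export
tidy.vlamy_part <- function(x, ...) {
  rows <- purrr::imap_dfr(x$rules, function(r, i) {
    tibble::tibble(
      rule = i,
      conditions = paste(vapply(r$conditions, function(cn) {
        sprintf("%s %s %.4g", cn$feature, cn$op, cn$threshold)
      }, character(1)), collapse = " & "),
      n_covered = r$n_covered, n_pos = r$n_pos, n_neg = r$n_neg,
      p_amyloid = (r$n_pos + 1) / (r$n_covered + 2)
    )
  })
  dc <- x$default_counts
  dplyr::bind_rows(rows, tibble::tibble(
    rule = length(x$rules) + 1L, conditions = "<default>",
    n_covered = as.integer(dc[["n_pos"]] + dc[["n_neg"]]),
    n_pos = as.integer(dc[["n_pos"]]), n_neg = as.integer(dc[["n_neg"]]),
    p_amyloid = (dc[["n_pos"]] + 1) / (dc[["n_pos"]] + dc[["n_neg"]] + 2)
  ))
}

#' Model-level summary of a rule list
#'
#' @param x A `vlamy_part` model.
#' @param ... Unused.
#' @return One-row tibble: `n_rules`, `n_features`, `n_train`,
#'   `mean_conditions`, `coverage` (training instances covered by rules, the
#'   rest falling to the default).
#' @export
glance.vlamy_part <- function(x, ...) {
  tibble::tibble(
    n_rules = length(x$rules),
    n_features = length(x$feature_names),
    n_train = x$meta$n_train,
    mean_conditions = if (length(x$rules)) {
      mean(vapply(x$rules, function(r) length(r$conditions), numeric(1)))
    } else 0,
    coverage = sum(vapply(x$rules, `[[`, numeric(1), "n_covered"))
  )
}

#' Serialize a rule list to JSON
#'
#' The model file is human-readable JSON carrying the ordered rules with
#' their leaf class counts, the default counts and the training metadata;
#' [read_part_model()] restores an identical model.
#'
#' @param model A `vlamy_part` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_part_model <- function(model, path) {
  payload <- list(
    format = "vlamy_part/1",
    feature_names = model$feature_names,
    positive = model$positive,
    default_counts = as.list(model$default_counts),
    meta = model$meta,
    rules = lapply(model$rules, function(r) {
      list(conditions = lapply(r$conditions, function(cn) {
        list(feature = cn$feature, op = cn$op, threshold = cn$threshold)
      }),
      n_covered = r$n_covered, n_pos = r$n_pos, n_neg = r$n_neg)
    })
  )
  # I(17) significant digits: doubles round-trip exactly
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_part_model
#' @return `read_part_model()` returns the restored `vlamy_part` model.
#' @export
read_part_model <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) NULL)
  if (is.null(x) || is.null(x$format) || !identical(x$format, "vlamy_part/1")) {
    stop("not a vlamy_part model file: ", path, call. = FALSE)
  }
  structure(list(
    rules = lapply(x$rules, function(r) {
      list(conditions = lapply(r$conditions, function(cn) {
        list(feature = cn$feature, op = cn$op,
             threshold = as.numeric(cn$threshold))
      }),
      n_covered = as.integer(r$n_covered), n_pos = as.integer(r$n_pos),
      n_neg = as.integer(r$n_neg))
    }),
    default_counts = c(n_pos = as.integer(x$default_counts$n_pos),
                       n_neg = as.integer(x$default_counts$n_neg)),
    feature_names = unlist(x$feature_names),
    positive = x$positive,
    meta = x$meta
  ), class = "vlamy_part")
}
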