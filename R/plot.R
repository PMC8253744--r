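#' Class-wise distribution of a feature
#'
#' Boxplot of one extracted feature split by label (and optionally by
#' isotype), the standard way to inspect the direction of class contrasts
#' such as higher CDR hydrophobicity or lower FR gatekeeper content in
#' amyloidogenic sequences.
#'
#' @param features Feature tibble from [vl_features()].
#' @param feature Feature column name (default `"f_hyd_cdr"`).
#' @param by Grouping column, `"label"` or `"isotype"`.
#' @return A ggplot.
#' @export
plot_feature_by_class <- function(features, feature = "f_hyd_cdr",
                                  by = "label") {
  if (!feature %in% names(features)) {
    stop("no such feature column: ", feature, call. = FALSE)
  }
  ggplot2::ggplot(features, ggplot2::aes(x = .data[[by]],
                                         y = .data[[feature]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
}
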