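#' Built-in per-residue disorder profiles
#'
#' Computes a per-residue disorder score for each record by smoothing a
#' disorder-propensity scale with a centered sliding window. The window is
#' truncated at the termini (the effective window shrinks near the ends),
#' so scores never leave the range of the scale. The default scale is the
#' bundled TOP-IDP propensity; this provider deliberately does not emulate
#' IUPred2A's energy-estimation scheme — externally computed IUPred2A scores
#' can be supplied instead through [read_disorder()].
#'
#' @param records VL record tibble.
#' @param scale A `property_scale` of disorder propensities.
#' @param window Odd window width (residues), default 11.
#' @return Tibble with columns `id`, `position` (1-based), `score`.
#' @export
disorder_builtin <- function(records, scale = vl_scale("TOP_IDP"),
                             window = 11) {
  if (window < 1 || window %% 2 == 0) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  half <- (window - 1) / 2
  purrr::map2_dfr(records$id, records$sequence, function(id, seq) {
    n <- nchar(seq)
    if (window > n) {
      stop("window (", window, ") exceeds length of sequence ", id,
           call. = FALSE)
    }
    v <- as.numeric(scale[strsplit(seq, "")[[1]]])
    # masked/nonstandard positions carry no value and drop out of the window
    ok <- !is.na(v)
    cs <- cumsum(c(0, ifelse(ok, v, 0)))
    cn <- cumsum(c(0, ok))
    i <- seq_len(n)
    lo <- pmax(i - half, 1L)
    hi <- pmin(i + half, n)
    tibble::tibble(id = id, position = i,
                   score = (cs[hi + 1] - cs[lo]) / (cn[hi + 1] - cn[lo]))
  })
}

#' Read externally computed disorder scores
#'
#' Reads a TSV with columns `id`, `position` (1-based) and `score` — e.g.
#' exported IUPred2A output. Positions of every id must form a complete,
#' duplicate-free run 1..N.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `id`, `position`, `score`.
#' @export
read_disorder <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols())
  stopifnot(all(c("id", "position", "score") %in% names(x)))
  for (one in split(x, factor(x$id, levels = unique(x$id)))) {
    pos <- sort(one$position)
    if (anyDuplicated(pos)) {
      stop("duplicate position(s) for id ", one$id[1], call. = FALSE)
    }
    want <- seq_len(max(pos))
    miss <- setdiff(want, pos)
    if (length(miss)) {
      stop("id ", one$id[1], " is missing position(s) ",
           paste(head(miss, 5), collapse = ", "), call. = FALSE)
    }
  }
  tibble::as_tibble(x[c("id", "position", "score")])
}

#' Write disorder profiles to TSV
#'
#' Inverse of [read_disorder()].
#'
#' @param profiles Tibble `id`, `position`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disorder <- function(profiles, path) {
  readr::write_tsv(profiles[c("id", "position", "score")], path,
                   progress = FALSE)
  invisible(path)
}

# resolve the disorder argument of vl_features(): "builtin" or a profile tibble
resolve_disorder <- function(records, disorder, window) {
  if (is.character(disorder) && length(disorder) == 1 &&
      disorder == "builtin") {
    return(disorder_builtin(records, window = window))
  }
  if (is.data.frame(disorder)) {
    missing_ids <- setdiff(records$id, disorder$id)
    if (length(missing_ids)) {
      stop("no disorder profile for id(s): ",
           paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
    }
    bad <- records$id[nchar(records$sequence) !=
                        table(factor(disorder$id,
                                     levels = records$id))[records$id]]
    if (length(bad)) {
      stop("disorder profile length mismatch for id(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    return(disorder)
  }
  stop("disorder must be \"builtin\" or a tibble of id/position/score",
       call. = FALSE)
}
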