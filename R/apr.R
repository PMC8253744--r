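#' Read aggregation-prone region (APR) intervals
#'
#' APR intervals come from any external predictor (e.g. TANGO or WALTZ
#' exports) as a TSV with columns `seq_id`, `start`, `end` (1-based,
#' inclusive), optionally `source` (predictor name) and `score`.
#'
#' @param path Path to the TSV.
#' @return Tibble `seq_id`, `start`, `end`, `source`, `score`.
#' @export
read_aprs <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols())
  stopifnot(all(c("seq_id", "start", "end") %in% names(x)))
  if (!"source" %in% names(x)) x$source <- "unknown"
  if (!"score" %in% names(x)) x$score <- NA_real_
  if (any(x$start < 1) || any(x$end < x$start)) {
    stop("APR intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  tibble::as_tibble(x[c("seq_id", "start", "end", "source", "score")])
}

#' Gatekeeper residues in the flanks of APRs
#'
#' Counts gatekeeper residues (D, E, R, K, P) in the k-residue flanks on
#' either side of each APR — positions `[start-k, start-1]` and
#' `[end+1, end+k]`, truncated at the sequence boundaries. An APR is
#' "protected" when at least one gatekeeper occurs in the union of the two
#' flanks; unprotected APRs are the aggregation-permissive cases enriched in
#' amyloidogenic sequences.
#'
#' @param records VL record tibble.
#' @param aprs APR tibble from [read_aprs()] (or with the same columns).
#' @param k Flank width in residues, default 3.
#' @return The APR tibble with added columns `n_gk_left`, `n_gk_right`,
#'   `protected`.
#' @export
flank_gatekeepers <- function(records, aprs, k = 3) {
  stopifnot(k >= 0)
  gk <- residue_category("gatekeeper")
  seqs <- setNames(records$sequence, records$id)
  missing_ids <- setdiff(aprs$seq_id, names(seqs))
  if (length(missing_ids)) {
    stop("APR(s) reference unknown sequence id(s): ",
         paste(unique(missing_ids), collapse = ", "), call. = FALSE)
  }
  count_gk <- function(seq, lo, hi) {
    n <- nchar(seq)
    lo <- max(lo, 1L); hi <- min(hi, n)
    if (lo > hi) return(0L)
    sum(strsplit(substr(seq, lo, hi), "")[[1]] %in% gk)
  }
  res <- purrr::pmap_dfr(aprs, function(seq_id, start, end, ...) {
    s <- seqs[[seq_id]]
    if (start < 1 || end > nchar(s) || end < start) {
      stop("APR [", start, ", ", end, "] out of bounds for ", seq_id,
           call. = FALSE)
    }
    tibble::tibble(
      n_gk_left = count_gk(s, start - k, start - 1),
      n_gk_right = count_gk(s, end + 1, end + k)
    )
  })
  dplyr::mutate(dplyr::bind_cols(aprs, res),
                protected = (.data$n_gk_left + .data$n_gk_right) >= 1)
}

#' Map APRs onto CDR/FR regions
#'
#' For each APR, lists every FR/CDR region it overlaps together with the
#' number of overlapping residues; the per-APR overlap lengths sum to the
#' APR length.
#'
#' @param records VL record tibble.
#' @param aprs APR tibble.
#' @return Long tibble `seq_id`, `start`, `end`, `source`, `region`,
#'   `overlap`.
#' @export
apr_region_map <- function(records, aprs) {
  missing_ids <- setdiff(aprs$seq_id, records$id)
  if (length(missing_ids)) {
    stop("APR(s) reference unknown sequence id(s): ",
         paste(unique(missing_ids), collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(aprs)), function(i) {
    apr <- aprs[i, ]
    rec <- records[records$id == apr$seq_id, ]
    purrr::map_dfr(REGION_NAMES, function(r) {
      rs <- rec[[paste0(tolower(r), "_start")]]
      re <- rec[[paste0(tolower(r), "_end")]]
      ov <- min(apr$end, re) - max(apr$start, rs) + 1
      if (ov <= 0) return(NULL)
      tibble::tibble(seq_id = apr$seq_id, start = apr$start, end = apr$end,
                     source = if ("source" %in% names(apr)) apr$source else
                       "unknown",
                     region = r, overlap = as.integer(ov))
    })
  })
}

#' Dataset-level APR summary
#'
#' @param records VL record tibble.
#' @param aprs APR tibble.
#' @param k Flank width for the gatekeeper analysis.
#' @return List with `region_counts` (tibble `region`, `n_aprs`: APRs
#'   overlapping each region) and `fraction_unprotected` (share of APRs with
#'   no gatekeeper in their +-k flanks).
#' @export
apr_summary <- function(records, aprs, k = 3) {
  region_counts <- tibble::tibble(region = REGION_NAMES, n_aprs = 0L)
  frac_unprot <- NA_real_
  if (nrow(aprs) > 0) {
    rm_ <- apr_region_map(records, aprs)
    cnt <- dplyr::summarise(rm_, n_aprs = dplyr::n(), .by = "region")
    region_counts$n_aprs <- dplyr::coalesce(
      cnt$n_aprs[match(REGION_NAMES, cnt$region)], 0L)
    fl <- flank_gatekeepers(records, aprs, k = k)
    frac_unprot <- mean(!fl$protected)
  } else {
    frac_unprot <- 0
  }
  list(region_counts = region_counts, fraction_unprotected = frac_unprot)
}
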