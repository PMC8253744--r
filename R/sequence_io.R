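# column layout of the region-annotation table (1-based, inclusive)
region_coord_cols <- function() {
  as.vector(t(outer(tolower(REGION_NAMES), c("start", "end"), paste, sep = "_")))
}

#' Read an annotated VL dataset
#'
#' Assembles labeled, IMGT-segmented light-chain variable-domain records from
#' an unaligned FASTA file and a region-annotation TSV. The TSV has one row
#' per sequence id with columns `id`, `fr1_start`, `fr1_end`, `cdr1_start`,
#' ..., `fr4_end` (1-based, inclusive on both ends) and optionally `isotype`
#' (`kappa`/`lambda`/`unknown`) and `label` (`amyloid`/`non_amyloid`).
#' Records whose regions do not tile the sequence exactly in the order
#' FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4, whose boundaries fall outside the
#' sequence, or (under the default `"strict"` policy) whose sequence contains
#' a nonstandard residue, are excluded with a warning — mirroring the removal
#' of sequences with missing or unmatched FRs/CDRs when the reference dataset
#' was curated.
#'
#' @param fasta Path to a FASTA file of unaligned amino-acid sequences.
#' @param regions Path to the region-annotation TSV.
#' @param labels Optional path to a two-column TSV `id`, `label`; overrides
#'   any `label` column in the regions table.
#' @param policy `"strict"` drops records containing residues outside the 20
#'   standard letters; `"mask"` keeps them (masked positions are excluded from
#'   scale averages downstream).
#' @return A tibble with columns `id`, `sequence`, `isotype`, `label` and the
#'   14 region coordinates, one row per accepted record, in input order. The
#'   excluded records are attached as `attr(, "excluded")` (tibble of
#'   `id`, `reason`).
#' @export
read_vl_dataset <- function(fasta, regions, labels = NULL,
                            policy = c("strict", "mask")) {
  policy <- match.arg(policy)
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta, call. = FALSE)
  if (!file.exists(regions)) {
    stop("regions file not found: ", regions, call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- setNames(as.character(aa), ids)

  reg <- readr::read_tsv(regions, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols())
  needed <- c("id", region_coord_cols())
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols)) {
    stop("regions table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reg$id)) {
    stop("duplicate id(s) in regions table", call. = FALSE)
  }
  if (!"isotype" %in% names(reg)) reg$isotype <- "unknown"
  if (!"label" %in% names(reg)) reg$label <- "unlabeled"
  reg$label[is.na(reg$label)] <- "unlabeled"
  reg$isotype[is.na(reg$isotype)] <- "unknown"

  if (!is.null(labels)) {
    lab <- readr::read_tsv(labels, show_col_types = FALSE,
                           progress = FALSE, col_types = readr::cols())
    stopifnot(all(c("id", "label") %in% names(lab)))
    reg$label <- dplyr::coalesce(
      lab$label[match(reg$id, lab$id)], reg$label)
  }

  orphan_fasta <- setdiff(ids, reg$id)
  if (length(orphan_fasta)) {
    warning(length(orphan_fasta),
            " FASTA record(s) without a regions row skipped: ",
            paste(head(orphan_fasta, 5), collapse = ", "))
  }
  excluded <- list()
  orphan_regions <- setdiff(reg$id, ids)
  for (id in orphan_regions) {
    excluded[[length(excluded) + 1]] <-
      tibble::tibble(id = id, reason = "no matching sequence")
  }
  # keep FASTA input order for rows that have annotation
  reg <- reg[match(intersect(ids, reg$id), reg$id), ]

  keep <- logical(nrow(reg))
  sequences <- character(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    id <- reg$id[i]
    s <- seqs[[id]]
    sequences[i] <- s
    reason <- validate_record(s, as.numeric(reg[i, region_coord_cols()]),
                              policy)
    if (is.null(reason)) {
      keep[i] <- TRUE
    } else {
      excluded[[length(excluded) + 1]] <- tibble::tibble(id = id,
                                                         reason = reason)
    }
  }
  excluded <- if (length(excluded)) dplyr::bind_rows(excluded) else
    tibble::tibble(id = character(), reason = character())
  if (nrow(excluded)) {
    warning(nrow(excluded), " record(s) excluded (",
            paste(unique(excluded$reason), collapse = "; "), ")")
  }

  out <- tibble::tibble(
    id = reg$id[keep],
    sequence = sequences[keep],
    isotype = reg$isotype[keep],
    label = reg$label[keep]
  )
  out <- dplyr::bind_cols(
    out, tibble::as_tibble(reg[keep, region_coord_cols()]))
  attr(out, "excluded") <- excluded
  out
}

# NULL if valid, otherwise a reason string
validate_record <- function(sequence, coords, policy = "strict") {
  n <- nchar(sequence)
  if (policy == "strict" &&
      !grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), sequence)) {
    return("nonstandard residue")
  }
  if (anyNA(coords)) return("missing region boundary")
  starts <- coords[seq(1, 13, by = 2)]
  ends <- coords[seq(2, 14, by = 2)]
  if (any(ends < starts)) return("region end before start")
  if (any(starts < 1) || any(ends > n)) return("region outside sequence")
  # regions must tile [1, n] in order with no gap or overlap
  if (starts[1] != 1 || ends[7] != n) return("regions do not span sequence")
  if (any(starts[-1] != ends[-7] + 1)) return("regions overlap or leave gaps")
  NULL
}

#' Extract region sequences from VL records
#'
#' @param records Tibble from [read_vl_dataset()] or [simulate_vl()].
#' @param region One of `"VL"` (whole sequence), `"CDR_all"` (CDR1+CDR2+CDR3
#'   concatenated), `"FR_all"` (FR1+FR2+FR3+FR4 concatenated) or a single
#'   region name (`"FR1"`, `"CDR1"`, ...).
#' @return Character vector of one subsequence per record, in row order.
#' @export
vl_region_seq <- function(records, region = "VL") {
  if (region == "VL") return(records$sequence)
  parts <- switch(region,
    CDR_all = CDR_REGIONS,
    FR_all = FR_REGIONS,
    {
      if (!region %in% REGION_NAMES) {
        stop("unknown region '", region, "'; expected VL, CDR_all, FR_all or ",
             paste(REGION_NAMES, collapse = ", "), call. = FALSE)
      }
      region
    })
  out <- rep("", nrow(records))
  for (p in parts) {
    s <- records[[paste0(tolower(p), "_start")]]
    e <- records[[paste0(tolower(p), "_end")]]
    out <- paste0(out, substr(records$sequence, s, e))
  }
  out
}

#' Write a VL dataset back to FASTA + regions TSV
#'
#' Inverse of [read_vl_dataset()]: the emitted pair of files re-reads to an
#' identical record tibble.
#'
#' @param records VL record tibble.
#' @param fasta,regions Output paths.
#' @return Invisibly, a named list of the two paths.
#' @export
write_vl_dataset <- function(records, fasta, regions) {
  writeLines(paste0(">", records$id, "\n", records$sequence), fasta)
  tab <- dplyr::select(records, "id", dplyr::all_of(region_coord_cols()),
                       "isotype", "label")
  readr::write_tsv(tab, regions, progress = FALSE)
  invisible(list(fasta = fasta, regions = regions))
}

#' Write per-sequence predictions to TSV
#'
#' @param records VL record tibble.
#' @param probabilities Numeric vector, one P(amyloid) per record.
#' @param calls Character vector of calls (`amyloid`/`non_amyloid`).
#' @param path Output path.
#' @param threshold Decision threshold recorded with every row.
#' @return Tibble of the written table, invisibly.
#' @export
write_predictions <- function(records, probabilities, calls, path,
                              threshold = 0.15) {
  if (length(probabilities) != nrow(records) ||
      length(calls) != nrow(records)) {
    stop("records, probabilities and calls must have equal length",
         call. = FALSE)
  }
  out <- tibble::tibble(
    id = records$id,
    isotype = records$isotype,
    P_amyloid = sprintf("%.6f", probabilities),
    call = calls,
    threshold = sprintf("%.6f", rep(threshold, length.out = nrow(records)))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
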