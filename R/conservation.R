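#' Shannon entropy of an alignment column
#'
#' \eqn{H = -\sum_a p_a \log_2 p_a} over the 20 standard residues, with
#' \eqn{p_a} the count of residue a divided by the non-gap total. Gaps are
#' excluded from the distribution (they are reported separately as
#' occupancy); low entropy means high conservation. An all-gap column has
#' undefined entropy and returns `NA`.
#'
#' @param counts Named integer vector of residue counts (names are residue
#'   letters; gap symbols are ignored).
#' @param base Logarithm base; 2 (bits) by default.
#' @return Entropy in `log(base)` units.
#' @examples
#' column_entropy(c(A = 10, V = 10)) # 1 bit
#' @export
column_entropy <- function(counts, base = 2) {
  counts <- counts[names(counts) %in% AA20]
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

gap_chars <- c("-", ".")

# alignment input: path to aligned FASTA, AAStringSet, or named character
as_alignment_matrix <- function(msa) {
  if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    msa <- Biostrings::readAAStringSet(msa)
  }
  if (methods::is(msa, "XStringSet")) {
    msa <- setNames(as.character(msa), sub("\\s.*$", "", names(msa)))
  }
  if (!is.character(msa) || is.null(names(msa))) {
    stop("msa must be an aligned FASTA path, an AAStringSet or a named ",
         "character vector", call. = FALSE)
  }
  widths <- nchar(msa)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: sequences have differing aligned lengths",
         call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Conservation profile of a multiple sequence alignment
#'
#' Computes, per group and alignment column: Shannon entropy over the
#' residue distribution (gaps excluded), occupancy (fraction of non-gap
#' characters) and the consensus residue (modal non-gap residue, ties broken
#' alphabetically; `-` for all-gap columns). Grouping supports the
#' amyloid/non-amyloid and kappa/lambda contrasts of conservation analyses.
#'
#' @param msa Aligned FASTA path, `AAStringSet` or named character vector of
#'   equal-length aligned sequences.
#' @param groups Optional tibble `id`, `group` partitioning the sequence
#'   ids; default puts every sequence in group `"all"`.
#' @param base Entropy logarithm base (2 = bits).
#' @return A tibble of class `msa_profile` with columns `group`, `position`,
#'   `entropy`, `occupancy`, `consensus`, `n_sequences`.
#' @export
profile_msa <- function(msa, groups = NULL, base = 2) {
  m <- as_alignment_matrix(msa)
  if (is.null(groups)) {
    groups <- tibble::tibble(id = rownames(m), group = "all")
  }
  unknown <- setdiff(groups$id, rownames(m))
  if (length(unknown)) {
    stop("group assignment for unknown id(s): ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  out <- purrr::map_dfr(split(groups$id, groups$group), function(ids) {
    sub <- m[ids, , drop = FALSE]
    purrr::map_dfr(seq_len(ncol(sub)), function(j) {
      col <- sub[, j]
      counts <- table(factor(col[col %in% AA20], levels = AA20))
      occ <- mean(!col %in% gap_chars)
      cons <- if (sum(counts) == 0) "-" else {
        names(counts)[which.max(counts)] # ties: alphabetically first
      }
      tibble::tibble(position = j,
                     entropy = column_entropy(counts, base = base),
                     occupancy = occ, consensus = cons,
                     n_sequences = length(ids))
    })
  }, .id = "group")
  class(out) <- c("msa_profile", class(out))
  out
}

#' Consensus sequence from a conservation profile
#'
#' @param profile An `msa_profile` tibble.
#' @param group Group to extract (defaults to the first).
#' @param min_occupancy Columns with occupancy below this floor are rendered
#'   as gaps; the default 0 gaps only all-gap columns.
#' @return A single consensus string.
#' @export
consensus_sequence <- function(profile, group = NULL, min_occupancy = 0) {
  if (is.null(group)) group <- profile$group[1]
  p <- dplyr::arrange(dplyr::filter(profile, .data$group == !!group),
                      .data$position)
  if (nrow(p) == 0) stop("no such group: ", group, call. = FALSE)
  sym <- ifelse(p$occupancy <= 0 |
                  (min_occupancy > 0 & p$occupancy < min_occupancy),
                "-", p$consensus)
  paste(sym, collapse = "")
}

#' Per-region mean entropy
#'
#' Summarises a conservation profile over a region map on alignment columns
#' (e.g. CDR/FR intervals of the consensus numbering).
#'
#' @param profile An `msa_profile`.
#' @param region_map Tibble `region`, `start`, `end` (1-based inclusive
#'   alignment columns).
#' @return Tibble `group`, `region`, `mean_entropy`, `mean_occupancy`.
#' @export
profile_region_summary <- function(profile, region_map) {
  purrr::map_dfr(seq_len(nrow(region_map)), function(i) {
    cols <- seq(region_map$start[i], region_map$end[i])
    profile |>
      dplyr::filter(.data$position %in% cols) |>
      dplyr::summarise(mean_entropy = mean(.data$entropy, na.rm = TRUE),
                       mean_occupancy = mean(.data$occupancy),
                       .by = "group") |>
      dplyr::mutate(region = region_map$region[i], .after = "group")
  })
}

#' Entropy/occupancy plot of a conservation profile
#'
#' Entropy is drawn as bars and occupancy as a line, per group.
#'
#' @param object An `msa_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msa_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$entropy), width = 0.8,
                      fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$occupancy * max(
      object$entropy, na.rm = TRUE)), colour = "firebrick") +
    ggplot2::facet_wrap(~ group, ncol = 1) +
    ggplot2::labs(x = "Alignment position", y = "Shannon entropy (bits)",
                  subtitle = "line: occupancy (rescaled)") +
    ggplot2::theme_minimal()
}

#' Write a conservation profile to TSV
#'
#' @param profile An `msa_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(profile, path, progress = FALSE)
  invisible(path)
}
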