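#' Per-residue property scales
#'
#' A property scale maps each of the 20 standard amino acids to a real value.
#' The registry ships the scales needed by the seven-feature amyloidogenicity
#' model: `HNC` (consensus normalized hydrophobicity), `CHAM830107`
#' (charge-transfer capability), `BULH740101` (transfer free energy to
#' surface), `CF_BETA` (Chou-Fasman beta-sheet propensity) and `TOP_IDP`
#' (intrinsic disorder propensity). Additional scales can be loaded from
#' AAIndex1 flat files with [read_aaindex()] and registered for the session
#' with [register_scale()].
#'
#' @param scale_id Character id of a registered scale.
#' @return `vl_scale()` returns a `property_scale`: a named numeric vector of
#'   length 20 (names are the amino-acid one-letter codes) with attributes
#'   `scale_id`, `description` and `source`.
#' @examples
#' vl_scale("HNC")["I"] # hydrophobic Ile, high on the scale
#' vl_scale_ids()
#' @export
vl_scale <- function(scale_id) {
  reg <- scale_registry()
  if (!scale_id %in% names(reg)) {
    stop("unknown scale id '", scale_id, "'; known scales: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[scale_id]]
}

#' @rdname vl_scale
#' @return `vl_scale_ids()` returns the character vector of registered ids.
#' @export
vl_scale_ids <- function() {
  names(scale_registry())
}

# session-level registry: bundled fixtures + anything added via register_scale
the <- new.env(parent = emptyenv())

scale_registry <- function() {
  if (is.null(the$scales)) {
    the$scales <- purrr::imap(.bundled_scale_values, function(v, id) {
      new_property_scale(setNames(v, .aaindex_order)[AA20], id,
                         .bundled_scale_descriptions[[id]], "bundled")
    })
  }
  the$scales
}

new_property_scale <- function(values, scale_id, description = "", source = "user") {
  if (!setequal(names(values), AA20)) {
    stop("a property scale needs exactly the 20 standard residues as names",
         call. = FALSE)
  }
  values <- values[AA20]
  if (!all(is.finite(values))) {
    stop("scale '", scale_id, "' contains non-finite values", call. = FALSE)
  }
  structure(values, scale_id = scale_id, description = description,
            source = source, class = "property_scale")
}

#' @export
print.property_scale <- function(x, ...) {
  cat("<property_scale> ", attr(x, "scale_id"), " (", attr(x, "source"), ")\n",
      sep = "")
  desc <- attr(x, "description")
  if (nzchar(desc)) cat("  ", desc, "\n", sep = "")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Register a property scale for the session
#'
#' @param values Named numeric vector over the 20 standard residues, or a
#'   `property_scale`.
#' @param scale_id Id under which to register it.
#' @param description Free-text description.
#' @return The registered `property_scale`, invisibly.
#' @export
register_scale <- function(values, scale_id, description = "") {
  sc <- new_property_scale(values, scale_id, description,
                           source = if (inherits(values, "property_scale"))
                             attr(values, "source") else "user")
  reg <- scale_registry()
  reg[[scale_id]] <- sc
  the$scales <- reg
  invisible(sc)
}

#' Read property scales from an AAIndex1 flat file
#'
#' Parses the `H` (accession), `D` (description) and `I` (value) records of
#' the AAIndex1 format. The two 10-column rows of each `I` block are read in
#' the standard AAIndex residue order `ARNDCQEGHILKMFPSTWYV`. Entries with
#' `NA` values are rejected with a warning.
#'
#' @param path Path to an AAIndex1 flat file.
#' @param accessions Optional character vector restricting (and checking) the
#'   accessions to return.
#' @return Named list of `property_scale` objects, one per accession.
#' @export
read_aaindex <- function(path, accessions = NULL) {
  if (!file.exists(path)) stop("AAIndex file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  starts <- grep("^H ", lines)
  if (length(starts) == 0) stop("no AAIndex H records in ", path, call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    acc <- trimws(sub("^H ", "", block[1]))
    d_i <- grep("^D ", block)
    desc <- if (length(d_i)) {
      paste(trimws(sub("^D ", "", block[d_i])), collapse = " ")
    } else ""
    i_i <- grep("^I ", block)
    if (length(i_i) != 1 || i_i + 2 > length(block)) {
      warning("accession ", acc, " has no complete I block; skipped")
      next
    }
    vals <- unlist(strsplit(trimws(paste(block[i_i + 1], block[i_i + 2])),
                            "[[:space:]]+"))
    if (length(vals) != 20) {
      warning("accession ", acc, " I block does not have 20 values; skipped")
      next
    }
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) {
      warning("accession ", acc, " contains NA values; rejected")
      next
    }
    out[[acc]] <- new_property_scale(setNames(num, .aaindex_order)[AA20],
                                     acc, desc, "aaindex_file")
  }
  if (!is.null(accessions)) {
    missing <- setdiff(accessions, names(out))
    if (length(missing)) {
      stop("accession(s) not found in ", path, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    out <- out[accessions]
  }
  out
}

#' Write property scales to an AAIndex1 flat file
#'
#' Inverse of [read_aaindex()]; values round-trip exactly at 6 significant
#' digits.
#'
#' @param scales List of `property_scale` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(scales, path) {
  if (inherits(scales, "property_scale")) scales <- list(scales)
  con <- file(path, "w")
  on.exit(close(con))
  for (sc in scales) {
    v <- as.numeric(sc[.aaindex_order])
    writeLines(c(
      paste("H", attr(sc, "scale_id")),
      paste("D", attr(sc, "description")),
      paste0("I    A/L     R/K     N/M     D/F     C/P",
             "     Q/S     E/T     G/W     H/Y     I/V"),
      paste0("  ", paste(formatC(v[1:10], format = "g", digits = 6),
                         collapse = " ")),
      paste0("  ", paste(formatC(v[11:20], format = "g", digits = 6),
                         collapse = " ")),
      "//"
    ), con)
  }
  invisible(path)
}

#' Normalize a property scale
#'
#' @param scale A `property_scale`.
#' @param mode `"zscore"` (mean 0, sd 1 over the 20 values) or `"minmax"`
#'   (min 0, max 1).
#' @return A normalized `property_scale`.
#' @export
normalize_scale <- function(scale, mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  v <- as.numeric(scale)
  if (diff(range(v)) == 0) {
    stop("cannot normalize a constant scale", call. = FALSE)
  }
  out <- switch(mode,
    zscore = (v - mean(v)) / sd(v),
    minmax = (v - min(v)) / diff(range(v))
  )
  new_property_scale(setNames(out, names(scale)),
                     paste0(attr(scale, "scale_id"), "_", mode),
                     attr(scale, "description"), attr(scale, "source"))
}

#' Residue category sets
#'
#' Named residue sets used by the composition features: `gatekeeper`
#' (D, E, R, K, P — charged or beta-breaking residues that suppress
#' aggregation), `nonpolar` (A, G, I, L, M, P, V), `polar`, `charged`
#' (D, E, K, R), `aromatic` (F, W, Y) and `charge_transfer_acceptor`
#' (D, E, N, Q).
#'
#' @param name Category name.
#' @return Character vector of one-letter residue codes.
#' @examples
#' residue_category("gatekeeper")
#' @export
residue_category <- function(name) {
  if (!name %in% names(.residue_categories)) {
    stop("unknown residue category '", name, "'; known: ",
         paste(names(.residue_categories), collapse = ", "), call. = FALSE)
  }
  .residue_categories[[name]]
}
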