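#' Region-averaged property value
#'
#' The mean of a per-residue property over a region:
#' \eqn{F_{avg} = \sum_{i=1}^{N} F_i / N} where \eqn{F_i} is the scale value
#' of the i-th residue and N the region length. Vectorized over sequences.
#'
#' @param seq Character vector of amino-acid strings.
#' @param scale A `property_scale` (or named numeric over the 20 residues).
#' @return Numeric vector of averages.
#' @examples
#' region_average("AV", vl_scale("HNC"))
#' @export
region_average <- function(seq, scale) {
  if (any(!nzchar(seq))) stop("empty region", call. = FALSE)
  vapply(strsplit(seq, ""), function(ch) {
    v <- scale[ch]
    if (anyNA(v)) {
      stop("residue(s) missing from scale: ",
           paste(unique(ch[is.na(v)]), collapse = ", "), call. = FALSE)
    }
    mean(as.numeric(v))
  }, numeric(1))
}

#' Fraction of residues belonging to a category
#'
#' @param seq Character vector of amino-acid strings.
#' @param category A category name understood by [residue_category()], or a
#'   character vector of residues.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' category_fraction("DAKA", "gatekeeper")
#' @export
category_fraction <- function(seq, category) {
  if (any(!nzchar(seq))) stop("empty sequence", call. = FALSE)
  if (length(category) == 1 && category %in% names(.residue_categories)) {
    category <- residue_category(category)
  }
  vapply(strsplit(seq, ""), function(ch) mean(ch %in% category), numeric(1))
}

#' PAGE-style global sequence features
#'
#' `aromaticity()` is the fraction of F/W/Y residues. `symmetric_charge()` is
#' \eqn{(n_+ - n_-)^2 / L^2} with \eqn{n_+} the count of K/R and \eqn{n_-} the
#' count of D/E — a squared net-charge density that is zero for
#' charge-balanced sequences (a local convention; the original feature has no
#' published formula).
#'
#' @param seq Character vector of amino-acid strings.
#' @return Numeric vector.
#' @export
symmetric_charge <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence", call. = FALSE)
  vapply(strsplit(seq, ""), function(ch) {
    (sum(ch %in% c("K", "R")) - sum(ch %in% c("D", "E")))^2 / length(ch)^2
  }, numeric(1))
}

#' @rdname symmetric_charge
#' @export
aromaticity <- function(seq) {
  category_fraction(seq, c("F", "W", "Y"))
}

final7_feature_names <- function() {
  c("f_hyd_cdr", "f_gk_fr", "f_dis_vl", "f_beta_vl", "f_np_vl",
    "f_ct_cdr", "f_tfe_fr")
}

#' Extract the amyloidogenicity feature matrix
#'
#' Computes per-record features from IMGT-segmented VL records. The
#' `"final7"` panel is the seven-feature model:
#' \describe{
#'   \item{f_hyd_cdr}{mean consensus hydrophobicity (`HNC`) over the pooled
#'     CDR residues}
#'   \item{f_gk_fr}{gatekeeper (D,E,R,K,P) fraction over the pooled FR
#'     residues (stored as a fraction; reports render it as a percentage)}
#'   \item{f_dis_vl}{mean per-residue disorder score over the whole VL}
#'   \item{f_beta_vl}{mean beta-sheet propensity over the whole VL}
#'   \item{f_np_vl}{non-polar (A,G,I,L,M,P,V) fraction over the whole VL}
#'   \item{f_ct_cdr}{mean charge-transfer capability (`CHAM830107`) over the
#'     pooled CDR residues}
#'   \item{f_tfe_fr}{mean transfer free energy to surface (`BULH740101`)
#'     over the pooled FR residues}
#' }
#' The `"extended"` panel adds, for every registered scale, its mean over VL,
#' pooled CDRs and pooled FRs; every residue-category fraction over the same
#' three regions; and the PAGE-style features (symmetric charge, aromaticity,
#' beta-sheet propensity) over VL.
#'
#' @param records VL record tibble.
#' @param disorder `"builtin"` (sliding-window TOP-IDP smoother, see
#'   [disorder_builtin()]) or a tibble of imported scores (`id`, `position`,
#'   `score`).
#' @param panel `"final7"` or `"extended"`.
#' @param cdr_pooling `"pooled"` concatenates all CDR residues before
#'   averaging (length-weighted); `"mean_of_means"` averages the three
#'   per-CDR means.
#' @param beta_scale Scale id used for the beta-propensity feature.
#' @param window Window width for the builtin disorder provider.
#' @return Tibble with columns `id`, `isotype`, `label` and one column per
#'   feature, rows in record order.
#' @export
vl_features <- function(records, disorder = "builtin",
                        panel = c("final7", "extended"),
                        cdr_pooling = c("pooled", "mean_of_means"),
                        beta_scale = "CF_BETA", window = 11) {
  panel <- match.arg(panel)
  cdr_pooling <- match.arg(cdr_pooling)
  prof <- resolve_disorder(records, disorder, window)

  # under the "mask" read policy nonstandard residues may be present; they
  # are excluded from every average and fraction
  strip <- function(s) gsub(paste0("[^", paste(AA20, collapse = ""), "]"),
                            "", s)
  vl <- strip(records$sequence)
  cdr <- strip(vl_region_seq(records, "CDR_all"))
  fr <- strip(vl_region_seq(records, "FR_all"))

  cdr_avg <- function(scale) {
    if (cdr_pooling == "pooled") return(region_average(cdr, scale))
    per_cdr <- vapply(CDR_REGIONS, function(r) {
      region_average(strip(vl_region_seq(records, r)), scale)
    }, numeric(nrow(records)))
    if (!is.matrix(per_cdr)) per_cdr <- t(per_cdr) # single record
    rowMeans(per_cdr)
  }

  dis_mean <- prof |>
    dplyr::summarise(f_dis_vl = mean(.data$score), .by = "id")
  out <- tibble::tibble(
    id = records$id,
    isotype = records$isotype,
    label = records$label,
    f_hyd_cdr = cdr_avg(vl_scale("HNC")),
    f_gk_fr = category_fraction(fr, "gatekeeper"),
    f_dis_vl = dis_mean$f_dis_vl[match(records$id, dis_mean$id)],
    f_beta_vl = region_average(vl, vl_scale(beta_scale)),
    f_np_vl = category_fraction(vl, "nonpolar"),
    f_ct_cdr = cdr_avg(vl_scale("CHAM830107")),
    f_tfe_fr = region_average(fr, vl_scale("BULH740101"))
  )

  if (panel == "extended") {
    segs <- list(vl = vl, cdr = cdr, fr = fr)
    for (sid in vl_scale_ids()) {
      sc <- vl_scale(sid)
      for (seg in names(segs)) {
        out[[paste0("avg_", tolower(sid), "_", seg)]] <-
          region_average(segs[[seg]], sc)
      }
    }
    for (cat in names(.residue_categories)) {
      for (seg in names(segs)) {
        out[[paste0("frac_", cat, "_", seg)]] <-
          category_fraction(segs[[seg]], cat)
      }
    }
    out$symmetric_charge_vl <- symmetric_charge(vl)
    out$aromaticity_vl <- aromaticity(vl)
  }
  out
}

#' Write a feature matrix to TSV
#'
#' @param features Tibble from [vl_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}
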