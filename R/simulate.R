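# default per-region length ranges, approximating IMGT VL geometry
default_region_lengths <- function() {
  list(FR1 = 23:26, CDR1 = 5:12, FR2 = 17, CDR2 = 3, FR3 = 36:39,
       CDR3 = 8:13, FR4 = 10:11)
}

# base residue distributions. CDRs: uniform over the 20 residues. FRs:
# gatekeepers carry 0.25 total mass (0.05 each) so that gatekeeper depletion
# in positives has headroom; the remaining mass is spread evenly. These are
# documented simulation constants, not biological claims.
base_residue_probs <- function() {
  gk <- residue_category("gatekeeper")
  cdr <- setNames(rep(1 / 20, 20), AA20)
  fr <- setNames(rep(0.75 / 15, 20), AA20)
  fr[gk] <- 0.25 / 5
  list(cdr = cdr, fr = fr)
}

#' Simulate a labeled kappa/lambda-like VL dataset
#'
#' Generates IMGT-segmented light-chain variable-domain records with planted
#' class differences. Residues are drawn per position from region-specific
#' categorical distributions; for the positive (amyloid) class the CDR
#' distribution is exponentially tilted toward hydrophobic residues
#' (weight proportional to `exp(delta_hyd * HNC)`), every region is tilted
#' toward disorder-prone residues (`exp(delta_dis * TOP_IDP)`), and the
#' framework gatekeeper probabilities are depleted by the factor
#' `1 - delta_gk`. Setting every delta to 0 makes the two classes
#' exchangeable (a null model). The generator is deterministic given the
#' seed, and its output always passes [read_vl_dataset()] validation.
#'
#' The default deltas plant strong, recoverable effects whose directions
#' mirror the real contrasts between amyloidogenic and non-amyloidogenic
#' light chains: higher CDR hydrophobicity, fewer FR gatekeepers and higher
#' disorder in the positive class. Isotypes are metadata only: 75% of
#' positives are lambda (echoing the real class composition) and negatives
#' are split evenly.
#'
#' @param n_pos,n_neg Number of positive (amyloid) / negative records.
#' @param delta_hyd CDR hydrophobicity tilt for positives (>= 0).
#' @param delta_gk Fractional depletion of FR gatekeeper probability in
#'   positives, in \[0, 1\].
#' @param delta_dis Disorder-propensity tilt for positives (>= 0).
#' @param seed Integer seed.
#' @param region_lengths Named list of candidate lengths per region.
#' @return A VL record tibble (same shape as [read_vl_dataset()] output).
#' @examples
#' sim <- simulate_vl(5, 5, seed = 42)
#' @export
simulate_vl <- function(n_pos, n_neg, delta_hyd = 1.5, delta_gk = 0.5,
                        delta_dis = 1.5, seed = 1,
                        region_lengths = default_region_lengths()) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_pos + n_neg > 0)
  if (delta_hyd < 0 || delta_dis < 0) {
    stop("delta_hyd and delta_dis must be >= 0", call. = FALSE)
  }
  if (delta_gk < 0 || delta_gk > 1) {
    stop("delta_gk must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(setequal(names(region_lengths), REGION_NAMES))

  base <- base_residue_probs()
  hyd <- as.numeric(vl_scale("HNC"))
  dis <- as.numeric(vl_scale("TOP_IDP"))
  gk_mask <- AA20 %in% residue_category("gatekeeper")

  class_probs <- function(positive) {
    cdr <- as.numeric(base$cdr)
    fr <- as.numeric(base$fr)
    if (positive) {
      cdr <- cdr * exp(delta_hyd * hyd + delta_dis * dis)
      fr <- fr * exp(delta_dis * dis)
      # gatekeeper depletion acts on the gatekeepers' share of the FR mass:
      # the positive-class share is the base share scaled by (1 - delta_gk),
      # whatever the other tilts did. (A naive multiplicative factor would be
      # overwhelmed by the disorder tilt, which favours P/E/K.)
      if (delta_gk > 0) {
        s_target <- sum(base$fr[gk_mask]) * (1 - delta_gk)
        fr <- fr / sum(fr)
        gk_sum <- sum(fr[gk_mask])
        if (gk_sum > 0) {
          fr[gk_mask] <- fr[gk_mask] * s_target / gk_sum
          fr[!gk_mask] <- fr[!gk_mask] * (1 - s_target) / (1 - gk_sum)
        }
      }
    }
    if (sum(cdr) <= 0 || sum(fr) <= 0) {
      stop("planted effects reduce a residue distribution to zero mass",
           call. = FALSE)
    }
    list(cdr = cdr / sum(cdr), fr = fr / sum(fr))
  }

  set.seed(seed)
  one_record <- function(id, positive, isotype) {
    pr <- if (positive) probs_pos else probs_neg
    lens <- vapply(REGION_NAMES, function(r) {
      cand <- region_lengths[[r]]
      if (length(cand) == 1) cand else sample(cand, 1)
    }, numeric(1))
    seqs <- vapply(REGION_NAMES, function(r) {
      p <- if (r %in% CDR_REGIONS) pr$cdr else pr$fr
      paste(sample(AA20, lens[[r]], replace = TRUE, prob = p), collapse = "")
    }, character(1))
    ends <- cumsum(lens)
    starts <- ends - lens + 1
    row <- tibble::tibble(
      id = id, sequence = paste(seqs, collapse = ""),
      isotype = isotype,
      label = if (positive) "amyloid" else "non_amyloid")
    for (i in seq_along(REGION_NAMES)) {
      row[[paste0(tolower(REGION_NAMES[i]), "_start")]] <- starts[[i]]
      row[[paste0(tolower(REGION_NAMES[i]), "_end")]] <- ends[[i]]
    }
    row
  }

  probs_pos <- class_probs(TRUE)
  probs_neg <- class_probs(FALSE)
  iso_pos <- sample(c("lambda", "kappa"), n_pos, replace = TRUE,
                    prob = c(0.75, 0.25))
  iso_neg <- sample(c("lambda", "kappa"), n_neg, replace = TRUE)
  dplyr::bind_rows(
    purrr::map(seq_len(n_pos), function(i) {
      one_record(sprintf("sim_pos_%04d", i), TRUE, iso_pos[i])
    }),
    purrr::map(seq_len(n_neg), function(i) {
      one_record(sprintf("sim_neg_%04d", i), FALSE, iso_neg[i])
    })
  )
}

#' Simulate a class-imbalanced VL dataset
#'
#' Reproduces a stated class mix (default 19% amyloidogenic, the imbalance
#' of the reference AL dataset), rounding the positive count to the nearest
#' integer.
#'
#' @param n_total Total number of records (>= 2).
#' @param pos_fraction Fraction of positives in (0, 1).
#' @param ... Passed on to [simulate_vl()] (deltas, seed, region lengths).
#' @return A VL record tibble.
#' @export
simulate_vl_imbalanced <- function(n_total, pos_fraction = 0.19, ...) {
  if (n_total < 2) stop("n_total must be at least 2", call. = FALSE)
  if (pos_fraction <= 0 || pos_fraction >= 1) {
    stop("pos_fraction must lie in (0, 1)", call. = FALSE)
  }
  n_pos <- round(n_total * pos_fraction)
  simulate_vl(n_pos = n_pos, n_neg = n_total - n_pos, ...)
}
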