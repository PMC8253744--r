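# Fixtures are built in code: toy segmented VL records with known geometry,
# plus an independent (brute-force) re-implementation of the C4.5-style
# split chooser used as an oracle for the rule learner.

AA20 <- vlamy:::AA20

# one-row record tibble from explicit region strings
make_record <- function(id, fr1, cdr1, fr2, cdr2, fr3, cdr3, fr4,
                        isotype = "kappa", label = "unlabeled") {
  parts <- c(fr1, cdr1, fr2, cdr2, fr3, cdr3, fr4)
  lens <- nchar(parts)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  row <- tibble::tibble(id = id, sequence = paste(parts, collapse = ""),
                        isotype = isotype, label = label)
  nm <- c("fr1", "cdr1", "fr2", "cdr2", "fr3", "cdr3", "fr4")
  for (i in seq_along(nm)) {
    row[[paste0(nm[i], "_start")]] <- starts[i]
    row[[paste0(nm[i], "_end")]] <- ends[i]
  }
  row
}

# three small valid records with distinct composition
toy_records <- function() {
  dplyr::bind_rows(
    make_record("vl1", "DIQMTQSPSS", "RASQSIS", "WYQQKPGKA", "AAS",
                "GVPSRFSGSGSGTDFTLTISSL", "QQSYSTPL", "FGQGTKVEIK",
                isotype = "kappa", label = "non_amyloid"),
    make_record("vl2", "QSVLTQPPSA", "SGSSSNI", "WYQQLPGTA", "SNN",
                "GVPDRFSGSKSGTSASLAISGL", "AAWDDSLN", "FGGGTKLTVL",
                isotype = "lambda", label = "amyloid"),
    make_record("vl3", "EIVLTQSPGT", "RASQSVS", "WYQQKPGQA", "GAS",
                "GIPDRFSGSGSGTDFTLTISRL", "QQYGSSPR", "FGQGTKVEIK",
                isotype = "kappa", label = "non_amyloid")
  )
}

write_dataset_files <- function(records, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  fa <- file.path(dir, "seqs.fasta")
  rg <- file.path(dir, "regions.tsv")
  write_vl_dataset(records, fa, rg)
  list(fasta = fa, regions = rg, dir = dir)
}

# named scale over all 20 residues, defaulting to `fill`
mk_scale <- function(fill = 0, ...) {
  v <- stats::setNames(rep(fill, 20), AA20)
  dots <- list(...)
  v[names(dots)] <- unlist(dots)
  v
}

# --- independent split-chooser oracle (plain R, brute-force) ----------------
# Same definition as the learner: midpoint candidates between consecutive
# distinct values, per-feature average-gain screen, gain ratio selection,
# ties to lower feature index then lower threshold; most-balanced fallback
# when no candidate has positive gain.
oracle_best_split <- function(X, y) {
  ent <- function(pos, neg) {
    n <- pos + neg
    if (n == 0) return(0)
    p <- c(pos, neg) / n
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  best <- list(feature = 0L, threshold = NA_real_, gain_ratio = -1)
  fallback <- list(feature = 0L, threshold = NA_real_, si = -1)
  m <- nrow(X)
  h_root <- ent(sum(y), m - sum(y))
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    mids <- (head(xs, -1) + tail(xs, -1)) / 2
    mids <- ifelse(mids < tail(xs, -1), mids, head(xs, -1))
    cand <- lapply(mids, function(thr) {
      l <- X[, j] <= thr
      gain <- h_root - mean(l) * ent(sum(y[l]), sum(l) - sum(y[l])) -
        mean(!l) * ent(sum(y[!l]), sum(!l) - sum(y[!l]))
      si <- ent(sum(l), sum(!l))
      list(thr = thr, gain = gain, si = si)
    })
    gains <- vapply(cand, `[[`, numeric(1), "gain")
    keep <- gains >= mean(gains) - 1e-12
    for (cn in cand[keep]) {
      if (cn$gain > 1e-12) {
        gr <- cn$gain / cn$si
        if (gr > best$gain_ratio + 1e-12) {
          best <- list(feature = j, threshold = cn$thr, gain_ratio = gr)
        }
      }
      if (cn$si > fallback$si + 1e-12) {
        fallback <- list(feature = j, threshold = cn$thr, si = cn$si)
      }
    }
  }
  if (best$feature == 0L && fallback$feature > 0L) {
    best <- list(feature = fallback$feature, threshold = fallback$threshold,
                 gain_ratio = 0)
  }
  best
}

# brute-force pairwise AUC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_pairwise_auc <- function(scores, labels, positive = "amyloid") {
  y <- if (is.logical(labels)) labels else labels == positive
  sp <- scores[y]
  sn <- scores[!y]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
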