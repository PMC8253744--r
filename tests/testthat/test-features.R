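test_that("region averages follow the arithmetic-mean definition", {
  expect_equal(region_average("MNPQRS", mk_scale(fill = 2.5)), 2.5)
  av <- mk_scale(A = 0, V = 1)
  expect_equal(region_average("AV", av), 0.5)
  expect_equal(region_average("AAV", av), 1 / 3)
  expect_error(region_average("", av), "empty")
  expect_error(region_average("AZ", av), "missing from scale")
})

test_that("category fractions count members over length", {
  expect_equal(category_fraction("DERKP", "gatekeeper"), 1)
  expect_equal(category_fraction("DAKA", "gatekeeper"), 0.5)
  expect_equal(category_fraction("AGILMPV", "nonpolar"), 1)
  expect_equal(category_fraction("AAA", c("G")), 0)
  expect_error(category_fraction("", "gatekeeper"), "empty")
})

test_that("PAGE-style global features follow their definitions", {
  expect_equal(aromaticity("FWY"), 1)
  expect_equal(aromaticity("AAAA"), 0)
  expect_equal(symmetric_charge("KRDE"), 0) # balanced charges
  expect_equal(symmetric_charge("KKKK"), 1)
  expect_equal(symmetric_charge("KKAA"), (2 / 4)^2)
})

test_that("region averaging is linear in the scale", {
  set.seed(11)
  sc <- mk_scale()
  sc[] <- rnorm(20)
  for (i in 1:20) {
    seq <- paste(sample(AA20, sample(5:40, 1), replace = TRUE),
                 collapse = "")
    a <- runif(1, -2, 2); b <- runif(1, -1, 1)
    expect_equal(region_average(seq, a * sc + b),
                 a * region_average(seq, sc) + b, tolerance = 1e-12)
  }
})

test_that("the VL mean is the length-weighted pool of CDR and FR means", {
  set.seed(12)
  sc <- mk_scale()
  sc[] <- runif(20)
  sim <- simulate_vl(10, 10, seed = 7)
  cdr <- vl_region_seq(sim, "CDR_all")
  fr <- vl_region_seq(sim, "FR_all")
  pooled <- (nchar(cdr) * region_average(cdr, sc) +
               nchar(fr) * region_average(fr, sc)) / nchar(sim$sequence)
  expect_equal(region_average(sim$sequence, sc), pooled, tolerance = 1e-12)
})

test_that("features are invariant to residue shuffling within regions", {
  set.seed(13)
  rec <- toy_records()[2, ]
  shuffle_region <- function(rec) {
    parts <- vapply(vlamy:::REGION_NAMES, function(r) {
      s <- vl_region_seq(rec, r)
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1))
    out <- rec
    out$sequence <- paste(parts, collapse = "")
    out
  }
  # window = 1 disorder makes all seven features purely compositional
  f0 <- vl_features(rec, window = 1)
  for (i in 1:5) {
    fi <- vl_features(shuffle_region(rec), window = 1)
    expect_equal(fi[-1], f0[-1], tolerance = 1e-12)
  }
})

test_that("the seven-feature vector matches brute-force per-residue sums", {
  rec <- make_record("oracle",
                     fr1 = "DIQMTQSPSSLSASVGDRVTITC",  # 23
                     cdr1 = "RASQSISSYLN",              # 11
                     fr2 = "WYQQKPGKAPKLLIYAA",         # 17
                     cdr2 = "SSL",                      # 3
                     fr3 = "QSGVPSRFSGSGSGTDFTLTISSLQPEDFATYYCQQ", # 36
                     cdr3 = "SYSTPLTF",                 # 8
                     fr4 = "GQGTKVEIKRTV")              # 12
  expect_equal(nchar(rec$sequence), 110)

  chars <- strsplit(rec$sequence, "")[[1]]
  cdr_chars <- strsplit(vl_region_seq(rec, "CDR_all"), "")[[1]]
  fr_chars <- strsplit(vl_region_seq(rec, "FR_all"), "")[[1]]

  hnc <- vl_scale("HNC"); ct <- vl_scale("CHAM830107")
  tfe <- vl_scale("BULH740101"); cf <- vl_scale("CF_BETA")
  idp <- vl_scale("TOP_IDP")

  # independent oracle: explicit residue-by-residue summation
  s_hyd <- 0; for (a in cdr_chars) s_hyd <- s_hyd + hnc[[a]]
  s_ct <- 0; for (a in cdr_chars) s_ct <- s_ct + ct[[a]]
  s_tfe <- 0; for (a in fr_chars) s_tfe <- s_tfe + tfe[[a]]
  s_cf <- 0; for (a in chars) s_cf <- s_cf + cf[[a]]
  n_gk <- sum(fr_chars %in% c("D", "E", "R", "K", "P"))
  n_np <- sum(chars %in% c("A", "G", "I", "L", "M", "P", "V"))
  # windowed disorder, brute force over positions
  w <- 11; half <- 5; n <- length(chars)
  dis <- vapply(seq_len(n), function(i) {
    win <- chars[max(1, i - half):min(n, i + half)]
    mean(vapply(win, function(a) idp[[a]], numeric(1)))
  }, numeric(1))

  f <- vl_features(rec, window = 11)
  expect_equal(f$f_hyd_cdr, s_hyd / length(cdr_chars), tolerance = 1e-12)
  expect_equal(f$f_ct_cdr, s_ct / length(cdr_chars), tolerance = 1e-12)
  expect_equal(f$f_tfe_fr, s_tfe / length(fr_chars), tolerance = 1e-12)
  expect_equal(f$f_beta_vl, s_cf / n, tolerance = 1e-12)
  expect_equal(f$f_gk_fr, n_gk / length(fr_chars), tolerance = 1e-12)
  expect_equal(f$f_np_vl, n_np / n, tolerance = 1e-12)
  expect_equal(f$f_dis_vl, mean(dis), tolerance = 1e-12)
})

test_that("cdr_pooling switches between pooled and mean-of-means averaging", {
  rec <- make_record("p", "AAAA", "II", "CCCC", "D", "GGGG", "LLL", "SSSS")
  hnc <- vl_scale("HNC")
  pooled <- vl_features(rec, cdr_pooling = "pooled", window = 1)$f_hyd_cdr
  momean <- vl_features(rec, cdr_pooling = "mean_of_means",
                        window = 1)$f_hyd_cdr
  expect_equal(pooled,
               (2 * hnc[["I"]] + hnc[["D"]] + 3 * hnc[["L"]]) / 6)
  expect_equal(momean, (hnc[["I"]] + hnc[["D"]] + hnc[["L"]]) / 3)
})

test_that("the extended panel is rectangular, finite and self-consistent", {
  sim <- simulate_vl(6, 6, seed = 21)
  f7 <- vl_features(sim)
  expect_equal(dim(f7), c(12, 3 + 7))
  ext <- vl_features(sim, panel = "extended")
  expect_gt(ncol(ext), ncol(f7) + 15 + 18) # 5 scales x3 + 6 categories x3
  num <- dplyr::select(ext, dplyr::where(is.numeric))
  expect_true(all(vapply(num, function(x) all(is.finite(x)), logical(1))))
  expect_equal(ext$frac_nonpolar_vl,
               category_fraction(sim$sequence, "nonpolar"))
  expect_equal(ext$f_np_vl, ext$frac_nonpolar_vl)
  expect_equal(ext$avg_hnc_cdr, ext$f_hyd_cdr)
})

test_that("planted class effects move features in the reference directions", {
  sim <- simulate_vl(80, 80, seed = 31)
  f <- vl_features(sim)
  pos <- f$label == "amyloid"
  expect_gt(mean(f$f_hyd_cdr[pos]), mean(f$f_hyd_cdr[!pos]))
  expect_lt(mean(f$f_gk_fr[pos]), mean(f$f_gk_fr[!pos]))
  expect_gt(mean(f$f_dis_vl[pos]), mean(f$f_dis_vl[!pos]))
})
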