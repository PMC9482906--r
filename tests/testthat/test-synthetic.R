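test_that("generators are pure functions of config and seed", {
  cfg <- generator_config(seed = 101)
  expect_identical(generate_calibration(cfg, analytes = c("A4", "11KA4")),
                   generate_calibration(cfg, analytes = c("A4", "11KA4")))
  expect_identical(generate_qc(cfg, analytes = "A4"),
                   generate_qc(cfg, analytes = "A4"))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  conc <- c(A4 = 10, P4 = 50)
  expect_identical(generate_scans(cfg, conc), generate_scans(cfg, conc))
  # different seeds differ
  cfg2 <- generator_config(seed = 102)
  expect_false(identical(generate_cohort(cfg)$cohort,
                         generate_cohort(cfg2)$cohort))
})

test_that("noiseless calibration reproduces the true slope exactly", {
  cfg <- generator_config(seed = 103, noise_cv = 0)
  cal <- generate_calibration(cfg, analytes = "A4")$calibration
  cv <- fit_calibration(cal$level_nmol_per_L,
                        compute_response(cal$area, cal$is_area))
  expect_equal(cv$slope, cfg$response_slope, tolerance = 1e-12)
  expect_equal(cv$intercept, 0, tolerance = 1e-12)
})

test_that("fitted slopes concentrate around truth at 5% noise (Monte Carlo)", {
  # sampling theory for the 1/x^2-weighted line over this 12-point design:
  # SE(slope)/slope = cv * sqrt(S_w / (S_w*S_wxx - S_wx^2)) with S_w = sum(1/x^2),
  # S_wx = sum(1/x), S_wxx = n, which evaluates to ~1.6% at cv = 5%;
  # +/-3% is ~1.9 SE, so expected coverage is ~94%
  err <- vapply(1:200, function(i) {
    cfg <- generator_config(seed = 1000 + i)
    cal <- generate_calibration(cfg, analytes = "A4")$calibration
    cv <- fit_calibration(cal$level_nmol_per_L,
                          compute_response(cal$area, cal$is_area))
    cv$slope / cfg$response_slope - 1
  }, numeric(1))
  expect_gte(mean(abs(err) <= 0.03), 0.90)
  expect_lt(mean(abs(err)), 0.02)
  expect_lt(abs(mean(err)), 0.005)  # unbiased
})

test_that("QC generation follows the requested bias and CV design", {
  cfg <- generator_config(seed = 104)
  qc0 <- generate_qc(cfg, analytes = "A4",
                     bias = c(LLOQ = 0, low = 0, mid = 0, high = 0),
                     cv = c(LLOQ = 0, low = 0, mid = 0, high = 0))
  expect_equal(nrow(qc0), 4 * 3 * 6)
  s <- summarise_qc(qc0)
  expect_equal(s$inter_day$rsd_percent, rep(0, 4))
  expect_equal(s$inter_day$relative_error_percent, rep(0, 4))
  # +20% mid-level bias must fail validation at the mid level
  qc_bias <- generate_qc(cfg, analytes = "A4",
                         bias = c(LLOQ = 0, low = 0, mid = 0.2, high = 0))
  rules <- apply_fda_rules(summarise_qc(qc_bias)$inter_day)
  lv <- rules$levels
  expect_false(lv$pass[lv$level_name == "mid"])
  expect_false(rules$analytes$pass)
})

test_that("an 18% LLOQ CV usually stays inside the 20% acceptance rule", {
  hits <- vapply(1:40, function(i) {
    cfg <- generator_config(seed = 2000 + i)
    qc <- generate_qc(cfg, analytes = "A4",
                      cv = c(LLOQ = 0.18, low = 0.05, mid = 0.05, high = 0.05))
    rules <- apply_fda_rules(summarise_qc(qc)$inter_day)
    rules$analytes$pass
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("cohort structure matches the study design", {
  cfg <- generator_config(seed = 105)
  coh <- generate_cohort(cfg)$cohort
  expect_equal(nrow(coh), 2 * (11 + 16 + 11 + 9))
  counts <- table(coh$phase[coh$matrix == "serum"])
  expect_equal(unname(counts[c("menstruation", "proliferative", "secretory",
                               "dienogest")]),
               c(11, 16, 11, 9), ignore_attr = TRUE)
  # every PF row is paired with a serum row of the same subject
  pf <- coh[coh$matrix == "PF", ]
  serum <- coh[coh$matrix == "serum", ]
  expect_setequal(pf$subject_id, serum$subject_id)
  expect_equal(anyDuplicated(pf$subject_id), 0)
})

test_that("secretory elevation and dienogest suppression are encoded in truth", {
  cfg <- generator_config(seed = 106)
  truth <- generate_cohort(cfg)$truth
  serum <- truth[truth$matrix == "serum", ]
  p4_secr <- serum$P4[serum$phase == "secretory"]
  p4_prol <- serum$P4[serum$phase == "proliferative"]
  expect_gt(median(p4_secr) / median(p4_prol), 3)
  p4_dien <- serum$P4[serum$phase == "dienogest"]
  expect_lt(median(p4_dien) / median(p4_prol), 0.5)
  # corticoids are untouched by phase
  f_secr <- serum$cortisol[serum$phase == "secretory"]
  f_prol <- serum$cortisol[serum$phase == "proliferative"]
  expect_equal(log(median(f_secr) / median(f_prol)), 0, tolerance = 0.6)
})

test_that("flat phase multipliers abolish classifier separation", {
  cfg <- generator_config(seed = 107, secretory_multiplier = 1,
                          dienogest_suppression = 1)
  coh <- generate_cohort(cfg)$cohort
  cls <- cohort_classifiers(coh)
  d <- cls[cls$classifier == "pf_combined" & is.finite(cls$value), ]
  out <- group_compare(d$value, d$phase)
  expect_gt(out$kruskal$p, 0.05)
  expect_true(all(out$pairwise$label == "Ns"))
})

test_that("secretory-phase classifiers separate in the generator-encoded direction", {
  cfg <- generator_config(seed = 108)
  coh <- generate_cohort(cfg)$cohort
  cls <- cohort_classifiers(coh)
  # generator truth: P4 and 20aOHP4 rise 10x in secretory phase, so the
  # serum classifier numerator rises against activity ratios that cancel
  d <- cls[cls$classifier == "serum_combined" & is.finite(cls$value), ]
  expect_gt(median(d$value[d$phase == "secretory"]),
            median(d$value[d$phase == "proliferative"]))
  d2 <- cls[cls$classifier == "pf_combined" & is.finite(cls$value), ]
  expect_gt(median(d2$value[d2$phase == "secretory"]),
            median(d2$value[d2$phase == "proliferative"]))
})

test_that("permuting the serum/PF pairing destroys the combined classifier's separation less than pairing preserves it", {
  cfg <- generator_config(seed = 109)
  coh <- generate_cohort(cfg)$cohort
  cls <- cohort_classifiers(coh)
  d <- cls[cls$classifier == "serum_pf_combined" & is.finite(cls$value), ]
  sep <- function(v, ph) {
    abs(median(v[ph == "secretory"]) - median(v[ph == "proliferative"]))
  }
  observed <- sep(log10(d$value), d$phase)
  set.seed(1)
  perm <- replicate(20, sep(log10(d$value), sample(d$phase)))
  expect_gt(observed, stats::quantile(perm, 0.9))
})

test_that("scan generation places integrable peaks of the constructed area", {
  cfg <- generator_config(seed = 110, noise_cv = 0)
  conc <- c(A4 = 20)
  sc <- generate_scans(cfg, conc, noise = FALSE)
  p <- cfg$panel
  mz <- p$steroids$mz[p$steroids$abbreviation == "A4"]
  rt <- p$steroids$expected_rt[p$steroids$abbreviation == "A4"]
  x <- extract_xic(sc, mz, 0.005)
  pk <- integrate_peak(x, rt)
  expected_area <- cfg$response_slope * 20 * cfg$is_area * cfg$extraction_recovery
  expect_equal(pk$area, expected_area, tolerance = 0.01)
  # zero concentration gives a blank trace
  sc0 <- generate_scans(cfg, c(A4 = 0), noise = FALSE)
  pk0 <- integrate_peak(extract_xic(sc0, mz, 0.005), rt)
  expect_true(grepl("not_detected", pk0$flags))
})

test_that("m/z jitter beyond the XIC window makes analytes undetectable", {
  cfg <- generator_config(seed = 111, mz_jitter = 0.008)
  conc <- c(A4 = 20)
  sc <- generate_scans(cfg, conc, noise = FALSE)
  p <- cfg$panel
  mz <- p$steroids$mz[p$steroids$abbreviation == "A4"]
  rt <- p$steroids$expected_rt[p$steroids$abbreviation == "A4"]
  pk <- integrate_peak(extract_xic(sc, mz, 0.005), rt)
  # at 8-mmu jitter a 5-mmu window loses a large part of the centroids
  full <- generate_scans(generator_config(seed = 111, mz_jitter = 0.002),
                         conc, noise = FALSE)
  pk_full <- integrate_peak(extract_xic(full, mz, 0.005), rt)
  expect_lt(pk$area, 0.75 * pk_full$area)
})
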