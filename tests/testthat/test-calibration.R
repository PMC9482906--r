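test_that("response ratio is area/IS-area with a hard guard on missing IS", {
  expect_equal(compute_response(1000, 500), 2)
  expect_equal(compute_response(0, 500), 0)
  expect_error(compute_response(100, 0), class = "steroquant_data_error")
  expect_error(compute_response(100, -5), class = "steroquant_data_error")
})

test_that("an exact line is recovered exactly", {
  conc <- c(0.5, 1, 5, 10, 50, 100)
  cv <- fit_calibration(conc, 0.05 * conc, analyte = "A4")
  expect_equal(cv$slope, 0.05, tolerance = 1e-12)
  expect_equal(cv$intercept, 0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-10)
  expect_true(cv$accepted)
  expect_true(all(cv$accuracy$pass))
})

test_that("weighted fit equals the closed-form weighted least-squares accumulation", {
  set.seed(21)
  conc <- exp(seq(log(0.1), log(2000), length.out = 12))
  resp <- 0.05 * conc * exp(rnorm(12, 0, 0.05))
  for (wt in c("1/x^2", "1/x", "none")) {
    cv <- fit_calibration(conc, resp, weighting = wt)
    w <- switch(wt, "1/x^2" = 1 / conc^2, "1/x" = 1 / conc,
                none = rep(1, 12))
    # scalar accumulation of the normal equations
    sw <- sum(w); sx <- sum(w * conc); sy <- sum(w * resp)
    sxx <- sum(w * conc^2); sxy <- sum(w * conc * resp)
    slope <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
    intercept <- (sy - slope * sx) / sw
    expect_equal(cv$slope, slope, tolerance = 1e-10)
    expect_equal(cv$intercept, intercept, tolerance = 1e-10)
  }
})

test_that("a gross outlier level fails back-calculation and is flagged", {
  conc <- c(1, 2, 5, 10, 20, 50, 100)
  resp <- 0.05 * conc
  resp[4] <- resp[4] * 1.8  # +80% at a mid level
  cv <- fit_calibration(conc, resp)
  expect_false(cv$accuracy$pass[4])
  expect_true(all(cv$accuracy$pass[-4]))
  # one failing level out of 7 (14%) still leaves the curve accepted
  expect_true(cv$accepted)
})

test_that("curves reject when more than a quarter of levels fail back-calculation", {
  conc <- c(1, 2, 5, 10, 20, 50)
  resp <- 0.05 * conc
  resp[c(2, 4)] <- resp[c(2, 4)] * c(1.6, 0.4)
  cv <- fit_calibration(conc, resp)
  expect_false(cv$accepted)
  expect_error(back_calculate(cv, 1), class = "steroquant_data_error")
})

test_that("noiseless calibration is linear over four decades", {
  conc <- exp(seq(log(0.1), log(2000), length.out = 12))
  cv <- fit_calibration(conc, 0.05 * conc)
  expect_gte(cv$r_squared, 0.999)
  expect_gte(log10(max(conc) / min(conc)), 4)
})

test_that("back-calculation inverts the curve and applies range flags", {
  conc <- c(1, 5, 25, 100, 500)
  cv <- fit_calibration(conc, 0.05 * conc, analyte = "A4",
                        valid_range = c(1, 500))
  bc <- back_calculate(cv, 2.5)
  expect_equal(bc$concentration, 50)
  expect_identical(bc$flags, "")
  expect_true(grepl("below_lloq", back_calculate(cv, 0.01)$flags))
  expect_true(grepl("above_uloq", back_calculate(cv, 50)$flags))
  # declared 1:4 dilution multiplies before the range check
  bc4 <- back_calculate(cv, 2.5, dilution_factor = 4)
  expect_equal(bc4$concentration, 200)
  expect_true(grepl("diluted", bc4$flags))
  # round trip conc -> response -> conc is the identity on noiseless data
  resp <- cv$intercept + cv$slope * conc
  expect_equal(back_calculate(cv, resp)$concentration, conc,
               tolerance = 1e-9)
})

test_that("correction factor derivation recovers constructed factors exactly", {
  conc <- exp(seq(log(0.5), log(500), length.out = 8))
  surrogate <- fit_calibration(conc, 0.05 * conc, analyte = "A4")
  # analyte ionizes 1/0.329 times as efficiently as the surrogate
  cf <- derive_correction_factor(conc, 0.05 * conc / 0.329, surrogate,
                                 analyte = "11KA4")
  expect_equal(cf$value, 0.329, tolerance = 1e-9)
  expect_equal(cf$surrogate, "A4")
  expect_true(cf$constant)
  # an analyte identical to its surrogate has factor 1
  cf1 <- derive_correction_factor(conc, 0.05 * conc, surrogate)
  expect_equal(cf1$value, 1, tolerance = 1e-9)
})

test_that("correction factors are recovered from noisy series across magnitudes", {
  set.seed(33)
  conc <- exp(seq(log(0.5), log(500), length.out = 12))
  surrogate <- fit_calibration(conc, 0.05 * conc * exp(rnorm(12, 0, 0.05)),
                               analyte = "A4")
  for (f in c(0.1, 0.329, 1, 3)) {
    resp <- 0.05 * conc / f * exp(rnorm(12, 0, 0.05))
    cf <- derive_correction_factor(conc, resp, surrogate)
    expect_equal(cf$value, f, tolerance = 0.08)
  }
})

test_that("surrogate quantitation multiplies the apparent concentration by the factor", {
  conc <- c(1, 5, 25, 100, 500)
  curve <- fit_calibration(conc, 0.05 * conc, analyte = "A4",
                           valid_range = c(1, 500))
  cf <- derive_correction_factor(conc, 0.05 * conc / 0.329, curve,
                                 analyte = "11KA4")
  # apparent 100 nmol/L on the A4 scale -> 32.9 nmol/L of 11KA4
  q <- quantify_untargeted(0.05 * 100, curve, cf, sample_id = "s1")
  expect_equal(q$concentration, 32.9, tolerance = 1e-9)
  expect_equal(q$mode, "untargeted")
  expect_false(grepl("unverified", q$flags))
  # factor 1 reduces to the surrogate back-calculation
  cf1 <- derive_correction_factor(conc, 0.05 * conc, curve)
  expect_equal(quantify_untargeted(0.05 * 40, curve, cf1)$concentration,
               back_calculate(curve, 0.05 * 40)$concentration)
  # surrogate mismatch is a configuration error
  p4_curve <- fit_calibration(conc, 0.05 * conc, analyte = "P4")
  expect_error(quantify_untargeted(1, p4_curve, cf),
               class = "steroquant_config_error")
})

test_that("placeholder factors propagate the unverified flag", {
  p <- tiny_panel()
  conc <- c(1, 5, 25, 100, 500)
  p4 <- fit_calibration(conc, 0.05 * conc, analyte = "P4",
                        valid_range = c(1, 500))
  cf <- panel_correction_factor(p, "20aOHP4")
  expect_false(cf$verified)
  q <- quantify_untargeted(0.05 * 10, p4, cf)
  expect_true(grepl("unverified_factor", q$flags))
  expect_true(panel_correction_factor(p, "11KA4")$verified)
})

test_that("surrogate quantitation is scale-consistent in the analyte area", {
  conc <- c(1, 5, 25, 100, 500)
  curve <- fit_calibration(conc, 0.05 * conc, analyte = "A4",
                           valid_range = c(0.1, 1e4))
  cf <- derive_correction_factor(conc, 0.05 * conc / 0.329, curve)
  is_area <- 5e5
  for (area in c(1e4, 3e4)) {
    q1 <- quantify_untargeted(compute_response(area, is_area), curve, cf)
    q2 <- quantify_untargeted(compute_response(2 * area, is_area), curve, cf)
    expect_equal(q2$concentration / q1$concentration, 2, tolerance = 1e-9)
  }
})

test_that("agreement regression reports slope, offset and offset-vs-median", {
  x <- c(1, 2, 4, 8, 16, 32)
  out <- agreement_analysis(x, x)
  expect_equal(out$slope, 1, tolerance = 1e-12)
  expect_equal(out$offset, 0, tolerance = 1e-12)
  expect_equal(out$r, 1)
  out2 <- agreement_analysis(x, 1.2 * x)
  expect_equal(out2$slope, 1.2, tolerance = 1e-12)
  expect_equal(out2$offset, 0, tolerance = 1e-12)
  out3 <- agreement_analysis(x, x + 3)
  expect_equal(out3$offset_percent_of_median, 100 * 3 / median(x))
  expect_error(agreement_analysis(c(1, 1, 1), c(1, 2, 3)),
               class = "steroquant_data_error")
})

test_that("simulated matrix bias is recovered by the agreement slope", {
  set.seed(8)
  targeted <- exp(rnorm(22, log(10), 1))
  untargeted <- 1.15 * targeted * exp(rnorm(22, 0, 0.05))
  out <- agreement_analysis(targeted, untargeted)
  expect_equal(out$slope, 1.15, tolerance = 0.08)
  expect_lt(abs(out$offset_percent_of_median), 10)
})
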