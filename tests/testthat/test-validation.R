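test_that("RSD and relative error follow their defining formulas", {
  expect_equal(rsd_percent(c(10, 10, 10)), 0)
  expect_equal(rsd_percent(c(9, 10, 11)), 10)  # sample SD 1, mean 10
  expect_equal(relative_error_percent(c(9.5, 9.5), 10), -5)
  expect_equal(relative_error_percent(c(10, 10), 10), 0)
  expect_error(rsd_percent(5), class = "steroquant_data_error")
  expect_error(relative_error_percent(numeric(), 10),
               class = "steroquant_data_error")
  expect_error(relative_error_percent(c(1, 2), 0),
               class = "steroquant_data_error")
})

test_that("RSD matches an independent two-pass SD oracle", {
  set.seed(41)
  x <- rnorm(6, 100, 5)
  m <- sum(x) / length(x)
  ss <- sum((x - m)^2)
  oracle <- 100 * sqrt(ss / (length(x) - 1)) / m
  expect_equal(rsd_percent(x), oracle, tolerance = 1e-12)
})

test_that("the transcribed inter-day validation table passes for all 17 analytes", {
  long <- validation_fixture_long()
  expect_equal(nrow(long), 17 * 4)
  rules <- apply_fda_rules(long)
  expect_equal(rules$summary$n_analytes, 17)
  expect_equal(rules$summary$n_pass, 17)
  expect_equal(rules$summary$n_fail, 0)
  # worst-case dispersion in the table
  lloq <- long[long$level_name == "LLOQ", ]
  expect_equal(max(lloq$rsd_percent), 16.6)
  high <- long[long$level_name == "high", ]
  expect_equal(max(high$rsd_percent), 14.9)
})

test_that("acceptance thresholds are 20% at LLOQ and 15% elsewhere, inclusive", {
  row <- function(level, rsd, re) {
    tibble::tibble(analyte = "X", level_name = level, rsd_percent = rsd,
                   relative_error_percent = re)
  }
  lv <- apply_fda_rules(row("LLOQ", 21, 0), require_levels = "LLOQ")
  expect_false(lv$analytes$pass)
  expect_true(apply_fda_rules(row("LLOQ", 20, -20),
                              require_levels = "LLOQ")$analytes$pass)
  expect_false(apply_fda_rules(row("mid", 15.1, 0),
                               require_levels = "mid")$analytes$pass)
  expect_true(apply_fda_rules(row("mid", 15, 15),
                              require_levels = "mid")$analytes$pass)
  # signed relative error is judged by magnitude
  expect_false(apply_fda_rules(row("low", 3, -16),
                               require_levels = "low")$analytes$pass)
})

test_that("the decision agrees with a brute-force rule table on a metric grid", {
  grid <- tidyr::crossing(
    level_name = c("LLOQ", "low", "mid", "high"),
    rsd_percent = c(0, 5, 14.9, 15, 15.1, 19.9, 20, 20.1, 30),
    relative_error_percent = c(-21, -15, -5, 0, 5, 15, 16, 25)
  )
  grid$analyte <- paste0("g", seq_len(nrow(grid)))
  out <- apply_fda_rules(grid, require_levels = NULL)
  tol <- ifelse(grid$level_name == "LLOQ", 20, 15)
  oracle <- abs(grid$rsd_percent) <= tol & abs(grid$relative_error_percent) <= tol
  expect_equal(unname(out$levels$pass), unname(oracle))
})

test_that("the pass decision is monotone in both metrics", {
  set.seed(42)
  for (i in 1:50) {
    lvl <- sample(c("LLOQ", "low", "mid", "high"), 1)
    rsd <- runif(1, 0, 30)
    re <- runif(1, -30, 30)
    base <- apply_fda_rules(
      tibble::tibble(analyte = "X", level_name = lvl, rsd_percent = rsd,
                     relative_error_percent = re),
      require_levels = lvl)$analytes$pass
    worse <- apply_fda_rules(
      tibble::tibble(analyte = "X", level_name = lvl,
                     rsd_percent = rsd + runif(1, 0, 10),
                     relative_error_percent = re + sign(re + 1e-9) * runif(1, 0, 10)),
      require_levels = lvl)$analytes$pass
    expect_false(!base && worse)  # worsening never flips fail -> pass
  }
})

test_that("missing QC levels leave the analyte incomplete and failing", {
  m <- tibble::tibble(analyte = "X", level_name = c("low", "mid", "high"),
                      rsd_percent = 1, relative_error_percent = 1)
  out <- apply_fda_rules(m)
  expect_false(out$analytes$complete)
  expect_false(out$analytes$pass)
  expect_equal(out$summary$n_incomplete, 1)
})

test_that("carryover passes below 20% of the LLOQ signal", {
  expect_true(check_carryover(0.19 * 1000, 1000)$pass)
  expect_equal(check_carryover(0.19 * 1000, 1000)$percent_of_lloq, 19)
  expect_false(check_carryover(0.25 * 1000, 1000)$pass)
  blank0 <- check_carryover(0, 1000)
  expect_true(blank0$pass)
  expect_equal(blank0$percent_of_lloq, 0)
  expect_error(check_carryover(10, 0), class = "steroquant_data_error")
})

test_that("LLOQ is the lowest level meeting the 20% rule on every day", {
  mk <- function(nominal, day, cv, bias = 0) {
    tibble::tibble(nominal = nominal, day = day,
                   measured = nominal * (1 + bias) *
                     (1 + cv * c(-1.2, -0.6, 0, 0.3, 0.6, 0.9)))
  }
  qc <- dplyr::bind_rows(
    mk(0.1, 1, 0.30), mk(0.1, 2, 0.30), # fails: RSD ~25%+
    mk(0.2, 1, 0.05), mk(0.2, 2, 0.05),
    mk(0.5, 1, 0.05), mk(0.5, 2, 0.05)
  )
  expect_equal(determine_lloq(qc), 0.2)
  # all levels passing returns the lowest level
  qc_all <- dplyr::bind_rows(mk(0.1, 1, 0.05), mk(0.1, 2, 0.05),
                             mk(0.2, 1, 0.05), mk(0.2, 2, 0.05))
  expect_equal(determine_lloq(qc_all), 0.1)
  qc_none <- dplyr::bind_rows(mk(0.1, 1, 0.5), mk(0.2, 1, 0.5))
  expect_error(determine_lloq(qc_none), class = "steroquant_data_error")
})

test_that("LLOQ determination matches the generator's noise model", {
  # CV rises steeply below 0.15 nmol/L: 35% at 0.1, 8% at 0.15, 4% above
  cv_model <- function(level) ifelse(level < 0.15, 0.35,
                                     ifelse(level < 0.3, 0.08, 0.04))
  set.seed(17)
  levels <- c(0.1, 0.15, 0.3, 0.6)
  qc <- dplyr::bind_rows(lapply(levels, function(lv) {
    dplyr::bind_rows(lapply(1:3, function(d) {
      tibble::tibble(nominal = lv, day = d,
                     measured = lv * exp(rnorm(6, 0, cv_model(lv))))
    }))
  }))
  expect_equal(determine_lloq(qc), 0.15)
})

test_that("stability bias and recovery follow their paired definitions", {
  ref <- c(10, 20, 30)
  expect_equal(stability_bias(ref, ref)$bias_percent, 0)
  expect_equal(stability_bias(ref, 0.9 * ref)$bias_percent, -10,
               tolerance = 1e-12)
  expect_error(stability_bias(ref, ref[1:2]), class = "steroquant_data_error")
  expect_equal(recovery_percent(c(8.5, 17), c(10, 20)), 85)
})

test_that("simulated 85% extraction recovery is estimated from raw areas", {
  cfg <- generator_config(seed = 19, extraction_recovery = 0.85)
  cal <- generate_calibration(cfg, analytes = "A4")$calibration
  # raw IS areas are is_area * recovery * noise; spiked equivalent is is_area
  rec <- recovery_percent(cal$is_area, rep(cfg$is_area, nrow(cal)))
  expect_equal(rec, 85, tolerance = 0.03)
})

test_that("QC summarisation pools days for inter-day and splits for intra-day", {
  qc <- tidyr::crossing(day = 1:3, replicate = 1:6) |>
    dplyr::mutate(analyte = "A4", level_name = "mid", nominal = 10,
                  measured = 10 + day)  # identical within day
  s <- summarise_qc(qc)
  expect_equal(nrow(s$intra_day), 3)
  expect_equal(s$intra_day$rsd_percent, rep(0, 3))
  expect_equal(s$inter_day$n, 18)
  expect_gt(s$inter_day$rsd_percent, 0)
  expect_equal(s$inter_day$relative_error_percent,
               100 * (mean(qc$measured) - 10) / 10)
})

test_that("report rendering swaps only the headers, never the numbers", {
  wide <- load_validation_fixture()
  plain <- render_validation_report(wide, paper_labels = FALSE)
  paper <- render_validation_report(wide, paper_labels = TRUE)
  expect_equal(unname(as.matrix(plain[, -1])), unname(as.matrix(paper[, -1])))
  expect_true(any(grepl("Accuracy \\(RSD", names(paper))))
  expect_true(any(grepl("rsd_percent", names(plain))))
  expect_equal(nrow(plain), 17)
  expect_equal(ncol(plain), 11)  # analyte + 10 numeric columns
})
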