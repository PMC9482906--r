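# Internal-standard-normalised calibration, back-calculation, and the
# surrogate-calibration scheme: untargeted analytes are quantified through
# the calibration curve of a targeted surrogate (A4 or P4) and corrected by
# a compound-specific ionization-efficiency factor.

#' Internal-standard response ratio
#'
#' The quantitation response of isotope-dilution assays: analyte peak area
#' divided by the area of the assigned internal standard.
#'
#' @param area Analyte peak area (counts x min), >= 0.
#' @param is_area Internal-standard peak area, > 0.
#' @return Dimensionless response ratio.
#' @examples
#' compute_response(1000, 500) # 2
#' @export
compute_response <- function(area, is_area) {
  if (any(is_area <= 0)) {
    data_error("internal-standard area is zero or negative; sample must be flagged, not zeroed")
  }
  if (any(area < 0)) data_error("negative peak area")
  area / is_area
}

#' Fit a weighted calibration line
#'
#' Weighted least-squares fit of response on concentration over the
#' calibrant series (12-point by design). Per-level back-calculated
#' concentrations are compared to nominal; a level fails when its
#' back-calculated accuracy deviates more than 15% (20% at the lowest
#' level) from nominal, and the curve as a whole is rejected when more
#' than 25% of levels fail.
#'
#' @param levels Calibrant concentrations (nmol/L), >= 5 distinct values.
#' @param responses IS-normalised responses, same length, >= 0.
#' @param weighting `"1/x^2"` (default), `"1/x"` or `"none"`.
#' @param analyte Label carried into the curve.
#' @param valid_range Optional `c(lloq, uloq)`; defaults to the fitted
#'   level range.
#' @return A `calibration_curve`: list with `analyte`, `slope`,
#'   `intercept`, `weighting`, `r_squared`, `level_concs`, `valid_range`,
#'   `accuracy` (per-level back-calculation tibble) and `accepted`.
#' @export
fit_calibration <- function(levels, responses, weighting = c("1/x^2", "1/x", "none"),
                            analyte = NA_character_, valid_range = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(length(levels) == length(responses))
  if (length(unique(levels)) < 5) {
    data_error("calibration needs >= 5 distinct levels")
  }
  if (any(responses < 0)) data_error("negative responses")
  if (any(levels <= 0)) data_error("calibrant concentrations must be > 0")
  w <- switch(weighting, "1/x^2" = 1 / levels^2, "1/x" = 1 / levels, none = rep(1, length(levels)))
  fit <- stats::lm(responses ~ levels, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  rss <- sum(w * stats::residuals(fit)^2)
  tss <- sum(w * (responses - stats::weighted.mean(responses, w))^2)
  r_squared <- if (tss > 0) 1 - rss / tss else NA_real_
  if (!is.finite(slope) || slope <= 0) {
    data_error("calibration fit degenerate (slope <= 0)")
  }
  back <- (responses - intercept) / slope
  tol <- ifelse(levels == min(levels), 20, 15)
  acc <- tibble::tibble(
    level = levels, response = responses, back_calculated = back,
    accuracy_percent = 100 * (back - levels) / levels,
    tolerance_percent = tol,
    pass = abs(100 * (back - levels) / levels) <= tol
  )
  accepted <- mean(!acc$pass) <= 0.25
  structure(list(
    analyte = analyte, slope = slope, intercept = intercept,
    weighting = weighting, r_squared = r_squared,
    level_concs = sort(unique(levels)),
    valid_range = valid_range %||% range(levels),
    accuracy = acc, accepted = accepted
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: slope %.4g, intercept %.4g, r2 %.5f (%s)\n",
              x$analyte %||% "?", x$slope, x$intercept, x$r_squared,
              if (x$accepted) "accepted" else "REJECTED"))
  invisible(x)
}

#' Back-calculate a concentration from a response
#'
#' Inverts the calibration line: `conc = (response - intercept) / slope`,
#' then applies `below_lloq` / `above_uloq` flags against the curve's
#' valid range. A declared dilution multiplies the concentration by the
#' dilution factor before the range check.
#'
#' @param curve An accepted `calibration_curve`.
#' @param response Response ratio(s).
#' @param dilution_factor Multiplier applied to the back-calculated value
#'   (e.g. 4 for a 1:4 dilution); flagged `diluted` when != 1.
#' @return Tibble with `concentration` (nmol/L) and `flags`.
#' @export
back_calculate <- function(curve, response, dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    data_error("invalid calibration curve (slope <= 0)")
  }
  if (!isTRUE(curve$accepted)) {
    data_error("calibration curve was rejected; refusing to back-calculate")
  }
  conc <- (response - curve$intercept) / curve$slope * dilution_factor
  flags <- vapply(conc, function(cc) {
    f <- character(0)
    if (dilution_factor != 1) f <- c(f, "diluted")
    if (cc < curve$valid_range[1]) f <- c(f, "below_lloq")
    if (cc > curve$valid_range[2]) f <- c(f, "above_uloq")
    join_flags(f)
  }, character(1))
  tibble::tibble(concentration = conc, flags = flags)
}

#' Derive an ionization-efficiency correction factor
#'
#' Implements the surrogate-calibration comparison: each calibrant response
#' of the untargeted analyte is back-calculated through the surrogate's
#' curve into an apparent (surrogate-equivalent) concentration, and the
#' correction factor is the slope of the zero-intercept weighted regression
#' of true on apparent concentration. With `1/x^2` weights this equals the
#' mean per-level ratio true/apparent, so the factor is the constant by
#' which a surrogate-derived concentration must be multiplied (e.g. 0.329
#' for 11KA4 read off the A4 curve). Per-level estimates and their spread
#' are recorded; the factor is only accepted as constant when every
#' per-level estimate lies within 15% of the pooled value.
#'
#' @param conc True calibrant concentrations of the untargeted analyte
#'   (nmol/L), >= 3 levels inside the surrogate's valid range.
#' @param response IS-normalised responses of the untargeted analyte.
#' @param surrogate_curve The surrogate's accepted `calibration_curve`.
#' @param analyte Label carried into the result.
#' @return A `correction_factor`: list with `analyte`, `surrogate`,
#'   `value`, `r_squared`, `n_levels`, `per_level` tibble, `constant`
#'   (within-15% acceptance) and `verified = TRUE`.
#' @export
derive_correction_factor <- function(conc, response, surrogate_curve,
                                     analyte = NA_character_) {
  stopifnot(length(conc) == length(response))
  inside <- conc >= surrogate_curve$valid_range[1] &
    conc <= surrogate_curve$valid_range[2]
  conc <- conc[inside]
  response <- response[inside]
  if (length(unique(conc)) < 3) {
    data_error("need >= 3 levels inside the surrogate's valid range")
  }
  apparent <- back_calculate(surrogate_curve, response)$concentration
  if (any(apparent <= 0)) {
    data_error("non-positive apparent concentrations; cannot derive factor")
  }
  # zero-intercept weighted regression of true on apparent (1/x^2 weights)
  w <- 1 / apparent^2
  value <- sum(w * apparent * conc) / sum(w * apparent^2)
  # uncentred R^2, the zero-intercept convention
  r_squared <- 1 - sum(w * (conc - value * apparent)^2) / sum(w * conc^2)
  per_level <- tibble::tibble(conc = conc, apparent = apparent,
                              factor_estimate = conc / apparent)
  constant <- all(abs(per_level$factor_estimate / value - 1) <= 0.15)
  structure(list(analyte = analyte, surrogate = surrogate_curve$analyte,
                 value = value, r_squared = r_squared,
                 n_levels = length(unique(conc)), per_level = per_level,
                 constant = constant, verified = TRUE),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("<correction_factor> %s vs %s: %.4g (%d levels, %s)\n",
              x$analyte %||% "?", x$surrogate %||% "?", x$value, x$n_levels,
              if (isTRUE(x$constant)) "constant across range" else "NOT constant"))
  invisible(x)
}

#' Build a correction factor object from a panel entry
#'
#' Wraps a configured (rather than freshly derived) factor, propagating
#' whether it has been experimentally verified.
#'
#' @param panel A `steroid_panel`.
#' @param analyte Untargeted analyte abbreviation.
#' @return A `correction_factor` with `verified` taken from the panel.
#' @export
panel_correction_factor <- function(panel, analyte) {
  s <- panel$steroids[panel$steroids$abbreviation == analyte, ]
  if (nrow(s) != 1) reference_error(paste0("unknown analyte: ", analyte))
  if (s$quant_mode != "untargeted") {
    config_error(paste0(analyte, " is targeted; no correction factor applies"))
  }
  structure(list(analyte = analyte, surrogate = s$surrogate_ref,
                 value = s$correction_factor, r_squared = NA_real_,
                 n_levels = NA_integer_, per_level = NULL, constant = NA,
                 verified = isTRUE(s$cf_verified)),
            class = "correction_factor")
}

#' Quantify an untargeted analyte by surrogate calibration
#'
#' Back-calculates the response through the surrogate's calibration curve
#' and multiplies the apparent concentration by the analyte's correction
#' factor. Results from placeholder (unverified) factors carry an
#' `unverified_factor` flag.
#'
#' @param response Response ratio(s) of the untargeted analyte.
#' @param surrogate_curve Accepted `calibration_curve` of the surrogate.
#' @param cf A `correction_factor` whose `surrogate` matches the curve.
#' @param sample_id,analyte Identifiers carried into the result.
#' @param dilution_factor Passed to [back_calculate()].
#' @return A `QuantResult` tibble: `sample_id`, `analyte`,
#'   `concentration`, `mode = "untargeted"`, `flags`.
#' @examples
#' curve <- fit_calibration(c(1, 5, 25, 100, 500), 0.05 * c(1, 5, 25, 100, 500),
#'                          analyte = "A4")
#' cf <- structure(list(analyte = "11KA4", surrogate = "A4", value = 0.329,
#'                      verified = TRUE), class = "correction_factor")
#' quantify_untargeted(0.05 * 100, curve, cf) # 100 nmol/L apparent -> 32.9
#' @export
quantify_untargeted <- function(response, surrogate_curve, cf,
                                sample_id = NA_character_,
                                analyte = cf$analyte,
                                dilution_factor = 1) {
  stopifnot(inherits(cf, "correction_factor"))
  if (!identical(cf$surrogate, surrogate_curve$analyte)) {
    config_error(sprintf(
      "correction factor is relative to %s but the curve is for %s",
      cf$surrogate, surrogate_curve$analyte))
  }
  bc <- back_calculate(surrogate_curve, response, dilution_factor)
  flags <- bc$flags
  if (!isTRUE(cf$verified)) {
    flags <- vapply(flags, function(f) join_flags(f, "unverified_factor"),
                    character(1), USE.NAMES = FALSE)
  }
  tibble::tibble(sample_id = sample_id, analyte = analyte,
                 concentration = bc$concentration * cf$value,
                 mode = "untargeted", flags = flags)
}

#' Quantify a targeted analyte
#'
#' @param response Response ratio(s).
#' @param curve The analyte's own accepted `calibration_curve`.
#' @param sample_id Identifier carried into the result.
#' @param dilution_factor Passed to [back_calculate()].
#' @return A `QuantResult` tibble with `mode = "targeted"`.
#' @export
quantify_targeted <- function(response, curve, sample_id = NA_character_,
                              dilution_factor = 1) {
  bc <- back_calculate(curve, response, dilution_factor)
  tibble::tibble(sample_id = sample_id, analyte = curve$analyte,
                 concentration = bc$concentration, mode = "targeted",
                 flags = bc$flags)
}

#' Targeted-vs-untargeted agreement regression
#'
#' Ordinary least squares of untargeted on targeted concentrations for
#' paired measurements of the same samples, summarising the constant bias
#' (slope) and offset introduced by surrogate calibration. The offset is
#' also reported as a percentage of the median targeted concentration.
#'
#' @param targeted,untargeted Paired concentration vectors (>= 3 pairs).
#' @return List with `slope`, `offset`, `offset_percent_of_median`, `r`
#'   and `n`.
#' @export
agreement_analysis <- function(targeted, untargeted) {
  keep <- is.finite(targeted) & is.finite(untargeted)
  targeted <- targeted[keep]
  untargeted <- untargeted[keep]
  if (length(targeted) < 3) data_error("need >= 3 paired values")
  if (stats::var(targeted) == 0) {
    data_error("targeted concentrations have zero variance")
  }
  fit <- stats::lm(untargeted ~ targeted)
  list(slope = unname(stats::coef(fit)[2]),
       offset = unname(stats::coef(fit)[1]),
       offset_percent_of_median = 100 * unname(stats::coef(fit)[1]) /
         stats::median(targeted),
       r = stats::cor(targeted, untargeted),
       n = length(targeted))
}

#' Fit calibration curves for every analyte in a calibration table
#'
#' @param calib Tibble with columns `analyte`, `level_nmol_per_L`, `area`,
#'   `is_area`.
#' @param weighting Passed to [fit_calibration()].
#' @param valid_ranges Optional named list of `c(lloq, uloq)` per analyte.
#' @return Named list of `calibration_curve` objects.
#' @export
fit_calibration_table <- function(calib, weighting = "1/x^2",
                                  valid_ranges = NULL) {
  calib <- tibble::as_tibble(calib)
  out <- lapply(split(calib, calib$analyte), function(d) {
    fit_calibration(d$level_nmol_per_L,
                    compute_response(d$area, d$is_area),
                    weighting = weighting, analyte = d$analyte[1],
                    valid_range = valid_ranges[[d$analyte[1]]])
  })
  out
}

#' Quantify a sample-area table against fitted curves
#'
#' Runs the full quantitation over a long table of per-sample peak areas:
#' targeted analytes through their own curves, untargeted analytes through
#' their surrogate's curve and the panel correction factor.
#'
#' @param areas Tibble with columns `sample_id`, `analyte`, `area`,
#'   `is_area`.
#' @param curves Named list of accepted curves (from
#'   [fit_calibration_table()]); must include every targeted analyte and
#'   every referenced surrogate.
#' @param panel A `steroid_panel`.
#' @param dilution_factor Single declared dilution applied to all samples.
#' @return `QuantResult` tibble: `sample_id`, `analyte`, `concentration`,
#'   `mode`, `flags`.
#' @export
quantify_samples <- function(areas, curves, panel, dilution_factor = 1) {
  areas <- tibble::as_tibble(areas)
  rows <- lapply(seq_len(nrow(areas)), function(i) {
    r <- areas[i, ]
    s <- panel$steroids[panel$steroids$abbreviation == r$analyte, ]
    if (nrow(s) != 1) reference_error(paste0("unknown analyte: ", r$analyte))
    resp <- compute_response(r$area, r$is_area)
    if (s$quant_mode == "targeted") {
      curve <- curves[[r$analyte]]
      if (is.null(curve)) config_error(paste0("no curve for ", r$analyte))
      quantify_targeted(resp, curve, sample_id = r$sample_id,
                        dilution_factor = dilution_factor)
    } else {
      curve <- curves[[s$surrogate_ref]]
      if (is.null(curve)) {
        config_error(paste0("no surrogate curve (", s$surrogate_ref,
                            ") for ", r$analyte))
      }
      quantify_untargeted(resp, curve, panel_correction_factor(panel, r$analyte),
                          sample_id = r$sample_id, analyte = r$analyte,
                          dilution_factor = dilution_factor)
    }
  })
  dplyr::bind_rows(rows)
}
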