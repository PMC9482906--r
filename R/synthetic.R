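# Synthetic-data generator: calibration series, QC replicate sets, a
# phase-structured paired serum/PF cohort, and centroided scan data — all
# with known ground truth, so that every pipeline stage can be exercised
# and checked without instrument data.
#
# Distributional choices (documented defaults, not instrument-derived):
# biological between-subject variation is lognormal with geometric SD 1.6;
# measurement noise is multiplicative lognormal with CV 5%; extraction
# recovery 85% (cancels out of internal-standard-normalised responses, as
# calibrants and samples are extracted alike).

#' Generator configuration
#'
#' Fixes every knob of the synthetic-data generators. All generators are
#' pure functions of `(config, seed)`: the same config and seed give
#' byte-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param panel A `steroid_panel` (defaults to [default_panel()]).
#' @param calibration_range Design range of untargeted calibrations
#'   (nmol/L), default 0.1-2000.
#' @param n_levels Calibration points per curve (default 12).
#' @param noise_cv Multiplicative measurement noise CV (default 0.05).
#' @param extraction_recovery Fraction of analyte surviving sample
#'   preparation (default 0.85); scales raw areas, not responses.
#' @param biological_gsd Geometric SD of between-subject variation
#'   (default 1.6).
#' @param cohort_sizes Named subject counts per phase; defaults to the
#'   study design 11 menstruation / 16 proliferative / 11 secretory /
#'   9 dienogest.
#' @param pf_class_ratio Named PF:serum concentration ratio per steroid
#'   class: progestogens and their precursors are enriched ~2.5x in PF,
#'   corticoids and androgens ~2x higher in serum.
#' @param secretory_multiplier Fold-elevation of P4 and its direct
#'   (one-enzymatic-step) metabolites in the secretory phase (default 10).
#' @param dienogest_suppression Multiplier applied to progestogens under
#'   dienogest (default 0.1).
#' @param response_slope True response per nmol/L common to all analytes
#'   (default 0.05).
#' @param is_area Mean internal-standard raw area before recovery
#'   (default 5e5 counts x min).
#' @param chrom_sigma Chromatographic peak SD (minutes, default 0.03).
#' @param scan_interval Scan spacing (minutes, default 0.005).
#' @param mz_jitter Centroid m/z jitter half-width (Th, default 0.002,
#'   i.e. 2 mmu so the 5-mmu XIC window always captures the centroid).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             panel = default_panel(),
                             calibration_range = c(0.1, 2000),
                             n_levels = 12L,
                             noise_cv = 0.05,
                             extraction_recovery = 0.85,
                             biological_gsd = 1.6,
                             cohort_sizes = c(menstruation = 11L, proliferative = 16L,
                                              secretory = 11L, dienogest = 9L),
                             pf_class_ratio = c(progestogen = 2.5, precursor = 2.5,
                                                androgen = 0.5, `C11-oxy androgen` = 0.5,
                                                glucocorticoid = 0.5,
                                                mineralocorticoid = 0.5),
                             secretory_multiplier = 10,
                             dienogest_suppression = 0.1,
                             response_slope = 0.05,
                             is_area = 5e5,
                             chrom_sigma = 0.03,
                             scan_interval = 0.005,
                             mz_jitter = 0.002) {
  stopifnot(noise_cv >= 0, noise_cv <= 2,
            extraction_recovery > 0, extraction_recovery <= 2,
            length(calibration_range) == 2, all(calibration_range > 0))
  structure(list(
    seed = as.integer(seed), panel = panel,
    calibration_range = calibration_range, n_levels = as.integer(n_levels),
    noise_cv = noise_cv, extraction_recovery = extraction_recovery,
    biological_gsd = biological_gsd, cohort_sizes = cohort_sizes,
    pf_class_ratio = pf_class_ratio,
    secretory_multiplier = secretory_multiplier,
    dienogest_suppression = dienogest_suppression,
    response_slope = response_slope, is_area = is_area,
    chrom_sigma = chrom_sigma, scan_interval = scan_interval,
    mz_jitter = mz_jitter
  ), class = "generator_config")
}

# multiplicative lognormal noise with mean 1 and the requested CV
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

# P4 plus its one-enzymatic-step metabolites: the analytes elevated
# together with the corpus-luteum P4 surge
SECRETORY_ELEVATED <- c("P4", "17OHP4", "20aOHP4", "5aDHP4", "5bDHP4",
                        "11aOHP4", "11bOHP4", "16aOHP4", "6aOHP4")

# Baseline serum medians (nmol/L) for the cohort generator: class-level
# defaults with analyte overrides in the physiological range. Generator
# placeholders, not measured population values.
.BASELINE_DEFAULT <- c(progestogen = 0.6, androgen = 1.5,
                       `C11-oxy androgen` = 0.8, glucocorticoid = 2,
                       mineralocorticoid = 0.8, precursor = 3)
.BASELINE_OVERRIDE <- c(
  P4 = 1.5, P5 = 3, `17OHP4` = 2, A4 = 3.5, T = 1.2, DHT = 0.4, An = 1.5,
  Etio = 1.2, DHEA = 12, DHEAS = 3500, cortisol = 300, cortisone = 55,
  corticosterone = 12, `11DOC` = 0.25, `11deoxycortisol` = 1,
  `21deoxycortisol` = 0.3, aldosterone = 0.3, `11OHA4` = 4, `11KA4` = 0.5,
  `11KT` = 0.8, `11OHT` = 0.3, THF = 6, THE = 8
)

baseline_concentrations <- function(panel) {
  s <- panel$steroids
  base <- .BASELINE_DEFAULT[s$steroid_class]
  ov <- .BASELINE_OVERRIDE[s$abbreviation]
  out <- ifelse(is.na(ov), base, ov)
  names(out) <- s$abbreviation
  out
}

true_correction_factors <- function(panel) {
  s <- panel$steroids
  cf <- ifelse(s$quant_mode == "untargeted", s$correction_factor, NA_real_)
  names(cf) <- s$abbreviation
  cf
}

#' Generate a calibration series with known truth
#'
#' For each analyte, produces peak and internal-standard areas over the
#' calibration levels. Targeted analytes respond with the true slope;
#' untargeted analytes respond through their surrogate's slope divided by
#' the true correction factor (an analyte needing multiplication by 0.329
#' ionizes 1/0.329 times as efficiently as its surrogate). Multiplicative
#' lognormal noise at `noise_cv` is applied to analyte and IS areas.
#'
#' @param config A `generator_config`.
#' @param analytes Abbreviations to generate (default: whole panel).
#' @param levels Optional explicit calibrant concentrations used for every
#'   analyte (e.g. a matched surrogate/analyte series over the 0.1-2000
#'   design range); the default takes each targeted analyte's validated
#'   range and the design range for untargeted analytes.
#' @return List: `calibration` tibble (`analyte`, `level_nmol_per_L`,
#'   `area`, `is_area`) and `truth` (list with `response_slope`,
#'   `correction_factors`).
#' @export
generate_calibration <- function(config, analytes = NULL, levels = NULL) {
  stopifnot(inherits(config, "generator_config"))
  panel <- config$panel
  if (is.null(analytes)) analytes <- panel$steroids$abbreviation
  set.seed(config$seed)
  cf <- true_correction_factors(panel)
  forced_levels <- levels
  rows <- lapply(analytes, function(ab) {
    s <- panel$steroids[panel$steroids$abbreviation == ab, ]
    levels <- if (!is.null(forced_levels)) {
      forced_levels
    } else if (s$quant_mode == "targeted") {
      calibration_levels(panel, ab)
    } else {
      exp(seq(log(config$calibration_range[1]), log(config$calibration_range[2]),
              length.out = config$n_levels))
    }
    eff_slope <- if (s$quant_mode == "targeted") {
      config$response_slope
    } else {
      config$response_slope / cf[[ab]]
    }
    is_area <- config$is_area * config$extraction_recovery *
      lognormal_noise(length(levels), config$noise_cv)
    response <- eff_slope * levels * lognormal_noise(length(levels), config$noise_cv)
    tibble::tibble(analyte = ab, level_nmol_per_L = levels,
                   area = response * is_area, is_area = is_area)
  })
  list(calibration = dplyr::bind_rows(rows),
       truth = list(response_slope = config$response_slope,
                    correction_factors = cf[analytes]))
}

#' Generate QC replicate sets
#'
#' Six replicates at four QC levels (LLOQ, low, mid, high) on three days
#' per targeted analyte, with configurable per-level bias and CV.
#'
#' @param config A `generator_config`.
#' @param analytes Targeted abbreviations (default: all targeted).
#' @param bias Named per-level fractional bias (default 0 everywhere).
#' @param cv Named per-level CV (default: 10% at LLOQ, 5% elsewhere).
#' @param n_replicates,n_days Replication design (defaults 6 and 3).
#' @return Tibble: `analyte`, `level_name`, `nominal`, `day`, `replicate`,
#'   `measured`.
#' @export
generate_qc <- function(config, analytes = NULL,
                        bias = c(LLOQ = 0, low = 0, mid = 0, high = 0),
                        cv = c(LLOQ = 0.10, low = 0.05, mid = 0.05, high = 0.05),
                        n_replicates = 6L, n_days = 3L) {
  stopifnot(inherits(config, "generator_config"))
  panel <- config$panel
  if (is.null(analytes)) {
    analytes <- panel$steroids$abbreviation[panel$steroids$quant_mode == "targeted"]
  }
  set.seed(config$seed + 1L)
  qc <- panel$qc_levels[panel$qc_levels$analyte %in% analytes, ]
  rows <- lapply(seq_len(nrow(qc)), function(i) {
    r <- qc[i, ]
    tidyr::crossing(day = seq_len(n_days), replicate = seq_len(n_replicates)) |>
      dplyr::mutate(
        analyte = r$analyte, level_name = r$level_name, nominal = r$nominal,
        measured = r$nominal * (1 + bias[[r$level_name]]) *
          lognormal_noise(dplyr::n(), cv[[r$level_name]])) |>
      dplyr::select("analyte", "level_name", "nominal", "day", "replicate",
                    "measured")
  })
  dplyr::bind_rows(rows)
}

#' Generate a phase-structured paired serum/PF cohort
#'
#' Per-subject lognormal baselines shared between the two matrices (so
#' serum and PF correlate within subject), class-level PF:serum ratios,
#' secretory-phase elevation of P4 and its direct metabolites, and
#' dienogest suppression of progestogens. Measurement noise is applied on
#' top of the returned noiseless truth.
#'
#' @param config A `generator_config`.
#' @return List: `cohort` (wide tibble `sample_id`, `subject_id`,
#'   `matrix`, `phase`, one column per analyte) and `truth` (same shape,
#'   noiseless expected concentrations).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  panel <- config$panel
  set.seed(config$seed + 2L)
  s <- panel$steroids
  ab <- s$abbreviation
  base <- baseline_concentrations(panel)
  sdlog <- log(config$biological_gsd)
  phases <- rep(names(config$cohort_sizes), config$cohort_sizes)
  subjects <- sprintf("subj%02d", seq_along(phases))
  rows_truth <- list(); rows_obs <- list()
  for (i in seq_along(subjects)) {
    phase <- phases[i]
    subject_effect <- exp(stats::rnorm(length(ab), 0, sdlog))
    conc_serum <- base * subject_effect
    if (phase == "secretory") {
      idx <- ab %in% SECRETORY_ELEVATED
      conc_serum[idx] <- conc_serum[idx] * config$secretory_multiplier
    }
    if (phase == "dienogest") {
      idx <- s$steroid_class == "progestogen"
      conc_serum[idx] <- conc_serum[idx] * config$dienogest_suppression
    }
    conc_pf <- conc_serum * config$pf_class_ratio[s$steroid_class]
    for (mat in c("serum", "PF")) {
      truth <- if (mat == "serum") conc_serum else conc_pf
      obs <- truth * lognormal_noise(length(ab), config$noise_cv)
      meta <- tibble::tibble(sample_id = paste0(subjects[i], "_", mat),
                             subject_id = subjects[i], matrix = mat,
                             phase = phase)
      rows_truth[[length(rows_truth) + 1]] <-
        dplyr::bind_cols(meta, tibble::as_tibble(as.list(stats::setNames(truth, ab))))
      rows_obs[[length(rows_obs) + 1]] <-
        dplyr::bind_cols(meta, tibble::as_tibble(as.list(stats::setNames(obs, ab))))
    }
  }
  list(cohort = dplyr::bind_rows(rows_obs), truth = dplyr::bind_rows(rows_truth))
}

#' Generate centroided scan data for one sample
#'
#' Emulates a centroided full-scan acquisition: each analyte produces a
#' Gaussian chromatographic peak at its (m/z, RT) with total area
#' `response_slope x concentration x is_area x recovery`, each internal
#' standard a peak of the spike-equivalent area; centroid m/z values
#' jitter within `mz_jitter` (2 mmu default) of the true ion so the 5-mmu
#' XIC window captures them.
#'
#' @param config A `generator_config`.
#' @param concentrations Named vector of true concentrations (nmol/L) for
#'   any subset of panel analytes.
#' @param polarity Which acquisition channel to emulate.
#' @param noise Apply multiplicative area noise (default TRUE).
#' @return A `scan_series` spanning the 17-min gradient.
#' @export
generate_scans <- function(config, concentrations, polarity = "positive",
                           noise = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  panel <- config$panel
  set.seed(config$seed + 3L)
  s <- panel$steroids[panel$steroids$polarity == polarity, ]
  s <- s[s$abbreviation %in% names(concentrations), ]
  cf <- true_correction_factors(panel)
  rt_grid <- seq(0, 17, by = config$scan_interval)
  cv <- if (noise) config$noise_cv else 0
  is_pol <- panel$steroids$polarity[match(panel$internal_standards$labels_analyte,
                                          panel$steroids$abbreviation)]
  istd <- panel$internal_standards[!is.na(is_pol) & is_pol == polarity, ]
  peak_rows <- function(mz, rt, area) {
    if (area <= 0) return(NULL)
    sel <- which(abs(rt_grid - rt) <= 4 * config$chrom_sigma)
    if (!length(sel)) return(NULL)
    h <- area / (config$chrom_sigma * sqrt(2 * pi))
    intensity <- h * exp(-(rt_grid[sel] - rt)^2 / (2 * config$chrom_sigma^2))
    tibble::tibble(
      rt = rt_grid[sel],
      mz = mz + stats::runif(length(sel), -config$mz_jitter, config$mz_jitter),
      intensity = intensity)
  }
  analyte_peaks <- lapply(seq_len(nrow(s)), function(i) {
    ab <- s$abbreviation[i]
    eff_slope <- if (s$quant_mode[i] == "targeted") {
      config$response_slope
    } else {
      config$response_slope / cf[[ab]]
    }
    area <- eff_slope * concentrations[[ab]] * config$is_area *
      config$extraction_recovery * lognormal_noise(1, cv)
    peak_rows(s$mz[i], s$expected_rt[i], area)
  })
  is_peaks <- lapply(seq_len(nrow(istd)), function(i) {
    area <- config$is_area * config$extraction_recovery * lognormal_noise(1, cv)
    peak_rows(istd$mz[i], istd$expected_rt[i], area)
  })
  peaks <- dplyr::bind_rows(c(analyte_peaks, is_peaks))
  scan_series(peaks, polarity = polarity, scan_rt = rt_grid)
}

#' Convert measured peaks to a quantifiable area table
#'
#' Joins each analyte measurement of [measure_sample()] with the area of
#' its assigned internal standard (own IS for targeted analytes,
#' nearest-RT IS for untargeted ones).
#'
#' @param measurements Output of [measure_sample()] (possibly several
#'   samples bound together).
#' @param panel A `steroid_panel`.
#' @return Tibble: `sample_id`, `analyte`, `area`, `is_area`, `flags`.
#' @export
areas_from_measurements <- function(measurements, panel) {
  an <- measurements[measurements$kind == "analyte", ]
  ist <- measurements[measurements$kind == "internal_standard", ]
  rows <- lapply(seq_len(nrow(an)), function(i) {
    r <- an[i, ]
    is_id <- assign_internal_standard(r$analyte, panel)$id
    is_row <- ist[ist$sample_id == r$sample_id & ist$analyte == is_id, ]
    tibble::tibble(sample_id = r$sample_id, analyte = r$analyte,
                   area = r$area,
                   is_area = if (nrow(is_row)) is_row$area[1] else NA_real_,
                   flags = r$flags)
  })
  dplyr::bind_rows(rows)
}
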