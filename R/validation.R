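# FDA-style bioanalytical validation battery: accuracy (RSD), precision
# (relative error), acceptance rules (<= 20% at LLOQ, <= 15% elsewhere),
# carryover, LLOQ determination, stability and recovery.
#
# Naming note: the report tables of this assay family label the RSD column
# "Accuracy" and the relative-error column "Precision" (the reverse of the
# conventional mapping). Internally everything is named by formula;
# render_validation_report() can reproduce either header set.

FDA_TOL <- c(LLOQ = 20, low = 15, mid = 15, high = 15)

#' Relative standard deviation (percent)
#'
#' `100 * sd / mean` over replicate measurements (sample SD, n-1).
#'
#' @param measured Numeric vector, n >= 2, positive mean.
#' @return RSD in percent.
#' @examples
#' rsd_percent(c(9, 10, 11)) # 10
#' @export
rsd_percent <- function(measured) {
  measured <- measured[is.finite(measured)]
  if (length(measured) < 2) data_error("RSD needs >= 2 replicates")
  m <- mean(measured)
  if (m <= 0) data_error("RSD undefined for non-positive mean")
  100 * stats::sd(measured) / m
}

#' Relative error (percent, signed)
#'
#' `100 * (mean(measured) - nominal) / nominal`.
#'
#' @param measured Numeric vector of replicate measurements.
#' @param nominal Nominal (spiked) concentration, > 0.
#' @return Signed relative error in percent.
#' @examples
#' relative_error_percent(c(9, 10, 9.5), 10) # -5
#' @export
relative_error_percent <- function(measured, nominal) {
  measured <- measured[is.finite(measured)]
  if (length(measured) == 0) data_error("no measurements")
  if (nominal <= 0) data_error("nominal must be > 0")
  100 * (mean(measured) - nominal) / nominal
}

#' Summarise QC replicate sets into validation metrics
#'
#' Computes intra-day metrics per (analyte, level, day) and inter-day
#' metrics from all days' replicates pooled.
#'
#' @param qc Tibble with columns `analyte`, `level_name`
#'   (`LLOQ`/`low`/`mid`/`high`), `nominal`, `day`, `measured`.
#' @return List of tibbles `intra_day` and `inter_day`, each with
#'   `rsd_percent`, `relative_error_percent` and `n`.
#' @export
summarise_qc <- function(qc) {
  qc <- tibble::as_tibble(qc)
  need <- c("analyte", "level_name", "nominal", "day", "measured")
  if (!all(need %in% names(qc))) {
    config_error(paste0("QC table needs columns: ", paste(need, collapse = ", ")))
  }
  intra <- qc |>
    dplyr::group_by(.data$analyte, .data$level_name, .data$nominal, .data$day) |>
    dplyr::summarise(
      n = dplyr::n(),
      rsd_percent = rsd_percent(.data$measured),
      relative_error_percent = relative_error_percent(.data$measured, .data$nominal[1]),
      .groups = "drop")
  inter <- qc |>
    dplyr::group_by(.data$analyte, .data$level_name, .data$nominal) |>
    dplyr::summarise(
      n = dplyr::n(),
      rsd_percent = rsd_percent(.data$measured),
      relative_error_percent = relative_error_percent(.data$measured, .data$nominal[1]),
      .groups = "drop")
  list(intra_day = intra, inter_day = inter)
}

#' Apply the FDA acceptance rules to validation metrics
#'
#' A level passes when both |RSD| and |relative error| are within
#' tolerance: 20% at LLOQ, 15% at the other levels (inclusive thresholds).
#' An analyte passes when every one of its levels passes both metrics;
#' analytes missing a level are flagged incomplete (and do not pass).
#'
#' @param metrics Tibble with `analyte`, `level_name`, `rsd_percent`,
#'   `relative_error_percent` (e.g. the `inter_day` table of
#'   [summarise_qc()], or a transcribed report table).
#' @param require_levels Level names that must all be present per analyte.
#' @return List: `levels` (per-row pass), `analytes` (per-analyte pass +
#'   `complete`), and `summary` counts.
#' @export
apply_fda_rules <- function(metrics,
                            require_levels = c("LLOQ", "low", "mid", "high")) {
  metrics <- tibble::as_tibble(metrics)
  if (!all(metrics$level_name %in% names(FDA_TOL))) {
    config_error("level_name must be one of LLOQ/low/mid/high")
  }
  lv <- metrics |>
    dplyr::mutate(
      tolerance_percent = FDA_TOL[.data$level_name],
      rsd_pass = abs(.data$rsd_percent) <= .data$tolerance_percent,
      re_pass = abs(.data$relative_error_percent) <= .data$tolerance_percent,
      pass = .data$rsd_pass & .data$re_pass)
  an <- lv |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      complete = all(require_levels %in% .data$level_name),
      pass = all(.data$pass) & all(require_levels %in% .data$level_name),
      n_level_failures = sum(!.data$pass),
      .groups = "drop")
  list(levels = lv, analytes = an,
       summary = list(n_analytes = nrow(an), n_pass = sum(an$pass),
                      n_fail = sum(!an$pass),
                      n_incomplete = sum(!an$complete)))
}

#' Carryover check
#'
#' Compares the signal of a blank injected after the highest calibrant to
#' the signal at LLOQ; passes when the blank is below 20% of the LLOQ
#' signal.
#'
#' @param blank_signal Blank peak area (counts x min), >= 0.
#' @param lloq_signal LLOQ peak area, > 0.
#' @return List with `percent_of_lloq` and `pass`.
#' @export
check_carryover <- function(blank_signal, lloq_signal) {
  if (lloq_signal <= 0) data_error("LLOQ signal must be > 0")
  if (blank_signal < 0) data_error("blank signal must be >= 0")
  pct <- 100 * blank_signal / lloq_signal
  list(percent_of_lloq = pct, pass = pct < 20)
}

#' Determine the LLOQ from low-level QC results
#'
#' The LLOQ is the lowest calibration level at which both |RSD| and
#' |relative error| stay within 20% on every validation day.
#'
#' @param qc Tibble with `nominal` (candidate level), `day`, `measured`
#'   (replicates) for one analyte.
#' @return The LLOQ (nmol/L).
#' @export
determine_lloq <- function(qc) {
  qc <- tibble::as_tibble(qc)
  if (length(unique(qc$nominal)) < 2) {
    data_error("need QC results at >= 2 candidate levels")
  }
  per_day <- qc |>
    dplyr::group_by(.data$nominal, .data$day) |>
    dplyr::summarise(
      ok = abs(rsd_percent(.data$measured)) <= 20 &
        abs(relative_error_percent(.data$measured, .data$nominal[1])) <= 20,
      .groups = "drop")
  by_level <- per_day |>
    dplyr::group_by(.data$nominal) |>
    dplyr::summarise(ok = all(.data$ok), .groups = "drop")
  passing <- by_level$nominal[by_level$ok]
  if (length(passing) == 0) {
    data_error("no candidate level meets the 20% rule; assay range undefined")
  }
  min(passing)
}

#' Stability / robustness bias and recovery
#'
#' Paired comparison of a stressed condition (freeze-thaw, bench-top,
#' long-term storage, autosampler) or an alternative operator against the
#' reference determination, plus extraction recovery.
#'
#' @param reference,condition Paired measurement vectors (same samples,
#'   same order).
#' @return List with `bias_percent` (mean of paired condition/reference
#'   ratios minus 1, in percent), `rsd_percent` of the condition values,
#'   and `n`.
#' @export
stability_bias <- function(reference, condition) {
  if (length(reference) != length(condition)) {
    data_error("stability design must be paired")
  }
  keep <- is.finite(reference) & is.finite(condition) & reference > 0
  if (!any(keep)) data_error("no usable pairs")
  ratio <- condition[keep] / reference[keep]
  list(bias_percent = 100 * (mean(ratio) - 1),
       rsd_percent = rsd_percent(condition[keep]),
       n = sum(keep))
}

#' Extraction recovery (percent)
#'
#' @param measured Measured (post-extraction) amounts.
#' @param spiked Spiked (nominal) amounts, > 0.
#' @return Mean recovery in percent.
#' @export
recovery_percent <- function(measured, spiked) {
  if (length(measured) != length(spiked)) data_error("unpaired recovery design")
  if (any(spiked <= 0)) data_error("spiked amounts must be > 0")
  100 * mean(measured / spiked)
}

#' The packaged inter-day validation fixture
#'
#' Loads the transcribed inter-day validation table of the targeted assay:
#' 17 analytes with LLOQ/ULOQ range and RSD / relative error at the high,
#' mid, low and LLOQ QC levels.
#'
#' @return Tibble in wide form (one row per analyte).
#' @export
load_validation_fixture <- function() {
  path <- system.file("extdata", "interday_validation.csv",
                      package = "steroquant", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE) |> tibble::as_tibble()
}

#' Reshape the wide validation fixture to long metric rows
#'
#' @param wide Output of [load_validation_fixture()].
#' @return Tibble with `analyte`, `level_name`, `rsd_percent`,
#'   `relative_error_percent`, suitable for [apply_fda_rules()].
#' @export
validation_fixture_long <- function(wide = load_validation_fixture()) {
  long_rsd <- tidyr::pivot_longer(
    wide[, c("analyte", paste0("rsd_", c("high", "mid", "low", "lloq")))],
    -"analyte", names_to = "level_name", values_to = "rsd_percent",
    names_prefix = "rsd_")
  long_re <- tidyr::pivot_longer(
    wide[, c("analyte", paste0("re_", c("high", "mid", "low", "lloq")))],
    -"analyte", names_to = "level_name", values_to = "relative_error_percent",
    names_prefix = "re_")
  out <- dplyr::left_join(long_rsd, long_re, by = c("analyte", "level_name"))
  out$level_name <- ifelse(out$level_name == "lloq", "LLOQ", out$level_name)
  out
}

#' Render a validation report table
#'
#' @param wide Wide validation table (see [load_validation_fixture()]).
#' @param paper_labels If `TRUE`, use the assay-report convention that
#'   titles the RSD columns "Accuracy" and the relative-error columns
#'   "Precision"; the default uses formula-named headers. Numbers are
#'   identical in both modes.
#' @param path Optional output path; `.md` renders a Markdown table,
#'   anything else CSV.
#' @return The (possibly relabelled) table, invisibly if written.
#' @export
render_validation_report <- function(wide, paper_labels = FALSE, path = NULL) {
  lvl <- c("High", "Mid", "Low", "LLOQ")
  hdr <- if (paper_labels) {
    c("", "Range (nmol/L) LLOQ", "Range (nmol/L) ULOQ",
      paste("Accuracy (RSD, %)", lvl), paste("Precision (relative error, %)", lvl))
  } else {
    c("analyte", "lloq_nmol_per_L", "uloq_nmol_per_L",
      paste0("rsd_percent_", tolower(lvl)),
      paste0("relative_error_percent_", tolower(lvl)))
  }
  out <- wide[, c("analyte", "lloq", "uloq",
                  paste0("rsd_", tolower(lvl)), paste0("re_", tolower(lvl)))]
  names(out) <- hdr
  if (is.null(path)) return(out)
  if (tolower(tools::file_ext(path)) == "md") {
    lines <- c(paste0("| ", paste(names(out), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(out)), collapse = "|"), "|"),
               vapply(seq_len(nrow(out)), function(i)
                 paste0("| ", paste(unlist(out[i, ]), collapse = " | "), " |"),
                 character(1)))
    writeLines(lines, path)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(out)
}
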