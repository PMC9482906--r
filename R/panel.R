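# Panel definition: steroid registry, internal standards, enzyme-ratio
# definitions and calibration design.

STEROID_CLASSES <- c("progestogen", "androgen", "C11-oxy androgen",
                     "glucocorticoid", "mineralocorticoid", "precursor")

#' Construct a steroid panel
#'
#' A panel bundles the analyte registry (targeted and untargeted steroids),
#' the internal standards, the apparent-enzyme-activity (product/substrate)
#' definitions and the calibration design. Most users will start from
#' [default_panel()] or [load_panel()].
#'
#' @param steroids Tibble with columns `abbreviation`, `full_name`,
#'   `steroid_class`, `quant_mode` (`"targeted"`/`"untargeted"`),
#'   `polarity` (`"positive"`/`"negative"`), `formula` (optional), `mz` (Th),
#'   `expected_rt` (min), `is_ref` (targeted), `surrogate_ref`,
#'   `correction_factor`, `cf_verified` (untargeted), `lloq`, `uloq` (nmol/L,
#'   targeted).
#' @param internal_standards Tibble with columns `id`, `labels_analyte`,
#'   `formula` (optional), `mz`, `expected_rt`, `spike_amount_pmol`.
#' @param enzyme_ratios Tibble with columns `ratio_id`, `enzyme`, `products`,
#'   `substrates` (list columns of abbreviation vectors).
#' @param calibration List with `range` (length-2 nmol/L) and `n_levels`.
#' @param qc_levels Tibble with columns `analyte`, `level_name`
#'   (`LLOQ`/`low`/`mid`/`high`) and `nominal` (nmol/L).
#' @return An object of class `steroid_panel`.
#' @export
steroid_panel <- function(steroids, internal_standards,
                          enzyme_ratios = empty_enzyme_ratios(),
                          calibration = list(range = c(0.1, 2000), n_levels = 12L),
                          qc_levels = NULL) {
  steroids <- tibble::as_tibble(steroids)
  internal_standards <- tibble::as_tibble(internal_standards)
  enzyme_ratios <- tibble::as_tibble(enzyme_ratios)
  for (col in c("is_ref", "surrogate_ref")) {
    if (!col %in% names(steroids)) steroids[[col]] <- NA_character_
  }
  for (col in c("correction_factor", "lloq", "uloq")) {
    if (!col %in% names(steroids)) steroids[[col]] <- NA_real_
  }
  if (!"cf_verified" %in% names(steroids)) steroids$cf_verified <- NA
  if (!"formula" %in% names(steroids)) steroids$formula <- NA_character_
  canon <- c("abbreviation", "full_name", "steroid_class", "quant_mode",
             "polarity", "formula", "mz", "expected_rt", "is_ref",
             "surrogate_ref", "correction_factor", "cf_verified", "lloq", "uloq")
  steroids <- steroids[, c(intersect(canon, names(steroids)),
                           setdiff(names(steroids), canon))]
  canon_is <- c("id", "labels_analyte", "formula", "mz", "expected_rt",
                "spike_amount_pmol")
  internal_standards <- internal_standards[
    , c(intersect(canon_is, names(internal_standards)),
        setdiff(names(internal_standards), canon_is))]
  if (is.null(qc_levels)) qc_levels <- derive_qc_levels(steroids)
  panel <- structure(
    list(steroids = steroids, internal_standards = internal_standards,
         enzyme_ratios = enzyme_ratios, calibration = calibration,
         qc_levels = tibble::as_tibble(qc_levels)),
    class = "steroid_panel"
  )
  validate_panel(panel)
}

empty_enzyme_ratios <- function() {
  tibble::tibble(ratio_id = character(), enzyme = character(),
                 products = list(), substrates = list())
}

# QC nominals follow the usual bioanalytical placement: LLOQ at the assay
# floor, low at 3x LLOQ, mid at the geometric centre, high at 80% ULOQ.
derive_qc_levels <- function(steroids) {
  tg <- steroids[steroids$quant_mode == "targeted" & !is.na(steroids$lloq), ]
  if (nrow(tg) == 0) {
    return(tibble::tibble(analyte = character(), level_name = character(),
                          nominal = numeric()))
  }
  tidyr::crossing(analyte = tg$abbreviation,
                  level_name = c("LLOQ", "low", "mid", "high")) |>
    dplyr::left_join(
      tibble::tibble(analyte = tg$abbreviation, lloq = tg$lloq, uloq = tg$uloq),
      by = "analyte") |>
    dplyr::mutate(nominal = dplyr::case_when(
      .data$level_name == "LLOQ" ~ .data$lloq,
      .data$level_name == "low" ~ 3 * .data$lloq,
      .data$level_name == "mid" ~ sqrt(.data$lloq * .data$uloq),
      .data$level_name == "high" ~ 0.8 * .data$uloq
    )) |>
    dplyr::select("analyte", "level_name", "nominal")
}

#' Validate panel invariants
#'
#' Checks the structural invariants of a panel: targeted analytes carry an
#' internal-standard reference and no surrogate; untargeted analytes carry a
#' surrogate (A4 or P4, resolving to a targeted analyte) and a positive
#' correction factor; all m/z fall in the 200-500 acquisition window;
#' retention times fall inside the 17-min gradient; LLOQ < ULOQ.
#'
#' @param panel A `steroid_panel`.
#' @return The panel, invisibly unchanged, or an error describing the first
#'   violated field.
#' @export
validate_panel <- function(panel) {
  s <- panel$steroids
  is_tab <- panel$internal_standards
  need <- c("abbreviation", "full_name", "steroid_class", "quant_mode",
            "polarity", "mz", "expected_rt")
  missing_col <- setdiff(need, names(s))
  if (length(missing_col)) {
    config_error(paste0("panel steroids table lacks field(s): ",
                        paste(missing_col, collapse = ", ")))
  }
  if (anyDuplicated(s$abbreviation)) {
    config_error("duplicate steroid abbreviations in panel")
  }
  if (!all(s$steroid_class %in% STEROID_CLASSES)) {
    bad <- unique(s$steroid_class[!s$steroid_class %in% STEROID_CLASSES])
    config_error(paste0("unknown steroid_class: ", paste(bad, collapse = ", ")))
  }
  if (!all(s$quant_mode %in% c("targeted", "untargeted"))) {
    config_error("quant_mode must be 'targeted' or 'untargeted'")
  }
  if (!all(s$polarity %in% c("positive", "negative"))) {
    config_error("polarity must be 'positive' or 'negative'")
  }
  if (any(s$mz < 200 | s$mz > 500)) {
    bad <- s$abbreviation[s$mz < 200 | s$mz > 500]
    config_error(paste0("mz outside the 200-500 acquisition window for: ",
                        paste(bad, collapse = ", ")))
  }
  if (any(s$expected_rt <= 0 | s$expected_rt >= 17)) {
    config_error("expected_rt outside the 17-min elution window")
  }
  tg <- s$quant_mode == "targeted"
  if (any(tg & (is.na(s$is_ref) | !nzchar(s$is_ref)))) {
    config_error("targeted analytes must set is_ref")
  }
  if (any(tg & (!is.na(s$surrogate_ref) | !is.na(s$correction_factor)))) {
    config_error("targeted analytes must not set surrogate_ref/correction_factor")
  }
  if (any(!tg & !is.na(s$is_ref))) {
    config_error("untargeted analytes must not set is_ref")
  }
  if (any(!tg & is.na(s$surrogate_ref))) {
    config_error("untargeted analytes must set surrogate_ref")
  }
  if (any(!tg & (is.na(s$correction_factor) | s$correction_factor <= 0))) {
    config_error("untargeted analytes need correction_factor > 0")
  }
  surr <- unique(s$surrogate_ref[!tg])
  if (length(surr)) {
    if (!all(surr %in% c("A4", "P4"))) {
      reference_error(paste0("surrogate_ref must be A4 or P4, got: ",
                             paste(setdiff(surr, c("A4", "P4")), collapse = ", ")))
    }
    unresolved <- setdiff(surr, s$abbreviation[tg])
    if (length(unresolved)) {
      reference_error(paste0("surrogate(s) not targeted analytes in panel: ",
                             paste(unresolved, collapse = ", ")))
    }
  }
  unresolved_is <- setdiff(s$is_ref[tg], is_tab$id)
  if (length(unresolved_is)) {
    reference_error(paste0("is_ref does not resolve to an internal standard: ",
                           paste(unresolved_is, collapse = ", ")))
  }
  both <- !is.na(s$lloq) & !is.na(s$uloq)
  if (any(both & s$lloq >= s$uloq)) {
    config_error("lloq must be < uloq")
  }
  if (nrow(panel$enzyme_ratios)) {
    er <- panel$enzyme_ratios
    all_ab <- unlist(c(er$products, er$substrates))
    unresolved <- setdiff(all_ab, s$abbreviation)
    if (length(unresolved)) {
      reference_error(paste0("enzyme ratio references unknown analyte(s): ",
                             paste(unresolved, collapse = ", ")))
    }
    overlap <- mapply(function(p, su) length(intersect(p, su)) > 0,
                      er$products, er$substrates)
    if (any(overlap)) {
      config_error("enzyme ratio product and substrate sets must be disjoint")
    }
  }
  rng <- panel$calibration$range
  if (!is.numeric(rng) || length(rng) != 2 || rng[1] <= 0 || rng[2] <= rng[1]) {
    config_error("calibration range must be two increasing positive values")
  }
  invisible(panel)
}

#' @export
print.steroid_panel <- function(x, ...) {
  n_tg <- sum(x$steroids$quant_mode == "targeted")
  n_ut <- sum(x$steroids$quant_mode == "untargeted")
  cat(sprintf(
    "<steroid_panel> %d steroids (%d targeted, %d untargeted), %d internal standards\n",
    nrow(x$steroids), n_tg, n_ut, nrow(x$internal_standards)))
  cat(sprintf("  calibration: %d levels over %.3g-%.4g nmol/L; %d enzyme ratios\n",
              x$calibration$n_levels, x$calibration$range[1],
              x$calibration$range[2], nrow(x$enzyme_ratios)))
  invisible(x)
}

#' Calibration level series for an analyte
#'
#' Returns the ordered calibrant concentrations: a geometric series of
#' `n_levels` points spanning the analyte's validated LLOQ-ULOQ range for
#' targeted analytes, or the panel's design range (default 0.1-2000 nmol/L)
#' for untargeted analytes.
#'
#' @param panel A `steroid_panel`.
#' @param analyte Abbreviation of a panel steroid.
#' @return Increasing numeric vector of concentrations (nmol/L).
#' @export
calibration_levels <- function(panel, analyte) {
  s <- panel$steroids[panel$steroids$abbreviation == analyte, ]
  if (nrow(s) != 1) reference_error(paste0("unknown analyte: ", analyte))
  rng <- if (!is.na(s$lloq) && !is.na(s$uloq)) {
    c(s$lloq, s$uloq)
  } else {
    panel$calibration$range
  }
  exp(seq(log(rng[1]), log(rng[2]), length.out = panel$calibration$n_levels))
}

# --- config file I/O ---------------------------------------------------

#' Load a panel from a YAML or JSON config file
#'
#' The config holds `steroids`, `internal_standards`, `enzyme_ratios`,
#' `calibration` and optionally `qc_levels` blocks; units are fixed to
#' nmol/L and minutes. See the packaged default panel
#' (`system.file("extdata", "default_panel.yaml", package = "steroquant")`)
#' for the schema.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. Defaults to the
#'   packaged panel.
#' @return A validated `steroid_panel`.
#' @export
load_panel <- function(path = default_panel_path()) {
  if (!file.exists(path)) config_error(paste0("panel config not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    config_error("panel config must be YAML or JSON")
  }
  panel_from_list(raw)
}

panel_from_list <- function(raw) {
  scalar <- function(rec, field, cast, default = NA) {
    v <- rec[[field]]
    if (is.null(v)) cast(default) else cast(v)
  }
  steroids <- dplyr::bind_rows(lapply(raw$steroids, function(r) {
    tibble::tibble(
      abbreviation = scalar(r, "abbreviation", as.character),
      full_name = scalar(r, "full_name", as.character),
      steroid_class = scalar(r, "steroid_class", as.character),
      quant_mode = scalar(r, "quant_mode", as.character),
      polarity = scalar(r, "polarity", as.character),
      formula = scalar(r, "formula", as.character),
      mz = scalar(r, "mz", as.numeric),
      expected_rt = scalar(r, "expected_rt", as.numeric),
      is_ref = scalar(r, "is_ref", as.character),
      surrogate_ref = scalar(r, "surrogate_ref", as.character),
      correction_factor = scalar(r, "correction_factor", as.numeric),
      cf_verified = scalar(r, "cf_verified", as.logical),
      lloq = scalar(r, "lloq", as.numeric),
      uloq = scalar(r, "uloq", as.numeric)
    )
  }))
  istd <- dplyr::bind_rows(lapply(raw$internal_standards, function(r) {
    tibble::tibble(
      id = scalar(r, "id", as.character),
      labels_analyte = scalar(r, "labels_analyte", as.character),
      formula = scalar(r, "formula", as.character),
      mz = scalar(r, "mz", as.numeric),
      expected_rt = scalar(r, "expected_rt", as.numeric),
      spike_amount_pmol = scalar(r, "spike_amount_pmol", as.numeric)
    )
  }))
  er <- if (length(raw$enzyme_ratios)) {
    dplyr::bind_rows(lapply(raw$enzyme_ratios, function(r) {
      tibble::tibble(
        ratio_id = scalar(r, "ratio_id", as.character),
        enzyme = scalar(r, "enzyme", as.character),
        products = list(as.character(unlist(r$products))),
        substrates = list(as.character(unlist(r$substrates)))
      )
    }))
  } else {
    empty_enzyme_ratios()
  }
  calib <- list(
    range = as.numeric(unlist(raw$calibration$range %||% c(0.1, 2000))),
    n_levels = as.integer(raw$calibration$n_levels %||% 12L)
  )
  qc <- if (length(raw$qc_levels)) {
    dplyr::bind_rows(lapply(raw$qc_levels, function(r) {
      tibble::tibble(analyte = as.character(r$analyte),
                     level_name = as.character(r$level_name),
                     nominal = as.numeric(r$nominal))
    }))
  } else {
    NULL
  }
  steroid_panel(steroids, istd, er, calib, qc)
}

#' Write a panel to a YAML config file
#'
#' Inverse of [load_panel()]; `write_panel()` followed by [load_panel()]
#' reproduces the panel field-by-field.
#'
#' @param panel A `steroid_panel`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  drop_na <- function(rec) rec[!vapply(rec, function(v)
    length(v) == 0 || (length(v) == 1 && is.na(v)), logical(1))]
  out <- list(
    steroids = lapply(seq_len(nrow(panel$steroids)), function(i)
      drop_na(as.list(panel$steroids[i, ]))),
    internal_standards = lapply(seq_len(nrow(panel$internal_standards)), function(i)
      drop_na(as.list(panel$internal_standards[i, ]))),
    enzyme_ratios = lapply(seq_len(nrow(panel$enzyme_ratios)), function(i) {
      r <- panel$enzyme_ratios[i, ]
      list(ratio_id = r$ratio_id, enzyme = r$enzyme,
           products = as.list(r$products[[1]]),
           substrates = as.list(r$substrates[[1]]))
    }),
    calibration = list(range = as.list(panel$calibration$range),
                       n_levels = panel$calibration$n_levels),
    qc_levels = lapply(seq_len(nrow(panel$qc_levels)), function(i)
      as.list(panel$qc_levels[i, ]))
  )
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Path to the packaged default panel config
#' @return File path of the installed `default_panel.yaml`.
#' @export
default_panel_path <- function() {
  system.file("extdata", "default_panel.yaml", package = "steroquant",
              mustWork = TRUE)
}

#' Assign the internal standard for an analyte
#'
#' Targeted analytes use their own isotopically labelled standard
#' (`is_ref`). Untargeted analytes have no dedicated standard; because the
#' standards cover the whole elution-time range, each untargeted analyte is
#' normalised to the internal standard closest in retention time
#' (nearest-RT rule; ties resolved towards the earlier-eluting standard).
#'
#' @param analyte Abbreviation of a panel steroid.
#' @param panel A `steroid_panel`.
#' @return One row of `panel$internal_standards`.
#' @export
assign_internal_standard <- function(analyte, panel) {
  istd <- panel$internal_standards
  if (nrow(istd) == 0) config_error("panel has no internal standards")
  s <- panel$steroids[panel$steroids$abbreviation == analyte, ]
  if (nrow(s) != 1) reference_error(paste0("unknown analyte: ", analyte))
  if (s$quant_mode == "targeted") {
    return(istd[istd$id == s$is_ref, ])
  }
  d <- abs(istd$expected_rt - s$expected_rt)
  cand <- which(d == min(d))
  if (length(cand) > 1) cand <- cand[which.min(istd$expected_rt[cand])]
  istd[cand, ]
}
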