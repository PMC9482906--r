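# Pipeline orchestration and run manifests: ties the modules into the two
# workflows (targeted panel run; post hoc untargeted re-quantification)
# behind one entry point, used by the `steroquant` command-line script.

#' Run pipeline stages
#'
#' Executes stages in their natural order
#' `simulate -> quantify -> {validate | pathways | classify | correlate}`
#' against an output directory; later stages read the files earlier
#' stages wrote (or pre-existing files with the same names). Every run
#' writes a `manifest.json` with the seed, config digest and input file
#' digests so deterministic stages can be re-run bit-identically.
#'
#' @param stages Character vector of stage names, any subset of
#'   `simulate`, `quantify`, `validate`, `pathways`, `classify`,
#'   `correlate`.
#' @param out_dir Output directory (created if needed).
#' @param config A `generator_config` (panel + simulation settings).
#' @param seed Seed overriding `config$seed`.
#' @return Invisibly, a named list of the paths written per stage.
#' @export
run_pipeline <- function(stages, out_dir, config = generator_config(),
                         seed = NULL) {
  known <- c("simulate", "quantify", "validate", "pathways", "classify",
             "correlate")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    config_error(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  stages <- known[known %in% stages]
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(pth(f))) {
      data_error(paste0("stage '", stage, "' needs missing input ", f,
                        " (run 'simulate' first or provide the file)"))
    }
    pth(f)
  }
  written <- list()
  panel <- config$panel

  if ("simulate" %in% stages) {
    cal <- generate_calibration(config)
    utils::write.csv(cal$calibration, pth("calibration.csv"), row.names = FALSE)
    qc <- generate_qc(config)
    utils::write.csv(qc, pth("qc.csv"), row.names = FALSE)
    coh <- generate_cohort(config)
    utils::write.csv(coh$cohort, pth("cohort_concentrations.csv"), row.names = FALSE)
    utils::write.csv(coh$truth, pth("cohort_truth.csv"), row.names = FALSE)
    areas <- concentrations_to_areas(coh$cohort, config)
    utils::write.csv(areas, pth("sample_areas.csv"), row.names = FALSE)
    written$simulate <- pth(c("calibration.csv", "qc.csv",
                              "cohort_concentrations.csv", "cohort_truth.csv",
                              "sample_areas.csv"))
  }
  if ("quantify" %in% stages) {
    calib <- utils::read.csv(need("calibration.csv", "quantify"))
    areas <- utils::read.csv(need("sample_areas.csv", "quantify"))
    curves <- fit_calibration_table(calib)
    conc <- quantify_samples(areas, curves, panel)
    meta_cols <- intersect(c("sample_id", "subject_id", "matrix", "phase"),
                           names(areas))
    meta <- dplyr::distinct(tibble::as_tibble(areas)[meta_cols])
    conc <- dplyr::left_join(conc, meta, by = "sample_id")
    utils::write.csv(conc, pth("concentrations.csv"), row.names = FALSE)
    wide <- tidyr::pivot_wider(conc,
                               id_cols = dplyr::all_of(meta_cols),
                               names_from = "analyte",
                               values_from = "concentration")
    utils::write.csv(wide, pth("concentrations_wide.csv"), row.names = FALSE)
    written$quantify <- pth(c("concentrations.csv", "concentrations_wide.csv"))
  }
  if ("validate" %in% stages) {
    qc <- utils::read.csv(need("qc.csv", "validate"))
    metrics <- summarise_qc(qc)
    rules <- apply_fda_rules(metrics$inter_day)
    utils::write.csv(rules$levels, pth("validation_levels.csv"), row.names = FALSE)
    utils::write.csv(rules$analytes, pth("validation_analytes.csv"), row.names = FALSE)
    written$validate <- pth(c("validation_levels.csv", "validation_analytes.csv"))
  }
  if ("pathways" %in% stages || "classify" %in% stages || "correlate" %in% stages) {
    wide <- tibble::as_tibble(
      utils::read.csv(need("concentrations_wide.csv", "pathways"),
                      check.names = FALSE))
  }
  if ("pathways" %in% stages) {
    act <- cohort_enzyme_activities(wide, panel)
    utils::write.csv(act, pth("enzyme_activities.csv"), row.names = FALSE)
    written$pathways <- pth("enzyme_activities.csv")
  }
  if ("classify" %in% stages) {
    cls <- cohort_classifiers(wide)
    utils::write.csv(cls, pth("classifiers.csv"), row.names = FALSE)
    tests <- dplyr::bind_rows(lapply(split(cls, cls$classifier), function(d) {
      ok <- is.finite(d$value) & d$value > 0
      if (length(unique(d$phase[ok])) < 2 || min(table(d$phase[ok])) < 3) {
        return(NULL)
      }
      gc <- group_compare(d$value[ok], d$phase[ok])
      dplyr::mutate(gc$pairwise, classifier = d$classifier[1],
                    kruskal_p = gc$kruskal$p)
    }))
    utils::write.csv(tests, pth("classifier_tests.csv"), row.names = FALSE)
    written$classify <- pth(c("classifiers.csv", "classifier_tests.csv"))
  }
  if ("correlate" %in% stages) {
    out <- dplyr::bind_rows(lapply(c("serum", "PF"), function(mat) {
      cm <- spearman_matrix(wide, panel = panel, matrix_filter = mat)
      dplyr::mutate(correlation_long(cm), matrix = mat)
    }))
    utils::write.csv(out, pth("correlations.csv"), row.names = FALSE)
    written$correlate <- pth("correlations.csv")
  }
  write_manifest(out_dir, stages, config, written)
  invisible(written)
}

# concentrations -> raw areas under the generator's response model, so a
# simulated cohort can exercise the quantitation stage
concentrations_to_areas <- function(cohort, config) {
  panel <- config$panel
  s <- panel$steroids
  cf <- true_correction_factors(panel)
  long <- tidyr::pivot_longer(cohort,
                              dplyr::all_of(intersect(s$abbreviation, names(cohort))),
                              names_to = "analyte", values_to = "concentration")
  slope <- ifelse(s$quant_mode[match(long$analyte, s$abbreviation)] == "targeted",
                  config$response_slope,
                  config$response_slope / cf[long$analyte])
  is_area <- config$is_area * config$extraction_recovery
  long$area <- slope * long$concentration * is_area
  long$is_area <- is_area
  long$concentration <- NULL
  long
}

write_manifest <- function(out_dir, stages, config, written) {
  files <- sort(unique(unlist(written)))
  digests <- if (length(files)) {
    stats::setNames(unname(tools::md5sum(files)), basename(files))
  } else {
    NULL
  }
  cfg <- unclass(config)
  cfg$panel <- NULL
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    command = paste(stages, collapse = ","),
    seed = config$seed,
    config_digest = unname(tools::md5sum(cfg_file)),
    panel_size = nrow(config$panel$steroids),
    outputs = as.list(digests),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
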