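# Apparent enzyme activities (product-to-substrate ratios) and composite
# menstrual-cycle-phase classifiers, with nonparametric group statistics.

#' Apparent enzyme activity
#'
#' The product-to-substrate concentration ratio used as a proxy for
#' steroidogenic enzyme flux: `sum(products) / sum(substrates)`. Undefined
#' (NA with a reason) when any constituent is missing, non-positive, or
#' flagged below the LLOQ — a below-LLOQ substrate must never silently
#' produce a ratio.
#'
#' @param products,substrates Concentration vectors (nmol/L).
#' @param product_flags,substrate_flags Optional flag strings per
#'   constituent (semicolon-joined, as in `QuantResult`).
#' @return List with `value` (or NA) and `missing_reason` (or NA).
#' @examples
#' enzyme_activity(2, 4) # CYP17A1-style ratio: 0.5
#' @export
enzyme_activity <- function(products, substrates,
                            product_flags = NULL, substrate_flags = NULL) {
  undefined <- function(reason) list(value = NA_real_, missing_reason = reason)
  all_c <- c(products, substrates)
  if (any(is.na(all_c))) return(undefined("constituent missing"))
  if (!is.null(product_flags) && any(has_flag(product_flags, "below_lloq"))) {
    return(undefined("product below LLOQ"))
  }
  if (!is.null(substrate_flags) && any(has_flag(substrate_flags, "below_lloq"))) {
    return(undefined("substrate below LLOQ"))
  }
  if (any(all_c <= 0)) return(undefined("non-positive constituent"))
  list(value = sum(products) / sum(substrates), missing_reason = NA_character_)
}

#' Compute all panel enzyme activities over a cohort table
#'
#' @param cohort Wide cohort tibble: `sample_id` (plus any metadata
#'   columns) and one concentration column per analyte. Optional
#'   companion flag columns named `<analyte>_flags`.
#' @param panel A `steroid_panel` whose `enzyme_ratios` define the ratios.
#' @return Long tibble: `sample_id`, `ratio_id`, `enzyme`, `value`,
#'   `missing_reason`.
#' @export
cohort_enzyme_activities <- function(cohort, panel) {
  er <- panel$enzyme_ratios
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    r <- cohort[i, ]
    dplyr::bind_rows(lapply(seq_len(nrow(er)), function(j) {
      p_ab <- er$products[[j]]; s_ab <- er$substrates[[j]]
      get_conc <- function(ab) if (ab %in% names(r)) r[[ab]] else NA_real_
      get_flag <- function(ab) {
        col <- paste0(ab, "_flags")
        if (col %in% names(r)) r[[col]] else ""
      }
      act <- enzyme_activity(vapply(p_ab, get_conc, numeric(1)),
                             vapply(s_ab, get_conc, numeric(1)),
                             vapply(p_ab, get_flag, character(1)),
                             vapply(s_ab, get_flag, character(1)))
      tibble::tibble(sample_id = r$sample_id, ratio_id = er$ratio_id[j],
                     enzyme = er$enzyme[j], value = act$value,
                     missing_reason = act$missing_reason)
    }))
  })
  dplyr::bind_rows(rows)
}

classifier_undefined <- function(id, classifier, reason) {
  tibble::tibble(id = id, classifier = classifier, value = NA_real_,
                 missing_reason = reason)
}

get_defined <- function(row, ab) {
  flag_col <- paste0(ab, "_flags")
  v <- if (ab %in% names(row)) row[[ab]] else NA_real_
  if (!is.na(v) && flag_col %in% names(row) && has_flag(row[[flag_col]], "below_lloq")) {
    return(NA_real_)
  }
  v
}

#' Combined serum classifier for the menstrual-cycle phase
#'
#' The composite score `20aOHP4 / (CYP17A1 + HSD3B2)` where
#' `CYP17A1 = 17OHP4/P4` and `HSD3B2 = P4/P5`. Undefined whenever any
#' constituent is missing, below the LLOQ, or a denominator substrate is
#' non-positive. Note the score carries a concentration unit (numerator is
#' a concentration, denominator a unit-free activity sum), so values scale
#' with the unit chosen.
#'
#' @param row One-row cohort tibble (serum sample) with analyte columns
#'   `20aOHP4`, `17OHP4`, `P4`, `P5` and optional `*_flags` columns.
#' @param id Identifier carried into the result.
#' @return One-row tibble: `id`, `classifier = "serum_combined"`, `value`,
#'   `missing_reason`.
#' @export
serum_classifier <- function(row, id = row$sample_id %||% NA_character_) {
  v <- vapply(c("20aOHP4", "17OHP4", "P4", "P5"),
              function(ab) get_defined(row, ab), numeric(1))
  if (any(is.na(v))) {
    return(classifier_undefined(id, "serum_combined", "constituent undefined"))
  }
  if (v[["P4"]] <= 0 || v[["P5"]] <= 0) {
    return(classifier_undefined(id, "serum_combined", "non-positive substrate"))
  }
  cyp17a1 <- v[["17OHP4"]] / v[["P4"]]
  hsd3b2 <- v[["P4"]] / v[["P5"]]
  tibble::tibble(id = id, classifier = "serum_combined",
                 value = v[["20aOHP4"]] / (cyp17a1 + hsd3b2),
                 missing_reason = NA_character_)
}

#' Combined peritoneal-fluid classifier
#'
#' `(5aDHP4 + 20aOHP4) / CYP17A1` with `CYP17A1 = 17OHP4/P4`, computed on
#' a PF sample row. Missingness propagates as in [serum_classifier()].
#'
#' @inheritParams serum_classifier
#' @return One-row tibble with `classifier = "pf_combined"`.
#' @export
pf_classifier <- function(row, id = row$sample_id %||% NA_character_) {
  v <- vapply(c("5aDHP4", "20aOHP4", "17OHP4", "P4"),
              function(ab) get_defined(row, ab), numeric(1))
  if (any(is.na(v))) {
    return(classifier_undefined(id, "pf_combined", "constituent undefined"))
  }
  if (v[["P4"]] <= 0 || v[["17OHP4"]] <= 0) {
    return(classifier_undefined(id, "pf_combined", "non-positive activity"))
  }
  cyp17a1 <- v[["17OHP4"]] / v[["P4"]]
  tibble::tibble(id = id, classifier = "pf_combined",
                 value = (v[["5aDHP4"]] + v[["20aOHP4"]]) / cyp17a1,
                 missing_reason = NA_character_)
}

#' Combined serum + peritoneal-fluid classifier
#'
#' `(serum 5aDHP4 + serum 20aOHP4 + PF 20aOHP4) / PF CYP17A1`, requiring a
#' paired serum and PF sample of the same subject.
#'
#' @param serum_row,pf_row One-row cohort tibbles of the paired samples.
#' @param id Subject identifier carried into the result.
#' @return One-row tibble with `classifier = "serum_pf_combined"`.
#' @export
serum_pf_classifier <- function(serum_row, pf_row,
                                id = serum_row$subject_id %||% NA_character_) {
  if (is.null(pf_row) || nrow(pf_row) != 1 || nrow(serum_row) != 1) {
    data_error("serum + PF classifier requires one paired row per matrix")
  }
  s <- vapply(c("5aDHP4", "20aOHP4"), function(ab) get_defined(serum_row, ab),
              numeric(1))
  p <- vapply(c("20aOHP4", "17OHP4", "P4"), function(ab) get_defined(pf_row, ab),
              numeric(1))
  if (any(is.na(c(s, p)))) {
    return(classifier_undefined(id, "serum_pf_combined", "constituent undefined"))
  }
  if (p[["P4"]] <= 0 || p[["17OHP4"]] <= 0) {
    return(classifier_undefined(id, "serum_pf_combined", "non-positive activity"))
  }
  cyp17a1_pf <- p[["17OHP4"]] / p[["P4"]]
  tibble::tibble(id = id, classifier = "serum_pf_combined",
                 value = (s[["5aDHP4"]] + s[["20aOHP4"]] + p[["20aOHP4"]]) / cyp17a1_pf,
                 missing_reason = NA_character_)
}

#' Compute all classifiers over a paired cohort
#'
#' Applies the P4-only, combined serum, combined PF and combined serum+PF
#' classifiers to every subject of a cohort table.
#'
#' @param cohort Wide cohort tibble with `subject_id`, `sample_id`,
#'   `matrix` (`"serum"`/`"PF"`), `phase` and analyte columns.
#' @return Long tibble: `id` (subject), `phase`, `classifier`, `value`,
#'   `missing_reason`.
#' @export
cohort_classifiers <- function(cohort) {
  subjects <- unique(cohort$subject_id)
  rows <- lapply(subjects, function(sj) {
    serum <- cohort[cohort$subject_id == sj & cohort$matrix == "serum", ]
    pf <- cohort[cohort$subject_id == sj & cohort$matrix == "PF", ]
    phase <- unique(c(serum$phase, pf$phase))[1]
    out <- list()
    if (nrow(serum) == 1) {
      p4 <- get_defined(serum, "P4")
      out$p4_serum <- tibble::tibble(
        id = sj, classifier = "P4_serum", value = p4,
        missing_reason = if (is.na(p4)) "constituent undefined" else NA_character_)
      out$serum <- serum_classifier(serum, id = sj)
    }
    if (nrow(pf) == 1) {
      p4 <- get_defined(pf, "P4")
      out$p4_pf <- tibble::tibble(
        id = sj, classifier = "P4_PF", value = p4,
        missing_reason = if (is.na(p4)) "constituent undefined" else NA_character_)
      out$pf <- pf_classifier(pf, id = sj)
    }
    if (nrow(serum) == 1 && nrow(pf) == 1) {
      out$both <- serum_pf_classifier(serum, pf, id = sj)
    }
    dplyr::bind_rows(out) |> dplyr::mutate(phase = phase)
  })
  dplyr::bind_rows(rows)
}

#' Nonparametric group comparison with multiplicity adjustment
#'
#' Pipeline used for phase comparisons: values are log10-transformed and
#' z-scored per variable (non-positive and missing values dropped first),
#' then compared across groups with a Kruskal-Wallis test and pairwise
#' Mann-Whitney (Wilcoxon rank-sum) tests, Benjamini-Hochberg adjusted.
#' Stars follow the usual thresholds: * <= 0.05, ** <= 0.01, *** <= 0.001,
#' **** <= 0.0001, else "Ns".
#'
#' @param values Numeric vector.
#' @param groups Factor/character vector of group labels (>= 2 groups with
#'   >= 3 usable values each).
#' @param log_transform Log10 + z-score before testing (rank tests are
#'   invariant to the monotone log, but the normalised values are also
#'   returned for plotting).
#' @return List: `kruskal` (statistic, p), `pairwise` tibble
#'   (`group1`, `group2`, `p`, `p_adjusted`, `label`), and `normalised`
#'   tibble of the transformed values.
#' @export
group_compare <- function(values, groups, log_transform = TRUE) {
  keep <- is.finite(values) & !is.na(groups)
  if (log_transform) keep <- keep & values > 0
  values <- values[keep]
  groups <- as.character(groups[keep])
  tab <- table(groups)
  if (length(tab) < 2) data_error("need >= 2 non-empty groups")
  if (any(tab < 3)) data_error("each group needs >= 3 values")
  x <- if (log_transform) log10(values) else values
  z <- as.numeric(scale(x))
  if (all(!is.finite(z))) z <- rep(0, length(x))  # zero-variance guard
  kw <- suppressWarnings(stats::kruskal.test(z, factor(groups)))
  gl <- sort(unique(groups))
  pairs <- utils::combn(gl, 2)
  pw <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    # exact null distribution at small n without ties, else normal approx
    p <- suppressWarnings(stats::wilcox.test(z[groups == g1],
                                             z[groups == g2])$p.value)
    tibble::tibble(group1 = g1, group2 = g2, p = p)
  }))
  pw$p_adjusted <- stats::p.adjust(pw$p, method = "BH")
  pw$label <- significance_label(pw$p_adjusted)
  list(kruskal = list(statistic = unname(kw$statistic), p = kw$p.value),
       pairwise = pw,
       normalised = tibble::tibble(group = groups, value = z))
}

#' Significance star labels
#'
#' @param p Vector of (adjusted) p-values.
#' @return `"****"`, `"***"`, `"**"`, `"*"` or `"Ns"`.
#' @export
significance_label <- function(p) {
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "Ns"
  )
}
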