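# Spearman correlation matrices by steroid class and matrix, hierarchical
# ordering for heat maps, and serum-vs-PF ratio / regression comparison.

#' Pairwise-complete Spearman correlation matrix
#'
#' Spearman's rank correlation with average ranks for ties over all
#' analyte pairs of a cohort table, using pairwise-complete observations.
#' Two-sided p-values come from the exact permutation distribution for
#' n <= 9 complete pairs without ties, and from the t-approximation
#' otherwise. Pairs with fewer than `min_pairs` complete observations, or
#' involving a constant column, are reported as missing.
#'
#' @param cohort Wide cohort tibble with analyte concentration columns.
#' @param panel Optional `steroid_panel` used to resolve `class_filter`.
#' @param class_filter Optional steroid class(es) to keep (e.g.
#'   `"C11-oxy androgen"`).
#' @param matrix_filter Optional value of the cohort's `matrix` column to
#'   keep (`"serum"` or `"PF"`).
#' @param variables Optional explicit analyte columns (overrides filters).
#' @param min_pairs Minimum complete pairs per cell (default 3).
#' @return A `correlation_matrix`: list of matrices `rho`, `p`, `n_pairs`
#'   and the `variables` vector.
#' @export
spearman_matrix <- function(cohort, panel = NULL, class_filter = NULL,
                            matrix_filter = NULL, variables = NULL,
                            min_pairs = 3) {
  cohort <- tibble::as_tibble(cohort)
  if (!is.null(matrix_filter)) {
    cohort <- cohort[cohort$matrix %in% matrix_filter, ]
  }
  if (is.null(variables)) {
    variables <- if (!is.null(panel)) {
      keep <- panel$steroids$abbreviation
      if (!is.null(class_filter)) {
        keep <- keep[panel$steroids$steroid_class %in% class_filter]
      }
      intersect(keep, names(cohort))
    } else {
      setdiff(names(cohort),
              c("sample_id", "subject_id", "matrix", "phase",
                grep("_flags$", names(cohort), value = TRUE)))
    }
  }
  k <- length(variables)
  if (k < 2) data_error("need >= 2 variables for a correlation matrix")
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  n_pairs <- matrix(0L, k, k, dimnames = list(variables, variables))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    xi <- cohort[[variables[i]]]
    n_pairs[i, i] <- sum(is.finite(xi))
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- cohort[[variables[i]]]
      y <- cohort[[variables[j]]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      n_pairs[i, j] <- n_pairs[j, i] <- n
      if (n < min_pairs) next
      x <- x[ok]; y <- y[ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      sp <- spearman_test(x, y)
      rho[i, j] <- rho[j, i] <- sp$rho
      p[i, j] <- p[j, i] <- sp$p
    }
  }
  structure(list(variables = variables, rho = rho, p = p, n_pairs = n_pairs),
            class = "correlation_matrix")
}

# Spearman rho with average ranks; exact two-sided permutation p for
# n <= 9 with no ties, t-approximation otherwise.
spearman_test <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    perms <- all_permutations(n)
    ref <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(ref) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (!is.finite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d variables; rho in [%.2f, %.2f]\n",
              length(x$variables),
              min(x$rho[upper.tri(x$rho)], na.rm = TRUE),
              max(x$rho[upper.tri(x$rho)], na.rm = TRUE)))
  invisible(x)
}

#' Hierarchical cluster ordering of a correlation matrix
#'
#' Average-linkage hierarchical clustering on the distance `1 - rho`
#' (missing correlations imputed as 0, i.e. maximally uninformative, and
#' flagged). Returns the leaf order used to arrange heat-map rows/columns
#' so that strongly correlated steroids sit in contiguous blocks.
#'
#' @param corr A `correlation_matrix`.
#' @return List with `order` (variable names in leaf order), `hclust`
#'   (the dendrogram object) and `imputed` (count of imputed cells).
#' @export
cluster_order <- function(corr) {
  stopifnot(inherits(corr, "correlation_matrix"))
  rho <- corr$rho
  if (nrow(rho) < 2) data_error("need >= 2 variables to cluster")
  imputed <- sum(is.na(rho[upper.tri(rho)]))
  rho[is.na(rho)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  list(order = corr$variables[hc$order], hclust = hc, imputed = imputed)
}

#' Long-format export of a correlation matrix
#'
#' @param corr A `correlation_matrix`.
#' @return Tibble with `var1`, `var2`, `rho`, `p`, `n_pairs` (upper
#'   triangle only).
#' @export
correlation_long <- function(corr) {
  v <- corr$variables
  idx <- which(upper.tri(corr$rho), arr.ind = TRUE)
  tibble::tibble(var1 = v[idx[, 1]], var2 = v[idx[, 2]],
                 rho = corr$rho[idx], p = corr$p[idx],
                 n_pairs = corr$n_pairs[idx])
}

#' Correlation heat map
#'
#' Cluster-ordered Spearman heat map (requires the suggested `ggplot2`).
#'
#' @param corr A `correlation_matrix`.
#' @param order Reorder rows/columns by [cluster_order()] (default TRUE).
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(corr, order = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    config_error("plotting requires the 'ggplot2' package")
  }
  v <- if (order && length(corr$variables) > 2) cluster_order(corr)$order else corr$variables
  df <- expand.grid(var1 = v, var2 = v, stringsAsFactors = FALSE)
  df$rho <- corr$rho[cbind(df$var1, df$var2)]
  df$var1 <- factor(df$var1, levels = v)
  df$var2 <- factor(df$var2, levels = v)
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Serum-vs-peritoneal-fluid comparison per analyte
#'
#' For every analyte with at least `min_pairs` paired subjects: the median
#' serum and PF concentrations, the serum/PF ratio of medians, and the
#' ordinary least-squares regression of PF on serum with its slope p-value.
#'
#' @param cohort Wide cohort tibble with `subject_id`, `matrix` and
#'   analyte columns.
#' @param variables Analyte columns to compare (default: all analyte
#'   columns present).
#' @param min_pairs Minimum paired subjects per analyte (default 3).
#' @return Tibble: `analyte`, `n_pairs`, `median_serum`, `median_pf`,
#'   `serum_pf_ratio`, `slope`, `intercept`, `p_slope`, `skipped_reason`.
#' @export
serum_pf_compare <- function(cohort, variables = NULL, min_pairs = 3) {
  cohort <- tibble::as_tibble(cohort)
  if (is.null(variables)) {
    variables <- setdiff(names(cohort),
                         c("sample_id", "subject_id", "matrix", "phase",
                           grep("_flags$", names(cohort), value = TRUE)))
  }
  serum <- cohort[cohort$matrix == "serum", ]
  pf <- cohort[cohort$matrix == "PF", ]
  common <- intersect(serum$subject_id, pf$subject_id)
  serum <- serum[match(common, serum$subject_id), ]
  pf <- pf[match(common, pf$subject_id), ]
  dplyr::bind_rows(lapply(variables, function(v) {
    x <- serum[[v]]; y <- pf[[v]]
    ok <- is.finite(x) & is.finite(y)
    base <- tibble::tibble(analyte = v, n_pairs = sum(ok),
                           median_serum = NA_real_, median_pf = NA_real_,
                           serum_pf_ratio = NA_real_, slope = NA_real_,
                           intercept = NA_real_, p_slope = NA_real_,
                           skipped_reason = NA_character_)
    if (sum(ok) < min_pairs) {
      base$skipped_reason <- sprintf("fewer than %d complete pairs", min_pairs)
      return(base)
    }
    x <- x[ok]; y <- y[ok]
    base$median_serum <- stats::median(x)
    base$median_pf <- stats::median(y)
    base$serum_pf_ratio <- base$median_serum / base$median_pf
    if (stats::sd(x) > 0) {
      fit <- stats::lm(y ~ x)
      sm <- suppressWarnings(summary(fit))$coefficients
      base$slope <- sm["x", "Estimate"]
      base$intercept <- sm["(Intercept)", "Estimate"]
      base$p_slope <- sm["x", "Pr(>|t|)"]
    } else {
      base$skipped_reason <- "constant serum values"
    }
    base
  }))
}
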