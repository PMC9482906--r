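# XIC extraction at fixed absolute m/z tolerance and chromatographic peak
# integration. This stands in for the vendor processing step: centroided
# full-scan (or PRM-channel) data in, integrated peak areas out.

#' Construct a centroided scan series
#'
#' A scan series is the centroided spectra of one acquisition channel:
#' one row per centroid with the scan retention time, m/z and intensity.
#' Empty scans (no centroids) are retained through the `scan_rt` attribute
#' so that XICs carry one point per scan.
#'
#' @param peaks Tibble/data.frame with columns `rt` (minutes), `mz` (Th)
#'   and `intensity` (counts).
#' @param polarity `"positive"` or `"negative"`.
#' @param scan_rt Retention times of all scans (defaults to the distinct
#'   `rt` values present in `peaks`). Must be strictly increasing.
#' @return A `scan_series` object.
#' @export
scan_series <- function(peaks, polarity = "positive", scan_rt = NULL) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("rt", "mz", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) data_error("negative centroid intensities")
  if (is.null(scan_rt)) scan_rt <- sort(unique(peaks$rt))
  if (is.unsorted(scan_rt, strictly = TRUE)) {
    data_error("scan retention times must be strictly increasing")
  }
  if (nrow(peaks) && !all(peaks$rt %in% scan_rt)) {
    data_error("centroid rt not on the scan grid")
  }
  peaks <- peaks[order(peaks$rt, peaks$mz), ]
  structure(list(peaks = peaks, polarity = polarity, scan_rt = scan_rt),
            class = "scan_series")
}

#' @export
print.scan_series <- function(x, ...) {
  cat(sprintf("<scan_series> %d scans, %d centroids, polarity %s\n",
              length(x$scan_rt), nrow(x$peaks), x$polarity))
  invisible(x)
}

#' Extract an extracted-ion chromatogram (XIC)
#'
#' For every scan, sums the intensities of all centroids whose m/z lies
#' within an absolute window `target_mz +/- tolerance`. The default
#' tolerance of 0.005 Th (5 mmu) is the matching tolerance of the
#' acquisition method; it is absolute, not ppm.
#'
#' @param scans A `scan_series`.
#' @param target_mz Quantifier ion m/z (Th).
#' @param tolerance Absolute half-window (Th), > 0.
#' @return An `xic` object: tibble with `rt` and `intensity` (zeros where
#'   no centroid matches), plus `target_mz`/`tolerance` attributes.
#' @examples
#' s <- scan_series(data.frame(rt = c(1, 2), mz = c(300, 300.006),
#'                             intensity = c(1000, 500)), scan_rt = c(1, 2))
#' extract_xic(s, 300, 0.005) # second centroid is 6 mmu off: excluded
#' @export
extract_xic <- function(scans, target_mz, tolerance = 0.005) {
  stopifnot(inherits(scans, "scan_series"))
  if (tolerance <= 0) config_error("tolerance must be > 0")
  hit <- scans$peaks[abs(scans$peaks$mz - target_mz) <= tolerance, ]
  rt <- scans$scan_rt
  intensity <- numeric(length(rt))
  if (nrow(hit)) {
    agg <- stats::aggregate(intensity ~ rt, data = hit, FUN = sum)
    intensity[match(agg$rt, rt)] <- agg$intensity
  }
  structure(tibble::tibble(rt = rt, intensity = intensity),
            target_mz = target_mz, tolerance = tolerance,
            class = c("xic", class(tibble::tibble())))
}

#' Integrate a chromatographic peak
#'
#' Locates the apex as the intensity maximum inside
#' `expected_rt +/- rt_window`, walks the peak bounds outward from the apex
#' until the trace falls below 0.1% of the apex intensity or reaches a
#' local minimum below 5% of the apex, subtracts a linear baseline drawn between
#' the boundary points, and integrates by the trapezoidal rule. A peak is
#' flagged `not_detected` when the apex does not exceed 3x the median
#' intensity outside the search window (local background).
#'
#' @param xic An `xic` (or any tibble with `rt`/`intensity`).
#' @param expected_rt Expected apex retention time (minutes).
#' @param rt_window Half-width of the apex search window (minutes).
#' @param analyte,sample_id Identifiers carried into the result.
#' @param lower_frac,minimum_frac Boundary thresholds as fractions of the
#'   apex intensity (defaults 0.001 and 0.05; the 0.1% lower bound keeps
#'   the truncation-plus-baseline bias of a Gaussian peak below 0.5%).
#' @param detection_factor Apex must exceed this multiple of the local
#'   background median to count as detected (default 3).
#' @return A one-row tibble (`peak_measurement`): `analyte`, `sample_id`,
#'   `area` (counts x min), `apex_rt`, `apex_intensity`, `flags`.
#' @export
integrate_peak <- function(xic, expected_rt, rt_window = 0.2,
                           analyte = NA_character_, sample_id = NA_character_,
                           lower_frac = 0.001, minimum_frac = 0.05,
                           detection_factor = 3) {
  if (rt_window <= 0) config_error("rt_window must be > 0")
  rt <- xic$rt
  y <- xic$intensity
  empty <- tibble::tibble(analyte = analyte, sample_id = sample_id,
                          area = 0, apex_rt = NA_real_, apex_intensity = 0,
                          flags = "not_detected")
  if (length(rt) == 0) return(empty)
  in_win <- which(rt >= expected_rt - rt_window & rt <= expected_rt + rt_window)
  if (length(in_win) == 0) return(empty)
  apex <- in_win[which.max(y[in_win])]
  apex_y <- y[apex]
  bg <- y[-in_win]
  background <- if (length(bg)) stats::median(bg) else 0
  # all-zero window, or apex indistinguishable from local background
  if (apex_y <= 0 || apex_y < detection_factor * background) return(empty)
  lo_thr <- lower_frac * apex_y
  min_thr <- minimum_frac * apex_y
  left <- apex
  while (left > 1) {
    nxt <- left - 1L
    if (y[nxt] <= lo_thr) { left <- nxt; break }
    if (y[nxt] < min_thr && y[nxt] >= y[left]) break  # local minimum in the tail
    left <- nxt
  }
  right <- apex
  n <- length(rt)
  while (right < n) {
    nxt <- right + 1L
    if (y[nxt] <= lo_thr) { right <- nxt; break }
    if (y[nxt] < min_thr && y[nxt] >= y[right]) break
    right <- nxt
  }
  idx <- left:right
  # linear baseline between boundary points
  base <- y[left] + (y[right] - y[left]) *
    (rt[idx] - rt[left]) / max(rt[right] - rt[left], .Machine$double.eps)
  sig <- pmax(y[idx] - base, 0)
  area <- sum(diff(rt[idx]) * (utils::head(sig, -1) + utils::tail(sig, -1)) / 2)
  tibble::tibble(analyte = analyte, sample_id = sample_id,
                 area = area, apex_rt = rt[apex], apex_intensity = apex_y,
                 flags = "")
}

#' Read centroided spectra from an mzML file
#'
#' Thin wrapper around the `mzR` reader producing a [scan_series()] per
#' polarity. Requires the suggested `mzR` package.
#'
#' @param path Path to a centroided mzML file.
#' @param polarity Keep only scans of this polarity (`"positive"`,
#'   `"negative"`); scans with unknown polarity are kept in either case.
#' @return A `scan_series`.
#' @export
read_mzml <- function(path, polarity = "positive") {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    config_error("reading mzML requires the 'mzR' package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  want <- if (polarity == "positive") hdr$polarity != 0 else hdr$polarity != 1
  want[is.na(want)] <- TRUE
  keep <- which(want)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  rows <- lapply(keep, function(i) {
    m <- pk[[i]]
    if (length(m) == 0 || nrow(m) == 0) return(NULL)
    tibble::tibble(rt = hdr$retentionTime[i] / 60, mz = m[, 1],
                   intensity = m[, 2])
  })
  peaks <- dplyr::bind_rows(rows)
  scan_series(peaks, polarity = polarity,
              scan_rt = sort(unique(hdr$retentionTime[keep] / 60)))
}

#' Integrate all panel analytes of one sample
#'
#' Convenience wrapper: extracts the XIC of every panel steroid and
#' internal standard from a scan series and integrates each at its
#' expected retention time. The 5-mmu default window is applied.
#'
#' @param scans A `scan_series` (one sample, one polarity).
#' @param panel A `steroid_panel`.
#' @param sample_id Identifier carried into the results.
#' @param tolerance Absolute m/z half-window (Th).
#' @param rt_window Apex search half-window (minutes).
#' @return Tibble of peak measurements for analytes (`kind = "analyte"`)
#'   and internal standards (`kind = "internal_standard"`).
#' @export
measure_sample <- function(scans, panel, sample_id = "sample",
                           tolerance = 0.005, rt_window = 0.2) {
  pol <- scans$polarity
  st <- panel$steroids[panel$steroids$polarity == pol, ]
  # an internal standard acquires in the polarity of the analyte it labels
  is_pol <- panel$steroids$polarity[match(panel$internal_standards$labels_analyte,
                                          panel$steroids$abbreviation)]
  istd <- panel$internal_standards[!is.na(is_pol) & is_pol == pol, ]
  analyte_rows <- lapply(seq_len(nrow(st)), function(i) {
    x <- extract_xic(scans, st$mz[i], tolerance)
    cbind(integrate_peak(x, st$expected_rt[i], rt_window,
                         analyte = st$abbreviation[i], sample_id = sample_id),
          kind = "analyte")
  })
  is_rows <- lapply(seq_len(nrow(istd)), function(i) {
    r <- istd[i, ]
    x <- extract_xic(scans, r$mz, tolerance)
    cbind(integrate_peak(x, r$expected_rt, rt_window,
                         analyte = r$id, sample_id = sample_id),
          kind = "internal_standard")
  })
  dplyr::bind_rows(c(analyte_rows, is_rows))
}
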