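# Fluorescence membrane-profile quantification: relative-intensity profiles
# along a sampling path and peak/trough intensity ratios.

#' Sample an intensity profile along a path
#'
#' Bilinear samples at unit-pixel arclength steps along the polyline,
#' averaged across `width_px` pixels perpendicular to the local tangent.
#' The relative intensity normalises by the profile maximum, so the
#' profile's peak is exactly 1 and the result is invariant to detector gain.
#'
#' @param image numeric matrix (single fluorescence frame).
#' @param path `n x 2` polyline matrix (columns x, y, 0-based px) tracing
#'   the membrane; must lie within the image.
#' @param width_px odd number of perpendicular pixels to average.
#' @param pixel_size micrometres per pixel (calibrates `position`).
#' @return An `intensity_profile` data frame: `position` (um, arclength),
#'   `intensity` (raw), `relative_intensity` (fraction of maximum).
#' @export
sample_profile <- function(image, path, width_px = 1L, pixel_size = 1) {
  stopifnot(is.matrix(image), pixel_size > 0)
  path <- as.matrix(path)
  if (any(path[, 1] < 0 | path[, 1] > ncol(image) - 1 |
          path[, 2] < 0 | path[, 2] > nrow(image) - 1))
    stop("path outside image bounds")
  width_px <- odd_window(width_px)
  pts <- resample_polyline(path, step = 1)
  vals <- if (width_px == 1L) {
    bilinear(image, pts[, 1], pts[, 2])
  } else {
    nrm <- polyline_normals(pts)
    offs <- seq.int(-(width_px - 1L) %/% 2L, (width_px - 1L) %/% 2L)
    xs <- matrix(pts[, 1], nrow(pts), length(offs)) + outer(nrm[, 1], offs)
    ys <- matrix(pts[, 2], nrow(pts), length(offs)) + outer(nrm[, 2], offs)
    rowMeans(matrix(bilinear(image, as.vector(xs), as.vector(ys)),
                    nrow(pts), length(offs)))
  }
  mx <- max(vals)
  if (mx <= 0) stop("empty signal along path")
  out <- data.frame(position = (seq_len(nrow(pts)) - 1) * pixel_size,
                    intensity = vals,
                    relative_intensity = vals / mx)
  class(out) <- c("intensity_profile", class(out))
  out
}

#' Peak/trough quantification of a membrane intensity profile
#'
#' The relative-intensity profile is smoothed with a centred moving average,
#' peaks are local maxima with topographic prominence of at least
#' `prominence` (relative units) and troughs are the minima of the segments
#' between consecutive peaks (plus the leading/trailing segments when long
#' enough), so that flat inter-focus baselines still yield a trough value.
#' The ratio is `mean(peak values) / mean(trough values)` — the
#' average-maximum over average-minimum reading of a dotted-line
#' quantification; set `global_extrema = TRUE` for the simpler
#' max/min alternative. Profiles with no detectable peak/trough structure
#' (diffuse signal, the mutant-phenotype readout) return ratio 1 with
#' `diffuse = TRUE`.
#'
#' @param profile an `intensity_profile` from [sample_profile()] (any data
#'   frame with `relative_intensity` works).
#' @param smooth_window moving-average width, samples.
#' @param prominence peak prominence threshold, relative-intensity units.
#' @param min_height minimum relative intensity for a peak to count as a
#'   focus (foci are bright structures; faint noise bumps are not).
#' @param global_extrema use global max/min instead of averaged extrema.
#' @return A `foci_quant` list: `peak_values`, `trough_values`, `mean_max`,
#'   `mean_min`, `ratio`, `diffuse`.
#' @export
foci_quant <- function(profile, smooth_window = 5L, prominence = 0.1,
                       min_height = 0.5, global_extrema = FALSE) {
  stopifnot("relative_intensity" %in% names(profile))
  y <- profile$relative_intensity
  if (length(y) < 3 * smooth_window)
    stop("profile too short for smoothing window")
  sm <- moving_average(y, smooth_window)

  if (global_extrema) {
    ratio <- max(sm) / max(min(sm), .Machine$double.eps)
    return(structure(list(peak_values = max(sm), trough_values = min(sm),
                          mean_max = max(sm), mean_min = min(sm),
                          ratio = ratio, diffuse = FALSE),
                     class = "foci_quant"))
  }

  pk <- find_peaks(sm, prominence)
  pk <- pk[sm[pk] >= min_height]   # foci are bright: reject faint noise bumps
  if (!length(pk)) {
    return(structure(list(peak_values = numeric(0), trough_values = numeric(0),
                          mean_max = NA_real_, mean_min = NA_real_,
                          ratio = 1, diffuse = TRUE),
                     class = "foci_quant"))
  }
  # Peak value from the *unsmoothed* profile (median of the 3 samples around
  # the located maximum): the moving average attenuates sharp foci, and the
  # short median keeps single-sample noise out without that bias.
  peak_values <- vapply(pk, function(p) {
    stats::median(y[max(1L, p - 1L):min(length(y), p + 1L)])
  }, numeric(1))

  # Flank exclusion: estimate each focus' half-height half-width and mask
  # samples within 3 estimated SDs of the peak (HWHM = 1.177 sd for a
  # Gaussian focus), leaving only baseline-level samples.
  low <- stats::quantile(sm, 0.1, names = FALSE)
  flank <- rep(FALSE, length(sm))
  for (p in pk) {
    half <- (sm[p] + low) / 2
    r <- p; while (r < length(sm) && sm[r] > half) r <- r + 1L
    l <- p; while (l > 1 && sm[l] > half) l <- l - 1L
    hw <- max(r - p, p - l, 1L)
    zone <- max(1L, p - 3L * ceiling(hw / 1.177)):min(length(sm), p + 3L * ceiling(hw / 1.177))
    flank[zone] <- TRUE
  }

  # troughs: one per inter-peak segment (edge segments when long enough);
  # value = median of the segment's baseline-level (non-flank) samples — an
  # unbiased level estimate, where a raw segment minimum would inherit the
  # downward bias of an extreme-value statistic under noise. Crowded
  # segments with no baseline-level samples fall back to the segment
  # minimum.
  segs <- list()
  if (pk[1] - 1 >= smooth_window) segs <- c(segs, list(1:(pk[1] - 1)))
  if (length(pk) > 1)
    for (i in seq_len(length(pk) - 1))
      segs <- c(segs, list((pk[i] + 1):(pk[i + 1] - 1)))
  if (length(sm) - pk[length(pk)] >= smooth_window)
    segs <- c(segs, list((pk[length(pk)] + 1):length(sm)))
  trough_values <- vapply(segs, function(s) {
    flat <- s[!flank[s]]
    if (length(flat) >= smooth_window) stats::median(sm[flat]) else min(sm[s])
  }, numeric(1))
  if (!length(trough_values)) {
    return(structure(list(peak_values = peak_values, trough_values = numeric(0),
                          mean_max = mean(peak_values), mean_min = NA_real_,
                          ratio = 1, diffuse = TRUE),
                     class = "foci_quant"))
  }
  mean_max <- mean(peak_values)
  mean_min <- mean(trough_values)
  structure(list(peak_values = peak_values, trough_values = trough_values,
                 mean_max = mean_max, mean_min = mean_min,
                 ratio = mean_max / max(mean_min, .Machine$double.eps),
                 diffuse = FALSE),
            class = "foci_quant")
}

#' @export
print.foci_quant <- function(x, ...) {
  if (x$diffuse) {
    cat("<foci_quant> diffuse signal (no peak/trough structure), ratio 1\n")
  } else {
    cat(sprintf("<foci_quant> %d peaks (mean %.3f), %d troughs (mean %.3f), ratio %.2f\n",
                length(x$peak_values), x$mean_max,
                length(x$trough_values), x$mean_min, x$ratio))
  }
  invisible(x)
}
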