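# Kymograph blood-flow velocimetry.
#
# Orientation of the kymograph is fixed as rows = frames (time), columns =
# distance along the vessel. A blood cell moving at constant speed appears
# as a straight streak; its slope m = dframes/ddistance (frames per px) maps
# to velocity v = pixel_size * frame_rate / m, so a steeper slope (towards
# the time axis) means slower flow.

#' Space-time (kymograph) image with calibration
#'
#' @param image numeric matrix, rows = frames (time), columns = distance
#'   along the vessel in pixels.
#' @param pixel_size micrometres per pixel along the distance axis.
#' @param frame_rate frames per second.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(image, pixel_size = 1, frame_rate = 1) {
  image <- as.matrix(image)
  stopifnot(nrow(image) >= 2, ncol(image) >= 2, pixel_size > 0, frame_rate > 0)
  structure(list(image = image, pixel_size = pixel_size, frame_rate = frame_rate),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d px @ %g fps, %g um/px\n",
              nrow(x$image), ncol(x$image), x$frame_rate, x$pixel_size))
  invisible(x)
}

#' Build a kymograph from a video along a vessel ROI
#'
#' Row `t` of the kymograph is the intensity of frame `t` sampled by
#' bilinear interpolation at unit-arclength steps along the polyline,
#' averaged across `line_width` pixels perpendicular to the local tangent.
#'
#' @param video a [video_stack()].
#' @param roi `n x 2` polyline matrix (columns x, y, 0-based pixel
#'   coordinates) tracing the vessel centreline; must lie within the frame.
#' @param line_width odd number of perpendicular pixels to average.
#' @return A [kymograph()] inheriting the video's calibration.
#' @export
build_kymograph <- function(video, roi, line_width = 5L) {
  stopifnot(inherits(video, "video_stack"), n_frames(video) >= 2)
  line_width <- odd_window(line_width)
  d <- dim(video$frames)
  roi <- as.matrix(roi)
  if (any(roi[, 1] < 0 | roi[, 1] > d[2] - 1 | roi[, 2] < 0 | roi[, 2] > d[1] - 1))
    stop("roi outside image bounds")
  pts <- resample_polyline(roi, step = 1)
  nrm <- polyline_normals(pts)
  offs <- seq.int(-(line_width - 1L) %/% 2L, (line_width - 1L) %/% 2L)
  # sample coordinates: for each offset, points shifted along the normal
  xs <- matrix(pts[, 1], nrow(pts), length(offs)) + outer(nrm[, 1], offs)
  ys <- matrix(pts[, 2], nrow(pts), length(offs)) + outer(nrm[, 2], offs)
  kimg <- matrix(0, n_frames(video), nrow(pts))
  for (f in seq_len(n_frames(video))) {
    vals <- bilinear(video$frames[, , f], as.vector(xs), as.vector(ys))
    kimg[f, ] <- rowMeans(matrix(vals, nrow(pts), length(offs)))
  }
  kymograph(kimg, pixel_size = video$pixel_size, frame_rate = video$frame_rate)
}

# Structure-tensor orientation for one block of gradient products.
# Returns slope m (frames per px, >= 0), and coherence in [0, 1].
#' @noRd
tensor_orientation <- function(Jxx, Jxt, Jtt) {
  tr <- Jxx + Jtt
  if (tr <= 0) return(list(m = NA_real_, coherence = 0))
  diff2 <- sqrt((Jxx - Jtt)^2 + 4 * Jxt^2)
  coherence <- diff2 / tr
  # eigenvector of the SMALLEST eigenvalue = streak direction (vx, vt)
  l2 <- (tr - diff2) / 2
  vx <- -2 * Jxt
  vt <- Jxx - Jtt + diff2
  n <- sqrt(vx^2 + vt^2)
  if (n < 1e-12 * tr) {
    # Jxt ~ 0 and Jxx <= Jtt: streak lies along the distance axis (m = 0);
    # with no anisotropy at all there is no orientation to report.
    if (coherence < 1e-9) return(list(m = NA_real_, coherence = coherence))
    return(list(m = 0, coherence = coherence))
  }
  m <- abs(vt) / max(abs(vx), .Machine$double.eps * n)
  list(m = m, coherence = coherence)
}

#' Streak velocity trace from a kymograph
#'
#' Estimates the dominant streak orientation in sliding time windows by
#' structure-tensor eigenanalysis: image gradients from Gaussian-derivative
#' filters (scale `deriv_sigma`), gradient-product smoothing at
#' `integration_sigma`, then per-window averaging and closed-form 2x2
#' eigen-decomposition. With slope `m = dframes/ddistance` (frames per px),
#' velocity is `pixel_size * frame_rate / m`; larger `m` (streak steeper
#' towards the time axis) gives smaller velocity. Windows whose orientation
#' coherence falls below `coherence_min` are flagged missing rather than
#' forced to zero.
#'
#' @param k a [kymograph()].
#' @param window_frames sliding window length in frames (>= 8); windows
#'   overlap by 50%.
#' @param deriv_sigma,integration_sigma Gaussian derivative and integration
#'   scales, px.
#' @param coherence_min minimum orientation coherence to accept a window.
#' @param calibrated if `FALSE`, report velocity as 1/m in px/frame instead
#'   of um/s.
#' @return A `velocity_trace` data frame with columns `time` (s, window
#'   centre), `velocity`, `slope` (frames per px), `coherence`, `missing`.
#' @export
streak_velocity <- function(k, window_frames = 16L, deriv_sigma = 1.5,
                            integration_sigma = 4, coherence_min = 0.2,
                            calibrated = TRUE) {
  stopifnot(inherits(k, "kymograph"), window_frames >= 8)
  img <- k$image
  img <- img / max(abs(img), 1)
  g0 <- gauss_kernel(deriv_sigma, 0L)
  g1 <- gauss_kernel(deriv_sigma, 1L)
  gx <- sep_filter(img, g0, g1)   # d/ddistance (columns)
  gt <- sep_filter(img, g1, g0)   # d/dtime (rows)
  gi <- gauss_kernel(integration_sigma, 0L)
  Jxx <- sep_filter(gx * gx, gi, gi)
  Jxt <- sep_filter(gx * gt, gi, gi)
  Jtt <- sep_filter(gt * gt, gi, gi)

  # trim the column border contaminated by edge replication
  bc <- min(ceiling(4 * max(deriv_sigma, integration_sigma)), (ncol(img) - 1) %/% 3)
  cols <- (1 + bc):(ncol(img) - bc)

  hop <- max(1L, window_frames %/% 2L)
  starts <- seq.int(1L, nrow(img) - window_frames + 1L, by = hop)
  res <- lapply(starts, function(s) {
    rows <- s:(s + window_frames - 1L)
    o <- tensor_orientation(mean(Jxx[rows, cols]), mean(Jxt[rows, cols]),
                            mean(Jtt[rows, cols]))
    center <- (s - 1 + (window_frames - 1) / 2) / k$frame_rate
    miss <- !is.finite(o$m) || o$coherence < coherence_min
    v <- if (miss) NA_real_
         else if (calibrated) k$pixel_size * k$frame_rate / o$m
         else 1 / o$m
    data.frame(time = center, velocity = v, slope = o$m,
               coherence = o$coherence, missing = miss)
  })
  out <- do.call(rbind, res)
  class(out) <- c("velocity_trace", class(out))
  out
}

#' Label systolic and diastolic phases on a velocity trace
#'
#' Missing samples are linearly interpolated for segmentation only. The
#' trace is lightly smoothed, and the threshold is the midpoint of its 10th
#' and 90th percentiles: samples above are systole, below diastole. A flat
#' trace (10–90 percentile range below 5% of the mean) is labelled all
#' diastole and flagged with the attribute `flat_trace`.
#'
#' @param v a `velocity_trace` data frame (from [streak_velocity()] or
#'   [kinematics()]) spanning at least two cardiac cycles.
#' @param smooth_samples moving-average width for segmentation.
#' @return The input with a `phase` factor column (`"systole"`/`"diastole"`);
#'   attribute `flat_trace` is `TRUE` if the flat-trace fallback fired.
#' @export
segment_phases <- function(v, smooth_samples = 5L) {
  stopifnot(is.data.frame(v), "velocity" %in% names(v))
  vel <- v$velocity
  if (all(!is.finite(vel))) stop("no usable velocity samples")
  vel <- stats::approx(seq_along(vel)[is.finite(vel)], vel[is.finite(vel)],
                       xout = seq_along(vel), rule = 2)$y
  sm <- moving_average(vel, smooth_samples)
  q <- stats::quantile(sm, c(0.1, 0.9), names = FALSE)
  flat <- (q[2] - q[1]) < 0.05 * abs(mean(sm))
  if (flat) {
    warning("flat velocity trace: labelling all samples diastole")
    v$phase <- factor(rep("diastole", nrow(v)), levels = c("systole", "diastole"))
  } else {
    thr <- mean(q)
    v$phase <- factor(ifelse(sm > thr, "systole", "diastole"),
                      levels = c("systole", "diastole"))
  }
  attr(v, "flat_trace") <- flat
  v
}

#' Systolic/diastolic phase summary of a velocity trace
#'
#' Reports peak-systolic and end-diastolic velocity in the Doppler
#' convention: each contiguous systolic segment of the labelled trace
#' contributes its upper-quantile velocity (default 0.95, guarding against
#' single-sample spikes), each diastolic segment its lower-quantile
#' velocity, and the per-phase summaries are the means of those per-cycle
#' extremes. A mean over *all* samples of a phase would sit between the
#' extremes of the waveform rather than at them; the per-cycle extreme is
#' what a streak-angle readout of the steepest/shallowest kymograph angle
#' measures. Only measured (non-missing) samples contribute. Streak angles
#' are reported as `atan(m)` in degrees from the distance axis, `m` being
#' the matching per-cycle slope quantile (steeper angle = slower flow).
#'
#' @param v a phase-labelled `velocity_trace` (see [segment_phases()]).
#' @param extreme_quantile quantile used for the per-cycle extreme
#'   (`0.5` would give plain per-phase medians).
#' @return List with `v_systolic_mean`, `v_diastolic_mean`,
#'   `angle_systolic`, `angle_diastolic` (degrees) and per-phase sample
#'   counts.
#' @export
phase_summary <- function(v, extreme_quantile = 0.95) {
  stopifnot(is.data.frame(v), "phase" %in% names(v),
            extreme_quantile >= 0.5, extreme_quantile <= 1)
  miss <- if ("missing" %in% names(v)) v$missing else rep(FALSE, nrow(v))
  use <- is.finite(v$velocity) & !miss
  if (!any(use & v$phase == "systole") || !any(use & v$phase == "diastole"))
    stop("missing phase: both phases required")
  runs <- rle(as.character(v$phase))
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  summarise_phase <- function(phase_name, q_v) {
    idx_runs <- which(runs$values == phase_name)
    # a run cut off by the trace boundary is an incomplete cycle and does not
    # reach the phase extreme; drop it when complete runs exist
    complete <- idx_runs[starts[idx_runs] > 1L & ends[idx_runs] < nrow(v)]
    if (length(complete)) idx_runs <- complete
    vs <- numeric(0); ms <- numeric(0)
    for (i in idx_runs) {
      idx <- starts[i]:ends[i]
      idx <- idx[use[idx]]
      if (!length(idx)) next
      vs <- c(vs, stats::quantile(v$velocity[idx], q_v, names = FALSE))
      sl <- v$slope[idx]
      if (any(is.finite(sl)))
        ms <- c(ms, stats::quantile(sl[is.finite(sl)], 1 - q_v, names = FALSE))
    }
    list(v = mean(vs), angle = atan(mean(ms)) * 180 / pi, n_runs = length(vs))
  }
  sys <- summarise_phase("systole", extreme_quantile)
  dia <- summarise_phase("diastole", 1 - extreme_quantile)
  list(v_systolic_mean = sys$v, v_diastolic_mean = dia$v,
       angle_systolic = sys$angle, angle_diastolic = dia$angle,
       n_systole = sum(use & v$phase == "systole"),
       n_diastole = sum(use & v$phase == "diastole"))
}
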