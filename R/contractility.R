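# Ventricular contractility from per-frame outlines.
#
# Axis convention: "major axis" and "minor axis" are FULL axis lengths.
# Under that reading the printed area formula (0.5*major)*(0.5*minor)*pi is
# the exact ellipse area, and (1/6)*pi*major*minor^2 equals the standard
# prolate-spheroid volume (4/3)*pi*(major/2)*(minor/2)^2. Half-axis readings
# make neither identity hold, so full axes are used throughout.

#' Least-squares ellipse fit to a contour
#'
#' Direct least-squares conic fit (eigen-decomposition of the scatter matrix
#' under the ellipse constraint \eqn{4AC - B^2 = 1}), numerically conditioned
#' by centring/scaling. For vertices sampled exactly from an ellipse the
#' recovered axes are exact to floating-point precision.
#'
#' @param contour `n x 2` matrix of vertex coordinates (columns x, y) in
#'   pixels; at least 5 non-collinear vertices.
#' @param pixel_size micrometres per pixel (calibrates the axis lengths).
#' @return An object of class `ellipse_fit`: list with `center` (x, y in px),
#'   `major_axis` and `minor_axis` (*full* lengths, um) and `orientation`
#'   (radians, major-axis direction).
#' @export
fit_ellipse <- function(contour, pixel_size = 1) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 5) stop("degenerate contour: need at least 5 vertices")
  x <- contour[, 1]; y <- contour[, 2]
  mx <- mean(x); my <- mean(y)
  s <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(s) || s <= .Machine$double.eps) stop("degenerate contour")
  X <- (x - mx) / s; Y <- (y - my) / s

  D1 <- cbind(X^2, X * Y, Y^2)
  D2 <- cbind(X, Y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) stop("degenerate contour"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 1e-12)
  if (!length(ok)) stop("degenerate contour: no ellipse solution")
  a1 <- vec[, ok[1]]
  coef <- c(a1, as.vector(Tm %*% a1))   # A B C D E F in scaled coordinates

  geo <- conic_to_ellipse(coef)
  list_fit <- list(center = c(x = geo$cx * s + mx, y = geo$cy * s + my),
                   major_axis = 2 * geo$a * s * pixel_size,
                   minor_axis = 2 * geo$b * s * pixel_size,
                   orientation = geo$theta)
  structure(list_fit, class = "ellipse_fit")
}

# Conic Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0 -> centre, semi-axes, angle.
#' @noRd
conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("degenerate contour: not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  root <- sqrt((A - C)^2 + B^2)
  a <- -sqrt(num * (A + C + root)) / den
  b <- -sqrt(num * (A + C - root)) / den
  theta <- atan2(C - A - root, B)
  if (a < b) { tmp <- a; a <- b; b <- tmp; theta <- theta + pi / 2 }
  list(cx = cx, cy = cy, a = a, b = b, theta = theta)
}

#' Ellipse area from fitted axes
#'
#' Implements `(0.5 * major) * (0.5 * minor) * pi` on full axis lengths.
#'
#' @param e an `ellipse_fit` (or any list with `major_axis`, `minor_axis`).
#' @return Area in square micrometres.
#' @export
ellipse_area <- function(e) {
  stopifnot(e$major_axis > 0, e$minor_axis > 0)
  0.25 * pi * e$major_axis * e$minor_axis
}

#' Prolate-spheroid ventricular volume from fitted axes
#'
#' Implements `(1/6) * pi * major * minor^2` on full axis lengths, which is
#' identical to the prolate-spheroid volume
#' \eqn{(4/3)\pi (major/2)(minor/2)^2} obtained by rotating the ellipse
#' about its long axis.
#'
#' @inheritParams ellipse_area
#' @return Volume in cubic micrometres.
#' @export
ellipse_volume <- function(e) {
  stopifnot(e$major_axis > 0, e$minor_axis > 0)
  pi / 6 * e$major_axis * e$minor_axis^2
}

#' Detect end-diastolic and end-systolic frames in an area trace
#'
#' The trace is smoothed with a centred moving average of width
#' `round(frame_rate / 10)` frames (removing pixel-quantisation ripple
#' without shifting the extrema of beats longer than 0.2 s), then
#' end-diastolic frames are local maxima and end-systolic frames local
#' minima with topographic prominence of at least `prominence_frac` of the
#' smoothed trace's range. Each end-diastole is paired with the next
#' end-systole; beat intervals are successive ED-to-ED times.
#'
#' @param area_trace numeric vector, ventricular area per frame (um^2).
#' @param frame_rate frames per second.
#' @param prominence_frac prominence threshold as a fraction of trace range.
#' @param smooth_width smoothing window in frames; default
#'   `round(frame_rate / 10)`.
#' @return List with `ed_frames`, `es_frames` (0-based frame indices) and
#'   `beat_intervals` (seconds).
#' @export
detect_beats <- function(area_trace, frame_rate, prominence_frac = 0.2,
                         smooth_width = NULL) {
  stopifnot(length(area_trace) >= 3, frame_rate > 0)
  smooth_width <- smooth_width %||% round(frame_rate / 10)
  sm <- moving_average(area_trace, smooth_width)
  rng <- diff(range(sm))
  if (rng <= 0) stop("insufficient beats: flat trace")
  prom <- prominence_frac * rng
  ed <- find_peaks(sm, prom)
  es <- find_troughs(sm, prom)
  if (length(ed) < 2) stop("insufficient beats")
  # pair each ED with the next ES
  pairs <- vapply(ed, function(i) {
    nxt <- es[es > i]
    if (length(nxt)) nxt[1] else NA_integer_
  }, integer(1))
  list(ed_frames = ed - 1L, es_frames = pairs - 1L,
       beat_intervals = diff(ed) / frame_rate)
}

#' Contractility metrics from a contour series
#'
#' For every frame an ellipse is fitted to the outline; the resulting area
#' trace drives beat detection. Per beat, EDV/ESV come from
#' [ellipse_volume()] at the end-diastolic/end-systolic frames and areas from
#' [ellipse_area()]; then SV = EDV − ESV, EF = SV/EDV and
#' FAC = (area_d − area_s)/area_d. Metrics are averaged over all complete
#' beats (set `single_beat = TRUE` to use only the first), heart rate is
#' `60 / median(beat_intervals)` and `rhythm_cv` is the coefficient of
#' variation of the beat intervals (values above `irregular_cv` raise the
#' `irregular` flag).
#'
#' @param contours a [contour_series()] spanning at least two beats.
#' @param single_beat use only the first complete beat instead of averaging.
#' @param irregular_cv rhythm-irregularity threshold on the interval CV.
#' @param prominence_frac passed to [detect_beats()].
#' @return A `beat_metrics` list: `edv`, `esv`, `sv` (um^3), `ef`, `fac`
#'   (fractions), `area_diastole`, `area_systole` (um^2), `heart_rate`
#'   (beats/min), `beat_intervals` (s), `rhythm_cv`, `n_beats`, `irregular`.
#' @export
beat_metrics <- function(contours, single_beat = FALSE, irregular_cv = 0.1,
                         prominence_frac = 0.2) {
  stopifnot(inherits(contours, "contour_series"))
  fits <- lapply(contours$contours, fit_ellipse, pixel_size = contours$pixel_size)
  areas <- vapply(fits, ellipse_area, numeric(1))
  beats <- detect_beats(areas, contours$frame_rate,
                        prominence_frac = prominence_frac)
  ed <- beats$ed_frames + 1L
  es <- beats$es_frames + 1L
  ok <- !is.na(es)
  if (!any(ok)) stop("insufficient beats")
  ed <- ed[ok]; es <- es[ok]
  if (single_beat) { ed <- ed[1]; es <- es[1] }

  edv <- vapply(fits[ed], ellipse_volume, numeric(1))
  esv <- vapply(fits[es], ellipse_volume, numeric(1))
  area_d <- areas[ed]
  area_s <- areas[es]
  sv <- edv - esv
  iv <- beats$beat_intervals
  cv <- if (length(iv) >= 2 && mean(iv) > 0) stats::sd(iv) / mean(iv) else 0

  structure(list(
    edv = mean(edv), esv = mean(esv), sv = mean(sv),
    ef = mean(sv / edv),
    area_diastole = mean(area_d), area_systole = mean(area_s),
    fac = mean((area_d - area_s) / area_d),
    heart_rate = 60 / stats::median(iv),
    beat_intervals = iv,
    rhythm_cv = cv,
    n_beats = length(ed),
    irregular = cv > irregular_cv
  ), class = "beat_metrics")
}

#' @export
print.beat_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<beat_metrics> %d beats\n",
    "  EDV %.0f um^3  ESV %.0f um^3  SV %.0f um^3\n",
    "  EF %.3f  FAC %.3f\n",
    "  heart rate %.1f bpm, interval CV %.3f%s\n"),
    x$n_beats, x$edv, x$esv, x$sv, x$ef, x$fac, x$heart_rate, x$rhythm_cv,
    if (x$irregular) " (IRREGULAR)" else ""))
  invisible(x)
}

#' Extract per-frame ventricle contours from binary or grayscale masks
#'
#' Each frame is lightly smoothed, thresholded at `threshold_frac` of its
#' dynamic range, and the boundary pixels of the resulting ventricle mask
#' (mask pixels with at least one 4-neighbour outside the mask) are returned
#' ordered by angle about the mask centroid. The fit consuming these
#' contours is point-set based, so angular ordering suffices.
#'
#' @param video a [video_stack()] of bright-ventricle frames (or binary
#'   masks).
#' @param threshold_frac threshold as a fraction of each frame's range.
#' @param smooth_sigma Gaussian pre-smoothing SD in px (0 disables).
#' @return A [contour_series()].
#' @export
contours_from_masks <- function(video, threshold_frac = 0.5, smooth_sigma = 1) {
  stopifnot(inherits(video, "video_stack"))
  g <- if (smooth_sigma > 0) gauss_kernel(smooth_sigma) else NULL
  contours <- lapply(seq_len(n_frames(video)), function(f) {
    img <- video$frames[, , f]
    if (!is.null(g)) img <- sep_filter(img, g, g)
    thr <- min(img) + threshold_frac * diff(range(img))
    m <- img > thr
    if (sum(m) < 9) stop("empty ventricle mask in frame ", f - 1L)
    interior <- m
    interior[] <- FALSE
    nr <- nrow(m); nc <- ncol(m)
    interior[2:(nr - 1), 2:(nc - 1)] <-
      m[2:(nr - 1), 2:(nc - 1)] & m[1:(nr - 2), 2:(nc - 1)] &
      m[3:nr, 2:(nc - 1)] & m[2:(nr - 1), 1:(nc - 2)] & m[2:(nr - 1), 3:nc]
    bnd <- which(m & !interior, arr.ind = TRUE)
    xy <- cbind(x = bnd[, 2] - 1, y = bnd[, 1] - 1)
    ctr <- colMeans(xy)
    xy[order(atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1])), , drop = FALSE]
  })
  contour_series(contours, video$frame_rate, video$pixel_size)
}
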