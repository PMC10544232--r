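# Synthetic-data generators with ground-truth sidecars.
#
# Defaults reproduce the acquisition settings of the assays they emulate:
# bright-field heart recordings at 150 frames/s for 10 s, dorsal-aorta flow
# recordings at 400 frames/s for 500 frames. Rendering is deliberately
# simple — filled soft-edged shapes on a dark background — because the
# downstream estimators consume geometry and motion, not texture.

#' Parameters for the beating-heart simulator
#'
#' The ventricle is modelled as a filled ellipse whose full axes oscillate
#' between prescribed end-diastolic (ED) and end-systolic (ES) lengths with a
#' raised-cosine waveform: diastole at phase 0, systole at phase 0.5. Axis
#' lengths are *full* axes in micrometres (the convention under which
#' `(1/6)*pi*major*minor^2` is the prolate-spheroid volume).
#'
#' @param frame_rate frames per second (default 150, the acquisition rate of
#'   the bright-field heart recordings this emulates).
#' @param pixel_size micrometres per pixel.
#' @param duration recording length in seconds (default 10).
#' @param beat_period cardiac period in seconds (default 0.4 s, i.e. 150 bpm,
#'   a typical larval heart rate).
#' @param ed_major,ed_minor full end-diastolic major/minor axes, um.
#' @param es_major,es_minor full end-systolic major/minor axes, um; must not
#'   exceed the diastolic axes.
#' @param noise_sd additive Gaussian intensity noise, 16-bit units.
#' @param arrhythmia_jitter_sd per-beat period jitter SD, seconds (0 =
#'   perfectly regular rhythm).
#' @param orientation_deg fixed in-plane rotation of the ellipse, degrees.
#' @param seed integer seed controlling all randomness.
#' @return A validated parameter list of class `heart_sim_params`.
#' @export
heart_sim_params <- function(frame_rate = 150, pixel_size = 1, duration = 10,
                             beat_period = 0.4,
                             ed_major = 100, ed_minor = 60,
                             es_major = 80, es_minor = 48,
                             noise_sd = 0, arrhythmia_jitter_sd = 0,
                             orientation_deg = 20, seed = 1L) {
  p <- list(frame_rate = frame_rate, pixel_size = pixel_size, duration = duration,
            beat_period = beat_period, ed_major = ed_major, ed_minor = ed_minor,
            es_major = es_major, es_minor = es_minor, noise_sd = noise_sd,
            arrhythmia_jitter_sd = arrhythmia_jitter_sd,
            orientation_deg = orientation_deg, seed = as.integer(seed))
  with(p, {
    stopifnot(frame_rate > 0, pixel_size > 0, duration > 0,
              ed_major > 0, ed_minor > 0, es_major > 0, es_minor > 0,
              noise_sd >= 0, arrhythmia_jitter_sd >= 0)
    if (es_major > ed_major || es_minor > ed_minor)
      stop("end-systolic axes must not exceed end-diastolic axes")
    if (beat_period <= 2 / frame_rate)
      stop("beat_period must exceed two frame intervals")
  })
  structure(p, class = "heart_sim_params")
}

# Analytic contractility truths from the prescribed axes (full-axis
# convention; volumes via the prolate-spheroid formula).
#' @noRd
heart_truth_metrics <- function(p) {
  edv <- pi / 6 * p$ed_major * p$ed_minor^2
  esv <- pi / 6 * p$es_major * p$es_minor^2
  area_d <- pi / 4 * p$ed_major * p$ed_minor
  area_s <- pi / 4 * p$es_major * p$es_minor
  list(EDV = edv, ESV = esv, SV = edv - esv, EF = (edv - esv) / edv,
       area_diastole = area_d, area_systole = area_s,
       FAC = (area_d - area_s) / area_d,
       heart_rate = 60 / p$beat_period,
       rhythm_cv = if (p$beat_period > 0) p$arrhythmia_jitter_sd / p$beat_period else 0)
}

# Per-beat start times with optional Gaussian period jitter, covering
# [0, duration].
#' @noRd
beat_schedule <- function(p) {
  starts <- 0
  repeat {
    per <- p$beat_period +
      if (p$arrhythmia_jitter_sd > 0) stats::rnorm(1, 0, p$arrhythmia_jitter_sd) else 0
    per <- max(per, 3 / p$frame_rate)
    starts <- c(starts, starts[length(starts)] + per)
    if (starts[length(starts)] > p$duration) break
  }
  starts
}

#' Simulate a beating-heart video with ground truth
#'
#' Renders a filled bright ellipse on a dark background whose full axes
#' oscillate between the end-diastolic and end-systolic values of `params`
#' with a raised-cosine waveform, samples the true boundary as a per-frame
#' polygon, and computes the contractility truths analytically.
#'
#' @param params a [heart_sim_params()].
#' @param n_vertices vertices per boundary polygon (default 64).
#' @param render if `FALSE`, skip pixel rendering (contours and truth only;
#'   the returned video has zero-filled frames). Useful when only geometry is
#'   needed.
#' @return A list with elements `video` ([video_stack()]), `contours`
#'   ([contour_series()]) and `truth` ([ground_truth()]); the truth carries
#'   `EDV`, `ESV`, `SV`, `EF`, `FAC`, `heart_rate` and a per-frame axis table.
#' @export
make_beating_heart <- function(params, n_vertices = 64L, render = TRUE) {
  stopifnot(inherits(params, "heart_sim_params"))
  p <- params
  if (p$duration < 2 * p$beat_period) stop("too few beats")
  set.seed(p$seed)

  nf <- floor(p$duration * p$frame_rate)
  t <- (seq_len(nf) - 1L) / p$frame_rate
  starts <- beat_schedule(p)
  k <- findInterval(t, starts)
  phase <- (t - starts[k]) / (starts[k + 1L] - starts[k])
  w <- (1 + cos(2 * pi * phase)) / 2          # 1 at diastole, 0 at systole
  major <- p$es_major + (p$ed_major - p$es_major) * w   # um, full axes
  minor <- p$es_minor + (p$ed_minor - p$es_minor) * w

  # image geometry: centre the ellipse with a 25% margin around ED extent
  ed_px <- p$ed_major / p$pixel_size
  nc <- ceiling(ed_px * 1.5); nr <- ceiling(ed_px * 1.5)
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  th <- p$orientation_deg * pi / 180

  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  contours <- vector("list", nf)
  frames <- array(0, c(nr, nc, nf))
  if (render) {
    xg <- matrix(rep(0:(nc - 1), each = nr), nr, nc) - cx
    yg <- matrix(rep(0:(nr - 1), nc), nr, nc) - cy
    xr <- xg * cos(th) + yg * sin(th)
    yr <- -xg * sin(th) + yg * cos(th)
  }
  for (f in seq_len(nf)) {
    a <- major[f] / 2 / p$pixel_size   # semi-axes in px
    b <- minor[f] / 2 / p$pixel_size
    ex <- a * cos(ang) * cos(th) - b * sin(ang) * sin(th) + cx
    ey <- a * cos(ang) * sin(th) + b * sin(ang) * cos(th) + cy
    contours[[f]] <- cbind(x = ex, y = ey)
    if (render) {
      rn <- sqrt((xr / a)^2 + (yr / b)^2)
      # soft 1-px edge via approximate signed distance (1 - rn) * min semi-axis
      img <- pmin(pmax((1 - rn) * min(a, b) + 0.5, 0), 1) * 60000
      if (p$noise_sd > 0)
        img <- img + matrix(stats::rnorm(nr * nc, 0, p$noise_sd), nr, nc)
      frames[, , f] <- pmin(pmax(img, 0), INTENSITY_MAX)
    }
  }

  truth <- ground_truth("heart", heart_truth_metrics(p),
                        per_frame_truth = data.frame(frame = seq_len(nf) - 1L,
                                                     major_um = major,
                                                     minor_um = minor),
                        params = c(unclass(p), list(beat_starts = starts)))
  list(video = video_stack(frames, p$frame_rate, p$pixel_size),
       contours = contour_series(contours, p$frame_rate, p$pixel_size),
       truth = truth)
}

#' Parameters for the pulsatile-flow simulator
#'
#' Blood cells are bright disks advected along a straight horizontal vessel
#' with instantaneous velocity
#' `v(t) = v_dia + (v_sys - v_dia) * (1 + sin(2*pi*t/period)) / 2`,
#' the sine-like waveform arterial flow follows over the cardiac cycle.
#' Cells leaving the field re-enter at the inlet so the cell count stays
#' constant.
#'
#' @param frame_rate frames per second (default 400, the dorsal-aorta
#'   acquisition rate this emulates).
#' @param pixel_size micrometres per pixel.
#' @param n_frames number of frames (default 500).
#' @param vessel_length field of view along the vessel, um.
#' @param v_systolic,v_diastolic peak systolic and trough diastolic
#'   velocities, um/s (defaults 800 and 200, typical larval dorsal-aorta
#'   values).
#' @param cycle_period cardiac period, s.
#' @param n_cells number of cells in the field.
#' @param cell_radius cell radius, px.
#' @param noise_sd additive Gaussian intensity noise, 16-bit units.
#' @param vessel_halfwidth half-width of the band cells occupy, px.
#' @param seed integer seed.
#' @return A validated parameter list of class `flow_sim_params`.
#' @export
flow_sim_params <- function(frame_rate = 400, pixel_size = 1, n_frames = 500L,
                            vessel_length = 200, v_systolic = 800,
                            v_diastolic = 200, cycle_period = 0.4,
                            n_cells = 15L, cell_radius = 3,
                            noise_sd = 0, vessel_halfwidth = 4, seed = 1L) {
  p <- list(frame_rate = frame_rate, pixel_size = pixel_size,
            n_frames = as.integer(n_frames), vessel_length = vessel_length,
            v_systolic = v_systolic, v_diastolic = v_diastolic,
            cycle_period = cycle_period, n_cells = as.integer(n_cells),
            cell_radius = cell_radius, noise_sd = noise_sd,
            vessel_halfwidth = vessel_halfwidth, seed = as.integer(seed))
  with(p, {
    stopifnot(frame_rate > 0, pixel_size > 0, n_frames >= 2, vessel_length > 0,
              n_cells >= 1, cell_radius > 0, noise_sd >= 0)
    if (!(v_systolic >= v_diastolic && v_diastolic >= 0))
      stop("require v_systolic >= v_diastolic >= 0")
    if (cycle_period <= 2 / frame_rate)
      stop("cycle_period must exceed two frame intervals")
    if (v_systolic / frame_rate > vessel_length)
      stop("cell crosses field in one frame")
  })
  structure(p, class = "flow_sim_params")
}

#' @noRd
flow_velocity_waveform <- function(t, p) {
  p$v_diastolic + (p$v_systolic - p$v_diastolic) * (1 + sin(2 * pi * t / p$cycle_period)) / 2
}

#' Simulate a pulsatile blood-flow video with ground truth
#'
#' @param params a [flow_sim_params()].
#' @return A list with elements `video` ([video_stack()]), `roi` (the vessel
#'   centreline as an `n x 2` polyline matrix) and `truth`
#'   ([ground_truth()] with `v_systolic`, `v_diastolic`, `v_max` and the
#'   per-frame velocity table).
#' @export
make_flow_video <- function(params) {
  stopifnot(inherits(params, "flow_sim_params"))
  p <- params
  set.seed(p$seed)

  nc <- ceiling(p$vessel_length / p$pixel_size)
  nr <- 2L * ceiling(p$vessel_halfwidth + 3 * p$cell_radius) + 1L
  cy <- (nr - 1) / 2
  t <- (seq_len(p$n_frames) - 1L) / p$frame_rate
  v <- flow_velocity_waveform(t, p)                       # um/s
  step_px <- v / (p$pixel_size * p$frame_rate)            # px advanced after each frame

  x0 <- stats::runif(p$n_cells, 0, nc)
  y0 <- cy + stats::runif(p$n_cells, -p$vessel_halfwidth, p$vessel_halfwidth)
  amp <- 55000

  frames <- array(0, c(nr, nc, p$n_frames))
  xs <- matrix(0, p$n_frames, p$n_cells)
  x <- x0
  xg <- 0:(nc - 1)
  for (f in seq_len(p$n_frames)) {
    xs[f, ] <- x
    img <- matrix(0, nr, nc)
    for (i in seq_len(p$n_cells)) {
      # soft-edged disk of radius cell_radius at (x[i], y0[i])
      dx2 <- (xg - x[i])^2
      keep <- which(dx2 <= (p$cell_radius + 2)^2)
      if (length(keep)) {
        yg <- 0:(nr - 1)
        d <- sqrt(outer((yg - y0[i])^2, dx2[keep], "+"))
        img[, keep] <- img[, keep] + amp * pmin(pmax(p$cell_radius - d + 0.5, 0), 1)
      }
    }
    if (p$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, p$noise_sd), nr, nc)
    frames[, , f] <- pmin(pmax(img, 0), INTENSITY_MAX)
    x <- (x + step_px[f]) %% nc
  }

  roi <- cbind(x = c(0, nc - 1), y = c(cy, cy))
  truth <- ground_truth("flow",
                        list(v_systolic = p$v_systolic, v_diastolic = p$v_diastolic,
                             v_max = p$v_systolic, cycle_period = p$cycle_period),
                        per_frame_truth = data.frame(frame = seq_len(p$n_frames) - 1L,
                                                     time_s = t, v_um_s = v),
                        params = unclass(p))
  out <- list(video = video_stack(frames, p$frame_rate, p$pixel_size),
              roi = roi, truth = truth)
  out$positions <- data.frame(frame = rep(seq_len(p$n_frames) - 1L, p$n_cells),
                              cell = rep(seq_len(p$n_cells), each = p$n_frames),
                              x = as.vector(xs),
                              y = rep(y0, each = p$n_frames))
  out
}

#' Generate an ideal kymograph streak pattern with known slopes
#'
#' Draws parallel bright streaks (Gaussian cross-section, isotropic 1-px
#' thickness) on a dark background, piecewise-linear in time: within segment
#' `i` every streak advances `slopes[[i]][2]` pixels per frame for
#' `slopes[[i]][1]` frames. Rows are frames (time), columns distance.
#'
#' @param slopes list of `c(frame_span, px_per_frame)` pairs; all
#'   `px_per_frame` must be positive.
#' @param pixel_size micrometres per pixel.
#' @param frame_rate frames per second.
#' @param width kymograph width in pixels (distance axis).
#' @param spacing distance between adjacent streaks, px.
#' @param streak_sd Gaussian cross-section SD perpendicular to the streak, px.
#' @return A list with `kymo` (a [kymograph()]) and `truth`
#'   ([ground_truth()]; `per_frame_truth` holds the true velocity
#'   `px_per_frame * pixel_size * frame_rate` for every frame).
#' @export
make_kymograph_pattern <- function(slopes, pixel_size = 1, frame_rate = 400,
                                   width = 200L, spacing = 16, streak_sd = 1) {
  stopifnot(length(slopes) >= 1)
  slopes <- lapply(slopes, function(s) {
    stopifnot(length(s) == 2, s[1] >= 1, s[2] > 0)
    c(span = as.integer(s[1]), px_per_frame = as.numeric(s[2]))
  })
  nfr <- sum(vapply(slopes, `[`, 1, 1))
  img <- matrix(0, nfr, width)
  v_true <- numeric(nfr)

  offset0 <- 0   # phase of the streak comb, advances continuously across segments
  row <- 1L
  for (s in slopes) {
    span <- s[1]; m_inv <- s[2]          # px advanced per frame
    sd_eff <- streak_sd * sqrt(1 + m_inv^2)  # horizontal SD giving isotropic thickness
    for (j in seq_len(span)) {
      xc <- (offset0 + (j - 1) * m_inv) %% spacing
      centers <- seq(xc - spacing, width + spacing, by = spacing)
      x <- 0:(width - 1)
      prof <- rowSums(exp(-outer(x, centers, "-")^2 / (2 * sd_eff^2)))
      img[row, ] <- prof
      v_true[row] <- m_inv * pixel_size * frame_rate
      row <- row + 1L
    }
    offset0 <- (offset0 + span * m_inv) %% spacing
  }
  img <- img / max(img) * 60000
  k <- kymograph(img, pixel_size = pixel_size, frame_rate = frame_rate)
  truth <- ground_truth("kymo",
                        list(v_levels = unique(v_true)),
                        per_frame_truth = data.frame(frame = seq_len(nfr) - 1L,
                                                     v_um_s = v_true))
  list(kymo = k, truth = truth)
}

#' Generate a synthetic membrane intensity profile with Gaussian foci
#'
#' A flat baseline plus `n_foci` Gaussian bumps peaking at `focus_height`,
#' placed at random centres separated by at least `6 * focus_sd` samples.
#' This emulates the punctate fluorescence signal seen along cardiomyocyte
#' membranes, where the peak/trough intensity ratio quantifies how focal
#' (vs diffuse) the protein localisation is.
#'
#' @param n_points profile length, samples.
#' @param baseline baseline intensity level (>= 0).
#' @param focus_height peak intensity at a focus; must exceed `baseline`.
#' @param n_foci number of foci (0 gives a flat profile).
#' @param focus_sd Gaussian SD of a focus, samples.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param seed integer seed.
#' @return A list with `profile` (data frame: `position`, `intensity`) and
#'   `truth` ([ground_truth()] with `foci_ratio = focus_height / baseline`
#'   for the noiseless case, or 1 when `n_foci == 0`).
#' @export
make_membrane_profile <- function(n_points = 400L, baseline = 0.2,
                                  focus_height = 1.0, n_foci = 4L,
                                  focus_sd = 5, noise_sd = 0, seed = 1L) {
  stopifnot(n_points >= 10, baseline >= 0, focus_height > baseline,
            n_foci >= 0, focus_sd > 0, noise_sd >= 0)
  set.seed(as.integer(seed))
  min_sep <- 6 * focus_sd
  margin <- 3 * focus_sd
  centers <- numeric(0)
  if (n_foci > 0) {
    if ((n_points - 2 * margin) < (n_foci - 1) * min_sep)
      stop("foci cannot be placed without overlap")
    for (tries in seq_len(2000L)) {
      cand <- sort(stats::runif(n_foci, margin, n_points - 1 - margin))
      if (n_foci == 1 || min(diff(cand)) >= min_sep) { centers <- cand; break }
    }
    if (!length(centers)) stop("foci cannot be placed without overlap")
  }
  pos <- 0:(n_points - 1)
  y <- rep(baseline, n_points)
  for (c0 in centers)
    y <- y + (focus_height - baseline) * exp(-(pos - c0)^2 / (2 * focus_sd^2))
  if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
  ratio <- if (n_foci > 0) focus_height / baseline else 1  # Inf when baseline 0
  truth <- ground_truth("profile",
                        list(foci_ratio = ratio, n_foci = n_foci,
                             baseline = baseline, focus_height = focus_height),
                        per_frame_truth = NULL,
                        params = list(n_points = n_points, focus_sd = focus_sd,
                                      noise_sd = noise_sd, seed = seed,
                                      centers = centers))
  list(profile = data.frame(position = pos, intensity = y), truth = truth)
}
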