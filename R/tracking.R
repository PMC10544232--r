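# Single-cell blood-flow velocimetry: blob detection, greedy
# nearest-neighbour linking, and trajectory kinematics.
#
# Greedy per-transition linking (not global optimisation) is adequate for
# the sparse, quasi-one-dimensional dorsal-aorta scene this targets; tests
# verify it against exhaustive optimal assignment on small instances.

#' Detect bright blob centroids in a frame
#'
#' Scale-normalised Laplacian-of-Gaussian detection over a small sigma
#' ladder: local maxima of the negated LoG response across space and scale
#' above `threshold` become detections, and each is refined to sub-pixel
#' precision by the intensity-weighted centroid of a 5x5 patch of the raw
#' frame.
#'
#' @param frame numeric matrix (grayscale frame).
#' @param min_sigma,max_sigma blob scale range in px (blob radius is about
#'   `sigma * sqrt(2)`).
#' @param n_sigma number of scales in the ladder.
#' @param threshold detection threshold on the scale-normalised LoG response
#'   of the frame rescaled to `[0, 1]`.
#' @return `n x 2` matrix of centroids (columns x, y; 0-based, sub-pixel);
#'   zero rows when nothing is detected.
#' @export
detect_cells <- function(frame, min_sigma = 1.5, max_sigma = 4, n_sigma = 4L,
                         threshold = 0.03) {
  stopifnot(is.matrix(frame), min_sigma > 0, max_sigma >= min_sigma)
  rng <- diff(range(frame))
  if (rng <= 0) return(cbind(x = numeric(0), y = numeric(0)))
  img <- (frame - min(frame)) / rng
  sigmas <- if (n_sigma == 1L) min_sigma else
    exp(seq(log(min_sigma), log(max_sigma), length.out = n_sigma))
  resp <- array(0, c(dim(img), length(sigmas)))
  for (i in seq_along(sigmas)) {
    s <- sigmas[i]
    g0 <- gauss_kernel(s, 0L); g2 <- gauss_kernel(s, 2L)
    log_img <- sep_filter(img, g2, g0) + sep_filter(img, g0, g2)
    resp[, , i] <- -s^2 * log_img   # bright blobs -> positive
  }
  nr <- nrow(img); nc <- ncol(img)
  peaks <- NULL
  for (i in seq_along(sigmas)) {
    R <- resp[, , i]
    mask <- local_max_2d(R) & R > threshold
    if (i > 1) mask <- mask & R >= resp[, , i - 1]
    if (i < length(sigmas)) mask <- mask & R >= resp[, , i + 1]
    cand <- which(mask, arr.ind = TRUE)
    if (nrow(cand))
      peaks <- rbind(peaks, cbind(cand, sigmas[i], R[cand]))
  }
  if (is.null(peaks) || !nrow(peaks)) return(cbind(x = numeric(0), y = numeric(0)))

  # merge duplicates across scales / plateaus: keep strongest within 2 px
  ord <- order(peaks[, 4], decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 4)
  for (j in seq_len(nrow(peaks))) {
    p <- peaks[j, ]
    if (!nrow(kept) ||
        all((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2 > 4))
      kept <- rbind(kept, p)
  }

  # sub-pixel refinement: intensity-weighted centroid of a 5x5 raw patch
  cent <- t(apply(kept, 1, function(p) {
    r <- p[1]; c <- p[2]
    rr <- max(1, r - 2):min(nr, r + 2)
    cc <- max(1, c - 2):min(nc, c + 2)
    patch <- img[rr, cc, drop = FALSE]
    patch <- patch - min(patch)
    w <- sum(patch)
    if (w <= 0) return(c(c - 1, r - 1))
    cx <- sum(patch %*% (cc - 1)) / w
    cy <- sum((rr - 1) %*% patch) / w
    c(cx, cy)
  }))
  colnames(cent) <- c("x", "y")
  cent[order(cent[, 1]), , drop = FALSE]
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour assignment per frame transition: candidate
#' matches between open track ends and new detections are sorted by
#' Euclidean distance and accepted in order, rejecting matches beyond
#' `max_disp` (per frame of gap). Tracks missing a detection are kept open
#' for up to `max_gap` frames before being closed.
#'
#' @param detections list (one element per frame) of `n x 2` centroid
#'   matrices as returned by [detect_cells()].
#' @param max_disp maximum displacement per frame, px.
#' @param max_gap maximum number of consecutive frames a track may miss.
#' @return A data frame with columns `track`, `frame` (0-based), `x`, `y`.
#' @export
link_tracks <- function(detections, max_disp = 5, max_gap = 0L) {
  stopifnot(is.list(detections), length(detections) >= 2, max_disp > 0,
            max_gap >= 0)
  open_id <- integer(0); open_xy <- matrix(numeric(0), 0, 2)
  open_last <- integer(0)          # frame index of last detection per open track
  next_id <- 1L
  rows <- vector("list", length(detections))
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    det <- if (is.null(det) || !nrow(det)) matrix(numeric(0), 0, 2) else
      as.matrix(det)[, 1:2, drop = FALSE]
    assigned_det <- rep(FALSE, nrow(det))
    assigned_trk <- rep(FALSE, length(open_id))
    if (nrow(det) && length(open_id)) {
      gaps <- f - open_last                      # >= 1
      dmat <- sqrt(outer(open_xy[, 1], det[, 1], "-")^2 +
                   outer(open_xy[, 2], det[, 2], "-")^2)
      lim <- max_disp * gaps                      # allowance grows with gap
      cand <- which(dmat <= lim, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        for (j in seq_len(nrow(cand))) {
          ti <- cand[j, 1]; di <- cand[j, 2]
          if (assigned_trk[ti] || assigned_det[di]) next
          assigned_trk[ti] <- TRUE; assigned_det[di] <- TRUE
          open_xy[ti, ] <- det[di, ]
          open_last[ti] <- f
          rows[[f]] <- rbind(rows[[f]],
                             data.frame(track = open_id[ti], frame = f - 1L,
                                        x = det[di, 1], y = det[di, 2]))
        }
      }
    }
    # unmatched detections start new tracks
    for (di in which(!assigned_det)) {
      rows[[f]] <- rbind(rows[[f]],
                         data.frame(track = next_id, frame = f - 1L,
                                    x = det[di, 1], y = det[di, 2]))
      open_id <- c(open_id, next_id)
      open_xy <- rbind(open_xy, det[di, , drop = FALSE])
      open_last <- c(open_last, f)
      next_id <- next_id + 1L
    }
    # close tracks that exceeded the gap allowance
    alive <- (f - open_last) <= max_gap
    open_id <- open_id[alive]
    open_xy <- open_xy[alive, , drop = FALSE]
    open_last <- open_last[alive]
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(track = integer(0), frame = integer(0),
                                      x = numeric(0), y = numeric(0))
  out[order(out$track, out$frame), ]
}

#' Velocity, acceleration and maximum velocity of a trajectory
#'
#' Speed per sample by central differences of position times
#' `pixel_size * frame_rate`; acceleration by central differences of speed.
#' The maximum velocity `v_max` is the largest per-beat peak of the smoothed
#' speed trace, where each beat's peak is guarded as the 95th percentile of
#' the raw speeds within that beat window so that single-sample localisation
#' spikes cannot dominate. When no beat structure is detectable the guard
#' falls back to the 95th percentile of all speeds.
#'
#' @param traj data frame with columns `frame`, `x`, `y` (one track) with at
#'   least 3 samples on consecutive frames.
#' @param pixel_size micrometres per pixel.
#' @param frame_rate frames per second.
#' @return List with `trace` (a `velocity_trace` data frame: `time`,
#'   `velocity`, `acceleration`) and `v_max` (um/s).
#' @export
kinematics <- function(traj, pixel_size = 1, frame_rate = 1) {
  stopifnot(all(c("frame", "x", "y") %in% names(traj)))
  traj <- traj[order(traj$frame), ]
  n <- nrow(traj)
  if (n < 3) stop("trajectory too short: need at least 3 samples")
  ip <- pmin(seq_len(n) + 1L, n); im <- pmax(seq_len(n) - 1L, 1L)
  dt <- (traj$frame[ip] - traj$frame[im]) / frame_rate
  vx <- (traj$x[ip] - traj$x[im]) * pixel_size / dt
  vy <- (traj$y[ip] - traj$y[im]) * pixel_size / dt
  speed <- sqrt(vx^2 + vy^2)
  acc <- (speed[ip] - speed[im]) / dt
  trace <- data.frame(time = traj$frame / frame_rate, velocity = speed,
                      acceleration = acc)
  class(trace) <- c("velocity_trace", class(trace))
  list(trace = trace, v_max = v_max_from_speeds(speed, frame_rate))
}

# Per-beat peak extraction with a 95th-percentile spike guard. The quantile
# is taken on the lightly smoothed trace: localisation jitter and transient
# detection doublets otherwise dominate the within-beat maximum.
#' @noRd
v_max_from_speeds <- function(speed, frame_rate, smooth_s = 0.02) {
  if (!length(speed)) return(NA_real_)
  sm <- moving_average(speed, max(3, round(smooth_s * frame_rate)))
  pk <- find_peaks(sm, prominence = 0.2 * max(diff(range(sm)), .Machine$double.eps))
  if (length(pk) < 1) return(stats::quantile(sm, 0.95, names = FALSE))
  # beat windows: between midpoints of successive peaks
  bounds <- c(1, floor((pk[-1] + pk[-length(pk)]) / 2), length(speed))
  peaks <- vapply(seq_along(pk), function(i) {
    w <- sm[bounds[i]:bounds[i + 1]]
    stats::quantile(w, 0.95, names = FALSE)
  }, numeric(1))
  max(peaks)
}

#' Track a video end-to-end and summarise kinematics
#'
#' Runs [detect_cells()] on every frame, [link_tracks()], and pools
#' [kinematics()] over all sufficiently long trajectories. `v_max` is the
#' per-recording maximum: the per-beat-peak guard applied to the per-frame
#' mean speed across cells.
#'
#' @param video a [video_stack()].
#' @param max_disp,max_gap linking parameters (see [link_tracks()]).
#' @param min_track_len discard shorter trajectories.
#' @param ... passed to [detect_cells()].
#' @return List with `tracks` (data frame), `per_frame` (time, mean speed
#'   across cells), and `v_max` (um/s).
#' @export
track_video <- function(video, max_disp = 6, max_gap = 1L, min_track_len = 9L, ...) {
  stopifnot(inherits(video, "video_stack"))
  dets <- lapply(seq_len(n_frames(video)),
                 function(f) detect_cells(video$frames[, , f], ...))
  tracks <- link_tracks(dets, max_disp = max_disp, max_gap = max_gap)
  if (!nrow(tracks)) stop("no trajectories found")
  keep <- names(which(table(tracks$track) >= min_track_len))
  tracks <- tracks[tracks$track %in% as.integer(keep), ]
  if (!nrow(tracks)) stop("no trajectories of sufficient length")

  speeds <- lapply(split(tracks, tracks$track), function(tr) {
    kin <- kinematics(tr, video$pixel_size, video$frame_rate)
    data.frame(frame = tr$frame, speed = kin$trace$velocity)
  })
  all_speed <- do.call(rbind, speeds)
  per_frame <- stats::aggregate(speed ~ frame, all_speed, mean)
  per_frame$time <- per_frame$frame / video$frame_rate
  v_max <- v_max_from_speeds(per_frame$speed, video$frame_rate)
  list(tracks = tracks, per_frame = per_frame, v_max = v_max)
}

#' Percent change of a test value relative to a reference
#'
#' `100 * (reference - test) / reference`: positive values are reductions
#' (the convention used to report, e.g., a drop in maximum blood-cell
#' velocity relative to sibling controls).
#'
#' @param reference reference value (> 0).
#' @param test test value.
#' @return Percent change (positive = reduction).
#' @export
percent_change <- function(reference, test) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (reference - test) / reference
}
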