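# Calibrated containers and plain-file I/O (multi-page TIFF, ROI/contour CSV,
# ground-truth JSON). Intensities are kept in 16-bit units [0, 65535].

INTENSITY_MAX <- 65535

#' Calibrated grayscale video stack
#'
#' A `video_stack` wraps a 3-D numeric array `[row, col, frame]` of 16-bit
#' grayscale intensities together with its temporal and spatial calibration.
#'
#' @param frames numeric array `[row, col, frame]`, intensities in
#'   `[0, 65535]`; a single matrix is promoted to one frame.
#' @param frame_rate acquisition rate, frames per second.
#' @param pixel_size physical pixel pitch, micrometres per pixel.
#' @return An object of class `video_stack`.
#' @export
video_stack <- function(frames, frame_rate, pixel_size) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, frame_rate > 0, pixel_size > 0)
  structure(list(frames = frames, frame_rate = frame_rate, pixel_size = pixel_size),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_stack> %d x %d px, %d frames @ %g fps, %g um/px\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size))
  invisible(x)
}

#' @rdname video_stack
#' @param x object to test or print.
#' @param ... unused.
#' @export
n_frames <- function(x) dim(x$frames)[3]

#' Per-frame ventricle outlines with calibration
#'
#' @param contours list with one `n x 2` matrix per frame, columns `x`, `y`
#'   in 0-based pixel coordinates.
#' @param frame_rate frames per second.
#' @param pixel_size micrometres per pixel.
#' @return An object of class `contour_series`.
#' @export
contour_series <- function(contours, frame_rate, pixel_size) {
  stopifnot(is.list(contours), length(contours) >= 1,
            all(vapply(contours, nrow, 1L) >= 3L),
            frame_rate > 0, pixel_size > 0)
  structure(list(contours = contours, frame_rate = frame_rate, pixel_size = pixel_size),
            class = "contour_series")
}

#' @export
print.contour_series <- function(x, ...) {
  cat(sprintf("<contour_series> %d frames @ %g fps, %g um/px\n",
              length(x$contours), x$frame_rate, x$pixel_size))
  invisible(x)
}

#' Ground-truth sidecar for a synthetic dataset
#'
#' Records the simulator parameters and every metric a downstream analysis
#' can estimate from the matching synthetic input, enabling
#' parameter-recovery tests.
#'
#' @param kind one of `"heart"`, `"flow"`, `"kymo"`, `"profile"`.
#' @param true_metrics named list of scalar truths (e.g. `EF`, `heart_rate`,
#'   `v_systolic`, `foci_ratio`).
#' @param per_frame_truth optional data frame of per-frame truths.
#' @param params the simulation parameter list that produced the dataset.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(kind, true_metrics, per_frame_truth = NULL, params = NULL) {
  kind <- match.arg(kind, c("heart", "flow", "kymo", "profile"))
  structure(list(kind = kind, true_metrics = true_metrics,
                 per_frame_truth = per_frame_truth, params = params),
            class = "ground_truth")
}

# --- TIFF -----------------------------------------------------------------

#' Read / write calibrated video as multi-page 16-bit TIFF
#'
#' Calibration is not stored in the TIFF; supply it on read.
#'
#' @param video a [video_stack()].
#' @param path file path.
#' @return `write_video_tiff()` returns `path` invisibly; `read_video_tiff()`
#'   returns a [video_stack()].
#' @export
write_video_tiff <- function(video, path) {
  stopifnot(inherits(video, "video_stack"))
  pages <- lapply(seq_len(n_frames(video)), function(k)
    pmin(pmax(video$frames[, , k] / INTENSITY_MAX, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_video_tiff
#' @param frame_rate,pixel_size calibration to attach on read.
#' @export
read_video_tiff <- function(path, frame_rate, pixel_size) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * INTENSITY_MAX
  video_stack(arr, frame_rate, pixel_size)
}

# --- CSV ------------------------------------------------------------------

#' Read / write contour series as CSV
#'
#' Long format with columns `frame` (0-based), `vertex` (0-based), `x`, `y`
#' (0-based pixel coordinates).
#'
#' @param cs a [contour_series()].
#' @param path file path.
#' @export
write_contours_csv <- function(cs, path) {
  stopifnot(inherits(cs, "contour_series"))
  rows <- do.call(rbind, lapply(seq_along(cs$contours), function(f) {
    m <- cs$contours[[f]]
    data.frame(frame = f - 1L, vertex = seq_len(nrow(m)) - 1L,
               x = m[, 1], y = m[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @param frame_rate,pixel_size calibration to attach on read.
#' @export
read_contours_csv <- function(path, frame_rate, pixel_size) {
  d <- utils::read.csv(path)
  stopifnot(all(c("frame", "vertex", "x", "y") %in% names(d)))
  frames <- sort(unique(d$frame))
  contours <- lapply(frames, function(f) {
    sub <- d[d$frame == f, ]
    sub <- sub[order(sub$vertex), ]
    cbind(x = sub$x, y = sub$y)
  })
  contour_series(contours, frame_rate, pixel_size)
}

#' Read / write a polyline ROI as CSV (columns `x`, `y`)
#'
#' @param roi `n x 2` matrix of 0-based pixel coordinates.
#' @param path file path.
#' @export
write_roi_csv <- function(roi, path) {
  utils::write.csv(data.frame(x = roi[, 1], y = roi[, 2]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("x", "y") %in% names(d)))
  cbind(x = d$x, y = d$y)
}

# --- JSON -----------------------------------------------------------------

#' Write / read a ground-truth sidecar as JSON
#'
#' @param gt a [ground_truth()].
#' @param path file path, conventionally `"<stem>.truth.json"`.
#' @export
write_truth_json <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(obj$kind, as.list(obj$true_metrics),
               per_frame_truth = if (!is.null(obj$per_frame_truth))
                 as.data.frame(obj$per_frame_truth) else NULL,
               params = obj$params)
}
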