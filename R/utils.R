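# Internal numerical helpers shared across modules.
# Image convention throughout the package: matrices are [row, col] with
# row = y and col = x; pixel (r, c) sits at continuous coordinate
# (x = c - 1, y = r - 1), i.e. 0-based pixel-centre coordinates.

#' @noRd
odd_window <- function(w) {
  w <- max(1L, as.integer(round(w)))
  if (w %% 2L == 0L) w + 1L else w
}

# Centered moving average with edge replication; width coerced to odd.
#' @noRd
moving_average <- function(x, width) {
  width <- odd_window(width)
  if (width <= 1L || length(x) < 2L) return(x)
  r <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[(r + 1L):(r + length(x))]
}

# Local maxima of x with topographic prominence >= prominence.
# Plateaus count once (their first index). Returns integer indices.
#' @noRd
find_peaks <- function(x, prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(integer(0))
  keep <- vapply(cand, function(p) peak_prominence(x, p) >= prominence, logical(1))
  cand[keep]
}

# Prominence of peak at index p: height above the higher of the two key cols
# (lowest points on the walk towards the nearest higher terrain on each side,
# or towards the signal edge).
#' @noRd
peak_prominence <- function(x, p) {
  h <- x[p]
  left <- x[seq_len(p - 1L)]
  right <- x[seq.int(p + 1L, length(x))]
  col_left <- if (length(left)) {
    higher <- which(left > h)
    if (length(higher)) min(left[(max(higher) + 1L):length(left)]) else min(left)
  } else h
  col_right <- if (length(right)) {
    higher <- which(right > h)
    if (length(higher)) min(right[seq_len(min(higher) - 1L)]) else min(right)
  } else h
  h - max(col_left, col_right)
}

#' @noRd
find_troughs <- function(x, prominence = 0) find_peaks(-x, prominence)

# Bilinear interpolation of img at 0-based (x, y); out-of-range queries clamp
# to the border pixel so callers can validate bounds themselves.
#' @noRd
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x0 + 2)]
  i10 <- img[cbind(y0 + 2, x0 + 1)]
  i11 <- img[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# --- separable filtering --------------------------------------------------

#' @noRd
gauss_kernel <- function(sigma, order = 0L, radius = ceiling(4 * sigma)) {
  x <- seq.int(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = { k <- -x / sigma^2 * g; k - mean(k) },
    "2" = { k <- (x^2 - sigma^2) / sigma^4 * g; k - mean(k) },
    stop("unsupported derivative order")
  )
}

# Correlate each column of M with kernel k (edge replication), via shifted
# whole-matrix accumulation — faster than stats::filter for many small calls.
#' @noRd
filter_cols <- function(M, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(M)
  Mp <- M[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
  out <- matrix(0, n, ncol(M))
  for (j in seq_along(k))
    if (k[j] != 0) out <- out + k[j] * Mp[j:(j + n - 1L), , drop = FALSE]
  out
}

# 8-neighbour local-maximum mask (ties count as maxima; border excluded).
#' @noRd
local_max_2d <- function(R) {
  nr <- nrow(R); nc <- ncol(R)
  M <- matrix(FALSE, nr, nc)
  if (nr < 3 || nc < 3) return(M)
  Ri <- R[2:(nr - 1), 2:(nc - 1)]
  M[2:(nr - 1), 2:(nc - 1)] <-
    Ri >= R[1:(nr - 2), 2:(nc - 1)] & Ri >= R[3:nr, 2:(nc - 1)] &
    Ri >= R[2:(nr - 1), 1:(nc - 2)] & Ri >= R[2:(nr - 1), 3:nc] &
    Ri >= R[1:(nr - 2), 1:(nc - 2)] & Ri >= R[1:(nr - 2), 3:nc] &
    Ri >= R[3:nr, 1:(nc - 2)] & Ri >= R[3:nr, 3:nc]
  M
}

#' @noRd
filter_rows <- function(M, k) t(filter_cols(t(M), k))

# Separable Gaussian (or Gaussian-derivative) filter; k_row acts along rows
# (the y/time axis), k_col along columns (the x/distance axis).
#' @noRd
sep_filter <- function(M, k_row, k_col) filter_rows(filter_cols(M, k_row), k_col)

# Resample a polyline (n x 2 matrix, columns x, y) at arclength steps of
# `step` pixels. Returns matrix of sample points including both endpoints.
#' @noRd
resample_polyline <- function(poly, step = 1) {
  stopifnot(ncol(poly) == 2, nrow(poly) >= 2)
  seg <- diff(poly)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  if (total <= 0) stop("polyline has zero length")
  s <- seq(0, total, by = step)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(seg))
  frac <- (s - cum[idx]) / pmax(len[idx], .Machine$double.eps)
  poly[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
}

# Unit normals of a resampled polyline (one per sample, from local tangent).
#' @noRd
polyline_normals <- function(pts) {
  n <- nrow(pts)
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  tang <- pts[ip, , drop = FALSE] - pts[im, , drop = FALSE]
  nrm <- sqrt(rowSums(tang^2))
  tang <- tang / pmax(nrm, .Machine$double.eps)
  cbind(-tang[, 2], tang[, 1])
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
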