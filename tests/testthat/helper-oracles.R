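# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: alignment scores come from exhaustive path
# enumeration, assignments from exhaustive permutation search, and volumes
# from numerical quadrature.

# Exact points on an ellipse with full axes (major, minor), rotation theta,
# centre (cx, cy).
ellipse_points <- function(n, major, minor, theta = 0, cx = 0, cy = 0) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  a <- major / 2; b <- minor / 2
  cbind(x = a * cos(ang) * cos(theta) - b * sin(ang) * sin(theta) + cx,
        y = a * cos(ang) * sin(theta) + b * sin(ang) * cos(theta) + cy)
}

# Brute-force global affine-gap alignment score by enumerating every
# monotone alignment path. Gap run of length L costs open + L * ext
# (the same convention the package documents). Only feasible for short
# sequences (Delannoy-number growth).
brute_force_align_score <- function(a, b, mat, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, state, score) {
    # state: 0 none/diagonal, 1 gap in b (up), 2 gap in a (left)
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, 0, score + mat[ca[i], cb[j]])
    if (i <= length(ca))
      rec(i + 1, j, 1, score - ext - if (state == 1) 0 else open)
    if (j <= length(cb))
      rec(i, j + 1, 2, score - ext - if (state == 2) 0 else open)
  }
  rec(1, 1, 0, 0)
  best
}

# Exhaustive optimal one-to-one assignment between two point sets (n <= 4):
# minimises total Euclidean distance, forbidding matches beyond max_disp.
# Returns the matched index pairs, ordered by the first set.
brute_force_assignment <- function(p1, p2, max_disp) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  d <- sqrt(outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  # maximise the number of matches first, then minimise total distance
  for (k in rev(seq_len(min(n1, n2)))) {
    best <- NULL; best_cost <- Inf
    for (s1 in utils::combn(n1, k, simplify = FALSE))
      for (s2 in utils::combn(n2, k, simplify = FALSE))
        for (p in perms(s2)) {
          costs <- d[cbind(s1, p)]
          if (any(costs > max_disp)) next
          tot <- sum(costs)
          if (tot < best_cost) { best_cost <- tot; best <- cbind(from = s1, to = p) }
        }
    if (!is.null(best)) return(best[order(best[, 1]), , drop = FALSE])
  }
  cbind(from = integer(0), to = integer(0))
}

# Prolate-spheroid volume by numerical quadrature of circular cross-sections
# along the major axis.
quadrature_spheroid_volume <- function(major, minor) {
  L <- major; D <- minor
  stats::integrate(function(z) pi * (D / 2)^2 * (1 - (2 * z / L)^2),
                   -L / 2, L / 2, rel.tol = 1e-10)$value
}

# Synthetic heart parameterised by ejection fraction: ES axes are a uniform
# scaling s of the ED axes with EF = 1 - s^3.
heart_params_for_ef <- function(ef, seed, duration = 2, noise_sd = 0,
                                jitter = 0) {
  s <- (1 - ef)^(1 / 3)
  heart_sim_params(duration = duration, noise_sd = noise_sd,
                   arrhythmia_jitter_sd = jitter,
                   ed_major = 100, ed_minor = 60,
                   es_major = 100 * s, es_minor = 60 * s, seed = seed)
}
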