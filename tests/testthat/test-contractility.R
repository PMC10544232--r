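test_that("ellipse fitting recovers exact axes and rejects degenerate input", {
  pts <- ellipse_points(64, 100, 60, theta = 0.4, cx = 40, cy = 55)
  e <- fit_ellipse(pts, pixel_size = 1)
  expect_equal(e$major_axis, 100, tolerance = 1e-9)
  expect_equal(e$minor_axis, 60, tolerance = 1e-9)
  expect_equal(unname(e$center), c(40, 55), tolerance = 1e-9)

  # circle: both axes equal the diameter
  circ <- ellipse_points(32, 20, 20, cx = 5, cy = 5)
  ec <- fit_ellipse(circ)
  expect_equal(ec$major_axis, 20, tolerance = 1e-9)
  expect_equal(ec$minor_axis, 20, tolerance = 1e-9)

  # calibration scales axes
  e2 <- fit_ellipse(pts, pixel_size = 0.5)
  expect_equal(e2$major_axis, 50, tolerance = 1e-9)

  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10) + 3)), "degenerate")
  expect_error(fit_ellipse(pts[1:4, ]), "degenerate")
})

test_that("area and volume implement the printed formulas with their identities", {
  e <- list(major_axis = 100, minor_axis = 60)
  expect_equal(ellipse_area(e), 1500 * pi)
  expect_equal(ellipse_volume(e), 60000 * pi)
  # prolate-spheroid identity and sphere limit
  expect_equal(ellipse_volume(e), 4 / 3 * pi * 50 * 30^2, tolerance = 1e-13)
  d <- 7.3
  expect_equal(ellipse_volume(list(major_axis = d, minor_axis = d)),
               pi * d^3 / 6, tolerance = 1e-13)
  # unit circle area
  expect_equal(ellipse_area(list(major_axis = 2, minor_axis = 2)), pi)
  # homogeneity: k scaling -> k^2 area, k^3 volume
  for (k in c(0.5, 2, 3.7)) {
    ek <- list(major_axis = 100 * k, minor_axis = 60 * k)
    expect_equal(ellipse_area(ek), k^2 * ellipse_area(e), tolerance = 1e-12)
    expect_equal(ellipse_volume(ek), k^3 * ellipse_volume(e), tolerance = 1e-12)
  }
  # quadrature oracle
  expect_equal(ellipse_volume(e), quadrature_spheroid_volume(100, 60),
               tolerance = 1e-8)
})

test_that("beat detection finds regular periods and rejects beatless traces", {
  t <- 0:599
  area <- 1000 + 200 * cos(2 * pi * t / 60)   # period 60 frames at 150 fps
  b <- detect_beats(area, 150)
  expect_true(all(abs(b$beat_intervals - 0.4) < 1e-9))
  expect_true(length(b$ed_frames) >= 2)
  # ED maxima pair with following ES minima
  expect_true(all(b$es_frames > b$ed_frames, na.rm = TRUE))
  expect_error(detect_beats(seq(1, 2, length.out = 100), 150), "insufficient beats")
  expect_error(detect_beats(rep(1, 100), 150), "insufficient beats|flat")
})

test_that("beat metrics recover EF and FAC from noiseless synthetic contours", {
  p <- heart_sim_params(duration = 2, ed_major = 100, ed_minor = 60,
                        es_major = 80, es_minor = 48, seed = 1)
  h <- make_beating_heart(p, render = FALSE)
  bm <- beat_metrics(h$contours)
  expect_equal(bm$ef, 0.488, tolerance = 1e-3)
  expect_equal(bm$fac, 0.36, tolerance = 1e-3)
  expect_equal(bm$heart_rate, 150, tolerance = 1e-6)
  expect_equal(bm$rhythm_cv, 0)
  expect_false(bm$irregular)
  expect_equal(bm$sv, bm$edv - bm$esv, tolerance = 1e-9)
  # single-beat mode agrees on this regular heart
  bm1 <- beat_metrics(h$contours, single_beat = TRUE)
  expect_equal(bm1$ef, bm$ef, tolerance = 1e-6)
})

test_that("EF/FAC from a uniform axis scaling satisfy EF = 1 - s^3, FAC = 1 - s^2", {
  for (s in c(0.95, 0.8, 0.6)) {
    p <- heart_sim_params(duration = 2, ed_major = 90, ed_minor = 50,
                          es_major = 90 * s, es_minor = 50 * s, seed = 2)
    h <- make_beating_heart(p, render = FALSE)
    bm <- beat_metrics(h$contours)
    expect_equal(bm$ef, 1 - s^3, tolerance = 2e-3)
    expect_equal(bm$fac, 1 - s^2, tolerance = 2e-3)
    tm <- h$truth$true_metrics
    expect_equal(tm$EF, 1 - s^3, tolerance = 1e-12)   # exact on the truth side
    expect_equal(tm$FAC, 1 - s^2, tolerance = 1e-12)
  }
})

test_that("rhythm irregularity is recovered from jittered beats", {
  p <- heart_sim_params(duration = 10, arrhythmia_jitter_sd = 0.04, seed = 7)
  h <- make_beating_heart(p, render = FALSE)
  bm <- beat_metrics(h$contours)
  expect_lt(abs(bm$rhythm_cv - 0.1), 0.03)
  # CV 0.1 sits at the default irregularity threshold; a calmer heart is regular
  p2 <- heart_sim_params(duration = 10, arrhythmia_jitter_sd = 0, seed = 7)
  bm2 <- beat_metrics(make_beating_heart(p2, render = FALSE)$contours)
  expect_false(bm2$irregular)
})

test_that("contours extracted from rendered masks support metric recovery", {
  p <- heart_sim_params(duration = 2, noise_sd = 0, seed = 9)
  h <- make_beating_heart(p)
  cs <- contours_from_masks(h$video)
  bm <- beat_metrics(cs)
  expect_lt(abs(bm$ef - h$truth$true_metrics$EF), 0.02)
  expect_lt(abs(bm$fac - h$truth$true_metrics$FAC), 0.02)
})
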