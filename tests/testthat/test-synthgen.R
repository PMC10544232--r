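test_that("beating-heart ground truth satisfies the contractility identities", {
  p <- heart_sim_params(duration = 2, ed_major = 100, ed_minor = 60,
                        es_major = 80, es_minor = 48, seed = 1)
  h <- make_beating_heart(p, render = FALSE)
  tm <- h$truth$true_metrics
  expect_equal(tm$EF, 1 - (80 * 48^2) / (100 * 60^2))  # 0.488
  expect_equal(tm$EF, 0.488, tolerance = 1e-12)
  expect_equal(tm$SV, tm$EDV - tm$ESV)
  expect_equal(tm$EF, 1 - tm$ESV / tm$EDV)
  expect_equal(tm$FAC, 1 - tm$area_systole / tm$area_diastole)
  expect_equal(tm$heart_rate, 150)  # 60 / 0.4 s

  # no contraction: ED == ES
  p0 <- heart_sim_params(duration = 2, es_major = 100, es_minor = 60,
                         ed_major = 100, ed_minor = 60, seed = 1)
  tm0 <- make_beating_heart(p0, render = FALSE)$truth$true_metrics
  expect_equal(tm0$EF, 0)
  expect_equal(tm0$FAC, 0)
})

test_that("heart simulator validates parameters and minimum duration", {
  expect_error(heart_sim_params(es_major = 120), "end-systolic")
  expect_error(heart_sim_params(beat_period = 0.01, frame_rate = 150), "beat_period")
  expect_error(make_beating_heart(heart_sim_params(duration = 0.5)), "too few beats")
})

test_that("heart contours trace the prescribed oscillating ellipse", {
  p <- heart_sim_params(duration = 2, seed = 3)
  h <- make_beating_heart(p, render = FALSE)
  tr <- h$truth$per_frame_truth
  # frame 0 is end-diastole
  expect_equal(tr$major_um[1], p$ed_major)
  # axes bounded by the prescribed extremes
  expect_true(all(tr$major_um <= p$ed_major + 1e-9))
  expect_true(all(tr$major_um >= p$es_major - 1e-9))
  # contour of frame 0 has the ED extent
  c0 <- h$contours$contours[[1]]
  d <- as.matrix(stats::dist(c0))
  expect_equal(max(d) * p$pixel_size, p$ed_major, tolerance = 1e-3)
})

test_that("flow simulator waveform is bounded, attains its extremes, and is reproducible", {
  p <- flow_sim_params(v_systolic = 800, v_diastolic = 200, n_frames = 200, seed = 5)
  f1 <- make_flow_video(p)
  v <- f1$truth$per_frame_truth$v_um_s
  expect_true(all(v >= 200 - 1e-9 & v <= 800 + 1e-9))
  expect_equal(max(v), 800, tolerance = 1e-3)
  expect_equal(min(v), 200, tolerance = 1e-3)
  expect_equal(f1$truth$true_metrics$v_max, 800)

  f2 <- make_flow_video(p)
  expect_identical(f1$video$frames, f2$video$frames)  # bit-reproducible

  # constant flow
  pc <- flow_sim_params(v_systolic = 500, v_diastolic = 500, n_frames = 50, seed = 1)
  vc <- make_flow_video(pc)$truth$per_frame_truth$v_um_s
  expect_true(all(vc == 500))

  expect_error(flow_sim_params(v_systolic = 100, v_diastolic = 200), "v_systolic")
  expect_error(flow_sim_params(v_systolic = 9e5, vessel_length = 100,
                               frame_rate = 400), "crosses field")
})

test_that("ideal kymograph patterns carry the prescribed velocities", {
  kp <- make_kymograph_pattern(list(c(40, 2)), pixel_size = 1, frame_rate = 400)
  expect_equal(unique(kp$truth$per_frame_truth$v_um_s), 800)
  kp2 <- make_kymograph_pattern(list(c(10, 1)), pixel_size = 1, frame_rate = 1)
  expect_equal(unique(kp2$truth$per_frame_truth$v_um_s), 1)
  # two segments give a two-level step trace
  kp3 <- make_kymograph_pattern(list(c(30, 1), c(30, 4)), pixel_size = 0.5,
                                frame_rate = 100)
  v <- kp3$truth$per_frame_truth$v_um_s
  expect_equal(unique(v), c(1 * 0.5 * 100, 4 * 0.5 * 100))
  expect_equal(v, rep(c(50, 200), each = 30))
  expect_error(make_kymograph_pattern(list(c(30, -1))))
})

test_that("membrane profiles encode the prescribed foci ratio", {
  mp <- make_membrane_profile(baseline = 0.2, focus_height = 1, seed = 4)
  expect_equal(mp$truth$true_metrics$foci_ratio, 5)
  expect_equal(max(mp$profile$intensity), 1, tolerance = 0.02)
  # flat profile when no foci
  mp0 <- make_membrane_profile(n_foci = 0, baseline = 0.3, seed = 1)
  expect_true(all(mp0$profile$intensity == 0.3))
  expect_equal(mp0$truth$true_metrics$foci_ratio, 1)
  # noiseless output is exactly reproducible across seeds
  a <- make_membrane_profile(seed = 1, n_foci = 0)$profile$intensity
  b <- make_membrane_profile(seed = 99, n_foci = 0)$profile$intensity
  expect_identical(a, b)
  expect_error(make_membrane_profile(n_points = 30, n_foci = 10, focus_sd = 5),
               "overlap")
  expect_error(make_membrane_profile(baseline = 1, focus_height = 0.5))
})

test_that("generators are bit-reproducible under a fixed seed", {
  p <- heart_sim_params(duration = 1, noise_sd = 2000, seed = 11,
                        arrhythmia_jitter_sd = 0.02)
  h1 <- make_beating_heart(p)
  h2 <- make_beating_heart(p)
  expect_identical(h1$video$frames, h2$video$frames)
  expect_identical(h1$contours$contours, h2$contours$contours)
  m1 <- make_membrane_profile(noise_sd = 0.05, seed = 8)
  m2 <- make_membrane_profile(noise_sd = 0.05, seed = 8)
  expect_identical(m1$profile$intensity, m2$profile$intensity)
})
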