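make_constant_flow <- function(v, seed = 1, noise_sd = 0, n_frames = 120) {
  make_flow_video(flow_sim_params(v_systolic = v, v_diastolic = v,
                                  n_frames = n_frames, noise_sd = noise_sd,
                                  seed = seed))
}

test_that("kymograph rows replicate a static scene and follow constant flow", {
  # static scene: all rows identical
  img <- matrix(stats::runif(40 * 60), 40, 60)
  vid <- video_stack(array(rep(img, 5), c(40, 60, 5)), 100, 1)
  roi <- cbind(x = c(2, 57), y = c(20, 20))
  k <- build_kymograph(vid, roi, line_width = 1)
  expect_true(all(abs(sweep(k$image, 2, k$image[1, ])) < 1e-9))

  # constant-velocity simulator video: streak slope v / (pixel_size * frame_rate)
  fl <- make_constant_flow(400)
  kk <- build_kymograph(fl$video, fl$roi, line_width = 9)
  vt <- streak_velocity(kk)
  est <- stats::median(vt$velocity, na.rm = TRUE)
  expect_equal(est, 400, tolerance = 0.02)

  expect_error(build_kymograph(vid, cbind(x = c(-5, 10), y = c(2, 2))), "roi outside")
})

test_that("line width does not change the kymograph of a uniform perpendicular profile", {
  arr <- array(0, c(30, 50, 4))
  for (f in 1:4) arr[, , f] <- matrix(rep(sin((0:49) / 5), each = 30), 30, 50)
  vid <- video_stack(arr, 100, 1)
  roi <- cbind(x = c(3, 46), y = c(15, 15))
  k1 <- build_kymograph(vid, roi, line_width = 1)
  k3 <- build_kymograph(vid, roi, line_width = 3)
  expect_equal(k1$image, k3$image, tolerance = 1e-6)
})

test_that("streak angles recover velocity across slopes with the steeper-is-slower ordering", {
  slopes <- c(0.25, 0.5, 1, 2, 4)
  est <- vapply(slopes, function(s) {
    kp <- make_kymograph_pattern(list(c(96, s)), pixel_size = 1, frame_rate = 400)
    stats::median(streak_velocity(kp$kymo)$velocity, na.rm = TRUE)
  }, numeric(1))
  truth <- slopes * 1 * 400
  expect_true(all(abs(est - truth) / truth <= 0.02))
  # px/frame slope s means m = 1/s frames/px: larger m must give smaller v
  expect_true(all(diff(est) > 0))
  # velocity-slope reciprocity: v * m = pixel_size * frame_rate within 2%
  kp <- make_kymograph_pattern(list(c(96, 2)), pixel_size = 1, frame_rate = 400)
  vt <- streak_velocity(kp$kymo)
  ok <- !vt$missing
  expect_true(all(abs(vt$velocity[ok] * vt$slope[ok] - 400) / 400 <= 0.02))
})

test_that("vertical streaks (stationary cells) give zero velocity", {
  fl <- make_constant_flow(0)
  k <- build_kymograph(fl$video, fl$roi, line_width = 9)
  vt <- streak_velocity(k)
  expect_true(all(vt$velocity[!vt$missing] < 5))
})

test_that("uncalibrated mode reports px/frame and calibration is linear in frame rate", {
  kp <- make_kymograph_pattern(list(c(96, 2)), pixel_size = 1, frame_rate = 400)
  vt_cal <- streak_velocity(kp$kymo)
  vt_unc <- streak_velocity(kp$kymo, calibrated = FALSE)
  expect_equal(stats::median(vt_unc$velocity, na.rm = TRUE), 2, tolerance = 0.02)
  # doubling the frame rate at identical px/frame doubles reported velocity
  kp2 <- make_kymograph_pattern(list(c(96, 2)), pixel_size = 1, frame_rate = 800)
  vt2 <- streak_velocity(kp2$kymo)
  expect_equal(stats::median(vt2$velocity, na.rm = TRUE),
               2 * stats::median(vt_cal$velocity, na.rm = TRUE), tolerance = 0.02)
})

test_that("a two-segment pattern yields a step trace recovering both levels", {
  kp <- make_kymograph_pattern(list(c(120, 1), c(120, 4)), pixel_size = 1,
                               frame_rate = 400)
  vt <- streak_velocity(kp$kymo)
  third <- nrow(vt) %/% 3
  lo <- stats::median(vt$velocity[seq_len(third)], na.rm = TRUE)
  hi <- stats::median(vt$velocity[(nrow(vt) - third):nrow(vt)], na.rm = TRUE)
  expect_equal(lo, 400, tolerance = 0.05)
  expect_equal(hi, 1600, tolerance = 0.05)
})

test_that("phase segmentation labels the sine waveform half systolic", {
  fl <- make_flow_video(flow_sim_params(seed = 2))
  k <- build_kymograph(fl$video, fl$roi, line_width = 9)
  vt <- segment_phases(streak_velocity(k))
  frac <- mean(vt$phase == "systole")
  expect_true(abs(frac - 0.5) <= 0.05)
  # flat trace warns and labels everything diastole
  flc <- make_constant_flow(500)
  kc <- build_kymograph(flc$video, flc$roi, line_width = 9)
  expect_warning(vtc <- segment_phases(streak_velocity(kc)), "flat")
  expect_true(all(vtc$phase == "diastole"))
  expect_true(attr(vtc, "flat_trace"))
})

test_that("phase summary recovers systolic and diastolic velocities end to end", {
  for (seed in 1:3) {
    fl <- make_flow_video(flow_sim_params(seed = seed, noise_sd = 2000))
    k <- build_kymograph(fl$video, fl$roi, line_width = 9)
    ps <- phase_summary(segment_phases(streak_velocity(k)))
    expect_true(abs(ps$v_systolic_mean - 800) / 800 <= 0.1)
    expect_true(abs(ps$v_diastolic_mean - 200) / 200 <= 0.1)
    expect_true(ps$v_systolic_mean >= ps$v_diastolic_mean)
    # reported angles follow the steeper-is-slower convention
    expect_true(ps$angle_systolic < ps$angle_diastolic)
  }
  # forced labels on a constant trace: both phases report the same velocity
  flc <- make_constant_flow(500)
  kc <- build_kymograph(flc$video, flc$roi, line_width = 9)
  vtc <- streak_velocity(kc)
  vtc$phase <- factor(rep(c("systole", "diastole"), length.out = nrow(vtc)),
                      levels = c("systole", "diastole"))
  psc <- phase_summary(vtc)
  expect_equal(psc$v_systolic_mean, psc$v_diastolic_mean, tolerance = 0.02)
  # missing phase errors
  vtc$phase <- factor(rep("systole", nrow(vtc)), levels = c("systole", "diastole"))
  expect_error(phase_summary(vtc), "missing phase")
})
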