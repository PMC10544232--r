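disk_frame <- function(nr, nc, centers, radius = 3, amp = 55000) {
  img <- matrix(0, nr, nc)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(outer((0:(nr - 1) - centers[i, 2])^2,
                    (0:(nc - 1) - centers[i, 1])^2, "+"))
    img <- img + amp * pmin(pmax(radius - d + 0.5, 0), 1)
  }
  img
}

test_that("blob detection localises disks to sub-pixel accuracy", {
  f <- disk_frame(50, 60, cbind(20, 30))
  d <- detect_cells(f)
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d[1, "x"] - 20)^2 + (d[1, "y"] - 30)^2), 0.5)

  expect_equal(nrow(detect_cells(matrix(0, 40, 40))), 0)

  f2 <- disk_frame(50, 60, cbind(c(15, 35), c(25, 25)))
  expect_equal(nrow(detect_cells(f2)), 2)
})

test_that("greedy linking builds, fragments, and separates trajectories as expected", {
  # one cell moving 3 px/frame
  det <- lapply(0:9, function(f) cbind(x = 5 + 3 * f, y = 10))
  tr <- link_tracks(det, max_disp = 5)
  expect_equal(length(unique(tr$track)), 1)
  expect_equal(nrow(tr), 10)
  # too-small max_disp fragments the trajectory
  trf <- link_tracks(det, max_disp = 2)
  expect_gt(length(unique(trf$track)), 1)
  # two parallel cells separated beyond max_disp: two tracks, no swaps
  det2 <- lapply(0:9, function(f) cbind(x = c(5 + 3 * f, 5 + 3 * f),
                                        y = c(10, 30)))
  tr2 <- link_tracks(det2, max_disp = 5)
  expect_equal(length(unique(tr2$track)), 2)
  ys <- tapply(tr2$y, tr2$track, function(v) length(unique(v)))
  expect_true(all(ys == 1))   # each track stays on its own line
})

test_that("greedy linking matches exhaustive optimal assignment on sparse instances", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    # cells separated by > 2 * step so nearest-neighbour is unambiguous
    p1 <- cbind(x = runif(n, 0, 100), y = 30 * seq_len(n) + runif(n, -3, 3))
    step <- runif(n, 0, 4)
    p2 <- p1 + cbind(step, runif(n, -1, 1))
    shuffle <- sample(n)
    oracle <- brute_force_assignment(p1, p2[shuffle, , drop = FALSE], max_disp = 6)
    tr <- link_tracks(list(p1, p2[shuffle, , drop = FALSE]), max_disp = 6)
    # greedy must link detection i in frame 1 to its true partner
    linked <- tr[tr$frame == 1, ]
    expect_equal(nrow(linked[linked$track %in% tr$track[tr$frame == 0], ]), n)
    for (i in seq_len(n)) {
      trk <- tr$track[tr$frame == 0 & tr$x == p1[i, 1]]
      got <- tr[tr$frame == 1 & tr$track == trk, ]
      expect_equal(unname(c(got$x, got$y)),
                   unname(p2[shuffle, , drop = FALSE][oracle[i, "to"], ]),
                   tolerance = 1e-9)
    }
  }
})

test_that("kinematics converts constant pixel motion to physical velocity", {
  traj <- data.frame(frame = 0:19, x = 10 + 3 * (0:19), y = 7)
  kin <- kinematics(traj, pixel_size = 0.5, frame_rate = 400)
  expect_true(all(abs(kin$trace$velocity - 600) < 1e-9))  # 3 * 0.5 * 400
  expect_true(all(abs(kin$trace$acceleration) < 1e-9))
  # stationary cell
  kin0 <- kinematics(data.frame(frame = 0:9, x = 5, y = 5), 0.5, 400)
  expect_true(all(kin0$trace$velocity == 0))
  expect_error(kinematics(data.frame(frame = 0:1, x = 1:2, y = 0), 1, 1),
               "too short")
})

test_that("tracked synthetic flow recovers positions, velocity and v_max", {
  # noiseless single-cell constant flow: trajectory matches simulator truth
  p <- flow_sim_params(v_systolic = 400, v_diastolic = 400, n_cells = 1,
                       n_frames = 80, seed = 3)
  fl <- make_flow_video(p)
  out <- track_video(fl$video, max_disp = 3)
  main <- out$tracks[out$tracks$track ==
                       names(which.max(table(out$tracks$track))), ]
  truth <- fl$positions[match(main$frame, fl$positions$frame), ]
  expect_lt(max(abs(main$x - truth$x)), 0.5)
  expect_lt(max(abs(main$y - truth$y)), 0.5)
  expect_equal(out$v_max, 400, tolerance = 0.02)

  # pulsatile flow: v_max recovers the systolic peak
  fl2 <- make_flow_video(flow_sim_params(v_systolic = 800, v_diastolic = 200,
                                         n_frames = 300, seed = 4))
  out2 <- track_video(fl2$video)
  expect_equal(out2$v_max, 800, tolerance = 0.05)
})

test_that("percent change matches the reduction convention", {
  expect_equal(percent_change(500, 280), 44)
  expect_equal(percent_change(3, 3), 0)
  expect_equal(percent_change(10, 0), 100)
  expect_error(percent_change(0, 1), "positive")
})
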