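# Chain-track metrics: path, displacement, velocity, event splits,
# profiles and relative positions.

test_that("a straight track yields the textbook metrics", {
  trk <- data.frame(track_id = 1, frame = 1:11, x = 0:10, y = 0)
  m <- track_metrics(trk, frame_interval = 10)
  expect_equal(m$path_length, 10)
  expect_equal(m$displacement, 10)
  expect_equal(m$mean_velocity, 6)          # 10 px / (100 min)
  expect_equal(m$displacement_velocity, 6)
  expect_equal(m$straightness, 1)
})

test_that("an out-and-back track has zero displacement but positive path", {
  trk <- data.frame(frame = 1:5, x = c(0, 2, 4, 2, 0), y = 0)
  m <- track_metrics(trk, frame_interval = 10)
  expect_equal(m$displacement, 0)
  expect_equal(m$path_length, 8)
})

test_that("simulated persistent walks have exact path length", {
  trk <- simulate_tracks(track_sim_spec(n_frames = 25, speed_pre = 2,
                                        persistence = 1, noise_sd = 0,
                                        seed = 3))
  m <- track_metrics(trk)
  expect_equal(m$path_length, 2 * 24, tolerance = 1e-10)
})

test_that("path length dominates displacement over random walks", {
  trk <- simulate_tracks(track_sim_spec(n_tracks = 200, n_frames = 40,
                                        speed_pre = 1.5, persistence = 0.4,
                                        noise_sd = 0.5, seed = 4))
  m <- track_metrics(trk)
  expect_true(all(m$path_length >= m$displacement - 1e-9))
})

test_that("metrics are invariant under rigid motions of the coordinates", {
  trk <- simulate_tracks(track_sim_spec(n_frames = 30, persistence = 0.6,
                                        seed = 5))
  m0 <- track_metrics(trk, frame_interval = 10)
  th <- 0.83
  rot <- trk
  rot$x <- cos(th) * trk$x - sin(th) * trk$y + 42
  rot$y <- sin(th) * trk$x + cos(th) * trk$y - 7
  m1 <- track_metrics(rot, frame_interval = 10)
  expect_equal(m1$path_length, m0$path_length, tolerance = 1e-9)
  expect_equal(m1$displacement, m0$displacement, tolerance = 1e-9)
})

test_that("event splits recover the simulated speed change", {
  trk <- simulate_tracks(track_sim_spec(n_frames = 100, speed_pre = 2,
                                        speed_post = 0.5,
                                        detachment_frame = 50,
                                        persistence = 1, noise_sd = 0,
                                        seed = 6))
  sp <- split_at_event(trk[trk$track_id == 1, ], 50, frame_interval = 10)
  expect_equal(sp$pre$mean_velocity / sp$post$mean_velocity, 4,
               tolerance = 1e-10)
  expect_equal(sp$pre$n_samples, 50)
  expect_equal(sp$post$n_samples, 51)
})

test_that("an event at the second sample yields a minimal but valid pre half", {
  trk <- data.frame(frame = 1:5, x = c(0, 1, 3, 6, 10), y = 0)
  sp <- split_at_event(trk, 2, frame_interval = 10)
  expect_equal(sp$pre$n_samples, 2)
  expect_equal(sp$pre$path_length, 1)
})

test_that("a symmetric track splits into equal halves", {
  trk <- data.frame(frame = 1:9, x = c(0:4, 3:0), y = 0)
  sp <- split_at_event(trk, 5, frame_interval = 10)
  expect_equal(sp$pre$path_length, sp$post$path_length)
})

test_that("distance profiles are monotone, linear at constant speed, flat when arrested", {
  trk <- data.frame(frame = 1:10, x = c(0:5, 5, 5, 5, 5), y = 0)
  pr <- distance_profile(trk, frame_interval = 60)
  expect_equal(pr$cumulative_path[1], 0)
  expect_true(all(diff(pr$cumulative_path) >= 0))
  expect_equal(diff(pr$cumulative_path[1:6]), rep(1, 5))  # linear while moving
  expect_equal(diff(pr$cumulative_path[7:10]), rep(0, 3)) # plateau after arrest
  expect_equal(pr$time_h, 0:9)
})

test_that("a noisy speed drop still shows a slope change across the event", {
  trk <- simulate_tracks(track_sim_spec(n_frames = 80, speed_pre = 2,
                                        speed_post = 0.4,
                                        detachment_frame = 40,
                                        persistence = 0.8, noise_sd = 0.2,
                                        seed = 7))
  t1 <- trk[trk$track_id == 1, ]
  pr <- distance_profile(t1, frame_interval = 10)
  pre_slope <- (pr$cumulative_path[40] - pr$cumulative_path[1]) / 39
  post_slope <- (pr$cumulative_path[80] - pr$cumulative_path[40]) / 40
  expect_lt(post_slope, pre_slope)
})

test_that("relative positions translate the reference to the origin", {
  trk <- data.frame(frame = 1:4, x = c(3, 4, 5, 6), y = c(1, 1, 2, 2))
  rel <- relative_positions(trk, c(3, 1))
  expect_equal(rel$x[1], 0); expect_equal(rel$y[1], 0)
  shifted <- trk; shifted$x <- trk$x + 5; shifted$y <- trk$y - 2
  rel2 <- relative_positions(shifted, c(3 + 5, 1 - 2))
  expect_equal(rel2$x, rel$x); expect_equal(rel2$y, rel$y)
})

test_that("a leader homing toward its chain ends closer than it started", {
  # inward-biased walk toward the reference point
  ref <- c(0, 0)
  pos <- matrix(NA_real_, 30, 2); pos[1, ] <- c(40, 30)
  set.seed(8)
  for (i in 2:30) {
    dir <- -pos[i - 1, ] / sqrt(sum(pos[i - 1, ]^2))
    pos[i, ] <- pos[i - 1, ] + 1.5 * dir + rnorm(2, sd = 0.3)
  }
  trk <- data.frame(frame = 1:30, x = pos[, 1], y = pos[, 2])
  rel <- relative_positions(trk, ref)
  d <- sqrt(rel$x^2 + rel$y^2)
  expect_lt(d[30], d[1])
})

test_that("invalid tracks and events are refused", {
  expect_error(track_metrics(data.frame(frame = 1, x = 0, y = 0)),
               ">= 2 samples")
  expect_error(track_metrics(data.frame(frame = c(1, 1, 2), x = 0:2, y = 0)),
               "strictly increasing")
  trk <- data.frame(frame = 1:5, x = 0:4, y = 0)
  expect_error(split_at_event(trk, 5, 10), "strictly inside")
  expect_error(split_at_event(trk, 0, 10), "strictly inside")
})
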