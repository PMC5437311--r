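# Synthetic-data generators: analytic phantom truth, persistent-random-walk
# tracks, and expression matrices with planted effects.

test_that("phantom truth follows the stated geometry", {
  # no branches: invasive radius equals the core radius at every frame
  ph0 <- simulate_spheroid_stack(spheroid_phantom_spec(
    image_shape = c(3, 3, 96, 96), core_radius = 20, n_branches = 0,
    noise_sd = 0, seed = 1))
  expect_equal(ph0$truth$true_branch_count, rep(0L, 3))
  expect_equal(ph0$truth$true_invasive_radius, rep(20, 3))
  expect_equal(ph0$truth$true_invasive_area, rep(0, 3))

  # growing branches: radius = core + rate * frame
  ph <- simulate_spheroid_stack(spheroid_phantom_spec(
    image_shape = c(10, 3, 128, 128), core_radius = 20, n_branches = 5,
    branch_growth_rate = 2, noise_sd = 0, seed = 2))
  expect_equal(ph$truth$true_invasive_radius[10], 40)
  expect_equal(ph$truth$true_branch_count, rep(5L, 10))
  expect_true(all(diff(ph$truth$true_invasive_radius) > 0))
})

test_that("rasterized phantom area matches analytic truth to the boundary bound", {
  ph <- simulate_spheroid_stack(spheroid_phantom_spec(
    image_shape = c(4, 3, 160, 160), core_radius = 18, n_branches = 4,
    branch_growth_rate = 6, noise_sd = 0, seed = 5))
  for (t in 1:4) {
    raster <- sum(ph$truth_mask[t, , ])
    analytic <- ph$truth$true_area[t]
    # discretization bound: about one pixel per boundary pixel
    perim <- 2 * pi * ph$spec$core_radius +
      ph$spec$n_branches * 2 * (ph$spec$branch_growth_rate * t)
    expect_lt(abs(raster - analytic), perim + 10)
  }
})

test_that("noiseless phantom has zero background z-variance and structured foreground", {
  ph <- simulate_spheroid_stack(spheroid_phantom_spec(
    image_shape = c(2, 4, 64, 64), core_radius = 12, n_branches = 0,
    noise_sd = 0, seed = 3))
  pr <- std_project(ph$stack)
  bg <- ph$truth_mask[1, , ] == 0
  expect_equal(max(pr[1, , ][bg]), 0)
  expect_true(min(pr[1, , ][!bg]) > 0)
})

test_that("phantom geometry exceeding the image errors naming the frame", {
  expect_error(
    spheroid_phantom_spec(image_shape = c(5, 3, 96, 96), core_radius = 20,
                          n_branches = 3, branch_growth_rate = 10,
                          noise_sd = 0, seed = 1),
    "frame 3")
  expect_error(spheroid_phantom_spec(seed = 1, fg_intensity = 5,
                                     bg_intensity = 10), "fg_intensity")
  expect_error(spheroid_phantom_spec(n_branches = 2), "seed")
})

test_that("generators are bit-identical under a fixed seed and leave the RNG alone", {
  spec <- spheroid_phantom_spec(image_shape = c(2, 3, 64, 64),
                                core_radius = 10, n_branches = 3,
                                branch_growth_rate = 4, seed = 11)
  set.seed(99); before <- runif(1)
  a <- simulate_spheroid_stack(spec)
  b <- simulate_spheroid_stack(spec)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth, b$truth)

  ts <- track_sim_spec(n_tracks = 4, n_frames = 30, seed = 12)
  expect_identical(simulate_tracks(ts), simulate_tracks(ts))

  es <- expression_sim_spec(n_genes = 30, seed = 13)
  expect_identical(simulate_expression(es)$matrix,
                   simulate_expression(es)$matrix)

  set.seed(99)
  expect_identical(runif(1), before)  # no global RNG side effects
})

test_that("fully persistent noiseless tracks take exact unit steps", {
  trk <- simulate_tracks(track_sim_spec(n_frames = 10, speed_pre = 1,
                                        persistence = 1, noise_sd = 0,
                                        seed = 7))
  steps <- sqrt(diff(trk$x)^2 + diff(trk$y)^2)
  expect_equal(steps, rep(1, 9), tolerance = 1e-12)
  # collinearity: displacement equals path
  expect_equal(sqrt((trk$x[10] - trk$x[1])^2 + (trk$y[10] - trk$y[1])^2), 9,
               tolerance = 1e-12)
})

test_that("detachment switches the simulated step speed at the stated frame", {
  trk <- simulate_tracks(track_sim_spec(n_frames = 100, speed_pre = 2,
                                        speed_post = 0.5,
                                        detachment_frame = 50,
                                        persistence = 0.7, noise_sd = 0,
                                        seed = 8))
  steps <- sqrt(diff(trk$x)^2 + diff(trk$y)^2)
  expect_equal(steps[1:49], rep(2, 49), tolerance = 1e-10)
  expect_equal(steps[50:99], rep(0.5, 50), tolerance = 1e-10)
  expect_equal(attr(trk, "truth")$detachment_frame, 50L)
})

test_that("expression effects land in the stated groups", {
  sim <- simulate_expression(expression_sim_spec(
    n_genes = 300, baseline_sd = 0.1, delta = 5,
    f_null = 0.4, f_leader_up = 0.2, f_follower_up = 0.2, f_artifact = 0.2,
    seed = 21))
  m <- sim$matrix; lab <- sim$truth$label
  gmean <- function(g, rows) rowMeans(m[rows, sim$design$group == g,
                                        drop = FALSE])
  lu <- lab == "leader_up"
  expect_equal(mean(gmean("leader", lu) - gmean("follower", lu)), 5,
               tolerance = 0.1)
  ar <- lab == "artifact"
  expect_equal(mean(gmean("leader", ar) - gmean("follower", ar)), 5,
               tolerance = 0.1)
  expect_equal(mean(gmean("ctrl_photo", ar) - gmean("ctrl_nonphoto", ar)), 5,
               tolerance = 0.1)
  nu <- lab == "null"
  expect_lt(abs(mean(gmean("leader", nu) - gmean("follower", nu))), 0.05)
  # class sizes follow the fractions
  expect_equal(as.vector(table(lab)[c("leader_up", "follower_up", "artifact")]),
               rep(60L, 3))
})

test_that("degenerate effect size gives four indistinguishable groups", {
  sim <- simulate_expression(expression_sim_spec(
    n_genes = 500, delta = 0, f_null = 0.7, f_leader_up = 0.1,
    f_follower_up = 0.1, f_artifact = 0.1, seed = 22))
  m <- sim$matrix
  gm <- vapply(EXPRESSION_GROUPS,
               function(g) mean(m[, sim$design$group == g]), numeric(1))
  expect_lt(max(gm) - min(gm), 0.02)
})

test_that("invalid simulation specs are rejected", {
  expect_error(expression_sim_spec(f_null = 0.5, f_leader_up = 0.1,
                                   f_follower_up = 0.1, f_artifact = 0.1,
                                   seed = 1), "sum to 1")
  expect_error(track_sim_spec(persistence = 1.2, seed = 1), "persistence")
  expect_error(track_sim_spec(detachment_frame = 100, n_frames = 100,
                              seed = 1), "detachment_frame")
})
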