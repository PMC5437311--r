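# Normalization utilities and the permutation differential-expression test.

sim_small <- function(...) simulate_expression(expression_sim_spec(...))

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(qn[, 2]), c(1.5, 3, 4.5))

  m2 <- cbind(c(5, 1, 9), c(5, 1, 9))
  expect_equal(quantile_normalize(m2), m2)  # identical columns: fixed point

  set.seed(1)
  m3 <- matrix(rnorm(60), 15, 4)
  qn3 <- quantile_normalize(m3)
  sorted <- apply(qn3, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_error(quantile_normalize(m3[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("log2 transform and probeset summarization behave", {
  expect_equal(log2_transform(matrix(8))[1], 3)
  expect_equal(log2_transform(matrix(0), offset = 1)[1], 0)
  m <- matrix(abs(rnorm(20)) + 0.1, 5, 4)
  expect_equal(2^log2_transform(m), m, tolerance = 1e-12)
  bad <- matrix(c(1, -2), 2, 1, dimnames = list(c("gA", "gB"), NULL))
  expect_error(log2_transform(bad), "gB")

  probes <- matrix(c(1, 3, 10, 2, 4, 20), 3, 2,
                   dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("g1", "g1", "g2"))
  gm <- summarize_probesets(probes, map)
  expect_equal(gm["g1", ], c(s1 = 2, s2 = 3))
  expect_equal(gm["g2", ], c(s1 = 10, s2 = 20))
  expect_message(summarize_probesets(probes, map[1:2, ]), "unmapped")
  expect_error(summarize_probesets(probes, map[0, ]), "non-empty")
})

test_that("difference pairs enumerate all treatment/control combinations", {
  sim <- sim_small(n_genes = 3, seed = 1)
  m <- sim$matrix
  m["gene_0001", sim$design$group == "leader"] <- 5
  m["gene_0001", sim$design$group == "follower"] <- 3
  pl <- make_difference_pairs(m, sim$design, "leader")
  expect_equal(ncol(pl$treatment), 9)
  expect_equal(ncol(pl$control), 9)
  expect_equal(unname(pl$treatment["gene_0001", ]), rep(2, 9))
  pf <- make_difference_pairs(m, sim$design, "follower")
  # direction reversal negates every treatment difference (cell (i,j)
  # becomes cell (j,i), so compare as per-gene multisets)
  expect_equal(t(apply(pf$treatment, 1, sort)),
               t(apply(-pl$treatment, 1, sort)), ignore_attr = TRUE)
  expect_equal(pf$control, pl$control)        # controls are shared
})

test_that("gene statistics match the textbook t formulas", {
  # worked example: treatment diffs 1,2,3
  pairs <- structure(list(treatment = matrix(c(1, 2, 3), 1),
                          control = matrix(c(0, 0, 0), 1)),
                     class = "difference_pairs", n_pairs = 3,
                     direction = "leader")
  gs <- gene_stats(pairs)
  expect_equal(gs$t_one, 2 * sqrt(3), tolerance = 1e-10)   # 3.4641
  expect_equal(gs$t_two, 2 * sqrt(3), tolerance = 1e-10)

  # cross-check against stats::t.test on random data
  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(9); b <- rnorm(9)
    pairs <- structure(list(treatment = matrix(a, 1),
                            control = matrix(b, 1)),
                       class = "difference_pairs", n_pairs = 9,
                       direction = "leader")
    gs <- gene_stats(pairs)
    expect_equal(gs$t_one, unname(t.test(a)$statistic), tolerance = 1e-9)
    expect_equal(gs$t_two,
                 unname(t.test(a, abs(b), var.equal = TRUE)$statistic),
                 tolerance = 1e-9)
    gw <- gene_stats(pairs, welch = TRUE)
    expect_equal(gw$t_two, unname(t.test(a, abs(b))$statistic),
                 tolerance = 1e-9)
  }
})

test_that("zero-variance statistics follow the sign convention", {
  pairs <- structure(list(treatment = matrix(rep(2, 9), 1),
                          control = matrix(rep(0, 9), 1)),
                     class = "difference_pairs", n_pairs = 9,
                     direction = "leader")
  gs <- gene_stats(pairs)
  expect_equal(gs$t_one, Inf)
  expect_equal(gs$t_two, Inf)

  flat <- structure(list(treatment = matrix(rep(1, 9), 1),
                         control = matrix(rep(1, 9), 1)),
                    class = "difference_pairs", n_pairs = 9,
                    direction = "leader")
  gsf <- gene_stats(flat)
  expect_equal(gsf$t_one, Inf)   # positive constant mean
  expect_equal(gsf$t_two, 0)     # equal constant means
})

test_that("a completely degenerate gene gets p = 1", {
  m <- matrix(7, 2, 12,
              dimnames = list(c("g1", "g2"),
                              paste(rep(EXPRESSION_GROUPS, each = 3),
                                    1:3, sep = "_")))
  design <- data.frame(sample_id = colnames(m),
                       group = rep(EXPRESSION_GROUPS, each = 3),
                       replicate = rep(1:3, 4))
  pairs <- make_difference_pairs(m, design, "leader")
  p_samp <- permutation_p(pairs, perm_params(B = 99, seed = 1))
  expect_equal(unname(p_samp), c(1, 1))
  res <- run_de(m, design, perm_params(B = 50, seed = 1))
  expect_equal(res$p_leader, c(1, 1))
  expect_equal(res$p_follower, c(1, 1))
})

test_that("sampled permutation p agrees with exhaustive enumeration", {
  # reduced design: 2 replicates per group, 4+4 difference pairs,
  # choose(8, 4) = 70 role assignments
  sim <- sim_small(n_genes = 50, n_reps = 2, delta = 0.5, f_null = 0.6,
                   f_leader_up = 0.2, f_follower_up = 0.1, f_artifact = 0.1,
                   seed = 5)
  pairs <- make_difference_pairs(sim$matrix, sim$design, "leader")
  expect_equal(attr(pairs, "n_pairs"), 4)
  p_ex <- permutation_p(pairs, perm_params(B = 500, seed = 2,
                                           exhaustive = TRUE))
  p_samp <- permutation_p(pairs, perm_params(B = 500, seed = 2))
  se <- sqrt(p_ex * (1 - p_ex) / 500)
  expect_true(all(abs(p_samp - p_ex) <= 3 * se + 2 / 501))
  expect_true(all(p_ex > 0 & p_ex <= 1))
  expect_true(all(p_samp > 0 & p_samp <= 1))
})

test_that("selection applies the alpha threshold to raw permutation p", {
  sim <- sim_small(n_genes = 40, delta = 2, baseline_sd = 0.25, seed = 6)
  res <- run_de(sim$matrix, sim$design, perm_params(B = 200, seed = 3))
  expect_equal(res$selected_leader, res$p_leader < 0.05)
  expect_equal(res$selected_follower, res$p_follower < 0.05)
  expect_equal(res$bh_q_leader, p.adjust(res$p_leader, "BH"))
  expect_true(all(res$p_leader > 0 & res$p_leader <= 1))
})

test_that("the test is reproducible and shift invariant", {
  sim <- sim_small(n_genes = 30, delta = 1, seed = 7)
  pp <- perm_params(B = 300, seed = 4)
  r1 <- run_de(sim$matrix, sim$design, pp)
  r2 <- run_de(sim$matrix, sim$design, pp)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "meta")$plan_digest, attr(r2, "meta")$plan_digest)

  # shift invariance holds up to floating-point tie reshuffling: shifting
  # all values perturbs each difference in its last ulp, which can move a
  # handful of exceedance counts
  shifted <- run_de(sim$matrix + 5, sim$design, pp)
  expect_lt(max(abs(shifted$p_leader - r1$p_leader)), 0.02)
  expect_lt(max(abs(shifted$p_follower - r1$p_follower)), 0.02)

  # the difference-level scheme is also deterministic and shift invariant
  ppp <- perm_params(B = 200, seed = 4, scheme = "pairs")
  q1 <- run_de(sim$matrix, sim$design, ppp)
  q2 <- run_de(sim$matrix + 3, sim$design, ppp)
  expect_lt(max(abs(q1$p_leader - q2$p_leader)), 0.03)
  expect_equal(attr(q1, "meta")$scheme, "pairs")
})

test_that("leader-specific genes are detected while artifact genes are screened out", {
  sim <- sim_small(n_genes = 300, delta = 1, f_null = 0.4, f_leader_up = 0.2,
                   f_follower_up = 0.2, f_artifact = 0.2, seed = 8)
  res <- run_de(sim$matrix, sim$design, perm_params(B = 500, seed = 5))
  rate <- tapply(res$selected_leader, sim$truth$label, mean)
  expect_gt(rate[["leader_up"]], 0.6)
  expect_lt(rate[["artifact"]], 0.25 * rate[["leader_up"]])
  expect_lt(rate[["follower_up"]], 0.05)
  rate_f <- tapply(res$selected_follower, sim$truth$label, mean)
  expect_gt(rate_f[["follower_up"]], 0.6)
  expect_lt(rate_f[["leader_up"]], 0.05)
})

test_that("incomplete or mismatched designs are refused", {
  sim <- sim_small(n_genes = 5, seed = 9)
  bad <- sim$design[sim$design$group != "ctrl_photo", ]
  expect_error(make_difference_pairs(sim$matrix, bad, "leader"),
               "ctrl_photo")
  bad2 <- sim$design
  bad2$sample_id[1] <- "nonexistent"
  expect_error(run_de(sim$matrix, bad2, perm_params(B = 10, seed = 1)),
               "column")
  expect_error(perm_params(B = 0), "B")
  expect_error(perm_params(alpha = 1.5), "alpha")
})
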