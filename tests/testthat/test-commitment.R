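test_that("commitment labelling uses the 2 m inclusive boundary", {
  expect_equal(label_commitment(c(2.0, 2.01, 0, 1.999)), c(1L, 0L, 1L, 1L))
})

test_that("class weight is the committed fraction", {
  expect_equal(commitment_weight(6392, 39828), 6392 / 46220)
  expect_equal(round(commitment_weight(6392, 39828), 2), 0.14)
  expect_equal(commitment_weight(5, 5), 0.5)
  expect_error(commitment_weight(0, 5))
})

test_that("contest extraction finds spoils/contested marks after a kick", {
  fx <- make_fixture("two_player_contest")
  cons <- consolidate(fx$tracking, fx$transactions)
  ct <- extract_contests(cons)
  expect_length(ct, 1)
  expect_equal(ct[[1]]$t_p, 2)
  expect_equal(ct[[1]]$t_c, 4)
  expect_equal(c(ct[[1]]$contest_x, ct[[1]]$contest_y), c(0, 20))
  # an uncontested mark after a kick is not a contest
  tx2 <- data.table::copy(fx$transactions)[event_type == "spoil",
                                           event_type := "mark"]
  expect_length(extract_contests(consolidate(fx$tracking, tx2)), 0)
  # a contest without a locatable preceding kick is skipped
  tx3 <- fx$transactions[event_type == "spoil"]
  ct3 <- extract_contests(consolidate(fx$tracking, tx3))
  expect_length(ct3, 0)
  expect_equal(attr(ct3, "skipped"), 1L)
})

test_that("observations apply the 35 m filter and label by position at t_c", {
  fx <- make_fixture("two_player_contest")
  cons <- consolidate(fx$tracking, fx$transactions)
  obs <- build_observations(extract_contests(cons), fx$tracking)
  expect_equal(nrow(obs), fx$expected$n_observations)
  expect_equal(obs[match(c("p1", "p2"), player_id)]$committed,
               unname(fx$expected$committed))
  expect_equal(obs$time_to_point, c(2, 2))
  # p1 at t_p = 2 is at (0, 10.5) heading +y at 5 m/s: contest dead ahead
  o1 <- obs[player_id == "p1"]
  expect_equal(o1$velocity, 5)
  expect_equal(o1$rel_x, 0, tolerance = 1e-9)
  expect_equal(o1$rel_y, 9.5, tolerance = 1e-9)

  # a player 36 m from the contest produces no observation
  far <- make_line("p3", "A", c(36, 20), c(0, 1), 1, 0, 4.2)
  tr <- validate_tracking(rbind(fx$tracking[, .SD, .SDcols = names(far)], far))
  obs2 <- build_observations(
    extract_contests(consolidate(tr, fx$transactions)), tr)
  expect_false("p3" %in% obs2$player_id)
  expect_equal(nrow(obs2), 2)
})

test_that("fit_commitment validates inputs and is deterministic", {
  obs <- random_obs(60)
  m1 <- fit_commitment(obs)
  m2 <- fit_commitment(obs)
  expect_identical(m1, m2)
  expect_equal(m1$w, mean(obs$committed))
  expect_error(fit_commitment(obs[committed == 1][1]), "at least 2 rows")
  expect_error(fit_commitment(obs[, !"committed"]), "missing column")
})

test_that("posterior equals w where class densities coincide", {
  # duplicate the same two rows in both classes: f1 == f0 everywhere
  base <- data.table::data.table(
    velocity = c(2, 4), time_to_point = c(1, 2),
    rel_x = c(0, 1), rel_y = c(2, 3))
  obs <- rbind(data.table::data.table(base, committed = 1L),
               data.table::data.table(base, committed = 0L),
               data.table::data.table(base, committed = 0L),
               data.table::data.table(base, committed = 0L))
  m <- fit_commitment(obs)
  expect_equal(m$w, 0.25)
  # query within kernel reach of the shared rows (far away both densities
  # underflow to zero and the convention Pr = 0 applies instead)
  q <- withr::with_seed(3, data.table::data.table(
    velocity = runif(20, 1, 5), time_to_point = runif(20, 1, 2),
    rel_x = runif(20, -2, 3), rel_y = runif(20, 1, 4)))
  p <- commit_probability(m, q$velocity, q$time_to_point, q$rel_x, q$rel_y)
  expect_equal(as.numeric(p), rep(0.25, 20), tolerance = 1e-9)
})

test_that("posterior concentrates near an isolated committed cluster", {
  obs <- rbind(
    data.table::data.table(velocity = 2, time_to_point = 2,
                           rel_x = 0, rel_y = c(0, 0), committed = 1L),
    data.table::data.table(velocity = 2, time_to_point = 2,
                           rel_x = 30, rel_y = c(30, 30), committed = 0L))
  m <- fit_commitment(obs)
  expect_gt(commit_probability(m, 2, 2, 0, 0), 0.999)
  expect_lt(commit_probability(m, 2, 2, 30, 30), 0.001)
})

test_that("posterior matches the naive double-loop oracle within 1e-6", {
  obs <- random_obs(180, seed = 5)
  m <- fit_commitment(obs)
  q <- as.matrix(random_obs(40, seed = 6)[, 1:4])
  p_pkg <- commit_probability(m, q[, 1], q[, 2], q[, 3], q[, 4])
  p_orc <- naive_posterior(q, m$x1, m$x0, m$w, m$bandwidth)
  expect_equal(as.numeric(p_pkg), p_orc, tolerance = 1e-6)
})

test_that("posterior is monotone in the prior weight", {
  obs <- random_obs(100, seed = 8)
  m <- fit_commitment(obs)
  q <- random_obs(15, seed = 9)
  p_lo <- commit_probability(m, q$velocity, q$time_to_point, q$rel_x, q$rel_y)
  m_hi <- m
  m_hi$w <- min(0.95, m$w + 0.3)
  p_hi <- commit_probability(m_hi, q$velocity, q$time_to_point,
                             q$rel_x, q$rel_y)
  expect_true(all(p_hi >= p_lo - 1e-12))
})

test_that("far from all data the posterior underflows to zero, flagged", {
  obs <- random_obs(50, seed = 10)
  m <- fit_commitment(obs)
  p <- commit_probability(m, 300, 300, 300, 300)
  expect_equal(as.numeric(p), 0)
  expect_equal(attr(p, "underflow"), 1L)
})

test_that("class densities integrate to ~1 (Monte-Carlo)", {
  obs <- random_obs(80, seed = 13)
  m <- fit_commitment(obs)
  withr::with_seed(14, {
    # importance sample from a wide uniform box covering the data
    lo <- apply(m$x1, 2, min) - 6
    hi <- apply(m$x1, 2, max) + 6
    nmc <- 40000
    qs <- sapply(seq_along(lo), function(j) runif(nmc, lo[j], hi[j]))
    f <- class_density(m, qs[, 1], qs[, 2], qs[, 3], qs[, 4], class = 1)
    integral <- mean(f) * prod(hi - lo)
    expect_equal(integral, 1, tolerance = 0.05)
  })
})

test_that("motion grid agrees with the elementwise path and stays in [0,1]", {
  m <- toy_model_for_tests()
  g <- motion_model_grid(m, 3, 2, half_width = 10)
  expect_true(all(g$prob >= 0 & g$prob <= 1))
  idx <- cbind(c(1, 5, 11, 21), c(21, 11, 3, 1))
  direct <- commit_probability(m, 3, 2, g$rel_x[idx[, 1]], g$rel_y[idx[, 2]])
  expect_lt(max(abs(g$prob[idx] - as.numeric(direct))), 1e-6)
  expect_equal(g$peak$value, max(g$prob[g$evidence >= 5]))
})

test_that("model archives round-trip to an identical refit", {
  m <- toy_model_for_tests()
  dir <- withr::local_tempdir()
  save_commitment_model(m, dir)
  m2 <- load_commitment_model(dir)
  expect_equal(m2$w, m$w)
  expect_equal(m2$bandwidth, m$bandwidth)
  q <- random_obs(10, seed = 21)
  expect_equal(
    as.numeric(commit_probability(m2, q$velocity, q$time_to_point,
                                  q$rel_x, q$rel_y)),
    as.numeric(commit_probability(m, q$velocity, q$time_to_point,
                                  q$rel_x, q$rel_y)),
    tolerance = 1e-12)
})
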