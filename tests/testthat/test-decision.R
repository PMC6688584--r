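make_eo_surface <- function(grid, eo, ball = c(0, 0)) {
  structure(list(grid = grid, eo = eo, ball = ball,
                 attacking_direction = 1L),
            class = "eo_surface")
}

test_that("raw EO follows the outcome-probability/equity combination", {
  m <- toy_model_for_tests()
  fx <- make_fixture("symmetric_field")
  grid <- make_grid(c(-20, 20), c(-12, 12))
  surf <- control_surface(m, fx$formation, "A", c(0, 0), grid)
  eq <- equity_surrogate()
  eo_s <- expected_outcome(surf, eq, 1L)
  # independent term-by-term recomputation at a handful of cells
  cells <- list(c(-15, -5), c(0, 0), c(12, 8))
  for (cl in cells) {
    nc <- nearest_cell(grid, cl[1], cl[2])
    e_a <- equity_value(eq, nc$x, nc$y, 1L)
    e_o <- equity_value(eq, nc$x, nc$y, -1L)
    manual <- surf$p_a[nc$i, nc$j] * e_a + surf$p_b[nc$i, nc$j] * e_a -
      surf$p_c[nc$i, nc$j] * e_o - surf$p_d[nc$i, nc$j] * e_o
    expect_equal(eo_s$eo[nc$i, nc$j], manual, tolerance = 1e-12)
  }
  # perfectly symmetric midpoint cell with e_a = e_o = 0 cancels exactly
  nc0 <- nearest_cell(grid, 0, 0)
  expect_equal(eo_s$eo[nc0$i, nc0$j], 0, tolerance = 1e-9)
})

test_that("EO is linear in the equity scale and DV is unchanged", {
  fx <- make_fixture("planted_optimum")
  lam <- 3.7
  eq_scaled <- fx$equity
  eq_scaled$max_value <- fx$equity$max_value * lam
  ev1 <- evaluate_pass_formation(fx$model, fx$equity, fx$formation,
                                 fx$kicker_id, fx$planted_location)
  ev2 <- evaluate_pass_formation(fx$model, eq_scaled, fx$formation,
                                 fx$kicker_id, fx$planted_location)
  expect_equal(ev2$eo_dec, lam * ev1$eo_dec, tolerance = 1e-9)
  expect_equal(ev2$eo_alt, lam * ev1$eo_alt, tolerance = 1e-9)
  expect_equal(as.numeric(ev2$dv), as.numeric(ev1$dv), tolerance = 1e-9)
})

test_that("kick smoothing is a renormalised contraction with a fixed point", {
  grid <- make_grid(c(-30, 30), c(-30, 30))
  const <- matrix(2.5, length(grid$gx), length(grid$gy))
  sm <- kick_smoothing(make_eo_surface(grid, const), kicker = c(0, 0))
  expect_equal(sm$eo_mod, const, tolerance = 1e-12)

  withr::with_seed(41, {
    rnd <- matrix(rnorm(length(grid$gx) * length(grid$gy)),
                  length(grid$gx), length(grid$gy))
  })
  sm2 <- kick_smoothing(make_eo_surface(grid, rnd), kicker = c(-30, -30))
  expect_true(all(sm2$eo_mod <= max(rnd) + 1e-12))
  expect_true(all(sm2$eo_mod >= min(rnd) - 1e-12))
  # short kicks (radius under one cell) keep the raw value: a cell ~7 m
  # from the kicker at (-30, -30) has r = 0.35 m
  nc <- nearest_cell(grid, -25, -25)
  expect_equal(sm2$eo_mod[nc$i, nc$j], rnd[nc$i, nc$j])
})

test_that("smoothing radius is 5% of kicking distance", {
  grid <- make_grid(c(-30, 30), c(-30, 30))
  # impulse at (20, 0): kicker at origin so r = 1 m there
  imp <- matrix(0, length(grid$gx), length(grid$gy))
  nc <- nearest_cell(grid, 20, 0)
  imp[nc$i, nc$j] <- 1
  sm <- kick_smoothing(make_eo_surface(grid, imp), kicker = c(0, 0))
  # at the impulse cell the average over the r = 1 neighbourhood (5 cells,
  # centre weight 1, four neighbours exp(-1/2)) applies
  wn <- exp(-0.5)
  expect_equal(sm$eo_mod[nc$i, nc$j], 1 / (1 + 4 * wn), tolerance = 1e-9)
  # a cell 30 m out has r = 1.5 m: the impulse leaks one cell away
  expect_gt(sm$eo_mod[nc$i + 1, nc$j], 0)
})

test_that("decision value clamps below and flags non-positive optima", {
  expect_equal(decision_value(2, 2), 1)
  expect_equal(decision_value(1, 2), 0.5)
  expect_equal(decision_value(-5, 2), -1)
  dv <- decision_value(1, -0.5)
  expect_true(is.na(dv))
  expect_true(attr(dv, "undefined"))
  expect_true(is.na(decision_value(1, 0)))
})

test_that("alternative search is exhaustive, bounded at 60 m, deterministic", {
  fx <- make_fixture("planted_optimum")
  grid <- make_grid(c(-63, 63), c(-60, 60))
  surf <- control_surface(fx$model, fx$formation, "A", c(0, 0), grid)
  eo_s <- kick_smoothing(expected_outcome(surf, fx$equity, 1L),
                         kicker = c(0, 0))
  alt <- find_alternative(eo_s, fx$formation, fx$kicker_id)
  # brute-force scan over teammates
  mates <- fx$formation[fx$formation$team_id == "A" &
                          fx$formation$player_id != fx$kicker_id]
  eo_all <- vapply(seq_len(nrow(mates)), function(k) {
    nc <- nearest_cell(grid, mates$x[k], mates$y[k])
    eo_s$eo_mod[nc$i, nc$j]
  }, numeric(1))
  d_all <- sqrt(mates$x^2 + mates$y^2)
  best <- which(eo_all == max(eo_all[d_all <= 60]) & d_all <= 60)
  expect_equal(alt$player_id, mates$player_id[min(best)])
  expect_equal(alt$player_id, fx$planted_id)

  # a teammate just outside 60 m is excluded even with maximal EO
  f2 <- data.table::copy(fx$formation)
  f2[f2$player_id == "t1", `:=`(x = 61, y = 0)]
  surf2 <- control_surface(fx$model, f2, "A", c(0, 0), grid)
  eo2 <- kick_smoothing(expected_outcome(surf2, fx$equity, 1L), c(0, 0))
  alt2 <- find_alternative(eo2, f2, "k1")
  expect_false(identical(alt2$player_id, "t1"))

  # ties break to the lowest player id
  f3 <- data.table::copy(fx$formation)
  f3[f3$player_id == "t2", `:=`(x = 35, y = 5)] # duplicate t1's position
  surf3 <- control_surface(fx$model, f3, "A", c(0, 0), grid)
  eo3 <- kick_smoothing(expected_outcome(surf3, fx$equity, 1L), c(0, 0))
  expect_equal(find_alternative(eo3, f3, "k1")$player_id, "t1")

  # no teammate in range -> NULL
  lonely <- fx$formation[fx$formation$player_id %in% c("k1", "o1")]
  expect_null(find_alternative(eo_s, lonely, "k1"))
})

test_that("a pass to the planted optimum has DV exactly 1", {
  fx <- make_fixture("planted_optimum")
  ev <- evaluate_pass_formation(fx$model, fx$equity, fx$formation,
                                fx$kicker_id, fx$planted_location)
  expect_equal(ev$alt_player_id, fx$planted_id)
  expect_gt(ev$eo_alt, 0)
  expect_equal(as.numeric(ev$dv), 1)
  expect_equal(ev$risk_dec, ev$dom_dec * ev$inf_dec)
  expect_equal(ev$dist_dec,
               sqrt(sum(fx$planted_location^2)), tolerance = 1e-9)
})

test_that("evaluate_passes scans mark->kick->mark chains and skips others", {
  sim <- shared_sim()
  cons <- consolidate(sim$tracking, sim$transactions)
  # use a cheap model so the scan stays fast
  ev <- evaluate_passes(cons, toy_model_for_tests(), equity_surrogate(),
                        match_id = "t")
  led_marks <- sim$ledger$passes[outcome == "mark"]
  skipped <- attr(ev, "skipped")
  # every clean planted pass whose kick follows the receiver's mark chain
  # is either evaluated or skipped for an accountable reason
  expect_equal(nrow(ev) + sum(skipped),
               nrow(sim$ledger$passes))
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$dist_dec <= 60 + 1e-9))
  expect_true(all(is.na(ev$dv) | ev$dv >= -1))
  # DV <= 1 whenever the optimum is positive (exhaustive search)
  ok <- !is.na(ev$dv)
  expect_true(all(ev$dv[ok] <= 1 + 1e-9))
})
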