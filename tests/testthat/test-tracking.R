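test_that("angle_between handles continuation, turns, reversal and errors", {
  expect_equal(angle_between(c(0, 0), c(0, 1), c(0, 2)), 0)
  expect_equal(angle_between(c(0, 0), c(0, 1), c(1, 1)), pi / 2)
  expect_equal(angle_between(c(0, 0), c(0, 1), c(0, 0)), pi)
  expect_error(angle_between(c(0, 0), c(0, 0), c(1, 1)), "degenerate")
})

test_that("velocity is the 1 s displacement and undefined without it", {
  tr <- make_line("p1", "A", c(0, 0), c(3 / 5, 4 / 5), 5, 0, 2)
  expect_equal(compute_velocity(tr, 2), 5)
  st <- make_line("p2", "A", c(4, 4), c(1, 0), 0, 0, 2)
  expect_equal(compute_velocity(st, 1), 0)
  expect_true(is.na(compute_velocity(tr, 0.5))) # no sample 1 s prior
})

test_that("velocity matches generator ground truth on a constant track", {
  v <- 3.7
  tr <- make_line("p1", "A", c(-5, 2), c(0, 1), v, 0, 3)
  expect_equal(compute_velocity(tr, 2.5), v, tolerance = 1e-9)
})

test_that("displacement direction uses the clockwise-from-+y convention", {
  for (case in list(list(d = c(0, 1), a = 0),
                    list(d = c(1, 0), a = pi / 2),
                    list(d = c(0, -1), a = pi),
                    list(d = c(-1, 0), a = 3 * pi / 2))) {
    tr <- make_line("p", "A", c(0, 0), case$d, 2, 0, 1)
    dd <- displacement_direction(tr, 1)
    expect_true(dd$defined)
    expect_equal(dd$direction, case$a)
  }
})

test_that("zero displacement carries the last defined direction", {
  mv <- make_line("p", "A", c(0, 0), c(1, 0), 2, 0, 1)
  still <- data.table::data.table(
    timestamp = seq(1.1, 2, by = 0.1), player_id = "p", team_id = "A",
    x = 2, y = 0)
  tr <- validate_tracking(rbind(mv, still))
  dd <- displacement_direction(tr, 2)
  expect_true(dd$defined)
  expect_equal(dd$direction, pi / 2) # carried from the moving phase
  # a player that never moved has no direction at all
  tr2 <- validate_tracking(data.table::data.table(
    timestamp = seq(0, 2, 0.1), player_id = "q", team_id = "A", x = 1, y = 1))
  expect_false(displacement_direction(tr2, 2)$defined)
})

test_that("to_relative translates, rotates, and is an isometry", {
  expect_equal(to_relative(3, 4, 0, 0, 0), cbind(rel_x = 3, rel_y = 4))
  # heading +x, location 5 m ahead along +x -> (0, 5)
  expect_equal(to_relative(5, 0, 0, 0, pi / 2), cbind(rel_x = 0, rel_y = 5),
               tolerance = 1e-12)
  withr::with_seed(11, {
    for (i in 1:25) {
      p <- runif(2, -50, 50); l <- runif(2, -50, 50)
      th <- runif(1, 0, 2 * pi)
      rel <- to_relative(l[1], l[2], p[1], p[2], th)
      expect_equal(sqrt(sum(rel^2)), sqrt(sum((l - p)^2)), tolerance = 1e-9)
    }
  })
})

test_that("relative coordinates are invariant under rigid field rotation", {
  withr::with_seed(12, {
    for (i in 1:25) {
      p <- runif(2, -40, 40); l <- runif(2, -40, 40)
      th <- runif(1, 0, 2 * pi)   # player heading (clockwise from +y)
      phi <- runif(1, 0, 2 * pi)  # field rotation (counter-clockwise)
      rot <- function(v) c(cos(phi) * v[1] - sin(phi) * v[2],
                           sin(phi) * v[1] + cos(phi) * v[2])
      # a ccw field rotation by phi decreases the clockwise heading by phi
      rel1 <- to_relative(l[1], l[2], p[1], p[2], th)
      lp <- rot(l); pp <- rot(p)
      rel2 <- to_relative(lp[1], lp[2], pp[1], pp[2],
                          (th - phi) %% (2 * pi))
      expect_equal(rel1, rel2, tolerance = 1e-9)
    }
  })
})

test_that("tracking CSV round-trips bit-exactly and reports schema errors", {
  sim <- shared_sim()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(sim$tracking, path)
  back <- read_tracking(path)
  # agreement at (well below) the documented 1e-6 m interchange precision
  expect_equal(back$x, sim$tracking$x, tolerance = 1e-9)
  expect_equal(back$y, sim$tracking$y, tolerance = 1e-9)
  expect_identical(back$timestamp, sim$tracking$timestamp)
  expect_identical(back$player_id, sim$tracking$player_id)
  # values already at file precision are a fixed point of write -> read
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_tracking(back, path2)
  again <- read_tracking(path2)
  expect_identical(again$x, back$x)
  expect_identical(again$y, back$y)
  # count check against generator bookkeeping: n players x m frames
  expect_equal(nrow(back),
               length(unique(back$player_id)) * length(unique(back$dsec)))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,player_id,x,y\n1,p1,0,0", bad)
  expect_error(read_tracking(bad), "missing column")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,player_id,team_id,x,y", "1,p1,A,zero,0"), bad2)
  expect_error(read_tracking(bad2), "non-numeric")
})

test_that("empty tracking file with header reads as empty", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,player_id,team_id,x,y", path)
  expect_equal(nrow(read_tracking(path)), 0)
})

test_that("transaction round-trip, ordering, and validation", {
  tx <- data.table::data.table(
    timestamp = c(5, 3), event_type = c("mark", "kick"),
    player_id = c("p2", "p1"), x = c(1.5, 0), y = c(-2, 0))
  v <- validate_transactions(tx)
  expect_equal(v$timestamp, c(3, 5)) # ordered
  path <- withr::local_tempfile(fileext = ".csv")
  write_transactions(v, path)
  expect_identical(read_transactions(path)$x, v$x)
  expect_error(validate_transactions(
    data.table::data.table(timestamp = 1, event_type = "tackle",
                           player_id = "p", x = 0, y = 0)),
    "event_type")
  expect_error(validate_transactions(
    data.table::data.table(timestamp = 1.5, event_type = "kick",
                           player_id = "p", x = 0, y = 0)),
    "whole seconds")
})

test_that("consolidate matches events to the start of their second", {
  tr <- validate_tracking(rbind(
    make_line("p1", "A", c(0, 0), c(1, 0), 2, 99, 101),
    make_line("p2", "B", c(10, 0), c(0, 1), 1, 99, 101)))
  tx <- validate_transactions(data.table::data.table(
    timestamp = 100, event_type = "kick", player_id = "p1", x = 2, y = 0))
  cons <- consolidate(tr, tx)
  expect_true(cons$transactions$matched)
  f <- cons$formations[[1]]
  # frame at 100.0, not a later sub-second frame
  expect_equal(f[f$player_id == "p1"]$x, 2) # moved 2 m in 1 s from x=0
  expect_equal(f[f$player_id == "p1"]$velocity, 2)
})

test_that("consolidate excludes passages with missing player tracks", {
  tr <- validate_tracking(rbind(
    make_line("p1", "A", c(0, 0), c(1, 0), 2, 99, 103),
    make_line("p2", "B", c(10, 0), c(0, 1), 1, 99, 100.5))) # p2 lost
  tx <- validate_transactions(data.table::data.table(
    timestamp = c(100, 102, 200),
    event_type = c("kick", "mark", "kick"),
    player_id = c("p1", "p1", "p1"), x = 0, y = 0))
  cons <- consolidate(tr, tx)
  expect_equal(cons$transactions$matched, c(TRUE, FALSE, FALSE))
  expect_equal(cons$transactions$reason[2], "missing_player_track")
  expect_equal(cons$transactions$reason[3], "outside_tracking_range")
})

test_that("every transaction of a complete synthetic match is matched", {
  sim <- shared_sim()
  cons <- consolidate(sim$tracking, sim$transactions)
  expect_true(all(cons$transactions$matched))
  # idempotent and never more formations than transactions
  cons2 <- consolidate(sim$tracking, cons$transactions[, !c("matched", "reason")])
  expect_equal(cons2$transactions$matched, cons$transactions$matched)
  expect_lte(sum(cons$transactions$matched), nrow(sim$transactions))
})
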