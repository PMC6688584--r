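# Seeded synthetic match generator. Emulates the structures the pipeline
# consumes: 10 Hz tracks for 36 on-field players (18 per side) on an oval
# field, whole-second transactions (mark -> kick -> mark or contest), ball
# flight at a constant speed, and a known ground-truth commitment process.
#
# Player movement: each player cruises towards a per-passage anchor at an
# individual preferred speed with Gaussian noise and a hard speed cap
# (mean-reverting velocities, smooth tracks). Around each planted contest,
# every player within 35 m draws commitment from a logistic ground-truth
# rule; committed players are steered to within 2 m of the contest location
# at contest time, non-committed players are kept outside 2 m. The rule is
# deliberately NOT in the fitted model's family (logistic vs KDE posterior)
# so recovery tests are non-circular.
#
# A ledger records every planted pass, contest and commitment draw with the
# true rule value, enabling exact (same-draw) cross-checks against the
# pipeline's extracted labels.

#' Simulation configuration
#'
#' Defaults describe a realistic elite-football world: 18 players per side
#' on a 160 x 129 m oval, 10 Hz tracking, 18.5 m/s ball flight, sprint
#' speeds capped at 10.5 m/s, pass distances 10-65 m (so whole-second ball
#' times-to-point span 1-4 s), and a forward-biased commitment rule whose
#' preferred commitment distance grows with player speed.
#'
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param n_passages number of pass passages to plant.
#' @param p_contest probability a pass ends in a contest (vs a clean mark).
#' @param players_per_team on-field players per side.
#' @param field a [field_spec()].
#' @param frame_rate tracking frequency, Hz.
#' @param ball_speed constant ball flight speed, m/s.
#' @param speed_cap maximum player speed, m/s.
#' @param cruise_range range of per-passage preferred speeds, m/s.
#' @param noise_accel standard deviation of velocity noise, m/s per sqrt(s).
#' @param pass_range pass distance range (min, max), metres.
#' @param decision_delay seconds a mark-taker holds before kicking.
#' @param warmup seconds of free play before the first mark.
#' @param commit_rule list of ground-truth rule parameters: `p_max` (ceiling
#'   probability), `mu_per_v` (preferred contest distance per unit speed,
#'   s), `base_reach` and `reach_scale` (logistic location/scale in metres),
#'   `time_decay` (per-second decay of commitment with time-to-point),
#'   `angle_base` (baseline forward bias) and `angle_penalty`
#'   (velocity-scaled addition to it).
#' @param match_id identifier written into outputs.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_passages = 60L, p_contest = 0.5,
                       players_per_team = 18L, field = field_spec(),
                       frame_rate = 10L, ball_speed = 18.5, speed_cap = 10.5,
                       cruise_range = c(0.3, 10), noise_accel = 0.8,
                       pass_range = c(10, 65), decision_delay = 2L,
                       warmup = 3L,
                       commit_rule = list(p_max = 0.95, mu_per_v = 1.25,
                                          base_reach = 3, reach_scale = 2,
                                          time_decay = 0.5,
                                          angle_base = 1,
                                          angle_penalty = 0.3),
                       match_id = "m1") {
  stopifnot(players_per_team >= 1, n_passages >= 1, ball_speed > 0,
            speed_cap >= 9, p_contest >= 0, p_contest <= 1,
            all(unlist(commit_rule[c("reach_scale", "time_decay")]) > 0))
  if (2 > min(field$axes))
    stop("infeasible config: commitment radius exceeds the field")
  structure(as.list(environment()), class = "sim_config")
}

#' Ground-truth commitment probability
#'
#' The generator's logistic rule: a player commits with probability
#' `p_max * plogis((base_reach - |d - mu_per_v * v|) / reach_scale)
#'  * exp(-time_decay * (t - 1))
#'  * exp(-(angle_base + angle_penalty * v) * (theta/pi)^2)`
#' where `d` is the distance to the contest, `v` the player speed, `t` the
#' ball time-to-point and `theta` the reorientation angle (0 = contest dead
#' ahead). The preferred commitment distance `mu_per_v * v` grows with
#' speed (moving players arrive at their natural braking point), the rule
#' decays with time-to-point, and the forward bias — present even at low
#' speed, since players face the play — strengthens with velocity so fast
#' players rarely commit behind themselves.
#'
#' @param distance metres from player (at kick time) to the contest.
#' @param velocity player speed at kick time, m/s.
#' @param time_to_point ball time-to-point, s.
#' @param angle reorientation angle in radians, `[0, pi]`.
#' @param rule parameter list (see [sim_config()]).
#' @return commitment probability in `[0, 1]`.
#' @export
sim_commit_prob <- function(distance, velocity, time_to_point, angle,
                            rule = sim_config()$commit_rule) {
  mu <- rule$mu_per_v * velocity
  rule$p_max *
    plogis((rule$base_reach - abs(distance - mu)) / rule$reach_scale) *
    exp(-rule$time_decay * (time_to_point - 1)) *
    exp(-(rule$angle_base + rule$angle_penalty * velocity) * (angle / pi)^2)
}

# sample a point uniformly inside a scaled copy of the elliptical field
sample_in_field <- function(n, field, shrink = 0.9) {
  a <- field$axes[1] / 2 * shrink
  b <- field$axes[2] / 2 * shrink
  r <- sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(a * r * cos(th), b * r * sin(th))
}

# pull a point radially towards the centre until inside the shrunken field
clamp_to_field <- function(p, field, shrink = 0.92) {
  a <- field$axes[1] / 2 * shrink
  b <- field$axes[2] / 2 * shrink
  s <- sqrt((p[1] / a)^2 + (p[2] / b)^2)
  if (s > 1) p / s else p
}

smoothstep <- function(tau) tau * tau * (3 - 2 * tau)

#' Simulate a synthetic match
#'
#' Runs the passage process described in the package's generator notes and
#' returns the tracking stream, the transaction stream, and the ground-truth
#' ledger (planted passes, contests, and per-player commitment draws with
#' the true rule values).
#'
#' @param config a [sim_config()].
#' @return list of class `"sim_match"` with `tracking`, `transactions`,
#'   `ledger` (list of `passes`, `contests`, `commitments`) and `config`.
#' @export
simulate_match <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  n <- 2L * config$players_per_team
  ids <- sprintf("p%02d", seq_len(n))
  teams <- rep(c("A", "B"), each = config$players_per_team)
  dt <- 1 / config$frame_rate
  fr <- config$frame_rate
  max_frames <- as.integer((config$warmup +
                              config$n_passages * 12 + 10) * fr)
  X <- matrix(NA_real_, max_frames, n)
  Y <- matrix(NA_real_, max_frames, n)

  P <- sample_in_field(n, config$field, shrink = 0.85)
  V <- matrix(rnorm(2 * n, 0, 0.5), n, 2)
  anchors <- P + matrix(rnorm(2 * n, 0, 5), n, 2)
  cruise <- runif(n, config$cruise_range[1], config$cruise_range[2])

  # steering overrides: per player, a precomputed path (frame -> position)
  steer_until <- integer(n)            # last overridden frame, 0 = none
  steer_path <- vector("list", n)      # matrix rows k_from..k_until
  steer_from <- integer(n)

  k <- 0L # last simulated frame (frame k holds time (k-1)*dt)
  step_frame <- function() {
    k <<- k + 1L
    if (k > 1L) {
      free <- steer_until < k
      if (any(free)) {
        d <- anchors[free, , drop = FALSE] - P[free, , drop = FALSE]
        dist <- sqrt(rowSums(d^2))
        des <- d * (cruise[free] / pmax(dist, 1e-9)) * pmin(dist / 3, 1)
        Vf <- V[free, , drop = FALSE]
        Vf <- Vf + (des - Vf) * (1.2 * dt) +
          matrix(rnorm(2 * sum(free), 0, config$noise_accel * sqrt(dt)),
                 ncol = 2)
        sp <- sqrt(rowSums(Vf^2))
        over <- sp > config$speed_cap
        if (any(over)) Vf[over, ] <- Vf[over, ] * config$speed_cap / sp[over]
        V[free, ] <<- Vf
        P[free, ] <<- P[free, , drop = FALSE] + Vf * dt
      }
      steered <- which(!free)
      for (pl in steered) {
        newp <- steer_path[[pl]][k - steer_from[pl], ]
        V[pl, ] <<- (newp - P[pl, ]) / dt
        P[pl, ] <<- newp
      }
    }
    # positions live at the documented interchange precision (1e-6 m) so
    # in-memory streams, CSV round-trips and the ledger agree exactly
    P[, ] <<- round(P, 6)
    X[k, ] <<- P[, 1]
    Y[k, ] <<- P[, 2]
  }
  advance_to <- function(t) { # simulate up to and including time t
    target <- as.integer(round(t * fr)) + 1L
    while (k < target) step_frame()
  }
  frame_of <- function(t) as.integer(round(t * fr)) + 1L

  plan_steer <- function(pl, k_from, k_to, endpoint) {
    nk <- k_to - k_from
    tau <- seq_len(nk) / nk
    start <- P[pl, ]
    base <- cbind(start[1] + (endpoint[1] - start[1]) * smoothstep(tau),
                  start[2] + (endpoint[2] - start[2]) * smoothstep(tau))
    wig <- rnorm(2, 0, 0.3)
    base[, 1] <- base[, 1] + wig[1] * sin(pi * tau)
    base[, 2] <- base[, 2] + wig[2] * sin(pi * tau)
    base[nk, ] <- endpoint
    steer_path[[pl]] <<- base
    steer_from[pl] <<- k_from
    steer_until[pl] <<- k_to
  }

  tx <- list(); passes <- list(); contests <- list(); commits <- list()
  add_tx <- function(t, type, pl, x, y)
    tx[[length(tx) + 1L]] <<- data.table::data.table(
      timestamp = t, event_type = type, player_id = pl,
      x = round(x, 6), y = round(y, 6))

  advance_to(config$warmup)
  holder <- which.min(rowSums((P - sample_in_field(1, config$field,
                                                   0.3)[rep(1, n), ])^2))
  t_now <- config$warmup
  add_tx(t_now, "mark", ids[holder], P[holder, 1], P[holder, 2])
  n_contests <- 0L

  for (pass_i in seq_len(config$n_passages)) {
    anchors <- P + sample_in_field(n, config$field, 0.35)
    for (i in seq_len(n)) anchors[i, ] <- clamp_to_field(anchors[i, ],
                                                         config$field)
    cruise <- runif(n, config$cruise_range[1], config$cruise_range[2])
    cruise[holder] <- min(cruise[holder], 1.5) # mark-taker settles

    # decide the passage outcome now so that, for contests, nearby players
    # from both teams can read the play and converge on the drop zone
    # during the hold (real contests draw packs)
    is_contest <- runif(1) < config$p_contest
    intended <- NA_integer_
    if (is_contest) {
      kd <- sqrt((P[, 1] - P[holder, 1])^2 + (P[, 2] - P[holder, 2])^2)
      recv_pool <- which(teams == teams[holder] & seq_len(n) != holder &
                           kd >= config$pass_range[1] &
                           kd <= config$pass_range[2])
      if (length(recv_pool)) {
        opp <- which(teams != teams[holder])
        nearest_opp <- vapply(recv_pool, function(rv)
          min(sqrt((P[opp, 1] - P[rv, 1])^2 + (P[opp, 2] - P[rv, 2])^2)),
          numeric(1))
        pool <- recv_pool[nearest_opp <= 15]
        intended <- if (length(pool)) pool[sample.int(length(pool), 1)]
          else recv_pool[sample.int(length(recv_pool), 1)]
        zone <- P[intended, ]
        others <- setdiff(seq_len(n), c(holder, intended))
        zd <- sqrt((P[others, 1] - zone[1])^2 + (P[others, 2] - zone[2])^2)
        pack <- others[order(zd)][seq_len(min(5, length(others)))]
        pack <- pack[zd[order(zd)][seq_along(pack)] <= 30]
        for (pl in pack) {
          anchors[pl, ] <- clamp_to_field(zone + rnorm(2, 0, 3),
                                          config$field)
          cruise[pl] <- runif(1, 5, config$cruise_range[2])
        }
        anchors[intended, ] <- clamp_to_field(zone + rnorm(2, 0, 2),
                                              config$field)
      }
    }

    t_p <- t_now + config$decision_delay
    advance_to(t_p)
    kick_loc <- P[holder, ]
    add_tx(t_p, "kick", ids[holder], kick_loc[1], kick_loc[2])
    k_p <- frame_of(t_p)

    if (is_contest) {
      # plant the contest at the pass destination near the intended
      # receiver, falling back to a random reachable location
      target <- NULL
      if (!is.na(intended)) {
        cand <- P[intended, ] + rnorm(2, 0, 2.5)
        if (in_field(cand[1], cand[2], config$field)) target <- cand
      }
      if (is.null(target)) {
        for (try in 1:50) {
          d <- runif(1, config$pass_range[1], config$pass_range[2])
          th <- runif(1, 0, 2 * pi)
          cand <- kick_loc + d * c(cos(th), sin(th))
          if (in_field(cand[1], cand[2], config$field)) {
            target <- cand
            break
          }
        }
      }
      if (is.null(target))
        target <- clamp_to_field(kick_loc + d * c(cos(th), sin(th)),
                                 config$field)
      d <- sqrt(sum((target - kick_loc)^2))
      ttp <- max(1L, as.integer(ceiling(d / config$ball_speed)))
      t_c <- t_p + ttp
      k_c <- frame_of(t_c)
      n_contests <- n_contests + 1L

      # ground-truth commitment draws for every player within 35 m
      pd <- sqrt((P[, 1] - target[1])^2 + (P[, 2] - target[2])^2)
      elig <- which(pd <= 35)
      vel <- sqrt((X[k_p, ] - X[k_p - fr, ])^2 +
                    (Y[k_p, ] - Y[k_p - fr, ])^2)
      hx <- X[k_p, ] - X[k_p - 1L, ]; hy <- Y[k_p, ] - Y[k_p - 1L, ]
      committed_set <- integer(0)
      if (length(elig)) {
        ang <- vapply(elig, function(pl) {
          hv <- c(hx[pl], hy[pl]); cv <- target - P[pl, ]
          nh <- sqrt(sum(hv^2)); ncv <- sqrt(sum(cv^2))
          if (nh < 1e-12 || ncv < 1e-12) return(0)
          acos(max(-1, min(1, sum(hv * cv) / (nh * ncv))))
        }, numeric(1))
        p_true <- sim_commit_prob(pd[elig], vel[elig], ttp, ang,
                                  config$commit_rule)
        draw <- runif(length(elig)) < p_true
        committed_set <- elig[draw]
        commits[[length(commits) + 1L]] <- data.table::data.table(
          contest_id = n_contests, player_id = ids[elig],
          distance = pd[elig], velocity = vel[elig],
          time_to_point = as.numeric(ttp), angle = ang,
          p_true = p_true, committed = as.integer(draw))
      }
      for (pl in committed_set) {
        rr <- sqrt(runif(1)) * 1.5; aa <- runif(1, 0, 2 * pi)
        plan_steer(pl, k_p, k_c, target + rr * c(cos(aa), sin(aa)))
      }
      advance_to(t_c)
      # keep non-committed eligible players honestly outside 2 m
      for (pl in setdiff(elig, committed_set)) {
        dd <- sqrt(sum((P[pl, ] - target)^2))
        if (dd < 2.3) {
          u <- if (dd > 1e-9) (P[pl, ] - target) / dd else c(1, 0)
          newp <- target + u * runif(1, 2.6, 3.5)
          delta <- newp - P[pl, ]
          ramp <- (seq_len(k_c - k_p)) / (k_c - k_p)
          idx <- (k_p + 1L):k_c
          X[idx, pl] <- round(X[idx, pl] + delta[1] * ramp, 6)
          Y[idx, pl] <- round(Y[idx, pl] + delta[2] * ramp, 6)
          P[pl, ] <- c(X[k_c, pl], Y[k_c, pl])
          V[pl, ] <- c(X[k_c, pl] - X[k_c - 1L, pl],
                       Y[k_c, pl] - Y[k_c - 1L, pl]) / dt
        }
      }
      near <- which.min(sqrt((P[, 1] - target[1])^2 +
                               (P[, 2] - target[2])^2))
      ctype <- if (runif(1) < 0.5) "spoil" else "contested_mark"
      add_tx(t_c, ctype, ids[near], target[1], target[2])
      contests[[length(contests) + 1L]] <- data.table::data.table(
        contest_id = n_contests, t_p = t_p, t_c = t_c,
        x = target[1], y = target[2], contest_type = ctype,
        n_eligible = length(elig), n_committed = length(committed_set))
      passes[[length(passes) + 1L]] <- data.table::data.table(
        pass_id = pass_i, t_p = t_p, kicker_id = ids[holder],
        outcome = "contest", target_x = target[1], target_y = target[2],
        distance = d, time_to_point = as.numeric(ttp))
      # loose ball gathered: a nearby player marks 2 s later
      t_now <- t_c + 2
      advance_to(t_now)
      holder <- near
      add_tx(t_now, "mark", ids[holder], P[holder, 1], P[holder, 2])
    } else {
      # clean pass to a teammate
      mates <- which(teams == teams[holder] & seq_len(n) != holder)
      md <- sqrt((P[mates, 1] - kick_loc[1])^2 +
                   (P[mates, 2] - kick_loc[2])^2)
      inrange <- mates[md >= 16 & md <= 55]
      recv <- if (length(inrange)) inrange[sample.int(length(inrange), 1)]
        else mates[which.min(abs(md - 30))]
      lead <- V[recv, ] * 0.5
      target <- clamp_to_field(P[recv, ] + lead + rnorm(2, 0, 1),
                               config$field)
      d <- sqrt(sum((target - kick_loc)^2))
      if (d < 15.5) {
        target <- kick_loc + (target - kick_loc) * (16 / max(d, 1e-9))
        d <- 16
      } else if (d > 58) {
        target <- kick_loc + (target - kick_loc) * (58 / d)
        d <- 58
      }
      ttp <- max(1L, as.integer(ceiling(d / config$ball_speed)))
      t_r <- t_p + ttp
      plan_steer(recv, k_p, frame_of(t_r), target)
      advance_to(t_r)
      add_tx(t_r, "mark", ids[recv], target[1], target[2])
      passes[[length(passes) + 1L]] <- data.table::data.table(
        pass_id = pass_i, t_p = t_p, kicker_id = ids[holder],
        outcome = "mark", target_x = target[1], target_y = target[2],
        distance = d, time_to_point = as.numeric(ttp))
      holder <- recv
      t_now <- t_r
    }
  }

  advance_to(t_now + 1)
  used <- seq_len(k)
  times <- (used - 1L) / fr
  tracking <- data.table::data.table(
    timestamp = rep(times, n),
    player_id = rep(ids, each = length(used)),
    team_id = rep(teams, each = length(used)),
    x = as.vector(X[used, ]), y = as.vector(Y[used, ]))
  tracking <- validate_tracking(tracking, where = "simulate_match")
  transactions <- validate_transactions(data.table::rbindlist(tx),
                                        where = "simulate_match")
  ledger <- list(
    passes = data.table::rbindlist(passes),
    contests = if (length(contests)) data.table::rbindlist(contests)
      else data.table::data.table(),
    commitments = if (length(commits)) data.table::rbindlist(commits)
      else data.table::data.table())
  structure(list(tracking = tracking, transactions = transactions,
                 ledger = ledger, config = config),
            class = "sim_match")
}

#' @export
print.sim_match <- function(x, ...) {
  cat(sprintf(
    "synthetic match %s: %d frames x %d players, %d transactions, %d contests\n",
    x$config$match_id, length(unique(x$tracking$dsec)),
    2 * x$config$players_per_team, nrow(x$transactions),
    if (nrow(x$ledger$contests)) nrow(x$ledger$contests) else 0L))
  invisible(x)
}

#' Write a simulated match to a directory
#'
#' Writes `tracking.csv`, `transactions.csv` and `ledger.csv` (commitment
#' draws joined with their contest metadata).
#'
#' @param sim a [simulate_match()] result.
#' @param dir destination directory (created if needed).
#' @export
write_match <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tracking(sim$tracking, file.path(dir, "tracking.csv"))
  write_transactions(sim$transactions, file.path(dir, "transactions.csv"))
  led <- merge(sim$ledger$commitments,
               sim$ledger$contests[, list(contest_id, t_p, t_c,
                                          contest_type)],
               by = "contest_id")
  data.table::fwrite(led, file.path(dir, "ledger.csv"))
  invisible(dir)
}

#' Build a pooled commitment training corpus from simulated matches
#'
#' Simulates `n_matches` independent matches (seeds derived from `seed`),
#' runs the full extraction pipeline (consolidate, extract contests, build
#' observations) on each, and pools the observations. With the defaults
#' (8 matches x 400 all-contest passages) the corpus holds ~3200 contests
#' and ~30000 observations.
#'
#' @param seed base seed; match `i` uses `seed * 1000 + i`.
#' @param n_matches number of matches to simulate.
#' @param n_passages passages per match.
#' @param p_contest contest probability per passage.
#' @return list with `observations` (pooled table), `n_contests`,
#'   `n_ledger_rows` and `n_ledger_committed` (ground-truth bookkeeping).
#' @export
build_commitment_corpus <- function(seed = 1L, n_matches = 8L,
                                    n_passages = 400L, p_contest = 1) {
  per <- lapply(seq_len(n_matches), function(i) {
    cfg <- sim_config(seed = as.integer(seed * 1000L + i),
                      n_passages = n_passages, p_contest = p_contest,
                      match_id = sprintf("m%02d", i))
    sim <- simulate_match(cfg)
    cons <- consolidate(sim$tracking, sim$transactions)
    ct <- extract_contests(cons)
    list(obs = build_observations(ct, sim$tracking),
         n_contests = length(ct),
         n_ledger = nrow(sim$ledger$commitments),
         n_committed = sum(sim$ledger$commitments$committed))
  })
  list(observations = data.table::rbindlist(lapply(per, `[[`, "obs")),
       n_contests = sum(vapply(per, `[[`, integer(1), "n_contests")),
       n_ledger_rows = sum(vapply(per, function(p) as.integer(p$n_ledger),
                                  integer(1))),
       n_ledger_committed = sum(vapply(per, function(p)
         as.integer(p$n_committed), integer(1))))
}

#' Deterministic miniature fixtures for tests and examples
#'
#' Registry of small, fully-deterministic datasets:
#' \describe{
#'   \item{`two_player_contest`}{two players, one contest, exactly two
#'     commitment observations with known labels.}
#'   \item{`symmetric_field`}{a formation mirrored about the field centre
#'     plus a small commitment model, so dominance at the midpoint is 0.5.}
#'   \item{`planted_optimum`}{a formation with a uniquely dominant
#'     high-equity teammate, a small model, and an equity provider; the
#'     planted option is the optimal alternative and a pass to it has DV 1.}
#'   \item{`mini_match`}{a short simulated match (seed 42, 12 passages).}
#' }
#'
#' @param name fixture name.
#' @return fixture contents (varies by fixture, see details).
#' @export
make_fixture <- function(name) {
  switch(name,
    two_player_contest = fixture_two_player_contest(),
    symmetric_field = fixture_symmetric_field(),
    planted_optimum = fixture_planted_optimum(),
    mini_match = simulate_match(sim_config(seed = 42L, n_passages = 12L,
                                           match_id = "fixture")),
    stop("unknown fixture: ", name)
  )
}

# straight-line track builder: player runs from `from` at `vel` m/s along
# `dir` (unit vector) from t0 to t1
line_track <- function(player_id, team_id, from, dir, vel, t0, t1, fr = 10) {
  t <- seq(t0, t1, by = 1 / fr)
  data.table::data.table(
    timestamp = t, player_id = player_id, team_id = team_id,
    x = from[1] + dir[1] * vel * (t - t0),
    y = from[2] + dir[2] * vel * (t - t0))
}

fixture_two_player_contest <- function() {
  # kick at t=2, spoil at t=4 at (0, 20); p1 (team A) runs +y and arrives
  # (ends 0.5 m short), p2 (team B) ambles +y to the side and does not
  tr <- rbind(
    line_track("p1", "A", c(0, 0.5), c(0, 1), 5, 0, 4.2),
    line_track("p2", "B", c(20, 12), c(0, 1), 2, 0, 4.2))
  tx <- data.table::data.table(
    timestamp = c(2, 4),
    event_type = c("kick", "spoil"),
    player_id = c("p1", "p2"),
    x = c(0, 0), y = c(0, 20))
  list(tracking = validate_tracking(tr),
       transactions = validate_transactions(tx),
       expected = list(n_observations = 2L,
                       committed = c(p1 = 1L, p2 = 0L)))
}

# a small deterministic commitment corpus: committed rows cluster just ahead
# of the player, non-committed rows spread over the 35 m disc
toy_model <- function(n1 = 40L, n0 = 160L, seed = 7L, bandwidth = 1.5) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  obs1 <- data.table::data.table(
    velocity = runif(n1, 1, 6), time_to_point = runif(n1, 1, 3),
    rel_x = rnorm(n1, 0, 1.5), rel_y = rnorm(n1, 2, 1.5), committed = 1L)
  r <- sqrt(runif(n0)) * 35; a <- runif(n0, 0, 2 * pi)
  obs0 <- data.table::data.table(
    velocity = runif(n0, 1, 6), time_to_point = runif(n0, 1, 3),
    rel_x = r * cos(a), rel_y = r * sin(a), committed = 0L)
  fit_commitment(rbind(obs1, obs0), bandwidth = bandwidth)
}

# a 5 v 5 formation mirrored through the origin; all players stationary-ish
# (direction +y, velocity 2) so the two teams are exact mirror images
fixture_symmetric_field <- function() {
  xs <- c(-20, -10, 0, 10, 20)
  f <- data.table::data.table(
    player_id = sprintf("p%02d", 1:10),
    team_id = rep(c("A", "B"), each = 5),
    x = c(xs, -xs), y = c(rep(-10, 5), rep(10, 5)),
    velocity = 2, velocity_defined = TRUE,
    direction = c(rep(0, 5), rep(pi, 5)), direction_defined = TRUE)
  list(formation = f, model = toy_model(), midpoint = c(0, 0))
}

fixture_planted_optimum <- function() {
  model <- toy_model()
  equity <- equity_surrogate()
  # kicker k1 at midfield; teammate t1 free in high-equity space ahead,
  # other teammates well covered by opponents in low-equity space behind
  f <- data.table::data.table(
    player_id = c("k1", "t1", "t2", "t3", "o1", "o2", "o3", "o4"),
    team_id = c("A", "A", "A", "A", "B", "B", "B", "B"),
    x = c(0, 35, -25, -30, -25, -30, 20, -45),
    y = c(0, 5, -10, 15, -10, 15, -30, 0),
    velocity = 2, velocity_defined = TRUE,
    direction = 0, direction_defined = TRUE)
  list(formation = f, model = model, equity = equity,
       kicker_id = "k1", planted_id = "t1", planted_location = c(35, 5))
}
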