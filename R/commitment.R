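# Commitment modelling: contests, the two-class training set, and the 4-D
# kernel density posterior that serves as the player motion model.
#
# A contest is a spoil or contested mark following a pass whose kick and
# receive locations can both be inferred from the consolidated streams.
# For each contest and each player within 35 m of the contest location at the
# time of the preceding kick, one training row is recorded:
#   (velocity [m/s], time_to_point [s], rel_x [m], rel_y [m], committed {0,1})
# with features taken at the kick instant t_p, the contest location expressed
# in the player's displacement frame, and committed = 1 iff the player ended
# within 2 m of the contest at the contest instant t_c.

#' Extract contest events from consolidated streams
#'
#' A qualifying contest is a `spoil` or `contested_mark` transaction with a
#' matched formation, preceded by a `kick` transaction that also has a matched
#' formation (the kick supplies the pass origin and the formation at the time
#' of the pass). Contests without a locatable preceding pass are skipped and
#' counted.
#'
#' @param cons a [consolidate()] result.
#' @return a list of contest events, each a list with `t_p`, `t_c`,
#'   `contest_x`, `contest_y`, `kick_x`, `kick_y`, `contest_type`, `event_id`
#'   and `formation` (the formation at `t_p`); the number of skipped contests
#'   is attached as attribute `"skipped"`.
#' @export
extract_contests <- function(cons) {
  tx <- cons$transactions
  out <- list()
  skipped <- 0L
  contest_rows <- which(tx$event_type %in% CONTEST_TYPES)
  for (i in contest_rows) {
    prior <- which(tx$event_type == "kick" & tx$timestamp < tx$timestamp[i] &
                     tx$matched)
    if (!length(prior) || !tx$matched[i]) {
      skipped <- skipped + 1L
      next
    }
    j <- prior[length(prior)]
    out[[length(out) + 1L]] <- list(
      event_id = tx$event_id[i],
      t_p = tx$timestamp[j], t_c = tx$timestamp[i],
      kick_x = tx$x[j], kick_y = tx$y[j],
      contest_x = tx$x[i], contest_y = tx$y[i],
      contest_type = tx$event_type[i],
      formation = cons$formations[[j]])
  }
  attr(out, "skipped") <- skipped
  out
}

#' Label commitment from distance to the contest
#'
#' A player committed to a contest iff their Euclidean distance from the
#' contest location at the contest instant is at most `radius` (default 2 m).
#'
#' @param distance metres from the contest location at `t_c`.
#' @param radius commitment radius in metres.
#' @return integer 0/1 vector.
#' @export
label_commitment <- function(distance, radius = 2) {
  as.integer(distance <= radius)
}

#' Build the commitment training set
#'
#' One observation per (contest, player) pair for every on-field player whose
#' velocity and direction are defined at the kick instant and who is within
#' `max_radius` (default 35 m) of the contest location at that instant.
#' Players with undefined kinematics are skipped and counted.
#'
#' @param contests output of [extract_contests()].
#' @param tracking validated tracking table (for positions at `t_c`).
#' @param max_radius inclusion radius around the contest location, metres.
#' @param commit_radius commitment labelling radius, metres.
#' @return a `data.table` with columns `velocity`, `time_to_point`, `rel_x`,
#'   `rel_y`, `committed`, plus bookkeeping columns `contest_id`, `player_id`;
#'   skipped-player count attached as attribute `"skipped_players"`.
#' @export
build_observations <- function(contests, tracking, max_radius = 35,
                               commit_radius = 2) {
  tracking <- data.table::as.data.table(tracking)
  data.table::setindex(tracking, dsec)
  rows <- vector("list", length(contests))
  skipped <- 0L
  for (ci in seq_along(contests)) {
    ct <- contests[[ci]]
    f <- ct$formation
    if (is.null(f)) next
    d_tp <- sqrt((f$x - ct$contest_x)^2 + (f$y - ct$contest_y)^2)
    elig <- d_tp <= max_radius
    bad <- elig & !(f$velocity_defined & f$direction_defined)
    skipped <- skipped + sum(bad)
    elig <- elig & !bad
    if (!any(elig)) next
    g <- f[elig]
    rel <- to_relative(ct$contest_x, ct$contest_y, g$x, g$y, g$direction)
    at_tc <- frame_at(tracking, dsec_of(ct$t_c))[
      , list(player_id, xc = x, yc = y)]
    g2 <- merge(g[, list(player_id, velocity)], at_tc, by = "player_id")
    if (nrow(g2) != nrow(g)) {
      # a tracked player vanished between t_p and t_c; drop the pair
      keep <- g$player_id %in% g2$player_id
      rel <- rel[keep, , drop = FALSE]
      g <- g[keep]
      g2 <- g2[match(g$player_id, g2$player_id)]
    } else {
      g2 <- g2[match(g$player_id, g2$player_id)]
    }
    d_tc <- sqrt((g2$xc - ct$contest_x)^2 + (g2$yc - ct$contest_y)^2)
    rows[[ci]] <- data.table::data.table(
      contest_id = ci, player_id = g$player_id,
      velocity = g$velocity, time_to_point = ct$t_c - ct$t_p,
      rel_x = rel[, 1], rel_y = rel[, 2],
      committed = label_commitment(d_tc, commit_radius))
  }
  out <- data.table::rbindlist(rows)
  if (!nrow(out))
    out <- data.table::data.table(
      contest_id = integer(), player_id = character(), velocity = numeric(),
      time_to_point = numeric(), rel_x = numeric(), rel_y = numeric(),
      committed = integer())
  attr(out, "skipped_players") <- skipped
  out[]
}

obs_matrix <- function(obs) {
  cbind(velocity = obs$velocity, time_to_point = obs$time_to_point,
        rel_x = obs$rel_x, rel_y = obs$rel_y)
}

#' Class-prior weight from class sizes
#'
#' `w = n1 / (n1 + n0)`: the size of the committed class over the total.
#' @param n1,n0 committed / non-committed row counts.
#' @return weight in (0, 1).
#' @export
commitment_weight <- function(n1, n0) {
  stopifnot(n1 > 0, n0 > 0)
  n1 / (n1 + n0)
}

#' Fit the two-class commitment model
#'
#' Fits a Gaussian-kernel density estimate separately to the committed and
#' non-committed rows of the 4-D feature space (velocity, time-to-point,
#' rel_x, rel_y), with a single shared bandwidth applied to all four
#' dimensions without standardisation. The class prior `w` is the committed
#' fraction of the training set. The fit is deterministic given the rows.
#'
#' @param observations a table with columns `velocity`, `time_to_point`,
#'   `rel_x`, `rel_y`, `committed`.
#' @param bandwidth kernel bandwidth (default 1.5, shared across dimensions).
#' @return an object of class `"commitment_model"`.
#' @export
fit_commitment <- function(observations, bandwidth = 1.5) {
  obs <- data.table::as.data.table(observations)
  need <- c("velocity", "time_to_point", "rel_x", "rel_y", "committed")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observations missing column(s): ", paste(miss, collapse = ", "))
  x1 <- obs_matrix(obs[committed == 1])
  x0 <- obs_matrix(obs[committed == 0])
  if (nrow(x1) < 2 || nrow(x0) < 2)
    stop("fit_commitment: each commitment class needs at least 2 rows ",
         "(got ", nrow(x1), " committed, ", nrow(x0), " non-committed); ",
         "provide a larger training corpus")
  structure(list(
    x1 = x1, x0 = x0,
    n1 = nrow(x1), n0 = nrow(x0),
    w = commitment_weight(nrow(x1), nrow(x0)),
    bandwidth = bandwidth, kernel = "gaussian"),
    class = "commitment_model")
}

#' @export
print.commitment_model <- function(x, ...) {
  cat(sprintf(
    "commitment model: n1 = %d, n0 = %d, w = %.4f, bandwidth = %.3g\n",
    x$n1, x$n0, x$w, x$bandwidth))
  invisible(x)
}

#' Commitment probability (the motion model posterior)
#'
#' Evaluates `Pr = w f1 / (w f1 + (1 - w) f0)` at query features, where `f1`
#' and `f0` are the fitted class densities. Far from all training data both
#' densities underflow to zero and the probability is defined as 0 (no
#' influence); an attribute `"underflow"` flags such rows.
#'
#' @param model a [fit_commitment()] model.
#' @param velocity,time_to_point,rel_x,rel_y query features (recycled to a
#'   common length).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
commit_probability <- function(model, velocity, time_to_point, rel_x, rel_y) {
  q <- cbind(velocity, time_to_point, rel_x, rel_y)
  p <- kde_posterior_cpp(q, model$x1, model$x0, model$w, model$bandwidth)
  # recompute the underflow flag cheaply: a zero posterior with a zero
  # non-committed density means both classes vanished numerically
  zero <- p == 0
  if (any(zero)) {
    f0 <- kde_density_cpp(q[zero, , drop = FALSE], model$x0, model$bandwidth)
    attr(p, "underflow") <- which(zero)[f0 == 0]
  }
  p
}

#' Class density evaluation
#'
#' Evaluates one of the fitted class densities (`f1` for committed, `f0` for
#' non-committed) at query features. Mainly useful for diagnostics and for
#' checking that each density integrates to ~1.
#'
#' @inheritParams commit_probability
#' @param class 1 or 0.
#' @return numeric density values.
#' @export
class_density <- function(model, velocity, time_to_point, rel_x, rel_y,
                          class = 1) {
  q <- cbind(velocity, time_to_point, rel_x, rel_y)
  kde_density_cpp(q, if (class == 1) model$x1 else model$x0, model$bandwidth)
}

#' Motion-model surface on a relative-coordinate grid
#'
#' Samples the commitment probability over `(rel_x, rel_y)` at fixed velocity
#' and time-to-point. Cells sit at integer-metre centres by default.
#'
#' @param model a [fit_commitment()] model.
#' @param velocity player speed, m/s.
#' @param time_to_point ball time-to-point, s.
#' @param half_width grid half-width in metres (default 35).
#' @param step cell size in metres (default 1).
#' @param min_evidence evidence floor for peak detection: cells whose
#'   combined (both-class) kernel mass amounts to fewer than this many
#'   training rows are excluded from the argmax. A ratio of two density
#'   estimates is unreliable where both are near zero, so an isolated
#'   training row in an otherwise empty region can spike the posterior;
#'   the floor keeps the reported peak on supported ground. The probability
#'   surface itself is returned unmasked.
#' @return a list with `rel_x`, `rel_y` (axis coordinates), `prob` (matrix,
#'   rows indexed by `rel_x`), `peak` (list with `rel_x`, `rel_y`, `value`)
#'   and `evidence` (per-cell kernel-mass counts).
#' @export
motion_model_grid <- function(model, velocity, time_to_point,
                              half_width = 35, step = 1, min_evidence = 5) {
  ax <- seq(-half_width, half_width, by = step)
  # at a fixed (velocity, time) slice the Gaussian product kernel separates:
  # each training row contributes a_j * exp(-(x-xj)^2/2h^2) (x) exp(-(y-yj)^2/2h^2),
  # so the whole grid is two crossproducts (rows x axis) per class
  slice_sum <- function(xm) {
    h2 <- 2 * model$bandwidth^2
    a <- exp(-((velocity - xm[, 1])^2 + (time_to_point - xm[, 2])^2) / h2)
    u <- exp(-outer(xm[, 3], ax, `-`)^2 / h2) * a # n x |ax|, rel_x part
    w <- exp(-outer(xm[, 4], ax, `-`)^2 / h2)     # n x |ax|, rel_y part
    crossprod(u, w)
  }
  k1 <- slice_sum(model$x1) # unnormalised kernel mass ~ local row counts
  k0 <- slice_sum(model$x0)
  s1 <- model$w * k1 / model$n1
  s0 <- (1 - model$w) * k0 / model$n0
  tot <- s1 + s0
  m <- ifelse(tot > 0, s1 / tot, 0)
  dimnames(m) <- list(ax, ax)
  evidence <- k1 + k0
  msearch <- m
  msearch[evidence < min_evidence] <- -Inf
  if (all(msearch == -Inf)) msearch <- m # degenerate tiny models
  i <- arrayInd(which.max(msearch), dim(m))
  list(rel_x = ax, rel_y = ax, prob = m, evidence = evidence,
       peak = list(rel_x = ax[i[1]], rel_y = ax[i[2]],
                   value = m[i[1], i[2]]))
}

#' Save a commitment model archive
#'
#' Writes the training rows and metadata (bandwidth, weight, kernel, version)
#' to a directory, sufficient to refit deterministically with
#' [load_commitment_model()].
#'
#' @param model a commitment model.
#' @param dir destination directory (created if needed).
#' @export
save_commitment_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- rbind(
    data.table::data.table(model$x1, committed = 1L),
    data.table::data.table(model$x0, committed = 0L))
  data.table::fwrite(obs, file.path(dir, "observations.csv"))
  jsonlite::write_json(
    list(bandwidth = model$bandwidth, w = model$w, kernel = model$kernel,
         n1 = model$n1, n0 = model$n0,
         package_version = as.character(utils::packageVersion("commitval"))),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a commitment model archive
#' @param dir a directory written by [save_commitment_model()].
#' @return a `"commitment_model"`.
#' @export
load_commitment_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  obs <- data.table::fread(file.path(dir, "observations.csv"))
  m <- fit_commitment(obs, bandwidth = meta$bandwidth)
  stopifnot(m$n1 == meta$n1, m$n0 == meta$n0)
  m
}
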