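# Pass decision valuation: expected outcome (EO) of every location in the
# kicker's range, kicking-variance smoothing, decision value (DV) relative
# to the best alternative, and evaluation of executed mark-to-mark passes.
#
#   EO(x)    = (p_A + p_B) e_a(x) - (p_C + p_D) e_o(x)
#   EO_mod(x)= truncated-Gaussian-weighted average of raw EO in a radius
#              r = 5% of the kicking distance around x (weights renormalised
#              so a constant field is a fixed point; r below one cell leaves
#              the raw value)
#   DV       = EO_decision / EO_opt, clamped below at -1; undefined when
#              EO_opt <= 0 (sign flip), such events are excluded from DV
#              summaries.

#' Raw expected-outcome surface
#'
#' Combines a control surface with an equity provider:
#' `EO = (p_a + p_b) * e_a - (p_c + p_d) * e_o`, where `e_a` is the equity
#' for the attacking team and `e_o` the equity for their opponent (the
#' mirrored-direction lookup) at the same cell.
#'
#' @param surface a [control_surface()].
#' @param equity_model an equity provider.
#' @param attacking_direction +1 if the attacking team attacks towards +x.
#' @return list of class `"eo_surface"` with `grid`, `eo` (raw matrix) and
#'   the inputs needed for smoothing.
#' @export
expected_outcome <- function(surface, equity_model, attacking_direction = 1L) {
  cells <- grid_cells(surface$grid)
  e_a <- equity_value(equity_model, cells$x, cells$y, attacking_direction,
                      strict = FALSE)
  e_o <- equity_value(equity_model, cells$x, cells$y, -attacking_direction,
                      strict = FALSE)
  eo <- (as.vector(surface$p_a) + as.vector(surface$p_b)) * e_a -
    (as.vector(surface$p_c) + as.vector(surface$p_d)) * e_o
  structure(list(grid = surface$grid, eo = grid_matrix(surface$grid, eo),
                 ball = surface$ball,
                 attacking_direction = attacking_direction),
            class = "eo_surface")
}

#' Kicking-variance smoothing of an EO surface
#'
#' Models imperfect kicking accuracy: the likely landing point of a kick to
#' `x` is an isotropic 2-D Gaussian centred at `x` with standard deviation
#' equal to 5% of the kicking distance. The modified EO is the weighted sum
#' of raw EO over the integer cells within that radius, with the truncated
#' Gaussian weights renormalised to sum to one. When the radius is below one
#' cell (short kicks) the raw value is kept.
#'
#' @param eo_surface an [expected_outcome()] result.
#' @param kicker length-2 kicker location, metres; defaults to the surface's
#'   ball origin.
#' @param spread_fraction standard deviation (and neighbourhood radius) as a
#'   fraction of kicking distance.
#' @return the surface with an added `eo_mod` matrix.
#' @export
kick_smoothing <- function(eo_surface, kicker = eo_surface$ball,
                           spread_fraction = 0.05) {
  grid <- eo_surface$grid
  step <- grid$step
  raw <- eo_surface$eo
  nx <- length(grid$gx); ny <- length(grid$gy)
  out <- raw
  cx <- grid$gx; cy <- grid$gy
  dist_k <- sqrt(outer(cx - kicker[1], cy - kicker[2],
                       function(a, b) a^2 + b^2))
  r_all <- spread_fraction * dist_k
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      r <- r_all[i, j]
      if (r < step) next
      ic <- ceiling(r / step)
      ii <- max(1, i - ic):min(nx, i + ic)
      jj <- max(1, j - ic):min(ny, j + ic)
      dx <- (cx[ii] - cx[i])
      dy <- (cy[jj] - cy[j])
      d2 <- outer(dx^2, dy^2, `+`)
      w <- exp(-d2 / (2 * r^2))
      w[d2 > r^2] <- 0
      sw <- sum(w)
      if (sw > 0) out[i, j] <- sum(w * raw[ii, jj]) / sw
    }
  }
  eo_surface$eo_mod <- out
  eo_surface$kicker <- kicker
  eo_surface
}

eo_at <- function(eo_surface, x, y, which = c("eo_mod", "eo")) {
  which <- match.arg(which)
  m <- eo_surface[[which]]
  if (is.null(m)) stop("surface component '", which, "' not computed")
  nc <- nearest_cell(eo_surface$grid, x, y)
  m[nc$i, nc$j]
}

#' Decision value
#'
#' `DV = EO / EO_opt`, clamped below at -1. When `EO_opt <= 0` the ratio is
#' sign-flipped and meaningless: DV is returned as `NA` with attribute
#' `"undefined"` set, and such events are excluded from DV summaries.
#'
#' @param eo_decision EO of the executed pass.
#' @param eo_opt maximum EO available within the kicking range.
#' @return DV in `[-1, 1]` (or above 1 only if the alternative search was
#'   not exhaustive), or `NA` when undefined.
#' @export
decision_value <- function(eo_decision, eo_opt) {
  if (is.na(eo_opt) || eo_opt <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  max(eo_decision / eo_opt, -1)
}

#' Best alternative pass within kicking range
#'
#' Evaluates the smoothed EO at every on-field teammate's current position
#' within `radius` of the kicker and returns the argmax; ties break towards
#' the lowest player id.
#'
#' @param eo_surface a smoothed EO surface (after [kick_smoothing()]).
#' @param formation the formation at the time of the pass.
#' @param kicker_id the kicker's player id.
#' @param radius kicking radius, metres (default 60).
#' @return list with `player_id`, `x`, `y`, `eo`, `distance`; or `NULL` when
#'   no teammate is in range.
#' @export
find_alternative <- function(eo_surface, formation, kicker_id, radius = 60) {
  kr <- formation[formation$player_id == kicker_id]
  if (nrow(kr) != 1L) stop("kicker ", kicker_id, " not in formation")
  mates <- formation[formation$team_id == kr$team_id &
                       formation$player_id != kicker_id]
  if (!nrow(mates)) return(NULL)
  d <- sqrt((mates$x - kr$x)^2 + (mates$y - kr$y)^2)
  keep <- d <= radius
  if (!any(keep)) return(NULL)
  mates <- mates[keep]; d <- d[keep]
  eo <- vapply(seq_len(nrow(mates)),
               function(k) eo_at(eo_surface, mates$x[k], mates$y[k]),
               numeric(1))
  ord <- order(-eo, mates$player_id)
  b <- ord[1]
  list(player_id = mates$player_id[b], x = mates$x[b], y = mates$y[b],
       eo = eo[b], distance = d[b])
}

#' Evaluate one pass from a frozen formation
#'
#' Builds the control and EO surfaces from the formation at the time of the
#' pass (ball at the kicker), reads the decision metrics at the receiver's
#' mark location, finds the optimal alternative among teammates within the
#' kicking radius, and computes DV.
#'
#' @param model a [fit_commitment()] model.
#' @param equity_model an equity provider.
#' @param formation formation at the time of the kick.
#' @param kicker_id kicker's player id.
#' @param target length-2 receiver mark location.
#' @param attacking_direction +1 if the kicker's team attacks towards +x.
#' @param kick_radius kicking radius, metres.
#' @param ball_speed ball flight speed, m/s.
#' @param field a [field_spec()] used to clip the evaluation grid.
#' @param step grid cell size, metres.
#' @param keep_surfaces retain the control/EO surfaces in the result.
#' @return list of class `"pass_evaluation"`: decision metrics (`dom_dec`,
#'   `inf_dec`, `risk_dec`, `eo_dec`, `dist_dec`), alternative metrics
#'   (`*_alt` plus `alt_player_id`), and `dv`.
#' @export
evaluate_pass_formation <- function(model, equity_model, formation, kicker_id,
                                    target, attacking_direction = 1L,
                                    kick_radius = 60, ball_speed = 18.5,
                                    field = field_spec(), step = 1,
                                    keep_surfaces = FALSE) {
  kr <- formation[formation$player_id == kicker_id]
  if (nrow(kr) != 1L) stop("kicker ", kicker_id, " not in formation")
  ball <- c(kr$x, kr$y)
  pad <- 3 # smoothing support beyond the kick radius (r <= 0.05 * 60 = 3 m)
  half_a <- field$axes[1] / 2; half_b <- field$axes[2] / 2
  grid <- make_grid(
    c(max(-half_a, ball[1] - kick_radius - pad),
      min(half_a, ball[1] + kick_radius + pad)),
    c(max(-half_b, ball[2] - kick_radius - pad),
      min(half_b, ball[2] + kick_radius + pad)), step)
  surf <- control_surface(model, formation, kr$team_id, ball, grid,
                          ball_speed = ball_speed)
  eo_s <- expected_outcome(surf, equity_model, attacking_direction)
  eo_s <- kick_smoothing(eo_s, kicker = ball)
  alt <- find_alternative(eo_s, formation, kicker_id, radius = kick_radius)
  nc <- nearest_cell(grid, target[1], target[2])
  dom_dec <- surf$dom_a[nc$i, nc$j]
  inf_dec <- surf$inf_a[nc$i, nc$j]
  eo_dec <- eo_s$eo_mod[nc$i, nc$j]
  dist_dec <- sqrt(sum((target - ball)^2))
  res <- list(
    kicker_id = kicker_id, team_id = kr$team_id,
    decision = list(x = target[1], y = target[2]),
    dom_dec = dom_dec, inf_dec = inf_dec,
    risk_dec = dom_dec * inf_dec, eo_dec = eo_dec, dist_dec = dist_dec)
  if (is.null(alt)) {
    res$alternative <- NULL
    res$dv <- structure(NA_real_, undefined = TRUE)
  } else {
    nca <- nearest_cell(grid, alt$x, alt$y)
    dom_alt <- surf$dom_a[nca$i, nca$j]
    inf_alt <- surf$inf_a[nca$i, nca$j]
    res$alternative <- alt
    res$alt_player_id <- alt$player_id
    res$dom_alt <- dom_alt
    res$inf_alt <- inf_alt
    res$risk_alt <- dom_alt * inf_alt
    res$eo_alt <- alt$eo
    res$dist_alt <- alt$distance
    res$dv <- decision_value(eo_dec, alt$eo)
  }
  if (keep_surfaces) {
    res$control <- surf
    res$eo_surface <- eo_s
  }
  structure(res, class = "pass_evaluation")
}

#' @export
print.pass_evaluation <- function(x, ...) {
  cat(sprintf(
    "pass by %s -> (%.1f, %.1f): EO %.3f (risk %.3f), best alt %s EO %.3f, DV %s\n",
    x$kicker_id, x$decision$x, x$decision$y, x$eo_dec, x$risk_dec,
    if (is.null(x$alternative)) "<none>" else x$alt_player_id,
    if (is.null(x$alternative)) NA_real_ else x$eo_alt,
    if (is.na(x$dv)) "undefined" else sprintf("%.3f", x$dv)))
  invisible(x)
}

#' Evaluate all mark-to-mark passes in consolidated streams
#'
#' Scans the transaction sequence for kicks that are immediately preceded by
#' a mark by the same player (an unpressured decision) and immediately
#' followed by a mark (a locatable intended target), and evaluates each with
#' [evaluate_pass_formation()] using the formation frozen at the kick.
#' Other kicks are skipped with a reason.
#'
#' @param cons a [consolidate()] result.
#' @param model a commitment model.
#' @param equity_model an equity provider.
#' @param attacking_direction named vector mapping team id to +1/-1, or a
#'   single value applied to every kick.
#' @param match_id identifier copied into the output rows.
#' @inheritParams evaluate_pass_formation
#' @return a `data.table`, one row per evaluated pass, with the decision and
#'   alternative metric columns and `dv`; skipped kicks are summarised in
#'   attribute `"skipped"`.
#' @export
evaluate_passes <- function(cons, model, equity_model,
                            attacking_direction = 1L, match_id = "match",
                            kick_radius = 60, ball_speed = 18.5,
                            field = field_spec(), step = 1) {
  tx <- cons$transactions
  rows <- list()
  skipped <- c(not_after_mark = 0L, target_not_mark = 0L, unmatched = 0L,
               too_far = 0L)
  kicks <- which(tx$event_type == "kick")
  for (i in kicks) {
    if (i == 1L || tx$event_type[i - 1L] != "mark" ||
        tx$player_id[i - 1L] != tx$player_id[i]) {
      skipped["not_after_mark"] <- skipped["not_after_mark"] + 1L
      next
    }
    if (i == nrow(tx) || tx$event_type[i + 1L] != "mark") {
      skipped["target_not_mark"] <- skipped["target_not_mark"] + 1L
      next
    }
    if (!tx$matched[i]) {
      skipped["unmatched"] <- skipped["unmatched"] + 1L
      next
    }
    f <- cons$formations[[i]]
    kicker <- tx$player_id[i]
    target <- c(tx$x[i + 1L], tx$y[i + 1L])
    kr <- f[f$player_id == kicker]
    if (nrow(kr) != 1L ||
        sqrt((target[1] - kr$x)^2 + (target[2] - kr$y)^2) > kick_radius) {
      skipped["too_far"] <- skipped["too_far"] + 1L
      next
    }
    dir_a <- if (length(attacking_direction) > 1L)
      attacking_direction[[kr$team_id]] else attacking_direction
    ev <- evaluate_pass_formation(model, equity_model, f, kicker, target,
                                  attacking_direction = dir_a,
                                  kick_radius = kick_radius,
                                  ball_speed = ball_speed, field = field,
                                  step = step)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      match_id = match_id, t_p = tx$timestamp[i],
      kicker_id = kicker, team_id = kr$team_id,
      receiver_id = tx$player_id[i + 1L],
      dom_dec = ev$dom_dec, inf_dec = ev$inf_dec, risk_dec = ev$risk_dec,
      eo_dec = ev$eo_dec, dist_dec = ev$dist_dec,
      alt_player_id = ev$alt_player_id %||% NA_character_,
      dom_alt = ev$dom_alt %||% NA_real_,
      inf_alt = ev$inf_alt %||% NA_real_,
      risk_alt = ev$risk_alt %||% NA_real_,
      eo_alt = ev$eo_alt %||% NA_real_,
      dist_alt = ev$dist_alt %||% NA_real_,
      dv = as.numeric(ev$dv))
  }
  out <- data.table::rbindlist(rows)
  attr(out, "skipped") <- skipped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
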