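# Team-level spatial control: per-cell influence (summed commitment
# probabilities), dominance (share of total influence) and the four
# pass-outcome probabilities.
#
# Ball time-to-point at a cell is the straight-line distance from the ball
# origin divided by a constant flight speed (default 18.5 m/s). A player's
# contribution is evaluated only within the motion model's support radius
# (35 m, the training inclusion radius); beyond it the commitment probability
# is treated as 0.

#' Integer-metre evaluation grid
#'
#' Cells sit at integer multiples of `step` (metre centres by default) within
#' the given limits.
#'
#' @param xlim,ylim numeric length-2 limits in metres.
#' @param step cell size in metres.
#' @return list of class `"grid_spec"` with axis coordinates `gx`, `gy`.
#' @export
make_grid <- function(xlim, ylim, step = 1) {
  gx <- seq(ceiling(xlim[1] / step) * step, floor(xlim[2] / step) * step,
            by = step)
  gy <- seq(ceiling(ylim[1] / step) * step, floor(ylim[2] / step) * step,
            by = step)
  structure(list(gx = gx, gy = gy, step = step), class = "grid_spec")
}

grid_cells <- function(grid) {
  expand.grid(x = grid$gx, y = grid$gy, KEEP.OUT.ATTRS = FALSE)
}

grid_matrix <- function(grid, v) {
  matrix(v, nrow = length(grid$gx), dimnames = list(grid$gx, grid$gy))
}

#' Nearest grid cell index for a point
#' @param grid a [make_grid()] spec.
#' @param x,y point coordinates.
#' @return list with row/col indices `i`, `j` and the cell coordinates.
#' @export
nearest_cell <- function(grid, x, y) {
  i <- which.min(abs(grid$gx - x))
  j <- which.min(abs(grid$gy - y))
  list(i = i, j = j, x = grid$gx[i], y = grid$gy[j])
}

#' Team spatial influence surface
#'
#' Influence at a cell is the sum over the team's on-field players of their
#' commitment probability for that cell, each evaluated at the player's
#' velocity, the ball's time-to-point to the cell, and the cell expressed in
#' the player's displacement frame. Players with undefined kinematics are
#' treated as stationary (velocity 0, direction 0).
#'
#' @param model a [fit_commitment()] model.
#' @param formation a [formation_at()] table.
#' @param team team id whose influence is computed.
#' @param ball length-2 ball origin (kicker location), metres.
#' @param grid a [make_grid()] spec.
#' @param ball_speed constant ball flight speed, m/s.
#' @param influence_radius motion-model support radius, metres.
#' @param players_required if non-NULL, error unless the team has exactly
#'   this many players in the formation.
#' @return matrix of per-cell influence (rows indexed by `gx`).
#' @export
team_influence <- function(model, formation, team, ball, grid,
                           ball_speed = 18.5, influence_radius = 35,
                           players_required = NULL) {
  f <- formation[formation$team_id == team]
  if (!is.null(players_required) && nrow(f) != players_required)
    stop("formation error: team ", team, " has ", nrow(f),
         " players, expected ", players_required)
  cells <- grid_cells(grid)
  ttp <- sqrt((cells$x - ball[1])^2 + (cells$y - ball[2])^2) / ball_speed
  inf <- numeric(nrow(cells))
  for (k in seq_len(nrow(f))) {
    rel <- to_relative(cells$x, cells$y, f$x[k], f$y[k], f$direction[k])
    sel <- rel[, 1]^2 + rel[, 2]^2 <= influence_radius^2
    if (!any(sel)) next
    p <- commit_probability(model, f$velocity[k], ttp[sel],
                            rel[sel, 1], rel[sel, 2])
    inf[sel] <- inf[sel] + p
  }
  grid_matrix(grid, inf)
}

#' Spatial dominance from two influence surfaces
#'
#' `DOM_a = INF_a / (INF_a + INF_o)` cellwise; cells where neither team has
#' influence are neutral (0.5).
#'
#' @param inf_a,inf_o influence surfaces on the same grid.
#' @return dominance surface in `[0, 1]`.
#' @export
dominance <- function(inf_a, inf_o) {
  tot <- inf_a + inf_o
  d <- ifelse(tot > 0, inf_a / tot, 0.5)
  if (is.matrix(inf_a)) d <- matrix(d, nrow = nrow(inf_a),
                                    dimnames = dimnames(inf_a))
  d
}

#' Mark probability (pass risk)
#'
#' The probability of a successful pass resulting in a mark: dominance times
#' influence. For the attacking team this is the risk of a pass — higher
#' values indicate a safer option.
#'
#' @param dom,inf dominance and influence surfaces on the same grid.
#' @return per-cell product.
#' @export
mark_probability <- function(dom, inf) dom * inf

#' Full control surface for a formation
#'
#' Computes both teams' influence, attacking dominance, and the four
#' pass-outcome probabilities: a mark by the attacking team
#' (`p_a = DOM_a * INF_a`), possession after a bounce (`p_b = DOM_a`), and
#' the opponent analogues (`p_c = DOM_o * INF_o`, `p_d = DOM_o`). The four
#' are used as printed, without renormalisation; `normalized = TRUE`
#' optionally rescales them to sum to 1 cellwise.
#'
#' @inheritParams team_influence
#' @param attacking_team team id of the team in possession.
#' @param normalized rescale the four outcome probabilities to sum to 1.
#' @return list of class `"control_surface"` with matrices `inf_a`, `inf_o`,
#'   `dom_a`, `p_a`, `p_b`, `p_c`, `p_d` and the call geometry.
#' @export
control_surface <- function(model, formation, attacking_team, ball, grid,
                            ball_speed = 18.5, influence_radius = 35,
                            players_required = NULL, normalized = FALSE) {
  teams <- unique(formation$team_id)
  if (!attacking_team %in% teams)
    stop("formation error: attacking team ", attacking_team, " not present")
  opponent <- setdiff(teams, attacking_team)
  if (length(opponent) != 1L)
    stop("formation error: expected exactly 2 teams, got ",
         paste(teams, collapse = ", "))
  inf_a <- team_influence(model, formation, attacking_team, ball, grid,
                          ball_speed, influence_radius, players_required)
  inf_o <- team_influence(model, formation, opponent, ball, grid,
                          ball_speed, influence_radius, players_required)
  dom_a <- dominance(inf_a, inf_o)
  dom_o <- 1 - dom_a
  p_a <- mark_probability(dom_a, inf_a)
  p_b <- dom_a
  p_c <- mark_probability(dom_o, inf_o)
  p_d <- dom_o
  if (normalized) {
    tot <- p_a + p_b + p_c + p_d
    tot[tot == 0] <- 1
    p_a <- p_a / tot; p_b <- p_b / tot; p_c <- p_c / tot; p_d <- p_d / tot
  }
  structure(list(grid = grid, inf_a = inf_a, inf_o = inf_o, dom_a = dom_a,
                 p_a = p_a, p_b = p_b, p_c = p_c, p_d = p_d,
                 attacking_team = attacking_team, opponent = opponent,
                 ball = ball, ball_speed = ball_speed,
                 normalized = normalized),
            class = "control_surface")
}

#' Extract the four outcome probabilities from a control surface
#' @param surface a [control_surface()].
#' @return list with matrices `p_a`, `p_b`, `p_c`, `p_d`.
#' @export
outcome_probabilities <- function(surface) {
  surface[c("p_a", "p_b", "p_c", "p_d")]
}

#' Export a control surface as a long table
#' @param surface a [control_surface()].
#' @return `data.table` with one row per cell:
#'   `x,y,inf_a,inf_o,dom_a,p_a,p_b,p_c,p_d`.
#' @export
surface_table <- function(surface) {
  cells <- grid_cells(surface$grid)
  data.table::data.table(
    x = cells$x, y = cells$y,
    inf_a = as.vector(surface$inf_a), inf_o = as.vector(surface$inf_o),
    dom_a = as.vector(surface$dom_a),
    p_a = as.vector(surface$p_a), p_b = as.vector(surface$p_b),
    p_c = as.vector(surface$p_c), p_d = as.vector(surface$p_d))
}

#' @export
print.control_surface <- function(x, ...) {
  cat(sprintf(
    "control surface: %d x %d cells, attacking team %s vs %s, ball (%.1f, %.1f)\n",
    length(x$grid$gx), length(x$grid$gy), x$attacking_team, x$opponent,
    x$ball[1], x$ball[2]))
  invisible(x)
}
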