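# Field equity: the expected scoring value of possession at a field
# position, the reward term of the decision model. The real AFL equity
# metric comes from proprietary historical modelling, so the default
# provider here is a clearly-labelled parametric SURROGATE: a difference of
# exponential goal-proximity terms, antisymmetric between the two attacking
# directions and scaled to the value of a goal (6 points). A gridded lookup
# provider can substitute a real equity table when one is available.
#
# Convention: a team attacking towards +x scores at the goal (a/2, 0); its
# opponent's equity at the same location is the mirrored (direction -1)
# lookup. For the surrogate this equals the negated value.

#' Surrogate field-equity model
#'
#' `e(x) = V * (g(d_att, th_att) - g(d_def, th_def))` where
#' `g(d, th) = exp(-d / decay) * cos(th / 2)^angle_weight`, `d` the distance
#' and `th` the absolute angle to the goal measured off the goal-to-goal
#' axis. `g` is monotone decreasing in both, so equity grows towards the
#' attacking goal and is negative deep in defence; it is exactly
#' antisymmetric under team exchange.
#'
#' @param max_value equity scale in points (default 6, the value of a goal).
#' @param decay exponential decay length in metres.
#' @param angle_weight exponent on the angular falloff (0 disables it).
#' @param field a [field_spec()].
#' @return list of class `c("equity_surrogate", "equity_model")`.
#' @export
equity_surrogate <- function(max_value = 6, decay = 35, angle_weight = 1,
                             field = field_spec()) {
  structure(list(kind = "surrogate", max_value = max_value, decay = decay,
                 angle_weight = angle_weight, field = field),
            class = c("equity_surrogate", "equity_model"))
}

#' Gridded lookup field-equity model
#'
#' Nearest-cell lookup in a table of equity values for a team attacking
#' towards +x; the attacking-left value is the mirrored (`-x`) lookup.
#'
#' @param table data.frame with columns `x`, `y`, `equity_attacking_right`.
#' @param field a [field_spec()].
#' @return list of class `c("equity_lookup", "equity_model")`.
#' @export
equity_lookup <- function(table, field = field_spec()) {
  tb <- data.table::as.data.table(table)
  need <- c("x", "y", "equity_attacking_right")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("equity table missing column(s): ", paste(miss, collapse = ", "))
  gx <- sort(unique(tb$x)); gy <- sort(unique(tb$y))
  full <- data.table::CJ(x = gx, y = gy)
  m <- merge(full, tb, by = c("x", "y"), all.x = TRUE)
  if (anyNA(m$equity_attacking_right)) {
    gaps <- m[is.na(equity_attacking_right)]
    stop("equity table has coverage gaps at ", nrow(gaps), " cell(s), e.g. (",
         gaps$x[1], ", ", gaps$y[1], ")")
  }
  # CJ sorts by x then y: with byrow = TRUE rows index gx, columns gy
  vals <- matrix(m[order(x, y)]$equity_attacking_right,
                 nrow = length(gx), byrow = TRUE)
  structure(list(kind = "lookup", gx = gx, gy = gy, values = vals,
                 field = field),
            class = c("equity_lookup", "equity_model"))
}

#' Load an equity lookup table from CSV
#' @param path CSV with columns `x,y,equity_attacking_right`.
#' @return an `"equity_lookup"` model.
#' @export
load_equity_table <- function(path) {
  if (!file.exists(path)) stop("equity table not found: ", path)
  equity_lookup(data.table::fread(path))
}

#' Write an equity lookup table to CSV
#' @param model an `"equity_lookup"` model.
#' @param path destination file.
#' @export
write_equity_table <- function(model, path) {
  stopifnot(inherits(model, "equity_lookup"))
  g <- data.table::CJ(x = model$gx, y = model$gy)
  g[, equity_attacking_right := as.vector(t(model$values))]
  data.table::fwrite(g[order(x, y)], path)
  invisible(path)
}

#' Field equity at locations
#'
#' @param model an `"equity_model"`.
#' @param x,y field coordinates, metres (must lie inside the field bounds
#'   for the surrogate when `strict`).
#' @param direction +1 if the team whose equity is requested attacks towards
#'   +x, -1 for the opposite direction.
#' @param strict error on locations outside the field bounds. Surface code
#'   evaluates rectangular grids whose corners fall outside the oval and
#'   uses `strict = FALSE`; the surrogate extrapolates smoothly there.
#' @return signed equity in points.
#' @export
equity_value <- function(model, x, y, direction = 1L, strict = TRUE) {
  UseMethod("equity_value")
}

#' @export
equity_value.equity_surrogate <- function(model, x, y, direction = 1L,
                                          strict = TRUE) {
  if (strict && !all(in_field(x, y, model$field, use_margin = TRUE)))
    stop("equity_value: location outside field bounds")
  if (any(direction == -1L)) x <- x * ifelse(direction == -1L, -1, 1)
  gx <- model$field$axes[1] / 2
  g_term <- function(goal_x) {
    dx <- goal_x - x
    d <- sqrt(dx^2 + y^2)
    th <- atan2(abs(y), abs(dx)) # angle off the goal-to-goal axis
    exp(-d / model$decay) * cos(th / 2)^model$angle_weight
  }
  model$max_value * (g_term(gx) - g_term(-gx))
}

#' @export
equity_value.equity_lookup <- function(model, x, y, direction = 1L,
                                       strict = TRUE) {
  if (any(direction == -1L)) x <- x * ifelse(direction == -1L, -1, 1)
  # nearest-cell lookup on each axis
  i <- vapply(x, function(v) which.min(abs(model$gx - v)), integer(1))
  j <- vapply(y, function(v) which.min(abs(model$gy - v)), integer(1))
  model$values[cbind(i, j)]
}
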