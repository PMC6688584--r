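# Tracking and transaction streams: readers/writers, per-player kinematics,
# relative-coordinate transforms, and consolidation of the two streams.
#
# Conventions (fixed here, used everywhere downstream):
#   * field frame: origin at field centre, oval boundary an ellipse with
#     configurable axes (default 160 x 129 m); the team in possession attacks
#     towards +x.
#   * displacement direction: radians in [0, 2*pi), measured clockwise from
#     the positive y-axis, so (0,+1) -> 0, (+1,0) -> pi/2, (0,-1) -> pi.
#   * timestamps: tracking at 10 Hz (0.1 s resolution), transactions at whole
#     seconds; internally both are keyed on integer deciseconds to avoid
#     floating-point join hazards.

TRACKING_COLS <- c("timestamp", "player_id", "team_id", "x", "y")
TRANSACTION_COLS <- c("timestamp", "event_type", "player_id", "x", "y")
EVENT_TYPES <- c("kick", "mark", "contested_mark", "spoil")
CONTEST_TYPES <- c("spoil", "contested_mark")

#' Field geometry specification
#'
#' The playing surface is modelled as an ellipse centred at the origin.
#'
#' @param axes numeric length-2, full major and minor axes in metres
#'   (goal-to-goal along x, wing-to-wing along y).
#' @param margin tolerance margin in metres added to both semi-axes when
#'   validating coordinates.
#' @return a list with class `"field_spec"`.
#' @export
field_spec <- function(axes = c(160, 129), margin = 2) {
  stopifnot(length(axes) == 2, all(axes > 0), margin >= 0)
  structure(list(axes = as.numeric(axes), margin = margin),
            class = "field_spec")
}

#' Test whether points lie inside the (elliptical) field
#'
#' @param x,y coordinates in metres.
#' @param field a [field_spec()].
#' @param use_margin include the tolerance margin.
#' @return logical vector.
#' @export
in_field <- function(x, y, field = field_spec(), use_margin = FALSE) {
  a <- field$axes[1] / 2 + if (use_margin) field$margin else 0
  b <- field$axes[2] / 2 + if (use_margin) field$margin else 0
  (x / a)^2 + (y / b)^2 <= 1
}

dsec_of <- function(t) as.integer(round(t * 10))

ensure_dsec <- function(dt) {
  if (!"dsec" %in% names(dt)) {
    dt <- data.table::as.data.table(dt)
    dt[, dsec := dsec_of(timestamp)]
  }
  dt
}

#' Read a tracking CSV
#'
#' Expects columns `timestamp,player_id,team_id,x,y` (metres; timestamp in
#' seconds at 0.1 s resolution). Rows are returned ordered by
#' `(player_id, timestamp)`. Malformed numeric fields are reported with their
#' line number.
#'
#' @param path file path.
#' @return a `data.table` with the five schema columns plus an integer
#'   decisecond key `dsec`.
#' @export
read_tracking <- function(path) {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  dt <- data.table::fread(path)
  validate_tracking(dt, where = path)
}

#' Validate an in-memory tracking table
#'
#' @param dt a data.frame/data.table with the tracking schema columns.
#' @param where label used in error messages.
#' @return the validated, keyed `data.table` (see [read_tracking()]).
#' @export
validate_tracking <- function(dt, where = "tracking") {
  dt <- data.table::as.data.table(dt)
  miss <- setdiff(TRACKING_COLS, names(dt))
  if (length(miss))
    stop("schema error in ", where, ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (col in c("timestamp", "x", "y")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("parse error in ", where, ": non-numeric '", col,
             "' at data row(s) ", paste(head(bad, 5), collapse = ", "))
      data.table::set(dt, j = col, value = vn)
    }
  }
  dt[, player_id := as.character(player_id)]
  dt[, team_id := as.character(team_id)]
  dt[, dsec := dsec_of(timestamp)]
  data.table::setkeyv(dt, c("player_id", "dsec"))
  if (any(dt[, diff(dsec) <= 0L, by = player_id]$V1))
    stop("invalid tracking in ", where,
         ": timestamps not strictly increasing within a player track")
  dt[]
}

#' Write a tracking table to CSV
#'
#' Coordinates are written at the documented interchange precision of
#' 1e-6 m (far below tracking-hardware noise), at which the CSV round-trips
#' bit-exactly with [read_tracking()].
#' @param dt tracking table.
#' @param path destination file.
#' @export
write_tracking <- function(dt, path) {
  out <- data.table::as.data.table(dt)[, .SD, .SDcols = TRACKING_COLS]
  out[, `:=`(x = round(x, 6), y = round(y, 6))]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a transaction (match-event) CSV
#'
#' Expects `timestamp,event_type,player_id,x,y`; timestamps are whole seconds
#' and `event_type` must be one of `kick`, `mark`, `contested_mark`, `spoil`.
#'
#' @param path file path.
#' @return a `data.table` ordered by timestamp with an `event_id` column.
#' @export
read_transactions <- function(path) {
  if (!file.exists(path)) stop("transaction file not found: ", path)
  dt <- data.table::fread(path)
  validate_transactions(dt, where = path)
}

#' Validate an in-memory transaction table
#' @inheritParams validate_tracking
#' @return the validated `data.table` (see [read_transactions()]).
#' @export
validate_transactions <- function(dt, where = "transactions") {
  dt <- data.table::as.data.table(dt)
  miss <- setdiff(TRANSACTION_COLS, names(dt))
  if (length(miss))
    stop("schema error in ", where, ": missing column(s) ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(dt$event_type), EVENT_TYPES)
  if (length(bad))
    stop("invalid event_type in ", where, ": ", paste(bad, collapse = ", "))
  if (nrow(dt) && any(abs(dt$timestamp - round(dt$timestamp)) > 1e-9))
    stop("invalid transactions in ", where, ": timestamps must be whole seconds")
  dt[, timestamp := as.numeric(round(timestamp))]
  dt[, player_id := as.character(player_id)]
  data.table::setorder(dt, timestamp)
  dt[, event_id := seq_len(.N)]
  dt[]
}

#' Write a transaction table to CSV
#' @param dt transaction table.
#' @param path destination file.
#' @export
write_transactions <- function(dt, path) {
  out <- data.table::as.data.table(dt)[, .SD, .SDcols = TRANSACTION_COLS]
  out[, `:=`(x = round(x, 6), y = round(y, 6))]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Angle between consecutive displacement vectors
#'
#' For points A, B, C returns the angle between vectors AB and BC as
#' `acos` of their normalised dot product, in `[0, pi]`. Collinear
#' continuation gives 0; a full reversal gives pi.
#'
#' @param a,b,c numeric length-2 points.
#' @return angle in radians.
#' @export
angle_between <- function(a, b, c) {
  u <- c(b[1] - a[1], b[2] - a[2])
  v <- c(c[1] - b[1], c[2] - b[2])
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("angle_between: degenerate (zero-length) displacement vector")
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

#' Player speed from a 1-second displacement window
#'
#' Speed is the Euclidean distance between the player's position at `t` and
#' their position exactly 1 s earlier (10 frames at 10 Hz). If either frame
#' is absent the velocity is undefined (`NA`), never interpolated.
#'
#' @param track tracking rows for a single player.
#' @param t time in seconds.
#' @return speed in m/s, or `NA_real_`.
#' @export
compute_velocity <- function(track, t) {
  track <- ensure_dsec(track)
  ds <- dsec_of(t)
  cur <- track[dsec == ds]
  prv <- track[dsec == ds - 10L]
  if (nrow(cur) != 1L || nrow(prv) != 1L) return(NA_real_)
  sqrt((cur$x - prv$x)^2 + (cur$y - prv$y)^2)
}

# angle of a displacement (dx, dy), clockwise from +y, in [0, 2 pi)
heading_of <- function(dx, dy) atan2(dx, dy) %% (2 * pi)

#' Displacement direction at a frame
#'
#' The angle formed by consecutive tracking samples (the frame at `t` and the
#' frame 0.1 s before), measured clockwise from the positive y-axis, in
#' `[0, 2*pi)`. If the displacement is below `eps` the direction is undefined
#' at that frame; the last defined direction within `lookback` frames is
#' carried, and failing that 0 is returned with `defined = FALSE`.
#'
#' @param track tracking rows for a single player.
#' @param t time in seconds.
#' @param eps minimum displacement (metres) for a defined direction.
#' @param lookback frames to scan backwards for a carried direction.
#' @return list with `direction` (radians) and `defined` (logical).
#' @export
displacement_direction <- function(track, t, eps = 1e-3, lookback = 20L) {
  track <- ensure_dsec(track)
  ds <- dsec_of(t)
  for (k in 0:lookback) {
    cur <- track[dsec == ds - k]
    prv <- track[dsec == ds - k - 1L]
    if (nrow(cur) != 1L || nrow(prv) != 1L) next
    dx <- cur$x - prv$x; dy <- cur$y - prv$y
    if (sqrt(dx^2 + dy^2) >= eps)
      return(list(direction = heading_of(dx, dy), defined = TRUE))
  }
  list(direction = 0, defined = FALSE)
}

#' Transform field locations into a player's displacement frame
#'
#' Translates so the player sits at the origin and rotates so their
#' displacement direction is the positive y-axis: `rel_y > 0` is in front of
#' the player, `rel_x > 0` to their right.
#'
#' @param x,y field coordinates of the location(s) of interest.
#' @param px,py player position.
#' @param direction player displacement direction (radians, clockwise from +y).
#' @return a two-column matrix `(rel_x, rel_y)`.
#' @export
to_relative <- function(x, y, px, py, direction) {
  tx <- x - px; ty <- y - py
  s <- sin(direction); cth <- cos(direction)
  cbind(rel_x = cth * tx - s * ty, rel_y = s * tx + cth * ty)
}

frame_at <- function(tracking, ds) {
  tracking[list(dsec = as.integer(ds)), on = "dsec", nomatch = NULL]
}

#' Field formation at a frame
#'
#' Snapshot of every tracked player's state (position, 1 s velocity,
#' displacement direction) at time `t`. Players without a frame at `t` are
#' omitted; velocity/direction may individually be undefined.
#'
#' @param tracking validated tracking table (all players).
#' @param t time in seconds.
#' @param eps displacement epsilon passed to [displacement_direction()].
#' @param lookback frames scanned backwards to carry a direction for players
#'   with sub-epsilon displacement at `t`.
#' @return a `data.table` with one row per tracked player: `player_id`,
#'   `team_id`, `x`, `y`, `velocity`, `velocity_defined`, `direction`,
#'   `direction_defined`.
#' @export
formation_at <- function(tracking, t, eps = 1e-3, lookback = 20L) {
  tracking <- ensure_dsec(tracking)
  ds <- dsec_of(t)
  cur <- frame_at(tracking, ds)
  if (!nrow(cur)) {
    return(data.table::data.table(
      player_id = character(), team_id = character(), x = numeric(),
      y = numeric(), velocity = numeric(), velocity_defined = logical(),
      direction = numeric(), direction_defined = logical()))
  }
  prv10 <- frame_at(tracking, ds - 10L)
  prv1 <- frame_at(tracking, ds - 1L)
  i10 <- match(cur$player_id, prv10$player_id)
  i1 <- match(cur$player_id, prv1$player_id)
  x10 <- prv10$x[i10]; y10 <- prv10$y[i10]
  xp <- prv1$x[i1]; yp <- prv1$y[i1]
  velocity <- sqrt((cur$x - x10)^2 + (cur$y - y10)^2)
  velocity_defined <- !is.na(velocity)
  velocity[!velocity_defined] <- 0
  dx <- cur$x - xp; dy <- cur$y - yp
  disp <- sqrt(dx^2 + dy^2)
  ok <- !is.na(disp) & disp >= eps
  direction <- numeric(nrow(cur))
  direction[ok] <- heading_of(dx[ok], dy[ok])
  out <- data.table::data.table(
    player_id = cur$player_id, team_id = cur$team_id, x = cur$x, y = cur$y,
    velocity = velocity, velocity_defined = velocity_defined,
    direction = direction, direction_defined = ok)
  # carry the last defined direction for players momentarily stationary
  for (p in out$player_id[!ok]) {
    d <- displacement_direction(tracking[player_id == p], t,
                                eps = eps, lookback = lookback)
    out[player_id == p,
        `:=`(direction = d$direction, direction_defined = d$defined)]
  }
  out[]
}

#' Consolidate tracking and transaction streams
#'
#' Each transaction is matched to the tracking frame at the beginning of its
#' second (whole-second events joined to the frame at `floor(t)`). An event is
#' excluded (flagged, with a reason) when it falls outside the tracking time
#' range or when any rostered player lacks a frame at the matched instant.
#'
#' @param tracking validated tracking table.
#' @param transactions validated transaction table.
#' @param roster character vector of player ids expected on field; defaults
#'   to every player id present in `tracking`.
#' @param eps displacement epsilon for directions.
#' @return a list of class `"consolidated"` with `transactions` (the events
#'   plus `matched` and `reason` columns) and `formations` (a list, one
#'   formation or `NULL` per event).
#' @export
consolidate <- function(tracking, transactions, roster = NULL, eps = 1e-3) {
  tracking <- data.table::as.data.table(tracking)
  data.table::setindex(tracking, dsec)
  transactions <- data.table::copy(data.table::as.data.table(transactions))
  if (is.null(roster)) roster <- unique(tracking$player_id)
  rng <- range(tracking$dsec)
  formations <- vector("list", nrow(transactions))
  matched <- logical(nrow(transactions))
  reason <- character(nrow(transactions))
  # formations are frequently requested at the same instant; memoise by dsec
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(transactions))) {
    ds <- dsec_of(floor(transactions$timestamp[i]))
    if (ds < rng[1] || ds > rng[2]) {
      reason[i] <- "outside_tracking_range"
      next
    }
    key <- as.character(ds)
    f <- if (exists(key, envir = cache)) get(key, envir = cache) else {
      ff <- formation_at(tracking, ds / 10, eps = eps)
      assign(key, ff, envir = cache)
      ff
    }
    if (!all(roster %in% f$player_id)) {
      reason[i] <- "missing_player_track"
      next
    }
    formations[[i]] <- f
    matched[i] <- TRUE
  }
  transactions[, matched := matched]
  transactions[, reason := reason]
  structure(list(transactions = transactions, formations = formations,
                 roster = roster),
            class = "consolidated")
}

#' @export
print.consolidated <- function(x, ...) {
  cat("consolidated streams:", nrow(x$transactions), "events,",
      sum(x$transactions$matched), "matched;",
      length(x$roster), "rostered players\n")
  invisible(x)
}
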