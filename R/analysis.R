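# Statistical analysis of pass evaluations: descriptive summaries,
# rank-based two-sample comparison (Mann-Whitney U with tie-corrected
# normal approximation), Spearman rank correlation, 1-D density profiling,
# and team-level reports. Raw p-values are reported without multiple-testing
# correction.

DECISION_METRICS <- c("dom", "inf", "risk", "eo", "dist")

#' Descriptive summary of pass evaluations
#'
#' Mean and SD of dominance, influence, risk, EO and kick distance for
#' decisions and alternatives, mean and SD of DV (excluding undefined DV
#' events), and kicks per match.
#'
#' @param evaluations a table from [evaluate_passes()] (rows may span
#'   several matches via `match_id`).
#' @return list of class `"pass_summary"` with `metrics` (a `data.table` of
#'   variable, group, mean, sd, n), `dv` (mean, sd, n, n_undefined) and
#'   `kicks_per_match` (mean, sd, n_matches).
#' @export
summarize_passes <- function(evaluations) {
  ev <- data.table::as.data.table(evaluations)
  if (nrow(ev) < 2) stop("summarize_passes: need at least 2 evaluations")
  rows <- list()
  for (m in DECISION_METRICS) {
    for (grp in c("dec", "alt")) {
      col <- paste0(m, "_", grp)
      if (!col %in% names(ev)) next
      v <- ev[[col]]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        variable = m, group = if (grp == "dec") "decision" else "alternative",
        mean = mean(v), sd = sd(v), n = length(v))
    }
  }
  metrics <- data.table::rbindlist(rows)
  dvv <- ev$dv[!is.na(ev$dv)]
  kicks <- ev[, .N, by = match_id]$N
  structure(list(
    metrics = metrics,
    dv = list(mean = mean(dvv), sd = sd(dvv), n = length(dvv),
              n_undefined = sum(is.na(ev$dv))),
    kicks_per_match = list(mean = mean(kicks), sd = sd(kicks),
                           n_matches = length(kicks))),
    class = "pass_summary")
}

#' @export
print.pass_summary <- function(x, ...) {
  cat(sprintf("pass summary: %.2f +/- %.2f kicks per match (%d matches)\n",
              x$kicks_per_match$mean,
              if (is.na(x$kicks_per_match$sd)) 0 else x$kicks_per_match$sd,
              x$kicks_per_match$n_matches))
  print(x$metrics)
  cat(sprintf("DV: %.3f +/- %.3f (n = %d, %d undefined)\n",
              x$dv$mean, x$dv$sd, x$dv$n, x$dv$n_undefined))
  invisible(x)
}

#' Mann-Whitney U test (tie-corrected normal approximation)
#'
#' Two-sided rank-sum test. `U` is reported for the first sample (the number
#' of pairs in which `a` exceeds `b`, counting ties as half); the p-value
#' uses the normal approximation with the tie-corrected variance and a
#' continuity correction. When every value in both samples is identical the
#' convention `p = 1` is returned.
#'
#' @param a,b numeric samples.
#' @return list with `U`, `p`, `n_a`, `n_b`.
#' @export
rank_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("rank_compare: both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled) # average ranks for ties
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p = 1, n_a = n1, n_b = n2))
  ties <- table(pooled)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (U - n1 * n2 / 2)
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), n_a = n1, n_b = n2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks. Returns `NA` (with a warning) when
#' either variable has zero rank variance.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return rho in `[-1, 1]` or `NA`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("rank_correlation: zero rank variance")
    return(NA_real_)
  }
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' One-dimensional density profile with peak detection
#'
#' Gaussian-kernel density over a regular grid with a plug-in bandwidth by
#' default, reporting the global peak and all local maxima (useful for
#' detecting bimodality).
#'
#' @param values numeric sample (length >= 5).
#' @param bandwidth kernel bandwidth; `NULL` uses `stats::bw.nrd0`.
#' @param n grid size.
#' @return list with `x`, `y`, `peak` (location of the global maximum) and
#'   `modes` (locations of all local maxima).
#' @export
distribution_profile <- function(values, bandwidth = NULL, n = 512) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 5)
  d <- if (is.null(bandwidth)) density(values, n = n)
    else density(values, bw = bandwidth, n = n)
  y <- d$y
  local_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (which.max(y) %in% c(1L, length(y)))
    local_max <- sort(unique(c(local_max, which.max(y))))
  list(x = d$x, y = y, bandwidth = d$bw,
       peak = d$x[which.max(y)], modes = d$x[local_max])
}

#' Team-level comparison report
#'
#' Per-team distributions of the decision metrics and DV, per-player means
#' and SDs within each team, and a rank-based p-value per variable for the
#' difference between the two teams' kickers.
#'
#' @param evaluations a table from [evaluate_passes()] with `team_id` and
#'   `kicker_id` columns.
#' @param team_a,team_b team ids to compare.
#' @return list of class `"team_report"` with `tests` (variable, U, p),
#'   `player_stats` (per-kicker mean/sd per variable) and group sizes.
#' @export
team_report <- function(evaluations, team_a, team_b) {
  ev <- data.table::as.data.table(evaluations)
  for (tm in c(team_a, team_b))
    if (!tm %in% ev$team_id) stop("team ", tm, " absent from evaluations")
  vars <- c(paste0(DECISION_METRICS, "_dec"), "dv")
  vars <- intersect(vars, names(ev))
  tests <- data.table::rbindlist(lapply(vars, function(v) {
    rc <- rank_compare(ev[team_id == team_a][[v]],
                       ev[team_id == team_b][[v]])
    data.table::data.table(variable = v, U = rc$U, p = rc$p,
                           n_a = rc$n_a, n_b = rc$n_b)
  }))
  player_stats <- ev[team_id %in% c(team_a, team_b),
                     c(list(n = .N),
                       unlist(lapply(.SD, function(v)
                         list(mean = mean(v, na.rm = TRUE),
                              sd = sd(v, na.rm = TRUE))),
                         recursive = FALSE)),
                     by = list(team_id, kicker_id), .SDcols = vars]
  structure(list(team_a = team_a, team_b = team_b, tests = tests,
                 player_stats = player_stats,
                 note = "raw p-values, no multiple-testing correction"),
            class = "team_report")
}

#' @export
print.team_report <- function(x, ...) {
  cat("team comparison", x$team_a, "vs", x$team_b, "(", x$note, ")\n")
  print(x$tests)
  invisible(x)
}
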