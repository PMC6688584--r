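# shared helpers: tiny deterministic builders used across test files

# single-player straight-line track (thin wrapper over the package builder)
make_line <- function(id, team, from, dir, vel, t0 = 0, t1 = 4) {
  commitval:::line_track(id, team, from, dir, vel, t0, t1)
}

# naive independent KDE-posterior oracle: double loop over training rows
naive_posterior <- function(q, x1, x0, w, h) {
  dens <- function(qrow, xm) {
    s <- 0
    for (j in seq_len(nrow(xm)))
      s <- s + exp(-sum((qrow - xm[j, ])^2) / (2 * h^2))
    s / (nrow(xm) * (2 * pi)^2 * h^4)
  }
  vapply(seq_len(nrow(q)), function(i) {
    f1 <- dens(q[i, ], x1)
    f0 <- dens(q[i, ], x0)
    tot <- w * f1 + (1 - w) * f0
    if (tot > 0) w * f1 / tot else 0
  }, numeric(1))
}

# random small observation table with both classes
random_obs <- function(n, seed = 1) {
  withr::with_seed(seed, {
    data.table::data.table(
      velocity = runif(n, 0, 8),
      time_to_point = runif(n, 1, 4),
      rel_x = runif(n, -20, 20),
      rel_y = runif(n, -20, 20),
      committed = as.integer(runif(n) < 0.3))
  })
}

# deterministic small commitment model (forward-biased committed cluster)
toy_model_for_tests <- function() commitval:::toy_model()

# small mid-scale simulated match shared by several test files (cached)
shared_sim <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- simulate_match(sim_config(seed = 7L, n_passages = 40L,
                                        p_contest = 0.7))
    val
  }
})
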