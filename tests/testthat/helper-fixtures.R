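# shared fixtures, built in code and memoised per test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small study: 6 subjects, short trips, 20 streets - enough spatial structure
# for aggregation/classification tests without long runtimes
mini_study <- function() {
  memo("mini_study", {
    cfg <- synth_config(seed = 42, n_subjects = 6, trips_per_subject = c(3, 5),
                        network = list(n_streets = 20, street_length_m = 100))
    simulate_study(cfg)
  })
}

mini_processed <- function() {
  memo("mini_processed", suppressWarnings(process_trips(mini_study()$trips)))
}

# deterministic single-trip gait signal with an optional pause
gait_channels <- function(duration_s = 120, pause = NULL, step_hz = 2,
                          amp = 0.8, noise = 0, rate = 50, seed = 7) {
  set.seed(seed)
  n <- duration_s * rate
  t <- (seq_len(n) - 1) / rate
  moving <- if (is.null(pause)) rep(TRUE, n) else !(t >= pause[1] & t < pause[2])
  ph <- cumsum(step_hz * moving) / rate
  mk <- function(v, kind) signal_channel(v + rnorm(n, 0, noise), kind, rate)
  list(
    acc_x = mk(0.24 * amp / 0.8 * sin(2 * pi * ph + 1.1) * moving, "acc_x"),
    acc_y = mk(0.2 * amp / 0.8 * sin(2 * pi * ph + 2.3) * moving, "acc_y"),
    acc_z = mk(1 + moving * (amp * sin(2 * pi * ph) + 0.3 * amp * sin(4 * pi * ph + 0.7)),
               "acc_z")
  )
}

filtered_gait <- function(...) lapply(gait_channels(...), filter_imu)

no_intervals <- function() tibble::tibble(start_s = numeric(0), end_s = numeric(0))

# brute-force PSC oracle: direct double sum over segments
psc_bruteforce <- function(series, segments, weighting = "inverse_distance") {
  k <- nrow(segments)
  centers <- (segments$start + segments$end) / 2
  a <- vapply(seq_len(k), function(i) {
    mean(series[segments$start[i]:segments$end[i]])
  }, numeric(1))
  out <- numeric(k)
  for (i in seq_len(k)) {
    num <- 0; den <- 0
    for (j in seq_len(k)) {
      if (j == i) next
      w <- if (weighting == "inverse_distance") 1 / abs(centers[i] - centers[j]) else 1
      num <- num + w * abs(a[i] - a[j])
      den <- den + w
    }
    out[i] <- if (k > 1) num / den else 0
  }
  out
}

# exhaustive single-boundary least-squares change point (oracle)
best_single_boundary <- function(x) {
  n <- length(x)
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  costs <- vapply(1:(n - 1), function(b) sse(x[1:b]) + sse(x[(b + 1):n]), numeric(1))
  which.min(costs)
}

# simulated LME pair data (long format) with known effect
sim_lme_pairs <- function(beta, n_subj = 30, n_pairs = 20, tau = 0.5, sigma = 1) {
  u <- rnorm(n_subj, 0, tau)
  do.call(rbind, lapply(seq_len(n_subj), function(i) {
    x <- rep(c(0, 1), n_pairs)
    data.frame(subject = i, x = x, value = beta * x + u[i] + rnorm(2 * n_pairs, 0, sigma))
  }))
}
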