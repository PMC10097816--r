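test_that("street network grids have the requested size and total length", {
  net <- make_street_network(4, 100)
  expect_equal(nrow(net), 4)
  expect_equal(sum(net$length_m), 400)
  single <- make_street_network(1, 250)
  expect_equal(nrow(single), 1)
  expect_equal(single$length_m, 250)
  # determinism: construction is seed-free and repeatable
  expect_identical(make_street_network(7, 60), make_street_network(7, 60))
})

test_that("the same seed reproduces a trip bit-identically", {
  net <- make_street_network(6, 100)
  cfg <- synth_config(seed = 5)
  set.seed(11)
  r <- walkstress:::sample_route(net, 3)
  stim <- tibble::tibble(stimulus_id = "G001", x_m = 50, y_m = 0,
                         types = list(3L))
  a <- simulate_trip("s", "t", r, stim, cfg, trip_seed = 77)
  b <- simulate_trip("s", "t", r, stim, cfg, trip_seed = 77)
  expect_identical(a$trip$channels$eda$values, b$trip$channels$eda$values)
  expect_identical(a$trip$channels$bvp$values, b$trip$channels$bvp$values)
  expect_identical(a$trip$track, b$trip$track)
  expect_identical(a$reports, b$reports)
})

test_that("study-level trip counts respect the configured range", {
  study <- mini_study()
  counts <- table(vapply(study$trips, function(t) t$subject_id, character(1)))
  expect_true(all(counts >= 3 & counts <= 5))
  expect_equal(length(study$trips), sum(counts))
})

test_that("zero stimulus density yields no stimuli or reports", {
  cfg <- synth_config(seed = 2, n_subjects = 1, trips_per_subject = c(2, 2),
                      stimulus_density_per_km = 0,
                      network = list(n_streets = 4, street_length_m = 100))
  study <- simulate_study(cfg)
  expect_equal(nrow(study$truth$stimuli), 0)
  expect_equal(nrow(study$reports), 0)
})

test_that("injected SCR bursts raise SCR counts in effect windows; null does not", {
  pooled_counts <- function(effect_scale, seed) {
    cfg <- synth_config(seed = seed, n_subjects = 8, trips_per_subject = c(3, 3),
                        effect_scale = effect_scale,
                        network = list(n_streets = 12, street_length_m = 100))
    study <- simulate_study(cfg)
    onsets <- study$truth$scr_onsets
    ew <- study$truth$effect_windows
    n_in <- 0; n_out <- 0; dur_in <- 0; dur_out <- 0
    for (k in seq_along(study$trips)) {
      tid <- study$trips[[k]]$trip_id
      w <- ew[ew$trip_id == tid, , drop = FALSE]
      dur <- channel_duration(study$trips[[k]]$channels$eda)
      inw <- sum(walkstress:::in_intervals(onsets[[tid]], w))
      n_in <- n_in + inw
      n_out <- n_out + length(onsets[[tid]]) - inw
      dur_in <- dur_in + sum(w$end_s - w$start_s)
      dur_out <- dur_out + dur - sum(w$end_s - w$start_s)
    }
    list(n = c(n_in, n_out), t = c(dur_in, dur_out))
  }
  strong <- pooled_counts(1, 31)
  expect_gt(strong$n[1] / strong$t[1], strong$n[2] / strong$t[2])
  expect_lt(stats::poisson.test(strong$n, strong$t,
                                alternative = "greater")$p.value, 0.05)
  null <- pooled_counts(0, 32)
  expect_gt(stats::poisson.test(null$n, null$t)$p.value, 0.05)
})

test_that("unmanipulated synthetic EDA passes the quality screen", {
  study <- mini_study()
  for (trip in study$trips[1:5]) {
    sm <- smooth_eda(align_trip(trip)$channels$eda)
    scr <- detect_scrs(sm)
    dec <- screen_eda(sm, scr$events)
    expect_true(dec$usable)
  }
})

test_that("report-location error is centred on the true stimulus position", {
  study <- mini_study()
  rep <- study$reports
  stim <- study$truth$stimuli
  err <- sqrt((rep$x_m - stim$x_m[match(rep$stimulus_id, stim$stimulus_id)])^2 +
              (rep$y_m - stim$y_m[match(rep$stimulus_id, stim$stimulus_id)])^2)
  expect_lt(median(err), 3 * study$config$report_location_sigma_m)
  expect_gt(mean(err), 0)
})
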