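# a compact handmade "processed" object: one trip, constant-rate features,
# full control over track, interruptions and duration
fake_processed <- function(duration_s = 600, interruptions = no_intervals(),
                           trip_id = "t1", subject_id = "s1",
                           feature_value = function(t) rep(1, length(t))) {
  track <- tibble::tibble(time_s = seq(0, duration_s, by = 3),
                          x_m = seq(0, duration_s, by = 3) * 1.4, y_m = 0)
  t <- seq(0, duration_s - 1)
  features <- tibble::tibble(
    trip_id = trip_id, subject_id = subject_id, feature = "scl",
    time_s = t, value = feature_value(t),
    x_m = t * 1.4, y_m = 0
  )
  clean <- structure(list(
    trip = walking_trip(trip_id, subject_id, channels = list(
      eda = signal_channel(rep(2, duration_s * 4), "eda", 4)
    ), track = track),
    interruptions = interruptions,
    usable = TRUE
  ), class = "clean_trip")
  list(features = features, clean = list(clean))
}

report_at <- function(x, id = 1L, trip = "t1") {
  tibble::tibble(report_id = id, trip_id = trip, x_m = x, y_m = 0,
                 types = list(1L), report_time_s = NA_real_,
                 stress_level = NA_real_)
}

test_that("window pairs are extracted mid-trip and excluded at boundaries", {
  proc <- fake_processed()
  # report at trip midpoint (t0 = 300 s)
  pairs <- extract_window_pairs(proc, report_at(300 * 1.4), L_s = 30)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$nonstimuli, 1)
  expect_equal(pairs$stimuli, 1)

  # report 10 s after trip start: nonstimuli window truncated
  early <- extract_window_pairs(proc, report_at(10 * 1.4), L_s = 30)
  expect_equal(nrow(early), 0)
  expect_equal(attr(early, "exclusions")$reason, "truncated")

  # off-route report
  off <- extract_window_pairs(proc, report_at(300 * 1.4) |>
                                dplyr::mutate(y_m = 100), L_s = 30)
  expect_equal(attr(off, "exclusions")$reason, "off_route")
})

test_that("overlapping stimuli windows exclude the later report only", {
  proc <- fake_processed()
  reps <- dplyr::bind_rows(report_at(300 * 1.4, id = 1L),
                           report_at(320 * 1.4, id = 2L))
  pairs <- extract_window_pairs(proc, reps, L_s = 60)
  expect_equal(pairs$report_id, 1L)
  excl <- attr(pairs, "exclusions")
  expect_equal(excl$report_id, 2L)
  expect_equal(excl$reason, "overlap")

  # permuting report order retains the same pair set
  pairs_rev <- extract_window_pairs(proc, reps[2:1, ], L_s = 60)
  expect_equal(pairs_rev$report_id, pairs$report_id)
})

test_that("windows crossing interruptions honour the 50% coverage rule", {
  iv <- tibble::tibble(start_s = 280, end_s = 300)   # 20 s inside the pre-window
  proc <- fake_processed(interruptions = iv)
  ok <- extract_window_pairs(proc, report_at(300 * 1.4), L_s = 60)
  expect_equal(nrow(ok), 1)                          # 20/60 < 50%: retained
  gone <- extract_window_pairs(proc, report_at(300 * 1.4), L_s = 30)
  expect_equal(nrow(gone), 0)                        # 20/30 > 50%: excluded
  expect_equal(attr(gone, "exclusions")$reason, "interrupted")
})

test_that("the LME recovers injected effects and matches the pooled oracle", {
  set.seed(103)
  d0 <- sim_lme_pairs(0.3, tau = 0)
  f0 <- fit_lme(d0)
  expect_true(f0$pooled_fallback)
  lmfit <- stats::lm(value ~ x, data = d0)
  expect_lt(abs(f0$beta - unname(coef(lmfit)["x"])), 1e-6)

  set.seed(104)
  d1 <- sim_lme_pairs(0.5, n_subj = 20, n_pairs = 15)
  f1 <- fit_lme(d1, feature = "scl", window_length_s = 30)
  expect_lt(abs(f1$beta - 0.5), 3 * f1$se)
  expect_lt(f1$p_value, 0.05)
  expect_gt(f1$var_subject, 0)

  td <- tidy(f1)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_equal(td$estimate[2], f1$beta)
  gl <- glance(f1)
  expect_equal(gl$nobs, nrow(d1))

  # error paths
  d_const <- transform(d1, x = 1)
  expect_error(fit_lme(d_const), "contrast")
  expect_error(fit_lme(d1[1:5, ]), "10 observations")
})

test_that("per-type t-tests behave at the edges and detect real shifts", {
  mk_pairs <- function(nonstim, stim, type = 3L) {
    tibble::tibble(
      report_id = seq_along(stim), trip_id = "t", subject_id = "s",
      types = replicate(length(stim), type, simplify = FALSE),
      feature = "scl", window_length_s = 30,
      nonstimuli = nonstim, stimuli = stim
    )
  }
  # identical groups: t = 0, p = 1
  same <- ttest_by_type(mk_pairs(rep(1, 5), rep(1, 5)), "scl")
  row3 <- same[same$stimulus_type == 3, ]
  expect_equal(row3$t_stat, 0)
  expect_equal(row3$p_value, 1)
  expect_false(row3$significant)

  # strong separation: significant at n = 50 per group
  set.seed(6)
  strong <- ttest_by_type(mk_pairs(rnorm(50), rnorm(50, 2)), "scl")
  expect_true(strong$significant[strong$stimulus_type == 3])
  expect_gt(strong$t_stat[strong$stimulus_type == 3], 0)

  # one observation per group: undefined with a reason
  one <- ttest_by_type(mk_pairs(1, 2), "scl")
  expect_true(is.na(one$t_stat[one$stimulus_type == 3]))
  expect_match(one$reason[one$stimulus_type == 3], "fewer than 2")
  # untested types carry the reason too
  expect_true(all(is.na(same$t_stat[same$stimulus_type != 3])))
})

test_that("the window sweep returns a grid and minimal significant lengths", {
  proc <- fake_processed(
    duration_s = 600,
    feature_value = function(t) 1 + 0.5 * (t >= 300 & t < 330) + rnorm(length(t), 0, 0.05)
  )
  # replicate the trip across subjects so the LME is estimable
  procs <- proc
  for (s in 2:6) {
    p2 <- fake_processed(
      duration_s = 600, trip_id = paste0("t", s), subject_id = paste0("s", s),
      feature_value = function(t) 1 + 0.5 * (t >= 300 & t < 330) + rnorm(length(t), 0, 0.05)
    )
    procs$features <- dplyr::bind_rows(procs$features, p2$features)
    procs$clean <- c(procs$clean, p2$clean)
  }
  reps <- dplyr::bind_rows(lapply(1:6, function(s) {
    report_at(300 * 1.4, id = s, trip = paste0("t", if (s == 1) "1" else s))
  }))
  set.seed(9)
  sweep <- sweep_window_lengths(procs, reps, lengths_s = c(10, 30, 60),
                                ttests = TRUE)
  expect_s3_class(sweep$lme_grid, "tbl_df")
  expect_true(all(sweep$lme_grid$p.value >= 0 & sweep$lme_grid$p.value <= 1))
  # the injected 30-s step is detectable at some tested length
  expect_true("scl" %in% sweep$minimal_significant$feature)
  expect_lte(sweep$minimal_significant$min_significant_L_s[1], 60)

  # empty report set: empty grids
  empty <- sweep_window_lengths(procs, reps[0, ], lengths_s = c(30),
                                ttests = FALSE)
  expect_equal(nrow(empty$lme_grid), 0)
})
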