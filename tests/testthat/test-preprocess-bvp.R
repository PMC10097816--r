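synth_bvp <- walkstress:::synth_bvp

test_that("the periodic db4 transform reconstructs perfectly", {
  lo <- walkstress:::.db4_lo
  set.seed(4)
  x <- rnorm(128)
  st <- walkstress:::dwt_step(x, lo)
  expect_equal(walkstress:::idwt_step(st$approx, st$detail, lo), x,
               tolerance = 1e-12)
  # energy preservation (orthonormal filters)
  expect_equal(sum(st$approx^2) + sum(st$detail^2), sum(x^2), tolerance = 1e-12)
})

test_that("cleaning preserves a clean pulse train and removes baseline wander", {
  cfg <- synth_config(seed = 2)
  set.seed(7)
  sb <- synth_bvp(120, cfg, no_intervals(), 72)
  cleaned <- clean_bvp(sb$channel)
  expect_equal(length(cleaned$values), length(sb$channel$values))
  expect_gt(cor(sb$channel$values, cleaned$values), 0.95)

  # 0.2 Hz wander is outside the cardiac band: removed
  t <- channel_times(sb$channel)
  wandered <- signal_channel(sb$channel$values + 2 * sin(2 * pi * 0.2 * t),
                             "bvp", 64)
  rewashed <- clean_bvp(wandered)
  expect_gt(cor(rewashed$values, clean_bvp(sb$channel)$values), 0.95)
})

test_that("wavelet stage reduces beat-count error on artifact-laden BVP", {
  errs <- vapply(1:3, function(s) {
    cfg <- synth_config(seed = 2, bvp_artifact_rate_per_min = 6,
                        bvp_artifact_amp = 6)
    set.seed(s * 11)
    sa <- synth_bvp(300, cfg, no_intervals(), 72)
    true_beats <- length(sa$beat_times)
    err <- function(ch) {
      hr <- suppressWarnings(estimate_heart_rate(ch))
      abs(nrow(hr) + 1 - true_beats)
    }
    c(bandpass_only = err(clean_bvp(sa$channel, dwt_levels = 0)),
      with_dwt = err(clean_bvp(sa$channel)))
  }, numeric(2))
  expect_true(all(errs["with_dwt", ] < errs["bandpass_only", ]))
})

test_that("heart rate is recovered within 2 bpm on artifact-free signals", {
  cfg <- synth_config(seed = 2)
  set.seed(7)
  sb <- synth_bvp(300, cfg, no_intervals(), 72)
  hr <- estimate_heart_rate(clean_bvp(sb$channel))
  expect_gt(nrow(hr), 100)
  expect_lt(abs(mean(hr$bpm) - mean(sb$true_hr$bpm)), 2)
  expect_true(all(hr$bpm >= 30 & hr$bpm <= 220))
})

test_that("a ramping rate yields a near-monotone smoothed series", {
  # build a 60 -> 90 bpm ramp directly from the pulse model
  rate <- 64
  dur <- 240
  t <- (seq_len(dur * rate) - 1) / rate
  hr <- 60 + 30 * t / dur
  phase <- cumsum(hr / 60) / rate
  beats <- t[which(diff(floor(phase)) >= 1) + 1]
  v <- numeric(length(t))
  for (b in beats) {
    idx <- which(t >= b - 0.2 & t <= b + 0.2)
    v[idx] <- v[idx] + cos(pi * (t[idx] - b) / 0.4)^2
  }
  est <- estimate_heart_rate(clean_bvp(signal_channel(v, "bvp", rate)))
  # smoothed series tracks the ramp: strong positive trend, small violations
  expect_gt(cor(est$time_s, est$bpm), 0.98)
  expect_lt(mean(diff(est$bpm) < -0.5), 0.02)
})

test_that("flat or near-empty signals return an empty series with a warning", {
  flat <- signal_channel(rep(0, 640), "bvp", 64)
  expect_warning(hr <- estimate_heart_rate(flat), "beats|flat")
  expect_equal(nrow(hr), 0)
})
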