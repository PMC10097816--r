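test_that("IMU low-pass keeps the gait band and kills high frequencies", {
  rate <- 50
  t <- (0:4999) / rate
  amp_out <- function(f) {
    ch <- signal_channel(sin(2 * pi * f * t), "acc_z", rate)
    y <- filter_imu(ch)$values
    # steady-state amplitude away from the edges
    max(abs(y[1000:4000]))
  }
  expect_gt(amp_out(1), 0.99)          # 1 Hz passband: preserved within 1%
  expect_lt(amp_out(10), 0.1)          # 10 Hz: attenuated > 90%
  # DC preserved (away from the filtfilt edge transient)
  dc <- filter_imu(signal_channel(rep(0.7, 1000), "acc_z", rate))$values
  expect_equal(dc[200:800], rep(0.7, 601), tolerance = 1e-6)
})

test_that("zero-phase filtering leaves event positions unshifted", {
  x <- rep(0, 2000); x[1000] <- 1
  y <- filter_imu(signal_channel(x, "acc_z", 50))$values
  expect_equal(which.max(y), 1000)
})

test_that("a 20-s pause is detected within one window hop; 10 s is not", {
  acc <- filtered_gait(duration_s = 120, pause = c(50, 70))
  iv <- detect_interruptions(acc$acc_x, acc$acc_y, acc$acc_z)
  expect_equal(nrow(iv), 1)
  expect_lt(abs(iv$start_s - 50), 1.5)
  expect_lt(abs(iv$end_s - 70), 1.5)

  acc10 <- filtered_gait(duration_s = 120, pause = c(50, 60))
  expect_equal(nrow(detect_interruptions(acc10$acc_x, acc10$acc_y, acc10$acc_z)), 0)

  clean <- filtered_gait(duration_s = 120)
  expect_equal(nrow(detect_interruptions(clean$acc_x, clean$acc_y, clean$acc_z)), 0)
})

test_that("detected intervals are disjoint, sorted, and never exceed the trip", {
  acc <- filtered_gait(duration_s = 200, pause = c(30, 50), noise = 0.02, seed = 3)
  # add a second pause by zeroing a stretch of all axes
  zero_span <- function(ch, a, b) {
    t <- channel_times(ch)
    v <- ch$values
    v[t >= a & t < b] <- if (ch$kind == "acc_z") 1 else 0
    signal_channel(v, ch$kind, ch$sampling_rate_hz, ch$start_time)
  }
  acc <- lapply(acc, zero_span, a = 120, b = 150)
  iv <- detect_interruptions(acc$acc_x, acc$acc_y, acc$acc_z)
  expect_equal(nrow(iv), 2)
  expect_true(all(diff(as.vector(t(iv[, c("start_s", "end_s")]))) > 0))
  expect_lte(sum(iv$end_s - iv$start_s), 200)
  expect_gte(min(iv$start_s), 0)
})
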