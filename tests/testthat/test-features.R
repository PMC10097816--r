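test_that("stride time matches the generator cadence, with slowdown windows", {
  acc <- filtered_gait(duration_s = 120, noise = 0.02, seed = 12)
  st <- compute_stride_time(acc, no_intervals())
  expect_gt(nrow(st), 100)
  expect_lt(abs(mean(st$value) - 1.0), 0.05)   # 2 Hz steps: 1 s strides

  # 20% slowdown inside an effect window
  cfg <- synth_config(seed = 2)
  set.seed(10)
  ac2 <- walkstress:::synth_acc(300, cfg, tibble::tibble(start_s = 100, end_s = 130),
                                no_intervals())
  st2 <- compute_stride_time(lapply(ac2, filter_imu), no_intervals())
  inw <- st2$time_s > 102 & st2$time_s < 128
  expect_lt(abs(mean(st2$value[inw]) - 1.2), 0.05)
  expect_lt(abs(mean(st2$value[!inw]) - 1.0), 0.05)
})

test_that("strides are not emitted inside interruption intervals", {
  acc <- filtered_gait(duration_s = 120, pause = c(50, 70), seed = 13)
  iv <- detect_interruptions(acc$acc_x, acc$acc_y, acc$acc_z)
  st <- compute_stride_time(acc, iv)
  expect_false(any(st$time_s >= iv$start_s[1] & st$time_s < iv$end_s[1]))
})

test_that("geocoding interpolates linearly along the track", {
  track <- tibble::tibble(time_s = c(0, 3, 6), x_m = c(0, 30, 60), y_m = c(0, 0, 30))
  fs <- tibble::tibble(time_s = c(1.5, 3, 4.5), value = 1:3)
  g <- geocode_features(fs, track)
  expect_equal(g$x_m, c(15, 30, 45))   # midpoint, exact fix, midpoint
  expect_equal(g$y_m, c(0, 0, 15))

  # timestamps outside the span are dropped with a warning
  fs2 <- tibble::tibble(time_s = c(-2, 3, 10), value = 1:3)
  expect_warning(g2 <- geocode_features(fs2, track), "dropped 2")
  expect_equal(nrow(g2), 1)

  # stationary track: all positions equal
  still <- tibble::tibble(time_s = c(0, 3, 6), x_m = 5, y_m = 7)
  g3 <- geocode_features(fs, still)
  expect_true(all(g3$x_m == 5 & g3$y_m == 7))
})

test_that("trip feature extraction yields all eight geocoded series", {
  proc <- mini_processed()
  feats <- proc$features
  expect_setequal(unique(feats$feature),
                  c("scl", "scr_amplitude", "scr_frequency", "stride_time",
                    "mean_hr", "eda_psc", "imu_psc", "bvp_psc"))
  expect_true(all(is.finite(feats$value)))
  expect_true(all(is.finite(feats$x_m)))
  # SCR frequency series is the single source of counts: consistent with QC
  expect_true(all(feats$value[feats$feature == "scr_frequency"] >= 0))
  # positions lie near the street grid (within the 40-m buffer + GPS noise)
  study <- mini_study()
  asg <- assign_to_streets(feats$x_m, feats$y_m, study$streets, buffer_m = 40)
  expect_gt(mean(!is.na(asg$street_id)), 0.95)
})

test_that("unusable trips produce no features", {
  flat <- signal_channel(rep(0.005, 1200), "eda", 4)
  trip <- walking_trip(
    "t", "s",
    channels = list(
      eda = flat,
      bvp = signal_channel(rep(0, 19200), "bvp", 64),
      acc_x = signal_channel(rnorm(15000, 0, 0.01), "acc_x", 50),
      acc_y = signal_channel(rnorm(15000, 0, 0.01), "acc_y", 50),
      acc_z = signal_channel(1 + rnorm(15000, 0, 0.01), "acc_z", 50)
    ),
    track = tibble::tibble(time_s = seq(0, 297, by = 3), x_m = seq(0, 297, by = 3),
                           y_m = 0)
  )
  cl <- suppressWarnings(preprocess_trip(trip))
  expect_false(cl$usable)
  expect_equal(nrow(extract_trip_features(cl)), 0)
})
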