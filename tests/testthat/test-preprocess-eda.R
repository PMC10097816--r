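test_that("Bateman kernel matches its closed form", {
  # h[0] = e^0 - e^0 = 0 before normalization
  k <- bateman_kernel(2, 0.75, 4, 12)
  expect_equal(k[1], 0)
  expect_equal(sum(k), 1)
  # peak index from a dense evaluation of the closed form
  kk <- seq(0, 11)
  dense <- exp(-kk / (2 * 4)) - exp(-kk / (0.75 * 4))
  expect_equal(which.max(k), which.max(dense))
  expect_equal(k, dense / sum(dense))
  expect_error(bateman_kernel(0.5, 0.75), "tau1 > tau2")
})

test_that("Bateman smoothing preserves level and reproduces the kernel on an impulse", {
  const <- signal_channel(rep(2, 100), "eda", 4)
  expect_equal(smooth_eda(const)$values, rep(2, 100))

  imp <- signal_channel(c(rep(0, 30), 1, rep(0, 40)), "eda", 4)
  sm <- smooth_eda(imp)
  expect_equal(sm$values[31:42], bateman_kernel(rate_hz = 4))

  expect_error(smooth_eda(signal_channel(rep(1, 5), "eda", 4)), "shorter")

  # white noise: variance strictly reduced, mean approximately preserved
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(500, 2, 0.3)
    ch <- signal_channel(x, "eda", 4)
    y <- smooth_eda(ch)$values
    expect_lt(var(y), var(x))
    expect_lt(abs(mean(y) - mean(x)) / mean(x), 0.01)
  }
})

test_that("screen_eda applies the three published rules", {
  # constant 0.005 uS: below the mean floor and (being constant) zero SCRs
  low <- signal_channel(rep(0.005, 400), "eda", 4)
  ev0 <- tibble::tibble(onset_s = numeric(0), peak_s = numeric(0),
                        amplitude_uS = numeric(0))
  dec <- screen_eda(low, ev0)
  expect_false(dec$usable)
  expect_setequal(dec$reasons[[1]], c("low_mean_eda", "zero_scr_frequency"))

  # healthy trip: 2 uS tonic, 5 SCRs over 10 min
  ok <- signal_channel(rep(2, 2400), "eda", 4)
  ev5 <- tibble::tibble(onset_s = seq(60, 540, length.out = 5),
                        peak_s = seq(63, 543, length.out = 5),
                        amplitude_uS = rep(0.3, 5))
  dec_ok <- screen_eda(ok, ev5)
  expect_true(dec_ok$usable)
  expect_length(dec_ok$reasons[[1]], 0)

  # 30 SCRs per minute: electrode-artifact level
  ev_many <- tibble::tibble(onset_s = seq(0, 599.9, length.out = 300),
                            peak_s = seq(1, 600, length.out = 300),
                            amplitude_uS = rep(0.1, 300))
  dec_hi <- screen_eda(ok, ev_many)
  expect_false(dec_hi$usable)
  expect_equal(dec_hi$reasons[[1]], "excess_scr_frequency")

  # screening is a pure function
  expect_identical(screen_eda(ok, ev5), screen_eda(ok, ev5))
})

test_that("SCR detection recovers injected Bateman responses", {
  t <- seq(0, 60, by = 0.25)
  one <- 2 + 0.5 * scr_shape(t - 20)
  sm <- smooth_eda(signal_channel(one, "eda", 4))
  res <- detect_scrs(sm)
  expect_equal(nrow(res$events), 1)
  expect_gte(res$events$amplitude_uS, 0.4)
  expect_lte(res$events$amplitude_uS, 0.5)

  two <- 2 + 0.5 * scr_shape(t - 20) + 0.5 * scr_shape(t - 30)
  res2 <- detect_scrs(smooth_eda(signal_channel(two, "eda", 4)))
  expect_equal(nrow(res2$events), 2)
  expect_lt(max(abs(res2$events$onset_s - c(20, 30))), 0.5)

  # constant signal: no events, SCL equals the constant
  res0 <- detect_scrs(signal_channel(rep(1.5, 200), "eda", 4))
  expect_equal(nrow(res0$events), 0)
  expect_equal(unique(res0$scl$value), 1.5)
})
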