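#' Low-pass filter an accelerometer axis
#'
#' 4th-order Butterworth low-pass at 4 Hz, applied zero-phase (forward and
#' backward with `signal::filtfilt`) so gait events are not shifted in time.
#'
#' @param acc an `acc_*` [signal_channel()] (nominally 50 Hz).
#' @param cutoff_hz low-pass cutoff, Hz.
#' @param order filter order.
#' @return filtered channel.
#' @export
filter_imu <- function(acc, cutoff_hz = 4, order = 4) {
  stopifnot(inherits(acc, "signal_channel"))
  if (!acc$kind %in% c("acc_x", "acc_y", "acc_z")) {
    stopf("filter_imu expects an acc_* channel")
  }
  bf <- signal::butter(order, cutoff_hz / (acc$sampling_rate_hz / 2), type = "low")
  y <- signal::filtfilt(bf, acc$values)
  signal_channel(y, acc$kind, acc$sampling_rate_hz, acc$start_time)
}

#' Detect walking interruptions from triaxial accelerometry
#'
#' Implements the four-step screen: (1) the acceleration magnitude
#' `sqrt(x^2 + y^2 + z^2)` is computed; (2) a short-time Fourier transform with
#' a 3-s Hann window (50% overlap) is taken; (3) contiguous runs of frames
#' whose peak amplitude in the gait band (0.5-3 Hz) falls below 0.5 (amplitude
#' units of the input, i.e. g: the spectrum is scaled so a sinusoid of
#' amplitude A reads A) lasting at least 15 s become non-walking intervals;
#' (4) intervals closer than one hop are merged.
#'
#' @param acc_x,acc_y,acc_z filtered acceleration channels (same rate/length).
#' @param window_s STFT window length, seconds.
#' @param amp_threshold spectral-amplitude threshold, g.
#' @param min_duration_s minimum interruption duration, seconds.
#' @param gait_band_hz numeric length-2: gait frequency band, Hz.
#' @return interval tibble (`start_s`, `end_s`), disjoint and sorted; each
#'   interval at least `min_duration_s` long.
#' @export
detect_interruptions <- function(acc_x, acc_y, acc_z, window_s = 3,
                                 amp_threshold = 0.5, min_duration_s = 15,
                                 gait_band_hz = c(0.5, 3)) {
  rate <- acc_x$sampling_rate_hz
  if (acc_y$sampling_rate_hz != rate || acc_z$sampling_rate_hz != rate) {
    stopf("acc channels must share one sampling rate")
  }
  n <- min(length(acc_x$values), length(acc_y$values), length(acc_z$values))
  mag <- sqrt(acc_x$values[1:n]^2 + acc_y$values[1:n]^2 + acc_z$values[1:n]^2)
  nwin <- round(window_s * rate)
  hop <- nwin %/% 2
  if (n < nwin) return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))   # Hann
  starts <- seq(1, n - nwin + 1, by = hop)
  freqs <- (seq_len(nwin) - 1) * rate / nwin
  band <- which(freqs >= gait_band_hz[1] & freqs <= gait_band_hz[2])
  # amplitude scaling: |FFT| * 2 / sum(win) maps a sinusoid of amplitude A -> A
  scale <- 2 / sum(win)
  peak_amp <- vapply(starts, function(s) {
    seg <- mag[s:(s + nwin - 1)]
    sp <- Mod(fft((seg - mean(seg)) * win)) * scale
    max(sp[band])
  }, numeric(1))
  low <- peak_amp < amp_threshold
  t0 <- acc_x$start_time
  frame_start <- t0 + (starts - 1) / rate
  frame_end <- frame_start + window_s
  runs <- rle(low)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- ends_idx - runs$lengths + 1
  iv <- list()
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    a <- frame_start[starts_idx[r]]
    b <- frame_end[ends_idx[r]]
    if (b - a >= min_duration_s) {
      iv[[length(iv) + 1]] <- tibble::tibble(start_s = a, end_s = b)
    }
  }
  if (length(iv) == 0) return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  out <- normalize_intervals(dplyr::bind_rows(iv))
  # merge intervals separated by less than one hop
  if (nrow(out) > 1) {
    keep_s <- out$start_s[1]; keep_e <- out$end_s[1]
    for (i in 2:nrow(out)) {
      k <- length(keep_s)
      if (out$start_s[i] - keep_e[k] < hop / rate) {
        keep_e[k] <- out$end_s[i]
      } else {
        keep_s <- c(keep_s, out$start_s[i]); keep_e <- c(keep_e, out$end_s[i])
      }
    }
    out <- tibble::tibble(start_s = keep_s, end_s = keep_e)
  }
  out
}
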