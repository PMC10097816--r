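#' Detect skin conductance responses and the tonic level
#'
#' Splits smoothed EDA into tonic (rolling-median skin conductance level) and
#' phasic components, then performs trough-to-peak detection on the phasic
#' component. Event amplitude is measured on the smoothed EDA itself as
#' peak minus preceding trough conductance; events below the minimum amplitude
#' (0.01 microsiemens by convention) are discarded.
#'
#' @param eda_smoothed smoothed `eda` [signal_channel()] (see [smooth_eda()]).
#' @param tonic_window_s rolling-median window for the SCL estimate, seconds.
#' @param min_amp_uS minimum SCR amplitude, microsiemens.
#' @return list: `events` tibble (`onset_s`, `peak_s`, `amplitude_uS`) and
#'   `scl` tibble (`time_s`, `value`) at the channel rate.
#' @export
detect_scrs <- function(eda_smoothed, tonic_window_s = 4, min_amp_uS = 0.01) {
  stopifnot(inherits(eda_smoothed, "signal_channel"))
  x <- eda_smoothed$values
  rate <- eda_smoothed$sampling_rate_hz
  k <- round(tonic_window_s * rate)
  if (k %% 2 == 0) k <- k + 1
  tonic <- if (length(x) > k) as.numeric(runmed(x, k, endrule = "median")) else
    rep(median(x), length(x))
  phasic <- x - tonic
  t <- channel_times(eda_smoothed)
  scl <- tibble::tibble(time_s = t, value = tonic)
  empty <- tibble::tibble(onset_s = numeric(0), peak_s = numeric(0),
                          amplitude_uS = numeric(0))
  if (length(x) < 5 || sd(phasic) == 0) {
    return(list(events = empty, scl = scl))
  }
  pk <- pracma::findpeaks(phasic, minpeakheight = min_amp_uS / 4,
                          minpeakdistance = max(1, round(rate)))
  if (is.null(pk)) return(list(events = empty, scl = scl))
  peaks <- sort(pk[, 2])
  rows <- list()
  prev_peak <- 0L
  for (p in peaks) {
    # preceding trough on the smoothed signal, searched back to the prior peak;
    # on flat stretches take the LAST near-minimal sample (where the rise starts)
    lo <- max(prev_peak + 1L, p - round(10 * rate))
    seg <- x[lo:p]
    tol <- 0.02 * (max(seg) - min(seg))
    on_rel <- max(which(seg <= min(seg) + tol))
    onset_idx <- lo + on_rel - 1L
    amp <- x[p] - x[onset_idx]
    if (amp >= min_amp_uS && onset_idx < p) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        onset_s = t[onset_idx], peak_s = t[p], amplitude_uS = amp
      )
    }
    prev_peak <- p
  }
  events <- if (length(rows)) dplyr::bind_rows(rows) else empty
  list(events = events, scl = scl)
}

#' Rolling SCR frequency series
#'
#' Counts detected SCR onsets in a centered rolling window and converts to
#' counts per minute, sampled on a 1-Hz grid. This is the series used both for
#' geocoded aggregation and as the single source of SCR counts for screening.
#'
#' @param events SCR event tibble.
#' @param duration_s trip duration.
#' @param window_s rolling window, seconds.
#' @return tibble `time_s`, `value` (counts/min).
#' @export
scr_frequency_series <- function(events, duration_s, window_s = 60) {
  t <- seq(0, max(0, floor(duration_s - 1)))
  half <- window_s / 2
  cnt <- vapply(t, function(tt) {
    lo <- max(0, tt - half); hi <- min(duration_s, tt + half)
    sum(events$onset_s >= lo & events$onset_s < hi) / ((hi - lo) / 60)
  }, numeric(1))
  tibble::tibble(time_s = t, value = cnt)
}
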