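#' Compute stride time from filtered accelerometry
#'
#' Heel strikes are detected as peaks on the vertical axis (the axis with the
#' largest variance). A stride is two successive steps of the same foot, so
#' stride time is the interval between alternate peaks, emitted at the stride
#' midpoint. Interruption intervals split the trip into walking bouts; bouts
#' with fewer than 4 peaks yield nothing, and no stride spans an interruption.
#'
#' @param acc_channels list of the three filtered `acc_*` channels.
#' @param interruptions interval tibble from [detect_interruptions()].
#' @param min_step_interval_s refractory period between step peaks, seconds.
#' @return tibble `time_s`, `value` (stride time, seconds).
#' @export
compute_stride_time <- function(acc_channels, interruptions,
                                min_step_interval_s = 0.3) {
  vars <- vapply(acc_channels, function(ch) var(ch$values), numeric(1))
  ch <- acc_channels[[which.max(vars)]]
  rate <- ch$sampling_rate_hz
  x <- ch$values - mean(ch$values)
  t <- channel_times(ch)
  empty <- tibble::tibble(time_s = numeric(0), value = numeric(0))
  if (sd(x) == 0) return(empty)
  pk <- pracma::findpeaks(x, minpeakdistance = max(1, round(min_step_interval_s * rate)),
                          minpeakheight = 0.3 * sd(x))
  if (is.null(pk) || nrow(pk) < 4) return(empty)
  peak_t <- sort(t[pk[, 2]])
  # split peaks into bouts at interruptions
  bout_id <- cumsum(c(0, diff(findInterval(peak_t, sort(c(interruptions$start_s,
                                                          interruptions$end_s)))) != 0))
  keep <- !in_intervals(peak_t, interruptions)
  rows <- list()
  for (b in unique(bout_id[keep])) {
    pt <- peak_t[keep & bout_id == b]
    if (length(pt) < 4) next
    i <- seq_len(length(pt) - 2)
    stride <- pt[i + 2] - pt[i]          # alternate peaks = two steps
    mid <- (pt[i] + pt[i + 2]) / 2
    rows[[length(rows) + 1]] <- tibble::tibble(time_s = mid, value = stride)
  }
  if (!length(rows)) return(empty)
  dplyr::arrange(dplyr::bind_rows(rows), .data$time_s)
}
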