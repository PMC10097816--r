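#' Preprocess one walking trip
#'
#' Runs the full per-channel cleaning chain: aligns streams onto the trip
#' clock, smooths and screens EDA, low-pass filters the accelerometer axes and
#' detects walking interruptions, band-passes and wavelet-denoises BVP and
#' estimates heart rate.
#'
#' @param trip a [walking_trip()].
#' @param params list of tuning parameters (see [default_config()]`$preprocess`).
#' @return list of class `clean_trip`: the aligned `trip` with cleaned
#'   channels, `eda_smooth`, `scr` (events), `scl` (tonic series), `screen`
#'   (QC tibble), `interruptions`, `heart_rate`, `usable` (logical).
#' @export
preprocess_trip <- function(trip, params = default_config()$preprocess) {
  trip <- align_trip(trip)
  if ("unusable_short_overlap" %in% trip$quality_flags) {
    return(structure(list(trip = trip, usable = FALSE,
                          screen = tibble::tibble(usable = FALSE,
                                                  reasons = list("short_overlap"))),
                     class = "clean_trip"))
  }
  eda_s <- smooth_eda(trip$channels$eda)
  scr <- detect_scrs(eda_s, tonic_window_s = params$tonic_window_s,
                     min_amp_uS = params$min_scr_amp_uS)
  screen <- screen_eda(eda_s, scr$events)

  acc <- lapply(trip$channels[c("acc_x", "acc_y", "acc_z")], filter_imu,
                cutoff_hz = params$imu_cutoff_hz)
  interruptions <- detect_interruptions(
    acc$acc_x, acc$acc_y, acc$acc_z,
    window_s = params$stft_window_s,
    amp_threshold = params$stft_amp_threshold,
    min_duration_s = params$min_interruption_s
  )
  bvp_c <- clean_bvp(trip$channels$bvp, band_hz = params$bvp_band_hz,
                     dwt_levels = params$dwt_levels)
  hr <- suppressWarnings(
    estimate_heart_rate(bvp_c, ma_beats = params$hr_ma_beats)
  )
  trip$channels$eda <- eda_s
  trip$channels$bvp <- bvp_c
  trip$channels[c("acc_x", "acc_y", "acc_z")] <- acc
  structure(
    list(
      trip = trip,
      eda_smooth = eda_s,
      scr = scr$events,
      scl = scr$scl,
      screen = screen,
      interruptions = interruptions,
      heart_rate = hr,
      usable = screen$usable
    ),
    class = "clean_trip"
  )
}

#' @export
print.clean_trip <- function(x, ...) {
  cat(sprintf(
    "<clean_trip %s: usable=%s, %d SCRs, %d interruptions, %d HR points>\n",
    x$trip$trip_id, x$usable,
    if (is.null(x$scr)) 0L else nrow(x$scr),
    if (is.null(x$interruptions)) 0L else nrow(x$interruptions),
    if (is.null(x$heart_rate)) 0L else nrow(x$heart_rate)
  ))
  invisible(x)
}
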