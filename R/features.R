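#' Extract the eight geocoded feature series from a preprocessed trip
#'
#' Raw features: skin conductance level (`scl`, 1-Hz tonic EDA), SCR amplitude
#' (`scr_amplitude`, per event), SCR frequency (`scr_frequency`, rolling
#' counts/min at 1 Hz), stride time (`stride_time`, per stride) and mean heart
#' rate (`mean_hr`, per beat, smoothed). Saliency features: `eda_psc` (PSC of
#' 1-Hz EDA), `imu_psc` (PSC of the stride-time series) and `bvp_psc` (PSC of
#' the heart-rate series) - saliency is computed on the representative series
#' of each modality so segment attributes are comparable. Every series is
#' geocoded by linear interpolation of the GPS track.
#'
#' @param clean a `clean_trip` from [preprocess_trip()].
#' @param params feature parameters (see [default_config()]`$features`).
#' @return tibble: `trip_id`, `subject_id`, `feature`, `time_s`, `value`,
#'   `x_m`, `y_m`.
#' @export
extract_trip_features <- function(clean, params = default_config()$features) {
  stopifnot(inherits(clean, "clean_trip"))
  if (!isTRUE(clean$usable)) {
    return(feature_table_empty())
  }
  trip <- clean$trip
  dur <- channel_duration(trip$channels$eda)

  # 1-Hz EDA (mean per second) for SCL/PSC comparability across modalities
  eda <- trip$channels$eda
  sec <- floor(channel_times(eda))
  eda_1hz <- tibble::tibble(time_s = sec, v = eda$values) |>
    dplyr::summarise(value = mean(.data$v), .by = "time_s")
  scl_1hz <- tibble::tibble(time_s = floor(clean$scl$time_s), v = clean$scl$value) |>
    dplyr::summarise(value = mean(.data$v), .by = "time_s")

  scr_amp <- tibble::tibble(time_s = clean$scr$peak_s, value = clean$scr$amplitude_uS)
  scr_freq <- scr_frequency_series(clean$scr, dur, window_s = params$scr_freq_window_s)
  stride <- compute_stride_time(
    clean$trip$channels[c("acc_x", "acc_y", "acc_z")], clean$interruptions
  )
  hr <- clean$heart_rate
  hr_series <- tibble::tibble(time_s = hr$time_s, value = hr$bpm)

  cost_cap <- function(v) if (length(v) > 1 && var(v) > 0) params$psc_cost_factor * var(v) else NULL
  series <- list(
    scl = scl_1hz,
    scr_amplitude = scr_amp,
    scr_frequency = scr_freq,
    stride_time = stride,
    mean_hr = hr_series,
    eda_psc = psc_series(eda_1hz$time_s, eda_1hz$value, cost_cap(eda_1hz$value),
                         params$psc_weighting),
    imu_psc = psc_series(stride$time_s, stride$value, cost_cap(stride$value),
                         params$psc_weighting),
    bvp_psc = psc_series(hr_series$time_s, hr_series$value, cost_cap(hr_series$value),
                         params$psc_weighting)
  )
  out <- purrr::imap(series, function(s, nm) {
    if (nrow(s) == 0) return(NULL)
    g <- suppressWarnings(geocode_features(s, trip$track))
    if (nrow(g) == 0) return(NULL)
    dplyr::mutate(g, feature = nm, .before = 1)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(feature_table_empty())
  dplyr::mutate(out, trip_id = trip$trip_id, subject_id = trip$subject_id,
                .before = 1)
}

feature_table_empty <- function() {
  tibble::tibble(
    trip_id = character(0), subject_id = character(0), feature = character(0),
    time_s = numeric(0), value = numeric(0), x_m = numeric(0), y_m = numeric(0)
  )
}

#' Feature families used for segment-level classification
#' @return character vector of the six family names.
#' @export
feature_families <- function() {
  c("scl", "eda_psc", "stride_time", "imu_psc", "mean_hr", "bvp_psc")
}

#' Preprocess and featurize every trip of a study
#'
#' @param trips list of [walking_trip()]s.
#' @param params full parameter list ([default_config()]).
#' @return list: `features` (one long tibble), `qc` (per-trip screening
#'   summary), `clean` (list of `clean_trip`s, invisibly heavy - kept for
#'   downstream window statistics).
#' @export
process_trips <- function(trips, params = default_config()) {
  clean <- lapply(trips, preprocess_trip, params = params$preprocess)
  qc <- dplyr::bind_rows(lapply(clean, function(cl) {
    tibble::tibble(
      trip_id = cl$trip$trip_id,
      subject_id = cl$trip$subject_id,
      usable = isTRUE(cl$usable),
      reasons = paste(unlist(cl$screen$reasons), collapse = ";"),
      interruption_s = if (is.null(cl$interruptions)) 0 else
        sum(cl$interruptions$end_s - cl$interruptions$start_s)
    )
  }))
  features <- dplyr::bind_rows(lapply(clean, extract_trip_features,
                                      params = params$features))
  list(features = features, qc = qc, clean = clean)
}
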