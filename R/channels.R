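#' Wearable signal channels
#'
#' A `signal_channel` is a light container for one evenly sampled stream:
#' electrodermal activity (`eda`, microsiemens, 4 Hz), blood volume pulse
#' (`bvp`, arbitrary units, 64 Hz) or one acceleration axis (`acc_x`/`acc_y`/
#' `acc_z`, g, 50 Hz). Sample `i` (1-based) is taken at
#' `start_time + (i - 1) / sampling_rate_hz`.
#'
#' @param values numeric vector of samples.
#' @param kind one of `"eda"`, `"bvp"`, `"acc_x"`, `"acc_y"`, `"acc_z"`.
#' @param sampling_rate_hz sampling rate, Hz (> 0).
#' @param start_time start of the stream, seconds (UTC epoch or seconds since
#'   trip start after [align_trip()]).
#' @return object of class `signal_channel`.
#' @examples
#' ch <- signal_channel(rnorm(40), "eda", 4)
#' channel_duration(ch)
#' @export
signal_channel <- function(values, kind, sampling_rate_hz, start_time = 0) {
  kind <- match.arg(kind, c("eda", "bvp", "acc_x", "acc_y", "acc_z"))
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      is.na(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stopf("sampling_rate_hz must be a single positive number")
  }
  values <- as.numeric(values)
  structure(
    list(
      kind = kind,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      start_time = as.numeric(start_time),
      values = values
    ),
    class = "signal_channel"
  )
}

#' @export
print.signal_channel <- function(x, ...) {
  cat(sprintf(
    "<signal_channel %s: %d samples @ %g Hz, %.1f s, start %.2f>\n",
    x$kind, length(x$values), x$sampling_rate_hz, channel_duration(x), x$start_time
  ))
  invisible(x)
}

#' @rdname signal_channel
#' @param ch a `signal_channel`.
#' @export
channel_duration <- function(ch) length(ch$values) / ch$sampling_rate_hz

#' @rdname signal_channel
#' @export
channel_times <- function(ch) {
  ch$start_time + (seq_along(ch$values) - 1) / ch$sampling_rate_hz
}

# crop a channel to [t0, t1) in absolute time
crop_channel <- function(ch, t0, t1) {
  t <- channel_times(ch)
  keep <- t >= t0 & t < t1
  signal_channel(ch$values[keep], ch$kind, ch$sampling_rate_hz,
                 start_time = if (any(keep)) t[which(keep)[1]] else t0)
}

#' Bundle channels and a geotrack into a walking trip
#'
#' @param trip_id,subject_id identifiers.
#' @param channels named list of [signal_channel()]s (at most one per kind).
#' @param track geotrack tibble with columns `time_s`, `x_m`, `y_m` (planar
#'   meters; see [read_geotrack()]), nominal spacing one fix per 3 s.
#' @param quality_flags character vector of QC flags.
#' @return object of class `walking_trip`.
#' @export
walking_trip <- function(trip_id, subject_id, channels, track,
                         quality_flags = character(0)) {
  kinds <- vapply(channels, function(c) c$kind, character(1))
  if (anyDuplicated(kinds)) stopf("at most one channel per kind in a trip")
  names(channels) <- kinds
  if (!all(c("time_s", "x_m", "y_m") %in% names(track))) {
    stopf("track must have columns time_s, x_m, y_m")
  }
  if (is.unsorted(track$time_s, strictly = TRUE)) {
    stopf("track timestamps must be strictly increasing")
  }
  structure(
    list(
      trip_id = trip_id, subject_id = subject_id,
      channels = channels, track = tibble::as_tibble(track),
      quality_flags = quality_flags
    ),
    class = "walking_trip"
  )
}

#' @export
print.walking_trip <- function(x, ...) {
  cat(sprintf(
    "<walking_trip %s (subject %s): %d channels [%s], %d GPS fixes%s>\n",
    x$trip_id, x$subject_id, length(x$channels),
    paste(names(x$channels), collapse = ", "), nrow(x$track),
    if (length(x$quality_flags)) paste0(", flags: ", paste(x$quality_flags, collapse = ",")) else ""
  ))
  invisible(x)
}

#' Re-express a trip on a common trip-local clock
#'
#' Trims all channels and the geotrack to their common time overlap and shifts
#' times to seconds since trip start, so every stream covers `[0, T)`. Sample
#' rates are untouched (each feature extractor works at native rate). Trips
#' whose overlap is shorter than 60 s are flagged `"unusable_short_overlap"`.
#' Idempotent.
#'
#' @param trip a [walking_trip()].
#' @return the aligned trip.
#' @export
align_trip <- function(trip) {
  spans <- vapply(trip$channels, function(ch) {
    c(ch$start_time, ch$start_time + channel_duration(ch))
  }, numeric(2))
  t0 <- max(spans[1, ])
  t1 <- min(spans[2, ])
  # each GPS fix covers its nominal 3-s interval
  track_cover <- min(t1, max(trip$track$time_s) + 3) - max(t0, min(trip$track$time_s))
  if (t1 - t0 < 60 || track_cover < 60) {
    trip$quality_flags <- union(trip$quality_flags, "unusable_short_overlap")
    return(trip)
  }
  trip$channels <- lapply(trip$channels, function(ch) {
    cc <- crop_channel(ch, t0, t1)
    cc$start_time <- cc$start_time - t0
    cc
  })
  # keep the boundary fix just before t0 so the track still covers time 0
  keep <- trip$track$time_s >= t0 - 3 & trip$track$time_s < t1
  trip$track <- trip$track[keep, , drop = FALSE]
  trip$track$time_s <- trip$track$time_s - t0
  trip
}
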