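#' Geocode a feature series along a trip's GPS track
#'
#' Positions are linearly interpolated from the geotrack at each feature
#' timestamp. Timestamps outside the track span are dropped (their count is
#' reported in a warning).
#'
#' @param feature_series tibble `time_s`, `value`.
#' @param track geotrack tibble `time_s`, `x_m`, `y_m`.
#' @return tibble `time_s`, `value`, `x_m`, `y_m`.
#' @export
geocode_features <- function(feature_series, track) {
  if (nrow(feature_series) == 0) {
    return(tibble::tibble(time_s = numeric(0), value = numeric(0),
                          x_m = numeric(0), y_m = numeric(0)))
  }
  lo <- min(track$time_s); hi <- max(track$time_s)
  inside <- feature_series$time_s >= lo & feature_series$time_s <= hi
  dropped <- sum(!inside)
  if (dropped > 0) {
    warnf("geocode_features: dropped %d points outside the track span", dropped)
  }
  fs <- feature_series[inside, , drop = FALSE]
  tibble::tibble(
    time_s = fs$time_s,
    value = fs$value,
    x_m = approx(track$time_s, track$x_m, xout = fs$time_s)$y,
    y_m = approx(track$time_s, track$y_m, xout = fs$time_s)$y
  )
}
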