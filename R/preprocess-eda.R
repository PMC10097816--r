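#' Discrete Bateman smoothing kernel
#'
#' `h[k] = exp(-k / (tau1 * rate)) - exp(-k / (tau2 * rate))` for
#' `k = 0, ..., length - 1`, normalized to unit sum so that smoothing preserves
#' signal level. `h[0] = 0` by construction. Defaults: 12 samples, the
#' conventional EDA time constants tau1 = 2 s / tau2 = 0.75 s, 4 Hz.
#'
#' @param tau1_s,tau2_s time constants in seconds (`tau1 > tau2 > 0`).
#' @param rate_hz sampling rate, Hz.
#' @param length_samples kernel length.
#' @return numeric vector summing to 1.
#' @export
bateman_kernel <- function(tau1_s = 2, tau2_s = 0.75, rate_hz = 4,
                           length_samples = 12) {
  if (tau1_s <= tau2_s || tau2_s <= 0) stopf("need tau1 > tau2 > 0")
  k <- seq_len(length_samples) - 1
  h <- exp(-k / (tau1_s * rate_hz)) - exp(-k / (tau2_s * rate_hz))
  h / sum(h)
}

#' Smooth EDA with the 12-sample Bateman low-pass kernel
#'
#' Causal FIR convolution with the unit-sum Bateman kernel (reflect padding at
#' the start keeps the output the same length as the input); a causal smoother
#' matches the physiology: a skin conductance response cannot precede its
#' driver. Unit kernel sum preserves a constant input exactly.
#'
#' @param eda an `eda` [signal_channel()].
#' @param kernel smoothing kernel (default [bateman_kernel()] at the channel
#'   rate).
#' @return smoothed `eda` channel.
#' @export
smooth_eda <- function(eda, kernel = NULL) {
  stopifnot(inherits(eda, "signal_channel"))
  if (eda$kind != "eda") stopf("smooth_eda expects an eda channel")
  kernel <- kernel %||% bateman_kernel(rate_hz = eda$sampling_rate_hz)
  m <- length(kernel)
  x <- eda$values
  if (length(x) < m) stopf("EDA channel shorter than the %d-sample kernel", m)
  pad <- rev(x[seq_len(m - 1) + 1])     # reflect (exclude the edge sample)
  xp <- c(pad, x)
  y <- stats::filter(xp, kernel, method = "convolution", sides = 1)
  y <- as.numeric(y)[m - 1 + seq_along(x)]
  signal_channel(y, "eda", eda$sampling_rate_hz, eda$start_time)
}

#' Screen an EDA channel for usability
#'
#' The three published screening rules: a trip's EDA is unusable when
#' (1) its mean is below 0.01 microsiemens, (2) it contains no skin
#' conductance responses, or (3) its SCR frequency exceeds 25 counts per
#' minute (an electrode-artifact level; the per-minute denominator keeps the
#' rule independent of trip length).
#'
#' @param eda smoothed `eda` [signal_channel()].
#' @param scr_events SCR event tibble from [detect_scrs()] (needs `onset_s`).
#' @return tibble with `usable` (logical) and `reasons` (list-column of
#'   character flags among `low_mean_eda`, `zero_scr_frequency`,
#'   `excess_scr_frequency`); `usable` is TRUE iff `reasons` is empty.
#' @export
screen_eda <- function(eda, scr_events) {
  stopifnot(inherits(eda, "signal_channel"))
  reasons <- character(0)
  if (mean(eda$values) < 0.01) reasons <- c(reasons, "low_mean_eda")
  n_scr <- nrow(scr_events)
  if (n_scr == 0) reasons <- c(reasons, "zero_scr_frequency")
  per_min <- n_scr / (channel_duration(eda) / 60)
  if (per_min > 25) reasons <- c(reasons, "excess_scr_frequency")
  tibble::tibble(
    usable = length(reasons) == 0,
    n_scr = n_scr,
    scr_per_min = per_min,
    mean_eda_uS = mean(eda$values),
    reasons = list(reasons)
  )
}
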