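# Per-channel synthetic signal models. Each emulates the qualitative structure
# the pipeline assumes, not detailed physiology: EDA = tonic drift + Bateman
# SCRs, ACC = quasi-periodic gait with pauses, BVP = raised-cosine pulse train
# with a controllable instantaneous rate.

#' Peak-normalized Bateman SCR waveform
#'
#' `h(t) = exp(-t / tau1) - exp(-t / tau2)` scaled to unit peak: the canonical
#' skin-conductance-response shape (slow recovery `tau1`, fast rise `tau2`).
#'
#' @param t times since SCR onset, seconds (values at `t < 0` are 0).
#' @param tau1_s,tau2_s recovery and rise time constants (`tau1 > tau2 > 0`);
#'   defaults 2 s and 0.75 s, standard EDA modeling values.
#' @return numeric vector, peak value 1.
#' @export
scr_shape <- function(t, tau1_s = 2, tau2_s = 0.75) {
  if (tau1_s <= tau2_s || tau2_s <= 0) stopf("need tau1 > tau2 > 0")
  tpk <- log(tau1_s / tau2_s) * tau1_s * tau2_s / (tau1_s - tau2_s)
  pk <- exp(-tpk / tau1_s) - exp(-tpk / tau2_s)
  out <- ifelse(t < 0, 0, exp(-t / tau1_s) - exp(-t / tau2_s)) / pk
  out
}

# add SCRs (onset times + amplitudes, µS) onto a sampled EDA vector
add_scrs <- function(values, rate_hz, onsets_s, amps, tau1_s = 2, tau2_s = 0.75) {
  n <- length(values)
  support <- ceiling(8 * tau1_s * rate_hz)   # kernel ~0 beyond 8 tau1
  for (i in seq_along(onsets_s)) {
    i0 <- floor(onsets_s[i] * rate_hz) + 1
    if (i0 > n) next
    idx <- i0:min(n, i0 + support)
    tt <- (idx - 1) / rate_hz - onsets_s[i]
    values[idx] <- values[idx] + amps[i] * scr_shape(tt, tau1_s, tau2_s)
  }
  values
}

# synthetic EDA channel: tonic baseline + slow drift + background & injected SCRs
synth_eda <- function(duration_s, cfg, effect_windows, baseline_uS) {
  rate <- 4
  n <- ceiling(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  tonic <- baseline_uS +
    0.15 * baseline_uS * sin(2 * pi * t / max(duration_s, 120) + runif(1, 0, 2 * pi))
  # background SCRs: Poisson in time
  n_bg <- rpois(1, cfg$scr_base_rate_per_min * duration_s / 60)
  onsets <- sort(runif(n_bg, 0, duration_s))
  amps <- exp(rnorm(n_bg, log(cfg$scr_amp_mean_uS), cfg$scr_amp_sdlog))
  # injected SCR bursts inside effect windows
  eff <- cfg$stimulus_effect
  if (eff$scr_burst_count > 0 && eff$extra_scr_amp_uS > 0 && nrow(effect_windows) > 0) {
    for (w in seq_len(nrow(effect_windows))) {
      on <- sort(runif(eff$scr_burst_count,
                       effect_windows$start_s[w],
                       max(effect_windows$start_s[w],
                           effect_windows$end_s[w] - 8)))  # leave room to rise
      onsets <- c(onsets, on)
      amps <- c(amps, rep(eff$extra_scr_amp_uS, length(on)))
    }
  }
  values <- add_scrs(tonic, rate, onsets, amps) + rnorm(n, 0, cfg$noise$eda_uS)
  list(
    channel = signal_channel(values, "eda", rate, 0),
    scr_onsets = sort(onsets)
  )
}

# synthetic triaxial gait accelerometry (g). Vertical axis (z) carries gravity
# plus the step oscillation; pauses null the oscillation.
synth_acc <- function(duration_s, cfg, effect_windows, pauses) {
  rate <- 50
  n <- ceiling(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  freq <- rep(cfg$step_freq_hz, n)
  slow <- cfg$stimulus_effect$stride_slowdown_frac
  if (slow > 0 && nrow(effect_windows) > 0) {
    # stride period lengthened by the slowdown fraction
    freq[in_intervals(t, effect_windows)] <- cfg$step_freq_hz / (1 + slow)
  }
  freq[in_intervals(t, pauses)] <- 0
  phase <- cumsum(freq) / rate
  a <- cfg$acc_amp_g
  moving <- freq > 0
  z <- 1 + moving * (a * sin(2 * pi * phase) + 0.3 * a * sin(4 * pi * phase + 0.7)) +
    rnorm(n, 0, cfg$noise$acc_g)
  x <- moving * 0.3 * a * sin(2 * pi * phase + 1.1) + rnorm(n, 0, cfg$noise$acc_g)
  y <- moving * 0.25 * a * sin(2 * pi * phase + 2.3) + rnorm(n, 0, cfg$noise$acc_g)
  list(
    acc_x = signal_channel(x, "acc_x", rate, 0),
    acc_y = signal_channel(y, "acc_y", rate, 0),
    acc_z = signal_channel(z, "acc_z", rate, 0)
  )
}

# synthetic BVP: one raised-cosine systolic bump per beat; instantaneous rate
# = baseline + slow wander + hr bump inside effect windows; optional artifact
# bursts. Returns the channel plus the true instantaneous rate at 1 Hz.
synth_bvp <- function(duration_s, cfg, effect_windows, hr_baseline_bpm) {
  rate <- 64
  n <- ceiling(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  hr <- hr_baseline_bpm + 2.5 * sin(2 * pi * t / 90 + runif(1, 0, 2 * pi))
  bump_bpm <- cfg$stimulus_effect$hr_bump_bpm
  if (bump_bpm != 0 && nrow(effect_windows) > 0) {
    hr <- hr + bump_bpm * in_intervals(t, effect_windows)
  }
  phase <- cumsum(hr / 60) / rate
  beat_idx <- which(diff(floor(phase)) >= 1) + 1
  beat_times <- t[beat_idx]
  values <- rep(0, n)
  ibi <- c(diff(beat_times), if (length(beat_times) > 1) median(diff(beat_times)) else 0.8)
  for (b in seq_along(beat_times)) {
    w <- min(0.5 * ibi[b], 0.45)          # systolic bump width, s
    idx0 <- max(1, floor((beat_times[b] - w / 2) * rate) + 1)
    idx1 <- min(n, ceiling((beat_times[b] + w / 2) * rate) + 1)
    tt <- (idx0:idx1 - 1) / rate - beat_times[b]
    values[idx0:idx1] <- values[idx0:idx1] + cos(pi * tt / w)^2 * (abs(tt) < w / 2)
  }
  # artifact bursts
  n_art <- rpois(1, cfg$bvp_artifact_rate_per_min * duration_s / 60)
  art_times <- sort(runif(n_art, 0, max(0.1, duration_s - 0.5)))
  for (at in art_times) {
    idx <- which(t >= at & t < at + 0.3)
    values[idx] <- values[idx] + runif(length(idx), -1, 1) * cfg$bvp_artifact_amp
  }
  values <- values + rnorm(n, 0, cfg$noise$bvp)
  list(
    channel = signal_channel(values, "bvp", rate, 0),
    true_hr = tibble::tibble(time_s = seq(0, duration_s - 1),
                             bpm = approx(t, hr, xout = seq(0, duration_s - 1), rule = 2)$y),
    beat_times = beat_times,
    artifact_times = art_times
  )
}
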