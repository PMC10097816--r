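# Stimulus-anchored window statistics: for each self-report, a nonstimuli
# window [t0 - L, t0) and a stimuli window [t0, t0 + L) around the passage
# time t0 (the time of the GPS fix nearest the reported location), compared
# with a random-intercept LME and per-type Welch t-tests over L = 5..240 s.

#' Passage times of reports along their trips
#'
#' @param reports report tibble (`report_id`, `trip_id`, `x_m`, `y_m`).
#' @param tracks named list (by trip_id) of geotrack tibbles.
#' @param max_offroute_m reports farther than this from every track fix are
#'   flagged `off_route` (default 40 m, the buffer width).
#' @return reports with `t0` and `exclude_reason` (NA when usable).
#' @export
report_passage_times <- function(reports, tracks, max_offroute_m = 40) {
  t0 <- rep(NA_real_, nrow(reports))
  reason <- rep(NA_character_, nrow(reports))
  for (i in seq_len(nrow(reports))) {
    tr <- tracks[[reports$trip_id[i]]]
    if (is.null(tr)) {
      reason[i] <- "unknown_trip"
      next
    }
    d <- sqrt((tr$x_m - reports$x_m[i])^2 + (tr$y_m - reports$y_m[i])^2)
    j <- which.min(d)
    if (d[j] > max_offroute_m) {
      reason[i] <- "off_route"
    } else {
      t0[i] <- tr$time_s[j]
    }
  }
  dplyr::mutate(reports, t0 = t0, exclude_reason = reason)
}

# cached per-(trip, feature) windowed-mean evaluator honouring interruptions
make_window_mean <- function(features, interruptions_by_trip) {
  keys <- split(seq_len(nrow(features)),
                paste(features$trip_id, features$feature, sep = "\r"))
  cache <- lapply(keys, function(idx) {
    t <- features$time_s[idx]
    v <- features$value[idx]
    o <- order(t)
    t <- t[o]; v <- v[o]
    iv <- interruptions_by_trip[[features$trip_id[idx[1]]]]
    valid <- if (is.null(iv)) rep(TRUE, length(t)) else !in_intervals(t, iv)
    list(t = t, cs = c(0, cumsum(v * valid)), cn = c(0, cumsum(as.numeric(valid))))
  })
  function(trip_id, feature, a, b) {
    key <- paste(trip_id, feature, sep = "\r")
    c_ <- cache[[key]]
    if (is.null(c_)) return(NA_real_)
    lo <- findInterval(a, c_$t, left.open = TRUE) + 1
    hi <- findInterval(b, c_$t, left.open = TRUE)
    if (hi < lo) return(NA_real_)
    nval <- c_$cn[hi + 1] - c_$cn[lo]
    if (nval < 1) return(NA_real_)
    (c_$cs[hi + 1] - c_$cs[lo]) / nval
  }
}

#' Extract matched nonstimuli/stimuli window pairs for one window length
#'
#' For every usable report: nonstimuli value = feature mean over
#' `[t0 - L, t0)`, stimuli value = mean over `[t0, t0 + L)`. A report is
#' excluded (with a reason) when its location is > 40 m off the route, either
#' window extends past the trip span, either window has less than 50% of its
#' span outside interruptions, or one of its windows overlaps the stimuli
#' window of an earlier retained report of the same trip (earlier by t0, so
#' the retained set is independent of input order).
#'
#' @param processed output of [process_trips()].
#' @param reports report tibble.
#' @param L_s window length, seconds (5-240 in the published sweep).
#' @param min_coverage minimum valid (non-interruption) fraction per window.
#' @return tibble with one row per retained (report, feature):
#'   `report_id`, `trip_id`, `subject_id`, `types`, `feature`,
#'   `window_length_s`, `nonstimuli`, `stimuli`. Exclusions (one row per
#'   report) are in `attr(, "exclusions")`.
#' @export
extract_window_pairs <- function(processed, reports, L_s, min_coverage = 0.5) {
  cl_by_trip <- setNames(processed$clean,
                         vapply(processed$clean, function(c) c$trip$trip_id,
                                character(1)))
  tracks <- lapply(cl_by_trip, function(cl) cl$trip$track)
  interruptions <- lapply(cl_by_trip, function(cl) {
    cl$interruptions %||% tibble::tibble(start_s = numeric(0), end_s = numeric(0))
  })
  durations <- vapply(cl_by_trip, function(cl) {
    channel_duration(cl$trip$channels$eda)
  }, numeric(1))
  subjects <- vapply(cl_by_trip, function(cl) cl$trip$subject_id, character(1))

  rp <- report_passage_times(reports, tracks)
  excl <- list()
  retained <- list()
  for (tid in unique(rp$trip_id)) {
    rows <- rp[rp$trip_id == tid, , drop = FALSE]
    rows <- rows[order(rows$t0, rows$report_id), , drop = FALSE]
    kept_windows <- NULL
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, , drop = FALSE]
      reason <- r$exclude_reason
      if (is.na(reason)) {
        t0 <- r$t0
        if (!isTRUE(cl_by_trip[[tid]]$usable)) {
          reason <- "trip_unusable"
        } else if (t0 - L_s < 0 || t0 + L_s > durations[[tid]]) {
          reason <- "truncated"
        } else {
          iv <- interruptions[[tid]]
          cov_pre <- 1 - interval_overlap_seconds(t0 - L_s, t0, iv) / L_s
          cov_post <- 1 - interval_overlap_seconds(t0, t0 + L_s, iv) / L_s
          if (cov_pre < min_coverage || cov_post < min_coverage) {
            reason <- "interrupted"
          } else if (!is.null(kept_windows) &&
                     any(t0 - L_s < kept_windows$end & t0 + L_s > kept_windows$start)) {
            reason <- "overlap"
          }
        }
      }
      if (is.na(reason)) {
        kept_windows <- dplyr::bind_rows(
          kept_windows, tibble::tibble(start = r$t0, end = r$t0 + L_s)
        )
        retained[[length(retained) + 1]] <- r
      } else {
        excl[[length(excl) + 1]] <- tibble::tibble(
          report_id = r$report_id, trip_id = tid, reason = reason
        )
      }
    }
  }
  exclusions <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(report_id = integer(0), trip_id = character(0),
                   reason = character(0))
  if (!length(retained)) {
    out <- tibble::tibble(
      report_id = integer(0), trip_id = character(0), subject_id = character(0),
      types = list(), feature = character(0), window_length_s = numeric(0),
      nonstimuli = numeric(0), stimuli = numeric(0)
    )
    attr(out, "exclusions") <- exclusions
    return(out)
  }
  kept <- dplyr::bind_rows(retained)
  wmean <- make_window_mean(processed$features, interruptions)
  feats <- unique(processed$features$feature)
  rows <- list()
  for (i in seq_len(nrow(kept))) {
    for (f in feats) {
      pre <- wmean(kept$trip_id[i], f, kept$t0[i] - L_s, kept$t0[i])
      post <- wmean(kept$trip_id[i], f, kept$t0[i], kept$t0[i] + L_s)
      if (is.na(pre) || is.na(post)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        report_id = kept$report_id[i], trip_id = kept$trip_id[i],
        subject_id = subjects[[kept$trip_id[i]]],
        types = kept$types[i],
        feature = f, window_length_s = L_s,
        nonstimuli = pre, stimuli = post
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- exclusions
  out
}

#' Fit the random-intercept linear mixed-effects model
#'
#' `y_ij = mu + beta * x_ij + u_i + e_ij`: feature value `y` for subject `i`
#' and window `j`, stimulus indicator `x` (0 = nonstimuli window, 1 = stimuli
#' window), fixed effect `beta`, subject random intercept `u_i`. Fitted by
#' REML via lme4; the p-value is a Wald z-test on `beta`. A singular fit
#' (zero between-subject variance) falls back to pooled ordinary regression,
#' flagged in the result.
#'
#' @param data long tibble with columns `subject`, `x` (0/1), `value`.
#' @param feature label carried into the result.
#' @param window_length_s label carried into the result.
#' @return object of class `walkstress_lme`; see [tidy()] / [glance()].
#' @export
fit_lme <- function(data, feature = NA_character_, window_length_s = NA_real_) {
  if (length(unique(data$x)) < 2) stopf("stimulus indicator x has no contrast")
  if (nrow(data) < 10) stopf("need at least 10 observations")
  if (length(unique(data$subject)) < 2) stopf("need at least 2 subjects")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ x + (1 | subject), data = data, REML = TRUE)
  ))
  pooled <- lme4::isSingular(fit, tol = 1e-5)
  if (pooled) {
    lmfit <- stats::lm(value ~ x, data = data)
    co <- summary(lmfit)$coefficients
    beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
    mu <- co["(Intercept)", "Estimate"]
    var_subj <- 0
    var_resid <- summary(lmfit)$sigma^2
  } else {
    co <- summary(fit)$coefficients
    beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
    mu <- co["(Intercept)", "Estimate"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_subj <- vc$vcov[vc$grp == "subject"]
    var_resid <- vc$vcov[vc$grp == "Residual"]
  }
  z <- beta / se
  structure(
    list(
      feature = feature, window_length_s = window_length_s,
      beta = beta, se = se, statistic = z,
      p_value = 2 * pnorm(-abs(z)),
      mu = mu, var_subject = var_subj, var_resid = var_resid,
      n_obs = nrow(data), n_subjects = length(unique(data$subject)),
      pooled_fallback = pooled
    ),
    class = "walkstress_lme"
  )
}

#' @export
print.walkstress_lme <- function(x, ...) {
  cat(sprintf(
    "<lme %s @ L=%s s: beta=%.4g (se %.3g), p=%.3g, n=%d obs / %d subjects%s>\n",
    x$feature, format(x$window_length_s), x$beta, x$se, x$p_value,
    x$n_obs, x$n_subjects, if (x$pooled_fallback) ", pooled fallback" else ""
  ))
  invisible(x)
}

#' @rdname fit_lme
#' @param x a `walkstress_lme`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.walkstress_lme <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$mu, x$beta),
    std.error = c(NA_real_, x$se),
    statistic = c(NA_real_, x$statistic),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @rdname fit_lme
#' @exportS3Method generics::glance
glance.walkstress_lme <- function(x, ...) {
  tibble::tibble(
    feature = x$feature, window_length_s = x$window_length_s,
    beta = x$beta, p.value = x$p_value, nobs = x$n_obs,
    n_subjects = x$n_subjects, var_subject = x$var_subject,
    var_resid = x$var_resid, pooled_fallback = x$pooled_fallback
  )
}

# long-format rows from a pair table for a single feature
pairs_to_long <- function(pairs, f) {
  pf <- pairs[pairs$feature == f, , drop = FALSE]
  tibble::tibble(
    subject = rep(pf$subject_id, 2),
    x = rep(c(0, 1), each = nrow(pf)),
    value = c(pf$nonstimuli, pf$stimuli)
  )
}

#' Per-type two-sample t-tests on window pairs
#'
#' For each stimulus type (1-14), Welch's two-sample t-test of stimuli-window
#' means against nonstimuli-window means over all pairs whose report includes
#' that type, at significance level 0.05. Types with fewer than 2 pairs are
#' returned with `NA` statistics and a reason.
#'
#' @param pairs pair table from [extract_window_pairs()].
#' @param feature feature to test.
#' @param alpha significance level.
#' @return tibble: `stimulus_type`, `feature`, `window_length_s`, `n_pairs`,
#'   `t_stat`, `p_value`, `significant`, `reason`.
#' @export
ttest_by_type <- function(pairs, feature, alpha = 0.05) {
  pf <- pairs[pairs$feature == feature, , drop = FALSE]
  L <- if (nrow(pf)) pf$window_length_s[1] else NA_real_
  purrr::map_dfr(1:14, function(tp) {
    sel <- vapply(pf$types, function(ts) tp %in% ts, logical(1))
    g <- pf[sel, , drop = FALSE]
    if (nrow(g) < 2) {
      return(tibble::tibble(
        stimulus_type = tp, feature = feature, window_length_s = L,
        n_pairs = nrow(g), t_stat = NA_real_, p_value = NA_real_,
        significant = NA, reason = "fewer than 2 pairs"
      ))
    }
    tt <- tryCatch(t.test(g$stimuli, g$nonstimuli),   # Welch by default
                   error = function(e) NULL)
    if (is.null(tt)) {
      # degenerate (essentially constant) data: no detectable difference
      equal <- isTRUE(all.equal(mean(g$stimuli), mean(g$nonstimuli)))
      tt <- list(statistic = if (equal) 0 else NA_real_,
                 p.value = if (equal) 1 else NA_real_)
    }
    tibble::tibble(
      stimulus_type = tp, feature = feature, window_length_s = L,
      n_pairs = nrow(g), t_stat = unname(tt$statistic),
      p_value = tt$p.value, significant = tt$p.value < alpha,
      reason = NA_character_
    )
  })
}

#' Sweep window lengths and find the minimal significant length per feature
#'
#' Runs [extract_window_pairs()], [fit_lme()] and [ttest_by_type()] for each
#' window length (published grid: 5 to 240 s in 1-s increments) and reports,
#' per feature, the smallest length whose LME fixed effect is significant at
#' `alpha`. Raw p-values only; no multiple-testing correction is applied.
#'
#' @param processed output of [process_trips()].
#' @param reports report tibble.
#' @param lengths_s vector of window lengths, seconds.
#' @param alpha significance level.
#' @param ttests also run the per-type t-tests (slower).
#' @return list of class `walkstress_window_sweep`: `lme_grid`, `ttest_grid`,
#'   `minimal_significant` tibbles.
#' @export
sweep_window_lengths <- function(processed, reports, lengths_s = 5:240,
                                 alpha = 0.05, ttests = TRUE) {
  lme_rows <- list()
  tt_rows <- list()
  for (L in lengths_s) {
    pairs <- extract_window_pairs(processed, reports, L)
    if (nrow(pairs) == 0) next
    for (f in unique(pairs$feature)) {
      long <- pairs_to_long(pairs, f)
      res <- tryCatch(
        glance(fit_lme(long, feature = f, window_length_s = L)),
        error = function(e) NULL
      )
      if (!is.null(res)) lme_rows[[length(lme_rows) + 1]] <- res
      if (ttests) tt_rows[[length(tt_rows) + 1]] <- ttest_by_type(pairs, f, alpha)
    }
  }
  lme_grid <- dplyr::bind_rows(lme_rows)
  ttest_grid <- dplyr::bind_rows(tt_rows)
  minimal <- if (nrow(lme_grid)) {
    lme_grid |>
      dplyr::filter(.data$p.value < alpha) |>
      dplyr::summarise(min_significant_L_s = min(.data$window_length_s),
                       .by = "feature")
  } else {
    tibble::tibble(feature = character(0), min_significant_L_s = numeric(0))
  }
  structure(
    list(lme_grid = lme_grid, ttest_grid = ttest_grid,
         minimal_significant = minimal, alpha = alpha),
    class = "walkstress_window_sweep"
  )
}

#' @export
print.walkstress_window_sweep <- function(x, ...) {
  cat(sprintf("<window sweep: %d LME fits over %d lengths>\n",
              nrow(x$lme_grid), length(unique(x$lme_grid$window_length_s))))
  print(x$minimal_significant)
  invisible(x)
}
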