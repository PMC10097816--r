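#' Physiological saliency cue (PSC)
#'
#' Scores each segment by the contrast between its representative attribute
#' and those of all other segments, weighted by inverse distance between
#' segment centers: for segment i,
#' `PSC(i) = sum_{j != i} w_ij * |a_i - a_j|` with
#' `w_ij = (1 / d_ij) / sum_{k != i} (1 / d_ik)` and `d_ij` the distance
#' between segment centers in samples. Weights are normalized, so PSC is a
#' weighted mean absolute contrast, nonnegative by construction. An unweighted
#' variant (`weighting = "uniform"`) averages `|a_i - a_j|` evenly.
#'
#' @param series the segmented numeric series.
#' @param segments a `bu_segments` tibble from [bottomup_segment()].
#' @param weighting `"inverse_distance"` (default) or `"uniform"`.
#' @return list: `per_segment` (tibble `segment`, `psc`), `per_sample`
#'   (numeric vector, each sample carries its segment's PSC). A single segment
#'   yields all-zero PSC.
#' @export
compute_psc <- function(series, segments,
                        weighting = c("inverse_distance", "uniform")) {
  weighting <- match.arg(weighting)
  k <- nrow(segments)
  n <- length(series)
  if (segments$end[k] != n || segments$start[1] != 1) {
    stopf("segment boundaries do not cover the series")
  }
  centers <- (segments$start + segments$end) / 2
  a <- segments$mean
  psc <- numeric(k)
  if (k > 1) {
    for (i in seq_len(k)) {
      d <- abs(centers[i] - centers[-i])
      contrast <- abs(a[i] - a[-i])
      w <- switch(weighting,
        inverse_distance = (1 / d) / sum(1 / d),
        uniform = rep(1 / (k - 1), k - 1)
      )
      psc[i] <- sum(w * contrast)
    }
  }
  per_sample <- rep(psc, times = segments$end - segments$start + 1)
  list(
    per_segment = tibble::tibble(segment = segments$segment, psc = psc),
    per_sample = per_sample
  )
}

#' Segment a series and return its per-sample PSC
#'
#' Convenience wrapper: [bottomup_segment()] then [compute_psc()], returning a
#' time-indexed tibble.
#'
#' @param time_s timestamps of the series samples.
#' @param values series values.
#' @param max_merge_cost see [bottomup_segment()].
#' @param weighting see [compute_psc()].
#' @return tibble `time_s`, `value` (PSC per sample).
#' @export
psc_series <- function(time_s, values, max_merge_cost = NULL,
                       weighting = "inverse_distance") {
  if (length(values) < 2) {
    return(tibble::tibble(time_s = numeric(0), value = numeric(0)))
  }
  seg <- bottomup_segment(values, max_merge_cost)
  psc <- compute_psc(values, seg, weighting)
  tibble::tibble(time_s = time_s, value = psc$per_sample)
}
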