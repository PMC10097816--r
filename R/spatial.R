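# Street-segment (POI) construction and feature aggregation. All geometry is
# planar; streets are straight centerline pieces, so point assignment reduces
# to point-to-segment projection. Points are first matched to streets (40-m
# flat-capped buffer, nearest centerline wins, lower id on ties); cutting a
# street into POI segments then only re-bins the along-street coordinate,
# which makes the 1-150 m segment-length sweep cheap.

#' Cut streets into POI segments
#'
#' Each centerline is cut into consecutive spans of `length_m`; a final
#' remainder span is kept as its own segment when at least `length_m / 2`,
#' otherwise merged into the previous span. Streets shorter than `length_m`
#' form a single segment. Each segment carries a flat-capped buffer of
#' `buffer_m` (the published width is 40 m).
#'
#' @param streets street tibble (see [make_street_network()]).
#' @param length_m target segment length, meters.
#' @param buffer_m buffer half-width, meters.
#' @return tibble of class `poi_segments`: `segment_id`, `street_id`, `a_m`,
#'   `b_m` (along-street span), endpoint coordinates, `length_m`, `buffer_m`.
#' @export
build_poi_segments <- function(streets, length_m, buffer_m = 40) {
  if (length_m <= 0) stopf("length_m must be positive")
  rows <- lapply(seq_len(nrow(streets)), function(i) {
    len <- streets$length_m[i]
    n_full <- floor(len / length_m)
    rem <- len - n_full * length_m
    if (n_full == 0) {
      cuts <- c(0, len)
    } else if (rem == 0) {
      cuts <- seq(0, len, by = length_m)
    } else if (rem >= length_m / 2) {
      cuts <- c(seq(0, n_full * length_m, by = length_m), len)
    } else {
      cuts <- c(seq(0, (n_full - 1) * length_m, by = length_m), len)
    }
    a <- head(cuts, -1); b <- tail(cuts, -1)
    ux <- (streets$x1[i] - streets$x0[i]) / len
    uy <- (streets$y1[i] - streets$y0[i]) / len
    tibble::tibble(
      street_id = streets$street_id[i],
      a_m = a, b_m = b,
      x0 = streets$x0[i] + a * ux, y0 = streets$y0[i] + a * uy,
      x1 = streets$x0[i] + b * ux, y1 = streets$y0[i] + b * uy
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, segment_id = dplyr::row_number(), .before = 1)
  out$length_m <- out$b_m - out$a_m
  out$buffer_m <- buffer_m
  class(out) <- c("poi_segments", class(out))
  out
}

#' Match points to streets within the flat-capped buffer
#'
#' A point belongs to the street whose centerline is nearest among those whose
#' buffer contains it (perpendicular distance at most `buffer_m` with the
#' orthogonal projection inside the street span); ties break to the lower
#' street index. Points in no buffer get `NA`.
#'
#' @param x,y point coordinates (meters).
#' @param streets street tibble.
#' @param buffer_m buffer half-width.
#' @return tibble `street_id`, `t_m` (along-street meters), `perp_m`.
#' @export
assign_to_streets <- function(x, y, streets, buffer_m = 40) {
  n <- length(x)
  best_d <- rep(Inf, n)
  best_i <- rep(NA_integer_, n)
  best_t <- rep(NA_real_, n)
  for (i in seq_len(nrow(streets))) {
    pd <- point_segment_distance(x, y, streets$x0[i], streets$y0[i],
                                 streets$x1[i], streets$y1[i])
    ok <- pd$inside & pd$perp <= buffer_m & pd$perp < best_d
    best_d[ok] <- pd$perp[ok]
    best_i[ok] <- i
    best_t[ok] <- pd$t_m[ok]
  }
  tibble::tibble(
    street_id = ifelse(is.na(best_i), NA_character_, streets$street_id[best_i]),
    t_m = best_t,
    perp_m = ifelse(is.infinite(best_d), NA_real_, best_d)
  )
}

# map street assignments to segment ids for one segment table
segment_ids_for <- function(assign, segments) {
  out <- rep(NA_integer_, nrow(assign))
  for (sid in unique(stats::na.omit(assign$street_id))) {
    seg <- segments[segments$street_id == sid, , drop = FALSE]
    idx <- which(assign$street_id == sid)
    j <- findInterval(assign$t_m[idx], c(seg$a_m, max(seg$b_m)),
                      rightmost.closed = TRUE)
    j[j < 1] <- 1L
    j[j > nrow(seg)] <- nrow(seg)
    out[idx] <- seg$segment_id[j]
  }
  out
}

#' Z-normalize feature values within each trip
#'
#' Removes between-subject/trip baseline differences before spatial pooling
#' (constant series normalize to 0).
#'
#' @param features geocoded feature tibble.
#' @return same tibble with `value` replaced by the per-(trip, feature)
#'   z-score.
#' @export
normalize_per_trip <- function(features) {
  features |>
    dplyr::mutate(
      value = {
        s <- sd(.data$value)
        if (is.na(s) || s == 0) rep(0, length(.data$value)) else
          (.data$value - mean(.data$value)) / s
      },
      .by = c("trip_id", "feature")
    )
}

#' Aggregate geocoded features onto POI segments
#'
#' Each geocoded point inside a segment buffer contributes to that segment
#' (nearest centerline on overlap); per segment and feature family the mean
#' and standard deviation are computed across all points of all trips.
#' Segments with no points are absent from the output (their count is in
#' `attr(, "n_empty")`).
#'
#' @param features geocoded feature tibble (already normalized if desired;
#'   see [normalize_per_trip()]).
#' @param segments POI segment tibble from [build_poi_segments()].
#' @param streets the street table the segments were built from.
#' @param assignment optional precomputed [assign_to_streets()] result for the
#'   feature points (lets a segment-length sweep reuse the matching).
#' @return wide tibble: `segment_id`, `n_points`, `n_trips`, then
#'   `<feature>_mean` / `<feature>_sd` columns.
#' @export
aggregate_to_segments <- function(features, segments, streets,
                                  assignment = NULL) {
  if (is.null(assignment)) {
    assignment <- assign_to_streets(features$x_m, features$y_m, streets,
                                    buffer_m = segments$buffer_m[1])
  }
  seg_id <- segment_ids_for(assignment, segments)
  df <- features
  df$segment_id <- seg_id
  df <- df[!is.na(df$segment_id), , drop = FALSE]
  long <- df |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else 0,
      n = dplyr::n(),
      .by = c("segment_id", "feature")
    )
  meta <- df |>
    dplyr::summarise(
      n_points = dplyr::n(),
      n_trips = dplyr::n_distinct(.data$trip_id),
      .by = "segment_id"
    )
  wide <- long |>
    tidyr::pivot_wider(
      id_cols = "segment_id", names_from = "feature",
      values_from = c("mean", "sd"), names_glue = "{feature}_{.value}"
    ) |>
    dplyr::left_join(meta, by = "segment_id") |>
    dplyr::arrange(.data$segment_id)
  attr(wide, "n_empty") <- nrow(segments) - nrow(wide)
  wide
}

#' Label POI segments from self-reports
#'
#' A segment containing at least one reported stimulus (report position inside
#' its buffer, nearest-centerline rule on overlaps, lower segment id on exact
#' ties) is a `stimuli` segment; all others are `nonstimuli`.
#'
#' @param samples segment sample tibble from [aggregate_to_segments()].
#' @param reports report tibble.
#' @param segments,streets as in [aggregate_to_segments()].
#' @return `samples` with `label` (factor `stimuli`/`nonstimuli`) and
#'   `n_reports`.
#' @export
label_segments <- function(samples, reports, segments, streets) {
  if (nrow(reports) > 0) {
    asg <- assign_to_streets(reports$x_m, reports$y_m, streets,
                             buffer_m = segments$buffer_m[1])
    seg_id <- segment_ids_for(asg, segments)
    counts <- table(seg_id)
    n_rep <- as.integer(counts[as.character(samples$segment_id)])
    n_rep[is.na(n_rep)] <- 0L
  } else {
    n_rep <- rep(0L, nrow(samples))
  }
  dplyr::mutate(
    samples,
    n_reports = n_rep,
    label = factor(ifelse(n_rep > 0, "stimuli", "nonstimuli"),
                   levels = c("nonstimuli", "stimuli"))
  )
}
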