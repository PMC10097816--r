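# small shared helpers (intervals, seeds, geometry primitives)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive reproducible sub-seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed; per-trip /
#' per-replicate streams are derived deterministically so that adding or
#' reordering trips does not perturb unrelated draws. Kept below 2^31.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- .Random.seed_exists()
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

with_seed <- function(seed, code) {
  old <- .Random.seed_exists()
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Merge, sort and validate half-open intervals
#'
#' @param intervals tibble with columns `start_s`, `end_s`.
#' @return tibble of disjoint sorted intervals.
#' @keywords internal
normalize_intervals <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  iv <- dplyr::arrange(intervals, .data$start_s)
  out_s <- iv$start_s[1]
  out_e <- iv$end_s[1]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      k <- length(out_s)
      if (iv$start_s[i] <= out_e[k]) {
        out_e[k] <- max(out_e[k], iv$end_s[i])
      } else {
        out_s <- c(out_s, iv$start_s[i])
        out_e <- c(out_e, iv$end_s[i])
      }
    }
  }
  tibble::tibble(start_s = out_s, end_s = out_e)
}

# total seconds of [a, b) covered by an interval set
interval_overlap_seconds <- function(a, b, intervals) {
  if (nrow(intervals) == 0) return(0)
  lo <- pmax(a, intervals$start_s)
  hi <- pmin(b, intervals$end_s)
  sum(pmax(0, hi - lo))
}

# TRUE for times falling inside any half-open interval
in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (t >= intervals$start_s[i] & t < intervals$end_s[i])
  }
  hit
}

#' Distance from points to a planar line segment, with projection parameter
#'
#' Flat-capped: the returned `dist` is the perpendicular distance where the
#' orthogonal projection falls inside the segment and `Inf` outside (callers
#' that want round caps can use `dist_end` instead).
#'
#' @param px,py point coordinates (vectors).
#' @param x0,y0,x1,y1 segment endpoints (scalars).
#' @return list with `t_m` (along-segment meters, clamped), `perp` (unsigned
#'   perpendicular distance), `inside` (projection within span), `dist_end`
#'   (distance to nearest point of the segment, round-capped).
#' @keywords internal
point_segment_distance <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    d <- sqrt((px - x0)^2 + (py - y0)^2)
    return(list(t_m = rep(0, length(px)), perp = d, inside = rep(TRUE, length(px)), dist_end = d))
  }
  tt <- ((px - x0) * dx + (py - y0) * dy) / len2
  inside <- tt >= 0 & tt <= 1
  tc <- pmin(pmax(tt, 0), 1)
  cx <- x0 + tc * dx
  cy <- y0 + tc * dy
  dist_end <- sqrt((px - cx)^2 + (py - cy)^2)
  # unclamped foot for perpendicular distance
  fx <- x0 + tt * dx
  fy <- y0 + tt * dy
  perp <- sqrt((px - fx)^2 + (py - fy)^2)
  list(t_m = tc * sqrt(len2), perp = perp, inside = inside, dist_end = dist_end)
}

# centered moving average, width k (odd), edges shrink symmetrically
moving_average <- function(x, k) {
  n <- length(x)
  if (n == 0) return(x)
  half <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# local equirectangular projection of lon/lat to meters around a reference
project_lonlat <- function(lon, lat, lon0 = NULL, lat0 = NULL) {
  lon0 <- lon0 %||% mean(lon)
  lat0 <- lat0 %||% mean(lat)
  r <- 6371008.8
  x <- (lon - lon0) * pi / 180 * r * cos(lat0 * pi / 180)
  y <- (lat - lat0) * pi / 180 * r
  list(x = x, y = y, lon0 = lon0, lat0 = lat0)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
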