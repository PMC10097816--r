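#' Bottom-up time-series segmentation
#'
#' Classical non-fixed-length change-point segmentation: start from minimal
#' two-sample segments and repeatedly merge the adjacent pair whose merge
#' increases the total within-segment squared error the least, until the
#' cheapest merge would exceed `max_merge_cost`. The representative attribute
#' of each segment is its mean. With `max_merge_cost = Inf` everything merges
#' into a single segment.
#'
#' @param series numeric vector (length >= 2).
#' @param max_merge_cost stopping cap on the squared-error increase of a single
#'   merge; default `2 * var(series)`.
#' @return tibble of class `bu_segments`: `segment` (index), `start`, `end`
#'   (1-based inclusive sample indices), `mean`. The boundary vector (0-based
#'   half-open convention: first 0, last `length(series)`) is in
#'   `attr(, "boundaries")`.
#' @examples
#' bottomup_segment(c(rep(0, 8), rep(5, 8)), max_merge_cost = 10)
#' @export
bottomup_segment <- function(series, max_merge_cost = NULL) {
  n <- length(series)
  if (n < 2) stopf("series must have length >= 2")
  max_merge_cost <- max_merge_cost %||% (2 * var(series))
  # initial two-sample segments (last takes the odd remainder)
  starts <- seq(1, n, by = 2)
  ends <- pmin(starts + 1, n)
  if (length(starts) > 1 && ends[length(ends)] - starts[length(starts)] < 1) {
    # fold a trailing singleton into the previous segment
    k <- length(starts)
    ends[k - 1] <- n
    starts <- starts[-k]; ends <- ends[-k]
  }
  cs <- c(0, cumsum(series))
  cs2 <- c(0, cumsum(series^2))
  seg_stats <- function(a, b) {
    nn <- b - a + 1
    s <- cs[b + 1] - cs[a]
    s2 <- cs2[b + 1] - cs2[a]
    c(nn, s, s2 - s^2 / nn)   # n, sum, sse
  }
  m <- length(starts)
  stats_mat <- t(vapply(seq_len(m), function(i) seg_stats(starts[i], ends[i]),
                        numeric(3)))
  merge_cost <- function(i, j) {
    st <- seg_stats(starts[i], ends[j])
    st[3] - stats_mat[i, 3] - stats_mat[j, 3]
  }
  if (m > 1) {
    costs <- vapply(seq_len(m - 1), function(i) merge_cost(i, i + 1), numeric(1))
  } else {
    costs <- numeric(0)
  }
  while (length(costs) > 0) {
    i <- which.min(costs)
    if (costs[i] > max_merge_cost) break
    # merge segments i and i+1
    ends[i] <- ends[i + 1]
    starts <- starts[-(i + 1)]; ends <- ends[-(i + 1)]
    stats_mat[i, ] <- seg_stats(starts[i], ends[i])
    stats_mat <- stats_mat[-(i + 1), , drop = FALSE]
    costs <- costs[-i]
    if (i > 1) costs[i - 1] <- merge_cost(i - 1, i)
    if (i <= length(costs)) costs[i] <- merge_cost(i, i + 1)
  }
  out <- tibble::tibble(
    segment = seq_along(starts),
    start = starts, end = ends,
    mean = (cs[ends + 1] - cs[starts]) / (ends - starts + 1)
  )
  attr(out, "boundaries") <- c(starts - 1L, n)
  class(out) <- c("bu_segments", class(out))
  out
}
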