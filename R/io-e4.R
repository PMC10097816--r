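#' Read an E4-style per-channel CSV
#'
#' The input convention mirrors the per-channel CSV export of E4-class wrist
#' sensors: line 1 is the UTC start timestamp (seconds), line 2 the sampling
#' rate in Hz, then one sample per line. Acceleration files carry three
#' comma-separated columns (x, y, z) and yield three channels; for those the
#' header lines may repeat the value per column.
#'
#' @param path file path.
#' @param kind `"eda"`, `"bvp"` or `"acc"` (the latter returns a list of three
#'   channels `acc_x`, `acc_y`, `acc_z`).
#' @return a [signal_channel()], or a named list of three for `"acc"`.
#' @export
read_e4_channel <- function(path, kind = c("eda", "bvp", "acc")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stopf("malformed E4 file %s: missing header lines 1-2", path)
  parse_header <- function(line, what, lineno) {
    vals <- suppressWarnings(as.numeric(strsplit(line, ",")[[1]]))
    if (length(vals) < 1 || anyNA(vals)) {
      stopf("malformed E4 file %s: non-numeric %s on line %d", path, what, lineno)
    }
    vals[1]
  }
  start_time <- parse_header(lines[1], "start timestamp", 1L)
  rate <- parse_header(lines[2], "sampling rate", 2L)
  if (rate <= 0) stopf("malformed E4 file %s: nonpositive sampling rate on line 2", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stopf("empty E4 channel body in %s", path)
  cells <- strsplit(body, ",")
  ncol <- length(cells[[1]])
  if (!all(lengths(cells) == ncol)) stopf("malformed E4 file %s: ragged rows", path)
  mat <- matrix(suppressWarnings(as.numeric(unlist(cells))), ncol = ncol, byrow = TRUE)
  if (anyNA(mat)) stopf("malformed E4 file %s: non-numeric sample value", path)
  if (kind == "acc") {
    if (ncol != 3) stopf("ACC file %s must have 3 columns, found %d", path, ncol)
    axes <- c("acc_x", "acc_y", "acc_z")
    out <- lapply(1:3, function(j) signal_channel(mat[, j], axes[j], rate, start_time))
    names(out) <- axes
    return(out)
  }
  if (ncol != 1) stopf("%s file %s must have 1 column, found %d", kind, path, ncol)
  signal_channel(mat[, 1], kind, rate, start_time)
}

#' Write an E4-style per-channel CSV
#'
#' Full-precision text so that write/read round-trips are bit-exact.
#'
#' @param ch a [signal_channel()], or a list of the three acc channels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_e4_channel <- function(ch, path) {
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  if (inherits(ch, "signal_channel")) {
    lines <- c(fmt(ch$start_time), fmt(ch$sampling_rate_hz), fmt(ch$values))
  } else {
    stopifnot(length(ch) == 3)
    rates <- vapply(ch, function(c) c$sampling_rate_hz, numeric(1))
    starts <- vapply(ch, function(c) c$start_time, numeric(1))
    ns <- vapply(ch, function(c) length(c$values), numeric(1))
    if (length(unique(rates)) != 1 || length(unique(starts)) != 1 ||
        length(unique(ns)) != 1) {
      stopf("acc channels must share rate, start and length")
    }
    body <- vapply(seq_len(ns[1]), function(i) {
      paste(fmt(c(ch[[1]]$values[i], ch[[2]]$values[i], ch[[3]]$values[i])),
            collapse = ",")
    }, character(1))
    lines <- c(
      paste(rep(fmt(starts[1]), 3), collapse = ","),
      paste(rep(fmt(rates[1]), 3), collapse = ","),
      body
    )
  }
  writeLines(lines, path)
  invisible(path)
}
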