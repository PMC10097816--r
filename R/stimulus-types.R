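#' The canonical 14 negative environmental stimulus types
#'
#' Nine types describe the presence of undesirable conditions and five the
#' absence of desirable ones. Self-reports must use these types; parsers accept
#' either the integer code (1-14) or a free-text token that normalizes to one
#' of the canonical names (case, punctuation and the parenthetical examples are
#' ignored).
#'
#' @return tibble with columns `code` (1-14) and `name` (snake_case token).
#' @examples
#' stimulus_types()
#' @export
stimulus_types <- function() {
  tibble::tibble(
    code = 1:14,
    name = c(
      "poor_walking_surface",
      "blocked_sidewalk",
      "steep_sidewalk_slope",
      "litter",
      "abandoned_vehicle",
      "high_speed_of_traffic",
      "unattended_dogs",
      "rowdy_people",
      "weather_condition",
      "lack_of_sidewalk",
      "lack_of_crosswalk",
      "lack_of_benches",
      "lack_of_crosswalk_and_pedestrian_light",
      "lack_of_street_trees"
    )
  )
}

normalize_type_token <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\(.*?\\)", "", x)        # drop parenthetical examples
  x <- gsub("[^a-z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  x
}

#' Map stimulus-type tokens to canonical codes
#'
#' @param tokens character or integer vector; character tokens may be names
#'   ("unattended dogs") or numbers ("7").
#' @return integer vector of codes in 1-14.
#' @examples
#' parse_stimulus_types(c("unattended dogs", "7", "Litter"))
#' @export
parse_stimulus_types <- function(tokens) {
  types <- stimulus_types()
  out <- integer(length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (is.numeric(tok) || grepl("^\\s*[0-9]+\\s*$", tok)) {
      code <- as.integer(tok)
      if (is.na(code) || code < 1L || code > 14L) {
        stopf("unknown stimulus type code: '%s'", tok)
      }
      out[i] <- code
    } else {
      norm <- normalize_type_token(tok)
      # tolerate the "high speed of traffic" / "high speed traffic" variants
      hit <- which(types$name == norm |
                     gsub("_of_", "_", types$name) == gsub("_of_", "_", norm))
      if (length(hit) != 1) stopf("unknown stimulus type token: '%s'", tok)
      out[i] <- types$code[hit]
    }
  }
  out
}
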