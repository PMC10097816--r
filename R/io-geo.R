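# Geospatial i/o. All internal computation is planar (meters): distances that
# matter (40-m buffers, 1-150 m segment lengths) are metric. WGS84 inputs are
# projected once at load with a local equirectangular projection.

#' Read a geotrack (GPS trace) from CSV or GPX
#'
#' CSV columns: `time_s` plus either planar `x_m`/`y_m` or WGS84 `lon`/`lat`.
#' GPX: `<trkpt lat lon><time>` elements (requires the xml2 package). Lon/lat
#' input is projected to planar meters around the track centroid (or a given
#' reference), matching the nominal one-fix-per-3-s convention.
#'
#' @param path file path (`.csv` or `.gpx`).
#' @param lon0,lat0 optional projection reference (defaults: track centroid).
#' @return tibble with `time_s`, `x_m`, `y_m` and a `crs` attribute
#'   (`"planar_m"`), plus `lon0`/`lat0` attributes when projected.
#' @export
read_geotrack <- function(path, lon0 = NULL, lat0 = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.gpx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("xml2", quietly = TRUE)) {
      stopf("reading GPX requires the xml2 package")
    }
    doc <- xml2::read_xml(path)
    pts <- xml2::xml_find_all(doc, ".//*[local-name()='trkpt']")
    if (length(pts) == 0) stopf("no trackpoints in %s", path)
    lat <- as.numeric(xml2::xml_attr(pts, "lat"))
    lon <- as.numeric(xml2::xml_attr(pts, "lon"))
    tim <- xml2::xml_text(xml2::xml_find_first(pts, ".//*[local-name()='time']"))
    time_s <- as.numeric(as.POSIXct(tim, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
    df <- tibble::tibble(time_s = time_s, lon = lon, lat = lat)
  } else {
    df <- tibble::as_tibble(read.csv(path))
  }
  geotrack_from_table(df, lon0 = lon0, lat0 = lat0)
}

geotrack_from_table <- function(df, lon0 = NULL, lat0 = NULL) {
  if (!"time_s" %in% names(df)) stopf("geotrack needs a time_s column")
  if (all(c("x_m", "y_m") %in% names(df))) {
    out <- tibble::tibble(time_s = df$time_s, x_m = df$x_m, y_m = df$y_m)
  } else if (all(c("lon", "lat") %in% names(df))) {
    pr <- project_lonlat(df$lon, df$lat, lon0, lat0)
    out <- tibble::tibble(time_s = df$time_s, x_m = pr$x, y_m = pr$y)
    attr(out, "lon0") <- pr$lon0
    attr(out, "lat0") <- pr$lat0
  } else {
    stopf("geotrack needs x_m/y_m or lon/lat columns")
  }
  if (anyNA(out) || any(!is.finite(out$x_m)) || any(!is.finite(out$y_m))) {
    stopf("geotrack contains non-finite positions")
  }
  if (is.unsorted(out$time_s, strictly = TRUE)) {
    stopf("geotrack timestamps must be strictly increasing")
  }
  attr(out, "crs") <- "planar_m"
  out
}

#' Read self-reported stimulus locations from CSV
#'
#' Expected columns: `trip_id`, coordinates (`x_m`/`y_m` or `lon`/`lat`),
#' `types` (one or more stimulus-type tokens or codes separated by `;`),
#' optional `report_time_s` and `stress_level`. Unknown type tokens are
#' rejected with the offending token named.
#'
#' @param path CSV path.
#' @param lon0,lat0 projection reference; must match the one used for tracks
#'   when coordinates are WGS84.
#' @return tibble with `report_id`, `trip_id`, `x_m`, `y_m`, `types`
#'   (list-column of integer codes), `report_time_s`, `stress_level`.
#' @export
read_stimulus_reports <- function(path, lon0 = NULL, lat0 = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tibble::as_tibble(read.csv(path))
  if (!all(c("trip_id", "types") %in% names(df))) {
    stopf("reports need trip_id and types columns")
  }
  if (all(c("x_m", "y_m") %in% names(df))) {
    x <- df$x_m; y <- df$y_m
  } else if (all(c("lon", "lat") %in% names(df))) {
    if (is.null(lon0) || is.null(lat0)) {
      stopf("lon/lat reports need the track projection reference (lon0, lat0)")
    }
    pr <- project_lonlat(df$lon, df$lat, lon0, lat0)
    x <- pr$x; y <- pr$y
  } else {
    stopf("reports need x_m/y_m or lon/lat columns")
  }
  types <- lapply(strsplit(as.character(df$types), ";"), function(tok) {
    tok <- trimws(tok)
    tok <- tok[nzchar(tok)]
    if (length(tok) == 0) stopf("report with empty stimulus type list")
    sort(unique(parse_stimulus_types(tok)))
  })
  tibble::tibble(
    report_id = if ("report_id" %in% names(df)) df$report_id else seq_len(nrow(df)),
    trip_id = as.character(df$trip_id),
    x_m = x, y_m = y,
    types = types,
    report_time_s = if ("report_time_s" %in% names(df)) df$report_time_s else NA_real_,
    stress_level = if ("stress_level" %in% names(df)) df$stress_level else NA_real_
  )
}

#' Write stimulus reports to CSV (round-trip safe)
#' @param reports tibble as returned by [read_stimulus_reports()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stimulus_reports <- function(reports, path) {
  n <- nrow(reports)
  opt <- function(col) {
    v <- if (col %in% names(reports)) reports[[col]] else rep(NA_real_, n)
    unname(v)
  }
  df <- data.frame(
    report_id = if ("report_id" %in% names(reports)) reports$report_id else seq_len(n),
    trip_id = reports$trip_id,
    x_m = format(reports$x_m, digits = 17, trim = TRUE),
    y_m = format(reports$y_m, digits = 17, trim = TRUE),
    types = vapply(reports$types, paste, character(1), collapse = ";"),
    report_time_s = opt("report_time_s"),
    stress_level = opt("stress_level")
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read street centerlines from GeoJSON
#'
#' Accepts a FeatureCollection of LineStrings. Coordinates are taken as planar
#' meters when the collection carries `"crs": "planar_m"` (the convention used
#' by [write_streets_geojson()]); otherwise they are treated as WGS84 lon/lat
#' and projected with the supplied (or centroid) reference. Multi-vertex lines
#' are split into straight sub-segments.
#'
#' @param path GeoJSON path.
#' @param lon0,lat0 projection reference for WGS84 input.
#' @return street tibble: `street_id`, `x0`, `y0`, `x1`, `y1`, `length_m`.
#' @export
read_streets_geojson <- function(path, lon0 = NULL, lat0 = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stopf("%s is not a GeoJSON FeatureCollection", path)
  planar <- identical(gj$crs, "planar_m") || identical(gj$crs$properties$name, "planar_m")
  rows <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "LineString")) {
      stopf("street features must be LineStrings, found %s", f$geometry$type %||% "NULL")
    }
    coords <- do.call(rbind, lapply(f$geometry$coordinates, function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    if (!planar) {
      if (is.null(lon0)) {
        lon0 <- mean(coords[, 1]); lat0 <- mean(coords[, 2])
      }
      pr <- project_lonlat(coords[, 1], coords[, 2], lon0, lat0)
      coords <- cbind(pr$x, pr$y)
    }
    sid <- f$properties$street_id %||% (length(rows) + 1L)
    for (k in seq_len(nrow(coords) - 1)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        street_id = as.character(sid),
        x0 = coords[k, 1], y0 = coords[k, 2],
        x1 = coords[k + 1, 1], y1 = coords[k + 1, 2]
      )
    }
  }
  streets <- dplyr::bind_rows(rows)
  if (nrow(streets) == 0) stopf("no street segments in %s", path)
  # re-key multi-part streets so each straight piece is one street row
  streets$street_id <- make.unique(streets$street_id, sep = "#")
  streets$length_m <- sqrt((streets$x1 - streets$x0)^2 + (streets$y1 - streets$y0)^2)
  attr(streets, "crs") <- "planar_m"
  streets
}

#' Write street centerlines (or any planar line table) as GeoJSON
#' @param streets street tibble (`street_id`, `x0`, `y0`, `x1`, `y1`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_streets_geojson <- function(streets, path) {
  features <- lapply(seq_len(nrow(streets)), function(i) {
    list(
      type = "Feature",
      properties = list(street_id = streets$street_id[i]),
      geometry = list(
        type = "LineString",
        coordinates = list(
          c(streets$x0[i], streets$y0[i]),
          c(streets$x1[i], streets$y1[i])
        )
      )
    )
  })
  gj <- list(type = "FeatureCollection", crs = "planar_m", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a geotrack to CSV at full precision
#' @param track geotrack tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geotrack <- function(track, path) {
  df <- data.frame(
    time_s = format(track$time_s, digits = 17, trim = TRUE),
    x_m = format(track$x_m, digits = 17, trim = TRUE),
    y_m = format(track$y_m, digits = 17, trim = TRUE)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read track, reports and streets together
#'
#' Convenience wrapper that loads the three geospatial inputs of a study and
#' checks they end up in one planar CRS.
#'
#' @param track_path,reports_path,streets_path file paths.
#' @return list with `track`, `reports`, `streets`.
#' @export
read_geo_inputs <- function(track_path, reports_path, streets_path) {
  track <- read_geotrack(track_path)
  lon0 <- attr(track, "lon0"); lat0 <- attr(track, "lat0")
  reports <- read_stimulus_reports(reports_path, lon0 = lon0, lat0 = lat0)
  streets <- read_streets_geojson(streets_path, lon0 = lon0, lat0 = lat0)
  list(track = track, reports = reports, streets = streets)
}
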