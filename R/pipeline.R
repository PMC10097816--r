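#' Default pipeline configuration
#'
#' Every default matches the published analysis constant where one exists:
#' 0.01 microsiemens mean-EDA floor, 25 SCR/min ceiling, 4 Hz IMU low-pass,
#' 3 s STFT window with the 0.5 amplitude threshold and 15 s minimum
#' interruption, 5-240 s stimulus window grid, 40 m buffer, 1-150 m segment
#' lengths, fivefold cross-validation. Synthetic-study fields are the
#' [synth_config()] defaults.
#'
#' @param seed master seed applied to every stochastic stage.
#' @return nested named list of class `walkstress_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    synth = unclass(synth_config(seed = seed)),
    preprocess = list(
      tonic_window_s = 4,
      min_scr_amp_uS = 0.01,
      imu_cutoff_hz = 4,
      stft_window_s = 3,
      stft_amp_threshold = 0.5,
      min_interruption_s = 15,
      bvp_band_hz = c(0.6, 4),
      dwt_levels = 5,
      hr_ma_beats = 5
    ),
    features = list(
      scr_freq_window_s = 60,
      psc_cost_factor = 2,
      psc_weighting = "inverse_distance"
    ),
    stats = list(
      window_lengths_s = c(5, 240),   # range, stepped by window_step_s
      window_step_s = 1,
      alpha = 0.05
    ),
    spatial = list(
      buffer_m = 40,
      segment_lengths_m = segment_length_grid(),
      report_length_m = 40,
      n_folds = 5,
      normalize = TRUE
    )
  ), class = "walkstress_config")
}

#' Validate a configuration against the schema
#'
#' Unknown keys anywhere in the hierarchy are rejected; known keys override
#' defaults.
#'
#' @param config partial or full configuration list.
#' @return complete validated `walkstress_config`.
#' @export
validate_config <- function(config) {
  ref <- default_config(seed = config$seed %||% 1L)
  merge_checked <- function(ref, cfg, path = "") {
    bad <- setdiff(names(cfg), names(ref))
    if (length(bad)) {
      stopf("unknown config key%s: %s", if (length(bad) > 1) "s" else "",
            paste0(path, bad, collapse = ", "))
    }
    for (nm in names(cfg)) {
      if (is.list(ref[[nm]]) && is.list(cfg[[nm]]) && !is.null(names(ref[[nm]]))) {
        ref[[nm]] <- merge_checked(ref[[nm]], cfg[[nm]], paste0(path, nm, "$"))
      } else {
        ref[[nm]] <- cfg[[nm]]
      }
    }
    ref
  }
  out <- merge_checked(unclass(ref), unclass(config))
  class(out) <- "walkstress_config"
  out
}

#' Read / write a configuration as YAML
#' @param path YAML file path.
#' @return [validate_config()]-checked configuration.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# --- clean-trip disk round trip (pipeline stage exchange) -------------------

write_clean_trip <- function(cl, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trip <- cl$trip
  write_e4_channel(trip$channels$eda, file.path(dir, "EDA.csv"))
  write_e4_channel(trip$channels$bvp, file.path(dir, "BVP.csv"))
  write_e4_channel(trip$channels[c("acc_x", "acc_y", "acc_z")],
                   file.path(dir, "ACC.csv"))
  write_geotrack(trip$track, file.path(dir, "track.csv"))
  write.csv(cl$scr, file.path(dir, "scr.csv"), row.names = FALSE)
  write.csv(cl$scl, file.path(dir, "scl.csv"), row.names = FALSE)
  write.csv(cl$heart_rate, file.path(dir, "hr.csv"), row.names = FALSE)
  write.csv(cl$interruptions, file.path(dir, "interruptions.csv"), row.names = FALSE)
  invisible(dir)
}

read_clean_trip <- function(dir, trip_id, subject_id, usable) {
  acc <- read_e4_channel(file.path(dir, "ACC.csv"), "acc")
  trip <- walking_trip(
    trip_id, subject_id,
    channels = c(
      list(eda = read_e4_channel(file.path(dir, "EDA.csv"), "eda"),
           bvp = read_e4_channel(file.path(dir, "BVP.csv"), "bvp")),
      acc
    ),
    track = read_geotrack(file.path(dir, "track.csv"))
  )
  structure(
    list(
      trip = trip,
      scr = tibble::as_tibble(read.csv(file.path(dir, "scr.csv"))),
      scl = tibble::as_tibble(read.csv(file.path(dir, "scl.csv"))),
      heart_rate = tibble::as_tibble(read.csv(file.path(dir, "hr.csv"))),
      interruptions = tibble::as_tibble(read.csv(file.path(dir, "interruptions.csv"))),
      usable = usable
    ),
    class = "clean_trip"
  )
}

read_clean_dir <- function(clean_dir) {
  qc <- tibble::as_tibble(read.csv(file.path(clean_dir, "qc.csv")))
  clean <- lapply(seq_len(nrow(qc)), function(i) {
    read_clean_trip(file.path(clean_dir, qc$trip_id[i]),
                    qc$trip_id[i], qc$subject_id[i], qc$usable[i])
  })
  list(clean = clean, qc = qc)
}

# --- staged pipeline --------------------------------------------------------

pipeline_stages <- c("simulate", "preprocess", "features", "stats", "spatial")

#' Run the full pipeline (or a subset of stages) against a directory
#'
#' Stages run in order `simulate` (write a synthetic study),
#' `preprocess` (per-trip cleaning + QC report), `features` (geocoded feature
#' CSV), `stats` (window-length sweep tables) and `spatial` (segment-length
#' sweep results + labeled segment GeoJSON at the 40-m reference length). Each
#' stage reads only the previous stage's on-disk outputs; missing upstream
#' outputs raise an error naming the stage to run first. A manifest with the
#' seed, parameters and per-stage output checksums is written; re-running the
#' same configuration reproduces all outputs bit-exactly.
#'
#' @param config a [default_config()]-style configuration (validated here).
#' @param out_dir working directory for all stage outputs.
#' @param stages subset of `c("simulate", "preprocess", "features", "stats",
#'   "spatial")`.
#' @return the manifest tibble, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = pipeline_stages) {
  config <- validate_config(config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study_dir <- file.path(out_dir, "study")
  clean_dir <- file.path(out_dir, "clean")
  feat_dir <- file.path(out_dir, "features")
  stats_dir <- file.path(out_dir, "stats")
  spatial_dir <- file.path(out_dir, "spatial")
  need <- function(dir, stage) {
    if (!dir.exists(dir)) {
      stopf("missing upstream outputs in %s: run stage '%s' first", dir, stage)
    }
  }
  manifest <- list()
  note <- function(stage, dir) {
    files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
    sums <- tools::md5sum(files)
    # one digest over the sorted per-file md5s
    tfc <- tempfile()
    writeLines(paste(basename(files), unname(sums)), tfc)
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, n_files = length(files),
      checksum = unname(tools::md5sum(tfc))
    )
    unlink(tfc)
  }

  if ("simulate" %in% stages) {
    cfg <- do.call(synth_config, config$synth[setdiff(names(config$synth), character(0))])
    study <- simulate_study(cfg)
    unlink(study_dir, recursive = TRUE)
    write_study(study, study_dir)
    note("simulate", study_dir)
  }
  if ("preprocess" %in% stages) {
    need(study_dir, "simulate")
    study <- read_study(study_dir)
    processed <- process_trips(study$trips, params = config)
    unlink(clean_dir, recursive = TRUE)
    dir.create(clean_dir, recursive = TRUE)
    for (cl in processed$clean) {
      if (!is.null(cl$trip$channels$eda) && isTRUE(cl$usable)) {
        write_clean_trip(cl, file.path(clean_dir, cl$trip$trip_id))
      }
    }
    qc <- processed$qc[processed$qc$usable, , drop = FALSE]
    write.csv(processed$qc, file.path(clean_dir, "qc_all.csv"), row.names = FALSE)
    write.csv(qc, file.path(clean_dir, "qc.csv"), row.names = FALSE)
    note("preprocess", clean_dir)
  }
  if ("features" %in% stages) {
    need(clean_dir, "preprocess")
    cd <- read_clean_dir(clean_dir)
    params <- config$features
    features <- dplyr::bind_rows(lapply(cd$clean, extract_trip_features,
                                        params = params))
    unlink(feat_dir, recursive = TRUE)
    dir.create(feat_dir, recursive = TRUE)
    write.csv(features, file.path(feat_dir, "features.csv"), row.names = FALSE)
    note("features", feat_dir)
  }
  if ("stats" %in% stages) {
    need(feat_dir, "features")
    need(clean_dir, "preprocess")
    need(study_dir, "simulate")
    cd <- read_clean_dir(clean_dir)
    features <- tibble::as_tibble(read.csv(file.path(feat_dir, "features.csv")))
    reports <- read_stimulus_reports(file.path(study_dir, "reports.csv"))
    lengths <- seq(config$stats$window_lengths_s[1],
                   config$stats$window_lengths_s[2],
                   by = config$stats$window_step_s)
    sweep <- sweep_window_lengths(
      list(features = features, clean = cd$clean), reports,
      lengths_s = lengths, alpha = config$stats$alpha
    )
    unlink(stats_dir, recursive = TRUE)
    dir.create(stats_dir, recursive = TRUE)
    write.csv(sweep$lme_grid, file.path(stats_dir, "lme_grid.csv"), row.names = FALSE)
    write.csv(sweep$ttest_grid, file.path(stats_dir, "ttest_grid.csv"), row.names = FALSE)
    write.csv(sweep$minimal_significant,
              file.path(stats_dir, "minimal_significant.csv"), row.names = FALSE)
    note("stats", stats_dir)
  }
  if ("spatial" %in% stages) {
    need(feat_dir, "features")
    need(study_dir, "simulate")
    features <- tibble::as_tibble(read.csv(file.path(feat_dir, "features.csv")))
    reports <- read_stimulus_reports(file.path(study_dir, "reports.csv"))
    streets <- read_streets_geojson(file.path(study_dir, "streets.geojson"))
    sweep <- sweep_segment_lengths(
      features, reports, streets,
      lengths_m = config$spatial$segment_lengths_m,
      buffer_m = config$spatial$buffer_m,
      n_folds = config$spatial$n_folds,
      seed = config$seed,
      normalize = config$spatial$normalize
    )
    unlink(spatial_dir, recursive = TRUE)
    dir.create(spatial_dir, recursive = TRUE)
    write.csv(sweep, file.path(spatial_dir, "results.csv"), row.names = FALSE)
    # heat-map-ready export at the reference length
    L <- config$spatial$report_length_m
    segs <- build_poi_segments(streets, L, config$spatial$buffer_m)
    feats_n <- if (config$spatial$normalize) normalize_per_trip(features) else features
    samples <- aggregate_to_segments(feats_n, segs, streets)
    samples <- label_segments(samples, reports, segs, streets)
    # predicted probabilities are a bonus layer; skip them when the demo study
    # is too small to cross-validate
    fit <- tryCatch(
      suppressWarnings(classify_segments(samples, seed = config$seed)),
      error = function(e) NULL
    )
    write_segments_geojson(segs, samples, fit, file.path(spatial_dir, "segments.geojson"))
    note("spatial", spatial_dir)
  }
  manifest <- dplyr::bind_rows(manifest)
  manifest$seed <- config$seed
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, stages = manifest,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("walkstress"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(manifest)
}

#' Export labeled, scored segments as GeoJSON (distress heat map)
#'
#' One LineString per POI segment with its aggregates, label and, when a
#' classification is supplied, the cross-validated predicted probability of
#' the stimuli class.
#'
#' @param segments POI segment tibble.
#' @param samples labeled segment samples.
#' @param fit optional `walkstress_classification` with `predictions`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_geojson <- function(segments, samples, fit = NULL, path) {
  prob <- NULL
  if (!is.null(fit) && !is.null(fit$predictions)) {
    prob <- setNames(fit$predictions$prob_stimuli, fit$predictions$segment_id)
  }
  features <- lapply(seq_len(nrow(samples)), function(i) {
    seg <- segments[segments$segment_id == samples$segment_id[i], ]
    props <- as.list(samples[i, setdiff(names(samples), "label")])
    props$label <- as.character(samples$label[i])
    props$prob_stimuli <- if (!is.null(prob))
      unname(prob[as.character(samples$segment_id[i])]) else NA
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "LineString",
        coordinates = list(c(seg$x0, seg$y0), c(seg$x1, seg$y1))
      )
    )
  })
  gj <- list(type = "FeatureCollection", crs = "planar_m", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
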