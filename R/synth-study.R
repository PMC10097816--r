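#' Configuration for the synthetic study generator
#'
#' Defaults define the package's standard benchmark: 30 subjects with 5-10
#' walking trips each on a 60-street grid (100-m streets), stimuli at 5 per km
#' whose passage injects a burst of 3 extra SCRs of 0.5 microsiemens, a 20%
#' stride slowdown and a +8 bpm heart-rate bump for 30 s starting 5 s after
#' passage (physiological reactivity appears 5-10 s after passing a stimulus).
#' `effect_scale = 0` gives the matched null benchmark (all effect sizes zero,
#' everything else identical). One integer seed fully determines the study;
#' per-trip substreams are derived from it.
#'
#' @param seed master integer seed.
#' @param n_subjects number of subjects.
#' @param trips_per_subject integer range (min, max), drawn uniformly.
#' @param effect_scale multiplier on all four stimulus effect sizes (1 =
#'   strong-effect benchmark, 0 = null benchmark).
#' @param ... overrides for any other field (see Details in the vignette);
#'   unknown names are rejected.
#' @return object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(seed = 1, n_subjects = 2, trips_per_subject = c(2, 3))
#' @export
synth_config <- function(seed = 1L, n_subjects = 30,
                         trips_per_subject = c(5, 10),
                         effect_scale = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_subjects = n_subjects,
    trips_per_subject = trips_per_subject,
    walk_speed_mps = 1.4,
    step_freq_hz = 2,
    scr_base_rate_per_min = 4,
    scr_amp_mean_uS = 0.3,
    scr_amp_sdlog = 0.4,
    stimulus_effect = list(
      extra_scr_amp_uS = 0.5 * effect_scale,
      scr_burst_count = if (effect_scale > 0) 3 else 0,
      stride_slowdown_frac = 0.2 * effect_scale,
      hr_bump_bpm = 8 * effect_scale
    ),
    effect_lag_s = 5,
    effect_duration_s = 30,
    report_location_sigma_m = 5,
    report_prob = 0.8,
    noise = list(eda_uS = 0.005, acc_g = 0.02, bvp = 0.02, gps_m = 1),
    network = list(n_streets = 60, street_length_m = 100),
    stimulus_density_per_km = 5,
    route_edges = 4,
    pause_rate_per_trip = 0.3,
    pause_duration_range = c(20, 40),
    eda_baseline_uS = 2,
    eda_baseline_sdlog = 0.2,
    hr_baseline_bpm = 75,
    hr_subject_sd = 5,
    acc_amp_g = 0.8,
    bvp_artifact_rate_per_min = 0,
    bvp_artifact_amp = 6
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stopf("unknown synth_config fields: %s", paste(bad, collapse = ", "))
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  nonneg <- c(cfg$walk_speed_mps, cfg$step_freq_hz, cfg$scr_base_rate_per_min,
              unlist(cfg$stimulus_effect), cfg$effect_duration_s,
              cfg$report_location_sigma_m, unlist(cfg$noise),
              cfg$stimulus_density_per_km)
  if (any(nonneg < 0)) stopf("synth_config rates/amplitudes must be >= 0")
  if (cfg$trips_per_subject[1] > cfg$trips_per_subject[2]) {
    stopf("trips_per_subject must be an increasing range")
  }
  structure(cfg, class = "synth_config")
}

#' Simulate one walking trip with injected stimulus effects
#'
#' @param subject_id,trip_id identifiers.
#' @param route list with `vertices` (polyline matrix) as from the network
#'   sampler; must lie on the street network.
#' @param stimuli ground-truth stimulus tibble (`stimulus_id`, `x_m`, `y_m`,
#'   `types` list-column).
#' @param config a [synth_config()].
#' @param trip_seed integer seed for this trip's substream.
#' @return list: `trip` ([walking_trip()]), `reports` tibble, `truth` (list
#'   with `passages`, `pauses`, `scr_onsets`, `true_hr`, `effect_windows`).
#' @export
simulate_trip <- function(subject_id, trip_id, route, stimuli, config,
                          trip_seed = config$seed) {
  cfg <- config
  with_seed(trip_seed, {
    verts <- route$vertices
    arcs <- polyline_arcs(verts)
    total_m <- max(arcs)
    walk_T <- total_m / cfg$walk_speed_mps

    # pauses inserted into the walking timeline
    n_pause <- rpois(1, cfg$pause_rate_per_trip)
    pause_at_walk <- sort(runif(n_pause, 0.1 * walk_T, 0.9 * walk_T))
    pause_dur <- runif(n_pause, cfg$pause_duration_range[1], cfg$pause_duration_range[2])
    walk_to_clock <- function(tw) {  # walking-time -> clock-time
      tw + vapply(tw, function(x) sum(pause_dur[pause_at_walk <= x]), numeric(1))
    }
    T_total <- walk_T + sum(pause_dur)
    # clock start of pause k = pause_at_walk[k] + sum(dur of earlier pauses)
    if (n_pause > 0) {
      starts <- pause_at_walk + c(0, cumsum(pause_dur))[seq_len(n_pause)]
      pauses <- tibble::tibble(start_s = starts, end_s = starts + pause_dur)
    } else {
      pauses <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))
    }
    arc_at_clock <- function(tc) {   # clock-time -> arc distance
      walked <- vapply(tc, function(x) {
        paused <- interval_overlap_seconds(0, x, pauses)
        (x - paused) * cfg$walk_speed_mps
      }, numeric(1))
      pmin(pmax(walked, 0), total_m)
    }

    # stimulus passages: stimuli lying on the route (within 1 m of centerline)
    passages <- tibble::tibble(stimulus_id = character(0), t_pass = numeric(0))
    if (nrow(stimuli) > 0) {
      for (i in seq_len(nrow(stimuli))) {
        near <- polyline_nearest_arc(verts, stimuli$x_m[i], stimuli$y_m[i])
        if (near$dist <= 1) {
          tw <- near$arc / cfg$walk_speed_mps
          passages <- dplyr::bind_rows(passages, tibble::tibble(
            stimulus_id = stimuli$stimulus_id[i],
            t_pass = walk_to_clock(tw)
          ))
        }
      }
    }
    passages <- dplyr::arrange(passages, .data$t_pass)
    effect_windows <- if (nrow(passages) > 0) {
      tibble::tibble(
        start_s = pmin(passages$t_pass + cfg$effect_lag_s, T_total),
        end_s = pmin(passages$t_pass + cfg$effect_lag_s + cfg$effect_duration_s, T_total)
      )
    } else {
      tibble::tibble(start_s = numeric(0), end_s = numeric(0))
    }

    baseline_uS <- cfg$eda_baseline_uS * exp(rnorm(1, 0, cfg$eda_baseline_sdlog))
    hr0 <- cfg$hr_baseline_bpm + rnorm(1, 0, cfg$hr_subject_sd)
    eda <- synth_eda(T_total, cfg, effect_windows, baseline_uS)
    acc <- synth_acc(T_total, cfg, effect_windows, pauses)
    bvp <- synth_bvp(T_total, cfg, effect_windows, hr0)

    gps_t <- seq(0, T_total, by = 3)
    pos <- polyline_point(verts, arc_at_clock(gps_t))
    track <- tibble::tibble(
      time_s = gps_t,
      x_m = pos[, 1] + rnorm(length(gps_t), 0, cfg$noise$gps_m),
      y_m = pos[, 2] + rnorm(length(gps_t), 0, cfg$noise$gps_m)
    )

    trip <- walking_trip(
      trip_id, subject_id,
      channels = c(list(eda = eda$channel, bvp = bvp$channel), acc),
      track = track
    )

    # self-reports: each passed stimulus reported with report_prob
    rep_rows <- list()
    if (nrow(passages) > 0) {
      for (i in seq_len(nrow(passages))) {
        if (runif(1) <= cfg$report_prob) {
          st <- stimuli[stimuli$stimulus_id == passages$stimulus_id[i], ]
          rep_rows[[length(rep_rows) + 1]] <- tibble::tibble(
            trip_id = trip_id,
            x_m = st$x_m + rnorm(1, 0, cfg$report_location_sigma_m),
            y_m = st$y_m + rnorm(1, 0, cfg$report_location_sigma_m),
            types = st$types,
            report_time_s = passages$t_pass[i],
            stimulus_id = st$stimulus_id
          )
        }
      }
    }
    reports <- if (length(rep_rows)) dplyr::bind_rows(rep_rows) else
      tibble::tibble(trip_id = character(0), x_m = numeric(0), y_m = numeric(0),
                     types = list(), report_time_s = numeric(0),
                     stimulus_id = character(0))

    list(
      trip = trip,
      reports = reports,
      truth = list(
        passages = dplyr::mutate(passages, trip_id = trip_id),
        pauses = dplyr::mutate(pauses, trip_id = trip_id),
        scr_onsets = eda$scr_onsets,
        true_hr = dplyr::mutate(bvp$true_hr, trip_id = trip_id),
        beat_times = bvp$beat_times,
        artifact_times = bvp$artifact_times,
        effect_windows = dplyr::mutate(effect_windows, trip_id = trip_id)
      )
    )
  })
}

#' Simulate a full synthetic study
#'
#' Builds the street network, scatters ground-truth stimuli along it at the
#' configured density (with 1-2 of the 14 types each), draws per-subject trip
#' counts uniformly from the configured range, simulates every trip and
#' collects self-reports and ground truth. Fully determined by `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_study`: `trips` (list of [walking_trip()]),
#'   `reports` (tibble), `streets`, `truth` (list), `config`.
#' @export
simulate_study <- function(config) {
  cfg <- config
  streets <- make_street_network(cfg$network$n_streets, cfg$network$street_length_m)
  total_km <- sum(streets$length_m) / 1000

  master <- derive_seeds(cfg$seed, 3)
  stimuli <- with_seed(master[1], {
    n_stim <- round(total_km * cfg$stimulus_density_per_km)
    if (n_stim == 0) {
      tibble::tibble(stimulus_id = character(0), street_id = character(0),
                     x_m = numeric(0), y_m = numeric(0), types = list())
    } else {
      pos_m <- runif(n_stim, 0, sum(streets$length_m))
      cum <- cumsum(streets$length_m)
      idx <- findInterval(pos_m, c(0, cum), rightmost.closed = TRUE)
      along <- pos_m - c(0, cum)[idx]
      frac <- along / streets$length_m[idx]
      tibble::tibble(
        stimulus_id = sprintf("G%03d", seq_len(n_stim)),
        street_id = streets$street_id[idx],
        x_m = streets$x0[idx] + frac * (streets$x1[idx] - streets$x0[idx]),
        y_m = streets$y0[idx] + frac * (streets$y1[idx] - streets$y0[idx]),
        types = lapply(seq_len(n_stim), function(i) {
          sort(sample(1:14, sample(1:2, 1)))
        })
      )
    }
  })

  n_trips_per_subj <- with_seed(master[2], {
    sample(cfg$trips_per_subject[1]:cfg$trips_per_subject[2],
           cfg$n_subjects, replace = TRUE)
  })
  n_total <- sum(n_trips_per_subj)
  trip_seeds <- derive_seeds(master[3], 2L * n_total)
  route_seeds <- trip_seeds[seq_len(n_total)]
  sig_seeds <- trip_seeds[n_total + seq_len(n_total)]

  trips <- vector("list", n_total)
  reports <- list()
  truth <- list(passages = list(), pauses = list(), scr_onsets = list(),
                true_hr = list(), effect_windows = list(),
                beat_times = list(), artifact_times = list())
  k <- 0
  for (s in seq_len(cfg$n_subjects)) {
    subject_id <- sprintf("subj%02d", s)
    for (tr in seq_len(n_trips_per_subj[s])) {
      k <- k + 1
      trip_id <- sprintf("%s_trip%02d", subject_id, tr)
      route <- with_seed(route_seeds[k], sample_route(streets, cfg$route_edges))
      sim <- simulate_trip(subject_id, trip_id, route, stimuli, cfg,
                           trip_seed = sig_seeds[k])
      trips[[k]] <- sim$trip
      if (nrow(sim$reports) > 0) reports[[length(reports) + 1]] <- sim$reports
      truth$passages[[k]] <- sim$truth$passages
      truth$pauses[[k]] <- sim$truth$pauses
      truth$effect_windows[[k]] <- sim$truth$effect_windows
      truth$true_hr[[k]] <- sim$truth$true_hr
      truth$scr_onsets[[k]] <- sim$truth$scr_onsets
      names(truth$scr_onsets)[k] <- trip_id
      truth$beat_times[[k]] <- sim$truth$beat_times
      names(truth$beat_times)[k] <- trip_id
      truth$artifact_times[[k]] <- sim$truth$artifact_times
      names(truth$artifact_times)[k] <- trip_id
    }
  }
  reports <- if (length(reports)) dplyr::bind_rows(reports) else
    tibble::tibble(trip_id = character(0), x_m = numeric(0), y_m = numeric(0),
                   types = list(), report_time_s = numeric(0),
                   stimulus_id = character(0))
  if (nrow(reports) > 0) reports$report_id <- seq_len(nrow(reports))

  structure(
    list(
      trips = trips,
      reports = reports,
      streets = streets,
      truth = list(
        stimuli = stimuli,
        passages = dplyr::bind_rows(truth$passages),
        pauses = dplyr::bind_rows(truth$pauses),
        effect_windows = dplyr::bind_rows(truth$effect_windows),
        true_hr = dplyr::bind_rows(truth$true_hr),
        scr_onsets = truth$scr_onsets,
        beat_times = truth$beat_times,
        artifact_times = truth$artifact_times
      ),
      config = cfg
    ),
    class = "synth_study"
  )
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf(
    "<synth_study: %d subjects, %d trips, %d reports, %d stimuli, %d streets (seed %d)>\n",
    x$config$n_subjects, length(x$trips), nrow(x$reports),
    nrow(x$truth$stimuli), nrow(x$streets), x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic study to disk in the pipeline's exchange formats
#'
#' One directory per trip with E4-style channel CSVs (`EDA.csv`, `BVP.csv`,
#' `ACC.csv`) and `track.csv`; study-level `reports.csv`,
#' `streets.geojson`, `trips.csv` (trip/subject index) and
#' `ground_truth.json`.
#'
#' @param study a `synth_study`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- tibble::tibble(
    trip_id = vapply(study$trips, function(t) t$trip_id, character(1)),
    subject_id = vapply(study$trips, function(t) t$subject_id, character(1))
  )
  write.csv(idx, file.path(dir, "trips.csv"), row.names = FALSE, quote = FALSE)
  for (trip in study$trips) {
    td <- file.path(dir, trip$trip_id)
    dir.create(td, showWarnings = FALSE)
    write_e4_channel(trip$channels$eda, file.path(td, "EDA.csv"))
    write_e4_channel(trip$channels$bvp, file.path(td, "BVP.csv"))
    write_e4_channel(trip$channels[c("acc_x", "acc_y", "acc_z")],
                     file.path(td, "ACC.csv"))
    write_geotrack(trip$track, file.path(td, "track.csv"))
  }
  rep_out <- study$reports
  write_stimulus_reports(rep_out, file.path(dir, "reports.csv"))
  write_streets_geojson(study$streets, file.path(dir, "streets.geojson"))
  truth <- study$truth
  truth$stimuli$types <- lapply(truth$stimuli$types, as.integer)
  jsonlite::write_json(
    list(
      stimuli = truth$stimuli,
      passages = truth$passages,
      pauses = truth$pauses,
      effect_windows = truth$effect_windows
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir study directory.
#' @return list with `trips`, `reports`, `streets` (no ground truth: the
#'   pipeline never consumes it).
#' @export
read_study <- function(dir) {
  idx <- read.csv(file.path(dir, "trips.csv"))
  trips <- lapply(seq_len(nrow(idx)), function(i) {
    td <- file.path(dir, idx$trip_id[i])
    acc <- read_e4_channel(file.path(td, "ACC.csv"), "acc")
    walking_trip(
      idx$trip_id[i], idx$subject_id[i],
      channels = c(
        list(
          eda = read_e4_channel(file.path(td, "EDA.csv"), "eda"),
          bvp = read_e4_channel(file.path(td, "BVP.csv"), "bvp")
        ),
        acc
      ),
      track = read_geotrack(file.path(td, "track.csv"))
    )
  })
  list(
    trips = trips,
    reports = read_stimulus_reports(file.path(dir, "reports.csv")),
    streets = read_streets_geojson(file.path(dir, "streets.geojson"))
  )
}
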