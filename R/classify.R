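#' Classify POI segments with Gaussian naive Bayes
#'
#' Binary stimuli/nonstimuli classification of labeled segment samples from
#' the selected feature families (mean and SD aggregate per family), assessed
#' with stratified fivefold cross-validation. Performance is the unweighted
#' average recall (UAR) - the mean of the per-class recalls pooled over folds,
#' which is chance 0.5 regardless of class imbalance. Missing aggregates are
#' imputed with the training-fold feature mean; rows missing every selected
#' feature are dropped. No resampling or reweighting is applied: UAR itself is
#' the answer to imbalance.
#'
#' @param samples labeled segment tibble from [label_segments()].
#' @param features feature families to use (default all six).
#' @param n_folds cross-validation folds.
#' @param seed integer seed for the fold split.
#' @return object of class `walkstress_classification`: per-fold and pooled
#'   confusion counts, per-class recalls, `uar`.
#' @export
classify_segments <- function(samples, features = feature_families(),
                              n_folds = 5, seed = 1) {
  cols <- as.vector(outer(features, c("mean", "sd"), paste, sep = "_"))
  cols <- intersect(cols, names(samples))
  if (length(cols) == 0) stopf("none of the requested feature columns present")
  X <- as.data.frame(samples[, cols, drop = FALSE])
  y <- samples$label
  keep <- rowSums(!is.na(X)) > 0
  X <- X[keep, , drop = FALSE]; y <- droplevels(y[keep])
  if (nlevels(y) < 2 || min(table(y)) < 2) {
    stopf("need at least 2 samples per class")
  }
  k <- min(n_folds, min(table(y)))
  if (k < n_folds) {
    warnf("reduced folds to %d to keep both classes in every fold", k)
  }
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  seg_ids <- if ("segment_id" %in% names(samples)) samples$segment_id[keep] else
    seq_along(y)
  fold_rows <- list()
  pred_rows <- list()
  pooled <- matrix(0, 2, 2, dimnames = list(truth = levels(y),
                                            pred = levels(y)))
  for (fold in seq_len(k)) {
    tr <- folds != fold; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    mu <- vapply(Xtr, function(col) mean(col, na.rm = TRUE), numeric(1))
    mu[is.na(mu)] <- 0
    for (j in seq_along(Xtr)) {
      Xtr[[j]][is.na(Xtr[[j]])] <- mu[j]
      Xte[[j]][is.na(Xte[[j]])] <- mu[j]
    }
    # drop zero-variance columns (degenerate gaussians)
    keepc <- vapply(Xtr, function(col) sd(col) > 0, logical(1))
    nb <- e1071::naiveBayes(Xtr[, keepc, drop = FALSE], y[tr])
    pred <- predict(nb, Xte[, keepc, drop = FALSE])
    praw <- predict(nb, Xte[, keepc, drop = FALSE], type = "raw")
    pred_rows[[fold]] <- tibble::tibble(
      segment_id = seg_ids[te], fold = fold,
      truth = y[te], pred = pred,
      prob_stimuli = praw[, "stimuli"]
    )
    cm <- table(truth = factor(y[te], levels(y)),
                pred = factor(pred, levels(y)))
    pooled <- pooled + cm
    rec <- diag(cm) / pmax(rowSums(cm), 1)
    fold_rows[[fold]] <- tibble::tibble(
      fold = fold,
      recall_nonstimuli = rec["nonstimuli"],
      recall_stimuli = rec["stimuli"],
      uar = mean(rec)
    )
  }
  rec <- diag(pooled) / rowSums(pooled)
  structure(
    list(
      confusion = pooled,
      per_fold = dplyr::bind_rows(fold_rows),
      predictions = dplyr::bind_rows(pred_rows),
      recall_nonstimuli = unname(rec["nonstimuli"]),
      recall_stimuli = unname(rec["stimuli"]),
      uar = mean(rec),
      features = features,
      n_folds = k,
      n_samples = length(y),
      class_counts = table(y),
      seed = seed
    ),
    class = "walkstress_classification"
  )
}

#' @export
print.walkstress_classification <- function(x, ...) {
  cat(sprintf(
    "<naive Bayes, %d-fold CV on %d segments (%d stimuli): UAR %.3f (recall stim %.3f / nonstim %.3f)>\n",
    x$n_folds, x$n_samples, x$class_counts["stimuli"],
    x$uar, x$recall_stimuli, x$recall_nonstimuli
  ))
  invisible(x)
}

#' @rdname classify_segments
#' @param x a `walkstress_classification`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.walkstress_classification <- function(x, ...) x$per_fold

#' @rdname classify_segments
#' @exportS3Method generics::glance
glance.walkstress_classification <- function(x, ...) {
  tibble::tibble(
    uar = x$uar,
    recall_stimuli = x$recall_stimuli,
    recall_nonstimuli = x$recall_nonstimuli,
    n_samples = x$n_samples,
    n_stimuli = unname(x$class_counts["stimuli"]),
    n_folds = x$n_folds,
    features = paste(x$features, collapse = "+")
  )
}

#' Published POI segment-length grid (1, 5, 10, 20, 30, ..., 150 m)
#' @return numeric vector of lengths in meters.
#' @export
segment_length_grid <- function() c(1, 5, 10, seq(20, 150, by = 10))

#' Sweep POI segment lengths and feature sets
#'
#' For every segment length, rebuilds POI segments, aggregates the (per-trip
#' z-normalized) geocoded features, labels segments from the reports and runs
#' the naive Bayes cross-validation for each requested feature set. The street
#' matching of points and reports is computed once and reused across lengths.
#'
#' @param features geocoded feature tibble (raw; normalization applied here
#'   unless `normalize = FALSE`).
#' @param reports report tibble.
#' @param streets street tibble.
#' @param lengths_m segment lengths to test.
#' @param feature_sets named list of feature-family vectors; default the
#'   six-family full set plus each single modality.
#' @param buffer_m buffer half-width.
#' @param n_folds,seed cross-validation controls.
#' @param normalize apply [normalize_per_trip()] first.
#' @return tibble of class `walkstress_segment_sweep`: one row per
#'   (length, feature set) with UAR, per-class recalls and class balance.
#' @export
sweep_segment_lengths <- function(features, reports, streets,
                                  lengths_m = segment_length_grid(),
                                  feature_sets = NULL, buffer_m = 40,
                                  n_folds = 5, seed = 1, normalize = TRUE) {
  if (is.null(feature_sets)) {
    feature_sets <- c(
      list(all = feature_families()),
      setNames(as.list(feature_families()), feature_families())
    )
  }
  if (normalize) features <- normalize_per_trip(features)
  point_asg <- assign_to_streets(features$x_m, features$y_m, streets, buffer_m)
  rows <- list()
  for (L in lengths_m) {
    segments <- build_poi_segments(streets, L, buffer_m)
    samples <- aggregate_to_segments(features, segments, streets,
                                     assignment = point_asg)
    samples <- label_segments(samples, reports, segments, streets)
    share <- mean(samples$label == "stimuli")
    for (nm in names(feature_sets)) {
      res <- tryCatch(
        suppressWarnings(classify_segments(samples, feature_sets[[nm]],
                                           n_folds = n_folds, seed = seed)),
        error = function(e) NULL
      )
      if (is.null(res)) next
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(segment_length_m = L, feature_set = nm,
                       share_stimuli = share),
        glance(res)[, c("uar", "recall_stimuli", "recall_nonstimuli",
                        "n_samples", "n_stimuli")]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      segment_length_m = numeric(0), feature_set = character(0),
      share_stimuli = numeric(0), uar = numeric(0),
      recall_stimuli = numeric(0), recall_nonstimuli = numeric(0),
      n_samples = integer(0), n_stimuli = integer(0)
    )
  }
  class(out) <- c("walkstress_segment_sweep", class(out))
  out
}
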