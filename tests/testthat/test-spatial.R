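test_that("POI segment cutting follows the remainder rule and partitions streets", {
  one <- tibble::tibble(street_id = "S", x0 = 0, y0 = 0, x1 = 100, y1 = 0,
                        length_m = 100)
  s40 <- build_poi_segments(one, 40)
  expect_equal(nrow(s40), 3)                       # 40, 40, 20 (20 >= 20 kept)
  expect_equal(s40$b_m - s40$a_m, c(40, 40, 20))
  expect_equal(sum(s40$length_m), 100)

  s150 <- build_poi_segments(one, 150)
  expect_equal(nrow(s150), 1)                      # street shorter than length
  expect_equal(s150$length_m, 100)

  s30 <- build_poi_segments(one, 30)               # remainder 10 < 15: merged
  expect_equal(nrow(s30), 3)
  expect_equal(s30$b_m - s30$a_m, c(30, 30, 40))

  # partition property across a grid and several lengths
  net <- make_street_network(12, 100)
  for (L in c(1, 7, 40, 150)) {
    segs <- build_poi_segments(net, L)
    tot <- dplyr::summarise(segs, s = sum(.data$length_m), .by = "street_id")
    expect_equal(sort(tot$s), sort(net$length_m))
  }
})

test_that("points are assigned to the nearest containing buffer, ties to lower id", {
  two <- tibble::tibble(street_id = c("A", "B"), x0 = c(0, 0), y0 = c(0, 100),
                        x1 = c(100, 100), y1 = c(0, 100),
                        length_m = c(100, 100))
  # parallel streets 100 m apart: 40-m buffers disjoint, midpoint in neither
  asg <- assign_to_streets(c(50, 50, 50), c(10, 90, 50), two, buffer_m = 40)
  expect_equal(asg$street_id[1], "A")
  expect_equal(asg$street_id[2], "B")
  expect_true(is.na(asg$street_id[3]))
  # outside every buffer (beyond the flat caps)
  off <- assign_to_streets(150, 50, two, buffer_m = 40)
  expect_true(is.na(off$street_id))
  # equidistant point inside both buffers: lower index wins
  near <- dplyr::mutate(two, y0 = c(0, 60), y1 = c(0, 60))
  tie <- assign_to_streets(50, 30, near, buffer_m = 40)
  expect_equal(tie$street_id, "A")

  closer <- tibble::tibble(street_id = c("A", "B"), x0 = c(0, 0), y0 = c(0, 30),
                           x1 = c(100, 100), y1 = c(0, 30),
                           length_m = c(100, 100))
  both <- assign_to_streets(50, 10, closer, buffer_m = 40)  # inside both buffers
  expect_equal(both$street_id, "A")                          # nearer centerline
})

test_that("aggregation computes per-segment means/SDs over buffer points", {
  one <- tibble::tibble(street_id = "S", x0 = 0, y0 = 0, x1 = 100, y1 = 0,
                        length_m = 100)
  segs <- build_poi_segments(one, 50)
  feats <- tibble::tibble(
    trip_id = "t", subject_id = "s", feature = "scl",
    time_s = 1:6,
    value = c(2, 2, 2, 1, 3, 5),
    x_m = c(5, 20, 45, 55, 70, 95), y_m = 0
  )
  agg <- aggregate_to_segments(feats, segs, one)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$scl_mean, c(2, 3))
  expect_equal(agg$scl_sd, c(0, 2))
  expect_equal(agg$n_points, c(3L, 3L))

  # empty segments are absent and counted
  far <- dplyr::mutate(feats, x_m = x_m / 10)      # all points on segment 1
  agg2 <- aggregate_to_segments(far, segs, one)
  expect_equal(nrow(agg2), 1)
  expect_equal(attr(agg2, "n_empty"), 1)
})

test_that("segments are labeled by report containment", {
  one <- tibble::tibble(street_id = "S", x0 = 0, y0 = 0, x1 = 100, y1 = 0,
                        length_m = 100)
  segs <- build_poi_segments(one, 50)
  feats <- tibble::tibble(trip_id = "t", subject_id = "s", feature = "scl",
                          time_s = 1:4, value = 1, x_m = c(10, 30, 60, 90),
                          y_m = 0)
  agg <- aggregate_to_segments(feats, segs, one)
  reports <- tibble::tibble(report_id = 1L, trip_id = "t", x_m = 20, y_m = 3,
                            types = list(1L))
  lab <- label_segments(agg, reports, segs, one)
  expect_equal(as.character(lab$label), c("stimuli", "nonstimuli"))
  expect_equal(lab$n_reports, c(1L, 0L))
  # no reports: everything nonstimuli
  lab0 <- label_segments(agg, reports[0, ], segs, one)
  expect_true(all(lab0$label == "nonstimuli"))
})

test_that("naive Bayes separates separable classes and is chance on shuffled labels", {
  set.seed(14)
  n <- 120
  samples <- tibble::tibble(
    segment_id = 1:n,
    scl_mean = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
    scl_sd = abs(rnorm(n, 1, 0.1)),
    label = factor(rep(c("nonstimuli", "stimuli"), each = n / 2),
                   levels = c("nonstimuli", "stimuli"))
  )
  res <- classify_segments(samples, features = "scl", seed = 3)
  expect_equal(res$uar, 1.0)
  expect_equal(res$recall_stimuli, 1.0)

  # UAR from pooled confusion equals the definition on given counts
  # TP 8/10 positives, TN 90/100 negatives -> UAR 0.85
  cm <- matrix(c(90, 10, 2, 8), 2, 2, byrow = TRUE,
               dimnames = list(truth = c("nonstimuli", "stimuli"),
                               pred = c("nonstimuli", "stimuli")))
  rec <- diag(cm) / rowSums(cm)
  expect_equal(mean(rec), 0.85)

  # shuffled labels: chance UAR
  uars <- vapply(1:12, function(s) {
    set.seed(100 + s)
    shuffled <- dplyr::mutate(samples, label = sample(label))
    classify_segments(shuffled, features = "scl", seed = s)$uar
  }, numeric(1))
  expect_lt(abs(mean(uars) - 0.5), 0.05)

  # pooled UAR tracks the mean of per-fold UARs on balanced data
  expect_lt(abs(res$uar - mean(res$per_fold$uar)), 0.02)

  expect_error(classify_segments(samples[c(1, 2, 61), ], features = "scl"),
               "2 samples per class")
})

test_that("tidy/glance expose the classification result", {
  set.seed(15)
  samples <- tibble::tibble(
    segment_id = 1:60,
    scl_mean = c(rnorm(30, -1), rnorm(30, 1)),
    scl_sd = abs(rnorm(60, 1, 0.1)),
    label = factor(rep(c("nonstimuli", "stimuli"), each = 30),
                   levels = c("nonstimuli", "stimuli"))
  )
  res <- classify_segments(samples, features = "scl", seed = 2)
  expect_equal(nrow(tidy(res)), res$n_folds)
  gl <- glance(res)
  expect_equal(gl$uar, res$uar)
  expect_equal(gl$n_samples, 60)
  expect_equal(nrow(res$predictions), 60)
  expect_true(all(res$predictions$prob_stimuli >= 0 &
                  res$predictions$prob_stimuli <= 1))
})

test_that("trip order does not change aggregation or labels", {
  study <- mini_study()
  proc <- mini_processed()
  segs <- build_poi_segments(study$streets, 40)
  f1 <- proc$features
  f2 <- dplyr::arrange(f1, dplyr::desc(dplyr::row_number()))
  a1 <- aggregate_to_segments(normalize_per_trip(f1), segs, study$streets)
  a2 <- aggregate_to_segments(normalize_per_trip(f2), segs, study$streets)
  a2 <- a2[match(a1$segment_id, a2$segment_id), names(a1)]
  expect_equal(as.data.frame(a1), as.data.frame(a2))
})
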