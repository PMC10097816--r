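test_that("bottom-up segmentation handles the degenerate cases", {
  seg1 <- bottomup_segment(rep(3, 20))
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$mean, 3)
  expect_equal(attr(seg1, "boundaries"), c(0L, 20L))

  set.seed(8)
  seg_inf <- bottomup_segment(rnorm(40), max_merge_cost = Inf)
  expect_equal(nrow(seg_inf), 1)
})

test_that("a clean step is split exactly at the change point", {
  x <- c(rep(0, 8), rep(5, 8))
  seg <- bottomup_segment(x, max_merge_cost = 10)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$end[1], 8)
  expect_equal(seg$mean, c(0, 5))
  expect_equal(seg$end[1], best_single_boundary(x))
})

test_that("noiseless single-change-point series match the exhaustive optimum", {
  set.seed(21)
  for (case in 1:25) {
    n <- sample(seq(10, 60, by = 2), 1)
    b <- sample(seq(2, n - 2, by = 2), 1)     # boundaries on even indices
    mu <- sort(runif(2, -5, 5))
    x <- c(rep(mu[1], b), rep(mu[2], n - b))
    if (abs(diff(mu)) < 0.1) next
    seg <- bottomup_segment(x, max_merge_cost = 0.01)
    expect_equal(nrow(seg), 2)
    expect_equal(seg$end[1], best_single_boundary(x))
    expect_equal(seg$end[1], b)
  }
})

test_that("total squared error is non-increasing in the number of merges", {
  set.seed(5)
  x <- rnorm(64)
  sse_of <- function(cap) {
    seg <- bottomup_segment(x, max_merge_cost = cap)
    sum(vapply(seq_len(nrow(seg)), function(i) {
      v <- x[seg$start[i]:seg$end[i]]
      sum((v - mean(v))^2)
    }, numeric(1)))
  }
  caps <- c(0.01, 0.1, 1, 10, Inf)
  sses <- vapply(caps, sse_of, numeric(1))
  expect_true(all(diff(sses) >= -1e-12))   # larger cap, more merges, larger SSE
})

test_that("PSC equals the brute-force contrast sum on random series", {
  set.seed(33)
  for (case in 1:40) {
    n <- sample(8:64, 1)
    x <- rnorm(n) + (runif(1) < 0.5) * rep(c(0, 3), each = ceiling(n / 2))[1:n]
    seg <- bottomup_segment(x)
    got <- compute_psc(x, seg)
    expect_equal(got$per_segment$psc, psc_bruteforce(x, seg), tolerance = 1e-12)
    # uniform variant too
    got_u <- compute_psc(x, seg, weighting = "uniform")
    expect_equal(got_u$per_segment$psc, psc_bruteforce(x, seg, "uniform"),
                 tolerance = 1e-12)
    expect_true(all(got$per_sample >= 0))
    expect_equal(length(got$per_sample), n)
  }
})

test_that("PSC marks a distinct middle segment and respects symmetry", {
  x <- c(rep(0, 10), rep(10, 10), rep(0, 10))
  seg <- bottomup_segment(x, max_merge_cost = 1)
  expect_equal(nrow(seg), 3)
  psc <- compute_psc(x, seg)$per_segment$psc
  expect_equal(which.max(psc), 2)
  expect_gt(psc[2], max(psc[-2]))
  # mirror symmetry of the series gives a mirror-symmetric PSC
  expect_equal(psc[1], psc[3], tolerance = 1e-12)
  per_sample <- compute_psc(x, seg)$per_sample
  expect_equal(per_sample, rev(per_sample), tolerance = 1e-12)

  # single segment: all-zero PSC
  seg1 <- bottomup_segment(rep(1, 12))
  expect_true(all(compute_psc(rep(1, 12), seg1)$per_sample == 0))
})
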