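## A small hand-built representation matrix for course tests.
make_rep <- function(mi, threshold, time_ms) {
  structure(list(mi = mi, fwer_threshold = threshold,
                 significant = mi > threshold, time_ms = time_ms,
                 n_perm = 0, percentile = 95),
            class = "representation_matrix")
}

test_that("max course reduces the matrix exactly as a nested loop would", {
  set.seed(12)
  k <- 3; V <- 7; Tn <- 20
  tm <- seq(0, 190, 10)
  rep1 <- make_rep(array(runif(k * V * Tn, 0, 0.1), c(k, V, Tn)), 0.08, tm)
  mc <- max_course(rep1, features = c(1, 3), window_ms = 20)
  expect_equal(dim(mc$curve), c(V, 10))
  ## brute-force oracle
  for (v in 1:V) for (w in 1:10) {
    tsel <- which(floor(tm / 20) + 1 == w)
    expect_equal(mc$curve[v, w], max(rep1$mi[c(1, 3), v, tsel]),
                 tolerance = 1e-12)
  }

  ## single-feature course equals that feature's windowed curve
  m1 <- max_course(rep1, features = 2, window_ms = 20)
  for (w in 1:10) {
    tsel <- which(floor(tm / 20) + 1 == w)
    expect_equal(m1$curve[4, w], max(rep1$mi[2, 4, tsel]), tolerance = 1e-12)
  }

  ## a never-significant voxel yields NaN onset/offset/duration
  quiet <- make_rep(array(0.01, c(1, 2, Tn)), 0.08, tm)
  mq <- max_course(quiet, 1)
  expect_true(all(is.nan(mq$onset_ms)))
  expect_true(all(is.nan(mq$duration_ms)))

  expect_error(max_course(rep1, integer(0)), "empty")
})

test_that("onset and offset respond monotonically to the threshold", {
  set.seed(13)
  tm <- seq(0, 390, 10)
  arr <- array(0, c(1, 5, 40))
  for (v in 1:5) arr[1, v, 8:30] <- 0.05 + 0.1 * sin(seq(0, pi, length.out = 23))
  rep1 <- make_rep(arr, 0.06, tm)
  low <- max_course(rep1, 1, threshold = 0.06)
  high <- max_course(rep1, 1, threshold = 0.12)
  ok <- !is.nan(high$onset_ms)
  expect_true(all(high$onset_ms[ok] >= low$onset_ms[ok]))
  expect_true(all(high$offset_ms[ok] <= low$offset_ms[ok]))
})

test_that("divergence similarity is de-meaned and calibrated under the null", {
  set.seed(14)
  tm <- seq(0, 390, 10)
  arr <- array(runif(2 * 60 * 40, 0, 0.2), c(2, 60, 40))
  rep1 <- make_rep(arr, 0.1, tm)
  a <- max_course(rep1, 1)
  b <- max_course(rep1, 2)

  ## self-similarity: de-meaned squared norm, positive and significant
  dv_self <- divergence(a, a, n_boot = 400, seed = 3)
  expect_equal(dv_self$similarity,
               apply(a$curve, 2, function(x) sum((x - mean(x))^2)),
               tolerance = 1e-12)
  expect_gt(mean(dv_self$significant), 0.9)

  ## adding a constant to either course leaves the similarity unchanged
  ashift <- a; ashift$curve <- a$curve + 5
  dv_shift <- divergence(ashift, b, n_boot = 10, seed = 3)
  dv_base <- divergence(a, b, n_boot = 10, seed = 3)
  expect_equal(dv_shift$similarity, dv_base$similarity, tolerance = 1e-9)

  ## independent random vectors: few significant windows across repeats
  hits <- 0; total <- 0
  for (i in 1:30) {
    arr2 <- array(runif(2 * 60 * 10, 0, 0.2), c(2, 60, 10))
    rep2 <- make_rep(arr2, 0.1, seq(0, 90, 10))
    dv <- divergence(max_course(rep2, 1), max_course(rep2, 2),
                     n_boot = 400, seed = i)
    hits <- hits + sum(dv$significant); total <- total + length(dv$significant)
  }
  expect_lt(hits / total, 0.05)

  expect_error(divergence(a, max_course(make_rep(arr[, 1:10, ], 0.1, tm), 1)),
               "share the voxel set")
})

test_that("wavefront regressions recover exact and contaminated structure", {
  set.seed(15)
  V <- 40
  coords <- matrix(runif(V * 3, 0, 50), V, 3)
  d0 <- sqrt(rowSums((coords - matrix(coords[1, ], V, 3, byrow = TRUE))^2))
  onset <- 40 + 1.5 * d0
  tm <- seq(0, 390, 10)
  course <- structure(list(curve = matrix(1, V, 40), onset_ms = onset,
                           offset_ms = onset + 100, duration_ms = rep(100, V),
                           window_start_ms = tm, window_ms = 10,
                           threshold = 0.5, subset = NULL),
                      class = "max_course")
  ## exact linear onsets: slope recovered to numerical precision
  fit <- wavefront_regressions(course, coords)
  expect_equal(unname(fit$onset_fit["slope"]), 1.5, tolerance = 1e-6)
  expect_identical(fit$excluded_fraction, 0)

  ## one extreme-onset voxel is excluded by the 3-SD rule
  dirty <- course
  dirty$onset_ms[V] <- 4000
  fit2 <- wavefront_regressions(dirty, coords)
  expect_gt(fit2$excluded_fraction, 0)
  expect_equal(unname(fit2$onset_fit["slope"]), 1.5, tolerance = 1e-6)

  ## planted decreasing durations give a negative significant slope
  noisy <- course
  noisy$onset_ms <- onset + rnorm(V, 0, 4)
  noisy$duration_ms <- pmax(120 - 0.8 * d0 + rnorm(V, 0, 6), 5)
  fit3 <- wavefront_regressions(noisy, coords)
  expect_lt(fit3$duration_fit["slope"], 0)
  expect_lt(fit3$duration_fit["p"], 0.05)

  flat <- course; flat$onset_ms <- rep(50, V)
  expect_error(wavefront_regressions(flat, coords), "identical")
  few <- course; few$onset_ms[6:V] <- NaN
  expect_error(wavefront_regressions(few, coords), "at least 10")
})

test_that("the junction selects the far quartile and its latest offset", {
  tm <- seq(0, 390, 10)
  V <- 100
  course <- structure(list(curve = matrix(1, V, 40),
                           onset_ms = rep(50, V), offset_ms = seq(100, 298, 2),
                           duration_ms = NULL, window_start_ms = tm,
                           window_ms = 10, threshold = 0.5, subset = NULL),
                      class = "max_course")
  ## uniformly spread distances: exactly the top quartile qualifies
  jc <- junction(course, distances = seq_len(V))
  expect_identical(length(jc$voxels), 25L)
  expect_identical(jc$marker_ms, max(course$offset_ms[76:100]))

  ## a single defined voxel is its own junction
  one <- course
  one$offset_ms[2:V] <- NaN
  one$onset_ms[2:V] <- NaN
  jc1 <- junction(one, distances = seq_len(V))
  expect_identical(jc1$voxels, 1L)
  expect_identical(jc1$marker_ms, one$offset_ms[1])

  none <- course; none$offset_ms[] <- NaN
  expect_error(junction(none, distances = seq_len(V)), "no voxels")
})
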