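## Minimal source_activity builder for focused tests.
make_activity <- function(amp, time_ms) {
  Tn <- dim(amp)[3]
  grad <- array(0, dim(amp))
  grad[, , 2:Tn] <- amp[, , 2:Tn, drop = FALSE] - amp[, , 1:(Tn - 1), drop = FALSE]
  grad[, , 1] <- grad[, , 2]
  structure(list(amplitude = amp, gradient = grad,
                 coords = matrix(0, dim(amp)[2], 3), time_ms = time_ms),
            class = "source_activity")
}

test_that("redundancy matrix flags decision-relevant encodings only", {
  set.seed(16)
  n <- 400; V <- 5; Tn <- 6
  dec <- sample(c("nuns", "voltaire", "dont_know"), n, TRUE)
  co <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  co[, 1] <- co[, 1] + 1.5 * (dec == "nuns")
  amp <- array(rnorm(n * V * Tn), c(n, V, Tn))
  amp[, 2, 3] <- amp[, 2, 3] + 2 * co[, 1]   # encodes the decision-driving feature
  amp[, 4, 5] <- amp[, 4, 5] + 2 * (dec == "voltaire")  # decision only, no feature
  act <- make_activity(amp, seq(0, 50, 10))

  red <- redundancy_matrix(co, act, dec, features = 1:2, n_perm = 80, seed = 6)
  expect_identical(red$contrast, "three_way")
  expect_equal(dim(red$red), c(2, V, Tn))
  expect_true(red$significant[1, 2, 3])
  ## activity dependent on the decision but independent of a
  ## decision-independent feature: the co-information terms cancel
  expect_lt(red$red[2, 4, 5], red$fwer_threshold)
  ## components reproduce the co-information identity cell by cell
  joint <- red$components$mi_fd + (red$components$mi_fm - red$red)
  expect_equal(red$red,
               red$components$mi_fd + red$components$mi_fm - joint,
               tolerance = 1e-12)

  expect_error(redundancy_matrix(co, act, dec, integer(0)), "no diagnostic")
})

test_that("complexity counts match a nested-loop oracle and are monotone", {
  set.seed(17)
  k <- 3; V <- 8
  tm <- seq(120, 220, 10)
  red <- structure(list(red = array(runif(k * V * length(tm), 0, 0.1),
                                    c(k, V, length(tm))),
                        fwer_threshold = 0.07, contrast = "three_way",
                        time_ms = tm),
                   class = "redundancy_matrix")
  red$significant <- red$red > red$fwer_threshold
  cx <- representational_complexity(red)
  expect_equal(dim(cx$counts), c(V, 5))
  win <- complexity_windows()
  for (v in 1:V) for (w in 1:5) {
    inw <- if (w == 5) tm >= win[w, 1] & tm <= win[w, 2]
           else tm >= win[w, 1] & tm < win[w, 2]
    cnt <- 0
    for (f in 1:k) if (any(red$significant[f, v, inw])) cnt <- cnt + 1
    expect_equal(cx$counts[v, w], cnt)
  }

  ## relaxing the threshold never decreases any count
  red2 <- red
  red2$fwer_threshold <- 0.05
  red2$significant <- red2$red > red2$fwer_threshold
  cx2 <- representational_complexity(red2)
  expect_true(all(cx2$counts >= cx$counts))

  ## empty significance gives all-zero counts; one cell gives one count
  red0 <- red; red0$significant[] <- FALSE
  expect_true(all(representational_complexity(red0)$counts == 0))
  red1 <- red0
  red1$significant[2, 3, which(tm >= 180 & tm < 200)[1]] <- TRUE
  cx1 <- representational_complexity(red1)
  expect_equal(sum(cx1$counts), 1)
  expect_equal(cx1$counts[3, 4], 1)

  expect_error(representational_complexity(red, cbind(0, 500)), "outside")

  ## median across observers combines maps elementwise
  med <- median_complexity(list(cx, cx2, cx2))
  expect_equal(med$counts, cx2$counts * 1)
})

test_that("decision MI finds class-dependent voxels and rejects constants", {
  set.seed(18)
  n <- 400; V <- 4; Tn <- 5
  dec <- sample(c("nuns", "voltaire", "dont_know"), n, TRUE)
  amp <- array(rnorm(n * V * Tn), c(n, V, Tn))
  amp[, 3, 2] <- amp[, 3, 2] + 1 * (dec == "nuns")   # d' = 1 separation
  act <- make_activity(amp, seq(0, 40, 10))
  dm <- decision_mi(act, dec, n_perm = 80, seed = 7)
  expect_true(dm$significant[3, 2])
  expect_lt(mean(dm$significant), 0.2)

  ## shuffled decisions leave (almost) nothing significant
  dm0 <- decision_mi(act, sample(dec), n_perm = 80, seed = 8)
  expect_lt(sum(dm0$significant), 3)

  const <- act; const$amplitude[, 1, 1] <- 1
  expect_error(decision_mi(const, dec), "constant")
})

test_that("decision-specific redundancy respects contrasts and selectivity", {
  set.seed(19)
  n <- 500; V <- 4; Tn <- 4
  dec <- sample(c("nuns", "voltaire", "dont_know"), n, TRUE)
  co <- cbind(nunsf = rnorm(n), voltf = rnorm(n))
  co[, 1] <- co[, 1] + 1.5 * (dec == "nuns")
  co[, 2] <- co[, 2] + 1.5 * (dec == "voltaire")
  amp <- array(rnorm(n * V * Tn), c(n, V, Tn))
  amp[, 1, 2] <- amp[, 1, 2] + 2 * co[, 1]
  amp[, 2, 2] <- amp[, 2, 2] + 2 * co[, 2]
  act <- make_activity(amp, seq(0, 30, 10))

  rn <- decision_specific_redundancy(co, act, dec, 1:2, "nuns_vs_dk",
                                     n_perm = 80, seed = 9)
  rv <- decision_specific_redundancy(co, act, dec, 1:2, "voltaire_vs_dk",
                                     n_perm = 80, seed = 10)
  ## the feature driving the contrast's percept is the one detected there
  expect_true(rn$significant[1, 1, 2])
  expect_true(rv$significant[2, 2, 2])
  expect_false(rn$significant[2, 2, 2] && rn$red[2, 2, 2] > rn$red[1, 1, 2])

  ## the three-way tag belongs to redundancy_matrix, not here
  expect_error(decision_specific_redundancy(co, act, dec, 1:2, "three_way"))
})
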