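test_that("copula normalization maps ranks to normal scores", {
  ## strictly increasing column: scores are exactly the equally spaced quantiles
  x <- matrix(c(3, 8, 15, 16, 23, 42, 99, 108), ncol = 1)
  expect_equal(drop(copula_normalize(x)), qnorm(((1:8) - 0.5) / 8),
               tolerance = 1e-12)

  ## invariance under strictly monotone transforms
  y <- matrix(rnorm(50), ncol = 1)
  expect_equal(copula_normalize(y), copula_normalize(exp(3 * y)),
               tolerance = 1e-12)

  ## one tie pair shares the averaged-rank quantile (hand-computed, n = 8)
  xt <- matrix(c(1, 2, 2, 3, 4, 5, 6, 7), ncol = 1)
  expect_equal(drop(copula_normalize(xt)),
               qnorm((c(1, 2.5, 2.5, 4, 5, 6, 7, 8) - 0.5) / 8),
               tolerance = 1e-12)

  expect_error(copula_normalize(matrix(1, 10, 1)), "constant")
  expect_error(copula_normalize(matrix(c(rnorm(15), NA), 8, 2)), "missing")
  expect_error(copula_normalize(matrix(1:4, 4, 1)), "at least 8")
})

test_that("gcmi matches the closed-form Gaussian MI and detects independence", {
  set.seed(11)
  n <- 30000; rho <- 0.6
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_equal(as.numeric(mi_gcc(x, y)), -0.5 * log2(1 - rho^2),
               tolerance = 0.02)
  expect_lt(abs(as.numeric(mi_gcc(rnorm(10000), rnorm(10000)))), 0.01)

  ## rank invariance under strictly monotone transforms of either input
  xs <- rnorm(500); ys <- 0.5 * xs + rnorm(500)
  expect_equal(as.numeric(mi_gcc(xs, ys)),
               as.numeric(mi_gcc(exp(xs), ys^3 + 2 * ys)), tolerance = 1e-12)

  ## perfectly dependent inputs are rejected with a condition-number report
  expect_error(mi_gcc(cbind(xs, xs), ys, normalize = FALSE), "condition number")
})

test_that("gcmi bias shrinks monotonically with sample size", {
  sizes <- c(64, 256, 1024, 4096)
  rho <- 0.5
  truth <- -0.5 * log2(1 - rho^2)
  set.seed(21)
  bias <- vapply(sizes, function(n) {
    mean(vapply(1:200, function(i) {
      x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      as.numeric(mi_gcc(x, y)) - truth
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(abs(bias)) < 0))
})

test_that("mixed and discrete estimators recover known channels", {
  ## identity channel, exactly balanced: 1 bit
  b <- rep(0:1, each = 500)
  expect_equal(as.numeric(mi_discrete(b, b)), 1.0, tolerance = 1e-12)

  ## skewed binary channel: MI = 1 - H(0.9) (closed form)
  set.seed(31)
  n <- 50000
  cl <- rbinom(n, 1, 0.5)
  xb <- rbinom(n, 1, ifelse(cl == 1, 0.9, 0.1))
  expect_equal(as.numeric(mi_discrete(xb, cl)),
               1 + 0.9 * log2(0.9) + 0.1 * log2(0.1), tolerance = 0.01)

  ## continuous-discrete independence: near-zero on average
  mis <- vapply(1:100, function(i)
    as.numeric(mi_gcd(rnorm(2000), sample(c("a", "b", "c"), 2000, TRUE))),
    numeric(1))
  expect_lt(abs(mean(mis)), 0.01)

  ## class with too few trials is rejected by name
  expect_error(mi_gcd(rnorm(100), c(rep("a", 98), "tiny", "tiny")), "tiny")
  expect_error(mi_gcd(rnorm(100), rep("a", 100)), "2 classes")
})

test_that("gcmi tracks plug-in MI on discretized Gaussian-copula data", {
  set.seed(41)
  n <- 50000
  x <- rnorm(n); y <- 0.6 * x + 0.8 * rnorm(n)
  qx <- cut(x, quantile(x, 0:4 / 4), include.lowest = TRUE, labels = FALSE)
  qy <- cut(y, quantile(y, 0:4 / 4), include.lowest = TRUE, labels = FALSE)
  expect_equal(as.numeric(mi_gcc(qx, qy)), as.numeric(mi_discrete(qx, qy)),
               tolerance = 0.05)
})

test_that("redundancy satisfies its defining identity and known signs", {
  ## identity holds exactly for random continuous datasets
  set.seed(51)
  for (i in 1:20) {
    r <- redundancy(rnorm(300), cbind(rnorm(300), rnorm(300)),
                    sample(c("x", "y", "z"), 300, TRUE))
    expect_lt(abs(r$value - (r$components["mi_fd"] + r$components["mi_fm"] -
                               r$components["mi_fmd"])), 1e-12)
  }

  ## feature = activity = decision (balanced binary): co-information is 1 bit
  b <- rep(0:1, each = 100)
  expect_equal(redundancy(b, b, b, estimator = "plugin")$value, 1.0,
               tolerance = 1e-12)

  ## XOR structure: synergy, so co-information is negative
  set.seed(52)
  f <- rbinom(4000, 1, 0.5); d <- rbinom(4000, 1, 0.5)
  m <- as.integer(xor(f == 1, d == 1))
  expect_lt(redundancy(f, m, d, estimator = "plugin")$value, 0)

  ## activity independent of feature and decision: redundancy near zero
  r0 <- redundancy(rnorm(3000), cbind(rnorm(3000), rnorm(3000)),
                   sample(c("a", "b"), 3000, TRUE))
  expect_lt(abs(r0$value), 0.01)
})
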