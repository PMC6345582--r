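test_that("reduced MI images have the stated geometry and find planted structure", {
  set.seed(3)
  n <- 300; p <- 16 * 16
  masks <- matrix(runif(n * p), n, p)
  ## template over a known pixel block drives one (component, time) cell
  supp <- as.vector(outer(1:16, 1:16, function(i, j) i <= 6 & j <= 6))
  coef <- masks[, supp, drop = FALSE] %*% rep(1, sum(supp))
  scores <- array(rnorm(n * 4 * 3), c(n, 4, 3))
  scores[, 2, 2] <- coef + 0.1 * rnorm(n)
  stack <- reduced_mi_images(masks, scores)
  expect_equal(dim(stack$images), c(12, p))
  expect_equal(nrow(stack$cell_index), 12)
  expect_true(all(stack$images >= 0))

  cell <- which(stack$cell_index$component == 2 & stack$cell_index$time == 2)
  img <- stack$images[cell, ]
  ## the top-decile MI pixels concentrate on the planted support
  top <- order(img, decreasing = TRUE)[1:round(p / 10)]
  expect_gt(mean(supp[top]), 0.85)
  ## noise cells stay near zero
  expect_lt(mean(stack$images[-cell, ]), 0.01)

  expect_error(reduced_mi_images(masks[1:100, ], scores), "trial count")
})

test_that("NMF recovers planted disjoint prototypes and honors its contracts", {
  set.seed(4)
  k <- 6; p <- 240; m <- 120
  protos <- matrix(0, k, p)
  for (i in 1:k) protos[i, ((i - 1) * 40 + 1):(i * 40)] <- runif(40, 0.5, 1)
  w <- matrix(rexp(m * k), m, k)
  x <- w %*% protos + matrix(runif(m * p, 0, 0.01), m, p)
  basis <- nmf_basis(x, k = k, seed = 2, n_restarts = 2)
  mt <- match_features(protos, basis$features)
  expect_gt(min(mt$cosine), 0.95)

  ## rows have unit L2 norm and sub-threshold pixels are exactly zero
  expect_equal(unname(sqrt(rowSums(basis$features^2))), rep(1, k),
               tolerance = 1e-10)
  ## every entry is either exactly zero or at least 15% of its row's maximum
  for (i in 1:k) {
    row <- basis$features[i, ]
    expect_true(all(row == 0 | row >= 0.15 * max(row) - 1e-12))
  }

  expect_error(nmf_fit(x, 0), "positive")
  expect_error(nmf_fit(matrix(0, 5, 5), 2), "zero")
  expect_error(nmf_fit(-x, 2), "nonnegative")
  expect_error(nmf_fit(x, 1000), "exceeds")
})

test_that("multiplicative updates never increase the reconstruction error", {
  set.seed(6)
  x <- matrix(rexp(40 * 30), 40, 30)
  fit <- nmf_fit(x, 4, seed = 3, maxit = 60, tol = 0, track_error = TRUE)
  expect_true(all(diff(fit$error_path) <= 1e-8))
})

test_that("feature coefficients equal the explicit dot product", {
  set.seed(7)
  masks <- matrix(runif(20 * 50), 20, 50)
  feats <- matrix(rexp(3 * 50), 3, 50)
  co <- feature_coefficients(masks, feats)
  ref <- matrix(0, 20, 3)
  for (t in 1:20) for (f in 1:3) ref[t, f] <- sum(masks[t, ] * feats[f, ])
  expect_equal(co, ref, tolerance = 1e-12)

  ## all-zero mask gives all-zero coefficients; unit-norm feature returns
  ## the mask norm when mask and feature are proportional
  expect_identical(as.vector(feature_coefficients(matrix(0, 1, 50), feats)),
                   rep(0, 3))
  u <- feats[1, ] / sqrt(sum(feats[1, ]^2))
  expect_equal(as.numeric(feature_coefficients(matrix(2 * u, 1), matrix(u, 1))),
               2, tolerance = 1e-12)

  expect_error(feature_coefficients(masks, feats[, 1:10]), "pixels")
})

test_that("representation matrix flags planted encodings and is rank-invariant", {
  set.seed(8)
  n <- 200; V <- 4; Tn <- 6
  coefs <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  truth <- structure(list(amplitude = array(rnorm(n * V * Tn), c(n, V, Tn)),
                          gradient = array(rnorm(n * V * Tn), c(n, V, Tn)),
                          coords = matrix(0, V, 3), time_ms = seq(0, 50, 10)),
                     class = "source_activity")
  for (t in 3:5) truth$amplitude[, 2, t] <- truth$amplitude[, 2, t] + 2 * coefs[, 1]
  rm1 <- representation_matrix(coefs, truth, n_perm = 60, seed = 4)
  expect_identical(dim(rm1$mi), c(2L, 4L, 6L))
  expect_true(all(rm1$significant[1, 2, 3:5]))
  expect_lt(sum(rm1$significant[, -2, ]), 4)

  ## determinism and invariance to positive rescaling of a coefficient
  rm2 <- representation_matrix(coefs, truth, n_perm = 60, seed = 4)
  expect_identical(rm1$mi, rm2$mi)
  rm3 <- representation_matrix(cbind(3.7 * coefs[, 1], coefs[, 2]), truth,
                               n_perm = 60, seed = 4)
  expect_equal(rm1$mi, rm3$mi, tolerance = 1e-10)
})

test_that("feature classification follows the percentile rules", {
  set.seed(9)
  n <- 900
  dec <- sample(c("nuns", "voltaire", "dont_know"), n, TRUE)
  co <- matrix(rnorm(n * 5), n, 5)
  co[, 1] <- co[, 1] + 2 * (dec == "nuns")       # drives nuns
  co[, 2] <- co[, 2] + 2 * (dec == "voltaire")   # drives voltaire
  lab <- classify_features(co, dec)
  expect_identical(as.character(lab[1]), "diagnostic_nuns")
  expect_identical(as.character(lab[2]), "diagnostic_voltaire")
  expect_true(all(as.character(lab[4:5]) %in% c("nondiagnostic", "unclassified")))
  expect_identical(sum(lab == "nondiagnostic"), 1L)

  ## invariance to feature order
  perm <- c(3, 1, 5, 2, 4)
  lab2 <- classify_features(co[, perm], dec)
  expect_identical(as.character(lab2), as.character(lab[perm]))

  ## identical features tie at every percentile and stay unclassified
  same <- co[, c(3, 3, 3, 3)]
  lab3 <- classify_features(same, dec)
  expect_true(all(lab3 == "unclassified"))

  expect_error(classify_features(co[, 1:3], dec), "at least 4")
  expect_error(classify_features(co, rep(c("nuns", "dont_know"), length.out = n)),
               "three decision classes")
})

test_that("cosine k-means separates planted clusters and accepts the pooled shape", {
  set.seed(10)
  centers <- matrix(rnorm(3 * 40), 3, 40)
  x <- centers[rep(1:3, each = 15), ] + 0.05 * matrix(rnorm(45 * 40), 45, 40)
  km <- kmeans_cosine(x, 3, n_restarts = 10, seed = 5)
  ## perfect recovery: each planted group maps to exactly one cluster
  expect_identical(dim(table(rep(1:3, each = 15), km$cluster)), c(3L, 3L))
  expect_true(all(apply(table(rep(1:3, each = 15), km$cluster), 1,
                        function(r) sum(r > 0)) == 1))

  ## duplicate rows always share a cluster
  xd <- rbind(x, x[1, ], x[1, ])
  kmd <- kmeans_cosine(xd, 3, n_restarts = 5, seed = 6)
  expect_identical(kmd$cluster[46], kmd$cluster[47])

  ## the pooled cross-observer shape (115 x 20480) is accepted
  big <- matrix(rexp(115 * 20480), 115, 20480)
  kb <- kmeans_cosine(big, 25, n_restarts = 2, max_iter = 20, seed = 7)
  expect_identical(length(kb$cluster), 115L)
  expect_identical(dim(kb$centroids), c(25L, 20480L))

  expect_error(kmeans_cosine(x, 100), "exceeds")
  expect_error(kmeans_cosine(rbind(x, 0), 3), "zero norm")
})
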