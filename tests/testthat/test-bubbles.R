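test_that("octave decomposition partitions the image and localizes energy", {
  ## flat image: all AC bands empty, the low band carries the constant
  flat <- sf_decompose(matrix(0.5, 64, 64))
  expect_lt(max(vapply(flat$bands[1:5], function(b) max(abs(b)), numeric(1))), 1e-12)
  expect_equal(flat$bands[[6]], matrix(0.5, 64, 64), tolerance = 1e-12)

  ## arbitrary image: bands sum back to the input exactly (partition of unity)
  img <- matrix(rnorm(256 * 256), 256)
  d <- sf_decompose(img)
  expect_equal(d$n_bands, 6)
  expect_identical(d$cutoffs_cpi, c(128, 64, 32, 16, 8, 4))
  expect_lt(max(abs(Reduce(`+`, d$bands) - img)), 1e-10)

  ## pure 48 cycles/image sinusoid: energy lands in the (32, 64] band;
  ## oracle = FFT energy partition of the band images themselves
  s <- outer(sin(2 * pi * 48 * (0:255) / 256), rep(1, 256))
  ds <- sf_decompose(s)
  en <- vapply(ds$bands, function(b) sum(b^2), numeric(1))
  expect_gt(en[2] / sum(en), 0.9)

  ## ideal filters partition exactly too
  di <- sf_decompose(img, filter = "ideal")
  expect_lt(max(abs(Reduce(`+`, di$bands) - img)), 1e-10)
})

test_that("decomposition rejects unsupported inputs with explicit messages", {
  expect_error(sf_decompose(matrix(0, 64, 32)), "square")
  expect_error(sf_decompose(matrix(0, 100, 100)), "power of two")
  expect_error(sf_decompose(matrix(0, 64, 64), cutoffs_cpi = 32), "at least 2")
  expect_error(sf_decompose(matrix(0, 64, 64), cutoffs_cpi = c(32, 16, 10)),
               "factors of two")
  expect_error(sf_decompose(matrix(0, 64, 64), cutoffs_cpi = c(16, 32)),
               "descending")
})

test_that("bubble masks follow the Gaussian closed form and are reproducible", {
  sig <- deg_to_px(bubbles_sigmas_deg, 64, 5.72)
  ## one aperture at a known center: exp(-r^2 / (2 sigma^2))
  m <- generate_bubble_masks(1, sig[2], 64, centers = list(matrix(c(32, 32), 1)))
  expect_equal(m$masks[[1]][32, 32], 1.0)
  for (r in c(1, 3, 6))
    expect_equal(m$masks[[1]][32 + r, 32], exp(-r^2 / (2 * sig[2]^2)),
                 tolerance = 1e-12)

  ## standard allocation keeps the total of 60 apertures
  alloc <- aperture_allocation(60, sig)
  expect_identical(sum(alloc), 60L)
  full <- generate_bubble_masks(alloc, sig, 64, seed = 7)
  expect_identical(full$total_apertures, 60L)
  expect_true(all(vapply(full$masks, function(x) min(x) >= 0 && max(x) <= 1,
                         logical(1))))

  ## identical seeds give bit-identical masks
  again <- generate_bubble_masks(alloc, sig, 64, seed = 7)
  expect_identical(full, again)

  expect_error(generate_bubble_masks(c(0, 0, 0, 0, 0), sig, 64), "positive aperture")
  expect_error(generate_bubble_masks(rep(1, 5), c(-1, 2, 3, 4, 5), 64), "positive")
  expect_error(generate_bubble_masks(rep(1, 5), rev(sig), 64), "increasing")
})

test_that("stimulus composition matches a brute-force pixel loop", {
  img <- matrix(runif(64 * 64), 64)
  d <- sf_decompose(img)
  sig <- deg_to_px(bubbles_sigmas_deg, 64, 5.72)
  masks <- generate_bubble_masks(aperture_allocation(60, sig), sig, 64, seed = 2)

  st <- compose_stimulus(d, masks)
  ref <- d$bands[[6]]
  for (k in 1:5) for (i in 1:64) for (j in 1:64)
    ref[i, j] <- ref[i, j] + masks$masks[[k]][i, j] * d$bands[[k]][i, j]
  expect_equal(st, ref, tolerance = 1e-12)

  ## full visibility reproduces the image; zero visibility leaves the low band
  ones <- masks; for (k in 1:5) ones$masks[[k]][] <- 1
  expect_lt(max(abs(compose_stimulus(d, ones) - img)), 1e-10)
  zeros <- masks; for (k in 1:5) zeros$masks[[k]][] <- 0
  expect_equal(compose_stimulus(d, zeros), d$bands[[6]], tolerance = 1e-12)

  small <- downsample_masks(masks, 32)
  expect_error(compose_stimulus(d, small), "different pixel grids")
})

test_that("composition is linear in the masks", {
  img <- matrix(runif(64 * 64), 64)
  d <- sf_decompose(img)
  sig <- deg_to_px(bubbles_sigmas_deg, 64, 5.72)
  masks <- generate_bubble_masks(aperture_allocation(60, sig), sig, 64, seed = 5)
  base <- compose_stimulus(d, masks)
  for (a in c(0.25, 0.5, 0.9)) {
    scaled <- masks; for (k in 1:5) scaled$masks[[k]] <- a * scaled$masks[[k]]
    expect_equal(compose_stimulus(d, scaled),
                 a * (base - d$bands[[6]]) + d$bands[[6]], tolerance = 1e-10)
  }
})

test_that("mask downsampling is bilinear with preserved peaks", {
  sig <- deg_to_px(bubbles_sigmas_deg, 256, 5.72)
  masks <- generate_bubble_masks(aperture_allocation(60, sig), sig, 256, seed = 9)
  down <- downsample_masks(masks, 64)
  expect_identical(dim(down$masks[[1]]), c(64L, 64L))
  expect_true(all(vapply(down$masks, function(x) min(x) >= 0 && max(x) <= 1,
                         logical(1))))

  ## constant masks stay constant under interpolation
  const <- masks; for (k in 1:5) const$masks[[k]][] <- 0.5
  dc <- downsample_masks(const, 64)
  expect_equal(dc$masks[[3]], matrix(0.5, 64, 64), tolerance = 1e-12)

  ## a single aperture's peak survives within one coarse pixel
  single <- generate_bubble_masks(1, sig[3], 256,
                                  centers = list(matrix(c(147, 101), 1)))
  ds <- downsample_masks(single, 64)
  peak <- which(ds$masks[[1]] == max(ds$masks[[1]]), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(peak - c(147, 101) / 4)), 1.5)

  expect_error(downsample_masks(down, 128), "upsampling")
})

test_that("mask coverage per band is stationary across trials", {
  sig <- deg_to_px(bubbles_sigmas_deg[1:2], 32, 5.72)
  n_rep <- 500
  cov <- matrix(0, n_rep, 2)
  set.seed(31)
  for (i in seq_len(n_rep)) {
    m <- generate_bubble_masks(c(20, 6), sig, 32)
    cov[i, ] <- vapply(m$masks, function(x) mean(x > 0.2), numeric(1))
  }
  ## relative SD of per-chunk mean coverage stays small
  chunks <- rep(1:5, each = n_rep / 5)
  for (b in 1:2) {
    mu <- tapply(cov[, b], chunks, mean)
    expect_lt(stats::sd(mu) / mean(mu), 0.05)
  }
})
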