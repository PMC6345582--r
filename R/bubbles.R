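## Bubbles stimulus sampling: spatial-frequency decomposition, Gaussian
## aperture masks, stimulus composition and mask downsampling.

#' Reference Bubbles sampling constants
#'
#' Aperture standard deviations per spatial-frequency band, in degrees of
#' visual angle, and the reference viewing geometry (a 256-pixel image
#' subtending 5.72 degrees).
#'
#' @name bubbles-constants
#' @export
bubbles_sigmas_deg <- c(0.13, 0.27, 0.54, 1.08, 2.15)

#' @rdname bubbles-constants
#' @export
sf_cutoffs_cpi <- c(128, 64, 32, 16, 8, 4)

#' Convert degrees of visual angle to pixels
#'
#' @param deg Size in degrees.
#' @param image_px Image size in pixels (default 256).
#' @param image_deg Image size in degrees (default 5.72).
#' @return Size in pixels.
#' @export
deg_to_px <- function(deg, image_px = 256, image_deg = 5.72) deg * image_px / image_deg

#' Decompose an image into octave spatial-frequency bands
#'
#' Zero-phase frequency-domain bandpass decomposition into one-octave bands.
#' Band `k` passes radial frequencies in `(cutoffs[k]/2, cutoffs[k]]`
#' cycles/image; the final band additionally absorbs all remaining low-pass
#' content (including the DC component), so the bands form an exact partition
#' of unity and sum back to the input.
#'
#' @param image Square numeric matrix (grayscale, power-of-two side length).
#' @param cutoffs_cpi Upper band cutoffs in cycles/image, strictly descending
#'   by factors of two (default `c(128, 64, 32, 16, 8, 4)`).
#' @param filter `"raised_cosine"` (default): cosine roll-off in log2-frequency
#'   with half-width `transition_oct` octaves at each boundary, which avoids
#'   ringing while keeping perfect reconstruction; `"ideal"`: hard annular
#'   filters.
#' @param transition_oct Transition half-width in octaves for the
#'   raised-cosine filter.
#' @return An object of class `sf_decomposition`: list with `bands` (list of
#'   matrices), `cutoffs_cpi`, `n_bands`, `filter`, `size`.
#' @export
sf_decompose <- function(image, cutoffs_cpi = sf_cutoffs_cpi,
                         filter = c("raised_cosine", "ideal"),
                         transition_oct = 0.25) {
  filter <- match.arg(filter)
  n <- .check_square_image(image, "base image")
  if (abs(log2(n) - round(log2(n))) > 1e-9)
    stop("image side length must be a power of two for the FFT band decomposition; got ", n)
  if (length(cutoffs_cpi) < 2) stop("need at least 2 band cutoffs")
  if (any(diff(cutoffs_cpi) >= 0)) stop("cutoffs must be strictly descending")
  ratios <- cutoffs_cpi[-length(cutoffs_cpi)] / cutoffs_cpi[-1]
  if (any(abs(ratios - 2) > 1e-9)) stop("cutoffs must descend by factors of two (octave bands)")

  fx <- c(0:(n / 2), seq(-(n / 2 - 1), -1))
  r <- sqrt(outer(fx^2, fx^2, "+"))
  ## rising step (0 below, 1 above) at boundary `b`, in log2-frequency
  step <- function(b) {
    if (filter == "ideal") return((r > b) * 1)
    s <- matrix(0, n, n)
    pos <- r > 0
    t <- (log2(pmax(r, 1e-12)) - (log2(b) - transition_oct)) / (2 * transition_oct)
    t <- pmin(pmax(t, 0), 1)
    s[pos] <- 0.5 - 0.5 * cos(pi * t[pos])
    s
  }
  nb <- length(cutoffs_cpi)
  ## boundaries between consecutive bands are the cutoffs of bands 2..nb;
  ## the top band extends to the Nyquist corner, the bottom band to DC.
  steps <- lapply(cutoffs_cpi[-1], step)
  filters <- vector("list", nb)
  filters[[1]] <- steps[[1]]
  if (nb > 2) for (k in 2:(nb - 1)) filters[[k]] <- steps[[k]] - steps[[k - 1]]
  filters[[nb]] <- 1 - steps[[nb - 1]]

  f <- stats::fft(image)
  bands <- lapply(filters, function(h) Re(stats::fft(f * h, inverse = TRUE)) / (n * n))
  structure(list(bands = bands, cutoffs_cpi = cutoffs_cpi, n_bands = nb,
                 filter = filter, transition_oct = transition_oct, size = n),
            class = "sf_decomposition")
}

#' @export
print.sf_decomposition <- function(x, ...) {
  cat("Spatial-frequency decomposition:", x$n_bands, "octave bands,",
      x$size, "x", x$size, "px\n")
  cat("  upper cutoffs (cycles/image):", paste(x$cutoffs_cpi, collapse = ", "), "\n")
  invisible(x)
}

#' Default allocation of apertures across bands
#'
#' Allocates a total aperture budget across bands proportionally to
#' `1/sigma^2`, so the expected revealed area is equal across bands, using
#' largest-remainder rounding (remainders tied toward the finest bands).
#'
#' @param total Total number of apertures per trial (default 60).
#' @param sigmas_px Aperture standard deviations in pixels, strictly increasing.
#' @return Integer vector of per-band aperture counts summing to `total`.
#' @export
aperture_allocation <- function(total = 60, sigmas_px) {
  stopifnot(total >= 1, all(sigmas_px > 0))
  w <- (1 / sigmas_px^2) / sum(1 / sigmas_px^2)
  raw <- total * w
  cnt <- floor(raw)
  rem <- total - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, -sigmas_px, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Generate per-band Bubbles aperture masks
#'
#' Each band's mask is built from randomly located Gaussian apertures with
#' value 1 at the aperture center, combined across apertures by pointwise
#' maximum (default) or by sum clipped to 1. Aperture centers are sampled
#' uniformly over the pixel grid; with `edge = "pad"` centers are kept at
#' least 2 sigma from the border.
#'
#' @param n_apertures Integer vector: apertures per band.
#' @param sigmas_px Gaussian standard deviations in pixels, strictly
#'   increasing, one per band.
#' @param size Image side length in pixels.
#' @param seed Optional integer seed; identical seeds give bit-identical masks.
#' @param combine `"max"` (default) or `"sum"` (clipped to 1).
#' @param edge `"none"` (default) or `"pad"`.
#' @param centers Optional list (one matrix of x,y rows per band) of fixed
#'   aperture centers, overriding random placement.
#' @return Object of class `bubble_mask_set`: `masks` (list of matrices in
#'   `[0,1]`), `centers`, `sigmas_px`, `size`, `total_apertures`.
#' @export
generate_bubble_masks <- function(n_apertures, sigmas_px, size, seed = NULL,
                                  combine = c("max", "sum"),
                                  edge = c("none", "pad"), centers = NULL) {
  combine <- match.arg(combine)
  edge <- match.arg(edge)
  if (length(n_apertures) != length(sigmas_px))
    stop("n_apertures and sigmas_px must have one entry per band")
  if (any(sigmas_px <= 0)) stop("aperture sigma must be positive")
  if (any(diff(sigmas_px) <= 0)) stop("sigmas must be strictly increasing across bands")
  if (sum(n_apertures) == 0) stop("at least one band must have a positive aperture count")

  .with_seed(seed, {
    nb <- length(sigmas_px)
    out <- vector("list", nb)
    ctr <- vector("list", nb)
    for (b in seq_len(nb)) {
      m <- matrix(0, size, size)
      nk <- n_apertures[b]
      if (is.null(centers)) {
        if (edge == "pad") {
          pad <- min(ceiling(2 * sigmas_px[b]), floor((size - 1) / 2))
          cs <- cbind(sample(seq(1 + pad, size - pad), nk, replace = TRUE),
                      sample(seq(1 + pad, size - pad), nk, replace = TRUE))
        } else {
          cs <- cbind(sample.int(size, nk, replace = TRUE),
                      sample.int(size, nk, replace = TRUE))
        }
      } else {
        cs <- centers[[b]]
        nk <- nrow(cs)
      }
      if (nk > 0) {
        s2 <- 2 * sigmas_px[b]^2
        halfw <- ceiling(4 * sigmas_px[b])
        ax <- seq_len(size)
        for (i in seq_len(nk)) {
          cx <- cs[i, 1]; cy <- cs[i, 2]
          xs <- max(1, cx - halfw):min(size, cx + halfw)
          ys <- max(1, cy - halfw):min(size, cy + halfw)
          g <- exp(-outer((xs - cx)^2, (ys - cy)^2, "+") / s2)
          if (combine == "max") {
            m[xs, ys] <- pmax(m[xs, ys], g)
          } else {
            m[xs, ys] <- m[xs, ys] + g
          }
        }
        if (combine == "sum") m <- pmin(m, 1)
      }
      out[[b]] <- m
      ctr[[b]] <- cs[seq_len(nk), , drop = FALSE]
    }
    structure(list(masks = out, centers = ctr, sigmas_px = sigmas_px,
                   size = size, total_apertures = sum(n_apertures)),
              class = "bubble_mask_set")
  })
}

#' @export
print.bubble_mask_set <- function(x, ...) {
  cat("Bubble mask set:", length(x$masks), "bands,", x$size, "x", x$size,
      "px,", x$total_apertures, "apertures\n")
  invisible(x)
}

#' Compose a sparse stimulus from a decomposition and bubble masks
#'
#' Multiplies each of the first `n_bands - 1` band images by its mask, sums
#' across bands, and adds the final (constant, unmasked) band.
#'
#' @param decomp An `sf_decomposition`.
#' @param masks A `bubble_mask_set` with one mask per sampled band
#'   (`n_bands - 1` masks).
#' @return Numeric matrix: the stimulus image.
#' @export
compose_stimulus <- function(decomp, masks) {
  stopifnot(inherits(decomp, "sf_decomposition"), inherits(masks, "bubble_mask_set"))
  if (masks$size != decomp$size)
    stop("masks (", masks$size, " px) and decomposition (", decomp$size,
         " px) are on different pixel grids")
  if (length(masks$masks) != decomp$n_bands - 1)
    stop("expected ", decomp$n_bands - 1, " masks, got ", length(masks$masks))
  px <- decomp$bands[[decomp$n_bands]]
  for (k in seq_len(decomp$n_bands - 1)) px <- px + masks$masks[[k]] * decomp$bands[[k]]
  px
}

#' Downsample bubble masks by bilinear interpolation
#'
#' @param masks A `bubble_mask_set`.
#' @param target_size Target side length in pixels (default 64); upsampling is
#'   rejected.
#' @return A `bubble_mask_set` at the target resolution (aperture centers
#'   rescaled accordingly).
#' @export
downsample_masks <- function(masks, target_size = 64) {
  stopifnot(inherits(masks, "bubble_mask_set"))
  if (target_size > masks$size)
    stop("target size ", target_size, " exceeds source size ", masks$size,
         "; upsampling is not supported")
  sc <- target_size / masks$size
  out <- lapply(masks$masks, function(m) pmin(pmax(.bilinear_resize(m, target_size), 0), 1))
  ctr <- lapply(masks$centers, function(cs) {
    if (length(cs) == 0) return(cs)
    pmin(pmax((cs - 0.5) * sc + 0.5, 1), target_size)
  })
  structure(list(masks = out, centers = ctr, sigmas_px = masks$sigmas_px * sc,
                 size = target_size, total_apertures = masks$total_apertures),
            class = "bubble_mask_set")
}

## Flatten a bubble_mask_set into one row vector (pixel-major within band,
## bands stacked); the layout matches `mask_dim = c(size, size, n_bands)`.
.flatten_masks <- function(masks) {
  unlist(lapply(masks$masks, as.vector), use.names = FALSE)
}
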