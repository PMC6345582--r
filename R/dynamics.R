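## Wavefront dynamics: per-voxel maximum-MI time courses with
## onset/offset/duration, spatial progression regressions, the
## diagnostic/nondiagnostic divergence statistic, and the spatio-temporal
## junction.

#' Maximum representation course over a feature subset
#'
#' For each voxel and time window, takes the maximum unthresholded MI across
#' the selected features and the time points falling in the window. A voxel's
#' onset is the start time of the first window whose maximum exceeds the
#' representation matrix's FWER threshold, the offset the start time of the
#' last such window, and the duration their difference; voxels never
#' significant get `NaN` for all three. Window w covers
#' `[start + (w-1)*window_ms, start + w*window_ms)`, with the final window
#' also including the right endpoint.
#'
#' @param rep A `representation_matrix`.
#' @param features Integer indices of the feature subset (nonempty).
#' @param window_ms Window width in ms (default 10; the reference span 0-400
#'   ms then yields 40 windows).
#' @param subset Optional tag stored with the course (e.g. `"diagnostic"`).
#' @param threshold Significance threshold; defaults to the representation
#'   matrix's FWER threshold.
#' @return Object of class `max_course`: `curve` (voxels x windows),
#'   `onset_ms`, `offset_ms`, `duration_ms`, `window_start_ms`, `threshold`,
#'   `subset`.
#' @export
max_course <- function(rep, features, window_ms = 10, subset = NULL,
                       threshold = NULL) {
  stopifnot(inherits(rep, "representation_matrix"))
  if (length(features) == 0) stop("feature subset is empty")
  if (is.null(threshold)) threshold <- rep$fwer_threshold
  tm <- rep$time_ms
  t0 <- min(tm)
  nw <- max(1L, ceiling((max(tm) - t0) / window_ms))
  win <- pmin(floor((tm - t0) / window_ms) + 1L, nw)
  if (!all(seq_len(nw) %in% win))
    stop("window_ms = ", window_ms, " leaves windows without any time sample; ",
         "use a window at least as wide as the time step")
  V <- dim(rep$mi)[2]
  sub <- rep$mi[features, , , drop = FALSE]
  vmax <- apply(sub, c(2, 3), max)                  # voxels x times
  curve <- matrix(-Inf, V, nw)
  for (w in seq_len(nw))
    curve[, w] <- apply(vmax[, win == w, drop = FALSE], 1, max)
  starts <- t0 + (seq_len(nw) - 1L) * window_ms
  onset <- offset <- rep(NaN, V)
  sig <- curve > threshold
  has <- rowSums(sig) > 0
  onset[has] <- starts[apply(sig[has, , drop = FALSE], 1, which.max)]
  offset[has] <- starts[nw + 1L - apply(sig[has, nw:1, drop = FALSE], 1, which.max)]
  structure(list(curve = curve, onset_ms = onset, offset_ms = offset,
                 duration_ms = offset - onset, window_start_ms = starts,
                 window_ms = window_ms, threshold = threshold, subset = subset),
            class = "max_course")
}

#' @export
print.max_course <- function(x, ...) {
  cat(sprintf("Max representation course%s: %d voxels x %d windows (%g ms)\n",
              if (!is.null(x$subset)) paste0(" [", x$subset, "]") else "",
              nrow(x$curve), ncol(x$curve), x$window_ms))
  cat(sprintf("  %d voxels with defined onsets\n", sum(!is.nan(x$onset_ms))))
  invisible(x)
}

#' Divergence profile between two representation courses
#'
#' Per time window, the similarity between the diagnostic and nondiagnostic
#' voxel vectors is their de-meaned dot product (each vector has its mean
#' subtracted before the product, making the statistic invariant to adding a
#' constant to either). The null distribution is built by shuffling the
#' entries of the two vectors (independently by default, or with a shared
#' permutation), and the significance bounds are the
#' `alpha/(2 * n_windows)`-tail percentiles of the null (two-tailed,
#' Bonferroni corrected over windows; with alpha 0.05 and 40 windows these
#' are the 0.0625th and 99.9375th percentiles).
#'
#' @param diag_course,nondiag_course `max_course` objects on the same voxel
#'   set and windows.
#' @param n_boot Null iterations per window (default 1000).
#' @param alpha Two-tailed family-wise level (default 0.05).
#' @param shuffle `"independent"` (default) or `"joint"`.
#' @param seed Optional integer seed.
#' @return Object of class `divergence_profile`: `similarity`, `null_low`,
#'   `null_high`, `significant`, `flat` (windows where both vectors were all
#'   zero), `window_start_ms`.
#' @export
divergence <- function(diag_course, nondiag_course, n_boot = 1000, alpha = 0.05,
                       shuffle = c("independent", "joint"), seed = NULL) {
  shuffle <- match.arg(shuffle)
  stopifnot(inherits(diag_course, "max_course"), inherits(nondiag_course, "max_course"))
  if (!identical(dim(diag_course$curve), dim(nondiag_course$curve)))
    stop("courses must share the voxel set and windows")
  A <- diag_course$curve; B <- nondiag_course$curve
  nw <- ncol(A); V <- nrow(A)
  p_lo <- 100 * alpha / (2 * nw)
  sim <- numeric(nw); lo <- hi <- numeric(nw); flat <- logical(nw)
  .with_seed(seed, {
    for (w in seq_len(nw)) {
      x <- A[, w]; y <- B[, w]
      flat[w] <- all(x == 0) && all(y == 0)
      xd <- x - mean(x); yd <- y - mean(y)
      sim[w] <- sum(xd * yd)
      null <- vapply(seq_len(n_boot), function(i) {
        px <- sample.int(V)
        py <- if (shuffle == "independent") sample.int(V) else px
        sum(xd[px] * yd[py])
      }, numeric(1))
      lo[w] <- .pctl(null, p_lo)
      hi[w] <- .pctl(null, 100 - p_lo)
    }
  })
  sig <- (sim < lo | sim > hi) & !flat
  structure(list(similarity = sim, null_low = lo, null_high = hi,
                 significant = sig, flat = flat,
                 window_start_ms = diag_course$window_start_ms,
                 n_boot = n_boot, alpha = alpha, shuffle = shuffle),
            class = "divergence_profile")
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat(sprintf("Divergence profile: %d windows, %d significant (%s shuffle)\n",
              length(x$similarity), sum(x$significant), x$shuffle))
  invisible(x)
}

#' Last window of significant positive similarity
#'
#' Helper to read the divergence time off a profile: the start time of the
#' last window whose similarity is significantly positive (after which the
#' two representations have diverged).
#'
#' @param profile A `divergence_profile`.
#' @return Window start time in ms, or `NaN` if no window qualifies.
#' @export
divergence_last_window <- function(profile) {
  stopifnot(inherits(profile, "divergence_profile"))
  ok <- which(profile$significant & profile$similarity > 0)
  if (length(ok) == 0) return(NaN)
  profile$window_start_ms[max(ok)]
}

#' Wavefront progression regressions
#'
#' Computes each voxel's Euclidean distance from the voxel of earliest onset,
#' excludes voxels whose onset lies more than 3 standard deviations from the
#' median onset, and fits robust linear regressions (iteratively reweighted
#' least squares with a bisquare weight) of onset vs. distance and duration
#' vs. distance.
#'
#' @param course A `max_course` with at least 10 defined onsets after
#'   exclusion.
#' @param coords Voxels x 3 coordinate matrix (mm).
#' @param sd_exclude Outlier cut in standard deviations from the median onset
#'   (default 3).
#' @return Object of class `wavefront_fit`: `onset_fit` and `duration_fit`
#'   (each slope, intercept, se, t, p), `excluded_fraction`, `origin_voxel`,
#'   `distance_mm`, `n_used`.
#' @export
wavefront_regressions <- function(course, coords, sd_exclude = 3) {
  stopifnot(inherits(course, "max_course"), is.matrix(coords))
  onset <- course$onset_ms
  defined <- which(!is.nan(onset))
  if (length(defined) < 2) stop("fewer than 2 voxels with defined onsets")
  o <- onset[defined]
  if (stats::sd(o) == 0)
    stop("all onsets are identical; the onset regression is degenerate")
  keep <- defined[abs(o - stats::median(o)) <= sd_exclude * stats::sd(o)]
  if (length(keep) < 10)
    stop("need at least 10 voxels with defined onsets after exclusion; have ",
         length(keep))
  origin <- keep[which.min(onset[keep])]
  d <- sqrt(rowSums((coords[keep, , drop = FALSE] -
                       matrix(coords[origin, ], length(keep), 3, byrow = TRUE))^2))
  fit_one <- function(yv) {
    ## an exact linear relation degenerates the bisquare scale estimate;
    ## ordinary least squares is then already the robust answer
    ols <- stats::lm(yv ~ d)
    scale_y <- max(stats::sd(yv), abs(mean(yv)), 1)
    if (stats::sd(stats::residuals(ols)) < 1e-8 * scale_y) {
      cf <- suppressWarnings(summary(ols))$coefficients
      return(c(slope = unname(cf["d", "Estimate"]),
               intercept = unname(cf["(Intercept)", "Estimate"]),
               se = unname(cf["d", "Std. Error"]), t = unname(cf["d", "t value"]),
               p = unname(cf["d", "Pr(>|t|)"])))
    }
    fit <- MASS::rlm(yv ~ d, psi = MASS::psi.bisquare, maxit = 100)
    cf <- summary(fit)$coefficients
    tval <- cf["d", "t value"]
    c(slope = unname(cf["d", "Value"]), intercept = unname(cf["(Intercept)", "Value"]),
      se = unname(cf["d", "Std. Error"]), t = unname(tval),
      p = 2 * stats::pt(-abs(tval), df = length(yv) - 2))
  }
  structure(list(onset_fit = fit_one(onset[keep]),
                 duration_fit = fit_one(course$duration_ms[keep]),
                 excluded_fraction = 1 - length(keep) / length(defined),
                 origin_voxel = origin, voxels = keep, distance_mm = d,
                 n_used = length(keep)),
            class = "wavefront_fit")
}

#' @export
print.wavefront_fit <- function(x, ...) {
  cat(sprintf("Wavefront regressions on %d voxels (%.1f%% excluded):\n",
              x$n_used, 100 * x$excluded_fraction))
  cat(sprintf("  onset ~ distance:    slope %+.3f ms/mm (p = %.3g)\n",
              x$onset_fit["slope"], x$onset_fit["p"]))
  cat(sprintf("  duration ~ distance: slope %+.3f ms/mm (p = %.3g)\n",
              x$duration_fit["slope"], x$duration_fit["p"]))
  invisible(x)
}

#' Spatio-temporal junction of the nondiagnostic wavefront
#'
#' Selects the voxels farthest along the wavefront - Euclidean distance
#' strictly greater than the 75th percentile of distances over all voxels
#' with defined offsets - and returns the latest representation offset among
#' them as the junction's temporal marker. A single qualifying voxel is its
#' own junction.
#'
#' @param course A `max_course` (typically over nondiagnostic features).
#' @param coords Voxels x 3 coordinates (mm); used to compute distances from
#'   the earliest-onset voxel when `distances` is not given.
#' @param distances Optional precomputed per-voxel distances (mm).
#' @param prob Distance percentile (default 75).
#' @return Object of class `sir_junction`: `voxels` (indices of the far set),
#'   `marker_ms`, `distance_threshold_mm`.
#' @export
junction <- function(course, coords = NULL, distances = NULL, prob = 75) {
  stopifnot(inherits(course, "max_course"))
  defined <- which(!is.nan(course$offset_ms))
  if (length(defined) == 0) stop("no voxels with defined offsets")
  if (is.null(distances)) {
    if (is.null(coords)) stop("provide coords or distances")
    origin <- defined[which.min(course$onset_ms[defined])]
    distances <- sqrt(rowSums((coords - matrix(coords[origin, ], nrow(coords), 3,
                                               byrow = TRUE))^2))
  }
  d <- distances[defined]
  if (length(defined) == 1L) {
    far <- defined
    thr <- d
  } else {
    thr <- .pctl(d, prob)
    far <- defined[d > thr]
    if (length(far) == 0)
      stop("no voxel lies strictly beyond the ", prob,
           "th distance percentile (distances are degenerate)")
  }
  structure(list(voxels = far, marker_ms = max(course$offset_ms[far]),
                 distance_threshold_mm = thr),
            class = "sir_junction")
}

#' @export
print.sir_junction <- function(x, ...) {
  cat(sprintf("Junction: %d far voxels, temporal marker %g ms\n",
              length(x$voxels), x$marker_ms))
  invisible(x)
}
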