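## Synthetic observer: planted stimulus templates, a noisy evidence-race
## decision rule calibrated to a target "don't know" rate, and encoding voxel
## activity with a planted wavefront, divergence junction, and an
## integration-hub region that accumulates diagnostic features. Provides
## ground truth for parameter-recovery validation of every pipeline stage.

## Gaussian blob truncated at `floor` of its peak, optionally flattened into a
## plateau (weights saturate at 1 above `plateau` of the peak). Fine-SF
## templates use a compact plateau profile so every support pixel carries
## comparable evidence weight; coarse-SF templates keep the Gaussian profile
## and a low floor (their band's wide apertures spread evidence into the
## tails anyway).
.template_blob <- function(size, cx_frac, cy_frac, r_px, floor = 0.05,
                           plateau = 1) {
  ax <- seq_len(size)
  g <- exp(-outer((ax - cx_frac * size)^2, (ax - cy_frac * size)^2, "+") /
             (2 * (r_px / 2)^2))
  g[g < floor] <- 0
  pmin(g / plateau, 1)
}

#' Planted ground truth for a synthetic observer
#'
#' Defines the stimulus templates (two high-spatial-frequency "nun" faces, a
#' low-spatial-frequency "Voltaire" face plus a mid-band eye - the diagnostic
#' features - and two nondiagnostic flanking features), a noisy evidence-race
#' decision rule whose "don't know" threshold is Monte-Carlo calibrated to the
#' target rate, and a voxel encoding map: two traveling wavefronts (onsets
#' increasing with distance from the planted origin; nondiagnostic durations
#' shrinking toward the junction time, diagnostic representations sustained
#' past it), an integration hub accumulating the diagnostic features with a
#' complexity peak in the fourth of five N/M170 windows, and pure-noise
#' voxels.
#'
#' @param mask_size Analysis mask resolution (default 64).
#' @param image_deg Image size in degrees of visual angle (default 5.72).
#' @param n_apertures Total Gaussian apertures per trial (default 60).
#' @param n_voxels Number of voxels (default 500).
#' @param time_ms Activity time grid in ms (default 0-400 every 2 ms).
#' @param junction_ms Planted divergence time (default 170).
#' @param dk_target Target "don't know" response fraction (default 0.25).
#' @param decision_noise_sd Noise SD on the standardized percept evidence
#'   (default 0.3).
#' @param gain Encoding gain: amplitude SD per unit standardized coefficient
#'   (default 1.5; activity noise has SD `activity_noise_sd`).
#' @param activity_noise_sd Additive white-noise SD on voxel amplitude
#'   (default 1).
#' @param kernel Temporal response kernel, `"halfcosine"` (default) or
#'   `"boxcar"`.
#' @param coord_extent_mm Side of the cubic voxel volume in mm (default 60).
#' @param frac_wavefront,frac_hub Fractions of voxels encoding the traveling
#'   wavefronts (each such voxel carries one nondiagnostic and one diagnostic
#'   feature) and the integration hub (the remainder is pure noise).
#' @param onset0_ms,speed_ms_per_mm Wavefront origin onset and progression
#'   speed.
#' @param n_calibration Trials used to calibrate coefficient scales and the
#'   don't-know threshold.
#' @param seed Integer seed; the whole truth object is deterministic in it.
#' @return Object of class `sir_ground_truth`.
#' @export
ground_truth <- function(mask_size = 64, image_deg = 5.72, n_apertures = 60,
                         n_voxels = 500, time_ms = seq(0, 400, by = 2),
                         junction_ms = 170, dk_target = 0.25,
                         decision_noise_sd = 0.3, gain = 1.5,
                         activity_noise_sd = 1,
                         kernel = c("halfcosine", "boxcar"),
                         coord_extent_mm = 60, frac_wavefront = 0.6,
                         frac_hub = 0.1,
                         onset0_ms = 40, speed_ms_per_mm = 1.2,
                         n_calibration = 400, seed = 1) {
  kernel <- match.arg(kernel)
  stopifnot(dk_target > 0, dk_target < 1, frac_wavefront + frac_hub <= 1)
  s <- mask_size
  n_bands <- 5
  sigmas_px <- bubbles_sigmas_deg * s / image_deg
  allocation <- aperture_allocation(n_apertures, sigmas_px)

  ## templates: (cx, cy, radius_frac, band, percept, diagnostic, floor, plateau)
  spec <- list(
    nun_left      = list(0.30, 0.38, 0.105, 1, "nuns",     TRUE,  0.30, 0.5),
    nun_right     = list(0.70, 0.38, 0.105, 1, "nuns",     TRUE,  0.30, 0.5),
    voltaire_eye  = list(0.62, 0.33, 0.100, 2, "voltaire", TRUE,  0.10, 1),
    voltaire_face = list(0.50, 0.55, 0.170, 3, "voltaire", TRUE,  0.05, 1),
    flank_left    = list(0.18, 0.70, 0.110, 2, NA,         FALSE, 0.10, 1),
    flank_right   = list(0.84, 0.72, 0.130, 3, NA,         FALSE, 0.05, 1))
  p <- s * s * n_bands
  templates <- matrix(0, length(spec), p)
  rownames(templates) <- names(spec)
  meta <- data.frame(feature = names(spec),
                     band = vapply(spec, function(z) z[[4]], numeric(1)),
                     percept = vapply(spec, function(z) as.character(z[[5]]), character(1)),
                     diagnostic = vapply(spec, function(z) z[[6]], logical(1)),
                     stringsAsFactors = FALSE)
  for (i in seq_along(spec)) {
    z <- spec[[i]]
    blob <- .template_blob(s, z[[1]], z[[2]], z[[3]] * s, floor = z[[7]],
                           plateau = z[[8]])
    off <- (z[[4]] - 1) * s * s
    templates[i, off + seq_len(s * s)] <- as.vector(blob)
  }

  truth <- list(mask_size = s, n_bands = n_bands, image_deg = image_deg,
                sigmas_px = sigmas_px, allocation = allocation,
                templates = templates, feature_meta = meta,
                junction_ms = junction_ms, dk_target = dk_target,
                decision_noise_sd = decision_noise_sd, gain = gain,
                activity_noise_sd = activity_noise_sd, kernel = kernel,
                time_ms = time_ms, seed = seed)
  class(truth) <- "sir_ground_truth"

  ## --- calibrate coefficient scales and the don't-know threshold ----------
  cal <- .with_seed(.subseed(seed, 7, 101), {
    M <- .simulate_masks(truth, n_calibration)
    raw <- M %*% t(templates)
    ctr <- colMeans(raw)
    scl <- apply(raw, 2, stats::sd)
    if (any(scl == 0)) stop("degenerate template coefficients during calibration")
    z <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
    ev <- .percept_evidence(z, meta)
    noisy <- ev + matrix(stats::rnorm(length(ev), 0, decision_noise_sd),
                         nrow(ev), ncol(ev))
    mx <- apply(noisy, 1, max)
    list(ctr = ctr, scl = scl, dk_threshold = .pctl(mx, 100 * dk_target),
         max_evidence = max(mx))
  })
  if (!is.finite(cal$dk_threshold) || cal$dk_threshold >= cal$max_evidence)
    stop("degenerate decision rule: the don't-know threshold (",
         format(cal$dk_threshold), ") is not attainable by the evidence")
  truth$coef_center <- cal$ctr
  truth$coef_scale <- cal$scl
  truth$dk_threshold <- cal$dk_threshold

  ## --- voxel coordinates and encoding map ---------------------------------
  ## Wavefront voxels carry one nondiagnostic AND one diagnostic feature, so
  ## the two representations share the same spatial profile early on (as in
  ## occipital cortex) and diverge when the nondiagnostic offsets collapse at
  ## the junction while the diagnostic representations are sustained.
  enc <- .with_seed(.subseed(seed, 7, 202), {
    coords <- matrix(stats::runif(n_voxels * 3, 0, coord_extent_mm), n_voxels, 3)
    origin_point <- c(0, coord_extent_mm / 2, coord_extent_mm / 2)
    d <- sqrt(colSums((t(coords) - origin_point)^2))
    roles <- rep("noise", n_voxels)
    ord <- sample.int(n_voxels)
    n_wf <- round(frac_wavefront * n_voxels)
    n_hb <- round(frac_hub * n_voxels)
    roles[ord[seq_len(n_wf)]] <- "wavefront"
    roles[ord[n_wf + seq_len(n_hb)]] <- "hub"
    nd_ids <- which(!meta$diagnostic)
    dg_ids <- which(meta$diagnostic)
    rows <- list()
    idx_wf <- which(roles == "wavefront")
    if (length(idx_wf)) {
      dmax <- max(d[idx_wf])
      onset <- onset0_ms + speed_ms_per_mm * d[idx_wf]
      nd_offset <- junction_ms - 0.05 * (dmax - d[idx_wf])
      onset <- pmin(onset, nd_offset - 20)
      rows$nd <- data.frame(voxel = idx_wf,
                            feature = nd_ids[1 + (seq_along(idx_wf) - 1) %% length(nd_ids)],
                            onset_ms = onset, duration_ms = nd_offset - onset,
                            gain = gain, role = "wavefront")
      rows$dg <- data.frame(voxel = idx_wf,
                            feature = dg_ids[1 + (seq_along(idx_wf) - 1) %% length(dg_ids)],
                            onset_ms = onset, duration_ms = 380 - onset,
                            gain = gain, role = "wavefront")
    }
    idx_hb <- which(roles == "hub")
    if (length(idx_hb)) {
      hub_onsets <- seq(130, by = 18, length.out = length(dg_ids))
      rows$hb <- do.call(rbind, lapply(seq_along(dg_ids), function(j)
        data.frame(voxel = idx_hb, feature = dg_ids[j],
                   onset_ms = hub_onsets[j], duration_ms = 198 - hub_onsets[j],
                   gain = gain, role = "hub")))
    }
    list(coords = coords, origin_point = origin_point, distance_mm = d,
         roles = roles, map = do.call(rbind, unname(rows)))
  })
  truth$coords <- enc$coords
  truth$origin_point <- enc$origin_point
  truth$distance_mm <- enc$distance_mm
  truth$voxel_roles <- enc$roles
  truth$encoding_map <- enc$map
  truth$n_voxels <- n_voxels
  truth$complexity_peak_window <- 4L
  truth
}

#' @export
print.sir_ground_truth <- function(x, ...) {
  cat("Synthetic observer ground truth:\n")
  cat(sprintf("  %d features (%d diagnostic) on %d x %d x %d masks\n",
              nrow(x$templates), sum(x$feature_meta$diagnostic),
              x$mask_size, x$mask_size, x$n_bands))
  cat(sprintf("  %d voxels (%s); junction %g ms; don't-know target %.0f%%\n",
              x$n_voxels, paste(names(table(x$voxel_roles)),
                                table(x$voxel_roles), sep = ":", collapse = " "),
              x$junction_ms, 100 * x$dk_target))
  invisible(x)
}

.percept_evidence <- function(z, meta) {
  percepts <- c("nuns", "voltaire")
  ev <- matrix(0, nrow(z), 2, dimnames = list(NULL, percepts))
  for (j in 1:2) {
    ids <- which(meta$percept %in% percepts[j])
    ev[, j] <- rowSums(z[, ids, drop = FALSE]) / sqrt(length(ids))
  }
  ev
}

## n trials of flattened bubble masks at the truth's analysis resolution
## (consumes the caller's RNG stream).
.simulate_masks <- function(truth, n) {
  p <- truth$mask_size^2 * truth$n_bands
  M <- matrix(0, n, p)
  for (i in seq_len(n)) {
    bm <- generate_bubble_masks(truth$allocation, truth$sigmas_px, truth$mask_size)
    M[i, ] <- .flatten_masks(bm)
  }
  attr(M, "mask_dim") <- c(truth$mask_size, truth$mask_size, truth$n_bands)
  M
}

#' Simulate Bubbles trials and perceptual decisions
#'
#' Generates per-trial bubble masks at the analysis resolution and decides
#' each trial by a noisy evidence race: the standardized visibility of each
#' percept's diagnostic templates plus Gaussian noise; the best percept wins
#' when its evidence clears the don't-know threshold, otherwise the response
#' is "don't know".
#'
#' @param truth A `sir_ground_truth`.
#' @param n_trials Number of trials (at least 100 when masks are generated).
#' @param seed Optional integer seed.
#' @param masks Optional precomputed trial-by-pixel mask matrix (for
#'   controlled tests); overrides generation.
#' @param decision_noise_sd,dk_threshold Optional overrides of the truth's
#'   decision-rule parameters (e.g. `dk_threshold = Inf` forces all
#'   "don't know").
#' @return Object of class `sir_trials`: `masks` (with `mask_dim` attribute),
#'   `decisions` (factor over [decision_levels()]), `evidence`, `coefs`
#'   (true-template standardized coefficients), `seed`.
#' @export
simulate_trials <- function(truth, n_trials, seed = NULL, masks = NULL,
                            decision_noise_sd = truth$decision_noise_sd,
                            dk_threshold = truth$dk_threshold) {
  stopifnot(inherits(truth, "sir_ground_truth"))
  .with_seed(seed, {
    if (is.null(masks)) {
      if (n_trials < 100) stop("n_trials must be at least 100; got ", n_trials)
      masks <- .simulate_masks(truth, n_trials)
    } else {
      n_trials <- nrow(masks)
      if (is.null(attr(masks, "mask_dim")))
        attr(masks, "mask_dim") <- c(truth$mask_size, truth$mask_size, truth$n_bands)
    }
    raw <- masks %*% t(truth$templates)
    z <- sweep(sweep(raw, 2, truth$coef_center), 2, truth$coef_scale, "/")
    ev <- .percept_evidence(z, truth$feature_meta) +
      matrix(stats::rnorm(2 * n_trials, 0, decision_noise_sd), n_trials, 2)
    best <- max.col(ev, ties.method = "first")
    dec <- ifelse(ev[cbind(seq_len(n_trials), best)] > dk_threshold,
                  colnames(ev)[best], "dont_know")
    structure(list(masks = masks,
                   mask_dim = attr(masks, "mask_dim"),
                   decisions = factor(dec, levels = decision_levels()),
                   evidence = ev, coefs = z, n_trials = n_trials, seed = seed),
              class = "sir_trials")
  })
}

#' @export
print.sir_trials <- function(x, ...) {
  tab <- table(x$decisions)
  cat(sprintf("Synthetic trials: %d trials, %d pixels/trial\n",
              x$n_trials, ncol(x$masks)))
  cat("  decisions:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

.temporal_kernel <- function(time_ms, onset, duration, kernel) {
  u <- (time_ms - onset) / duration
  k <- numeric(length(time_ms))
  inw <- u >= 0 & u <= 1
  k[inw] <- if (kernel == "boxcar") 1 else sin(pi * u[inw])
  k
}

#' Simulate source-space voxel activity
#'
#' Each encoding entry adds `gain * z(coefficient) * kernel(t)` to its voxel's
#' amplitude over `[onset, onset + duration]`; white Gaussian noise is added
#' everywhere, and the gradient channel is the discrete temporal derivative of
#' the (noisy) amplitude channel. Non-encoding voxels are pure noise. Voxel
#' coordinates come from the truth, laid out so that distance from the
#' planted origin tracks representation onset.
#'
#' @param truth A `sir_ground_truth`.
#' @param trials A `sir_trials` from the same truth.
#' @param time_ms Time grid (default the truth's).
#' @param noise_sd Amplitude noise SD (default the truth's).
#' @param seed Optional integer seed.
#' @return Object of class `source_activity`: `amplitude`, `gradient`
#'   (trials x voxels x times), `coords`, `time_ms`.
#' @export
simulate_activity <- function(truth, trials, time_ms = truth$time_ms,
                              noise_sd = truth$activity_noise_sd, seed = NULL) {
  stopifnot(inherits(truth, "sir_ground_truth"), inherits(trials, "sir_trials"))
  map <- truth$encoding_map
  if (!is.null(map) && any(map$duration_ms <= 0))
    stop("encoding map contains non-positive durations")
  n <- trials$n_trials
  V <- truth$n_voxels
  Tn <- length(time_ms)
  dt <- if (Tn > 1) diff(time_ms)[1] else 1
  .with_seed(seed, {
    amp <- array(stats::rnorm(n * V * Tn, 0, noise_sd), c(n, V, Tn))
    if (!is.null(map) && nrow(map) > 0) {
      z <- trials$coefs
      for (r in seq_len(nrow(map))) {
        k <- .temporal_kernel(time_ms, map$onset_ms[r], map$duration_ms[r],
                              truth$kernel)
        nzk <- which(k != 0)
        if (length(nzk))
          amp[, map$voxel[r], nzk] <- amp[, map$voxel[r], nzk] +
            outer(map$gain[r] * z[, map$feature[r]], k[nzk])
      }
    }
    grad <- array(0, c(n, V, Tn))
    if (Tn > 1) {
      grad[, , 2:Tn] <- (amp[, , 2:Tn, drop = FALSE] -
                           amp[, , 1:(Tn - 1), drop = FALSE]) / dt
      grad[, , 1] <- grad[, , 2]
    }
    structure(list(amplitude = amp, gradient = grad, coords = truth$coords,
                   time_ms = time_ms, n_trials = n),
              class = "source_activity")
  })
}

#' @export
print.source_activity <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf("Source activity: %d trials x %d voxels x %d times (%g-%g ms)\n",
              d[1], d[2], d[3], min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' Simulate a complete synthetic observer dataset
#'
#' @param truth A `sir_ground_truth`.
#' @param n_trials Number of trials.
#' @param seed Integer seed; trials and activity use derived substreams so the
#'   dataset is bit-reproducible.
#' @param time_ms,noise_sd Passed to [simulate_activity()].
#' @return Object of class `sir_dataset`: `trials`, `activity`, `truth`.
#' @export
simulate_observer <- function(truth, n_trials, seed = 1,
                              time_ms = truth$time_ms,
                              noise_sd = truth$activity_noise_sd) {
  trials <- simulate_trials(truth, n_trials, seed = .subseed(seed, 13, 1))
  activity <- simulate_activity(truth, trials, time_ms = time_ms,
                                noise_sd = noise_sd, seed = .subseed(seed, 13, 2))
  structure(list(trials = trials, activity = activity, truth = truth,
                 seed = seed),
            class = "sir_dataset")
}

#' @export
print.sir_dataset <- function(x, ...) {
  cat("Synthetic SIR dataset (seed", x$seed, ")\n")
  print(x$trials); print(x$activity)
  invisible(x)
}
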