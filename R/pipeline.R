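## End-to-end orchestration of the analysis stages with validated
## configuration, derived per-stage seeds, resumable RDS outputs and a
## manifest recording file hashes and wall time.

#' Build and validate a pipeline configuration
#'
#' All thresholds of the reference analysis (0.2 visibility binarization, 15%
#' feature thresholding, 75th/25th classification percentiles, 3-SD onset
#' exclusion, 75th-percentile junction distance, window spans) and all
#' permutation counts are configuration values, never hard-coded in the
#' stages.
#'
#' @param n_trials,n_voxels Synthetic dataset size.
#' @param mask_size Analysis mask resolution.
#' @param time_step_ms,time_span_ms Activity time grid.
#' @param junction_ms,dk_target,decision_noise_sd,gain,activity_noise_sd,kernel
#'   Ground-truth parameters (see [ground_truth()]).
#' @param n_perm_diagnostic,percentile_diagnostic Diagnostic-map permutation
#'   settings (reference: 10000 and 99.9).
#' @param n_perm_matrix,percentile_matrix 3D-matrix permutation settings
#'   (reference: 200 and 95).
#' @param n_boot_divergence,alpha_divergence Divergence null settings.
#' @param n_components,reduced_time_step_ms Activity reduction for the MI
#'   image stack.
#' @param nmf_k,nmf_kmax Brain-feature rank (`"auto"` = elbow rule).
#' @param nmf_maxit,nmf_tol,nmf_restarts Settings for the NMF fit.
#' @param window_ms Course window width.
#' @param complexity_from,complexity_to,complexity_n Complexity windows.
#' @param visibility_threshold Mask binarization cut.
#' @param run_decision_mi Include the decision-MI stage.
#' @param seed Top-level seed; every stage uses a derived substream.
#' @return Object of class `sir_config`.
#' @export
sir_config <- function(n_trials = 1500, n_voxels = 500, mask_size = 64,
                       time_step_ms = 2, time_span_ms = c(0, 400),
                       junction_ms = 170, dk_target = 0.25,
                       decision_noise_sd = 0.3, gain = 1.5,
                       activity_noise_sd = 1, kernel = "halfcosine",
                       n_perm_diagnostic = 10000, percentile_diagnostic = 99.9,
                       n_perm_matrix = 200, percentile_matrix = 95,
                       n_boot_divergence = 1000, alpha_divergence = 0.05,
                       n_components = 60, reduced_time_step_ms = 8,
                       nmf_k = "auto", nmf_kmax = 25, nmf_maxit = 200,
                       nmf_tol = 1e-4, nmf_restarts = 3, window_ms = 10,
                       complexity_from = 120, complexity_to = 220,
                       complexity_n = 5, visibility_threshold = 0.2,
                       run_decision_mi = TRUE, seed = 1) {
  cfg <- as.list(environment())
  pos <- c("n_trials", "n_voxels", "mask_size", "time_step_ms",
           "n_perm_diagnostic", "n_perm_matrix", "n_boot_divergence",
           "n_components", "reduced_time_step_ms", "window_ms", "complexity_n")
  for (f in pos) if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
    stop("config field '", f, "' must be a positive number; got ", cfg[[f]])
  if (cfg$dk_target <= 0 || cfg$dk_target >= 1)
    stop("config field 'dk_target' must lie in (0, 1)")
  if (cfg$visibility_threshold <= 0 || cfg$visibility_threshold >= 1)
    stop("config field 'visibility_threshold' must lie in (0, 1)")
  for (f in c("percentile_diagnostic", "percentile_matrix"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 100)
      stop("config field '", f, "' must lie in (0, 100)")
  if (!identical(cfg$nmf_k, "auto") && (!is.numeric(cfg$nmf_k) || cfg$nmf_k < 2))
    stop("config field 'nmf_k' must be 'auto' or an integer >= 2")
  if (diff(cfg$time_span_ms) <= 0) stop("time_span_ms must be increasing")
  if (cfg$window_ms < cfg$time_step_ms)
    stop("config field 'window_ms' must be at least time_step_ms so every ",
         "course window contains a time sample")
  structure(cfg, class = "sir_config")
}

#' @export
print.sir_config <- function(x, ...) {
  cat("SIR pipeline config: seed", x$seed, "\n")
  cat(sprintf("  %d trials, %d voxels, %d px masks, %g ms steps over %g-%g ms\n",
              x$n_trials, x$n_voxels, x$mask_size, x$time_step_ms,
              x$time_span_ms[1], x$time_span_ms[2]))
  invisible(x)
}

#' Run the full pipeline on a synthetic observer
#'
#' Executes simulate, diagnostic maps, brain features, representation matrix,
#' dynamics (courses, divergence, wavefront regressions, junction),
#' redundancy/complexity, optional decision MI, and the recovery report. Each
#' stage writes one RDS file under `out_dir` and is skipped (loaded from
#' disk) when `resume = TRUE` and its file exists; a manifest TSV with file
#' md5 hashes, and the configuration as YAML, are written alongside.
#'
#' @param config A `sir_config`.
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse existing stage files instead of recomputing.
#' @param quiet Suppress per-stage progress messages.
#' @return (Invisibly) list with all stage objects plus `manifest` and
#'   `out_dir`.
#' @export
sir_run_all <- function(config, out_dir, resume = FALSE, quiet = TRUE) {
  stopifnot(inherits(config, "sir_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- .with_seed(config$seed, sample.int(2^31 - 10, 12))
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0), seconds = numeric(0))
  stage <- function(name, fn) {
    file <- file.path(out_dir, paste0(name, ".rds"))
    t0 <- Sys.time()
    if (resume && file.exists(file)) {
      obj <- readRDS(file)
    } else {
      obj <- fn()
      saveRDS(obj, file)
    }
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest <<- rbind(manifest, data.frame(
      stage = name, file = basename(file),
      md5 = unname(tools::md5sum(file)), seconds = round(el, 3)))
    if (!quiet) message(sprintf("[%s] %.1fs", name, el))
    obj
  }

  time_ms <- seq(config$time_span_ms[1], config$time_span_ms[2],
                 by = config$time_step_ms)
  truth <- stage("truth", function() ground_truth(
    mask_size = config$mask_size, n_voxels = config$n_voxels,
    time_ms = time_ms, junction_ms = config$junction_ms,
    dk_target = config$dk_target, decision_noise_sd = config$decision_noise_sd,
    gain = config$gain, activity_noise_sd = config$activity_noise_sd,
    kernel = config$kernel, seed = config$seed))
  trials <- stage("trials", function()
    simulate_trials(truth, config$n_trials, seed = seeds[1]))
  activity <- stage("activity", function()
    simulate_activity(truth, trials, seed = seeds[2]))

  diagnostic <- stage("diagnostic", function() {
    vis <- binarize_visibility(trials$masks, config$visibility_threshold)
    list(nuns = diagnostic_map(vis, trials$decisions, "nuns",
                               n_perm = config$n_perm_diagnostic,
                               percentile = config$percentile_diagnostic,
                               seed = seeds[3]),
         voltaire = diagnostic_map(vis, trials$decisions, "voltaire",
                                   n_perm = config$n_perm_diagnostic,
                                   percentile = config$percentile_diagnostic,
                                   seed = seeds[4]))
  })

  features <- stage("features", function() {
    reduced <- reduce_activity(activity, config$n_components,
                               times_ms = seq(config$time_span_ms[1],
                                              config$time_span_ms[2],
                                              by = config$reduced_time_step_ms))
    stack <- reduced_mi_images(trials$masks, reduced)
    nmf_basis(stack, k = config$nmf_k, kmax = config$nmf_kmax,
              maxit = config$nmf_maxit, tol = config$nmf_tol,
              n_restarts = config$nmf_restarts, seed = seeds[5])
  })

  coefs <- stage("coefs", function() {
    co <- feature_coefficients(trials$masks, features)
    labels <- classify_features(co, trials$decisions)
    list(coefs = co, labels = labels)
  })
  labels <- coefs$labels

  repmat <- stage("repmat", function()
    representation_matrix(coefs$coefs, activity,
                          n_perm = config$n_perm_matrix,
                          percentile = config$percentile_matrix,
                          seed = seeds[6]))

  dyn <- stage("dynamics", function() {
    di <- which(labels %in% c("diagnostic_nuns", "diagnostic_voltaire"))
    nd <- which(labels == "nondiagnostic")
    if (length(di) == 0) stop("no diagnostic features recovered; cannot run dynamics")
    if (length(nd) == 0) stop("no nondiagnostic features recovered; cannot run dynamics")
    cd <- max_course(repmat, di, window_ms = config$window_ms, subset = "diagnostic")
    cn <- max_course(repmat, nd, window_ms = config$window_ms, subset = "nondiagnostic")
    div <- divergence(cd, cn, n_boot = config$n_boot_divergence,
                      alpha = config$alpha_divergence, seed = seeds[7])
    fit <- wavefront_regressions(cn, activity$coords)
    jc <- junction(cn, coords = activity$coords)
    list(course_diag = cd, course_nondiag = cn, divergence = div,
         wavefront = fit, junction = jc)
  })

  behavior <- stage("behavior", function() {
    di <- which(labels %in% c("diagnostic_nuns", "diagnostic_voltaire"))
    win_times <- seq(config$complexity_from, config$complexity_to,
                     by = config$time_step_ms)
    red <- redundancy_matrix(coefs$coefs, activity, trials$decisions, di,
                             n_perm = config$n_perm_matrix,
                             percentile = config$percentile_matrix,
                             seed = seeds[8], times_ms = win_times)
    cx <- representational_complexity(
      red, complexity_windows(config$complexity_from, config$complexity_to,
                              config$complexity_n))
    out <- list(redundancy = red, complexity = cx)
    if (isTRUE(config$run_decision_mi))
      out$decision_mi <- decision_mi(activity, trials$decisions,
                                     n_perm = config$n_perm_matrix,
                                     percentile = config$percentile_matrix,
                                     seed = seeds[9], times_ms = win_times)
    out
  })

  recovery <- stage("recovery", function() {
    ds <- structure(list(trials = trials, activity = activity, truth = truth,
                         seed = config$seed), class = "sir_dataset")
    recovery_report(ds, list(diag_nuns = diagnostic$nuns,
                             diag_voltaire = diagnostic$voltaire,
                             basis = features, labels = labels,
                             junction = dyn$junction,
                             complexity = behavior$complexity))
  })

  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(truth = truth, trials = trials, activity = activity,
                 diagnostic = diagnostic, features = features, coefs = coefs,
                 repmat = repmat, dynamics = dyn, behavior = behavior,
                 recovery = recovery, manifest = manifest, out_dir = out_dir))
}
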