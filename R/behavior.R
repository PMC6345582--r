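## Feature representation for behavior: co-information redundancy matrices,
## representational complexity over the extended N/M170 window, and decision
## information in voxel activity.

.prep_bivariate <- function(activity, times_ms) {
  tm <- activity$time_ms
  tidx <- if (is.null(times_ms)) seq_along(tm) else
    vapply(times_ms, function(t) which.min(abs(tm - t)), integer(1))
  n <- dim(activity$amplitude)[1]
  V <- dim(activity$amplitude)[2]
  list(a1 = matrix(activity$amplitude[, , tidx], n, V * length(tidx)),
       a2 = matrix(activity$gradient[, , tidx], n, V * length(tidx)),
       time_ms = tm[tidx], n = n, V = V, Tn = length(tidx))
}

.redundancy_core <- function(coefs, activity, decisions, features, n_perm,
                             percentile, seed, contrast, times_ms) {
  stopifnot(inherits(activity, "source_activity"), is.matrix(coefs))
  if (length(features) == 0) stop("no diagnostic features supplied")
  decisions <- .as_decisions(decisions)
  if (contrast == "three_way") {
    keep <- seq_along(decisions)
    cls <- droplevels(decisions)
    if (nlevels(cls) < 3) stop("three_way contrast needs all three decision classes")
  } else {
    target <- sub("_vs_dk$", "", contrast)
    sub <- .contrast_subset(decisions, target)
    keep <- sub$keep
    cls <- factor(ifelse(sub$y == 1, target, "dont_know"))
  }
  X <- coefs[keep, features, drop = FALSE]
  n <- length(keep)
  pa <- .prep_bivariate(activity, times_ms)
  a1 <- .center_cols(.copnorm_cols(pa$a1[keep, , drop = FALSE]))
  a2 <- .center_cols(.copnorm_cols(pa$a2[keep, , drop = FALSE]))
  Xc <- .center_cols(.copnorm_cols(X))
  ys <- .y2_stats(a1, a2, n)
  k <- ncol(Xc)

  mi_fm <- .mi_1x2_block(Xc, a1, a2, ys, n)
  mi_fd <- vapply(seq_len(k), function(f)
    as.numeric(mi_gcd(Xc[, f], cls, normalize = FALSE)), numeric(1))
  red <- mi_fm - .mi_1x2_cond(Xc, a1, a2, cls, n)
  thr <- .with_seed(seed, {
    maxima <- vapply(seq_len(n_perm), function(i) {
      clp <- cls[sample.int(n)]
      max(mi_fm - .mi_1x2_cond(Xc, a1, a2, clp, n))
    }, numeric(1))
    .pctl(maxima, percentile)
  })
  red <- array(red, c(k, pa$V, pa$Tn))
  mi_fm <- array(mi_fm, c(k, pa$V, pa$Tn))
  structure(list(red = red, fwer_threshold = thr, significant = red > thr,
                 contrast = contrast, time_ms = pa$time_ms,
                 features = features, n_perm = n_perm, percentile = percentile,
                 n_trials = n,
                 components = list(mi_fd = mi_fd, mi_fm = mi_fm)),
            class = "redundancy_matrix")
}

#' Redundancy matrix (feature x voxel x time)
#'
#' Evaluates the co-information redundancy
#' `RED = MI(F;D) + MI(F;M) - MI(F;M,D)` for every combination of diagnostic
#' brain feature, voxel and time point, where D is the three-class perceptual
#' decision and M the bivariate voxel activity. Significance is established by
#' recomputing the matrix with decisions shuffled across trials and taking the
#' stated percentile of the per-permutation maximum over the whole 3D matrix
#' (reference: 200 permutations, 95th percentile).
#'
#' @param coefs Trials x features coefficient matrix.
#' @param activity A `source_activity`.
#' @param decisions Decision labels (all three classes).
#' @param features Indices of the diagnostic features (first axis of the
#'   result).
#' @param n_perm,percentile Permutation settings (defaults 200 and 95).
#' @param seed Optional integer seed.
#' @param times_ms Optional subset of time points (ms).
#' @return Object of class `redundancy_matrix`: `red` (bits),
#'   `fwer_threshold`, `significant`, `contrast = "three_way"`, `time_ms`,
#'   and `components` (`mi_fd` per feature and the `mi_fm` array; the joint
#'   term is recoverable as `mi_fd + (mi_fm - red)`).
#' @export
redundancy_matrix <- function(coefs, activity, decisions, features,
                              n_perm = 200, percentile = 95, seed = NULL,
                              times_ms = NULL) {
  .redundancy_core(coefs, activity, decisions, features, n_perm, percentile,
                   seed, "three_way", times_ms)
}

#' Decision-specific redundancy matrix
#'
#' Same computation as [redundancy_matrix()] but restricted to the trials of
#' one two-class contrast (a percept vs. "don't know"), uncovering the
#' features redundantly represented for that specific decision.
#'
#' @inheritParams redundancy_matrix
#' @param contrast `"nuns_vs_dk"` or `"voltaire_vs_dk"` (the three-way tag is
#'   rejected here; use [redundancy_matrix()]).
#' @return A `redundancy_matrix` with the restricted contrast tag.
#' @export
decision_specific_redundancy <- function(coefs, activity, decisions, features,
                                         contrast = c("nuns_vs_dk", "voltaire_vs_dk"),
                                         n_perm = 200, percentile = 95,
                                         seed = NULL, times_ms = NULL) {
  contrast <- match.arg(contrast)
  .redundancy_core(coefs, activity, decisions, features, n_perm, percentile,
                   seed, contrast, times_ms)
}

#' @export
print.redundancy_matrix <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf("Redundancy matrix (%s): %d features x %d voxels x %d times\n",
              x$contrast, d[1], d[2], d[3]))
  cat(sprintf("  FWER threshold %.4g bits; %d significant cells\n",
              x$fwer_threshold, sum(x$significant)))
  invisible(x)
}

#' Evenly spaced complexity windows
#'
#' @param from,to Window span bounds in ms (reference: 120 and 220, the
#'   extended N/M170 time course).
#' @param n Number of contiguous equal-width windows (default 5).
#' @return `n x 2` matrix of window bounds.
#' @export
complexity_windows <- function(from = 120, to = 220, n = 5) {
  edges <- seq(from, to, length.out = n + 1)
  cbind(start = edges[-(n + 1)], end = edges[-1])
}

#' Representational complexity map
#'
#' For each voxel and time window, counts the number of distinct features with
#' at least one significant redundancy cell inside the window - the size of
#' the population code the voxel redundantly represents with behavior.
#' Windows are `[start, end)`, with the final window closed on the right.
#'
#' @param red A `redundancy_matrix`.
#' @param windows Window bounds matrix (default [complexity_windows()]); must
#'   lie within the matrix's time span.
#' @return Object of class `complexity_map`: `counts` (voxels x windows
#'   integer matrix) and `window_bounds_ms`.
#' @export
representational_complexity <- function(red, windows = complexity_windows()) {
  stopifnot(inherits(red, "redundancy_matrix"))
  tm <- red$time_ms
  if (min(windows) < min(tm) || max(windows) > max(tm))
    stop("windows [", min(windows), ", ", max(windows),
         "] ms fall outside the redundancy matrix time span [",
         min(tm), ", ", max(tm), "] ms")
  nw <- nrow(windows)
  V <- dim(red$red)[2]
  counts <- matrix(0L, V, nw)
  for (w in seq_len(nw)) {
    inw <- if (w == nw) tm >= windows[w, 1] & tm <= windows[w, 2]
           else tm >= windows[w, 1] & tm < windows[w, 2]
    if (!any(inw)) next
    sig <- red$significant[, , inw, drop = FALSE]
    counts[, w] <- colSums(apply(sig, c(1, 2), any))
  }
  structure(list(counts = counts, window_bounds_ms = windows,
                 contrast = red$contrast),
            class = "complexity_map")
}

#' Median complexity across observers
#'
#' Combines per-observer complexity maps on a shared voxel grid by the
#' elementwise median, the group summary used for reporting; single-observer
#' analyses simply use their own map.
#'
#' @param maps List of `complexity_map` objects with identical dimensions.
#' @return A `complexity_map` of medians.
#' @export
median_complexity <- function(maps) {
  stopifnot(length(maps) >= 1, all(vapply(maps, inherits, logical(1), "complexity_map")))
  arr <- simplify2array(lapply(maps, `[[`, "counts"))
  structure(list(counts = apply(arr, c(1, 2), stats::median),
                 window_bounds_ms = maps[[1]]$window_bounds_ms,
                 contrast = maps[[1]]$contrast),
            class = "complexity_map")
}

#' @export
print.complexity_map <- function(x, ...) {
  cat(sprintf("Representational complexity: %d voxels x %d windows; per-window totals: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(colSums(x$counts), collapse = ", ")))
  invisible(x)
}

#' Decision information in voxel activity
#'
#' Mixed continuous-discrete MI between each voxel's bivariate activity and
#' the three-class decision, per time point, with the maximum-statistic FWER
#' threshold from decision permutations.
#'
#' @param activity A `source_activity` with no constant activity channel.
#' @param decisions Decision labels.
#' @param n_perm,percentile Permutation settings (defaults 200 and 95).
#' @param seed Optional integer seed.
#' @param times_ms Optional subset of time points (ms).
#' @return Object of class `decision_mi_map`: `mi` (voxels x times, bits),
#'   `fwer_threshold`, `significant`, `time_ms`.
#' @export
decision_mi <- function(activity, decisions, n_perm = 200, percentile = 95,
                        seed = NULL, times_ms = NULL) {
  stopifnot(inherits(activity, "source_activity"))
  decisions <- droplevels(.as_decisions(decisions))
  if (nlevels(decisions) < 2) stop("need at least two decision classes")
  pa <- .prep_bivariate(activity, times_ms)
  n <- pa$n
  if (any(apply(pa$a1, 2, function(v) max(v) == min(v))))
    stop("constant activity across trials; decision MI is undefined")
  a1 <- .center_cols(.copnorm_cols(pa$a1))
  a2 <- .center_cols(.copnorm_cols(pa$a2))
  mi <- .mi_2d_labels(a1, a2, decisions, n)
  thr <- .with_seed(seed, {
    maxima <- vapply(seq_len(n_perm), function(i)
      max(.mi_2d_labels(a1, a2, decisions[sample.int(n)], n)), numeric(1))
    .pctl(maxima, percentile)
  })
  mi <- matrix(mi, pa$V, pa$Tn)
  structure(list(mi = mi, fwer_threshold = thr, significant = mi > thr,
                 time_ms = pa$time_ms, n_perm = n_perm, percentile = percentile),
            class = "decision_mi_map")
}

#' @export
print.decision_mi_map <- function(x, ...) {
  cat(sprintf("Decision MI map: %d voxels x %d times; threshold %.4g bits; %d significant\n",
              nrow(x$mi), ncol(x$mi), x$fwer_threshold, sum(x$significant)))
  invisible(x)
}
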