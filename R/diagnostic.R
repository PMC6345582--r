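## Diagnostic features of behavior: binarized pixel visibility, pixelwise
## plug-in MI maps against two-class decision contrasts, and permutation
## maximum-statistic FWER thresholds.

#' Binarize mask visibility values
#'
#' Converts real-valued per-pixel visibility into two bins: values strictly
#' greater than the threshold are "low to full visibility" (1), values less
#' than or equal to it (including the boundary value itself) are "no to low
#' visibility" (0).
#'
#' @param masks Numeric matrix of visibility values, trials in rows (e.g. the
#'   `masks` element of a trial set), values in `[0, 1]`.
#' @param threshold Visibility cut in `(0, 1)`, default 0.2.
#' @return 0/1 numeric matrix of the same shape, with attributes `threshold`
#'   and (if present on the input) `mask_dim`.
#' @export
binarize_visibility <- function(masks, threshold = 0.2) {
  if (threshold <= 0 || threshold >= 1)
    stop("visibility threshold must lie strictly inside (0, 1); got ", threshold)
  stopifnot(is.matrix(masks))
  bits <- (masks > threshold) * 1
  attr(bits, "threshold") <- threshold
  attr(bits, "mask_dim") <- attr(masks, "mask_dim")
  bits
}

.contrast_subset <- function(decisions, contrast = c("nuns", "voltaire")) {
  contrast <- match.arg(contrast)
  decisions <- .as_decisions(decisions)
  keep <- decisions %in% c(contrast, "dont_know")
  y <- as.integer(decisions[keep] == contrast)
  if (sum(y) == 0 || sum(y) == length(y))
    stop("contrast '", contrast, "' needs both '", contrast,
         "' and 'dont_know' trials")
  list(keep = which(keep), y = y, contrast = contrast)
}

#' Pixelwise diagnostic-feature map for one decision contrast
#'
#' Restricts the trials to the two classes of the contrast (the third decision
#' is excluded before any computation), computes the plug-in MI between each
#' pixel's binary visibility and the binary response, and determines the
#' family-wise error corrected threshold from the distribution of the maximum
#' MI across all pixels and bands under decision permutations.
#'
#' @param vis 0/1 visibility matrix from [binarize_visibility()] (trials in
#'   rows, pixels x bands in columns).
#' @param decisions Decision labels (see [decision_levels()]).
#' @param contrast `"nuns"` (nuns vs. don't know) or `"voltaire"`.
#' @param n_perm Number of permutations (reference analysis: 10000; smaller
#'   values are appropriate for simulation suites).
#' @param percentile Percentile of the max-MI null distribution used as
#'   threshold (reference: 99.9, i.e. FWER p < 0.001 one-tailed).
#' @param seed Optional integer seed for the permutations.
#' @return Object of class `diagnostic_map`: `mi` (per-pixel bits; shaped as a
#'   `size x size x bands` array when the input carries `mask_dim`),
#'   `fwer_threshold`, `significant`, `contrast`, `n_trials`, `n_perm`,
#'   `percentile`.
#' @export
diagnostic_map <- function(vis, decisions, contrast = c("nuns", "voltaire"),
                           n_perm = 10000, percentile = 99.9, seed = NULL) {
  sub <- .contrast_subset(decisions, contrast)
  V <- vis[sub$keep, , drop = FALSE]
  y <- sub$y
  n <- length(y)
  mi <- drop(.mi_binary_block(V, matrix(y, n, 1)))
  thr <- .with_seed(seed, {
    maxima <- numeric(n_perm)
    block <- 64L
    done <- 0L
    while (done < n_perm) {
      nb <- min(block, n_perm - done)
      Y <- vapply(seq_len(nb), function(i) sample(y), numeric(n))
      m <- .mi_binary_block(V, Y)
      maxima[done + seq_len(nb)] <- apply(m, 1, max)
      done <- done + nb
    }
    .pctl(maxima, percentile)
  })
  md <- attr(vis, "mask_dim")
  if (!is.null(md)) dim(mi) <- md
  structure(list(mi = mi, fwer_threshold = thr, significant = mi > thr,
                 contrast = sub$contrast, n_trials = n, n_perm = n_perm,
                 percentile = percentile),
            class = "diagnostic_map")
}

#' @export
print.diagnostic_map <- function(x, ...) {
  cat(sprintf("Diagnostic map (%s vs. don't know): %d trials, %d tests\n",
              x$contrast, x$n_trials, length(x$mi)))
  cat(sprintf("  FWER threshold %.4g bits (%g%% of %d permutation maxima); %d significant\n",
              x$fwer_threshold, x$percentile, x$n_perm, sum(x$significant)))
  invisible(x)
}

#' Permutation maximum-statistic FWER threshold
#'
#' Generic engine for the maximum-statistic procedure: for each permutation
#' the labels are shuffled across trials, the full statistic image is
#' recomputed, and its maximum recorded; the stated percentile of the maxima
#' is the family-wise corrected threshold. The reference analyses use
#' (10000 permutations, 99.9th percentile) for behavior maps and (200, 95th)
#' for the 3D representation and redundancy matrices.
#'
#' @param stat_fn Function taking a relabeled `labels` vector and returning a
#'   numeric array of statistics.
#' @param labels Label vector to permute (must contain at least two distinct
#'   values).
#' @param n_perm Number of permutations (>= 2).
#' @param percentile Percentile of the max distribution, in `(0, 100)`.
#' @param seed Optional integer seed.
#' @return The threshold (a single number).
#' @export
fwer_threshold <- function(stat_fn, labels, n_perm, percentile, seed = NULL) {
  if (n_perm < 2) stop("n_perm must be at least 2")
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  if (length(unique(labels)) < 2)
    stop("labels are degenerate (single class); nothing to permute")
  .with_seed(seed, {
    maxima <- vapply(seq_len(n_perm),
                     function(i) max(stat_fn(sample(labels))), numeric(1))
    .pctl(maxima, percentile)
  })
}
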