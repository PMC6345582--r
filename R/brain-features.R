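## Brain features: MI images over a reduced activity matrix, NMF feature
## basis, single-trial feature coefficients, the 3D representation matrix,
## diagnostic/nondiagnostic classification and the cross-observer k-means
## basis.

#' Reduce source activity to a component-by-time matrix
#'
#' PCA reduction of the amplitude channel: voxel loadings are estimated from
#' the trial-by-voxel matrices stacked over the selected time points, and each
#' time point is projected onto the leading components. A linear reduction of
#' this kind (the reference analysis used 60 ICA sources) makes the pixelwise
#' MI-image computation tractable; any caller-supplied reduction with the same
#' shape is accepted by [reduced_mi_images()].
#'
#' @param activity A `source_activity` object.
#' @param n_components Number of components to keep (default 60).
#' @param times_ms Time points (ms) at which to evaluate the reduced matrix;
#'   defaults to every 8 ms over the activity's span.
#' @return Object of class `reduced_activity`: `scores` (trials x components x
#'   times array), `rotation`, `times_ms`, `var_explained`.
#' @export
reduce_activity <- function(activity, n_components = 60, times_ms = NULL) {
  stopifnot(inherits(activity, "source_activity"))
  tm <- activity$time_ms
  if (is.null(times_ms)) times_ms <- seq(min(tm), max(tm), by = 8)
  tidx <- vapply(times_ms, function(t) which.min(abs(tm - t)), integer(1))
  a <- activity$amplitude
  n <- dim(a)[1]; V <- dim(a)[2]
  n_components <- min(n_components, V)
  z <- matrix(aperm(a[, , tidx, drop = FALSE], c(1, 3, 2)),
              n * length(tidx), V)
  z <- .center_cols(z)
  eg <- eigen(crossprod(z) / (nrow(z) - 1), symmetric = TRUE)
  rot <- eg$vectors[, seq_len(n_components), drop = FALSE]
  scores <- array(0, c(n, n_components, length(tidx)))
  for (i in seq_along(tidx))
    scores[, , i] <- .center_cols(a[, , tidx[i]]) %*% rot
  structure(list(scores = scores, rotation = rot, times_ms = tm[tidx],
                 var_explained = cumsum(eg$values) / sum(eg$values)),
            class = "reduced_activity")
}

#' Pixelwise MI images over a reduced activity matrix
#'
#' For every (component, time) cell of the reduced activity, computes the
#' Gaussian-copula MI between each pixel's visibility across trials and that
#' cell's activity, producing one vectorized MI image per cell. Estimates are
#' bias-corrected and clamped at zero (the image stack feeds a nonnegative
#' factorization).
#'
#' @param masks Trial-by-pixel visibility matrix (pixels stacked over bands).
#' @param reduced A `reduced_activity` object, or a trials x components x
#'   times array.
#' @return Object of class `mi_image_stack`: `images` (cells x pixels
#'   nonnegative matrix), `cell_index` (data frame: component, time index),
#'   `n_trials`.
#' @export
reduced_mi_images <- function(masks, reduced) {
  scores <- if (inherits(reduced, "reduced_activity")) reduced$scores else reduced
  stopifnot(is.matrix(masks), length(dim(scores)) == 3)
  n <- nrow(masks)
  if (dim(scores)[1] != n)
    stop("masks (", n, " trials) and reduced activity (", dim(scores)[1],
         ") disagree on trial count")
  k <- dim(scores)[2]; Tn <- dim(scores)[3]
  Vn <- .copnorm_cols(masks)
  sdv <- sqrt(colSums(.center_cols(Vn)^2) / (n - 1))
  Vs <- sweep(.center_cols(Vn), 2, pmax(sdv, .Machine$double.eps), "/")
  Vs[, sdv == 0] <- 0
  A <- .copnorm_cols(matrix(scores, n, k * Tn))
  sda <- sqrt(colSums(.center_cols(A)^2) / (n - 1))
  As <- sweep(.center_cols(A), 2, pmax(sda, .Machine$double.eps), "/")
  As[, sda == 0] <- 0
  R <- crossprod(As, Vs) / (n - 1)          # cells x pixels
  mi <- pmax(.mi_cc_1d(R, n), 0)
  dim(mi) <- dim(R)
  cell_index <- data.frame(component = rep(seq_len(k), Tn),
                           time = rep(seq_len(Tn), each = k))
  structure(list(images = mi, cell_index = cell_index, n_trials = n,
                 mask_dim = attr(masks, "mask_dim")),
            class = "mi_image_stack")
}

#' @export
print.mi_image_stack <- function(x, ...) {
  cat("MI image stack:", nrow(x$images), "cells x", ncol(x$images),
      "pixels (", x$n_trials, "trials )\n")
  invisible(x)
}

#' Brain-feature basis by nonnegative matrix factorization
#'
#' Factorizes the MI image stack, then post-processes each component image by
#' zeroing pixels below 15% of that component's maximum and normalizing to
#' unit L2 norm. With `k = "auto"` the rank is chosen by an elbow rule:
#' the smallest k whose reconstruction-error improvement from one additional
#' component falls below 1%, capped at `kmax`.
#'
#' @param stack An `mi_image_stack` (or nonnegative cells x pixels matrix).
#' @param k Number of features, or `"auto"`.
#' @param kmax Cap for automatic selection (reference analyses found 21-25
#'   components per observer; default 25).
#' @param seed Integer seed for the NMF initialization.
#' @param maxit,tol,n_restarts Passed to [nmf_fit()] for the final fit.
#' @param select_maxit Update sweeps used during rank selection.
#' @param threshold_frac Fraction of each feature's maximum below which pixel
#'   weights are set to zero (default 0.15).
#' @return Object of class `brain_feature_basis`: `features` (k x pixels,
#'   rows unit L2 norm after thresholding), `k`, `labels` (all `unclassified`
#'   until [classify_features()]), `recon_error`, `mask_dim`.
#' @export
nmf_basis <- function(stack, k = "auto", kmax = 25, seed = 1, maxit = 200,
                      tol = 1e-4, n_restarts = 3, select_maxit = 60,
                      threshold_frac = 0.15) {
  x <- if (inherits(stack, "mi_image_stack")) stack$images else stack
  stopifnot(is.matrix(x))
  if (identical(k, "auto")) {
    kmax <- min(kmax, dim(x) - 1)
    k <- .nmf_select_k(x, kmax = kmax, seed = seed, maxit = select_maxit)
  }
  fit <- nmf_fit(x, k, seed = seed, maxit = maxit, tol = tol,
                 n_restarts = n_restarts)
  feats <- fit$h
  for (i in seq_len(k)) {
    row <- feats[i, ]
    row[row < threshold_frac * max(row)] <- 0
    nrm <- sqrt(sum(row^2))
    feats[i, ] <- if (nrm > 0) row / nrm else row
  }
  structure(list(features = feats, k = k,
                 labels = factor(rep("unclassified", k),
                                 levels = c("diagnostic_nuns", "diagnostic_voltaire",
                                            "nondiagnostic", "unclassified")),
                 recon_error = fit$error, iterations = fit$iterations,
                 threshold_frac = threshold_frac,
                 mask_dim = if (inherits(stack, "mi_image_stack")) stack$mask_dim else NULL),
            class = "brain_feature_basis")
}

#' @export
print.brain_feature_basis <- function(x, ...) {
  cat("Brain feature basis:", x$k, "features x", ncol(x$features), "pixels\n")
  cat("  labels:", paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Single-trial brain-feature coefficients
#'
#' Spatially filters each trial's bubble masks with each brain feature (dot
#' product over all pixels and bands), giving one visibility scalar per trial
#' and feature.
#'
#' @param masks Trial-by-pixel mask matrix.
#' @param basis A `brain_feature_basis`, or a k x pixels matrix.
#' @return Numeric matrix, trials x features.
#' @export
feature_coefficients <- function(masks, basis) {
  feats <- if (inherits(basis, "brain_feature_basis")) basis$features else basis
  stopifnot(is.matrix(masks), is.matrix(feats))
  if (ncol(masks) != ncol(feats))
    stop("masks have ", ncol(masks), " pixels but features have ", ncol(feats))
  masks %*% t(feats)
}

#' Dynamic representation matrix (feature x voxel x time)
#'
#' For every brain feature, voxel and time point, computes the
#' Gaussian-copula MI between the feature's single-trial coefficient and the
#' bivariate voxel activity (amplitude, temporal gradient). Significance is
#' family-wise corrected by the maximum statistic: for each permutation the
#' coefficients are shuffled across trials and the maximum MI over the whole
#' 3D matrix recorded; the threshold is the stated percentile of these maxima
#' (reference: 200 permutations, 95th percentile).
#'
#' @param coefs Trials x features coefficient matrix.
#' @param activity A `source_activity` object.
#' @param n_perm Number of permutations (default 200).
#' @param percentile Max-distribution percentile (default 95).
#' @param seed Optional integer seed.
#' @param times_ms Optional subset of time points (ms) to analyze.
#' @return Object of class `representation_matrix`: `mi` (features x voxels x
#'   times, bits), `fwer_threshold`, `significant`, `time_ms`, `n_perm`,
#'   `percentile`.
#' @export
representation_matrix <- function(coefs, activity, n_perm = 200, percentile = 95,
                                  seed = NULL, times_ms = NULL) {
  stopifnot(inherits(activity, "source_activity"), is.matrix(coefs))
  n <- nrow(coefs)
  if (dim(activity$amplitude)[1] != n)
    stop("coefficients and activity disagree on trial count")
  tm <- activity$time_ms
  tidx <- if (is.null(times_ms)) seq_along(tm) else
    vapply(times_ms, function(t) which.min(abs(tm - t)), integer(1))
  V <- dim(activity$amplitude)[2]; Tn <- length(tidx)
  k <- ncol(coefs)

  Xc <- .center_cols(.copnorm_cols(coefs))
  a1 <- .center_cols(.copnorm_cols(matrix(activity$amplitude[, , tidx], n, V * Tn)))
  a2 <- .center_cols(.copnorm_cols(matrix(activity$gradient[, , tidx], n, V * Tn)))
  ys <- .y2_stats(a1, a2, n)
  mi <- .mi_1x2_block(Xc, a1, a2, ys, n)
  thr <- .with_seed(seed, {
    maxima <- vapply(seq_len(n_perm), function(i) {
      Xp <- Xc[sample.int(n), , drop = FALSE]
      max(.mi_1x2_block(Xp, a1, a2, ys, n))
    }, numeric(1))
    .pctl(maxima, percentile)
  })
  mi <- array(mi, c(k, V, Tn))
  structure(list(mi = mi, fwer_threshold = thr, significant = mi > thr,
                 time_ms = tm[tidx], n_perm = n_perm, percentile = percentile,
                 feature_names = colnames(coefs)),
            class = "representation_matrix")
}

#' @export
print.representation_matrix <- function(x, ...) {
  d <- dim(x$mi)
  cat(sprintf("Representation matrix: %d features x %d voxels x %d time points\n",
              d[1], d[2], d[3]))
  cat(sprintf("  FWER threshold %.4g bits (%g%% of %d permutation maxima); %d significant cells\n",
              x$fwer_threshold, x$percentile, x$n_perm, sum(x$significant)))
  invisible(x)
}

#' Classify brain features as diagnostic or nondiagnostic
#'
#' Three MI values are computed per feature: MI(coefficient; nuns vs. don't
#' know) on that contrast's trials, MI(coefficient; voltaire vs. don't know),
#' and MI(coefficient; all three decisions). A feature is diagnostic of a
#' percept when its contrast MI strictly exceeds the 75th percentile of that
#' MI's distribution across features, and nondiagnostic when its three-class
#' MI falls strictly below the 25th percentile. Features at a percentile
#' boundary (ties) remain unclassified; a feature satisfying both diagnostic
#' rules takes the percept with the larger MI; a feature satisfying a
#' diagnostic and the nondiagnostic rule is labeled diagnostic with a warning.
#'
#' @param coefs Trials x features coefficient matrix (at least 4 features).
#' @param decisions Decision labels with all three classes present.
#' @param q_diagnostic,q_nondiagnostic Percentiles for the two rules
#'   (defaults 75 and 25).
#' @return Factor of per-feature labels with levels `diagnostic_nuns`,
#'   `diagnostic_voltaire`, `nondiagnostic`, `unclassified`; the MI table is
#'   attached as attribute `mi`.
#' @export
classify_features <- function(coefs, decisions, q_diagnostic = 75,
                              q_nondiagnostic = 25) {
  stopifnot(is.matrix(coefs))
  k <- ncol(coefs)
  if (k < 4) stop("percentile classification needs at least 4 features; got ", k)
  decisions <- .as_decisions(decisions)
  if (nlevels(droplevels(decisions)) < 3)
    stop("all three decision classes must be present")
  sub_n <- .contrast_subset(decisions, "nuns")
  sub_v <- .contrast_subset(decisions, "voltaire")
  mi_one <- function(x, y) as.numeric(mi_gcd(x, factor(y)))
  mi_n <- vapply(seq_len(k), function(f) mi_one(coefs[sub_n$keep, f], sub_n$y), numeric(1))
  mi_v <- vapply(seq_len(k), function(f) mi_one(coefs[sub_v$keep, f], sub_v$y), numeric(1))
  mi_3 <- vapply(seq_len(k), function(f) mi_one(coefs[, f], decisions), numeric(1))
  thr_n <- .pctl(mi_n, q_diagnostic)
  thr_v <- .pctl(mi_v, q_diagnostic)
  thr_0 <- .pctl(mi_3, q_nondiagnostic)
  labels <- character(k)
  for (f in seq_len(k)) {
    dn <- mi_n[f] > thr_n
    dv <- mi_v[f] > thr_v
    nd <- mi_3[f] < thr_0
    lab <- if (dn && dv) {
      if (mi_n[f] >= mi_v[f]) "diagnostic_nuns" else "diagnostic_voltaire"
    } else if (dn) "diagnostic_nuns" else if (dv) "diagnostic_voltaire"
    else if (nd) "nondiagnostic" else "unclassified"
    if ((dn || dv) && nd) {
      warning("feature ", f, " satisfies both diagnostic and nondiagnostic rules; ",
              "diagnostic takes precedence")
    }
    labels[f] <- lab
  }
  structure(factor(labels, levels = c("diagnostic_nuns", "diagnostic_voltaire",
                                      "nondiagnostic", "unclassified")),
            mi = data.frame(mi_nuns = mi_n, mi_voltaire = mi_v, mi_three_class = mi_3))
}

#' Cosine k-means over pooled brain features
#'
#' Spherical k-means on L2-normalized feature rows: assignment by maximum
#' cosine similarity, centroids renormalized after each update, best of
#' `n_restarts` random initializations by total within-cluster cosine
#' dissimilarity. Used to index per-observer features onto a common basis.
#'
#' @param x Features x pixels matrix (rows with nonzero norm).
#' @param k Number of clusters (default 25).
#' @param n_restarts Random restarts (reference: 1000).
#' @param max_iter Maximum assignment/update sweeps per restart.
#' @param seed Optional integer seed.
#' @return List with `cluster`, `centroids` (k x pixels, unit rows),
#'   `objective` (total 1 - cosine), `n_restarts`.
#' @export
kmeans_cosine <- function(x, k = 25, n_restarts = 1000, max_iter = 100, seed = NULL) {
  stopifnot(is.matrix(x))
  m <- nrow(x)
  if (k > m) stop("k = ", k, " exceeds the number of rows (", m, ")")
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("rows with zero norm cannot be assigned a direction")
  xn <- x / nrm
  .with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      C <- xn[sample.int(m, k), , drop = FALSE]
      assign_old <- integer(m)
      for (it in seq_len(max_iter)) {
        sim <- xn %*% t(C)
        assign <- max.col(sim, ties.method = "first")
        for (j in which(tabulate(assign, k) == 0)) {
          far <- which.min(sim[cbind(seq_len(m), assign)])
          assign[far] <- j
          sim[far, ] <- -Inf; sim[far, j] <- Inf
        }
        if (identical(assign, assign_old)) break
        assign_old <- assign
        C <- rowsum(xn, assign)[as.character(seq_len(k)), , drop = FALSE]
        cn <- sqrt(rowSums(C^2))
        C <- C / pmax(cn, .Machine$double.eps)
      }
      obj <- sum(1 - (xn %*% t(C))[cbind(seq_len(m), assign)])
      if (is.null(best) || obj < best$objective)
        best <- list(cluster = assign, centroids = C, objective = obj,
                     n_restarts = n_restarts)
    }
    best
  })
}
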