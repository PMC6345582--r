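## Estimation core: Gaussian-copula mutual information (continuous-continuous
## and mixed continuous-discrete) and co-information (redundancy).
##
## Conventions: MI is reported in bits by default. The analytic small-sample
## bias correction for Gaussian entropies (digamma terms) is applied by
## default; raw estimates can then be slightly negative near independence and
## are stored as-is.

.LN2 <- log(2)

#' Rank-gaussianize (copula-normalize) data columns
#'
#' Replaces each column by standard-normal quantiles of its empirical ranks,
#' `qnorm((rank - 0.5)/n)`, with ties broken by average rank. The result is
#' invariant under strictly monotone transforms of any column.
#'
#' @param x Numeric vector or matrix (observations in rows), `n >= 8`, no
#'   missing values, no constant column.
#' @return Matrix of the same shape with standard-normal marginal scores.
#' @export
copula_normalize <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 8) stop("copula normalization needs at least 8 observations; got ", n)
  if (anyNA(x)) stop("input contains missing values")
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (max(v) == min(v))
      stop("column ", if (!is.null(colnames(x))) colnames(x)[j] else j,
           " is constant; copula normalization is undefined")
    out[, j] <- stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
  }
  out
}

## ---- internal Gaussian-entropy machinery -----------------------------------

## Bias-corrected differential entropy (nats, additive constants included) of a
## d-variate Gaussian with sample covariance C estimated from n observations.
.h_gauss <- function(C, n, bias_correct = TRUE) {
  C <- as.matrix(C)
  d <- nrow(C)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch))
    stop("singular covariance (condition number ", format(kappa(C), digits = 3),
         "); variables are linearly dependent")
  h <- sum(log(diag(ch))) + 0.5 * d * log(2 * pi * exp(1))
  if (bias_correct) {
    dterm <- (.LN2 - log(n - 1)) / 2
    h <- h - d * dterm - sum(digamma((n - seq_len(d)) / 2)) / 2
  }
  h
}

.cov_of <- function(x) {
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x))
  crossprod(xc) / (nrow(x) - 1)
}

## ---- continuous-continuous -------------------------------------------------

#' Gaussian-copula mutual information between two continuous variables
#'
#' Copula-normalizes both inputs (optional) and computes the Gaussian MI from
#' the joint covariance, `0.5 * log2(det(Cx) det(Cy) / det(Cxy))`, with the
#' analytic small-sample bias correction.
#'
#' @param x,y Numeric vectors or matrices (trials in rows).
#' @param normalize Apply [copula_normalize()] internally (default `TRUE`).
#' @param bias_correct Apply the digamma small-sample correction (default
#'   `TRUE`).
#' @param units `"bits"` (default) or `"nats"`.
#' @return A number (MI) with attributes `n` and `estimator = "gcmi_cc"`.
#' @export
mi_gcc <- function(x, y, normalize = TRUE, bias_correct = TRUE,
                   units = c("bits", "nats")) {
  units <- match.arg(units)
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of trials")
  n <- nrow(x)
  if (normalize) { x <- copula_normalize(x); y <- copula_normalize(y) }
  hx <- .h_gauss(.cov_of(x), n, bias_correct)
  hy <- .h_gauss(.cov_of(y), n, bias_correct)
  hxy <- .h_gauss(.cov_of(cbind(x, y)), n, bias_correct)
  mi <- hx + hy - hxy
  if (units == "bits") mi <- mi / .LN2
  structure(mi, n = n, estimator = "gcmi_cc")
}

## ---- mixed continuous-discrete ---------------------------------------------

#' Gaussian-copula mutual information between a continuous variable and labels
#'
#' Mixed estimator: marginal Gaussian entropy of the copula-normalized
#' continuous variable minus the class-weighted conditional entropies, each
#' bias-corrected with its own class size.
#'
#' @param x Numeric vector or matrix (trials in rows).
#' @param y Class labels (factor or coercible); at least two classes, each with
#'   at least `ncol(x) + 2` trials.
#' @inheritParams mi_gcc
#' @return A number with attributes `n` and `estimator = "gcmi_cd"`.
#' @export
mi_gcd <- function(x, y, normalize = TRUE, bias_correct = TRUE,
                   units = c("bits", "nats")) {
  units <- match.arg(units)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) != length(y)) stop("x and y must have the same number of trials")
  if (nlevels(y) < 2) stop("need at least 2 classes")
  n <- nrow(x); d <- ncol(x)
  cnt <- table(y)
  small <- names(cnt)[cnt < d + 2]
  if (length(small))
    stop("class '", small[1], "' has only ", cnt[small[1]],
         " trials; need at least ", d + 2)
  if (normalize) x <- copula_normalize(x)
  h <- .h_gauss(.cov_of(x), n, bias_correct)
  hc <- 0
  for (lv in levels(y)) {
    idx <- which(y == lv)
    hc <- hc + length(idx) / n * .h_gauss(.cov_of(x[idx, , drop = FALSE]),
                                          length(idx), bias_correct)
  }
  mi <- h - hc
  if (units == "bits") mi <- mi / .LN2
  structure(mi, n = n, estimator = "gcmi_cd")
}

#' Plug-in mutual information between two discrete variables
#'
#' Histogram (maximum-likelihood) MI on the contingency table. Zero-entropy
#' (constant) variables give MI 0 by convention.
#'
#' @param x,y Discrete vectors (factors or coercible) of equal length.
#' @param units `"bits"` (default) or `"nats"`.
#' @return A number with attributes `n` and `estimator = "plugin_dd"`.
#' @export
mi_discrete <- function(x, y, units = c("bits", "nats")) {
  units <- match.arg(units)
  if (length(x) != length(y)) stop("x and y must have the same number of trials")
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / e[nz]))
  if (units == "bits") mi <- mi / .LN2
  structure(mi, n = length(x), estimator = "plugin_dd")
}

## Conditional Gaussian-copula MI of x and y within classes of d:
## sum_c p(c) MI(x; y | d = c), inputs already copula-normalized globally.
.mi_gcc_cond <- function(x, y, d, bias_correct = TRUE) {
  n <- nrow(x)
  mi <- 0
  for (lv in levels(d)) {
    idx <- which(d == lv)
    nc <- length(idx)
    hx <- .h_gauss(.cov_of(x[idx, , drop = FALSE]), nc, bias_correct)
    hy <- .h_gauss(.cov_of(y[idx, , drop = FALSE]), nc, bias_correct)
    hxy <- .h_gauss(.cov_of(cbind(x[idx, , drop = FALSE], y[idx, , drop = FALSE])),
                    nc, bias_correct)
    mi <- mi + nc / n * (hx + hy - hxy)
  }
  mi
}

## ---- co-information / redundancy -------------------------------------------

#' Co-information redundancy among feature, activity, and decision
#'
#' Evaluates `RED = MI(F; D) + MI(F; M) - MI(F; M, D)` where F is a continuous
#' feature coefficient, M the (possibly bivariate) voxel activity, and D the
#' categorical decision. Positive values indicate information about the
#' feature shared between activity and behavior; negative values indicate
#' synergy. The joint term is computed by the chain rule,
#' `MI(F; M, D) = MI(F; D) + MI(F; M | D)`, with the conditional term as a
#' class-weighted Gaussian-copula MI. With `estimator = "plugin"` all three
#' variables must be discrete and plug-in contingency estimators are used.
#'
#' @param feature Numeric vector (continuous) or discrete vector (plugin).
#' @param activity Numeric matrix `n x d` (continuous) or discrete vector.
#' @param decision Class labels, aligned by trial.
#' @param estimator `"gcmi"` (default) or `"plugin"`.
#' @param bias_correct Digamma correction for the Gaussian terms.
#' @param units `"bits"` (default) or `"nats"`.
#' @return Object of class `sir_redundancy`: list with `value` and
#'   `components` (named `mi_fd`, `mi_fm`, `mi_fmd`); the value equals
#'   `mi_fd + mi_fm - mi_fmd` exactly.
#' @export
redundancy <- function(feature, activity, decision,
                       estimator = c("gcmi", "plugin"),
                       bias_correct = TRUE, units = c("bits", "nats")) {
  estimator <- match.arg(estimator)
  units <- match.arg(units)
  d <- droplevels(as.factor(decision))
  if (estimator == "plugin") {
    mi_fd <- as.numeric(mi_discrete(feature, d, units = units))
    mi_fm <- as.numeric(mi_discrete(feature, activity, units = units))
    joint <- interaction(as.factor(activity), d, drop = TRUE)
    mi_fmd <- as.numeric(mi_discrete(feature, joint, units = units))
  } else {
    x <- copula_normalize(as.matrix(feature))
    y <- copula_normalize(as.matrix(activity))
    if (nrow(x) != length(d)) stop("feature, activity and decision must be aligned by trial")
    mi_fd <- as.numeric(mi_gcd(x, d, normalize = FALSE, bias_correct = bias_correct,
                               units = units))
    mi_fm <- as.numeric(mi_gcc(x, y, normalize = FALSE, bias_correct = bias_correct,
                               units = units))
    cond <- .mi_gcc_cond(x, y, d, bias_correct)
    if (units == "bits") cond <- cond / .LN2
    mi_fmd <- mi_fd + cond
  }
  structure(list(value = mi_fd + mi_fm - mi_fmd,
                 components = c(mi_fd = mi_fd, mi_fm = mi_fm, mi_fmd = mi_fmd),
                 estimator = estimator, n = length(d)),
            class = "sir_redundancy")
}

#' @export
print.sir_redundancy <- function(x, ...) {
  cat(sprintf("Co-information redundancy: %.4f bits (%s, n = %d)\n",
              x$value, x$estimator, x$n))
  cat(sprintf("  MI(F;D) = %.4f  MI(F;M) = %.4f  MI(F;M,D) = %.4f\n",
              x$components["mi_fd"], x$components["mi_fm"], x$components["mi_fmd"]))
  invisible(x)
}
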