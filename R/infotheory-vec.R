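## Vectorized Gaussian-copula MI kernels shared by the pipeline stages.
## These operate on pre-normalized matrices and compute whole images / 3D
## matrices of MI values with a handful of BLAS calls so that the permutation
## max-statistic loops stay tractable.

## Copula-normalize every column of a matrix; zero-variance columns map to an
## all-zero score column (downstream MI is then 0 by convention).
.copnorm_cols <- function(x) {
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  q <- stats::qnorm((seq_len(n) - 0.5) / n)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (max(v) > min(v)) out[, j] <- stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
  }
  out
}

.center_cols <- function(x) sweep(x, 2, colMeans(x))

## Additive bias correction (nats) for Gaussian MI between a dx- and a
## dy-dimensional variable from n samples: MI_corrected = MI_raw + shift.
.mi_bias_shift <- function(dx, dy, n) {
  i_joint <- (dy + 1):(dx + dy)
  (sum(digamma((n - i_joint) / 2)) - sum(digamma((n - seq_len(dx)) / 2))) / 2
}

## MI (bits) from a vector/matrix of correlations between 1D variables.
.mi_cc_1d <- function(r, n, bias_correct = TRUE) {
  r2 <- pmin(r * r, 1 - 1e-12)
  mi <- -0.5 * log(1 - r2)
  if (bias_correct) mi <- mi + .mi_bias_shift(1, 1, n)
  mi / .LN2
}

## Second-moment summaries of a bivariate activity block.
## a1, a2: centered n x m matrices (one column per (voxel, time) cell).
.y2_stats <- function(a1, a2, n) {
  s11 <- colSums(a1 * a1) / (n - 1)
  s22 <- colSums(a2 * a2) / (n - 1)
  s12 <- colSums(a1 * a2) / (n - 1)
  detY <- pmax(s11 * s22 - s12 * s12, .Machine$double.eps)
  list(s11 = s11, s22 = s22, s12 = s12, detY = detY)
}

## MI (bits) between each column of Xc (centered, n x k) and each bivariate
## cell of (a1, a2) (centered, n x m). Returns a k x m matrix.
.mi_1x2_block <- function(Xc, a1, a2, ys, n, bias_correct = TRUE) {
  k <- ncol(Xc)
  vx <- colSums(Xc * Xc) / (n - 1)
  r1 <- crossprod(Xc, a1) / (n - 1)
  r2 <- crossprod(Xc, a2) / (n - 1)
  ## det of the 3x3 joint covariance, expanded along the x row
  det3 <- vx * rep(ys$detY, each = k) -
    r1 * r1 * rep(ys$s22, each = k) -
    r2 * r2 * rep(ys$s11, each = k) +
    2 * r1 * r2 * rep(ys$s12, each = k)
  det3 <- pmax(det3, .Machine$double.eps)
  mi <- 0.5 * log(vx * rep(ys$detY, each = k) / det3)
  if (bias_correct) mi <- mi + .mi_bias_shift(1, 2, n)
  mi <- mi / .LN2
  dim(mi) <- c(k, ncol(a1))
  ## zero-variance cells carry no information by convention
  mi[, ys$detY <= 2 * .Machine$double.eps] <- 0
  mi
}

## Class-conditional version: sum_c p(c) MI(x; y | class c), bits.
## cls: factor over trials. Xc, a1, a2 centered overall.
.mi_1x2_cond <- function(Xc, a1, a2, cls, n, bias_correct = TRUE) {
  k <- ncol(Xc); m <- ncol(a1)
  acc <- matrix(0, k, m)
  for (lv in levels(cls)) {
    idx <- which(cls == lv)
    nc <- length(idx)
    xs <- .center_cols(Xc[idx, , drop = FALSE])
    b1 <- .center_cols(a1[idx, , drop = FALSE])
    b2 <- .center_cols(a2[idx, , drop = FALSE])
    ys <- .y2_stats(b1, b2, nc)
    acc <- acc + nc / n * .mi_1x2_block(xs, b1, b2, ys, nc, bias_correct)
  }
  acc
}

## MI (bits) between each bivariate cell of (a1, a2) and the class labels:
## H(y) - sum_c p(c) H(y | c), every entropy bias-corrected at its own n.
.mi_2d_labels <- function(a1, a2, cls, n, bias_correct = TRUE) {
  h_bias <- function(nn) {
    if (!bias_correct) return(0)
    2 * (.LN2 - log(nn - 1)) / 2 + (digamma((nn - 1) / 2) + digamma((nn - 2) / 2)) / 2
  }
  ys <- .y2_stats(a1, a2, n)
  h <- 0.5 * log(ys$detY) - h_bias(n)
  hc <- 0
  for (lv in levels(cls)) {
    idx <- which(cls == lv)
    nc <- length(idx)
    b1 <- .center_cols(a1[idx, , drop = FALSE])
    b2 <- .center_cols(a2[idx, , drop = FALSE])
    ysc <- .y2_stats(b1, b2, nc)
    hc <- hc + nc / n * (0.5 * log(ysc$detY) - h_bias(nc))
  }
  mi <- (h - hc) / .LN2
  mi[ys$detY <= 2 * .Machine$double.eps] <- 0
  mi
}

## Plug-in MI (bits) between many binary columns and binary labels, for one or
## several relabelings at once. V: n x p in {0,1}; Y: n x q in {0,1}.
## Returns a q x p matrix of MI values.
.mi_binary_block <- function(V, Y) {
  n <- nrow(V)
  n11 <- crossprod(Y, V)                     # q x p
  nv1 <- colSums(V)                          # p
  ny1 <- colSums(Y)                          # q
  p11 <- n11 / n
  p10 <- (rep(ny1, ncol(V)) - n11) / n       # y = 1, v = 0 (recycled col-wise)
  dim(p10) <- dim(p11)
  p01 <- rep(nv1, each = nrow(n11)) / n - p11
  p00 <- 1 - p11 - p10 - p01
  py1 <- ny1 / n
  pv1 <- nv1 / n
  term <- function(p, a, b) {
    out <- p * log(p / (a * b))
    out[p <= 0] <- 0
    out
  }
  ey1 <- matrix(py1, nrow(p11), ncol(p11))
  ev1 <- matrix(pv1, nrow(p11), ncol(p11), byrow = TRUE)
  mi <- term(p11, ey1, ev1) + term(p10, ey1, 1 - ev1) +
    term(p01, 1 - ey1, ev1) + term(p00, 1 - ey1, 1 - ev1)
  mi / .LN2
}
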