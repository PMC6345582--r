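## Non-negative matrix factorization by Lee-Seung multiplicative updates
## (Frobenius objective). The update is monotone in the reconstruction error,
## which the test suite verifies; random restarts guard against the local
## minima the multiplicative update can settle into.

## NNDSVD initialization (nonnegative double SVD): each component is seeded
## from the dominant nonnegative part of a leading singular pair, so the
## multiplicative updates start from distinct principal parts instead of a
## random mixture. Zeros are filled with a small positive constant so the
## updates can still move them.
.nndsvd_init <- function(x, k) {
  m <- nrow(x); p <- ncol(x)
  ## leading singular pairs via the smaller Gram matrix (much faster than a
  ## full SVD on wide matrices)
  if (m <= p) {
    eg <- eigen(tcrossprod(x), symmetric = TRUE)
    d <- sqrt(pmax(eg$values[seq_len(k)], 0))
    u <- eg$vectors[, seq_len(k), drop = FALSE]
    v <- crossprod(x, u) %*% diag(1 / pmax(d, .Machine$double.eps), k)
  } else {
    eg <- eigen(crossprod(x), symmetric = TRUE)
    d <- sqrt(pmax(eg$values[seq_len(k)], 0))
    v <- eg$vectors[, seq_len(k), drop = FALSE]
    u <- x %*% v %*% diag(1 / pmax(d, .Machine$double.eps), k)
  }
  sv <- list(d = d, u = u, v = v)
  w <- matrix(0, m, k); h <- matrix(0, k, p)
  w[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  h[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (j in seq_len(k)[-1]) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg) {
      s <- sqrt(sv$d[j] * npos)
      w[, j] <- s * up / max(sqrt(sum(up^2)), .Machine$double.eps)
      h[j, ] <- s * vp / max(sqrt(sum(vp^2)), .Machine$double.eps)
    } else {
      s <- sqrt(sv$d[j] * nneg)
      w[, j] <- s * un / max(sqrt(sum(un^2)), .Machine$double.eps)
      h[j, ] <- s * vn / max(sqrt(sum(vn^2)), .Machine$double.eps)
    }
  }
  fill <- mean(x) / 100
  w[w == 0] <- fill; h[h == 0] <- fill
  list(w = w, h = h)
}

#' Non-negative matrix factorization
#'
#' Factorizes a nonnegative matrix `X (m x p)` as `W (m x k) %*% H (k x p)`
#' by multiplicative updates. The first start is the deterministic NNDSVD
#' initialization (components seeded on distinct principal parts, which
#' avoids the merged-component local minima random starts are prone to);
#' additional restarts use uniform random initializations under the seed,
#' and the best factorization by reconstruction error is kept.
#'
#' @param x Nonnegative numeric matrix.
#' @param k Rank of the factorization.
#' @param seed Integer seed for the random restarts (restart r uses
#'   `seed + r - 1`).
#' @param maxit Maximum number of update sweeps per start.
#' @param tol Relative reconstruction-error change (checked every 5 sweeps)
#'   below which iteration stops.
#' @param n_restarts Total number of starts (default 1: NNDSVD only).
#' @param init `"nndsvd"` (default) or `"random"` for the first start.
#' @param track_error Record the error after every sweep (slower; used by the
#'   monotonicity tests).
#' @return List with `w`, `h`, `error` (final Frobenius norm of the
#'   residual), `error_path`, `iterations`.
#' @export
nmf_fit <- function(x, k, seed = 1, maxit = 200, tol = 1e-4, n_restarts = 1,
                    init = c("nndsvd", "random"), track_error = FALSE) {
  init <- match.arg(init)
  stopifnot(is.matrix(x))
  if (k <= 0) stop("k must be a positive integer")
  if (any(x < 0)) stop("input matrix must be nonnegative")
  if (max(x) == 0) stop("input matrix is identically zero")
  m <- nrow(x); p <- ncol(x)
  if (k > min(m, p)) stop("k = ", k, " exceeds min(dim(x)) = ", min(m, p))
  eps <- .Machine$double.eps
  iterate <- function(w, h) {
    err <- function() sqrt(sum((x - w %*% h)^2))
    path <- numeric(0)
    last <- Inf
    it <- 0L
    for (it in seq_len(maxit)) {
      h <- h * crossprod(w, x) / (crossprod(w) %*% h + eps)
      w <- w * (x %*% t(h)) / (w %*% tcrossprod(h) + eps)
      if (track_error) path <- c(path, err())
      if (it %% 5 == 0) {
        e <- if (track_error) path[length(path)] else err()
        if (is.finite(last) && (last - e) / max(last, eps) < tol) { last <- e; break }
        last <- e
      }
    }
    e_final <- err()
    list(w = w, h = h, error = e_final,
         error_path = if (track_error) path else e_final, iterations = it)
  }
  rand_init <- function(s) .with_seed(s, {
    sc <- sqrt(mean(x) / k)
    list(w = matrix(stats::runif(m * k, 0.1, 1) * sc, m, k),
         h = matrix(stats::runif(k * p, 0.1, 1) * sc, k, p))
  })
  best <- NULL
  for (r in seq_len(n_restarts)) {
    st <- if (r == 1L && init == "nndsvd") .nndsvd_init(x, k)
          else rand_init(.subseed(seed, 1, r - 1))
    fit <- iterate(st$w, st$h)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  best
}

## Elbow rule: smallest k whose improvement from adding one more component
## falls below `improve`, capped at kmax. Evaluated on a row subsample (the
## error curve's shape, not its level, drives the choice) with restarted fits
## so local minima do not masquerade as elbows.
.nmf_select_k <- function(x, kmax, seed, maxit, improve = 0.01,
                          max_rows = 400, n_restarts = 2) {
  if (nrow(x) > max_rows) {
    idx <- .with_seed(seed, sample.int(nrow(x), max_rows))
    x <- x[idx, , drop = FALSE]
  }
  errs <- numeric(0)
  for (k in 2:kmax) {
    errs[k] <- nmf_fit(x, k, seed = .subseed(seed, 1, 37 * k), maxit = maxit,
                       n_restarts = n_restarts)$error
    if (k >= 3) {
      rel <- (errs[k - 1] - errs[k]) / max(errs[k - 1], .Machine$double.eps)
      if (rel < improve) return(k - 1L)
    }
  }
  kmax
}
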