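#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
## `seed = NULL` leaves the caller's RNG stream untouched (and consumed).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

## Derive a valid RNG seed from arithmetic on a user seed without 32-bit
## integer overflow.
.subseed <- function(seed, mult, add) {
  as.integer((as.numeric(seed) * mult + add) %% 2147483629)
}

## Percentile with the package-wide convention: linear interpolation between
## order statistics (stats::quantile type 7). `p` is on the 0-100 scale.
.pctl <- function(x, p) {
  stats::quantile(x, probs = p / 100, type = 7, names = FALSE)
}

#' Decision labels used throughout the package
#'
#' The three perceptual decisions, in canonical level order. Decisions are
#' treated everywhere as an unordered categorical variable.
#'
#' @return Character vector `c("nuns", "voltaire", "dont_know")`.
#' @export
decision_levels <- function() c("nuns", "voltaire", "dont_know")

.as_decisions <- function(x) {
  f <- factor(as.character(x), levels = decision_levels())
  if (anyNA(f)) stop("decisions must be one of: ", paste(decision_levels(), collapse = ", "))
  f
}

## Bilinear resampling of a square matrix to `nout` x `nout`.
## Pixel centers sit at integer coordinates 1..n; destination pixel i maps to
## source coordinate (i - 0.5) * n_in/n_out + 0.5, clamped at the border.
.bilinear_resize <- function(m, nout) {
  nin <- nrow(m)
  s <- nin / nout
  cc <- (seq_len(nout) - 0.5) * s + 0.5
  i0 <- pmin(pmax(floor(cc), 1), nin)
  i1 <- pmin(i0 + 1, nin)
  fr <- pmin(pmax(cc - i0, 0), 1)
  ## rows then columns (separable)
  a <- m[i0, , drop = FALSE] * (1 - fr) + m[i1, , drop = FALSE] * fr
  a[, i0, drop = FALSE] * rep(1 - fr, each = nout) +
    a[, i1, drop = FALSE] * rep(fr, each = nout)
}

.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Match two feature sets by maximal total cosine similarity
#'
#' One-to-one assignment between the rows of `a` and the rows of `b` that
#' maximizes the summed cosine similarity. Exact (full enumeration) for up to 8
#' features, greedy above that.
#'
#' @param a,b Numeric matrices with the same number of rows and columns
#'   (feature-by-pixel).
#' @return List with `assignment` (index into rows of `b` for each row of `a`)
#'   and `cosine` (per-pair cosine similarity).
#' @export
match_features <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), nrow(a) == nrow(b), ncol(a) == ncol(b))
  k <- nrow(a)
  an <- a / pmax(sqrt(rowSums(a^2)), .Machine$double.eps)
  bn <- b / pmax(sqrt(rowSums(b^2)), .Machine$double.eps)
  sim <- an %*% t(bn)
  if (k <= 8L) {
    perms <- .all_perms(k)
    scores <- apply(perms, 1L, function(p) sum(sim[cbind(seq_len(k), p)]))
    best <- perms[which.max(scores), ]
  } else {
    best <- integer(k)
    avail <- rep(TRUE, k)
    ord <- order(apply(sim, 1L, max), decreasing = TRUE)
    for (i in ord) {
      j <- which(avail)[which.max(sim[i, avail])]
      best[i] <- j
      avail[j] <- FALSE
    }
  }
  list(assignment = best, cosine = sim[cbind(seq_len(k), best)])
}

## Shared argument checks -----------------------------------------------------

.check_square_image <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix")
  if (nrow(img) != ncol(img))
    stop(what, " must be square; got ", nrow(img), " x ", ncol(img))
  invisible(nrow(img))
}
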