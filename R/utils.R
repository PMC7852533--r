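# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so generators are reproducible without clobbering the session RNG.
#' A `NULL` seed leaves the RNG untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Symmetry check used by kernel and covariance invariants.
#' @noRd
assert_symmetric <- function(M, tol = 1e-10, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(what, " must be a square matrix", call. = FALSE)
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop(what, " is not symmetric within tolerance ", tol, call. = FALSE)
  invisible(M)
}

# PSD check with relative tolerance: smallest eigenvalue must not be below
# -tol * largest eigenvalue. Returns eigenvalues invisibly for reuse.
#' @noRd
assert_psd <- function(M, tol = 1e-8, what = "matrix") {
  ev <- eigen(symmetrize(M), symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev); hi <- max(ev, 0)
  if (lo < -tol * max(hi, .Machine$double.eps))
    stop(what, " is not positive semidefinite within tolerance: min eigenvalue ",
         signif(lo, 4), " vs max ", signif(hi, 4), call. = FALSE)
  invisible(ev)
}

#' @noRd
symmetrize <- function(M) (M + t(M)) / 2

# Draw one multivariate-normal vector N(0, sigma2 * K) through the
# eigendecomposition of K; eigenvalues in (-tol*max, 0) are clipped to zero,
# more negative ones are an error (non-PSD input).
#' @noRd
rmvn_eigen <- function(K, sigma2, tol = 1e-8) {
  ed <- eigen(symmetrize(K), symmetric = TRUE)
  ev <- ed$values
  hi <- max(ev, 0)
  if (min(ev) < -tol * max(hi, .Machine$double.eps))
    stop("kernel is not positive semidefinite within tolerance", call. = FALSE)
  ev[ev < 0] <- 0
  drop(ed$vectors %*% (sqrt(ev * sigma2) * stats::rnorm(length(ev))))
}

# Restricted (REML-style) log-likelihood of y = 1*mu + u + e with
# u ~ N(0, lambda * sigma2 * K), e ~ N(0, sigma2 * I), profiled over mu and
# sigma2, maximized over a grid of variance ratios lambda. Used for kernel
# hyperparameter selection (bandwidth h, number of layers l).
#' @noRd
kernel_marglik <- function(K, y, lambda_grid = 10^seq(-6, 6, by = 0.5)) {
  n <- length(y)
  if (nrow(K) != n) stop("kernel and phenotype sizes differ", call. = FALSE)
  ed <- eigen(symmetrize(K), symmetric = TRUE)
  yt <- drop(crossprod(ed$vectors, y))
  xt <- drop(crossprod(ed$vectors, rep(1, n)))
  s <- pmax(ed$values, 0)
  best <- -Inf
  for (lam in lambda_grid) {
    w <- lam * s + 1
    xtx <- sum(xt^2 / w)
    if (xtx <= 0) next
    mu <- sum(xt * yt / w) / xtx
    rss <- sum((yt - xt * mu)^2 / w)
    if (rss <= 0) next
    sigma2 <- rss / (n - 1)
    ll <- -0.5 * (sum(log(w)) + (n - 1) * log(sigma2) + log(xtx) + (n - 1))
    if (is.finite(ll) && ll > best) best <- ll
  }
  best
}
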