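# Independent brute-force oracles, deliberately written without reusing the
# package's internals.

# Pearson correlation from first principles.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Type-7 quantile by sorting and linear interpolation.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# Gaussian kernel, per-pair loops.
oracle_gk <- function(X, h) {
  n <- nrow(X)
  D2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D2[i, j] <- sum((X[i, ] - X[j, ])^2)
  off <- D2[row(D2) > col(D2)]
  Q <- oracle_quantile7(off, 0.5)
  K <- exp(-h * D2 / Q)
  diag(K) <- 1
  K
}

# Level-1 arc-cosine kernel, per-pair loops.
oracle_dk <- function(X) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    ni <- sqrt(sum(X[i, ]^2)); nj <- sqrt(sum(X[j, ]^2))
    ca <- min(1, max(-1, sum(X[i, ] * X[j, ]) / (ni * nj)))
    th <- acos(ca)
    K[i, j] <- ni * nj * (sin(th) + (pi - th) * cos(th)) / pi
  }
  K
}

# Naive full-covariance Gibbs sampler for y = 1*mu + u + e with
# u ~ N(0, K s2u): no eigen-reparameterization, direct multivariate-normal
# conditional for u. K must be nonsingular.
oracle_naive_gibbs <- function(y, K, iterations = 20000, burn_in = 1000,
                               nu_u = 5, nu_e = 5, sc_u, sc_e, seed = 1) {
  set.seed(seed)
  n <- length(y)
  Kinv <- solve(K)
  mu <- mean(y); u <- rep(0, n)
  s2u <- sc_u; s2e <- sc_e
  n_keep <- iterations - burn_in
  mus <- numeric(n_keep); us <- matrix(0, n_keep, n)
  vs <- matrix(0, n_keep, 2); ki <- 0
  for (it in seq_len(iterations)) {
    mu <- rnorm(1, mean(y - u), sqrt(s2e / n))
    r <- y - mu
    Cv <- chol2inv(chol(diag(n) / s2e + Kinv / s2u))
    u <- drop(Cv %*% r / s2e) + drop(t(chol(Cv)) %*% rnorm(n))
    s2u <- (nu_u * sc_u + drop(crossprod(u, Kinv %*% u))) /
      rchisq(1, nu_u + n)
    s2e <- (nu_e * sc_e + sum((r - u)^2)) / rchisq(1, nu_e + n)
    if (it > burn_in) {
      ki <- ki + 1
      mus[ki] <- mu; us[ki, ] <- u; vs[ki, ] <- c(s2u, s2e)
    }
  }
  list(mu = mean(mus), u = colMeans(us), var_u = mean(vs[, 1]),
       var_e = mean(vs[, 2]))
}

# Conjugate Gibbs for the fixed-effects-only model y = 1*mu + e (flat mu,
# scaled-inverse-chi-squared prior on s2e); returns the s2e chain.
oracle_lm_gibbs <- function(y, iterations = 4000, burn_in = 500,
                            nu_e = 5, sc_e, seed = 1) {
  set.seed(seed)
  n <- length(y)
  mu <- mean(y); s2e <- sc_e
  out <- numeric(iterations - burn_in)
  for (it in seq_len(iterations)) {
    mu <- rnorm(1, mean(y), sqrt(s2e / n))
    s2e <- (nu_e * sc_e + sum((y - mu)^2)) / rchisq(1, nu_e + n)
    if (it > burn_in) out[it - burn_in] <- s2e
  }
  out
}

# Draw one N(0, sigma2 K) vector via the (lower-triangular) Cholesky factor.
oracle_mvn <- function(K, sigma2 = 1) {
  drop(t(chol(K + diag(1e-10, nrow(K)))) %*% rnorm(nrow(K))) * sqrt(sigma2)
}
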