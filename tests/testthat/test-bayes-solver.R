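test_that("mcmc_config enforces chain invariants", {
  expect_error(mcmc_config(iterations = 100, burn_in = 100), "iterations")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(gibbs_fit(build_model("EA", small_experiment(1)$phenotypes,
                                     small_experiment(1)$kernels$A),
                         mcmc_config(iterations = 50, burn_in = 0, seed = 1,
                                     fix_variances = c(bogus = 1))),
               "fix_variances")
})

test_that("eigendecompose_terms truncates and reconstructs", {
  ed <- eigendecompose_terms(list(diag(4)))[[1]]
  expect_equal(ed$values, rep(1, 4))
  expect_equal(crossprod(ed$vectors), diag(4), tolerance = 1e-12)
  v <- c(1, -2, 0.5)
  ed1 <- eigendecompose_terms(list(tcrossprod(v)))[[1]]
  expect_equal(ed1$r, 1L)
  expect_equal(ed1$values, sum(v^2), tolerance = 1e-12)
  set.seed(17)
  K <- crossprod(matrix(rnorm(100), 10, 10))
  ed2 <- eigendecompose_terms(list(K))[[1]]
  expect_lt(max(abs(K - ed2$vectors %*% (ed2$values * t(ed2$vectors)))),
            1e-8)
  expect_error(eigendecompose_terms(list(matrix(1:4, 2, 2))),
               "not symmetric")
})

test_that("balanced Kronecker eigen path equals the dense expansion", {
  exp <- small_experiment(18)
  ts <- build_model("EADW+GW", exp$phenotypes, exp$kernels$A,
                    exp$kernels$D, exp$kernels$W)
  fit <- gibbs_fit(ts, mcmc_config(iterations = 30, burn_in = 5, seed = 1))
  for (t in names(ts$terms)) {
    K <- term_covariance(ts, t)
    ed <- fit$eig[[t]]
    expect_lt(max(abs(K - ed$vectors %*% (ed$values * t(ed$vectors)))),
              1e-8 * max(ed$values))
    expect_lt(max(abs(crossprod(ed$vectors) - diag(ed$r))), 1e-10)
  }
})

test_that("chains are reproducible and self-consistent", {
  exp <- small_experiment(19)
  ts <- build_model("EAD", exp$phenotypes, exp$kernels$A, exp$kernels$D)
  cfg <- mcmc_config(iterations = 300, burn_in = 50, seed = 5)
  fit1 <- gibbs_fit(ts, cfg)
  fit2 <- gibbs_fit(ts, cfg)
  expect_identical(fit1$var_samples, fit2$var_samples)
  expect_identical(fit1$beta_samples, fit2$beta_samples)
  # fitted = fixed part + sum of term effects at posterior means
  fx <- fit1$env_fixed[as.character(exp$phenotypes$records$env)]
  expect_lt(max(abs(fit1$fitted - (fx + fit1$u_hat$A + fit1$u_hat$D))),
            1e-8)
  # all saved variance draws are positive
  expect_true(all(fit1$var_samples > 0))
  expect_equal((300 - 50) %/% 2, nrow(fit1$var_samples))
})

test_that("zero-signal data shrink the genetic variance", {
  res <- vapply(1:3, function(s) {
    set.seed(s)
    g <- simulate_genotypes(small_config(s, n_hybrids = 50, n_parents = 15))
    ph <- phenotype_table(data.frame(
      env = rep(paste0("E", 1:3), each = 50),
      gid = rep(g$ids, 3), value = rnorm(150)))
    ts <- build_model("EA", ph, gb_kernel(additive_design(g)))
    fit <- gibbs_fit(ts, mcmc_config(iterations = 1500, burn_in = 300,
                                     seed = s))
    c(fit$var_mean[["A"]], fit$var_mean[["residual"]])
  }, numeric(2))
  # residual close to var(y) = 1; genetic variance clearly below it
  expect_equal(mean(res[2, ]), 1, tolerance = 0.2)
  expect_lt(mean(res[1, ]), 0.5 * mean(res[2, ]))
})

test_that("posterior means match the ridge solution with fixed variances", {
  set.seed(42)
  p <- 50
  ph <- phenotype_table(data.frame(env = "E1", gid = paste0("H", 1:p),
                                   value = rnorm(p, 5, 1.5)))
  ts <- build_model("EA", ph, K_A = diag(p))
  s2u <- 0.8; s2e <- 0.6
  fit <- gibbs_fit(ts, mcmc_config(iterations = 21000, burn_in = 1000,
                                   thin = 1, seed = 7,
                                   fix_variances = c(A = s2u,
                                                     residual = s2e)))
  lam <- s2e / s2u
  ridge <- solve((1 + lam) * diag(p), ph$records$value - fit$beta_mean[1])
  expect_lt(max(abs(fit$u_hat$A - ridge)), 0.02)
})

test_that("duplicating every record halves the posterior variance of mu", {
  set.seed(20)
  p <- 40
  y <- rnorm(p, 10, 1)
  ph1 <- phenotype_table(data.frame(env = "E1", gid = paste0("H", 1:p),
                                    value = y))
  ph2 <- phenotype_table(data.frame(env = "E1", gid = paste0("H", 1:(2 * p)),
                                    value = rep(y, 2)))
  cfg <- function(s) mcmc_config(iterations = 6000, burn_in = 1000, thin = 1,
                                 seed = s, sc_u = 1, sc_e = 1,
                                 fix_variances = c(A = 1e-9, residual = 1))
  v1 <- var(gibbs_fit(build_model("EA", ph1, diag(p)),
                      cfg(1))$beta_samples[, 1])
  v2 <- var(gibbs_fit(build_model("EA", ph2, diag(2 * p)),
                      cfg(2))$beta_samples[, 1])
  expect_equal(v2 / v1, 0.5, tolerance = 0.15)
})

test_that("residual variance conditional matches the conjugate oracle", {
  set.seed(21)
  n <- 200
  y <- rnorm(n, 3, 1.2)
  sc <- var(y) / 2
  ph <- phenotype_table(data.frame(env = "E1", gid = paste0("H", 1:n),
                                   value = y))
  # hold the single term at a negligible fixed variance so the model reduces
  # to y = mu + e, whose sigma2_e posterior has a closed conjugate form
  fit <- gibbs_fit(build_model("EA", ph, diag(n)),
                   mcmc_config(iterations = 4500, burn_in = 500, thin = 1,
                               seed = 3, sc_u = sc, sc_e = sc,
                               fix_variances = c(A = 1e-12)))
  oracle <- oracle_lm_gibbs(y, iterations = 4500, burn_in = 500,
                            sc_e = sc, seed = 4)
  ks <- suppressWarnings(ks.test(fit$var_samples[, "residual"], oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("variance partition sums to one and tracks simulated shares", {
  exp <- small_experiment(22)
  ts <- build_model("EAD", exp$phenotypes, exp$kernels$A, exp$kernels$D)
  fit <- gibbs_fit(ts, mcmc_config(iterations = 400, burn_in = 100,
                                   seed = 2))
  vp <- variance_partition(fit)
  expect_equal(sum(vp), 1, tolerance = 1e-10)
  # pure noise: residual dominates
  set.seed(23)
  g <- simulate_genotypes(small_config(23, n_hybrids = 60, n_parents = 15))
  phN <- phenotype_table(data.frame(env = rep(paste0("E", 1:3), each = 60),
                                    gid = rep(g$ids, 3),
                                    value = rnorm(180)))
  fitN <- gibbs_fit(build_model("EA", phN, gb_kernel(additive_design(g))),
                    mcmc_config(iterations = 1500, burn_in = 300, seed = 8))
  expect_gt(variance_partition(fitN)[["residual"]], 0.8)
  # equal A and residual variances -> shares near 0.5 each
  cfgE <- sim_config(n_parents = 60, n_hybrids = 200, n_markers = 1000,
                     n_environments = 6,
                     variance_components = c(A = 1, residual = 1), seed = 201)
  gE <- simulate_genotypes(cfgE)
  KE <- gb_kernel(additive_design(gE))
  simE <- simulate_phenotypes(gE, list(A = KE), cfgE)
  fitE <- gibbs_fit(build_model("EA", simE$phenotypes, KE),
                    mcmc_config(iterations = 2000, burn_in = 500, seed = 9))
  vpE <- variance_partition(fitE)
  expect_equal(unname(vpE[["A"]]), 0.5, tolerance = 0.15)
  expect_equal(unname(vpE[["residual"]]), 0.5, tolerance = 0.15)
})

test_that("predictions propagate through term covariances", {
  exp <- small_experiment(25)
  ph <- exp$phenotypes
  ts <- build_model("EAD", ph, exp$kernels$A, exp$kernels$D)
  tr <- seq_len(ph$n) > 15
  fit <- gibbs_fit(ts, mcmc_config(iterations = 500, burn_in = 100,
                                   seed = 4), train = tr)
  # a target identical to a training record reproduces its fitted value
  idx <- which(tr)[1:4]
  pr <- predict(fit, newdata = ph$records[idx, c("env", "gid")])
  expect_equal(pr, unname(fit$yhat[idx]), tolerance = 1e-8)
  # masked records receive finite conditional predictions
  expect_true(all(is.finite(fit$yhat)))
  expect_equal(nrow(fit$predictions), 15L)
  expect_error(predict(fit, newdata = data.frame(env = "E1", gid = "nope")),
               "unknown hybrid")
  expect_error(predict(fit, newdata = data.frame(env = "EX", gid = ph$gids[1])),
               "unknown environment")
  expect_error(gibbs_fit(ts, mcmc_config(seed = 1), train = rep(FALSE, ph$n)),
               "empty training set")
})

test_that("CV0 predictions for a new environment use averaged fixed effects", {
  exp <- small_experiment(26, n_environments = 4)
  ph <- exp$phenotypes
  ts <- build_model("EA", ph, exp$kernels$A)
  te <- as.integer(ph$env) == 4L
  fit <- gibbs_fit(ts, mcmc_config(iterations = 600, burn_in = 100,
                                   seed = 6), train = !te)
  # EA has no environment-specific random term: the prediction equals the
  # averaged training fixed part plus the hybrid's additive effect
  ef <- fit$env_fixed
  expect_equal(unname(ef[["E4"]]), mean(ef[c("E1", "E2", "E3")]))
  one <- which(te)[1]
  gid <- as.integer(ph$gid)[one]
  same_hyb_tr <- which(!te & as.integer(ph$gid) == gid)[1]
  u_pred <- fit$yhat[one] - ef[["E4"]]
  u_tr <- fit$fitted[which(which(!te) == same_hyb_tr)] -
    ef[[as.character(ph$records$env[same_hyb_tr])]]
  expect_equal(unname(u_pred), unname(u_tr), tolerance = 1e-8)
})

test_that("an all-ones K_W adds only an intercept shift under EADW", {
  exp <- small_experiment(27, n_environments = 4)
  ph <- exp$phenotypes
  te <- as.integer(ph$env) == 4L
  cfg <- mcmc_config(iterations = 3000, burn_in = 500, seed = 11)
  fit_ead <- gibbs_fit(build_model("EAD", ph, exp$kernels$A,
                                   exp$kernels$D), cfg, train = !te)
  fit_eadw <- gibbs_fit(build_model("EADW", ph, exp$kernels$A,
                                    exp$kernels$D, matrix(1, 4, 4)),
                        cfg, train = !te)
  d <- fit_eadw$yhat[te] - fit_ead$yhat[te]
  # the W term with exchangeable environments is a pure shift: predictions
  # differ by (approximately) a constant
  expect_lt(sd(d), 0.05 * sd(fit_ead$yhat[te]))
})
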