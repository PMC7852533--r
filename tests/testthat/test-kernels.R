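test_that("maf_filter removes monomorphic and threshold markers", {
  dos <- cbind(m1 = c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2),  # f = 1
               m2 = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0),  # f = 0.05 exactly
               m3 = c(2, 1, 1, 0, 1, 0, 0, 0, 0, 0))  # f = 0.25
  g <- genotype_table(dos)
  expect_equal(unname(g$freq), c(1, 0.05, 0.25))
  out <- suppressMessages(maf_filter(g, threshold = 0.05))
  expect_equal(colnames(out$dosage), "m3")   # strict <= removes f = 0.05
  expect_equal(attr(out, "n_removed"), 2L)
  expect_error(maf_filter(genotype_table(dos[, 1, drop = FALSE])),
               "all markers removed")
})

test_that("additive design centers dosages by 2f", {
  dos <- cbind(m1 = c(0, 1, 2, 1))               # f = 0.5
  g <- genotype_table(dos)
  expect_identical(additive_design(g, center = FALSE), g$dosage)
  expect_equal(unname(additive_design(g)[, 1]), c(-1, 0, 1, 0))
  # centered columns have mean zero under observed frequencies
  g2 <- simulate_genotypes(small_config(2))
  expect_lt(max(abs(colMeans(additive_design(g2)))), 1e-12)
})

test_that("dominance coding follows the orthogonal parameterization", {
  # f = 0.5: codes {0: -0.5, 1: 0.5, 2: -0.5}
  g <- genotype_table(cbind(m1 = c(0, 1, 2, 1)))
  expect_equal(unname(dominance_design(g)[, 1]), c(-0.5, 0.5, -0.5, 0.5))
  # guard against the +/-2f^2-scaled alternative convention
  expect_false(isTRUE(all.equal(unname(dominance_design(g)[, 1]),
                                2 * c(-0.5, 0.5, -0.5, 0.5))))
  # HWE-weighted mean of the codes is zero over a grid of f
  for (f in seq(0.05, 0.95, by = 0.05)) {
    codes <- c(-2 * f^2, 2 * f * (1 - f), -2 * (1 - f)^2)
    w <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    expect_lt(abs(sum(w * codes)), 1e-12)
  }
  # the package's codes match the analytic ones marker-wise
  g3 <- simulate_genotypes(small_config(3))
  f <- unname(g3$freq)
  D <- dominance_design(g3)
  for (j in c(1, 7, 40)) {
    expected <- c(`0` = -2 * f[j]^2, `1` = 2 * f[j] * (1 - f[j]),
                  `2` = -2 * (1 - f[j])^2)
    expect_equal(unname(D[, j]),
                 unname(expected[as.character(g3$dosage[, j])]))
  }
  bad <- genotype_table(cbind(m1 = c(2, 2, 2)))
  expect_error(dominance_design(bad), "monomorphic")
})

test_that("gb_kernel matches hand computations and trace normalization", {
  expect_equal(unclass(gb_kernel(diag(2))), diag(2), ignore_attr = TRUE)
  K <- gb_kernel(matrix(c(2, 0), 2, 1))
  expect_equal(unclass(K), matrix(c(2, 0, 0, 0), 2, 2), ignore_attr = TRUE)
  set.seed(4)
  X <- matrix(rnorm(60), 12, 5)
  expect_equal(sum(diag(gb_kernel(X))), 12, tolerance = 1e-10)
  # scale invariance forced by the normalization
  expect_equal(unclass(gb_kernel(3.7 * X)), unclass(gb_kernel(X)),
               tolerance = 1e-12)
  expect_error(gb_kernel(matrix(0, 3, 2)), "zero")
})

test_that("gk_kernel follows the negative-exponent median-scaled form", {
  K <- gk_kernel(matrix(c(0, 1, 2), 3, 1), h = 1)
  expect_equal(diag(unclass(K)), rep(1, 3))
  expect_equal(K[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(K[2, 3], exp(-1), tolerance = 1e-12)
  expect_equal(K[1, 3], exp(-4), tolerance = 1e-12)
  expect_equal(attr(K, "hyperparams")$Q, 1)
  # identical rows -> unit covariance
  K2 <- gk_kernel(rbind(c(1, 2), c(1, 2), c(0, 0)), h = 2)
  expect_equal(K2[1, 2], 1)
  expect_error(gk_kernel(rbind(c(1, 1), c(1, 1))), "degenerate")
  expect_error(gk_kernel(matrix(rnorm(10), 5, 2), h = -1), "positive")
})

test_that("gk entries lie in (0,1] and decay with distance", {
  set.seed(5)
  X <- matrix(rnorm(80), 16, 5)
  K <- unclass(gk_kernel(X, h = 0.8))
  expect_true(all(K > 0 & K <= 1))
  D2 <- as.matrix(dist(X))^2
  off <- row(K) > col(K)
  ord <- order(D2[off])
  expect_true(all(diff(K[off][ord]) <= 1e-12))
})

test_that("dk_base satisfies the norm and orthogonality identities", {
  set.seed(6)
  x <- rnorm(7)
  K <- unclass(dk_base(rbind(x, -x, x)))
  expect_equal(K[1, 1], sum(x^2), tolerance = 1e-12)
  expect_equal(K[1, 2], 0, tolerance = 1e-10)
  expect_equal(K[1, 3], sum(x^2), tolerance = 1e-12)
  K2 <- dk_base(rbind(c(1, 0), c(0, 1)))
  expect_equal(K2[1, 2], 1 / pi, tolerance = 1e-12)
  expect_error(dk_base(rbind(c(0, 0), c(1, 1))), "zero-norm")
})

test_that("dk_recurse preserves the diagonal and stays PSD", {
  set.seed(7)
  X <- matrix(rnorm(50), 10, 5)
  K1 <- dk_base(X)
  K2 <- dk_recurse(K1, 1)
  expect_equal(diag(unclass(K2)), diag(unclass(K1)), tolerance = 1e-10)
  expect_equal(attr(K2, "hyperparams")$layers, 2)
  # an orthogonal pair maps to a strictly positive entry at the next level
  xo <- rbind(c(2, 0), c(0, 3))
  Kb <- dk_base(xo)
  expect_equal(Kb[1, 2], 2 * 3 / pi, tolerance = 1e-12)
  Kn <- dk_recurse(Kb, 1)
  expect_gt(Kn[1, 2], 0)
  ev <- eigen(unclass(dk_recurse(K1, 3)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  expect_error(dk_recurse(structure(diag(c(1, 0)), class = c("kernel_matrix",
                                                             "matrix"))),
               "positive")
})

test_that("kernel builders match brute-force per-pair oracles", {
  set.seed(8)
  X <- matrix(rnorm(50), 10, 5)
  expect_lt(max(abs(unclass(gk_kernel(X, 1.3)) - oracle_gk(X, 1.3))), 1e-10)
  expect_lt(max(abs(unclass(dk_base(X)) - oracle_dk(X))), 1e-10)
})

test_that("kernel builders return symmetric PSD matrices on random input", {
  for (s in 1:4) {
    set.seed(s)
    X <- matrix(rnorm(20 * 8), 20, 8)
    for (K in list(gb_kernel(X), gk_kernel(X, 0.7), dk_kernel(X, 2))) {
      M <- unclass(K)
      expect_lt(max(abs(M - t(M))), 1e-10)
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-8 * max(ev))
    }
  }
})

test_that("normalize_kernel rescales to mean diagonal one, idempotently", {
  set.seed(9)
  X <- matrix(rnorm(40), 8, 5)
  K <- gb_kernel(X)
  expect_equal(unclass(normalize_kernel(K)), unclass(K), tolerance = 1e-12)
  K2 <- normalize_kernel(structure(2 * diag(3),
                                   class = c("kernel_matrix", "matrix"),
                                   method = "GB"))
  expect_equal(unclass(K2), diag(3), ignore_attr = TRUE)
  Kd <- dk_base(X)
  expect_equal(unclass(normalize_kernel(normalize_kernel(Kd))),
               unclass(normalize_kernel(Kd)), tolerance = 1e-12)
})

test_that("bandwidth selection recovers the generating bandwidth", {
  sel <- vapply(1:10, function(s) {
    cfg <- sim_config(n_parents = 25, n_hybrids = 250, n_markers = 400,
                      seed = s)
    X <- additive_design(simulate_genotypes(cfg))
    K <- unclass(gk_kernel(X, h = 1))
    set.seed(1000 + s)
    y <- 10 + 2 * oracle_mvn(K) + rnorm(250, 0, 0.5)
    select_bandwidth(X, y)
  }, numeric(1))
  mode_h <- as.numeric(names(sort(-table(sel)))[1])
  expect_equal(mode_h, 1)
  # single candidate returned unchanged; ties break to the smaller h
  expect_equal(select_bandwidth(matrix(rnorm(20), 10, 2), rnorm(10),
                                candidate_h = 0.42), 0.42)
})

test_that("layer selection lands near the generating depth", {
  sel <- vapply(1:8, function(s) {
    X <- structured_design(seed = 50 + s)
    K <- unclass(normalize_kernel(dk_kernel(X, 3)))
    set.seed(2000 + s)
    y <- 5 + 2 * oracle_mvn(K) + rnorm(100, 0, 0.5)
    select_layers(X, y, l_max = 6)
  }, numeric(1))
  expect_true(all(abs(sel - 3) <= 1))
  expect_identical(select_layers(matrix(rnorm(30), 10, 3), rnorm(10),
                                 l_max = 1), 1L)
})

test_that("impute_dosages mean-fills and genotype_table rejects NAs", {
  M <- cbind(c(0, NA, 2), c(1, 1, NA))
  expect_error(genotype_table(M), "missing")
  M2 <- suppressMessages(impute_dosages(M))
  expect_equal(attr(M2, "n_imputed"), 2L)
  expect_equal(M2[2, 1], 1)
  expect_equal(M2[3, 2], 1)
})
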