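# Marker codings and relationship-kernel constructions (GB, GK, DK).

#' Genotype table of hybrid marker dosages
#'
#' Wraps a hybrids-by-markers dosage matrix (counts 0/1/2 of the tracked
#' allele) together with per-marker allele frequencies computed from the
#' dosages. Missing entries are not allowed; use [impute_dosages()] first if
#' needed.
#'
#' @param dosage numeric matrix, rows = hybrids, columns = markers, entries in
#'   `{0, 1, 2}` (fractional values are allowed after mean imputation).
#' @param ids optional character vector of hybrid IDs (defaults to rownames).
#' @param parents optional two-column data frame recording the parental lines
#'   of each hybrid (as produced by [simulate_genotypes()]).
#' @return An object of class `genotype_table` with elements `dosage`, `ids`,
#'   `freq` (per-marker frequency of the counted allele) and `parents`.
#' @examples
#' g <- genotype_table(matrix(c(0, 1, 2, 1), 2, 2,
#'                            dimnames = list(c("H1", "H2"), c("m1", "m2"))))
#' g$freq
#' @export
genotype_table <- function(dosage, ids = NULL, parents = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (anyNA(dosage))
    stop("dosage matrix has missing entries; run impute_dosages() first",
         call. = FALSE)
  if (any(dosage < 0 | dosage > 2))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  ids <- ids %||% rownames(dosage) %||% paste0("H", seq_len(nrow(dosage)))
  rownames(dosage) <- ids
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("m", seq_len(ncol(dosage)))
  structure(
    list(dosage = dosage, ids = ids, freq = colMeans(dosage) / 2,
         parents = parents),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$dosage), "hybrids x", ncol(x$dosage),
      "markers\n")
  cat("  allele frequency range:",
      paste(signif(range(x$freq), 3), collapse = " - "), "\n")
  invisible(x)
}

#' Mean-impute missing dosages
#'
#' Replaces missing dosage entries with the marker (column) mean, the explicit
#' pre-step assumed by [genotype_table()]. The number of imputed cells is
#' reported via a message and stored as an attribute.
#'
#' @param dosage numeric matrix with possible `NA` entries.
#' @return The completed matrix with attribute `n_imputed`.
#' @export
impute_dosages <- function(dosage) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  n_na <- sum(is.na(dosage))
  if (n_na > 0) {
    mu <- colMeans(dosage, na.rm = TRUE)
    idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[idx] <- mu[idx[, 2]]
    message("impute_dosages: mean-imputed ", n_na, " missing entries")
  }
  attr(dosage, "n_imputed") <- n_na
  dosage
}

#' Remove markers with low minor allele frequency
#'
#' Markers whose minor allele frequency satisfies `MAF <= threshold` are
#' removed (strict "less than or equal"), so markers at exactly the threshold
#' are dropped. Monomorphic markers always fail this screen.
#'
#' @param genotypes a [genotype_table()].
#' @param threshold MAF cutoff, default 0.05.
#' @return A filtered `genotype_table`; the number of removed markers is
#'   stored in attribute `n_removed` and reported by message.
#' @export
maf_filter <- function(genotypes, threshold = 0.05) {
  stopifnot(inherits(genotypes, "genotype_table"))
  maf <- pmin(genotypes$freq, 1 - genotypes$freq)
  keep <- maf > threshold
  if (!any(keep))
    stop("maf_filter: all markers removed at threshold ", threshold,
         call. = FALSE)
  out <- genotype_table(genotypes$dosage[, keep, drop = FALSE],
                        ids = genotypes$ids, parents = genotypes$parents)
  n_removed <- sum(!keep)
  if (n_removed > 0)
    message("maf_filter: removed ", n_removed, " markers with MAF <= ",
            threshold)
  attr(out, "n_removed") <- n_removed
  out
}

#' Additive marker design matrix
#'
#' Returns the dosage matrix, by default column-centered by twice the allele
#' frequency (VanRaden-style), so each column has mean zero under the observed
#' frequencies. With `center = FALSE` the raw 0/1/2 dosages are returned.
#'
#' @param genotypes a [genotype_table()].
#' @param center center columns by `2 * f_l`? Default `TRUE`.
#' @return numeric matrix, hybrids x markers.
#' @export
additive_design <- function(genotypes, center = TRUE) {
  stopifnot(inherits(genotypes, "genotype_table"))
  X <- genotypes$dosage
  if (center) X <- sweep(X, 2L, 2 * genotypes$freq, `-`)
  X
}

#' Dominance-deviation design matrix
#'
#' Recodes dosages into dominance deviations using the orthogonal
#' parameterization of Vitezica et al. (2013): with `f` the frequency of the
#' counted allele, dosage 0 maps to `-2 f^2`, dosage 1 to `2 f (1 - f)`, and
#' dosage 2 to `-2 (1 - f)^2`. Under Hardy-Weinberg genotype weights each
#' column then has mean zero. Fractional (imputed) dosages are linearly
#' interpolated between the three codes.
#'
#' @param genotypes a [genotype_table()]; all allele frequencies must lie
#'   strictly inside (0, 1).
#' @return numeric matrix, hybrids x markers.
#' @export
dominance_design <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_table"))
  f <- genotypes$freq
  if (any(f <= 0 | f >= 1))
    stop("dominance deviations undefined for monomorphic markers (f in {0,1})",
         call. = FALSE)
  X <- genotypes$dosage
  # piecewise-linear in dosage through the three Vitezica codes
  c0 <- -2 * f^2
  c1 <- 2 * f * (1 - f)
  c2 <- -2 * (1 - f)^2
  lo <- pmin(X, 1); hi <- pmax(X, 1) - 1
  D <- sweep(1 - lo, 2L, c0, `*`) + sweep(lo - hi, 2L, c1, `*`) +
    sweep(hi, 2L, c2, `*`)
  dimnames(D) <- dimnames(X)
  D
}

# ---- kernel container -------------------------------------------------------

#' Labeled relationship kernel
#'
#' Internal constructor validating symmetry and positive semidefiniteness of
#' a relationship matrix and attaching the construction metadata.
#' @noRd
new_kernel_matrix <- function(values, method, hyperparams = list(),
                              psd_tolerance = 1e-8) {
  assert_symmetric(values, what = "kernel")
  values <- symmetrize(values)
  assert_psd(values, tol = psd_tolerance, what = paste0(method, " kernel"))
  structure(values, class = c("kernel_matrix", "matrix"),
            method = method, hyperparams = hyperparams,
            psd_tolerance = psd_tolerance)
}

#' @export
print.kernel_matrix <- function(x, ...) {
  hp <- attr(x, "hyperparams")
  cat("kernel_matrix (", attr(x, "method"), "), ", nrow(x), " x ", ncol(x),
      if (length(hp)) paste0("; ", paste(names(hp), unlist(hp), sep = "=",
                                         collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Extract kernel construction metadata
#'
#' @param K a `kernel_matrix`.
#' @return list with elements `method` and `hyperparams`.
#' @export
kernel_info <- function(K) {
  list(method = attr(K, "method"), hyperparams = attr(K, "hyperparams"))
}

# ---- the three kernel methods ----------------------------------------------

#' Trace-normalized linear (GBLUP) kernel
#'
#' Computes `K = X X' / (trace(X X') / nrow(X))`, the benchmark linear kernel.
#' The normalization forces `trace(K) = nrow(X)` (mean diagonal 1) and makes
#' the kernel invariant to rescaling of `X`.
#'
#' @param X numeric matrix with rows = entities (hybrids or environments).
#' @return a `kernel_matrix` with method `"GB"`.
#' @examples
#' gb_kernel(diag(2))          # identity
#' @export
gb_kernel <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("X needs at least one column", call. = FALSE)
  XXt <- tcrossprod(X)
  tr <- sum(diag(XXt))
  if (tr <= 0)
    stop("gb_kernel: trace(XX') is zero (all-zero X); cannot normalize",
         call. = FALSE)
  K <- XXt / (tr / nrow(X))
  dimnames(K) <- list(rownames(X), rownames(X))
  new_kernel_matrix(K, "GB")
}

#' @noRd
squared_euclidean <- function(X) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}

#' Gaussian kernel
#'
#' Computes `K[i, i'] = exp(-h * D2[i, i'] / Q)` where `D2` is the squared
#' Euclidean distance between rows of `X` and `Q` is the median of the strictly
#' off-diagonal `D2` entries. The bandwidth `h > 0` controls the rate of decay
#' of covariance with distance; the diagonal is exactly 1.
#'
#' @param X numeric matrix with at least two rows.
#' @param h bandwidth, positive scalar. Default 1.
#' @return a `kernel_matrix` with method `"GK"` and hyperparameters `h`, `Q`.
#' @examples
#' gk_kernel(matrix(c(0, 1, 2), 3, 1), h = 1)
#' @export
gk_kernel <- function(X, h = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("gk_kernel needs at least two rows", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("bandwidth h must be a positive scalar", call. = FALSE)
  D2 <- squared_euclidean(X)
  Q <- stats::median(D2[lower.tri(D2)])
  if (Q <= 0)
    stop("gk_kernel: median off-diagonal squared distance is zero ",
         "(degenerate input with identical rows)", call. = FALSE)
  K <- exp(-h * D2 / Q)
  diag(K) <- 1
  dimnames(K) <- list(rownames(X), rownames(X))
  new_kernel_matrix(K, "GK", hyperparams = list(h = h, Q = Q))
}

#' @noRd
j_theta <- function(theta) sin(theta) + (pi - theta) * cos(theta)

#' Base arc-cosine ("Deep") kernel
#'
#' The level-1 arc-cosine kernel
#' `DK1(x, x') = (1/pi) * ||x|| * ||x'|| * J(theta)`, with
#' `J(theta) = sin(theta) + (pi - theta) cos(theta)` and `theta` the angle
#' between the two row vectors. It emulates the covariance of a one-hidden-
#' layer neural network: `DK1(x, x) = ||x||^2` and `DK1(x, -x) = 0`.
#'
#' @param X numeric matrix; no all-zero rows.
#' @return a `kernel_matrix` with method `"DK"` and hyperparameter `layers = 1`.
#' @export
dk_base <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop("dk_base: zero-norm row(s) ", paste(which(nrm == 0), collapse = ", "),
         "; the angle is undefined", call. = FALSE)
  G <- tcrossprod(X)
  cosang <- G / outer(nrm, nrm)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  theta <- acos(cosang)
  K <- outer(nrm, nrm) * j_theta(theta) / pi
  dimnames(K) <- list(rownames(X), rownames(X))
  new_kernel_matrix(K, "DK", hyperparams = list(layers = 1L))
}

#' Deepen an arc-cosine kernel by recursion
#'
#' Applies the layer recursion
#' `DK(l+1)[i, i'] = (1/pi) * sqrt(DK(l)[i, i] * DK(l)[i', i']) * J(theta)` with
#' `theta = acos(DK(l)[i, i'] / sqrt(DK(l)[i, i] * DK(l)[i', i']))`, `levels`
#' times. The diagonal is preserved at every level.
#'
#' @param K_l kernel from [dk_base()] or a previous recursion; positive
#'   diagonal required.
#' @param levels number of additional layers to apply (default 1).
#' @return a `kernel_matrix` with method `"DK"` and updated `layers`.
#' @export
dk_recurse <- function(K_l, levels = 1L) {
  K <- unclass(K_l)
  assert_symmetric(K, what = "DK kernel")
  if (any(diag(K) <= 0))
    stop("dk_recurse: kernel diagonal must be strictly positive", call. = FALSE)
  levels <- as.integer(levels)
  stopifnot(levels >= 0L)
  layers <- attr(K_l, "hyperparams")$layers %||% 1L
  for (i in seq_len(levels)) {
    d <- sqrt(diag(K))
    nd <- outer(d, d)
    cosang <- K / nd
    cosang[cosang > 1] <- 1
    cosang[cosang < -1] <- -1
    K <- nd * j_theta(acos(cosang)) / pi
    K <- symmetrize(K)
  }
  new_kernel_matrix(K, "DK",
                    hyperparams = list(layers = layers + levels))
}

#' Arc-cosine kernel with a chosen number of layers
#'
#' Convenience wrapper: [dk_base()] followed by `layers - 1` recursions.
#'
#' @param X input matrix.
#' @param layers total number of layers, `>= 1`.
#' @return a `kernel_matrix`.
#' @export
dk_kernel <- function(X, layers = 1L) {
  layers <- as.integer(layers)
  stopifnot(layers >= 1L)
  dk_recurse(dk_base(X), levels = layers - 1L)
}

# ---- hyperparameter selection ----------------------------------------------

#' Select the Gaussian-kernel bandwidth by marginal likelihood
#'
#' Evaluates, for every candidate bandwidth, the restricted likelihood of the
#' single-kernel mixed model `y = 1 mu + u + e` with `u ~ N(0, K(h) sigma2_u)`,
#' profiled over the variance ratio on a grid, and returns the maximizing `h`.
#' Ties are broken toward the smaller bandwidth. Rows of `X` with missing `y`
#' are dropped before evaluation.
#'
#' @param X entity-level input matrix (e.g. centered dosages).
#' @param y phenotype vector aligned with rows of `X`; `NA` rows are dropped.
#' @param candidate_h candidate bandwidths; default `c(0.1, 0.25, 0.5, 1, 2, 5)`.
#' @return the selected bandwidth (scalar).
#' @export
select_bandwidth <- function(X, y, candidate_h = c(0.1, 0.25, 0.5, 1, 2, 5)) {
  if (length(candidate_h) < 1L) stop("empty candidate grid", call. = FALSE)
  keep <- !is.na(y)
  X <- as.matrix(X)[keep, , drop = FALSE]
  y <- y[keep]
  if (length(y) != nrow(X)) stop("y must align with rows of X", call. = FALSE)
  if (length(candidate_h) == 1L) return(candidate_h)
  candidate_h <- sort(candidate_h)
  ll <- vapply(candidate_h,
               function(h) kernel_marglik(unclass(gk_kernel(X, h)), y),
               numeric(1))
  if (all(!is.finite(ll)))
    stop("select_bandwidth: marginal likelihood non-finite for all candidates",
         call. = FALSE)
  candidate_h[which.max(ll)]  # which.max takes the first (smallest h) on ties
}

#' Select the number of arc-cosine layers by marginal likelihood
#'
#' Evaluates the single-kernel restricted likelihood for `l = 1..l_max` layers
#' and returns the argmax; ties go to the smaller `l`.
#'
#' @inheritParams select_bandwidth
#' @param l_max largest number of layers to consider (default 10).
#' @return the selected number of layers (integer).
#' @export
select_layers <- function(X, y, l_max = 10L) {
  l_max <- as.integer(l_max)
  stopifnot(l_max >= 1L)
  keep <- !is.na(y)
  X <- as.matrix(X)[keep, , drop = FALSE]
  y <- y[keep]
  if (l_max == 1L) return(1L)
  K <- dk_base(X)
  ll <- numeric(l_max)
  ll[1] <- kernel_marglik(unclass(K), y)
  for (l in seq(2L, l_max)) {
    K <- dk_recurse(K, 1L)
    ll[l] <- kernel_marglik(unclass(K), y)
  }
  if (all(!is.finite(ll)))
    stop("select_layers: marginal likelihood non-finite for all candidates",
         call. = FALSE)
  which.max(ll)
}

#' Rescale a kernel to mean diagonal one
#'
#' Optional comparability rescaling `K / mean(diag(K))`. GB kernels already
#' have mean diagonal 1 and pass through unchanged; for GK the diagonal is
#' exactly 1; for DK the heterogeneous diagonal is meaningful, so this is
#' never applied automatically.
#'
#' @param K a `kernel_matrix` or plain symmetric matrix with positive trace.
#' @return a `kernel_matrix` with mean diagonal 1.
#' @export
normalize_kernel <- function(K) {
  method <- attr(K, "method") %||% "GB"
  hp <- attr(K, "hyperparams") %||% list()
  M <- unclass(K)
  md <- mean(diag(M))
  if (md <= 0) stop("normalize_kernel: non-positive trace", call. = FALSE)
  new_kernel_matrix(M / md, method, hyperparams = hp)
}

# ---- builder dispatch -------------------------------------------------------

#' Build a relationship kernel with a named method
#'
#' Dispatches to [gb_kernel()], [gk_kernel()] or [dk_kernel()]. For `"GK"` a
#' bandwidth is required (or selected from `y` when supplied); for `"DK"` a
#' layer count (or selected from `y`).
#'
#' @param X input matrix (rows = entities).
#' @param method one of `"GB"`, `"GK"`, `"DK"`.
#' @param h Gaussian bandwidth (default 1 when `y` absent).
#' @param layers arc-cosine layers (default 1 when `y` absent).
#' @param y optional phenotypes for hyperparameter selection.
#' @return a `kernel_matrix`.
#' @export
build_kernel <- function(X, method = c("GB", "GK", "DK"), h = NULL,
                         layers = NULL, y = NULL) {
  method <- match.arg(method)
  switch(method,
    GB = gb_kernel(X),
    GK = {
      if (is.null(h)) h <- if (is.null(y)) 1 else select_bandwidth(X, y)
      gk_kernel(X, h)
    },
    DK = {
      if (is.null(layers))
        layers <- if (is.null(y)) 1L else select_layers(X, y)
      dk_kernel(X, layers)
    })
}
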