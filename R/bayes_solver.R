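# Eigen-reparameterized Gibbs sampler for MET kernel models.
#
# Every random-effect covariance K is eigendecomposed (K = U S U'); the
# effect is sampled in the eigenbasis (b = U'u), where its full conditional
# factorizes into independent normals because U has orthonormal columns.
# Variance components carry scaled-inverse-chi-squared priors and conjugate
# full conditionals; fixed effects get a flat prior.

#' MCMC configuration for the Gibbs sampler
#'
#' @param iterations total Gibbs iterations (default 10000).
#' @param burn_in discarded initial cycles (default 1000).
#' @param thin thinning interval (default 2): iterations
#'   `burn_in + thin, burn_in + 2*thin, ...` are saved.
#' @param seed RNG seed for a reproducible chain (optional).
#' @param nu_u,nu_e prior degrees of freedom of the scaled-inverse-chi-squared
#'   priors on the term and residual variances (default 5 each).
#' @param sc_u,sc_e prior scales; default `NULL` means the data-driven choice
#'   `var(y_train) / 2` for both.
#' @param eigen_tol relative eigenvalue truncation tolerance (default 1e-8).
#' @param fix_variances optional named numeric vector holding selected
#'   variance components (term names and/or `"residual"`) fixed at the given
#'   values instead of sampling them; mainly for validation against
#'   closed-form solutions.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 10000L, burn_in = 1000L, thin = 2L,
                        seed = NULL, nu_u = 5, nu_e = 5, sc_u = NULL,
                        sc_e = NULL, eigen_tol = 1e-8, fix_variances = NULL) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (!(iterations > burn_in && burn_in >= 0L && thin >= 1L))
    stop("need iterations > burn_in >= 0 and thin >= 1", call. = FALSE)
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = seed, nu_u = nu_u, nu_e = nu_e, sc_u = sc_u,
                 sc_e = sc_e, eigen_tol = eigen_tol,
                 fix_variances = fix_variances),
            class = "mcmc_config")
}

#' Eigendecompose a list of term covariance matrices
#'
#' Retains eigenpairs with `s_i > tol * max(s)`; negative eigenvalues within
#' the tolerance are clipped to zero.
#'
#' @param terms list of symmetric PSD matrices.
#' @param tol relative truncation tolerance.
#' @return list (one element per term) of lists with `vectors` (n x r),
#'   `values` (length r) and `r`.
#' @export
eigendecompose_terms <- function(terms, tol = 1e-8) {
  lapply(terms, function(K) {
    K <- as.matrix(K)
    assert_symmetric(K, what = "term covariance")
    ed <- eigen(symmetrize(K), symmetric = TRUE)
    ev <- pmax(ed$values, 0)
    keep <- ev > tol * max(ev)
    list(vectors = ed$vectors[, keep, drop = FALSE], values = ev[keep],
         r = sum(keep))
  })
}

# Eigendecomposition of one factored term restricted to the training records.
# When the training set is a complete (balanced) environment x hybrid grid the
# observation covariance is a Kronecker product of the two factors, whose
# eigenpairs are Kronecker products of the factor eigenpairs -- exactly
# equivalent to, and much cheaper than, eigendecomposing the n x n expansion.
#' @noRd
eigen_term <- function(term, ev_idx, gv_idx, tol = 1e-8) {
  n_t <- length(ev_idx)
  pe <- sort(unique(ev_idx)); pg <- sort(unique(gv_idx))
  balanced <- n_t == length(pe) * length(pg) &&
    !anyDuplicated(cbind(ev_idx, gv_idx))
  if (balanced && n_t > 4L) {
    edE <- eigen(symmetrize(term$env_cov[pe, pe, drop = FALSE]),
                 symmetric = TRUE)
    edG <- eigen(symmetrize(term$geno_cov[pg, pg, drop = FALSE]),
                 symmetric = TRUE)
    sE <- pmax(edE$values, 0); sG <- pmax(edG$values, 0)
    s <- as.vector(kronecker(sE, sG))
    keep <- s > tol * max(s)
    # columns of the Kronecker basis matching the retained eigenvalues
    U_sorted <- kronecker(edE$vectors, edG$vectors)[, keep, drop = FALSE]
    U <- matrix(0, n_t, sum(keep))
    U[order(match(ev_idx, pe), match(gv_idx, pg)), ] <- U_sorted
    list(vectors = U, values = s[keep], r = sum(keep))
  } else {
    K <- term$env_cov[ev_idx, ev_idx, drop = FALSE] *
      term$geno_cov[gv_idx, gv_idx, drop = FALSE]
    eigendecompose_terms(list(K), tol = tol)[[1L]]
  }
}

#' Fit a MET model by the eigen-reparameterized Gibbs sampler
#'
#' Runs the Gibbs cycle on the training records: (i) fixed effects from their
#' normal full conditional (flat prior); (ii) per term, eigenbasis
#' coefficients `b` from independent normal full conditionals with prior
#' variance `sigma2_t * s_i` against the current partial residual; (iii) every
#' term variance and the residual variance from scaled-inverse-chi-squared
#' full conditionals. Records excluded from `train` contribute nothing to the
#' likelihood; their predictions are the fixed part plus every term's
#' conditional effect propagated through the term covariance
#' (`K[test, train] U S^-1 b`), averaged over saved draws.
#'
#' The fixed design is rebuilt on the training records (intercept +
#' reference-coded indicators of the environments present in training). For a
#' record in an environment absent from training (new-environment
#' prediction), the fixed part is the average of the training environments'
#' fixed values, and only W/AW/DW terms carry environment-specific signal.
#'
#' @param term_set an [build_model()] result.
#' @param config an [mcmc_config()].
#' @param train logical or integer index of training records (default: all).
#' @param eigen_cache optional precomputed training-block eigendecompositions
#'   (named by term, as produced internally), reused across models sharing
#'   terms on the same training set; validated against the term names.
#' @return object of class `met_fit`; see [predict.met_fit()],
#'   [variance_partition()].
#' @export
gibbs_fit <- function(term_set, config = mcmc_config(), train = NULL,
                      eigen_cache = NULL) {
  stopifnot(inherits(term_set, "effect_term_set"),
            inherits(config, "mcmc_config"))
  ph <- term_set$phenotypes
  n_all <- ph$n
  train <- train %||% rep(TRUE, n_all)
  if (!is.logical(train)) {
    tr <- rep(FALSE, n_all); tr[train] <- TRUE; train <- tr
  }
  if (!any(train)) stop("empty training set", call. = FALSE)
  idx_tr <- which(train); idx_te <- which(!train)
  y <- ph$records$value[idx_tr]
  n <- length(y)
  ev_tr <- term_set$env_idx[idx_tr]; gv_tr <- term_set$gid_idx[idx_tr]

  # fixed design on the environments present in training
  env_tr <- droplevels(factor(ph$envs[ev_tr], levels = ph$envs))
  X <- env_design(env_tr)
  k <- ncol(X)
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e)
    stop("numerically singular fixed design", call. = FALSE))

  if (!is.null(eigen_cache)) {
    if (!all(names(term_set$terms) %in% names(eigen_cache)))
      stop("eigen_cache lacks terms: ",
           paste(setdiff(names(term_set$terms), names(eigen_cache)),
                 collapse = ", "), call. = FALSE)
    eig <- eigen_cache[names(term_set$terms)]
  } else {
    eig <- lapply(term_set$terms, eigen_term, ev_idx = ev_tr, gv_idx = gv_tr,
                  tol = config$eigen_tol)
  }
  tnames <- names(term_set$terms)
  n_terms <- length(eig)

  sc_u <- config$sc_u %||% (stats::var(y) / 2)
  sc_e <- config$sc_e %||% (stats::var(y) / 2)
  nu_u <- config$nu_u; nu_e <- config$nu_e

  n_saved <- (config$iterations - config$burn_in) %/% config$thin
  var_samples <- matrix(NA_real_, n_saved, n_terms + 1L,
                        dimnames = list(NULL, c(tnames, "residual")))
  beta_samples <- matrix(NA_real_, n_saved, k,
                         dimnames = list(NULL, colnames(X)))
  b_mean <- lapply(eig, function(e) numeric(e$r))

  fixed_v <- config$fix_variances %||% numeric(0)
  if (length(fixed_v) && (is.null(names(fixed_v)) ||
      !all(names(fixed_v) %in% c(tnames, "residual"))))
    stop("fix_variances names must be term names or 'residual'",
         call. = FALSE)

  with_seed(config$seed, {
    sigma2 <- stats::setNames(rep(sc_u, n_terms), tnames)
    sigma2_e <- sc_e
    fix_t <- intersect(names(fixed_v), tnames)
    sigma2[fix_t] <- fixed_v[fix_t]
    fix_e <- "residual" %in% names(fixed_v)
    if (fix_e) sigma2_e <- fixed_v[["residual"]]
    beta <- drop(backsolve(R, backsolve(R, crossprod(X, y),
                                        transpose = TRUE)))
    u <- lapply(eig, function(e) numeric(n))
    b <- lapply(eig, function(e) numeric(e$r))
    e_res <- y - drop(X %*% beta)
    saved <- 0L
    for (iter in seq_len(config$iterations)) {
      # fixed effects
      r_f <- e_res + drop(X %*% beta)
      m_b <- backsolve(R, backsolve(R, crossprod(X, r_f), transpose = TRUE))
      beta <- drop(m_b) + sqrt(sigma2_e) *
        drop(backsolve(R, stats::rnorm(k)))
      e_res <- r_f - drop(X %*% beta)
      # random terms in the eigenbasis
      for (t in seq_len(n_terms)) {
        s <- eig[[t]]$values; U <- eig[[t]]$vectors
        r_t <- e_res + u[[t]]
        d <- drop(crossprod(U, r_t))
        cvar <- 1 / (1 / sigma2_e + 1 / (sigma2[t] * s))
        b_t <- cvar * d / sigma2_e +
          sqrt(cvar) * stats::rnorm(length(s))
        u_t <- drop(U %*% b_t)
        e_res <- r_t - u_t
        b[[t]] <- b_t
        u[[t]] <- u_t
        if (!tnames[t] %in% fix_t)
          sigma2[t] <- (nu_u * sc_u + sum(b_t^2 / s)) /
            stats::rchisq(1L, nu_u + length(s))
      }
      if (!fix_e)
        sigma2_e <- (nu_e * sc_e + sum(e_res^2)) /
          stats::rchisq(1L, nu_e + n)
      if (iter > config$burn_in &&
          (iter - config$burn_in) %% config$thin == 0L) {
        saved <- saved + 1L
        var_samples[saved, ] <- c(sigma2, sigma2_e)
        beta_samples[saved, ] <- beta
        for (t in seq_len(n_terms))
          b_mean[[t]] <- b_mean[[t]] + (b[[t]] - b_mean[[t]]) / saved
      }
    }
  })

  beta_mean <- colMeans(beta_samples)
  var_mean <- colMeans(var_samples)
  u_hat <- lapply(seq_len(n_terms), function(t)
    drop(eig[[t]]$vectors %*% b_mean[[t]]))
  names(u_hat) <- tnames

  # per-environment fixed values on the training design
  present <- levels(env_tr)
  ef <- stats::setNames(rep(beta_mean[1L], length(present)), present)
  if (length(present) > 1L)
    ef[-1L] <- ef[-1L] + beta_mean[-1L]
  env_fixed <- stats::setNames(rep(mean(ef), ph$q), ph$envs)
  env_fixed[present] <- ef

  fitted_tr <- unname(env_fixed[ph$envs[ev_tr]]) +
    Reduce(`+`, u_hat, numeric(n))
  yhat <- rep(NA_real_, n_all)
  yhat[idx_tr] <- fitted_tr

  fit <- structure(
    list(model = term_set$model, term_set = term_set, config = config,
         train = train, eig = eig, b_mean = b_mean, u_hat = u_hat,
         beta_samples = beta_samples, var_samples = var_samples,
         beta_mean = beta_mean, var_mean = var_mean, env_fixed = env_fixed,
         fitted = fitted_tr, yhat = yhat, n_train = n,
         n_saved = n_saved),
    class = "met_fit")

  if (length(idx_te)) {
    preds <- predict_records(fit, idx_te)
    fit$yhat[idx_te] <- preds
    fit$predictions <- data.frame(
      ph$records[idx_te, c("env", "gid")], predicted = preds,
      observed = ph$records$value[idx_te])
  }
  fit$diagnostics <- chain_diagnostics(var_samples)
  fit
}

# Simple split-chain summaries and autocorrelation-based effective sample
# sizes for the variance chains.
#' @noRd
chain_diagnostics <- function(var_samples) {
  n <- nrow(var_samples)
  half <- n %/% 2L
  ess <- function(x) {
    if (stats::sd(x) == 0) return(length(x))
    ac <- stats::acf(x, plot = FALSE,
                     lag.max = min(length(x) - 1L, 200L))$acf[-1L]
    pos <- which(ac < 0)
    if (length(pos)) ac <- ac[seq_len(pos[1L] - 1L)]
    max(1, length(x) / (1 + 2 * sum(ac)))
  }
  data.frame(
    component = colnames(var_samples),
    mean_first_half = colMeans(var_samples[seq_len(half), , drop = FALSE]),
    mean_second_half = colMeans(var_samples[(half + 1L):n, , drop = FALSE]),
    ess = apply(var_samples, 2L, ess),
    row.names = NULL)
}

# Conditional predictions for record indices of the phenotype table: fixed
# part + sum over terms of K[target, train] U S^-1 b_mean.
#' @noRd
predict_records <- function(fit, idx) {
  ts <- fit$term_set
  idx_tr <- which(fit$train)
  ev <- ts$env_idx; gv <- ts$gid_idx
  out <- unname(fit$env_fixed[ts$phenotypes$envs[ev[idx]]])
  for (t in seq_along(ts$terms)) {
    term <- ts$terms[[t]]
    K_ts <- term$env_cov[ev[idx], ev[idx_tr], drop = FALSE] *
      term$geno_cov[gv[idx], gv[idx_tr], drop = FALSE]
    proj <- sweep(K_ts %*% fit$eig[[t]]$vectors, 2L, fit$eig[[t]]$values, `/`)
    out <- out + unname(drop(proj %*% fit$b_mean[[t]]))
  }
  out
}

#' Predict phenotypes for hybrid-environment combinations
#'
#' Computes `mu + beta_env + sum of conditional term effects` for the
#' requested records. With `newdata = NULL`, returns the fitted/predicted
#' values of every record of the phenotype table the model was built on
#' (fitted values for training records, conditional predictions for masked
#' ones). `newdata` may name any hybrid with a kernel row and any environment
#' of the table; unknown hybrids are an error.
#'
#' @param object a [gibbs_fit()] result.
#' @param newdata optional data frame with columns `env` and `gid`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.met_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$yhat)
  ph <- object$term_set$phenotypes
  ev <- match(as.character(newdata$env), ph$envs)
  gv <- match(as.character(newdata$gid), ph$gids)
  if (anyNA(gv))
    stop("unknown hybrid(s) without kernel rows: ",
         paste(unique(newdata$gid[is.na(gv)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(ev))
    stop("unknown environment(s): ",
         paste(unique(newdata$env[is.na(ev)]), collapse = ", "),
         call. = FALSE)
  ts <- object$term_set
  idx_tr <- which(object$train)
  out <- unname(object$env_fixed[ph$envs[ev]])
  for (t in seq_along(ts$terms)) {
    term <- ts$terms[[t]]
    K_ts <- term$env_cov[ev, ts$env_idx[idx_tr], drop = FALSE] *
      term$geno_cov[gv, ts$gid_idx[idx_tr], drop = FALSE]
    proj <- sweep(K_ts %*% object$eig[[t]]$vectors, 2L,
                  object$eig[[t]]$values, `/`)
    out <- out + unname(drop(proj %*% object$b_mean[[t]]))
  }
  out
}

#' @export
print.met_fit <- function(x, ...) {
  cat("met_fit: model", x$model, "on", x$n_train, "training records (",
      x$n_saved, "saved draws )\n")
  cat("posterior-mean variance components:\n")
  print(signif(x$var_mean, 4))
  invisible(x)
}

#' Posterior variance partition
#'
#' Proportion of the total posterior-mean variance attributed to each model
#' term (residual included); proportions sum to one.
#'
#' @param fit a [gibbs_fit()] result.
#' @return named numeric vector of proportions.
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "met_fit"))
  fit$var_mean / sum(fit$var_mean)
}
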