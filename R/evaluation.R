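# Cross-validation schemes, predictive-ability statistics, and the
# model x kernel x scheme evaluation grid.

#' Build cross-validation folds
#'
#' Three schemes mirror the prediction problems of hybrid MET breeding:
#' \describe{
#'   \item{CV1}{untested hybrids: each repetition samples
#'     `ceiling(train_fraction * p)` hybrids; training is all of their
#'     records, the test set is every record of the remaining hybrids.}
#'   \item{CV2}{sparse testing: each repetition samples
#'     `ceiling(train_fraction * n)` records uniformly as training.}
#'   \item{CV0}{new environments: deterministic leave-one-environment-out,
#'     one fold per environment.}
#' }
#'
#' @param phenotypes a [phenotype_table()].
#' @param scheme `"CV1"`, `"CV2"` or `"CV0"`.
#' @param repetitions number of random repetitions for CV1/CV2 (default 50;
#'   ignored for CV0).
#' @param train_fraction fraction of hybrids (CV1) or records (CV2) in
#'   training (default 0.7).
#' @param seed RNG seed for the random schemes.
#' @return object of class `cv_plan`: list with `scheme`, `folds` (each a
#'   list with integer `train` and `test` record indices), `train_fraction`.
#' @export
make_folds <- function(phenotypes, scheme = c("CV1", "CV2", "CV0"),
                       repetitions = 50L, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(phenotypes, "phenotype_table"))
  scheme <- match.arg(scheme)
  n <- phenotypes$n; p <- phenotypes$p; q <- phenotypes$q
  folds <- switch(scheme,
    CV1 = {
      if (p < 2L) stop("CV1 needs at least 2 hybrids", call. = FALSE)
      n_train_h <- ceiling(train_fraction * p)
      if (n_train_h >= p)
        stop("CV1: train_fraction leaves no test hybrids", call. = FALSE)
      with_seed(seed, lapply(seq_len(repetitions), function(r) {
        hyb <- sample.int(p, n_train_h)
        tr <- which(as.integer(phenotypes$gid) %in% hyb)
        list(train = tr, test = setdiff(seq_len(n), tr))
      }))
    },
    CV2 = {
      if (n < 2L) stop("CV2 needs at least 2 records", call. = FALSE)
      n_train <- ceiling(train_fraction * n)
      if (n_train >= n)
        stop("CV2: train_fraction leaves no test records", call. = FALSE)
      with_seed(seed, lapply(seq_len(repetitions), function(r) {
        tr <- sort(sample.int(n, n_train))
        list(train = tr, test = setdiff(seq_len(n), tr))
      }))
    },
    CV0 = {
      if (q < 2L) stop("CV0 needs at least 2 environments", call. = FALSE)
      lapply(seq_len(q), function(e) {
        te <- which(as.integer(phenotypes$env) == e)
        list(train = setdiff(seq_len(n), te), test = te,
             env = phenotypes$envs[e])
      })
    })
  structure(list(scheme = scheme, folds = folds,
                 train_fraction = train_fraction, n = n, p = p, q = q),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("cv_plan:", x$scheme, "with", length(x$folds), "fold(s);",
      "train sizes", paste(range(vapply(x$folds, function(f)
        length(f$train), integer(1))), collapse = "-"), "\n")
  invisible(x)
}

# Pearson correlation that returns NA (instead of an error) when either
# vector is constant or too short; used as the PA primitive.
#' @noRd
pa_cor <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(observed[ok]) == 0 || stats::sd(predicted[ok]) == 0)
    return(NA_real_)
  stats::cor(observed[ok], predicted[ok])
}

#' Predictive ability (Pearson correlation)
#'
#' Without `grouping`: a single Pearson correlation between observed and
#' predicted values. With `grouping` (e.g. the left-out environment in CV0,
#' or the hybrid ID for genotype-level resolution): one correlation per
#' group plus their average. Groups with zero variance or fewer than three
#' pairs are recorded as `NA`, logged, and excluded from the average (never
#' coerced to zero).
#'
#' @param observed,predicted aligned numeric vectors.
#' @param grouping optional vector of group labels.
#' @return a single correlation, or (with grouping) a list with `per_group`,
#'   `mean`, and `excluded` (labels of undefined groups).
#' @export
predictive_ability <- function(observed, predicted, grouping = NULL) {
  stopifnot(length(observed) == length(predicted))
  if (is.null(grouping)) return(pa_cor(observed, predicted))
  g <- factor(grouping)
  per <- vapply(levels(g), function(l) {
    i <- g == l
    pa_cor(observed[i], predicted[i])
  }, numeric(1))
  excluded <- names(per)[is.na(per)]
  if (length(excluded))
    message("predictive_ability: undefined correlation for group(s) ",
            paste(excluded, collapse = ", "), " (excluded from average)")
  list(per_group = per, mean = mean(per, na.rm = TRUE), excluded = excluded)
}

#' Standard error of a mean predictive ability
#'
#' Applies the Bouckaert-Frank style correction
#' `SE = SD * sqrt(1/n + n2/n1)` where `SD` is the standard deviation of the
#' per-fold correlations, `n = p*q` is the number of records, and `n1`, `n2`
#' are the training and test sizes.
#'
#' @param per_fold_pa vector of per-fold correlations (length >= 2).
#' @param n total number of records.
#' @param n1,n2 training and test sizes.
#' @return the standard error (scalar).
#' @export
standard_error <- function(per_fold_pa, n, n1, n2) {
  if (n1 <= 0) stop("training size n1 must be positive", call. = FALSE)
  if (length(per_fold_pa) < 2L)
    stop("need at least two folds to compute a standard error", call. = FALSE)
  stats::sd(per_fold_pa, na.rm = TRUE) * sqrt(1 / n + n2 / n1)
}

#' Typology of per-hybrid predictive abilities
#'
#' Bins genotype-level correlations into
#' `<= 0, (0, 0.25], (0.25, 0.50], (0.50, 0.75], (0.75, 1]` and reports
#' counts and relative frequencies.
#'
#' @param per_hybrid_pa numeric vector of per-hybrid correlations.
#' @return data frame with columns `bin`, `count`, `frequency`.
#' @export
pa_typology <- function(per_hybrid_pa) {
  x <- per_hybrid_pa[!is.na(per_hybrid_pa)]
  breaks <- c(-Inf, 0, 0.25, 0.5, 0.75, 1)
  labels <- c("<=0", "(0,0.25]", "(0.25,0.50]", "(0.50,0.75]", "(0.75,1]")
  counts <- table(cut(x, breaks = breaks, labels = labels, right = TRUE))
  data.frame(bin = labels, count = as.integer(counts),
             frequency = as.integer(counts) / max(length(x), 1L),
             stringsAsFactors = FALSE)
}

#' Evaluate the model x kernel x cross-validation grid
#'
#' Runs every combination of model structure, kernel method and CV scheme on
#' one data set: builds the additive, dominance and envirotype kernels with
#' each method (optionally re-selecting the GK bandwidth and DK layer count
#' per fold from the training records), fits each model with the Gibbs
#' sampler, and collects predictive abilities. For CV0 the per-record
#' predictions are pooled across folds and summarized per hybrid (resolution
#' analysis).
#'
#' @param phenotypes a [phenotype_table()].
#' @param genotypes a [genotype_table()] covering every hybrid of
#'   `phenotypes`.
#' @param W an `env_covariable_matrix` (or plain scaled matrix) whose rows
#'   match `phenotypes$envs`.
#' @param models model names (default: all five).
#' @param kernels kernel methods (default `c("GB", "GK", "DK")`).
#' @param schemes CV schemes (default all three).
#' @param mcmc an [mcmc_config()].
#' @param repetitions CV1/CV2 repetitions (default 50).
#' @param train_fraction training fraction (default 0.7).
#' @param seed seed for fold construction and chain seeds.
#' @param tune hyperparameter selection: `"per_fold"` (default) re-selects
#'   `h` and `l` on each fold's training records, `"once"` selects them once
#'   from all records, `"none"` uses `h = 1`, `layers = 1`.
#' @param l_max largest DK layer count considered.
#' @return object of class `met_grid`: list with `table` (long-format
#'   results: model, kernel, scheme, pa_mean, pa_se, gain_pct vs the EA
#'   baseline of the same kernel and scheme), `per_hybrid` (CV0 per-hybrid PA
#'   matrix), `typology` (per model-kernel CV0 typology).
#' @export
run_grid <- function(phenotypes, genotypes, W,
                     models = names(met_model_terms()),
                     kernels = c("GB", "GK", "DK"),
                     schemes = c("CV1", "CV2", "CV0"),
                     mcmc = mcmc_config(), repetitions = 50L,
                     train_fraction = 0.7, seed = 1L,
                     tune = c("per_fold", "once", "none"), l_max = 5L) {
  stopifnot(inherits(phenotypes, "phenotype_table"),
            inherits(genotypes, "genotype_table"))
  tune <- match.arg(tune)
  if (inherits(W, "env_covariable_matrix")) W <- W$values
  if (!all(phenotypes$gids %in% genotypes$ids))
    stop("phenotype hybrids missing from the genotype table", call. = FALSE)
  if (!all(phenotypes$envs %in% rownames(W)))
    stop("phenotype environments missing from W", call. = FALSE)
  # align entity order with the phenotype table
  geno <- genotype_table(
    genotypes$dosage[phenotypes$gids, , drop = FALSE])
  A <- additive_design(geno)
  Dm <- dominance_design(geno)
  Wm <- as.matrix(W)[phenotypes$envs, , drop = FALSE]
  catalog <- met_model_terms()
  stopifnot(all(models %in% names(catalog)))

  rows <- list()
  per_hybrid <- list()
  typology <- list()
  env_i <- as.integer(phenotypes$env)
  gid_i <- as.integer(phenotypes$gid)

  entity_means <- function(train_idx) {
    yh <- rep(NA_real_, phenotypes$p)
    ye <- rep(NA_real_, phenotypes$q)
    tg <- tapply(phenotypes$records$value[train_idx], gid_i[train_idx], mean)
    yh[as.integer(names(tg))] <- tg
    te <- tapply(phenotypes$records$value[train_idx], env_i[train_idx], mean)
    ye[as.integer(names(te))] <- te
    list(hyb = yh, env = ye)
  }
  make_kernels <- function(method, ym) {
    if (method == "GK" && tune != "none") {
      list(A = gk_kernel(A, select_bandwidth(A, ym$hyb)),
           D = gk_kernel(Dm, select_bandwidth(Dm, ym$hyb)),
           W = gk_kernel(Wm, select_bandwidth(Wm, ym$env)))
    } else if (method == "DK" && tune != "none") {
      # mean-diagonal normalization: exact scalar reparameterization that
      # aligns the arc-cosine kernel (diagonal ~ ||x||^2, i.e. the number of
      # covariables) with the data-driven prior scale of the sampler, while
      # preserving the kernel's relative diagonal heterogeneity
      list(A = normalize_kernel(dk_kernel(A, select_layers(A, ym$hyb, l_max))),
           D = normalize_kernel(dk_kernel(Dm, select_layers(Dm, ym$hyb,
                                                            l_max))),
           W = normalize_kernel(dk_kernel(Wm, select_layers(Wm, ym$env,
                                                            l_max))))
    } else {
      norm <- if (method == "DK") normalize_kernel else identity
      list(A = norm(build_kernel(A, method)),
           D = norm(build_kernel(Dm, method)),
           W = norm(build_kernel(Wm, method)))
    }
  }
  ym_all <- entity_means(seq_len(phenotypes$n))

  for (scheme in schemes) {
    plan <- make_folds(phenotypes, scheme, repetitions = repetitions,
                       train_fraction = train_fraction, seed = seed)
    for (kern in kernels) {
      t0 <- proc.time()[["elapsed"]]
      if (tune != "per_fold") K_fixed <- make_kernels(kern, ym_all)
      fold_pa <- matrix(NA_real_, length(plan$folds), length(models),
                        dimnames = list(NULL, models))
      cv0_pred <- if (scheme == "CV0")
        matrix(NA_real_, phenotypes$n, length(models),
               dimnames = list(NULL, models))
      for (f in seq_along(plan$folds)) {
        fold <- plan$folds[[f]]
        Ks <- if (tune == "per_fold") make_kernels(kern, entity_means(fold$train))
              else K_fixed
        # eigendecompose each distinct term once per fold, share across models
        all_terms <- unique(unlist(catalog[models]))
        master <- build_terms(all_terms, Ks, phenotypes)
        ev_tr <- env_i[fold$train]; gv_tr <- gid_i[fold$train]
        cache <- lapply(master, eigen_term, ev_idx = ev_tr, gv_idx = gv_tr,
                        tol = mcmc$eigen_tol)
        for (m in seq_along(models)) {
          ts <- build_model(models[m], phenotypes, Ks$A, Ks$D, Ks$W)
          cfg <- mcmc
          cfg$seed <- if (is.null(mcmc$seed)) NULL else
            mcmc$seed + 1000L * f + m
          fit <- gibbs_fit(ts, cfg, train = fold$train,
                           eigen_cache = cache[names(ts$terms)])
          obs <- phenotypes$records$value[fold$test]
          fold_pa[f, m] <- pa_cor(obs, fit$yhat[fold$test])
          if (scheme == "CV0")
            cv0_pred[fold$test, m] <- fit$yhat[fold$test]
        }
      }
      for (m in seq_along(models)) {
        n1 <- mean(vapply(plan$folds, function(x) length(x$train), numeric(1)))
        n2 <- mean(vapply(plan$folds, function(x) length(x$test), numeric(1)))
        rows[[length(rows) + 1L]] <- data.frame(
          model = models[m], kernel = kern, scheme = scheme,
          pa_mean = mean(fold_pa[, m], na.rm = TRUE),
          pa_se = if (length(plan$folds) > 1L)
            standard_error(fold_pa[, m], phenotypes$n, n1, n2) else NA_real_,
          stringsAsFactors = FALSE)
      }
      if (scheme == "CV0") {
        for (m in seq_along(models)) {
          key <- paste(models[m], kern, sep = ".")
          ph_pa <- vapply(seq_len(phenotypes$p), function(i) {
            sel <- gid_i == i
            pa_cor(phenotypes$records$value[sel], cv0_pred[sel, m])
          }, numeric(1))
          names(ph_pa) <- phenotypes$gids
          per_hybrid[[key]] <- ph_pa
          typology[[key]] <- pa_typology(ph_pa)
        }
      }
      message(sprintf("run_grid: %s / %s done in %.1fs", scheme, kern,
                      proc.time()[["elapsed"]] - t0))
    }
  }
  table <- do.call(rbind, rows)
  # percent gain vs the EA baseline of the same kernel and scheme
  table$gain_pct <- NA_real_
  if ("EA" %in% models) {
    for (i in seq_len(nrow(table))) {
      base <- table$pa_mean[table$model == "EA" &
                              table$kernel == table$kernel[i] &
                              table$scheme == table$scheme[i]]
      if (length(base) == 1L && is.finite(base) && base != 0)
        table$gain_pct[i] <- 100 * (table$pa_mean[i] - base) / abs(base)
    }
  }
  structure(list(table = table, per_hybrid = per_hybrid,
                 typology = typology),
            class = "met_grid")
}

# Factored random-effect terms for an arbitrary term-name set (superset of
# what build_model() assembles for one model).
#' @noRd
build_terms <- function(term_names, Ks, phenotypes) {
  q <- phenotypes$q; p <- phenotypes$p
  J_q <- matrix(1, q, q); J_p <- matrix(1, p, p); I_q <- diag(q)
  maker <- list(
    A  = function() new_term("A", J_q, as.matrix(Ks$A)),
    D  = function() new_term("D", J_q, as.matrix(Ks$D)),
    W  = function() new_term("W", as.matrix(Ks$W), J_p),
    AE = function() new_term("AE", I_q, as.matrix(Ks$A)),
    DE = function() new_term("DE", I_q, as.matrix(Ks$D)),
    AW = function() new_term("AW", as.matrix(Ks$W), as.matrix(Ks$A)),
    DW = function() new_term("DW", as.matrix(Ks$W), as.matrix(Ks$D)))
  out <- lapply(term_names, function(t) maker[[t]]())
  names(out) <- term_names
  out
}

#' @export
print.met_grid <- function(x, ...) {
  cat("met_grid results:\n")
  print(x$table, digits = 3)
  invisible(x)
}
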