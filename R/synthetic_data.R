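# Synthetic single-cross MET experiments: genotypes, weather, phenotypes.

#' Configuration of a synthetic MET experiment
#'
#' Describes the simulated world: fully inbred parental lines crossed into F1
#' hybrids, a panel of biallelic markers, q trial environments with daily
#' weather series over one crop cycle, and phenotypes generated from the
#' additive + dominance + envirotype reaction-norm model with user-chosen
#' variance components.
#'
#' @param n_parents number of inbred parental lines.
#' @param n_hybrids number of F1 hybrids (distinct parent pairs); must not
#'   exceed `n_parents * (n_parents - 1) / 2`.
#' @param n_markers number of biallelic SNP markers.
#' @param maf_range interval in (0, 0.5] from which per-marker allele
#'   frequencies are drawn.
#' @param n_environments number of trial environments.
#' @param days crop-cycle length in days after emergence; default 120, the
#'   span of the default phenology intervals.
#' @param variance_components named non-negative variances for the terms
#'   `A, D, W, AE, DE, AW, DW, residual`; `residual` must be positive. Terms
#'   may be omitted (treated as zero).
#' @param mu grand mean of the trait (t/ha).
#' @param env_fixed_effects per-environment fixed offsets (length
#'   `n_environments`); default: evenly spaced on \[-1, 1\] t/ha.
#' @param nonlinear add pairwise multiplicative marker-interaction signal to
#'   the genetic value (off by default)?
#' @param nonlinear_variance target variance of that epistatic signal.
#' @param seed RNG seed (the weather and phenotype generators use offsets of
#'   it so the three generators draw from distinct streams).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 30, n_hybrids = 100, n_markers = 1000,
                       maf_range = c(0.1, 0.5), n_environments = 5,
                       days = 120,
                       variance_components = c(A = 1, D = 0.5, W = 0.5,
                                               AE = 0.5, DE = 0.25,
                                               AW = 0.25, DW = 0.25,
                                               residual = 1),
                       mu = 7, env_fixed_effects = NULL,
                       nonlinear = FALSE, nonlinear_variance = 0.25,
                       seed = 1L) {
  stopifnot(n_parents >= 2, n_markers >= 1, n_environments >= 1, days >= 1)
  max_crosses <- n_parents * (n_parents - 1) / 2
  if (n_hybrids > max_crosses)
    stop("n_hybrids (", n_hybrids, ") exceeds the number of distinct crosses ",
         "n_parents*(n_parents-1)/2 = ", max_crosses, call. = FALSE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval inside (0, 0.5]", call. = FALSE)
  all_terms <- c("A", "D", "W", "AE", "DE", "AW", "DW", "residual")
  vc <- stats::setNames(numeric(length(all_terms)), all_terms)
  if (is.null(names(variance_components)) ||
      !all(names(variance_components) %in% all_terms))
    stop("variance_components must be named among: ",
         paste(all_terms, collapse = ", "), call. = FALSE)
  vc[names(variance_components)] <- variance_components
  if (any(vc < 0)) stop("variances must be non-negative", call. = FALSE)
  if (vc["residual"] <= 0) stop("residual variance must be > 0", call. = FALSE)
  env_fixed_effects <- env_fixed_effects %||%
    (if (n_environments == 1) 0 else seq(-1, 1, length.out = n_environments))
  if (length(env_fixed_effects) != n_environments)
    stop("env_fixed_effects must have length n_environments", call. = FALSE)
  structure(
    list(n_parents = as.integer(n_parents), n_hybrids = as.integer(n_hybrids),
         n_markers = as.integer(n_markers), maf_range = maf_range,
         n_environments = as.integer(n_environments), days = as.integer(days),
         variance_components = vc, mu = mu,
         env_fixed_effects = env_fixed_effects,
         nonlinear = isTRUE(nonlinear),
         nonlinear_variance = nonlinear_variance,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate parental lines and F1 hybrid genotypes
#'
#' Parents are fully inbred (homozygous) lines: at each marker the parental
#' allele is drawn with a frequency sampled uniformly from `maf_range`. Each
#' hybrid is a distinct cross of two parents, so its dosage is the
#' deterministic sum of the two parental alleles and always lies in
#' `{0, 1, 2}`. Markers that end up monomorphic across the sampled hybrids
#' are redrawn, so every marker segregates (as in a post-QC marker panel).
#'
#' @param config a [sim_config()].
#' @return a [genotype_table()] with the parent pairs recorded in `$parents`
#'   and the parental allele matrix in attribute `parent_alleles`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    np <- config$n_parents; m <- config$n_markers
    pairs <- t(utils::combn(np, 2))
    sel <- pairs[sample.int(nrow(pairs), config$n_hybrids), , drop = FALSE]
    f <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    # parental alleles: np x m in {0,1}; redraw markers monomorphic in hybrids
    P <- matrix(stats::rbinom(np * m, 1L, rep(f, each = np)), np, m)
    dosage <- P[sel[, 1], , drop = FALSE] + P[sel[, 2], , drop = FALSE]
    for (it in 1:100) {
      mono <- colSums(dosage) %in% c(0L, 2L * nrow(dosage))
      if (!any(mono)) break
      P[, mono] <- stats::rbinom(np * sum(mono), 1L,
                                 rep(f[mono], each = np))
      dosage[, mono] <- P[sel[, 1], mono, drop = FALSE] +
        P[sel[, 2], mono, drop = FALSE]
    }
    ids <- paste0("H", formatC(seq_len(config$n_hybrids),
                               width = nchar(config$n_hybrids), flag = "0"))
    parent_ids <- paste0("P", seq_len(np))
    rownames(P) <- parent_ids
    colnames(P) <- paste0("m", seq_len(m))
    parents <- data.frame(hybrid = ids,
                          parent1 = parent_ids[sel[, 1]],
                          parent2 = parent_ids[sel[, 2]],
                          stringsAsFactors = FALSE)
    dimnames(dosage) <- list(ids, colnames(P))
    out <- genotype_table(dosage, ids = ids, parents = parents)
    attr(out, "parent_alleles") <- P
    out
  })
}

# Variable schema of the daily environmental tables: 16 weather and derived
# ecophysiological factors with plausible base levels, seasonal amplitudes
# and day-to-day noise scales (units are irrelevant downstream because every
# covariable is centered and scaled).
#' @noRd
env_variable_schema <- function() {
  data.frame(
    name = c("insolation_toa", "insolation_surface", "longwave_flux",
             "wind_speed_10m", "temp_min_2m", "temp_max_2m", "dewpoint_2m",
             "rel_humidity", "precipitation", "temp_rue_effect", "etp",
             "water_deficit", "vpd", "svp_slope", "temp_range",
             "solar_radiation"),
    base = c(35, 20, 30, 2.5, 18, 30, 16, 70, 5, 0.8, 4.5, 0.5, 1.2, 0.18,
             12, 22),
    amp = c(5, 4, 3, 0.8, 4, 4, 3, 10, 3, 0.15, 1.2, 2, 0.4, 0.04, 3, 4),
    noise = c(1, 2, 1.5, 0.6, 1.5, 1.5, 1.5, 5, 4, 0.08, 0.8, 2, 0.25, 0.02,
              1.5, 2),
    stringsAsFactors = FALSE)
}

#' Simulate per-environment daily weather tables
#'
#' Each of the 16 environmental variables is built as a seasonal sinusoid
#' plus an environment-specific offset plus Gaussian day-to-day noise --
#' minimal structure sufficient to give environments distinguishable
#' envirotypes.
#'
#' @param config a [sim_config()].
#' @param env_offsets optional q x 16 matrix of environment offsets on the
#'   per-variable noise scale (default: drawn `N(0, offset_sd)`).
#' @param offset_sd spread of the drawn environment offsets, in per-variable
#'   noise-scale units (default 2).
#' @param noise_sd day-to-day noise multiplier (default 1; 0 gives
#'   deterministic series).
#' @return named list of data frames (one per environment `E1..Eq`), each
#'   with a `day` column and the 16 variable columns.
#' @export
simulate_weather <- function(config, env_offsets = NULL, offset_sd = 2,
                             noise_sd = 1) {
  stopifnot(inherits(config, "sim_config"))
  schema <- env_variable_schema()
  q <- config$n_environments
  nv <- nrow(schema)
  with_seed(config$seed + 1L, {
    if (is.null(env_offsets))
      env_offsets <- matrix(stats::rnorm(q * nv, 0, offset_sd), q, nv)
    if (!is.matrix(env_offsets))
      env_offsets <- matrix(env_offsets, q, nv)
    stopifnot(nrow(env_offsets) == q, ncol(env_offsets) == nv)
    days <- seq_len(config$days)
    season <- sin(2 * pi * (days + 30) / 365)
    envs <- paste0("E", seq_len(q))
    out <- lapply(seq_len(q), function(e) {
      tab <- data.frame(day = days)
      for (v in seq_len(nv)) {
        tab[[schema$name[v]]] <- schema$base[v] + schema$amp[v] * season +
          env_offsets[e, v] * schema$noise[v] +
          stats::rnorm(config$days, 0, noise_sd * schema$noise[v])
      }
      tab
    })
    names(out) <- envs
    out
  })
}

#' Simulate phenotypes from the additive/dominance/reaction-norm model
#'
#' Generates one record per hybrid-environment combination:
#' `y = mu + beta_env + u_A + u_D + u_W + u_AE + u_DE + u_AW + u_DW + e`,
#' where each random vector is drawn from a zero-mean multivariate normal
#' with covariance (term kernel expansion) x (term variance), restricted to
#' terms with positive configured variance, and `e` is iid with the residual
#' variance. Returns the records together with the ground truth (every term's
#' observation-level effect vector and the configured variances).
#'
#' @param genotypes a [genotype_table()] with `config$n_hybrids` hybrids.
#' @param kernels named list with entries `A`, `D` (p x p) and `W` (q x q) as
#'   required by the positive-variance terms.
#' @param config a [sim_config()].
#' @return list with `phenotypes` (a [phenotype_table()]) and `truth` (list:
#'   `effects` per term, `variances`, `mu`, `beta`, `genetic_value`).
#' @export
simulate_phenotypes <- function(genotypes, kernels, config) {
  stopifnot(inherits(genotypes, "genotype_table"),
            inherits(config, "sim_config"))
  p <- nrow(genotypes$dosage)
  q <- config$n_environments
  vc <- config$variance_components
  envs <- paste0("E", seq_len(q))
  records <- expand.grid(gid = genotypes$ids, env = envs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  records <- records[, c("env", "gid")]
  n <- nrow(records)
  active <- setdiff(names(vc)[vc > 0], "residual")
  need_kernel <- list(A = "A", D = "D", W = "W", AE = "A", DE = "D",
                      AW = c("A", "W"), DW = c("D", "W"))
  for (t in active) {
    for (k in need_kernel[[t]]) {
      if (is.null(kernels[[k]]))
        stop("term ", t, " has positive variance but kernel ", k,
             " is missing", call. = FALSE)
    }
  }
  check_sq <- function(K, d, what) {
    K <- as.matrix(K)
    if (nrow(K) != d || ncol(K) != d)
      stop("kernel ", what, " must be ", d, " x ", d, call. = FALSE)
    assert_psd(K, what = what)
    K
  }
  J_q <- matrix(1, q, q); J_p <- matrix(1, p, p); I_q <- diag(q)
  factors <- list(
    A  = function() list(E = J_q, G = check_sq(kernels$A, p, "A")),
    D  = function() list(E = J_q, G = check_sq(kernels$D, p, "D")),
    W  = function() list(E = check_sq(kernels$W, q, "W"), G = J_p),
    AE = function() list(E = I_q, G = check_sq(kernels$A, p, "A")),
    DE = function() list(E = I_q, G = check_sq(kernels$D, p, "D")),
    AW = function() list(E = check_sq(kernels$W, q, "W"),
                         G = check_sq(kernels$A, p, "A")),
    DW = function() list(E = check_sq(kernels$W, q, "W"),
                         G = check_sq(kernels$D, p, "D")))
  with_seed(config$seed + 2L, {
    effects <- list()
    y <- rep(config$mu, n) + config$env_fixed_effects[
      match(records$env, envs)]
    for (t in active) {
      fac <- factors[[t]]()
      # records are env-major with hybrids fastest, so the observation-level
      # covariance is E (x) G and u = vec(L_G Z L_E') is an exact draw
      u_mat <- kron_mvn_draw(fac$G, fac$E, vc[[t]])
      u <- as.vector(u_mat)
      effects[[t]] <- u
      y <- y + u
    }
    genetic_value <- Reduce(`+`, effects[intersect(names(effects),
                                                   c("A", "D"))],
                            accumulate = FALSE) %||% numeric(n)
    if (config$nonlinear && config$nonlinear_variance > 0) {
      Xc <- additive_design(genotypes, center = TRUE)
      n_pairs <- min(2L * ncol(Xc), 2000L)
      i1 <- sample.int(ncol(Xc), n_pairs, replace = TRUE)
      i2 <- sample.int(ncol(Xc), n_pairs, replace = TRUE)
      wts <- stats::rnorm(n_pairs)
      g_epi <- as.vector((Xc[, i1, drop = FALSE] *
                            Xc[, i2, drop = FALSE]) %*% wts)
      g_epi <- g_epi - mean(g_epi)
      sde <- stats::sd(g_epi)
      if (sde > 0)
        g_epi <- g_epi * sqrt(config$nonlinear_variance) / sde
      u <- rep(g_epi, times = q)
      effects[["epistasis"]] <- u
      y <- y + u
      genetic_value <- genetic_value + u
    }
    eps <- stats::rnorm(n, 0, sqrt(vc[["residual"]]))
    y <- y + eps
    records$value <- y
    list(
      phenotypes = phenotype_table(records, env_levels = envs,
                                   gid_levels = genotypes$ids),
      truth = list(effects = effects, variances = vc, mu = config$mu,
                   beta = config$env_fixed_effects,
                   genetic_value = genetic_value, residual = eps))
  })
}

# Draw vec(U) with U ~ matrix normal so that vec has covariance
# sigma2 * (E (x) G) (columns indexed by the E dimension).
#' @noRd
kron_mvn_draw <- function(G, E, sigma2) {
  LG <- psd_sqrt(G)
  LE <- psd_sqrt(E)
  Z <- matrix(stats::rnorm(nrow(G) * nrow(E)), nrow(G), nrow(E))
  sqrt(sigma2) * LG %*% Z %*% t(LE)
}

#' @noRd
psd_sqrt <- function(K, tol = 1e-8) {
  ed <- eigen(symmetrize(as.matrix(K)), symmetric = TRUE)
  ev <- ed$values
  if (min(ev) < -tol * max(max(ev), .Machine$double.eps))
    stop("matrix is not positive semidefinite within tolerance", call. = FALSE)
  ev[ev < 0] <- 0
  ed$vectors %*% (sqrt(ev) * t(ed$vectors))
}

#' Run the full synthetic pipeline
#'
#' Convenience orchestrator: simulates genotypes and weather, builds the
#' envirotype covariable matrix (interval-percentile summaries, scaling and
#' QC) and the three kernels with one method, then simulates phenotypes.
#'
#' @param config a [sim_config()].
#' @param kernel_method kernel used for `K_A`, `K_D`, `K_W` (default `"GB"`).
#' @param h,layers kernel hyperparameters passed to [build_kernel()].
#' @return list with `config`, `genotypes`, `weather`, `W`
#'   (`env_covariable_matrix`), `kernels` (list `A`, `D`, `W`), `phenotypes`
#'   and `truth`.
#' @export
simulate_met_experiment <- function(config, kernel_method = "GB", h = 1,
                                    layers = 1L) {
  geno <- simulate_genotypes(config)
  weather <- simulate_weather(config)
  raw <- summarize_interval_percentiles(weather)
  W <- scale_and_qc(raw)
  K_A <- build_kernel(additive_design(geno), kernel_method, h = h,
                      layers = layers)
  K_D <- build_kernel(dominance_design(geno), kernel_method, h = h,
                      layers = layers)
  K_W <- env_kernel(W, kernel_method, h = h, layers = layers)
  sim <- simulate_phenotypes(geno, list(A = K_A, D = K_D, W = K_W), config)
  list(config = config, genotypes = geno, weather = weather, W = W,
       kernels = list(A = K_A, D = K_D, W = K_W),
       phenotypes = sim$phenotypes, truth = sim$truth)
}

#' Write a synthetic experiment to plain-text files
#'
#' Writes the genotype CSV (hybrids x markers), phenotype CSV
#' (`env,gid,value`), one weather CSV per environment (`env,day,` 16 variable
#' columns) and a ground-truth JSON.
#'
#' @param experiment result of [simulate_met_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
write_simulation <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  gp <- file.path(dir, "genotypes.csv")
  utils::write.csv(data.frame(gid = experiment$genotypes$ids,
                              experiment$genotypes$dosage,
                              check.names = FALSE),
                   gp, row.names = FALSE)
  pp <- file.path(dir, "phenotypes.csv")
  utils::write.csv(experiment$phenotypes$records, pp, row.names = FALSE)
  paths <- c(paths, gp, pp)
  for (e in names(experiment$weather)) {
    wp <- file.path(dir, paste0("weather_", e, ".csv"))
    utils::write.csv(cbind(env = e, experiment$weather[[e]]), wp,
                     row.names = FALSE)
    paths <- c(paths, wp)
  }
  tp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(variances = as.list(experiment$truth$variances),
         mu = experiment$truth$mu, beta = experiment$truth$beta,
         effects = experiment$truth$effects),
    tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tp))
}
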