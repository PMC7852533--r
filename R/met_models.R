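# Assembly of the five MET model structures: fixed design plus ordered sets
# of observation-level random-effect covariances.

#' Phenotype table for multi-environment trials
#'
#' Validates and wraps trial records of one trait (typically grain yield in
#' t/ha): one row per (environment, hybrid) combination, at most one record
#' per pair.
#'
#' @param data data frame with columns `env`, `gid`, `value`.
#' @param env_levels,gid_levels optional factor levels fixing environment and
#'   hybrid order (defaults: order of first appearance).
#' @return object of class `phenotype_table`: list with `records` (the data
#'   frame), `env` / `gid` (factors), `envs`, `gids` (level sets), `n`, `q`,
#'   `p`.
#' @export
phenotype_table <- function(data, env_levels = NULL, gid_levels = NULL) {
  req <- c("env", "gid", "value")
  if (!all(req %in% colnames(data)))
    stop("phenotype data needs columns env, gid, value", call. = FALSE)
  data <- as.data.frame(data)[, req]
  if (anyDuplicated(data[, c("env", "gid")]))
    stop("at most one record per (environment, hybrid) pair", call. = FALSE)
  env <- factor(data$env, levels = env_levels %||% unique(as.character(data$env)))
  gid <- factor(data$gid, levels = gid_levels %||% unique(as.character(data$gid)))
  if (anyNA(env) || anyNA(gid))
    stop("records contain environments or hybrids outside the given levels",
         call. = FALSE)
  structure(
    list(records = data, env = env, gid = gid,
         envs = levels(env), gids = levels(gid),
         n = nrow(data), q = nlevels(env), p = nlevels(gid)),
    class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("phenotype_table:", x$n, "records;", x$p, "hybrids x", x$q,
      "environments\n")
  invisible(x)
}

#' Incidence matrix of a factor
#'
#' @param f a factor of length n.
#' @return n x nlevels 0/1 matrix.
#' @export
incidence_matrix <- function(f) {
  stopifnot(is.factor(f))
  Z <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

# Intercept + reference-coded environment indicators (first level as
# reference); intercept-only when a single environment is present.
#' @noRd
env_design <- function(env) {
  if (nlevels(env) < 2L) {
    X <- matrix(1, length(env), 1L, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  X <- stats::model.matrix(~env, data = data.frame(env = env))
  colnames(X)[1] <- "(Intercept)"
  X
}

# ---- observation-level covariance constructors ------------------------------

#' Observation-level expansion of a genomic main-effect covariance
#'
#' Expands an entity-level kernel `K` (p x p) to the n observations through
#' the incidence matrix `Z`, returning `Z K Z'`. For a main genetic effect
#' shared across environments this is the incidence-form equivalent of the
#' Kronecker structure `J_q (x) K`.
#'
#' @param K_geno p x p kernel.
#' @param Z n x p incidence matrix.
#' @return n x n covariance matrix.
#' @export
main_effect_cov <- function(K_geno, Z) {
  K_geno <- as.matrix(K_geno)
  if (ncol(Z) != nrow(K_geno))
    stop("incidence and kernel dimensions differ (", ncol(Z), " vs ",
         nrow(K_geno), ")", call. = FALSE)
  Z %*% K_geno %*% t(Z)
}

#' Observation-level environmental main-effect covariance
#'
#' Expands the environmental kernel `K_W` (q x q) to the observations:
#' `Z_E K_W Z_E'`, the incidence-form equivalent of `J_p (x) K_W` (shared
#' across hybrids).
#'
#' @param K_W q x q environmental kernel.
#' @param Z_E n x q environment incidence matrix.
#' @return n x n covariance matrix.
#' @export
env_main_cov <- function(K_W, Z_E) {
  main_effect_cov(K_W, Z_E)
}

#' Observation-level interaction covariance
#'
#' Hadamard product of the environmental and genomic observation-level
#' expansions: `(Z_E E Z_E') .* (Z_G K Z_G')`, with `E = I_q` for classic
#' genotype-by-environment interaction (environments unrelated) or `E = K_W`
#' for the envirotype-informed reaction norm.
#'
#' @param env_part q x q matrix (`diag(q)` or an environmental kernel).
#' @param K_geno p x p genomic kernel.
#' @param Z_E n x q environment incidence.
#' @param Z_G n x p genotype incidence.
#' @return n x n covariance matrix.
#' @export
interaction_cov <- function(env_part, K_geno, Z_E, Z_G) {
  main_effect_cov(env_part, Z_E) * main_effect_cov(K_geno, Z_G)
}

# ---- model catalog ----------------------------------------------------------

#' Random-effect terms of the five model structures
#'
#' @return named list mapping each model name to its ordered term names.
#' @export
met_model_terms <- function() {
  list(
    "EA"      = c("A"),
    "EAD"     = c("A", "D"),
    "EAD+GE"  = c("A", "D", "AE", "DE"),
    "EADW"    = c("A", "D", "W"),
    "EADW+GW" = c("A", "D", "W", "AW", "DW"))
}

# Factored description of one random-effect term: the observation-level
# covariance entry between records (e, i) and (e', i') is
# env_cov[e, e'] * geno_cov[i, i'].
#' @noRd
new_term <- function(name, env_cov, geno_cov) {
  list(name = name, env_cov = env_cov, geno_cov = geno_cov)
}

#' Assemble one of the five MET model structures
#'
#' Builds the fixed-effect design (intercept plus reference-coded environment
#' indicators, first environment as reference) and the ordered list of
#' random-effect covariance structures for the requested model:
#' \describe{
#'   \item{EA}{main additive effects only}
#'   \item{EAD}{additive + dominance}
#'   \item{EAD+GE}{additive + dominance + their interactions with unrelated
#'     environments (AE, DE)}
#'   \item{EADW}{additive + dominance + main envirotype effect (W)}
#'   \item{EADW+GW}{EADW + envirotype reaction norms (AW, DW)}
#' }
#' Each term is stored in factored form (q x q environmental part, p x p
#' genomic part); [term_covariance()] materializes the dense n x n matrix.
#'
#' @param name model name, one of `names(met_model_terms())`.
#' @param phenotypes a [phenotype_table()].
#' @param K_A,K_D,K_W kernels over hybrids (p x p) and environments (q x q);
#'   `K_D` is required for every model except EA, `K_W` only for EADW /
#'   EADW+GW. Kernel row order must match `phenotypes$gids` / `phenotypes$envs`.
#' @return object of class `effect_term_set`: list with `model`, `phenotypes`,
#'   `X` (fixed design), `terms`, `env_idx`, `gid_idx`.
#' @export
build_model <- function(name, phenotypes, K_A, K_D = NULL, K_W = NULL) {
  stopifnot(inherits(phenotypes, "phenotype_table"))
  catalog <- met_model_terms()
  if (!name %in% names(catalog))
    stop("unknown model '", name, "'; use one of: ",
         paste(names(catalog), collapse = ", "), call. = FALSE)
  q <- phenotypes$q; p <- phenotypes$p
  check_kernel <- function(K, dim, what) {
    K <- as.matrix(K)
    if (nrow(K) != dim || ncol(K) != dim)
      stop("kernel ", what, " must be ", dim, " x ", dim, call. = FALSE)
    K
  }
  K_A <- check_kernel(K_A, p, "K_A")
  need <- catalog[[name]]
  if (any(c("D", "DE", "DW") %in% need)) {
    if (is.null(K_D))
      stop("model ", name, " requires kernel K_D for term D", call. = FALSE)
    K_D <- check_kernel(K_D, p, "K_D")
  }
  if (any(c("W", "AW", "DW") %in% need)) {
    if (is.null(K_W))
      stop("model ", name, " requires kernel K_W for term W", call. = FALSE)
    K_W <- check_kernel(K_W, q, "K_W")
  }
  if (q == 1L && any(c("AE", "DE") %in% need))
    warning("single environment: AE/DE interaction terms duplicate the A/D ",
            "main-effect covariances", call. = FALSE)
  J_q <- matrix(1, q, q); J_p <- matrix(1, p, p); I_q <- diag(q)
  maker <- list(
    A  = function() new_term("A", J_q, K_A),
    D  = function() new_term("D", J_q, K_D),
    W  = function() new_term("W", K_W, J_p),
    AE = function() new_term("AE", I_q, K_A),
    DE = function() new_term("DE", I_q, K_D),
    AW = function() new_term("AW", K_W, K_A),
    DW = function() new_term("DW", K_W, K_D))
  terms <- lapply(need, function(t) maker[[t]]())
  names(terms) <- need
  # fixed design: intercept + reference-coded environment indicators
  X <- env_design(phenotypes$env)
  structure(
    list(model = name, phenotypes = phenotypes, X = X, terms = terms,
         env_idx = as.integer(phenotypes$env),
         gid_idx = as.integer(phenotypes$gid)),
    class = "effect_term_set")
}

#' @export
print.effect_term_set <- function(x, ...) {
  cat("effect_term_set: model", x$model, "with", length(x$terms),
      "random term(s):", paste(names(x$terms), collapse = ", "), "\n")
  cat("  n =", x$phenotypes$n, "observations; fixed design:",
      ncol(x$X), "columns\n")
  invisible(x)
}

#' Materialize the dense observation-level covariance of one term
#'
#' @param term_set an [build_model()] result.
#' @param which term name (e.g. `"A"`, `"AW"`).
#' @param rows,cols optional record indices selecting a block (defaults: all).
#' @return covariance matrix over the selected records.
#' @export
term_covariance <- function(term_set, which, rows = NULL, cols = NULL) {
  stopifnot(inherits(term_set, "effect_term_set"))
  term <- term_set$terms[[which]]
  if (is.null(term)) stop("no term named ", which, call. = FALSE)
  rows <- rows %||% seq_len(term_set$phenotypes$n)
  cols <- cols %||% seq_len(term_set$phenotypes$n)
  e1 <- term_set$env_idx[rows]; e2 <- term_set$env_idx[cols]
  g1 <- term_set$gid_idx[rows]; g2 <- term_set$gid_idx[cols]
  term$env_cov[e1, e2, drop = FALSE] * term$geno_cov[g1, g2, drop = FALSE]
}
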