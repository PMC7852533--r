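# Envirotyping: daily environmental tables -> scaled covariable matrix W
# and the environmental kernel K_W.

#' Phenology intervals for interval-percentile summaries
#'
#' Defines the ordered, contiguous, non-overlapping crop-cycle intervals (in
#' days after emergence, DAE) over which daily series are summarized. The
#' default follows tropical-maize phenology: emergence to V1, V1-V4, V4-VT
#' (tasseling), VT-R3 (kernel milk), R3 to physiological maturity. The
#' convention is 1-based and inclusive: the interval labeled "0-14" covers
#' day-of-cycle indices 1 to 14.
#'
#' @param starts,ends integer vectors of interval endpoints (DAE).
#' @param labels optional interval labels; default `"I<start>_<end>"`.
#' @return data frame of class `phenology_intervals` with columns `start`,
#'   `end`, `label`, `day_from`, `day_to` (the 1-based day indices covered).
#' @examples
#' phenology_intervals()
#' @export
phenology_intervals <- function(starts = c(0L, 15L, 36L, 66L, 91L),
                                ends = c(14L, 35L, 65L, 90L, 120L),
                                labels = NULL) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) != length(ends) || length(starts) < 1L)
    stop("starts and ends must be non-empty and of equal length", call. = FALSE)
  if (any(ends < starts))
    stop("interval ends must be >= starts", call. = FALSE)
  if (length(starts) > 1L && any(starts[-1L] != ends[-length(ends)] + 1L))
    stop("intervals must be contiguous, non-overlapping and increasing",
         call. = FALSE)
  labels <- labels %||% paste0("I", starts, "_", ends)
  out <- data.frame(start = starts, end = ends, label = labels,
                    day_from = pmax(starts, 1L), day_to = ends,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenology_intervals", "data.frame")
  out
}

#' Interval-percentile summaries of daily environmental series
#'
#' For every combination of environmental variable, phenology interval and
#' percentile, computes one summary value per environment: the type-7
#' (linear-interpolation) quantile of the variable's daily values inside the
#' interval window. Column labels encode the triplet as
#' `<variable>_<interval>_q<percentile>`.
#'
#' @param daily_tables named list of per-environment data frames, each with a
#'   `day` column (1-based day of cycle, DAE) and one numeric column per
#'   environmental variable.
#' @param intervals a [phenology_intervals()] object.
#' @param percentiles percentile levels; default `c(0.25, 0.50, 0.75)`.
#' @return numeric matrix, environments x covariables.
#' @export
summarize_interval_percentiles <- function(daily_tables,
                                           intervals = phenology_intervals(),
                                           percentiles = c(0.25, 0.50, 0.75)) {
  stopifnot(inherits(intervals, "phenology_intervals"),
            is.list(daily_tables), length(daily_tables) >= 1L)
  envs <- names(daily_tables) %||% paste0("E", seq_along(daily_tables))
  vars <- setdiff(colnames(daily_tables[[1L]]), "day")
  if (length(vars) == 0L) stop("no variable columns found", call. = FALSE)
  W <- matrix(NA_real_, nrow = length(envs),
              ncol = length(vars) * nrow(intervals) * length(percentiles))
  colnames(W) <- rep("", ncol(W))
  rownames(W) <- envs
  col <- 0L
  for (v in vars) {
    for (i in seq_len(nrow(intervals))) {
      for (p in seq_along(percentiles)) {
        col <- col + 1L
        colnames(W)[col] <- paste0(
          v, "_", intervals$label[i], "_q",
          formatC(round(100 * percentiles[p]), width = 2, flag = "0"))
      }
    }
  }
  for (e in seq_along(envs)) {
    tab <- daily_tables[[e]]
    if (!"day" %in% colnames(tab))
      stop("environment ", envs[e], ": daily table lacks a 'day' column",
           call. = FALSE)
    if (!setequal(setdiff(colnames(tab), "day"), vars))
      stop("environment ", envs[e], ": variable columns differ from the ",
           "first environment", call. = FALSE)
    col <- 0L
    for (v in vars) {
      for (i in seq_len(nrow(intervals))) {
        win <- tab$day >= intervals$day_from[i] & tab$day <= intervals$day_to[i]
        if (!any(win))
          stop("environment ", envs[e], ": interval ", intervals$label[i],
               " lies outside the table's day range", call. = FALSE)
        x <- tab[[v]][win]
        qs <- stats::quantile(x, probs = percentiles, type = 7, names = FALSE)
        for (p in seq_along(percentiles)) {
          col <- col + 1L
          W[e, col] <- qs[p]
        }
      }
    }
  }
  W
}

#' Append management covariables
#'
#' Adds one raw covariable column per management variable (for example the
#' amount of nitrogen applied per environment) to an interval-percentile
#' table, before scaling and quality control.
#'
#' @param raw_table environments x covariables matrix (rownames = environment
#'   IDs).
#' @param management named list: one element per management variable, each a
#'   named vector mapping every environment to its value. An empty list
#'   returns the table unchanged.
#' @return the augmented matrix.
#' @export
append_management_covariables <- function(raw_table, management) {
  stopifnot(is.matrix(raw_table))
  if (length(management) == 0L) return(raw_table)
  if (is.null(names(management)) || any(!nzchar(names(management))))
    stop("management variables must be named", call. = FALSE)
  envs <- rownames(raw_table)
  for (nm in names(management)) {
    if (nm %in% colnames(raw_table))
      stop("duplicate covariable name: ", nm, call. = FALSE)
    v <- management[[nm]]
    missing_env <- setdiff(envs, names(v))
    if (length(missing_env))
      stop("management variable ", nm, " lacks environments: ",
           paste(missing_env, collapse = ", "), call. = FALSE)
    raw_table <- cbind(raw_table, unname(v[envs]))
    colnames(raw_table)[ncol(raw_table)] <- nm
  }
  raw_table
}

#' Scale covariables and apply quality control
#'
#' Builds the envirotype covariable matrix `W` (q environments x k retained
#' covariables, each column standard normal across environments): columns
#' with zero variance are dropped, the remaining columns are centered and
#' scaled to unit standard deviation, and any column containing a
#' standardized entry with `|z| > z_threshold` is then dropped. All dropped
#' columns are logged.
#'
#' @param raw_table environments x covariables matrix.
#' @param z_threshold standardized-value cutoff for the outlier screen,
#'   default 3.
#' @return object of class `env_covariable_matrix`: list with `values`
#'   (scaled matrix), `center`, `scale` (per retained column) and
#'   `dropped_columns` (data frame with columns `column`, `reason`).
#' @export
scale_and_qc <- function(raw_table, z_threshold = 3) {
  stopifnot(is.matrix(raw_table))
  if (nrow(raw_table) < 2L)
    stop("scale_and_qc needs at least two environments", call. = FALSE)
  sds <- apply(raw_table, 2L, stats::sd)
  dropped <- data.frame(column = character(), reason = character(),
                        stringsAsFactors = FALSE)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    dropped <- rbind(dropped, data.frame(
      column = colnames(raw_table)[zero], reason = "zero_variance",
      stringsAsFactors = FALSE))
  M <- raw_table[, !zero, drop = FALSE]
  ctr <- colMeans(M)
  scl <- apply(M, 2L, stats::sd)
  Z <- scale(M, center = ctr, scale = scl)
  outlier <- apply(abs(Z) > z_threshold, 2L, any)
  if (any(outlier))
    dropped <- rbind(dropped, data.frame(
      column = colnames(Z)[outlier], reason = "outlier_gt_z",
      stringsAsFactors = FALSE))
  keep <- !outlier
  if (!any(keep))
    stop("scale_and_qc: all covariable columns dropped by QC", call. = FALSE)
  values <- Z[, keep, drop = FALSE]
  attr(values, "scaled:center") <- NULL
  attr(values, "scaled:scale") <- NULL
  structure(
    list(values = values, center = ctr[keep], scale = scl[keep],
         dropped_columns = dropped),
    class = "env_covariable_matrix")
}

#' @export
print.env_covariable_matrix <- function(x, ...) {
  cat("env_covariable_matrix:", nrow(x$values), "environments x",
      ncol(x$values), "covariables (", nrow(x$dropped_columns),
      "dropped by QC )\n")
  invisible(x)
}

#' Environmental relationship kernel
#'
#' Builds the q x q environmental kernel `K_W` from the scaled covariable
#' matrix `W` with any of the three kernel methods, labeled by environment.
#'
#' @param W an [scale_and_qc()] result or a plain scaled matrix
#'   (environments x covariables).
#' @param method `"GB"`, `"GK"` or `"DK"`.
#' @param ... passed to [build_kernel()] (`h`, `layers`, `y`).
#' @return a `kernel_matrix` over environments.
#' @export
env_kernel <- function(W, method = c("GB", "GK", "DK"), ...) {
  if (inherits(W, "env_covariable_matrix")) W <- W$values
  build_kernel(as.matrix(W), method = match.arg(method), ...)
}
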