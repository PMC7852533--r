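# Readers and writers for the plain-text interchange formats.

#' Read a genotype dosage table from CSV/TSV
#'
#' Expects hybrids in rows and markers in columns, with the first column
#' holding hybrid IDs (or rownames via `row.names = 1` semantics).
#'
#' @param path CSV or TSV file.
#' @param sep field separator; guessed from the extension by default.
#' @return a [genotype_table()].
#' @export
read_genotypes_csv <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  genotype_table(impute_dosages(M), ids = ids)
}

#' Read genotype dosages from a VCF
#'
#' Converts diploid GT calls of biallelic records into ALT-allele dosages
#' (0/1/2). Multiallelic sites and sites with any missing call are skipped
#' with a logged count. Requires the VariantAnnotation package.
#'
#' @param path an (uncompressed or bgzipped) VCF file.
#' @return a [genotype_table()] with samples as hybrids.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_genotypes_vcf requires the VariantAnnotation package",
         call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  n_alt <- lengths(VariantAnnotation::alt(vcf))
  biallelic <- n_alt == 1L
  dose_one <- function(g) {
    a <- strsplit(g, "[/|]")[[1L]]
    if (length(a) != 2L || any(a == ".")) return(NA_real_)
    sum(a == "1")
  }
  D <- apply(gt, c(1L, 2L), dose_one)
  complete <- !apply(D, 1L, anyNA)
  keep <- biallelic & complete
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message("read_genotypes_vcf: skipped ", n_skipped,
            " multiallelic or incomplete site(s)")
  M <- t(D[keep, , drop = FALSE])
  genotype_table(M, ids = colnames(gt))
}

#' Read phenotype records from CSV
#'
#' @param path CSV with columns `env`, `gid`, `value`.
#' @return a [phenotype_table()].
#' @export
read_phenotypes_csv <- function(path) {
  phenotype_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read daily weather tables
#'
#' Accepts either one long-format CSV with an `env` column, or a vector of
#' per-environment CSVs (environment names taken from an `env` column or the
#' file names). Each table must have a `day` column plus variable columns.
#'
#' @param paths one or more CSV files.
#' @return named list of per-environment data frames.
#' @export
read_weather_csv <- function(paths) {
  tabs <- lapply(paths, utils::read.csv, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(seq_along(tabs), function(i) {
    t <- tabs[[i]]
    if (!"env" %in% colnames(t))
      t$env <- sub("\\.csv$", "", basename(paths[i]))
    t
  }))
  out <- split(long[setdiff(colnames(long), "env")], long$env)
  lapply(out, function(t) { rownames(t) <- NULL; t })
}

#' Write a kernel to CSV with a JSON metadata sidecar
#'
#' @param K a `kernel_matrix`.
#' @param path CSV destination; metadata goes to `<path>.json`.
#' @return invisibly, the two written paths.
#' @export
write_kernel_csv <- function(K, path) {
  utils::write.csv(as.data.frame(unclass(K)), path, row.names = TRUE)
  meta <- kernel_info(K)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(path, paste0(path, ".json")))
}

#' Read a kernel written by [write_kernel_csv()]
#'
#' @param path the CSV path.
#' @return a `kernel_matrix`.
#' @export
read_kernel_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  M <- as.matrix(df)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(method = "GB", hyperparams = list())
  new_kernel_matrix(M, meta$method, hyperparams = as.list(meta$hyperparams))
}

#' Write the envirotype covariable matrix
#'
#' @param W an `env_covariable_matrix`.
#' @param path CSV destination; the QC log goes to `<path>.qc.json`.
#' @return invisibly, the written paths.
#' @export
write_env_covariables <- function(W, path) {
  stopifnot(inherits(W, "env_covariable_matrix"))
  utils::write.csv(as.data.frame(W$values), path, row.names = TRUE)
  jsonlite::write_json(
    list(dropped_columns = W$dropped_columns,
         center = as.list(W$center), scale = as.list(W$scale)),
    paste0(path, ".qc.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(path, paste0(path, ".qc.json")))
}
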