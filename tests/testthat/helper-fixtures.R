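# Shared fixture builders (everything generated in code; no stored binaries).

small_config <- function(seed = 1, ...) {
  args <- list(n_parents = 10, n_hybrids = 30, n_markers = 120,
               n_environments = 3, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

small_experiment <- function(seed = 1, ...) {
  simulate_met_experiment(small_config(seed, ...))
}

# Structured marker design (related hybrids), used where iid noise rows are
# too exchangeable to identify kernel hyperparameters.
structured_design <- function(seed = 1, n_hybrids = 100, n_markers = 400,
                              n_parents = 15) {
  cfg <- sim_config(n_parents = n_parents, n_hybrids = n_hybrids,
                    n_markers = n_markers, seed = seed)
  additive_design(simulate_genotypes(cfg))
}

# Minimal uncompressed VCF with 4 samples: 3 biallelic sites, 1 multiallelic,
# 1 with a missing call.
write_tiny_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"),
    paste("1", "100", "snp1", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "0/1", sep = "\t"),
    paste("1", "200", "snp2", "G", "C", ".", "PASS", ".", "GT",
          "0/1", "0/0", "0/0", "1/1", sep = "\t"),
    paste("1", "300", "snp3", "T", "A,G", ".", "PASS", ".", "GT",
          "0/1", "0/2", "0/0", "1/1", sep = "\t"),
    paste("1", "400", "snp4", "C", "G", ".", "PASS", ".", "GT",
          "0/0", "./.", "0/1", "1/1", sep = "\t"),
    paste("1", "500", "snp5", "A", "G", ".", "PASS", ".", "GT",
          "1/1", "0/1", "0/0", "0/0", sep = "\t"))
  writeLines(lines, path)
  path
}
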