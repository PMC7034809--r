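#' Run the full synthetic-cohort pipeline
#'
#' One invocation regenerates the complete synthetic result set: cohort
#' truth, libraries, consensus collapse, error-rate series per family size
#' and correction set, CHIP and patterned catalogs, duplicate comparison,
#' substitution spectra, allele-frequency bins, a UDI index-hopping table,
#' and the truth-label audit. Deterministic under the config seed. When
#' `out_dir` is given, plain-text artifacts (TSV ledger, BED patterned
#' positions, TSV CHIP catalog, per-sample NRA BED, FASTA reference, and a
#' YAML manifest carrying the seed and a config hash) are written; no
#' output is written without its manifest.
#'
#' @param config a [sim_config()] object or the path to a YAML config.
#' @param out_dir optional output directory.
#' @param corrections,family_sizes,relatedness_k,min_depth,... passed to
#'   [run_decomposition()].
#' @param spectrum_fs family size at which spectra and AF bins are
#'   reported (default 2).
#' @return object of class `ccf_study`: list with `config`, `cohort`,
#'   `decomposition`, `spectrum` (baseline and fully corrected),
#'   `af_bins`, `udi`, `hopping`, `audit`, `fraction_reads_paired` (duplex
#'   only), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         corrections = c("C", "P", "D"),
                         family_sizes = 1:3,
                         relatedness_k = NULL,
                         min_depth = 50L,
                         spectrum_fs = 2L, ...) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  cohort <- simulate_cohort(config,
                            duplicates = "D" %in% corrections,
                            seq_duplicates = "D" %in% corrections,
                            buffy = "C" %in% corrections)
  dec <- run_decomposition(cohort, corrections = corrections,
                           family_sizes = family_sizes,
                           relatedness_k = relatedness_k,
                           min_depth = min_depth, ...)

  all_nras <- do.call(rbind, dec$nras)
  spec_baseline <- substitution_spectrum(all_nras)
  audit_set <- paste(intersect(c("C", "P", "D"), corrections), collapse = "")
  corrected_nras <- do.call(rbind, lapply(
    dec$reports[[as.character(spectrum_fs)]][[
      if (nzchar(audit_set)) audit_set else "baseline"]],
    function(r) centers_to_nras(r$centers)))
  spec_corrected <- substitution_spectrum(corrected_nras)
  bins <- af_bins(all_nras)

  udi <- simulate_udi_counts(config$n_samples, config$udi_reads_per_sample,
                             config$hop_rate,
                             seed = derive_seed(config$seed, "udi"))
  hopping <- index_hopping_rate(udi)

  audit <- if (nzchar(audit_set) && spectrum_fs %in% family_sizes) {
    audit_truth(dec, family_size = spectrum_fs, corrections = audit_set)
  } else NULL

  frac_paired <- if (config$adapter_scheme == "duplex") {
    s2 <- pair_duplex_strands(dec$consensus[[1]]$ccf1)
    attr(s2, "fraction_reads_paired")
  } else NA_real_

  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_samples = config$n_samples,
    corrections = paste(corrections, collapse = ""),
    family_sizes = family_sizes,
    created = "run_pipeline"
  )
  out <- list(config = config, cohort = cohort, decomposition = dec,
              spectrum = list(baseline = spec_baseline,
                              corrected = spec_corrected),
              af_bins = bins, udi = udi, hopping = hopping, audit = audit,
              fraction_reads_paired = frac_paired, manifest = manifest)
  class(out) <- "ccf_study"
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

# Deterministic content hash of a config (no external digest dependency;
# a 32-bit FNV-style fold over the deparsed object).
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  h <- 216613626
  for (x in v) h <- ((h * 16777) + x) %% 268435456
  sprintf("%08x", as.integer(h))
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(study$manifest, file.path(out_dir, "manifest.yaml"))
  dec <- study$decomposition
  tab <- dec$table
  tab$config_hash <- study$manifest$config_hash
  tab$seed <- study$manifest$seed
  utils::write.table(tab, file.path(out_dir, "error_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dec$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(dec$patterned)) {
    bed <- data.frame(chrom = dec$patterned$chrom, start = dec$patterned$pos,
                      end = dec$patterned$pos + 1L,
                      name = "patterned", score = dec$patterned$n_samples)
    utils::write.table(bed, file.path(out_dir, "patterned_positions.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  if (!is.null(dec$chip)) {
    utils::write.table(dec$chip$variants, file.path(out_dir, "chip_catalog.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (s in seq_along(dec$nras)) {
    write_nra_bed(dec$nras[[s]],
                  file.path(out_dir, sprintf("nra_sample%d.bed", s)))
  }
  write_reference(study$cohort$truth$reference,
                  file.path(out_dir, "reference.fa"))
  utils::write.table(study$spectrum$baseline,
                     file.path(out_dir, "spectrum_baseline.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.ccf_study <- function(x, ...) {
  cat(sprintf("ccfDNA noise study (seed %d, %s adapters)\n",
              x$config$seed, x$config$adapter_scheme))
  print(x$decomposition)
  cat(sprintf("  index hopping: %.4f%% | NRAs below 0.1%% AF: %.1f%%\n",
              100 * x$hopping$hopping, 100 * x$af_bins$fraction[1]))
  if (!is.null(x$audit)) {
    cat(sprintf("  truth audit (FS>=2, all corrections): %.1f%% early-PCR or true-variant\n",
                100 * attr(x$audit, "fraction_early_or_true")))
  }
  invisible(x)
}
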