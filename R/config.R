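#' Simulation configuration
#'
#' Collects every tunable of the synthetic ccfDNA cohort generator. The
#' defaults are the package's desk-scale study conditions: a seven-sample
#' cohort (matching the typical healthy-control cohort such experiments
#' use), 10 ng-analogue molecule input amplified through 10 PCR cycles, and
#' error channels (early/late PCR substitutions, sequencing-layer
#' substitutions, CHIP variants visible in buffy coat at 2-30% allele
#' frequency, recurrent patterned positions, spiked low-frequency true
#' variants) sized so that each channel is present at measurable counts on
#' a 1 kb reference.
#'
#' @param reference_length reference contig length in bases. The default
#'   (600, four fragment lengths) concentrates coverage so that every
#'   plateau position is covered by roughly 75 input molecules and 140
#'   consensus families -- enough that presence/absence of the truth
#'   channels and the 0.4 germline gate are decided by the truth, not by
#'   sampling noise.
#' @param gc_fraction expected G+C fraction of the simulated reference.
#' @param n_samples number of cohort samples.
#' @param molecules_per_sample double-stranded input molecules per ccfDNA
#'   library (the 10 ng input analogue).
#' @param buffy_molecules input molecules for buffy-coat libraries; the
#'   default is three times `molecules_per_sample` (white-blood-cell DNA
#'   is not limiting -- real protocols use roughly tenfold more buffy-coat
#'   than ccfDNA input -- and the larger molecule pool keeps buffy-coat
#'   allele-frequency estimates stable against the 0.4 germline gate).
#' @param fragment_length fragment (and fused read) length in bases.
#' @param pcr_cycles number of PCR cycles (>= 1).
#' @param pcr_efficiency per-amplicon per-cycle copy probability in [0, 1].
#' @param pcr_error_rate substitution probability per base per copy event.
#' @param seq_error_rate substitution probability per base per sequencing
#'   read (applied after PCR).
#' @param q_low fraction of sequenced bases assigned the low quality Q11
#'   (the rest get Q37); exercises the >= Q20 quality gates.
#' @param reads_sampled sequencing reads drawn (without replacement) from
#'   the post-PCR amplicon pool per library.
#' @param adapter_scheme `"duplex"` (3+3 dual UMI) or `"singleton"` (single
#'   8-mer UMI per strand).
#' @param umi_length total UMI width; defaults to 6 for duplex, 8 for
#'   singleton and must match the scheme.
#' @param umi_error_rate optional per-base UMI read error rate (default 0).
#'   Positive values reproduce the family-splitting inflation caused by
#'   exact UMI matching.
#' @param chip_variants number of CHIP variants per sample.
#' @param chip_af_range range the truth CHIP allele frequencies are drawn
#'   from; must lie within the canonical detection window [0.02, 0.30].
#'   The default (0.05, 0.25) sits inside the window so that desk-scale
#'   sampling noise in the observed buffy-coat AF does not straddle the
#'   window edges (at ~150X an AF drawn at the 2% edge is observed below
#'   it roughly a third of the time).
#' @param patterned_positions number of recurrent patterned-error positions.
#' @param patterned_hit_prob per-sample Bernoulli probability that a
#'   patterned position affects a given sample. The default 1 reflects that
#'   patterned error models sequence-context/mapping artifacts shared by
#'   every library; lower it to simulate partially shared artifacts.
#' @param patterned_af per-molecule probability of the patterned alternate
#'   allele at an affected position (per library).
#' @param spike_variants data.frame with columns `position` (0-based),
#'   `af`, and optionally `alt` and `sample_id`, of true variants spiked
#'   into ccfDNA. A spike with `sample_id = NA` goes into every sample's
#'   ccfDNA; a numbered spike only into that sample (the usual situation
#'   for tumor-derived variants, which are patient-specific -- a variant
#'   shared by the whole cohort would be indistinguishable from patterned
#'   error). `NULL` gives the default of two per-sample spikes at AF 5%
#'   and 10%, comfortably above the binomial detection limit of the
#'   desk-scale consensus depth.
#' @param hop_rate index-hopping probability per read used by the unique
#'   dual index (UDI) counts simulation.
#' @param udi_reads_per_sample reads per sample in the UDI count table.
#' @param seed master integer seed; every downstream random stream is
#'   derived from it.
#' @return an object of class `sim_config` (a named list).
#' @seealso [generate_cohort()], [simulate_cohort()], [simulate_library()]
#' @export
sim_config <- function(reference_length = 600L,
                       gc_fraction = 0.5,
                       n_samples = 7L,
                       molecules_per_sample = 300L,
                       buffy_molecules = NULL,
                       fragment_length = 150L,
                       pcr_cycles = 10L,
                       pcr_efficiency = 0.35,
                       pcr_error_rate = 3e-4,
                       seq_error_rate = 1e-3,
                       q_low = 0.02,
                       reads_sampled = 3000L,
                       adapter_scheme = c("duplex", "singleton"),
                       umi_length = NULL,
                       umi_error_rate = 0,
                       chip_variants = 2L,
                       chip_af_range = c(0.05, 0.25),
                       patterned_positions = 20L,
                       patterned_hit_prob = 1,
                       patterned_af = 0.15,
                       spike_variants = NULL,
                       hop_rate = 2e-4,
                       udi_reads_per_sample = 1e5,
                       seed = 1L) {
  adapter_scheme <- match.arg(adapter_scheme)
  expected_umi <- if (adapter_scheme == "duplex") 6L else 8L
  umi_length <- as.integer(umi_length %||% expected_umi)
  if (umi_length != expected_umi) {
    stop("umi_length must be ", expected_umi, " for the ", adapter_scheme,
         " scheme (got ", umi_length, ")")
  }
  rates <- c(pcr_efficiency = pcr_efficiency, pcr_error_rate = pcr_error_rate,
             seq_error_rate = seq_error_rate, q_low = q_low,
             umi_error_rate = umi_error_rate, gc_fraction = gc_fraction,
             patterned_hit_prob = patterned_hit_prob,
             patterned_af = patterned_af, hop_rate = hop_rate)
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    stop("rates must lie in [0, 1]: ", paste(names(rates)[bad], collapse = ", "))
  }
  if (pcr_cycles < 1L) stop("pcr_cycles must be >= 1")
  if (fragment_length < 1L || fragment_length > reference_length) {
    stop("fragment_length must be in [1, reference_length]")
  }
  if (chip_af_range[1] >= chip_af_range[2]) {
    stop("chip_af_range must be an increasing pair")
  }
  if (chip_af_range[1] < 0.02 || chip_af_range[2] > 0.30) {
    stop("chip allele frequencies must lie within [0.02, 0.30]")
  }
  if (is.null(spike_variants)) {
    # Per-sample spikes, placed on the coverage plateau (at least one
    # fragment length away from the contig ends), at AFs the desk-scale
    # consensus depth can detect.
    k <- 3L * n_samples
    interior <- reference_length - 2L * fragment_length
    spike_variants <- data.frame(
      position = as.integer(fragment_length +
                              round(interior * seq_len(k) / (k + 1))),
      alt = NA_character_,
      af = rep(c(0.05, 0.10, 0.15), times = n_samples),
      sample_id = rep(seq_len(n_samples), each = 3L),
      stringsAsFactors = FALSE
    )
  } else {
    spike_variants <- as.data.frame(spike_variants)
    if (!all(c("position", "af") %in% names(spike_variants))) {
      stop("spike_variants needs columns 'position' and 'af'")
    }
    if (is.null(spike_variants$alt)) {
      spike_variants$alt <- rep(NA_character_, nrow(spike_variants))
    }
    if (is.null(spike_variants$sample_id)) {
      spike_variants$sample_id <- rep(NA_integer_, nrow(spike_variants))
    }
  }
  if (nrow(spike_variants) &&
      any(spike_variants$position < 0 |
          spike_variants$position >= reference_length)) {
    stop("spike positions must fall inside [0, reference_length)")
  }
  cfg <- list(
    reference_length = as.integer(reference_length),
    gc_fraction = gc_fraction,
    n_samples = as.integer(n_samples),
    molecules_per_sample = as.integer(molecules_per_sample),
    buffy_molecules = as.integer(buffy_molecules %||%
                                   (3L * molecules_per_sample)),
    fragment_length = as.integer(fragment_length),
    pcr_cycles = as.integer(pcr_cycles),
    pcr_efficiency = pcr_efficiency,
    pcr_error_rate = pcr_error_rate,
    seq_error_rate = seq_error_rate,
    q_low = q_low,
    reads_sampled = as.integer(reads_sampled),
    adapter_scheme = adapter_scheme,
    umi_length = umi_length,
    umi_error_rate = umi_error_rate,
    chip_variants = as.integer(chip_variants),
    chip_af_range = chip_af_range,
    patterned_positions = as.integer(patterned_positions),
    patterned_hit_prob = patterned_hit_prob,
    patterned_af = patterned_af,
    spike_variants = spike_variants,
    hop_rate = hop_rate,
    udi_reads_per_sample = udi_reads_per_sample,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("ccfDNA simulation config\n")
  cat(sprintf("  reference: %d bp (GC %.2f), %d samples, seed %d\n",
              x$reference_length, x$gc_fraction, x$n_samples, x$seed))
  cat(sprintf("  library: %d molecules, %d bp fragments, %d reads sampled, %s adapters\n",
              x$molecules_per_sample, x$fragment_length, x$reads_sampled,
              x$adapter_scheme))
  cat(sprintf("  PCR: %d cycles, efficiency %.2f, error %.1e /base/copy; seq error %.1e\n",
              x$pcr_cycles, x$pcr_efficiency, x$pcr_error_rate, x$seq_error_rate))
  cat(sprintf("  truth: %d CHIP/sample (AF %.2f-%.2f), %d patterned (AF %.2f, hit %.2f), %d spikes\n",
              x$chip_variants, x$chip_af_range[1], x$chip_af_range[2],
              x$patterned_positions, x$patterned_af, x$patterned_hit_prob,
              nrow(x$spike_variants)))
  invisible(x)
}

#' Read or write a simulation config as YAML
#'
#' @param path file path.
#' @return `read_sim_config()` returns a validated [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$spike_variants)) {
    raw$spike_variants <- as.data.frame(raw$spike_variants)
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a [sim_config()] object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out$spike_variants <- as.list(out$spike_variants)
  yaml::write_yaml(out, path)
  invisible(path)
}
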