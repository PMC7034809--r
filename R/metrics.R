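# Stand-alone assay-level calculators: index hopping, ligation efficiency
# (densitometry and ddPCR), theoretical consensus depth.

AVOGADRO <- 6.02214076e23

#' Index hopping rate from a UDI count table
#'
#' The hopping rate is the total of reads mapping unambiguously to
#' mixed-sample unique-dual-index pairs divided by the total number of
#' reads in the lane. The lane total includes undetermined reads (reads
#' unaffiliated with any configured pair); the complementary
#' sample-associated and unaffiliated rates are reported alongside.
#'
#' @param counts a `udi_counts` object (see [simulate_udi_counts()]), or a
#'   square count matrix whose diagonal holds the correct pairs (then
#'   `undetermined` is taken from the argument).
#' @param undetermined undetermined read count when `counts` is a bare
#'   matrix.
#' @return list with `hopping`, `sample_associated`, `unaffiliated` rates
#'   and the underlying counts.
#' @export
index_hopping_rate <- function(counts, undetermined = 0L) {
  if (inherits(counts, "udi_counts")) {
    m <- counts$counts
    undetermined <- counts$undetermined
  } else {
    m <- as.matrix(counts)
  }
  if (nrow(m) != ncol(m)) stop("count matrix must be square")
  if (nrow(m) < 2L) stop("index hopping needs at least 2 samples")
  total <- sum(m) + undetermined
  if (total == 0) stop("zero total reads")
  mixed <- sum(m) - sum(diag(m))
  list(hopping = mixed / total,
       sample_associated = sum(diag(m)) / total,
       unaffiliated = undetermined / total,
       mixed_reads = mixed, total_reads = total)
}

#' Ligation efficiency from densitometry regions
#'
#' Converts each densitometry region (reported concentration and average
#' fragment size) to molarity via `concentration / (average_size * 650)`
#' (650 g/mol per base pair) and returns the percent of dual-end ligated
#' molarity among all three ligation states. Invariant to rescaling all
#' concentrations by a common factor.
#'
#' @param regions data.frame with columns `label` (exactly one each of
#'   `"unligated"`, `"single_end"`, `"dual_end"`), `concentration` (mass
#'   per volume), `average_size` (bp).
#' @return percent dual-end ligated product.
#' @export
ligation_efficiency_densitometry <- function(regions) {
  needed <- c("unligated", "single_end", "dual_end")
  if (!all(needed %in% regions$label) || nrow(regions) != 3L ||
      anyDuplicated(regions$label)) {
    stop("regions must contain exactly one row per label: ",
         paste(needed, collapse = ", "))
  }
  if (any(regions$average_size <= 0)) stop("average_size must be positive")
  if (any(regions$concentration < 0)) stop("concentrations must be >= 0")
  molarity <- regions$concentration / (regions$average_size * 650)
  total <- sum(molarity)
  if (total == 0) stop("zero total molarity")
  100 * molarity[regions$label == "dual_end"] / total
}

#' Ligation efficiency from ddPCR copy numbers
#'
#' Percent dual-end ligated copies: the flanking-primer copy number
#' (adapter-flanking amplicon, requiring adapters on both ends) over the
#' internal-primer copy number (insert-specific amplicon, counting all
#' template copies). Flanking counts exceeding the internal count are
#' physically implausible and flagged with a warning, not an error.
#'
#' @param flanking_copies copies measured with adapter-flanking primers.
#' @param internal_copies copies measured with internal primers (> 0).
#' @return percent dual-end ligated.
#' @export
ligation_efficiency_ddpcr <- function(flanking_copies, internal_copies) {
  if (internal_copies <= 0) stop("internal_copies must be positive")
  if (flanking_copies < 0) stop("flanking_copies must be >= 0")
  if (flanking_copies > internal_copies) {
    warning("flanking copies exceed internal copies; efficiency > 100%")
  }
  100 * flanking_copies / internal_copies
}

#' Theoretical consensus read depth limit
#'
#' The maximum consensus depth a library can reach equals the number of
#' haploid genome copies in the input mass:
#' `mass * N_A / (bp_weight * genome_length)`. For 10 ng of human DNA
#' (650 Da per base pair, 3.3e9 bp) this is about 2,800X.
#'
#' @param input_mass_ng DNA input in nanograms.
#' @param genome_length haploid genome length in bp.
#' @param bp_weight average base-pair weight in Daltons.
#' @return list with `depth` (unrounded fold-coverage) and `depth_rounded`
#'   (nearest 100, the conventional way this limit is quoted).
#' @export
theoretical_depth <- function(input_mass_ng, genome_length = 3.3e9,
                              bp_weight = 650) {
  if (input_mass_ng <= 0 || genome_length <= 0 || bp_weight <= 0) {
    stop("all inputs must be positive")
  }
  depth <- input_mass_ng * 1e-9 * AVOGADRO / (bp_weight * genome_length)
  list(depth = depth, depth_rounded = round(depth / 100) * 100)
}
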