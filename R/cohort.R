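#' Generate cohort-level ground truth
#'
#' Draws the reference sequence and the three truth sets that seed every
#' library of the cohort: per-sample CHIP variants (clonal-hematopoiesis
#' variants visible in matched buffy coat at 2-30% allele frequency),
#' recurrent patterned-error positions with their affected samples, and the
#' spiked low-frequency true variants copied verbatim from the config.
#'
#' Patterned positions are assigned to samples by independent Bernoulli
#' draws with probability `patterned_hit_prob`, so for probabilities below
#' one any relatedness level between 1 and `n_samples` can arise.
#' Everything is deterministic under the config seed.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `cohort_truth`: list with elements
#'   `reference` (character scalar), `chip_set` (data.frame: `sample_id`,
#'   `chrom`, `position`, `ref`, `alt`, `af`), `patterned_set` (data.frame:
#'   `chrom`, `position`, `ref`, `alt`, `sample_id`, one row per affected
#'   sample), and `spike_set` (data.frame: `chrom`, `position`, `ref`,
#'   `alt`, `af`). Positions are 0-based.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "cohort-truth"))
  L <- config$reference_length
  reference <- random_sequence(L, config$gc_fraction)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  samples <- seq_len(config$n_samples)

  used <- integer(0)  # 0-based positions already claimed by a truth set

  # Truth positions are drawn from the coverage plateau (at least one
  # fragment length from either contig end), the synthetic analogue of a
  # capture panel targeting well-covered exons: on the terminal coverage
  # ramps per-sample depth flickers around the gates and a recurrent
  # artifact there would not be consistently observable.
  interior <- seq.int(config$fragment_length,
                      L - config$fragment_length - 1L)
  pick_positions <- function(n, avoid) {
    free <- setdiff(interior, avoid)
    if (length(free) < n) stop("reference too short for requested truth sets")
    sort(sample(free, n))
  }

  # Spikes first: positions come from the config verbatim.
  spikes <- config$spike_variants
  if (nrow(spikes)) {
    if (any(spikes$position >= L)) stop("spike position beyond reference")
    spike_ref <- ref_chars[spikes$position + 1L]
    alt <- spikes$alt
    fill <- is.na(alt)
    if (any(fill)) {
      alt[fill] <- offset_base(spike_ref[fill],
                               sample(1:3, sum(fill), replace = TRUE))
    }
    if (any(alt == spike_ref)) stop("spike alt equals the reference base")
    spike_set <- data.frame(chrom = "ref", position = spikes$position,
                            ref = spike_ref, alt = alt, af = spikes$af,
                            sample_id = spikes$sample_id %||% NA_integer_,
                            stringsAsFactors = FALSE)
    used <- c(used, spikes$position)
  } else {
    spike_set <- data.frame(chrom = character(0), position = integer(0),
                            ref = character(0), alt = character(0),
                            af = numeric(0), sample_id = integer(0),
                            stringsAsFactors = FALSE)
  }

  # Patterned positions: one alt per position (a context artifact produces
  # the same miscalled base in every affected library).
  np <- config$patterned_positions
  if (np > 0L) {
    ppos <- pick_positions(np, used)
    used <- c(used, ppos)
    palt <- offset_base(ref_chars[ppos + 1L], sample(1:3, np, replace = TRUE))
    hits <- matrix(stats::rbinom(np * length(samples), 1L,
                                 config$patterned_hit_prob) == 1L,
                   nrow = np)
    idx <- which(hits, arr.ind = TRUE)
    patterned_set <- data.frame(
      chrom = "ref",
      position = ppos[idx[, 1]],
      ref = ref_chars[ppos[idx[, 1]] + 1L],
      alt = palt[idx[, 1]],
      sample_id = samples[idx[, 2]],
      stringsAsFactors = FALSE
    )
    patterned_set <- patterned_set[order(patterned_set$position,
                                         patterned_set$sample_id), ]
    rownames(patterned_set) <- NULL
  } else {
    patterned_set <- data.frame(chrom = character(0), position = integer(0),
                                ref = character(0), alt = character(0),
                                sample_id = integer(0), stringsAsFactors = FALSE)
  }

  # CHIP: per-sample somatic variants; AFs inside the 2-30% window.
  nc <- config$chip_variants
  if (nc > 0L) {
    chip <- do.call(rbind, lapply(samples, function(s) {
      cpos <- pick_positions(nc, used)
      used <<- c(used, cpos)
      data.frame(
        sample_id = s, chrom = "ref", position = cpos,
        ref = ref_chars[cpos + 1L],
        alt = offset_base(ref_chars[cpos + 1L],
                          sample(1:3, nc, replace = TRUE)),
        af = stats::runif(nc, config$chip_af_range[1], config$chip_af_range[2]),
        stringsAsFactors = FALSE
      )
    }))
    rownames(chip) <- NULL
  } else {
    chip <- data.frame(sample_id = integer(0), chrom = character(0),
                       position = integer(0), ref = character(0),
                       alt = character(0), af = numeric(0),
                       stringsAsFactors = FALSE)
  }
  if (nrow(chip) && (any(chip$af < 0.02) || any(chip$af > 0.30))) {
    stop("CHIP allele frequencies must lie in [0.02, 0.30]")
  }

  out <- list(reference = reference, chip_set = chip,
              patterned_set = patterned_set, spike_set = spike_set,
              n_samples = config$n_samples)
  class(out) <- "cohort_truth"
  out
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("cohort truth: %d bp reference, %d samples\n",
              nchar(x$reference), x$n_samples))
  cat(sprintf("  CHIP variants: %d | patterned position-sample pairs: %d | spikes: %d\n",
              nrow(x$chip_set), nrow(x$patterned_set), nrow(x$spike_set)))
  invisible(x)
}
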