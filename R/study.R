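# Cohort-level orchestration: simulate all libraries of a study, run the
# noise decomposition across family sizes and correction sets, and audit
# surviving NRAs against the simulator's truth labels.

#' Simulate a complete synthetic cohort
#'
#' Generates the cohort truth and all libraries of the study design: per
#' sample a ccfDNA library (replicate 1), optionally an independent full
#' library duplicate (replicate 2), optionally a sequencing duplicate
#' (resampled reads from replicate 1's post-PCR pool), and a matched
#' buffy-coat library.
#'
#' @param config a [sim_config()] object.
#' @param duplicates simulate the full library duplicate (default TRUE).
#' @param seq_duplicates simulate the sequencing duplicate (default TRUE).
#' @param buffy simulate buffy-coat libraries (default TRUE).
#' @return object of class `ccf_cohort`: list with `config`, `truth`, and
#'   `samples`, a list with per-sample elements `ccf1`, `ccf2`, `seqdup`,
#'   `buffy` (each an `aligned_reads` data.frame or NULL).
#' @export
simulate_cohort <- function(config, duplicates = TRUE, seq_duplicates = TRUE,
                            buffy = TRUE) {
  truth <- generate_cohort(config)
  samples <- lapply(seq_len(config$n_samples), function(s) {
    list(
      ccf1 = simulate_library(truth, s, config, replicate_id = 1L),
      ccf2 = if (duplicates)
        simulate_library(truth, s, config, replicate_id = 2L) else NULL,
      seqdup = if (seq_duplicates)
        simulate_library(truth, s, config, replicate_id = 3L,
                         mode = "seq_duplicate", duplicate_of = 1L) else NULL,
      buffy = if (buffy)
        simulate_library(truth, s, config, material = "buffy") else NULL
    )
  })
  out <- list(config = config, truth = truth, samples = samples)
  class(out) <- "ccf_cohort"
  out
}

#' @export
print.ccf_cohort <- function(x, ...) {
  have <- names(Filter(Negate(is.null), x$samples[[1]]))
  cat(sprintf("synthetic ccfDNA cohort: %d samples (%s adapters), libraries per sample: %s\n",
              x$config$n_samples, x$config$adapter_scheme,
              paste(have, collapse = ", ")))
  invisible(x)
}

subset_strings <- function(corrections) {
  corrections <- intersect(c("C", "P", "D"), corrections)
  sets <- list(character(0))
  for (c_ in corrections) sets <- c(sets, lapply(sets, c, c_))
  unique(vapply(sets, paste, character(1), collapse = ""))
}

#' Run the stepwise noise decomposition over a cohort
#'
#' The package's main analysis. For every family-size threshold and every
#' subset of the requested corrections it computes a region-gated error
#' report per sample: `C` subtracts buffy-coat-confirmed CHIP variants
#' from the sample's NRAs, `P` drops patterned positions from the
#' footprint, and `D` keeps only NRAs confirmed in the sample duplicate.
#' Per-sample error prior to UMI consensus collapsing is computed from the
#' raw replicate-1 reads for reduction accounting.
#'
#' @param cohort a [simulate_cohort()] object (or a compatible list with
#'   `config`, `truth`, `samples`).
#' @param corrections corrections to sweep, subset of `c("C", "P", "D")`;
#'   all subsets of this set are evaluated.
#' @param family_sizes family-size thresholds to sweep.
#' @param relatedness_k patterned-error relatedness (default: all
#'   samples, i.e. "highly patterned" positions only).
#' @param duplicate_source which duplicate the `D` correction intersects
#'   with: the full library duplicate (`"full"`) or the sequencing
#'   duplicate (`"seq"`).
#' @param min_depth,max_af,window gates passed to
#'   [estimate_error_rates()] / [parse_positions()]. The default
#'   `min_depth = 50` matches the package's desk-scale consensus depth of
#'   roughly 80-110X (the estimator functions themselves default to the
#'   production gate of 100).
#' @param chip_fs,patterned_fs family-size threshold at which the CHIP and
#'   patterned catalogs are built (default 2); the catalogs are then
#'   applied across all family sizes.
#' @param recurrence_cutoff see [detect_chip()].
#' @param match_on_alt see [intersect_duplicates()].
#' @param concordance_threshold see [call_consensus()].
#' @return object of class `decomposition_result` with elements
#'   `table` (per sample x family size x correction set: error rate, NRA
#'   and base counts, footprint), `pre_umi` (per-sample pre-consensus
#'   error), `summary` (per family size x correction set: mean and SD of
#'   the error rate and of percent reductions versus the uncorrected
#'   consensus baseline and versus pre-UMI error), `chip`, `patterned`,
#'   `relatedness_sweep`, `duplicate_comparison` (error with D-only using
#'   the full versus the sequencing duplicate, when both exist), `nras`
#'   (per-sample baseline NRA records at `patterned_fs`), `consensus`
#'   (cached consensus reads), `reports` (nested `error_report` objects:
#'   `reports[[as.character(fs)]][[set]][[sample]]`), and `params`.
#' @export
run_decomposition <- function(cohort,
                              corrections = c("C", "P", "D"),
                              family_sizes = 1:3,
                              relatedness_k = NULL,
                              regions = NULL,
                              duplicate_source = c("full", "seq"),
                              min_depth = 50L, max_af = 0.4, window = 7L,
                              chip_fs = 2L, patterned_fs = 2L,
                              recurrence_cutoff = 6L,
                              match_on_alt = TRUE,
                              concordance_threshold = 0.66) {
  duplicate_source <- match.arg(duplicate_source)
  corrections <- intersect(c("C", "P", "D"), corrections)
  config <- cohort$config
  truth <- cohort$truth
  reference <- truth$reference
  ns <- config$n_samples
  relatedness_k <- relatedness_k %||% ns
  # Default target regions: the coverage plateau of the synthetic contig
  # (the analogue of restricting error analysis to captured exons).
  regions <- regions %||% data.frame(
    chrom = "ref", start = config$fragment_length,
    end = config$reference_length - config$fragment_length)

  if ("C" %in% corrections &&
      any(vapply(cohort$samples, function(s) is.null(s$buffy), logical(1)))) {
    stop("correction C requires buffy-coat libraries for every sample")
  }
  need_partner <- if (duplicate_source == "full") "ccf2" else "seqdup"
  if ("D" %in% corrections &&
      any(vapply(cohort$samples, function(s) is.null(s[[need_partner]]),
                 logical(1)))) {
    stop("correction D requires ", need_partner, " libraries for every sample")
  }

  consensus <- lapply(cohort$samples, function(s) {
    lapply(s, function(lib) {
      if (is.null(lib)) NULL else
        collapse_families(lib, scheme = config$adapter_scheme,
                          concordance_threshold = concordance_threshold)
    })
  })

  pe_report <- function(reads) {
    estimate_error_rates(
      build_pileup(reads, reference, regions), min_depth = min_depth,
      max_af = max_af, window = window)
  }
  fs_report <- function(cons, fs) {
    r <- pe_report(filter_by_family_size(cons, fs))
    r$family_size_threshold <- fs
    r
  }
  fs_nras <- function(cons, fs) {
    parse_positions(build_pileup(filter_by_family_size(cons, fs), reference,
                                 regions),
                    min_depth = min_depth, max_af = max_af,
                    reference = reference)
  }

  pre_umi_reports <- lapply(seq_len(ns), function(s) {
    r <- pe_report(cohort$samples[[s]]$ccf1)
    r$family_size_threshold <- 0L
    r
  })
  pre_umi <- data.frame(
    sample_id = seq_len(ns),
    error_rate = vapply(pre_umi_reports, `[[`, numeric(1), "error_rate"),
    nra = vapply(pre_umi_reports, `[[`, numeric(1), "total_nra_observations"),
    bases = vapply(pre_umi_reports, `[[`, numeric(1), "total_quality_bases")
  )

  ccf_nras_cat <- lapply(seq_len(ns), function(s)
    fs_nras(consensus[[s]]$ccf1, patterned_fs))
  names(ccf_nras_cat) <- as.character(seq_len(ns))

  chip <- NULL
  if ("C" %in% corrections) {
    buffy_nras <- lapply(seq_len(ns), function(s)
      fs_nras(consensus[[s]]$buffy, chip_fs))
    names(buffy_nras) <- as.character(seq_len(ns))
    chip <- detect_chip(buffy_nras, recurrence_cutoff = recurrence_cutoff)
  }
  patterned <- patterned_positions(ccf_nras_cat, relatedness_k)

  relatedness_sweep <- data.frame(
    relatedness_k = seq_len(ns),
    n_positions = vapply(seq_len(ns), function(k)
      nrow(patterned_positions(ccf_nras_cat, k)), integer(1))
  )

  sets <- subset_strings(corrections)
  reports <- list()
  rows <- list()
  dup_rows <- list()
  for (fs in family_sizes) {
    fs_key <- as.character(fs)
    reports[[fs_key]] <- list()
    base_reports <- lapply(seq_len(ns), function(s)
      fs_report(consensus[[s]]$ccf1, fs))
    partner_nras <- if ("D" %in% corrections) {
      lapply(seq_len(ns), function(s)
        fs_nras(consensus[[s]][[need_partner]], fs))
    } else NULL
    for (set in sets) {
      labels <- strsplit(set, "", fixed = TRUE)[[1]]
      reps <- lapply(seq_len(ns), function(s) {
        apply_corrections(base_reports[[s]], labels, chip = chip,
                          patterned = patterned,
                          partner_nras = partner_nras[[s]],
                          sample_id = s, match_on_alt = match_on_alt)
      })
      reports[[fs_key]][[if (nzchar(set)) set else "baseline"]] <- reps
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = seq_len(ns), family_size = fs,
        corrections = if (nzchar(set)) set else "",
        error_rate = vapply(reps, `[[`, numeric(1), "error_rate"),
        nra = vapply(reps, `[[`, numeric(1), "total_nra_observations"),
        bases = vapply(reps, `[[`, numeric(1), "total_quality_bases"),
        footprint = vapply(reps, `[[`, numeric(1), "n_passing_positions"),
        stringsAsFactors = FALSE
      )
    }
    # full vs sequencing duplicate comparison (D-only), when both exist
    have_both <- !vapply(cohort$samples, function(s)
      is.null(s$ccf2) || is.null(s$seqdup), logical(1))
    if (all(have_both)) {
      full_nras <- lapply(seq_len(ns), function(s)
        fs_nras(consensus[[s]]$ccf2, fs))
      seq_nras <- lapply(seq_len(ns), function(s)
        fs_nras(consensus[[s]]$seqdup, fs))
      dup_rows[[length(dup_rows) + 1L]] <- data.frame(
        sample_id = seq_len(ns), family_size = fs,
        error_full = vapply(seq_len(ns), function(s)
          apply_corrections(base_reports[[s]], "D",
                            partner_nras = full_nras[[s]])$error_rate,
          numeric(1)),
        error_seq = vapply(seq_len(ns), function(s)
          apply_corrections(base_reports[[s]], "D",
                            partner_nras = seq_nras[[s]])$error_rate,
          numeric(1))
      )
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  baseline <- table[table$corrections == "", c("sample_id", "family_size",
                                               "error_rate")]
  names(baseline)[3] <- "baseline_rate"
  merged <- merge(table, baseline, by = c("sample_id", "family_size"))
  merged$reduction_vs_baseline <- 100 * (1 - merged$error_rate /
                                           merged$baseline_rate)
  merged$reduction_vs_preumi <- 100 * (1 - merged$error_rate /
                                         pre_umi$error_rate[merged$sample_id])
  agg <- function(v, by) {
    m <- stats::aggregate(v, by, mean)
    s <- stats::aggregate(v, by, stats::sd)
    m$sd <- s$x
    names(m)[names(m) == "x"] <- "mean"
    m
  }
  by <- list(family_size = merged$family_size, corrections = merged$corrections)
  sm <- agg(merged$error_rate, by)
  names(sm)[names(sm) %in% c("mean", "sd")] <- c("error_mean", "error_sd")
  r1 <- agg(merged$reduction_vs_baseline, by)
  names(r1)[names(r1) %in% c("mean", "sd")] <- c("reduction_vs_baseline_mean",
                                                 "reduction_vs_baseline_sd")
  r2 <- agg(merged$reduction_vs_preumi, by)
  names(r2)[names(r2) %in% c("mean", "sd")] <- c("reduction_vs_preumi_mean",
                                                 "reduction_vs_preumi_sd")
  summary_tab <- Reduce(function(a, b) merge(a, b,
                                             by = c("family_size", "corrections")),
                        list(sm, r1, r2))

  out <- list(
    table = table, pre_umi = pre_umi, summary = summary_tab,
    chip = chip, patterned = patterned,
    relatedness_sweep = relatedness_sweep,
    duplicate_comparison = if (length(dup_rows)) do.call(rbind, dup_rows) else NULL,
    nras = ccf_nras_cat, consensus = consensus, reports = reports,
    params = list(corrections = corrections, family_sizes = family_sizes,
                  relatedness_k = relatedness_k, min_depth = min_depth,
                  max_af = max_af, window = window, chip_fs = chip_fs,
                  patterned_fs = patterned_fs,
                  regions = regions,
                  duplicate_source = duplicate_source,
                  recurrence_cutoff = recurrence_cutoff,
                  match_on_alt = match_on_alt)
  )
  class(out) <- "decomposition_result"
  out
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("ccfDNA noise decomposition\n")
  s <- x$summary
  s <- s[order(s$family_size, nchar(s$corrections), s$corrections), ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  FS>=%d %-4s error %.3e (+/- %.1e)  vs baseline %6.1f%%  vs pre-UMI %6.1f%%\n",
                s$family_size[i],
                ifelse(nzchar(s$corrections[i]), s$corrections[i], "-"),
                s$error_mean[i], s$error_sd[i],
                s$reduction_vs_baseline_mean[i],
                s$reduction_vs_preumi_mean[i]))
  }
  invisible(x)
}

#' Audit surviving NRAs against simulation truth labels
#'
#' Classifies every NRA that survives a given correction set at a given
#' family size by the truth tags of the consensus reads that contribute
#' the alternate allele. Categories, in priority order: `true_variant`
#' (spiked variant), `first_cycle_error` (early PCR), `chip_variant`,
#' `patterned_error`, `late_pcr_error`, `seq_error`, `untagged`. The
#' attribute `fraction_early_or_true` gives the share of surviving records
#' explained by early PCR errors or true variants -- the computable
#' analogue of attributing post-correction residual error to early, random
#' PCR events.
#'
#' @param result a [run_decomposition()] object.
#' @param family_size family-size threshold to audit.
#' @param corrections correction-set label (e.g. `"CPD"`; `""` for the
#'   baseline).
#' @return data.frame `sample_id`, `pos`, `alt`, `alt_count`, `category`
#'   with attribute `fraction_early_or_true`.
#' @export
audit_truth <- function(result, family_size = 2L, corrections = "CPD") {
  fs_key <- as.character(family_size)
  set_key <- if (nzchar(corrections)) corrections else "baseline"
  reps <- result$reports[[fs_key]][[set_key]]
  if (is.null(reps)) stop("no stored reports for FS>=", family_size,
                          " corrections '", corrections, "'")
  priority <- c("true_variant", "first_cycle_error", "chip_variant",
                "patterned_error", "late_pcr_error", "seq_error")
  rows <- list()
  for (s in seq_along(reps)) {
    surv <- centers_to_nras(reps[[s]]$centers)
    if (nrow(surv) == 0L) next
    cons <- filter_by_family_size(result$consensus[[s]]$ccf1, family_size)
    lens <- nchar(cons$seq)
    for (i in seq_len(nrow(surv))) {
      p <- surv$pos[i]
      cover <- which(cons$left <= p & p < cons$left + lens)
      carriers <- cover[substr(cons$seq[cover], p - cons$left[cover] + 1L,
                               p - cons$left[cover] + 1L) == surv$alt[i]]
      tags <- unlist(cons$truth_tags[carriers])
      tags <- tags[endsWith(tags, paste0("@", p))]
      kinds <- unique(sub("@.*$", "", tags))
      hit <- priority[priority %in% kinds]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, pos = p, alt = surv$alt[i],
        alt_count = surv$alt_count[i],
        category = if (length(hit)) hit[1] else "untagged",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = integer(0), pos = integer(0),
               alt = character(0), alt_count = integer(0),
               category = character(0), stringsAsFactors = FALSE)
  attr(out, "fraction_early_or_true") <-
    if (nrow(out)) mean(out$category %in% c("first_cycle_error",
                                            "true_variant")) else NA_real_
  out
}
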