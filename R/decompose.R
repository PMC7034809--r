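# Stepwise noise decomposition: CHIP filtering against matched buffy-coat
# data (C), patterned-position removal at configurable relatedness (P),
# and sample-duplicate intersection (D).

#' Detect candidate CHIP variants from buffy-coat NRA records
#'
#' Clonal-hematopoiesis (CHIP) variants are real somatic variants of white
#' blood cells that contaminate ccfDNA; they are identified as buffy-coat
#' NRAs with allele frequency in the [`af_low`, `af_high`] window.
#' Positions recurring in at least `recurrence_cutoff` samples are excluded
#' from the CHIP pool: such recurrence marks a position-specific artifact
#' (patterned error), not independent clonal hematopoiesis. Recurrence is
#' counted at position level (the alternate allele is ignored), matching
#' the position-level nature of mapping artifacts.
#'
#' @param buffy_nras named list (one element per sample) of `nra_records`
#'   computed from buffy-coat consensus data at family size >= 2.
#' @param af_low,af_high allele-frequency window (defaults 0.02 / 0.30).
#' @param recurrence_cutoff samples at/above which a position is treated as
#'   patterned rather than CHIP (default 6).
#' @return object of class `chip_set`: list with `variants` (data.frame
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`, `af`), `excluded_recurrent`
#'   (data.frame `chrom`, `pos`, `n_samples`), and the parameters.
#' @export
detect_chip <- function(buffy_nras, af_low = 0.02, af_high = 0.30,
                        recurrence_cutoff = 6L) {
  if (af_low >= af_high) stop("af_low must be smaller than af_high")
  samples <- names(buffy_nras) %||% as.character(seq_along(buffy_nras))
  cand <- do.call(rbind, lapply(seq_along(buffy_nras), function(k) {
    x <- buffy_nras[[k]]
    x <- x[x$af >= af_low & x$af <= af_high, , drop = FALSE]
    if (nrow(x) == 0L) return(NULL)
    data.frame(sample_id = samples[k], chrom = x$chrom, pos = x$pos,
               ref = x$ref, alt = x$alt, af = x$af, stringsAsFactors = FALSE)
  }))
  if (is.null(cand)) {
    cand <- data.frame(sample_id = character(0), chrom = character(0),
                       pos = integer(0), ref = character(0),
                       alt = character(0), af = numeric(0),
                       stringsAsFactors = FALSE)
  }
  key <- paste(cand$chrom, cand$pos)
  per_pos <- tapply(cand$sample_id, key, function(s) length(unique(s)))
  recurrent <- names(per_pos)[per_pos >= recurrence_cutoff]
  excluded <- cand[key %in% recurrent, , drop = FALSE]
  variants <- cand[!key %in% recurrent, , drop = FALSE]
  rownames(variants) <- NULL
  excl <- unique(excluded[, c("chrom", "pos")])
  excl$n_samples <- as.integer(per_pos[paste(excl$chrom, excl$pos)])
  rownames(excl) <- NULL
  out <- list(variants = variants, excluded_recurrent = excl,
              af_low = af_low, af_high = af_high,
              recurrence_cutoff = as.integer(recurrence_cutoff))
  class(out) <- "chip_set"
  out
}

#' @export
print.chip_set <- function(x, ...) {
  cat(sprintf("CHIP set: %d variant(s) in AF [%.2f, %.2f]; %d recurrent position(s) excluded (cutoff %d)\n",
              nrow(x$variants), x$af_low, x$af_high,
              nrow(x$excluded_recurrent), x$recurrence_cutoff))
  invisible(x)
}

#' Identify patterned-error positions across a cohort
#'
#' A position is patterned at relatedness `relatedness_k` when at least
#' `relatedness_k` samples show any NRA there (allele identity ignored).
#' `relatedness_k = n_samples` reproduces "highly patterned error"
#' (positions with error in every sample); lower values are progressively
#' more lenient and remove more footprint.
#'
#' @param ccf_nras named list (one per sample) of `nra_records` from
#'   ccfDNA consensus data at family size >= 2.
#' @param relatedness_k minimum number of samples sharing an NRA
#'   (1 <= k <= number of samples).
#' @return object of class `patterned_set`: data.frame `chrom`, `pos`,
#'   `n_samples` (samples with an NRA there), with attribute
#'   `relatedness_k`.
#' @export
patterned_positions <- function(ccf_nras, relatedness_k) {
  n_samples <- length(ccf_nras)
  if (relatedness_k < 1L || relatedness_k > n_samples) {
    stop("relatedness_k must lie in [1, n_samples]")
  }
  pos <- do.call(rbind, lapply(seq_along(ccf_nras), function(k) {
    x <- ccf_nras[[k]]
    if (nrow(x) == 0L) return(NULL)
    unique(data.frame(sample = k, chrom = x$chrom, pos = x$pos,
                      stringsAsFactors = FALSE))
  }))
  if (is.null(pos)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      n_samples = integer(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(pos$chrom, pos$pos)
    cnt <- table(key)
    sel <- names(cnt)[cnt >= relatedness_k]
    u <- unique(pos[key %in% sel, c("chrom", "pos")])
    u$n_samples <- as.integer(cnt[paste(u$chrom, u$pos)])
    u <- u[order(u$chrom, u$pos), , drop = FALSE]
    rownames(u) <- NULL
    out <- u
  }
  attr(out, "relatedness_k") <- as.integer(relatedness_k)
  class(out) <- c("patterned_set", class(out))
  out
}

#' Intersect NRA sets of two sample duplicates
#'
#' Error confirmation by technical duplication: only NRAs present in both
#' duplicates of the same sample are retained. By default the match
#' requires the identical alternate allele at the position
#' (`match_on_alt = TRUE`); position-only matching is available since
#' duplicate confirmation at allele level versus position level are both
#' defensible readings.
#'
#' @param nras_a,nras_b `nra_records` (or compatible data.frames with
#'   `chrom`, `pos`, `alt`) from the two duplicates.
#' @param match_on_alt require identical alternate alleles (default TRUE).
#' @return the rows of `nras_a` confirmed by `nras_b`.
#' @export
intersect_duplicates <- function(nras_a, nras_b, match_on_alt = TRUE) {
  key <- function(x) {
    if (match_on_alt) paste(x$chrom, x$pos, x$alt) else paste(x$chrom, x$pos)
  }
  out <- nras_a[key(nras_a) %in% key(nras_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent error reduction of a corrected report versus baseline
#'
#' `100 * (1 - corrected / baseline)` on the error rates. A zero baseline
#' with nonzero corrected error is undefined and returns `NA` with a
#' warning; a zero baseline with zero corrected error returns 0.
#'
#' @param baseline,corrected `error_report` objects (or bare rates).
#' @return percent reduction (can be negative if error increased).
#' @export
error_reduction <- function(baseline, corrected) {
  b <- if (inherits(baseline, "error_report")) baseline$error_rate else baseline
  c_ <- if (inherits(corrected, "error_report")) corrected$error_rate else corrected
  if (is.na(b) || is.na(c_)) return(NA_real_)
  if (b == 0) {
    if (c_ == 0) return(0)
    warning("baseline error is zero with nonzero corrected error: reduction undefined")
    return(NA_real_)
  }
  100 * (1 - c_ / b)
}

#' Substitution spectrum over the 12 ordered ref>alt types
#'
#' @param nras an `nra_records` data.frame.
#' @param weight `"observations"` counts each alternate observation
#'   (`alt_count`); `"records"` counts each position/alt record once.
#' @return data.frame `substitution_type`, `count`, `percent` (percentages
#'   sum to 100 for non-empty input).
#' @export
substitution_spectrum <- function(nras, weight = c("observations", "records")) {
  weight <- match.arg(weight)
  if (nrow(nras) == 0L) {
    return(data.frame(substitution_type = SUBSTITUTION_TYPES, count = 0L,
                      percent = 0, stringsAsFactors = FALSE))
  }
  ty <- factor(paste0(nras$ref, ">", nras$alt), levels = SUBSTITUTION_TYPES)
  w <- if (weight == "observations") nras$alt_count else rep(1L, nrow(nras))
  count <- as.integer(tapply(w, ty, sum, default = 0L))
  total <- sum(count)
  data.frame(substitution_type = SUBSTITUTION_TYPES, count = count,
             percent = if (total > 0) 100 * count / total else 0,
             stringsAsFactors = FALSE)
}

#' Allele-frequency binning of NRA records
#'
#' Fraction of NRA records per allele-frequency bin; used to show how much
#' of the observed error sits below 0.1% allele frequency.
#'
#' @param nras an `nra_records` data.frame with AFs in (0, 0.4].
#' @param edges internal bin edges (default `c(0.001, 0.01)`, i.e. bins
#'   (0, 0.1%], (0.1%, 1%], (1%, 40%]).
#' @return data.frame `bin`, `count`, `fraction` (fractions sum to 1 for
#'   non-empty input).
#' @export
af_bins <- function(nras, edges = c(0.001, 0.01)) {
  breaks <- c(0, edges, 0.4)
  labs <- paste0("(", utils::head(breaks, -1), ",", breaks[-1], "]")
  b <- cut(nras$af, breaks = breaks, labels = labs)
  count <- as.integer(table(b))
  total <- sum(count)
  data.frame(bin = labs, count = count,
             fraction = if (total > 0) count / total else 0,
             stringsAsFactors = FALSE)
}

#' Apply noise corrections to an error report
#'
#' The correction ledger, acting on the per-center table of an
#' [estimate_error_rates()] report:
#' * `C` zeroes the counts of this sample's CHIP (position, alt) alleles
#'   (sample-specific biology removed from the error tally; the position
#'   stays in the footprint),
#' * `P` drops patterned positions from the footprint entirely (numerator
#'   and denominator),
#' * `D` keeps only NRAs confirmed in the partner duplicate
#'   (numerator only; the denominator still counts the position's depth).
#'
#' `C` and `P` commute (they act on disjoint axes); `D` is applied last.
#'
#' @param report an `error_report`.
#' @param corrections character vector, subset of `c("C", "P", "D")`.
#' @param chip a [detect_chip()] object (required for `C`).
#' @param patterned a [patterned_positions()] object (required for `P`).
#' @param partner_nras NRA data.frame of the partner duplicate (required
#'   for `D`).
#' @param sample_id sample whose CHIP variants apply (required for `C`).
#' @param match_on_alt see [intersect_duplicates()].
#' @return a corrected `error_report` with updated `correction_labels` and
#'   footprint.
#' @export
apply_corrections <- function(report, corrections = character(0),
                              chip = NULL, patterned = NULL,
                              partner_nras = NULL, sample_id = NULL,
                              match_on_alt = TRUE) {
  stopifnot(inherits(report, "error_report"))
  corrections <- intersect(c("C", "P", "D"), corrections)
  centers <- report$centers
  if ("C" %in% corrections) {
    if (is.null(chip) || is.null(sample_id)) {
      stop("correction C requires a chip_set and a sample_id")
    }
    v <- chip$variants[chip$variants$sample_id == as.character(sample_id) |
                         chip$variants$sample_id == sample_id, , drop = FALSE]
    if (nrow(v)) {
      m <- match(paste(v$chrom, v$pos), paste(centers$chrom, centers$pos))
      hit <- which(!is.na(m))
      for (i in hit) {
        row <- m[i]
        removed <- centers[row, v$alt[i]]
        centers[row, v$alt[i]] <- 0L
        centers$depth[row] <- centers$depth[row] - removed
      }
    }
  }
  if ("P" %in% corrections) {
    if (is.null(patterned)) stop("correction P requires a patterned_set")
    if (nrow(patterned)) {
      drop <- paste(centers$chrom, centers$pos) %in%
        paste(patterned$chrom, patterned$pos)
      centers <- centers[!drop, , drop = FALSE]
    }
  }
  if ("D" %in% corrections) {
    if (is.null(partner_nras)) stop("correction D requires partner NRAs")
    nras <- centers_to_nras(centers)
    confirmed <- intersect_duplicates(nras, partner_nras, match_on_alt)
    ckey <- paste(confirmed$chrom, confirmed$pos, confirmed$alt)
    if (nrow(nras)) {
      for (i in seq_len(nrow(nras))) {
        k <- paste(nras$chrom[i], nras$pos[i], nras$alt[i])
        if (!k %in% ckey) {
          row <- match(paste(nras$chrom[i], nras$pos[i]),
                       paste(centers$chrom, centers$pos))
          centers[row, nras$alt[i]] <- 0L
        }
      }
    }
  }
  report_from_centers(centers, params = report$params,
                      correction_labels = sort(corrections),
                      family_size_threshold = report$family_size_threshold)
}
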