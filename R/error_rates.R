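# The two base-level error estimators: a region-gated global error rate
# and a per-position nonreference-allele (NRA) track.

SUBSTITUTION_TYPES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                        "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Region-gated base-level error rate
#'
#' Slides a window over every run of `window` adjacent covered reference
#' positions. A region passes iff all its columns have depth >=
#' `min_depth`, show no indel evidence, and every alternate allele has
#' frequency <= `max_af` (which excludes heterozygous/homozygous germline
#' sites). Only the center base of each passing region is tabulated;
#' windows slide by one so interior positions of a clean run each serve as
#' the center of exactly one window. The error rate is the number of
#' nonreference center-base observations divided by the number of quality
#' center-base observations.
#'
#' @param pileup a [build_pileup()] data.frame, sorted by position.
#' @param min_depth minimum quality base depth per column (default 100).
#' @param max_af maximum tolerated alternate allele frequency (default 0.4).
#' @param window region width in adjacent bases (default 7).
#' @return object of class `error_report`: list with `error_rate`,
#'   `total_nra_observations`, `total_quality_bases`,
#'   `n_passing_positions`, `family_size_threshold` (filled by callers),
#'   `correction_labels`, `empty` flag, and `centers`, the per-center
#'   data.frame (`chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`, `depth`) on
#'   which the decomposition module operates.
#' @export
estimate_error_rates <- function(pileup, min_depth = 100L, max_af = 0.4,
                                 window = 7L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (nrow(pileup) == 0L) {
    return(new_error_report(pileup[0, ], min_depth, max_af, window,
                            empty = TRUE))
  }
  pileup <- pileup[order(pileup$chrom, pileup$pos), , drop = FALSE]
  cm <- as.matrix(pileup[, BASES])
  n <- nrow(pileup)
  ri <- match(pileup$ref, BASES)
  alt_cm <- cm
  alt_cm[cbind(seq_len(n), ri)] <- 0L
  max_alt <- do.call(pmax, as.data.frame(alt_cm))
  pass <- pileup$depth >= min_depth & !pileup$indel &
    (max_alt / pileup$depth) <= max_af

  # maximal runs of consecutive reference positions that all pass
  new_run <- c(TRUE, diff(pileup$pos) != 1L |
                 pileup$chrom[-1] != pileup$chrom[-n]) | !pass
  run_id <- cumsum(new_run)
  run_id[!pass] <- NA_integer_
  centers_idx <- integer(0)
  h <- (window - 1L) %/% 2L
  for (rid in unique(stats::na.omit(run_id))) {
    idx <- which(!is.na(run_id) & run_id == rid)
    len <- length(idx)
    if (len >= window) {
      centers_idx <- c(centers_idx, idx[(h + 1L):(len - h)])
    }
  }
  new_error_report(pileup[centers_idx, , drop = FALSE],
                   min_depth, max_af, window)
}

new_error_report <- function(centers, min_depth, max_af, window,
                             empty = FALSE) {
  centers <- centers[, c("chrom", "pos", "ref", BASES, "depth"), drop = FALSE]
  rownames(centers) <- NULL
  report_from_centers(centers, params = list(min_depth = min_depth,
                                             max_af = max_af,
                                             window = window),
                      empty = empty)
}

# Recompute totals from a centers table (used after corrections too).
report_from_centers <- function(centers, params, correction_labels = character(0),
                                family_size_threshold = NA_integer_,
                                empty = NULL) {
  n <- nrow(centers)
  total_bases <- sum(centers$depth)
  if (n > 0L) {
    # NRA count is the sum of alternate-base cells, not depth minus
    # reference: after duplicate confirmation the unconfirmed alternate
    # counts are zeroed while the denominator keeps the position's depth.
    cm <- as.matrix(centers[, BASES])
    ref_counts <- cm[cbind(seq_len(n), match(centers$ref, BASES))]
    total_nra <- sum(cm) - sum(ref_counts)
  } else {
    total_nra <- 0L
  }
  out <- list(
    error_rate = if (total_bases > 0) total_nra / total_bases else NA_real_,
    total_nra_observations = total_nra,
    total_quality_bases = total_bases,
    n_passing_positions = n,
    family_size_threshold = family_size_threshold,
    correction_labels = correction_labels,
    empty = empty %||% (total_bases == 0),
    centers = centers,
    params = params
  )
  class(out) <- "error_report"
  out
}

#' @export
print.error_report <- function(x, ...) {
  lab <- if (length(x$correction_labels)) {
    paste(x$correction_labels, collapse = "")
  } else "none"
  cat(sprintf("error report: %d passing centers, %d NRA / %d quality bases\n",
              x$n_passing_positions, x$total_nra_observations,
              x$total_quality_bases))
  cat(sprintf("  error rate: %s | family size >= %s | corrections: %s\n",
              formatC(x$error_rate, digits = 4, format = "g"),
              ifelse(is.na(x$family_size_threshold), "?",
                     x$family_size_threshold), lab))
  if (x$empty) cat("  [empty: zero denominator]\n")
  invisible(x)
}

#' Per-position nonreference-allele records
#'
#' Emits one record per position per observed alternate allele for
#' positions with quality depth >= `min_depth`; positions with evidence of
#' a heterozygous or homozygous germline allele (any alternate frequency >
#' `max_af`) are ignored entirely. When `reference` is supplied each
#' record also carries the GC fraction of the +/-`gc_flank` bp context.
#'
#' @inheritParams estimate_error_rates
#' @param reference optional reference sequence for GC context.
#' @param gc_flank flank for [gc_context()] (default 10).
#' @return data.frame of class `nra_records`: `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `alt_count`, `depth`, `af`, `substitution_type` (factor
#'   over the 12 ordered ref>alt types), `gc` (or `NA`).
#' @export
parse_positions <- function(pileup, min_depth = 100L, max_af = 0.4,
                            reference = NULL, gc_flank = 10L) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_count = integer(0), depth = integer(0),
                      af = numeric(0),
                      substitution_type = factor(character(0),
                                                 levels = SUBSTITUTION_TYPES),
                      gc = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("nra_records", class(empty))
  if (nrow(pileup) == 0L) return(empty)
  cm <- as.matrix(pileup[, BASES])
  n <- nrow(pileup)
  ri <- match(pileup$ref, BASES)
  alt_cm <- cm
  alt_cm[cbind(seq_len(n), ri)] <- 0L
  max_alt <- do.call(pmax, as.data.frame(alt_cm))
  keep <- pileup$depth >= min_depth & (max_alt / pileup$depth) <= max_af
  rows <- which(alt_cm > 0L & keep, arr.ind = TRUE)
  if (nrow(rows) == 0L) return(empty)
  i <- rows[, 1]; a <- rows[, 2]
  out <- data.frame(
    chrom = pileup$chrom[i], pos = pileup$pos[i], ref = pileup$ref[i],
    alt = BASES[a], alt_count = alt_cm[rows], depth = pileup$depth[i],
    stringsAsFactors = FALSE
  )
  out$af <- out$alt_count / out$depth
  out$substitution_type <- factor(paste0(out$ref, ">", out$alt),
                                  levels = SUBSTITUTION_TYPES)
  out$gc <- if (!is.null(reference)) {
    vapply(out$pos, function(p) as.numeric(gc_context(reference, p, gc_flank)),
           numeric(1))
  } else NA_real_
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nra_records", class(out))
  out
}

# Melt an error_report centers table into position/alt NRA rows (used for
# duplicate confirmation inside the decomposition).
centers_to_nras <- function(centers) {
  if (nrow(centers) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_count = integer(0), depth = integer(0),
                      af = numeric(0), stringsAsFactors = FALSE))
  }
  cm <- as.matrix(centers[, BASES])
  cm[cbind(seq_len(nrow(centers)), match(centers$ref, BASES))] <- 0L
  rows <- which(cm > 0L, arr.ind = TRUE)
  out <- data.frame(
    chrom = centers$chrom[rows[, 1]], pos = centers$pos[rows[, 1]],
    ref = centers$ref[rows[, 1]], alt = BASES[rows[, 2]],
    alt_count = cm[rows], depth = centers$depth[rows[, 1]],
    stringsAsFactors = FALSE
  )
  out$af <- out$alt_count / out$depth
  out[order(out$pos, out$alt), , drop = FALSE]
}
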