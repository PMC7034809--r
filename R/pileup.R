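#' Build a quality-filtered pileup from placed reads
#'
#' Stacks base observations per reference position, counting only bases
#' with quality >= `min_base_qual` from reads with mapping quality >=
#' `min_mapq`, restricted to the target regions (error analysis is
#' restricted to exons in the real workflow; the default region is the
#' whole reference). N bases never count: consensus Ns carry quality zero,
#' which is the exclusion mechanism.
#'
#' @param reads an `aligned_reads` or `consensus_reads` data.frame (needs
#'   columns `left`, `seq`, `qual`, `mapq`).
#' @param reference reference sequence (character scalar).
#' @param regions data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open); `NULL` means the whole reference.
#' @param min_base_qual,min_mapq Phred gates (defaults 20/20).
#' @return a data.frame of class `pileup` with one row per covered in-region
#'   position: `chrom`, `pos` (0-based), `ref`, counts `A`, `C`, `G`, `T`,
#'   `depth`, and logical `indel` (always `FALSE` here; fixtures may set it
#'   to exercise the indel gate).
#' @export
build_pileup <- function(reads, reference, regions = NULL,
                         min_base_qual = 20L, min_mapq = 20L) {
  ref_len <- nchar(reference)
  if (is.null(regions)) {
    regions <- data.frame(chrom = "ref", start = 0L, end = ref_len)
  }
  if (any(regions$start < 0L) || any(regions$end > ref_len) ||
      any(regions$start >= regions$end)) {
    stop("regions must be non-empty 0-based half-open intervals inside the reference")
  }
  in_region <- rep(FALSE, ref_len)
  for (i in seq_len(nrow(regions))) {
    in_region[(regions$start[i] + 1L):regions$end[i]] <- TRUE
  }

  keep <- reads$mapq >= min_mapq
  reads <- reads[keep, , drop = FALSE]
  counts <- matrix(0L, nrow = ref_len, ncol = 4L,
                   dimnames = list(NULL, BASES))
  if (nrow(reads) > 0L) {
    lens <- nchar(reads$seq)
    pos <- rep(reads$left, lens) + sequence(lens) - 1L       # 0-based
    bases <- unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE)
    quals <- unlist(lapply(reads$qual, string_to_phred), use.names = FALSE)
    bi <- match(bases, BASES)
    ok <- !is.na(bi) & quals >= min_base_qual & pos >= 0L & pos < ref_len
    ok[ok] <- in_region[pos[ok] + 1L]
    idx <- pos[ok] * 4L + bi[ok]                             # 1 .. 4*ref_len
    tab <- tabulate(idx, nbins = 4L * ref_len)
    counts <- matrix(tab, ncol = 4L, byrow = TRUE,
                     dimnames = list(NULL, BASES))
  }
  depth <- rowSums(counts)
  sel <- which(depth > 0L & in_region)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  out <- data.frame(chrom = rep("ref", length(sel)), pos = sel - 1L,
                    ref = ref_chars[sel], counts[sel, , drop = FALSE],
                    depth = depth[sel], indel = rep(FALSE, length(sel)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pileup", class(out))
  out
}

#' Local GC content around a position
#'
#' G+C fraction of the window of `flank` bases either side of `position`
#' (21 bases at the default flank of 10), truncated at the contig ends;
#' truncation is flagged in the `truncated` attribute.
#'
#' @param reference reference sequence (character scalar).
#' @param position 0-based position.
#' @param flank flank width in bases.
#' @return numeric fraction in [0, 1] with attribute `truncated`.
#' @export
gc_context <- function(reference, position, flank = 10L) {
  n <- nchar(reference)
  if (position < 0L || position >= n) stop("position outside the reference")
  lo <- max(0L, position - flank)
  hi <- min(n - 1L, position + flank)
  win <- strsplit(substr(reference, lo + 1L, hi + 1L), "", fixed = TRUE)[[1]]
  out <- mean(win %in% c("G", "C"))
  attr(out, "truncated") <- (hi - lo + 1L) < (2L * flank + 1L)
  out
}
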