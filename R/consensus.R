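# UMI family grouping and consensus calling.
#
# A family is the set of PCR duplicates sharing (chrom, unclipped start,
# mate unclipped start, UMI) with exact UMI matching -- no mismatch
# tolerance, so a single UMI sequencing error founds a new family. Family
# size is the number of reads collapsed into one consensus sequence.

# Core consensus rule, shared by every entry point. `seqs` is a character
# vector, `quals` a list of integer Phred vectors, `lefts` the 0-based
# leftmost reference positions. Per column: if the predominant vote has
# fraction strictly greater than `threshold` of the informative (non-N)
# votes among covering members, the column gets that base with the maximum
# quality observed among the members carrying it; otherwise an N with
# quality zero. Columns covered by no member are clipped at the span ends
# and emitted as N/q0 inside coverage gaps.
consensus_core <- function(seqs, quals, lefts, threshold = 0.66) {
  k <- length(seqs)
  lens <- nchar(seqs)
  if (k == 1L) {
    return(list(seq = seqs, qual = quals[[1]], left = lefts))
  }
  if (all(lefts == lefts[1]) && all(lens == lens[1])) {
    if (all(seqs == seqs[1]) && !grepl("N", seqs[1], fixed = TRUE)) {
      return(list(seq = seqs[1], qual = Reduce(pmax, quals), left = lefts[1]))
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    qmat <- do.call(rbind, quals)
    L <- lens[1]
    cons <- mat[1, ]
    consq <- Reduce(pmax, quals)
    neq <- mat != matrix(mat[1, ], k, L, byrow = TRUE)
    fix <- which(colSums(neq) > 0L | mat[1, ] == "N")
    for (j in fix) {
      r <- column_call(mat[, j], qmat[, j], threshold)
      cons[j] <- r$base
      consq[j] <- r$qual
    }
    return(list(seq = paste(cons, collapse = ""), qual = consq,
                left = lefts[1]))
  }
  # General path: unequal spans (fixture territory; the simulator emits
  # equal spans). Denominator at each column is the covering subset.
  lo <- min(lefts)
  hi <- max(lefts + lens)
  W <- hi - lo
  cons <- rep("N", W)
  consq <- rep(0L, W)
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (j in seq_len(W)) {
    p <- lo + j - 1L
    cov <- which(lefts <= p & p < lefts + lens)
    if (!length(cov)) next
    b <- vapply(cov, function(i) chars[[i]][p - lefts[i] + 1L], character(1))
    q <- vapply(cov, function(i) quals[[i]][p - lefts[i] + 1L], integer(1))
    r <- column_call(b, q, threshold)
    cons[j] <- r$base
    consq[j] <- r$qual
  }
  list(seq = paste(cons, collapse = ""), qual = consq, left = lo)
}

column_call <- function(bases, quals, threshold) {
  inf <- bases != "N"
  if (!any(inf)) return(list(base = "N", qual = 0L))
  b <- bases[inf]; q <- quals[inf]
  tab <- table(b)
  top <- max(tab)
  if (top / length(b) > threshold) {
    winners <- names(tab)[tab == top]
    if (length(winners) > 1L) return(list(base = "N", qual = 0L))
    list(base = winners, qual = max(q[b == winners]))
  } else {
    list(base = "N", qual = 0L)
  }
}

family_key_string <- function(reads) {
  paste(reads$chrom, reads$start, reads$mate_start, reads$umi, sep = "|")
}

#' Group aligned reads into UMI families
#'
#' Partitions reads by the family key (chrom, unclipped start, mate
#' unclipped start, UMI). UMI matching is exact, so reads whose UMIs differ
#' at a single base fall into distinct families, and the two strand
#' lineages of a duplex molecule (rotated UMIs "abc,def" vs "def,abc")
#' form two separate families.
#'
#' @param reads an `aligned_reads` data.frame (see [simulate_library()],
#'   [read_alignments()]).
#' @param scheme optional adapter scheme; when given, UMI widths are
#'   checked (8 for singleton, 6 for duplex).
#' @return a list of class `family_list`; each element is a `read_family`
#'   list with `key` (chrom, start, mate_start, umi), `members` (the reads
#'   data.frame rows) and `size`. Reads with missing UMIs are rejected with
#'   a warning reporting the count (also stored as attribute
#'   `n_rejected`).
#' @export
group_families <- function(reads, scheme = NULL) {
  if (!is.null(scheme)) {
    w <- if (scheme == "duplex") 6L else 8L
    ok <- !is.na(reads$umi) & nchar(reads$umi) == w
  } else {
    ok <- !is.na(reads$umi) & nzchar(reads$umi)
  }
  n_rej <- sum(!ok)
  if (n_rej > 0L) {
    warning(n_rej, " read(s) rejected for missing/invalid UMI")
    reads <- reads[ok, , drop = FALSE]
  }
  key <- family_key_string(reads)
  groups <- split(seq_len(nrow(reads)), key)
  fams <- lapply(groups, function(idx) {
    structure(list(
      key = list(chrom = reads$chrom[idx[1]], start = reads$start[idx[1]],
                 mate_start = reads$mate_start[idx[1]],
                 umi = reads$umi[idx[1]]),
      members = reads[idx, , drop = FALSE],
      size = length(idx)
    ), class = "read_family")
  })
  structure(fams, class = "family_list", n_rejected = n_rej)
}

#' Call the consensus sequence of one UMI family
#'
#' Implements the concordance rule used throughout the package: at each
#' base position, if the predominant base exceeds `concordance_threshold`
#' (strictly) among the members covering the position, it is assigned with
#' the maximum quality observed for that base; otherwise an N with quality
#' zero. A two-member tie (1/2) and a 3-of-5 majority (0.6) both fall to N
#' under the default 0.66 threshold, while 2-of-3 (0.667) passes.
#'
#' @param family a `read_family` from [group_families()].
#' @param concordance_threshold strict lower bound on the predominant-base
#'   fraction.
#' @return a one-row `consensus_reads` data.frame (see
#'   [collapse_families()] for the columns).
#' @export
call_consensus <- function(family, concordance_threshold = 0.66) {
  stopifnot(inherits(family, "read_family"))
  m <- family$members
  if (is.null(m) || nrow(m) == 0L) stop("cannot call consensus of an empty family")
  r <- consensus_core(m$seq, lapply(m$qual, string_to_phred), m$left,
                      concordance_threshold)
  out <- data.frame(
    chrom = family$key$chrom, left = r$left, start = family$key$start,
    mate_start = family$key$mate_start, umi = family$key$umi,
    strand = m$strand[1], seq = r$seq, qual = phred_to_string(r$qual),
    family_size = family$size, duplex_step = "step1_single_strand",
    mapq = min(m$mapq), sample_id = m$sample_id[1],
    replicate_id = m$replicate_id[1], stringsAsFactors = FALSE
  )
  out$truth_tags <- list(unique(unlist(m$truth_tags)))
  class(out) <- c("consensus_reads", class(out))
  out
}

#' Collapse a whole library to consensus reads
#'
#' Groups reads into UMI families and calls every consensus in one pass
#' (the vectorised equivalent of [group_families()] +
#' [call_consensus()]). Truth tags of a consensus read are the union over
#' its members.
#'
#' @inheritParams group_families
#' @param concordance_threshold see [call_consensus()].
#' @return a `consensus_reads` data.frame with columns `chrom`, `left`,
#'   `start`, `mate_start`, `umi`, `strand`, `seq`, `qual`, `family_size`,
#'   `duplex_step`, `mapq`, `sample_id`, `replicate_id` and list column
#'   `truth_tags`.
#' @export
collapse_families <- function(reads, scheme = NULL,
                              concordance_threshold = 0.66) {
  if (!is.null(scheme)) {
    w <- if (scheme == "duplex") 6L else 8L
    ok <- !is.na(reads$umi) & nchar(reads$umi) == w
  } else {
    ok <- !is.na(reads$umi) & nzchar(reads$umi)
  }
  if (any(!ok)) {
    warning(sum(!ok), " read(s) rejected for missing/invalid UMI")
    reads <- reads[ok, , drop = FALSE]
  }
  n <- nrow(reads)
  if (n == 0L) stop("no reads to collapse")
  key <- family_key_string(reads)
  groups <- split(seq_len(n), key)
  nf <- length(groups)
  quals <- lapply(reads$qual, string_to_phred)

  seq_out <- character(nf); qual_out <- character(nf)
  left_out <- integer(nf); size_out <- integer(nf)
  first_idx <- integer(nf); tags_out <- vector("list", nf)
  for (g in seq_len(nf)) {
    idx <- groups[[g]]
    first_idx[g] <- idx[1]
    size_out[g] <- length(idx)
    r <- consensus_core(reads$seq[idx], quals[idx], reads$left[idx],
                        concordance_threshold)
    seq_out[g] <- r$seq
    qual_out[g] <- phred_to_string(r$qual)
    left_out[g] <- r$left
    tags_out[g] <- list(unique(unlist(reads$truth_tags[idx])))
  }
  out <- data.frame(
    chrom = reads$chrom[first_idx], left = left_out,
    start = reads$start[first_idx], mate_start = reads$mate_start[first_idx],
    umi = reads$umi[first_idx], strand = reads$strand[first_idx],
    seq = seq_out, qual = qual_out, family_size = size_out,
    duplex_step = "step1_single_strand",
    mapq = vapply(groups, function(idx) min(reads$mapq[idx]), integer(1)),
    sample_id = reads$sample_id[first_idx],
    replicate_id = reads$replicate_id[first_idx],
    stringsAsFactors = FALSE
  )
  out$truth_tags <- tags_out
  rownames(out) <- NULL
  for (a in c("sample_id", "replicate_id", "material", "mode", "scheme")) {
    attr(out, a) <- attr(reads, a)
  }
  class(out) <- c("consensus_reads", class(out))
  out
}

#' Pair duplex strand consensi (step 2)
#'
#' Second collapse step for the duplex scheme: step-1 consensus reads whose
#' UMI halves are mutual rotations ("abc,def" vs "def,abc") at swapped
#' start/mate coordinates derive from the two template strands of one
#' molecule and are collapsed with the same concordance rule over the two
#' sequences -- with two members any disagreement (1/2 <= 0.66) yields an
#' N, which is what removes early PCR errors confined to one strand.
#' Unpaired step-1 reads pass through unchanged. The fraction of reads
#' paired is reported via attributes `fraction_consensus_paired` (share of
#' step-1 consensus reads that found a partner) and
#' `fraction_reads_paired` (share of underlying sequencing reads, the
#' quantity comparable to real duplex libraries).
#'
#' @param step1 a `consensus_reads` data.frame from the duplex scheme.
#' @param concordance_threshold see [call_consensus()].
#' @return a `consensus_reads` data.frame where paired rows carry
#'   `duplex_step = "step2_paired"` and `family_size` equal to the sum of
#'   the two paired families.
#' @export
pair_duplex_strands <- function(step1, concordance_threshold = 0.66) {
  if (nrow(step1) == 0L) return(step1)
  if (any(nchar(step1$umi) != 6L)) {
    stop("duplex pairing requires 6-mer UMIs")
  }
  self_key <- paste(step1$chrom, step1$start, step1$mate_start, step1$umi,
                    sep = "|")
  partner_key <- paste(step1$chrom, step1$mate_start, step1$start,
                       rotate_umi(step1$umi), sep = "|")
  j <- match(partner_key, self_key)
  i <- seq_len(nrow(step1))
  paired <- !is.na(j) & j != i
  lead <- which(paired & i < j)

  quals <- lapply(step1$qual, string_to_phred)
  rows <- vector("list", length(lead))
  for (u in seq_along(lead)) {
    a <- lead[u]; b <- j[lead[u]]
    r <- consensus_core(step1$seq[c(a, b)], quals[c(a, b)],
                        step1$left[c(a, b)], concordance_threshold)
    row <- step1[a, , drop = FALSE]
    row$seq <- r$seq
    row$qual <- phred_to_string(r$qual)
    row$left <- r$left
    row$family_size <- step1$family_size[a] + step1$family_size[b]
    row$duplex_step <- "step2_paired"
    row$truth_tags <- list(unique(unlist(step1$truth_tags[c(a, b)])))
    rows[[u]] <- row
  }
  keep <- step1[!paired, , drop = FALSE]
  out <- rbind(do.call(rbind, rows), keep)
  rownames(out) <- NULL
  n_cons <- nrow(step1)
  attr(out, "fraction_consensus_paired") <- sum(paired) / n_cons
  attr(out, "fraction_reads_paired") <-
    sum(step1$family_size[paired]) / sum(step1$family_size)
  class(out) <- c("consensus_reads", class(out))
  out
}

#' Filter consensus reads by family size
#'
#' @param consensus a `consensus_reads` data.frame.
#' @param min_size minimum family size to keep (>= 1).
#' @return the filtered data.frame.
#' @export
filter_by_family_size <- function(consensus, min_size) {
  stopifnot(min_size >= 1L)
  out <- consensus[consensus$family_size >= min_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}
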