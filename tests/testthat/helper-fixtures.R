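# Fixture builders and naive reference implementations (oracles).

# One fused read record. `qual` is a scalar or per-base integer Phred.
make_read <- function(left, seq, qual = 37L, umi = "ACGTAA",
                      strand = "top", chrom = "ref", mapq = 60L,
                      sample_id = 1L, replicate_id = 1L,
                      truth_tags = character(0), qname = NULL) {
  L <- nchar(seq)
  if (length(qual) == 1L) qual <- rep(qual, L)
  stopifnot(length(qual) == L)
  start <- if (strand == "top") left else left + L
  mate <- if (strand == "top") left + L else left
  out <- data.frame(
    qname = qname %||% sprintf("fix:s%d:r%d:%06d:%s", sample_id,
                               replicate_id,
                               sample.int(1e6, 1), umi),
    sample_id = sample_id, replicate_id = replicate_id, chrom = chrom,
    left = left, start = start, mate_start = mate, strand = strand,
    umi = umi, seq = seq, qual = intToUtf8(qual + 33L), mapq = mapq,
    mol = NA_integer_, stringsAsFactors = FALSE
  )
  out$truth_tags <- list(truth_tags)
  class(out) <- c("aligned_reads", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bind_reads <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("aligned_reads", class(out))
  out
}

# A family of n reads over `seq` at the same coordinates/UMI, with
# optional per-read substitutions given as list of c(pos = , base = ).
make_family <- function(n, seq, umi = "ACGTAA", left = 0L,
                        subs = vector("list", n), qual = 37L, ...) {
  reads <- lapply(seq_len(n), function(i) {
    s <- seq
    if (!is.null(subs[[i]])) {
      ch <- strsplit(s, "")[[1]]
      ch[as.integer(subs[[i]][["pos"]])] <- subs[[i]][["base"]]
      s <- paste(ch, collapse = "")
    }
    make_read(left, s, qual = qual, umi = umi, ...)
  })
  do.call(bind_reads, reads)
}

random_ref <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- naive oracles (independent re-implementations by direct looping) ----

naive_pileup <- function(reads, reference, regions = NULL,
                         min_base_qual = 20L, min_mapq = 20L) {
  ref_len <- nchar(reference)
  if (is.null(regions)) regions <- data.frame(start = 0L, end = ref_len)
  counts <- matrix(0L, ref_len, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(reads))) {
    if (reads$mapq[i] < min_mapq) next
    bases <- strsplit(reads$seq[i], "")[[1]]
    quals <- utf8ToInt(reads$qual[i]) - 33L
    for (j in seq_along(bases)) {
      p <- reads$left[i] + j - 1L
      inreg <- any(regions$start <= p & p < regions$end)
      if (inreg && quals[j] >= min_base_qual &&
          bases[j] %in% c("A", "C", "G", "T")) {
        counts[p + 1L, bases[j]] <- counts[p + 1L, bases[j]] + 1L
      }
    }
  }
  refc <- strsplit(reference, "")[[1]]
  keep <- which(rowSums(counts) > 0)
  keep <- keep[sapply(keep, function(r)
    any(regions$start <= r - 1L & r - 1L < regions$end))]
  data.frame(chrom = "ref", pos = keep - 1L, ref = refc[keep],
             counts[keep, , drop = FALSE], depth = rowSums(counts)[keep],
             indel = FALSE, stringsAsFactors = FALSE)
}

# Enumerates every window of `window` adjacent positions and tabulates
# center observations of passing windows.
naive_error_rate <- function(pileup, min_depth = 100L, max_af = 0.4,
                             window = 7L) {
  pileup <- pileup[order(pileup$pos), ]
  bases <- c("A", "C", "G", "T")
  passes <- function(row) {
    alt <- unlist(row[bases])
    alt[row$ref] <- 0L
    row$depth >= min_depth && !row$indel && all(alt / row$depth <= max_af)
  }
  nra <- 0L; tot <- 0L; centers <- integer(0)
  h <- (window - 1L) %/% 2L
  all_pos <- pileup$pos
  for (p in all_pos) {
    win <- p + (-h:h)
    rows <- match(win, all_pos)
    if (any(is.na(rows))) next
    if (all(sapply(rows, function(r) passes(pileup[r, ])))) {
      ctr <- pileup[match(p, all_pos), ]
      alt <- unlist(ctr[bases]); alt[ctr$ref] <- 0L
      nra <- nra + sum(alt)
      tot <- tot + ctr$depth
      centers <- c(centers, p)
    }
  }
  list(error_rate = if (tot > 0) nra / tot else NA_real_,
       nra = nra, bases = tot, centers = centers)
}

naive_parse_positions <- function(pileup, min_depth = 100L, max_af = 0.4) {
  bases <- c("A", "C", "G", "T")
  out <- NULL
  for (i in seq_len(nrow(pileup))) {
    row <- pileup[i, ]
    if (row$depth < min_depth) next
    alt <- unlist(row[bases]); alt[row$ref] <- 0L
    if (any(alt / row$depth > max_af)) next
    for (b in bases[alt > 0]) {
      out <- rbind(out, data.frame(pos = row$pos, ref = row$ref, alt = b,
                                   alt_count = alt[[b]], depth = row$depth,
                                   af = alt[[b]] / row$depth,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# Small cohort config for fast end-to-end tests (not the default study
# conditions; unit-test scale only).
tiny_config <- function(seed = 1, ...) {
  args <- list(reference_length = 600L, n_samples = 3L,
               molecules_per_sample = 120L, reads_sampled = 1200L,
               fragment_length = 100L, chip_variants = 1L,
               patterned_positions = 6L,
               spike_variants = data.frame(position = c(250L, 320L),
                                           af = c(0.1, 0.15),
                                           sample_id = c(1L, 2L)),
               seed = seed)
  over <- list(...)
  args[names(over)] <- over   # no modifyList: it would recurse into data.frames
  do.call(sim_config, args)
}

no_truth <- function() {
  list(chip_variants = 0L, patterned_positions = 0L,
       spike_variants = data.frame(position = integer(0), af = numeric(0)))
}
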