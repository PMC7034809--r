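# Plain-text interchange: SAM for alignments, FASTA for the reference,
# BED for NRA tracks, TSV for reports. All intermediate artifacts are
# plain text so pipeline outputs diff cleanly in tests.

#' Write / read the reference as FASTA
#'
#' @param reference character scalar.
#' @param path file path.
#' @param name sequence name (default "ref").
#' @export
write_reference <- function(reference, path, name = "ref") {
  x <- Biostrings::DNAStringSet(reference)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as.character(x[[1]])
}

#' Write aligned reads as coordinate-sorted SAM
#'
#' One fused record per read pair spanning the fragment. The UMI is the
#' last colon-delimited field of the read name; `POS` is the 1-based
#' leftmost base, bottom-strand records carry flag 16, and `PNEXT` is the
#' mate unclipped start + 1. Simulation metadata travels in optional tags:
#' `sm:i` sample, `rp:i` replicate, `mi:i` founding molecule, `fs:i`
#' family size (consensus reads), `tt:Z` comma-joined truth tags.
#'
#' @param reads an `aligned_reads` or `consensus_reads` data.frame.
#' @param path output path.
#' @param reference_length reference length for the `@SQ` header line.
#' @return the path, invisibly.
#' @export
write_alignments <- function(reads, path, reference_length) {
  reads <- reads[order(reads$chrom, reads$left), , drop = FALSE]
  if (is.null(reads$qname)) {
    # consensus reads carry no read name; synthesize one with the UMI as
    # the last colon-delimited field
    reads$qname <- sprintf("cons:s%s:%06d:%s", reads$sample_id,
                           seq_len(nrow(reads)), reads$umi)
  }
  con <- file(path, "w")
  on.exit(close(con))
  sn <- if (nrow(reads)) reads$chrom[1] else "ref"
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", sn,
                       as.integer(reference_length))), con)
  if (nrow(reads) == 0L) return(invisible(path))
  flag <- ifelse(reads$strand == "bottom", 16L, 0L)
  lens <- nchar(reads$seq)
  tags <- vapply(reads$truth_tags %||% vector("list", nrow(reads)),
                 function(t) paste(t, collapse = ","), character(1))
  fields <- cbind(
    reads$qname, flag, reads$chrom, reads$left + 1L, reads$mapq,
    paste0(lens, "M"), "=", reads$mate_start + 1L, 0L,
    reads$seq, reads$qual,
    sprintf("sm:i:%d", reads$sample_id),
    sprintf("rp:i:%d", reads$replicate_id)
  )
  extra <- character(nrow(reads))
  if (!is.null(reads$mol)) extra <- paste0(extra, sprintf("\tmi:i:%d", reads$mol))
  if (!is.null(reads$family_size)) {
    extra <- paste0(extra, sprintf("\tfs:i:%d", reads$family_size))
  }
  has_tags <- nzchar(tags)
  extra[has_tags] <- paste0(extra[has_tags], "\ttt:Z:", tags[has_tags])
  writeLines(paste0(apply(fields, 1, paste, collapse = "\t"), extra), con)
  invisible(path)
}

#' Read aligned reads from SAM
#'
#' Inverse of [write_alignments()] for simulator-produced files; also
#' accepts generic coordinate-sorted SAM with the UMI in the last
#' colon-delimited read-name field (or in a tag via `umi_tag`). Records
#' with fewer than 11 mandatory fields are reported with their line
#' numbers. Mapping quality is retained as-is; downstream MQ gates decide
#' what is counted.
#'
#' @param path SAM file path.
#' @param umi_from `"qname"` (default) or `"tag"`.
#' @param umi_tag tag holding the UMI when `umi_from = "tag"` (default
#'   `"RX"`).
#' @return an `aligned_reads` data.frame (see [simulate_library()]).
#' @export
read_alignments <- function(path, umi_from = c("qname", "tag"),
                            umi_tag = "RX") {
  umi_from <- match.arg(umi_from)
  lines <- readLines(path)
  body <- !startsWith(lines, "@")
  recs <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(vapply(recs, length, integer(1)) < 11L)
  if (length(bad)) {
    stop("malformed SAM record(s) at line(s): ",
         paste(which(body)[bad], collapse = ", "))
  }
  n <- length(recs)
  get <- function(i) vapply(recs, `[[`, character(1), i)
  qname <- get(1)
  flag <- as.integer(get(2))
  pos <- as.integer(get(4))
  seqs <- get(10)
  lens <- nchar(seqs)
  pnext <- as.integer(get(8))
  opt <- lapply(recs, function(r) if (length(r) > 11L) r[12:length(r)] else
    character(0))
  tag_val <- function(tags, prefix) {
    hit <- tags[startsWith(tags, prefix)]
    if (length(hit)) sub(prefix, "", hit[1], fixed = TRUE) else NA_character_
  }
  umi <- if (umi_from == "qname") {
    vapply(strsplit(qname, ":", fixed = TRUE), function(p) p[length(p)],
           character(1))
  } else {
    vapply(opt, tag_val, character(1), paste0(umi_tag, ":Z:"))
  }
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "bottom", "top")
  left <- pos - 1L
  sm <- suppressWarnings(as.integer(vapply(opt, tag_val, character(1), "sm:i:")))
  rp <- suppressWarnings(as.integer(vapply(opt, tag_val, character(1), "rp:i:")))
  mi <- suppressWarnings(as.integer(vapply(opt, tag_val, character(1), "mi:i:")))
  tt <- vapply(opt, tag_val, character(1), "tt:Z:")
  out <- data.frame(
    qname = qname, sample_id = ifelse(is.na(sm), 1L, sm),
    replicate_id = ifelse(is.na(rp), 1L, rp), chrom = get(3),
    left = left,
    start = ifelse(strand == "top", left, left + lens),
    mate_start = pnext - 1L,
    strand = strand, umi = umi, seq = seqs, qual = get(11),
    mapq = as.integer(get(5)),
    mol = mi,
    stringsAsFactors = FALSE
  )
  out$truth_tags <- lapply(tt, function(t)
    if (is.na(t) || !nzchar(t)) character(0) else
      strsplit(t, ",", fixed = TRUE)[[1]])
  class(out) <- c("aligned_reads", class(out))
  out
}

#' Write an NRA track as BED
#'
#' Five-column BED (0-based half-open): chrom, start, end, name = allele
#' frequency, score = depth.
#'
#' @param nras an `nra_records` data.frame.
#' @param path output path.
#' @export
write_nra_bed <- function(nras, path) {
  bed <- data.frame(chrom = nras$chrom, start = nras$pos,
                    end = nras$pos + 1L,
                    name = formatC(nras$af, format = "g", digits = 6),
                    score = nras$depth)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write one or more error reports as TSV
#'
#' @param reports an `error_report` or list of them.
#' @param path output path.
#' @export
write_error_reports <- function(reports, path) {
  if (inherits(reports, "error_report")) reports <- list(reports)
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      family_size_threshold = r$family_size_threshold,
      corrections = paste(r$correction_labels, collapse = ""),
      error_rate = r$error_rate,
      total_nra_observations = r$total_nra_observations,
      total_quality_bases = r$total_quality_bases,
      n_passing_positions = r$n_passing_positions
    )
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
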