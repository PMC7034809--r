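#' Simulate one UMI-tagged sequencing library
#'
#' Composes the full generative model for a single library: fragment
#' sampling from the reference, molecule-level variant injection from the
#' cohort truth (CHIP and patterned positions in both materials, spiked
#' true variants in ccfDNA only), branching PCR via the amplicon engine,
#' read sampling without replacement from the post-PCR pool, and a
#' sequencing-error layer with two-point base qualities (Q37, or Q11 with
#' probability `q_low`). Every read carries truth tags that reconstruct the
#' provenance of each non-reference base.
#'
#' Randomness is split into a pool stream (molecules, variants, PCR, UMIs)
#' and a read stream (read sampling, sequencing errors, qualities), both
#' derived from the config seed. A full replicate (`mode = "full"`) re-runs
#' library formation from fresh molecule sampling; a sequencing duplicate
#' (`mode = "seq_duplicate"`) reuses the post-PCR pool of the replicate
#' given by `duplicate_of` and only resamples reads from it.
#'
#' @param truth a [generate_cohort()] object.
#' @param sample_id integer sample index in `1:n_samples`.
#' @param config the [sim_config()] used to build `truth`.
#' @param replicate_id integer replicate label stored on the reads.
#' @param material `"ccfdna"` or `"buffy"` (buffy-coat libraries carry CHIP
#'   and patterned truth but no spiked variants).
#' @param mode `"full"` or `"seq_duplicate"`.
#' @param duplicate_of replicate whose post-PCR pool a sequencing duplicate
#'   reuses.
#' @return a data.frame of class `aligned_reads`, one row per fused
#'   read-pair record: `qname`, `sample_id`, `replicate_id`, `chrom`,
#'   `left` (0-based leftmost aligned base), `start` (0-based unclipped
#'   start of the read's 5' end: the left end for top-strand reads, the
#'   right end for bottom-strand reads), `mate_start`, `strand`
#'   ("top"/"bottom"), `umi`, `seq`, `qual` (Phred+33 string), `mapq`,
#'   `mol` (founding molecule), plus list column `truth_tags` with labels
#'   of the form `first_cycle_error@pos`, `late_pcr_error@pos`,
#'   `seq_error@pos`, `true_variant@pos`, `chip_variant@pos`,
#'   `patterned_error@pos` (0-based reference positions).
#' @export
simulate_library <- function(truth, sample_id, config, replicate_id = 1L,
                             material = c("ccfdna", "buffy"),
                             mode = c("full", "seq_duplicate"),
                             duplicate_of = 1L) {
  stopifnot(inherits(truth, "cohort_truth"), inherits(config, "sim_config"))
  material <- match.arg(material)
  mode <- match.arg(mode)
  if (!sample_id %in% seq_len(truth$n_samples)) {
    stop("sample_id ", sample_id, " is not in the cohort")
  }
  L <- config$fragment_length
  ref_len <- config$reference_length
  pool_rep <- if (mode == "seq_duplicate") duplicate_of else replicate_id
  pool_seed <- derive_seed(config$seed,
                           sprintf("pool|s%d|%s|r%d", sample_id, material, pool_rep))
  read_seed <- derive_seed(config$seed,
                           sprintf("reads|s%d|%s|r%d|%s", sample_id, material,
                                   replicate_id, mode))

  ## ---- pool stream ----------------------------------------------------
  set.seed(pool_seed)
  n_mol <- if (material == "buffy") config$buffy_molecules else
    config$molecules_per_sample
  starts <- sample.int(ref_len - L + 1L, n_mol, replace = TRUE) - 1L

  variant_rows <- list()
  add_variants <- function(pos, alt, af, label) {
    for (i in seq_along(pos)) {
      covering <- which(starts <= pos[i] & pos[i] < starts + L)
      if (!length(covering)) next
      carriers <- covering[stats::runif(length(covering)) < af[i]]
      if (length(carriers)) {
        variant_rows[[length(variant_rows) + 1L]] <<- data.frame(
          mol = carriers, pos = pos[i], alt = alt[i], label = label,
          stringsAsFactors = FALSE)
      }
    }
  }
  chip <- truth$chip_set[truth$chip_set$sample_id == sample_id, ]
  if (nrow(chip)) add_variants(chip$position, chip$alt, chip$af, "chip_variant")
  pat <- truth$patterned_set[truth$patterned_set$sample_id == sample_id, ]
  if (nrow(pat)) {
    add_variants(pat$position, pat$alt,
                 rep(config$patterned_af, nrow(pat)), "patterned_error")
  }
  if (material == "ccfdna" && nrow(truth$spike_set)) {
    sp <- truth$spike_set
    sp <- sp[is.na(sp$sample_id) | sp$sample_id == sample_id, , drop = FALSE]
    if (nrow(sp)) add_variants(sp$position, sp$alt, sp$af, "true_variant")
  }
  variants <- if (length(variant_rows)) do.call(rbind, variant_rows) else
    data.frame(mol = integer(0), pos = integer(0), alt = character(0),
               label = character(0), stringsAsFactors = FALSE)

  if (config$adapter_scheme == "singleton") {
    u <- random_umis(2L * n_mol, config$umi_length)
    umi_by_lineage <- matrix(u, ncol = 2L, byrow = TRUE)  # [mol, lineage]
  } else {
    a <- random_umis(n_mol, 3L)
    b <- random_umis(n_mol, 3L)
    umi_by_lineage <- cbind(paste0(a, b), paste0(b, a))
  }

  pool <- batch_pcr(n_mol, L, config$pcr_cycles, config$pcr_efficiency,
                    config$pcr_error_rate)
  pool_size <- length(pool$mol)

  ## ---- read stream ----------------------------------------------------
  set.seed(read_seed)
  n_reads <- config$reads_sampled
  if (n_reads > pool_size) {
    stop(sprintf(
      "reads_sampled (%d) exceeds the post-PCR amplicon pool (%d): short by %d",
      n_reads, pool_size, n_reads - pool_size))
  }
  idx <- sample.int(pool_size, n_reads)

  mol <- pool$mol[idx]
  lineage <- pool$lineage[idx]
  rstart <- starts[mol]
  ref_chars <- strsplit(truth$reference, "", fixed = TRUE)[[1]]
  base_seq <- substring(truth$reference, rstart + 1L, rstart + L)

  var_by_mol <- if (nrow(variants)) split(variants, variants$mol) else list()
  n_err <- stats::rbinom(n_reads, L, config$seq_error_rate)

  seqs <- base_seq
  tags <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    v <- var_by_mol[[as.character(mol[i])]]
    m <- pool$muts[[idx[i]]]
    tg <- character(0)
    dirty <- FALSE
    ch <- NULL
    if (!is.null(v) && nrow(v)) {
      ch <- ref_chars[(rstart[i] + 1L):(rstart[i] + L)]
      ch[v$pos - rstart[i] + 1L] <- v$alt
      tg <- paste0(v$label, "@", v$pos)
      dirty <- TRUE
    }
    if (!is.null(m)) {
      if (is.null(ch)) ch <- ref_chars[(rstart[i] + 1L):(rstart[i] + L)]
      r <- resolve_muts(ch, m)
      ch[r$pos] <- r$alt
      tg <- c(tg, paste0(ifelse(r$first, "first_cycle_error@",
                                "late_pcr_error@"), rstart[i] + r$pos - 1L))
      dirty <- TRUE
    }
    if (n_err[i] > 0L) {
      if (is.null(ch)) ch <- ref_chars[(rstart[i] + 1L):(rstart[i] + L)]
      ep <- sample.int(L, n_err[i])
      ch[ep] <- offset_base(ch[ep], sample.int(3L, n_err[i], replace = TRUE))
      tg <- c(tg, paste0("seq_error@", rstart[i] + ep - 1L))
      dirty <- TRUE
    }
    if (dirty) seqs[i] <- paste(ch, collapse = "")
    tags[[i]] <- tg
  }

  umi <- umi_by_lineage[cbind(mol, lineage)]
  if (config$umi_error_rate > 0) {
    w <- config$umi_length
    n_ue <- stats::rbinom(n_reads, w, config$umi_error_rate)
    for (i in which(n_ue > 0L)) {
      uc <- strsplit(umi[i], "", fixed = TRUE)[[1]]
      up <- sample.int(w, n_ue[i])
      uc[up] <- offset_base(uc[up], sample.int(3L, n_ue[i], replace = TRUE))
      umi[i] <- paste(uc, collapse = "")
    }
  }

  low <- matrix(stats::runif(n_reads * L) < config$q_low, nrow = n_reads)
  q_hi <- phred_to_string(rep(37L, L))
  qual <- vapply(seq_len(n_reads), function(i) {
    if (!any(low[i, ])) q_hi else
      phred_to_string(ifelse(low[i, ], 11L, 37L))
  }, character(1))

  top <- lineage == 1L
  reads <- data.frame(
    qname = sprintf("%s:s%d:r%d:%06d:%s", material, sample_id, replicate_id,
                    seq_len(n_reads), umi),
    sample_id = sample_id,
    replicate_id = as.integer(replicate_id),
    chrom = "ref",
    left = rstart,
    start = ifelse(top, rstart, rstart + L),
    mate_start = ifelse(top, rstart + L, rstart),
    strand = ifelse(top, "top", "bottom"),
    umi = umi,
    seq = seqs,
    qual = qual,
    mapq = 60L,
    mol = mol,
    stringsAsFactors = FALSE
  )
  reads$truth_tags <- tags
  attr(reads, "sample_id") <- sample_id
  attr(reads, "replicate_id") <- as.integer(replicate_id)
  attr(reads, "material") <- material
  attr(reads, "mode") <- mode
  attr(reads, "scheme") <- config$adapter_scheme
  attr(reads, "molecules") <- list(starts = starts, variants = variants,
                                   pool_size = pool_size)
  class(reads) <- c("aligned_reads", class(reads))
  reads
}
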