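# Branching-process PCR at single-strand amplicon granularity.
#
# Each double-stranded input molecule founds two template strands ("top",
# "bottom"). Every cycle, each existing amplicon spawns one copy with
# probability `efficiency`; each copied base substitutes independently with
# probability `error_rate`. The "first cycle" of a strand is the first copy
# event of that original template strand (with limiting-primer chemistry
# only one primer works on the template in its first cycle), so errors
# introduced there are flagged `first = TRUE` and propagate to exactly the
# descendants of that first copy.

# Internal vectorised engine, shared by simulate_pcr() (one molecule) and
# simulate_library() (all molecules of a library at once).
#
# Mutations are stored per amplicon as an integer matrix with columns
# pos (1-based within the fragment), off (base offset 1..3 relative to the
# base being copied), cycle, first (0/1). NULL means no mutations.
batch_pcr <- function(n_mol, frag_len, cycles, efficiency, error_rate,
                      inject = NULL) {
  if (cycles < 1L) stop("cycles must be >= 1")
  if (error_rate > 0 && frag_len == 0L) {
    stop("cannot apply a positive error_rate to a zero-length fragment")
  }
  n0 <- 2L * n_mol
  mol <- rep(seq_len(n_mol), each = 2L)
  lineage <- rep(1:2, times = n_mol)           # 1 = top, 2 = bottom
  born <- rep(0L, n0)
  founder_id <- seq_len(n0)                    # 0 for copies
  muts <- vector("list", n0)
  founder_copied <- rep(FALSE, n0)

  inj_off <- NULL
  if (!is.null(inject)) {
    inj_strand <- match(inject$strand %||% "top", c("top", "bottom"))
    inj_pos <- as.integer(inject$pos)
    inj_off <- as.integer(inject$offset %||% 1L)
    stopifnot(inj_pos >= 1L, inj_pos <= frag_len, inj_off %in% 1:3)
  }

  for (cyc in seq_len(cycles)) {
    n_amp <- length(mol)
    cop <- which(stats::runif(n_amp) < efficiency)
    if (length(cop) == 0L) next
    p_f <- founder_id[cop]
    first_copy <- p_f > 0L & !founder_copied[pmax(p_f, 1L)]
    new_muts <- muts[cop]

    k <- stats::rbinom(length(cop), frag_len, error_rate)
    hit <- which(k > 0L)
    for (i in hit) {
      add <- cbind(pos = sample.int(frag_len, k[i]),
                   off = sample.int(3L, k[i], replace = TRUE),
                   cycle = cyc, first = as.integer(first_copy[i]))
      new_muts[[i]] <- rbind(new_muts[[i]], add)
    }
    if (!is.null(inj_off)) {
      tgt <- which(first_copy & lineage[cop] == inj_strand &
                     mol[cop] == 1L)
      for (i in tgt) {
        add <- cbind(pos = inj_pos, off = inj_off, cycle = cyc, first = 1L)
        new_muts[[i]] <- rbind(new_muts[[i]], add)
      }
    }

    founder_copied[p_f[first_copy]] <- TRUE
    mol <- c(mol, mol[cop])
    lineage <- c(lineage, lineage[cop])
    born <- c(born, rep(cyc, length(cop)))
    founder_id <- c(founder_id, rep(0L, length(cop)))
    muts <- c(muts, new_muts)
  }
  list(mol = mol, lineage = lineage, born = born,
       is_template = founder_id > 0L, muts = muts)
}

# Materialise the final base at each mutated position of one amplicon.
# Returns list(pos, alt, cycle, first) with one entry per *mutation event*
# (later events at the same position are applied on top of earlier ones).
resolve_muts <- function(frag_chars, m) {
  if (is.null(m)) {
    return(list(pos = integer(0), alt = character(0),
                cycle = integer(0), first = logical(0)))
  }
  cur <- frag_chars
  alt <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- m[i, "pos"]
    cur[p] <- offset_base(cur[p], m[i, "off"])
    alt[i] <- cur[p]
  }
  list(pos = m[, "pos"], alt = alt, cycle = m[, "cycle"],
       first = m[, "first"] == 1L)
}

#' Simulate branching PCR of one double-stranded fragment
#'
#' Amplifies a single molecule through `cycles` cycles of a branching
#' process and returns the full single-stranded amplicon pool with lineage
#' and error-provenance annotation. The two template strands found two
#' lineages; under the singleton scheme each lineage receives an
#' independent 8-mer UMI, under the duplex scheme the molecule receives one
#' (alpha, beta) 3+3 UMI pair read as "alpha,beta" from the top-strand
#' lineage and "beta,alpha" from the bottom-strand lineage.
#'
#' @param fragment character scalar: the top-strand fragment sequence in
#'   reference orientation (all amplicon sequences are reported in this
#'   orientation).
#' @param scheme `"singleton"` or `"duplex"`.
#' @param cycles number of PCR cycles (>= 1).
#' @param efficiency per-amplicon per-cycle copy probability.
#' @param error_rate substitution probability per base per copy event.
#' @param inject optional forced substitution on the first copy event of a
#'   template strand: `list(strand = "top", pos = <1-based>, offset = 1..3)`.
#'   Used to construct deterministic early-error scenarios.
#' @return data.frame with one row per single-stranded amplicon:
#'   `lineage` ("top"/"bottom" founding strand), `born` (cycle of origin, 0
#'   for the templates), `is_template`, `umi` (read-out UMI of the
#'   lineage), `sequence`, and a list column `muts` where each element is a
#'   data.frame `pos` (1-based within fragment), `alt`, `cycle`, `first`
#'   recording every inherited substitution.
#' @export
simulate_pcr <- function(fragment, scheme = c("singleton", "duplex"),
                         cycles, efficiency, error_rate, inject = NULL) {
  scheme <- match.arg(scheme)
  frag_len <- nchar(fragment)
  pool <- batch_pcr(1L, frag_len, cycles, efficiency, error_rate, inject)
  if (scheme == "singleton") {
    umis <- random_umis(2L, 8L)
  } else {
    halves <- random_umis(2L, 3L)
    umis <- c(paste0(halves[1], halves[2]), paste0(halves[2], halves[1]))
  }
  frag_chars <- strsplit(fragment, "", fixed = TRUE)[[1]]
  n <- length(pool$mol)
  seqs <- character(n)
  mut_dfs <- vector("list", n)
  for (i in seq_len(n)) {
    r <- resolve_muts(frag_chars, pool$muts[[i]])
    mut_dfs[[i]] <- data.frame(pos = r$pos, alt = r$alt, cycle = r$cycle,
                               first = r$first, stringsAsFactors = FALSE)
    if (length(r$pos)) {
      ch <- frag_chars
      ch[r$pos] <- r$alt
      seqs[i] <- paste(ch, collapse = "")
    } else {
      seqs[i] <- fragment
    }
  }
  out <- data.frame(
    lineage = c("top", "bottom")[pool$lineage],
    born = pool$born,
    is_template = pool$is_template,
    umi = umis[pool$lineage],
    sequence = seqs,
    stringsAsFactors = FALSE
  )
  out$muts <- mut_dfs
  out
}
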