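#' Simulate a unique-dual-index read-count table with index hopping
#'
#' Each sample owns one i7 and one i5 barcode; a read with correct pairing
#' falls on the diagonal of the count matrix. With probability `hop_rate` a
#' read hops exactly one of its two indices to another sample's barcode,
#' uniformly over the `2 * (n_samples - 1)` eligible mixed pairs, producing
#' an off-diagonal count. Total read count is conserved.
#'
#' @param n_samples number of multiplexed samples (>= 2 when hopping).
#' @param reads_per_sample reads loaded per sample.
#' @param hop_rate per-read index-hopping probability in [0, 1).
#' @param seed integer seed.
#' @param undetermined reads unaffiliated with any configured pair (counted
#'   in the lane total; default 0).
#' @param return_reads if `TRUE`, also return the per-sample hop
#'   assignments (for small inputs / auditing).
#' @return object of class `udi_counts`: list with `samples` (data.frame of
#'   i7/i5 barcode labels), `counts` (n x n integer matrix, rows = i7
#'   owner, cols = i5 owner, diagonal = correct pairs), `undetermined`,
#'   and optionally `reads` (data.frame `sample`, `i7`, `i5`, `hopped`).
#' @seealso [index_hopping_rate()]
#' @export
simulate_udi_counts <- function(n_samples, reads_per_sample, hop_rate,
                                seed = 1L, undetermined = 0L,
                                return_reads = FALSE) {
  if (hop_rate < 0 || hop_rate >= 1) stop("hop_rate must lie in [0, 1)")
  if (n_samples < 2L && hop_rate > 0) {
    stop("index hopping requires at least 2 samples")
  }
  set.seed(seed)
  n <- as.integer(n_samples)
  counts <- matrix(0L, n, n,
                   dimnames = list(paste0("i7_", seq_len(n)),
                                   paste0("i5_", seq_len(n))))
  reads <- NULL
  for (k in seq_len(n)) {
    n_hop <- stats::rbinom(1L, reads_per_sample, hop_rate)
    counts[k, k] <- counts[k, k] + (reads_per_sample - n_hop)
    if (n_hop > 0L) {
      others <- setdiff(seq_len(n), k)
      # eligible mixed pairs: (i7_j, i5_k) and (i7_k, i5_j) for j != k
      pairs <- rbind(cbind(others, k), cbind(k, others))
      pick <- pairs[sample.int(nrow(pairs), n_hop, replace = TRUE), ,
                    drop = FALSE]
      for (i in seq_len(n_hop)) {
        counts[pick[i, 1], pick[i, 2]] <- counts[pick[i, 1], pick[i, 2]] + 1L
      }
    }
    if (return_reads) {
      own <- data.frame(sample = k, i7 = k, i5 = k, hopped = FALSE)
      own <- own[rep(1L, reads_per_sample - n_hop), , drop = FALSE]
      hop <- if (n_hop > 0L) data.frame(sample = k, i7 = pick[, 1],
                                        i5 = pick[, 2], hopped = TRUE)
             else NULL
      reads <- rbind(reads, own, hop)
    }
  }
  out <- list(samples = data.frame(i7 = paste0("i7_", seq_len(n)),
                                   i5 = paste0("i5_", seq_len(n))),
              counts = counts, undetermined = as.integer(undetermined))
  if (return_reads) {
    rownames(reads) <- NULL
    out$reads <- reads
  }
  class(out) <- "udi_counts"
  out
}

#' @export
print.udi_counts <- function(x, ...) {
  n <- nrow(x$counts)
  total <- sum(x$counts) + x$undetermined
  mixed <- sum(x$counts) - sum(diag(x$counts))
  cat(sprintf("UDI counts: %d samples, %d reads (%d mixed-pair, %d undetermined)\n",
              n, total, mixed, x$undetermined))
  invisible(x)
}
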