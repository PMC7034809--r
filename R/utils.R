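# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Derive a child seed from a master seed and a string key
#'
#' Deterministic, keeps the result inside the 32-bit integer range so it is
#' safe to pass to [set.seed()].
#' @param seed master integer seed
#' @param key character scalar naming the random stream
#' @return integer seed
#' @keywords internal
derive_seed <- function(seed, key) {
  v <- utf8ToInt(key)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 48271 + h * 2654435) %% 2147483629)
}

#' Rotate a duplex UMI
#'
#' A duplex UMI is two 3-mers; reads from the opposite template strand of
#' the same molecule report the halves in swapped order ("abc-def" vs
#' "def-abc"). UMIs are stored hyphenless.
#'
#' @param umi character vector of 6-mers
#' @return character vector with halves swapped
#' @export
#' @examples
#' rotate_umi("ACGTTT")  # "TTTACG"
rotate_umi <- function(umi) {
  stopifnot(all(nchar(umi) == 6L))
  paste0(substr(umi, 4L, 6L), substr(umi, 1L, 3L))
}

random_umis <- function(n, width) {
  m <- matrix(sample(BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

random_sequence <- function(n, gc_fraction = 0.5) {
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Substitute: given reference bases (character vector) and an integer offset
# in 1:3, return a different base deterministically.
offset_base <- function(ref, offset) {
  ri <- match(ref, BASES)
  BASES[((ri - 1L + offset) %% 4L) + 1L]
}

phred_to_string <- function(q) intToUtf8(q + 33L)
string_to_phred <- function(s) utf8ToInt(s) - 33L

# Apply point substitutions to a sequence string. `pos` is 1-based within
# the string; later entries overwrite earlier ones at the same position.
apply_substitutions <- function(seq, pos, base) {
  if (length(pos) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- base
  paste(ch, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
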