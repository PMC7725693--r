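# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character strings; IUPAC degenerate codes are represented as
# 4-bit masks over {A,C,G,T} so a primer base matches a read base iff the
# masks intersect.

.iupac_bits <- local({
  bits <- integer(256)
  codes <- c(
    A = 1L, C = 2L, G = 4L, T = 8L,
    R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
    B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
  )
  bits[utf8ToInt(paste(names(codes), collapse = "")) ] <- unname(codes)
  bits
})

#' @noRd
seq_bits <- function(x) {
  .iupac_bits[utf8ToInt(x)]
}

#' Reverse complement of DNA strings
#'
#' IUPAC-aware, vectorised reverse complement.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "GGAT"))
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr(
    "ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x
  ))
}

# Mismatch counts between an IUPAC pattern and the length-matched prefixes
# of many ACGT reads. Reads shorter than the pattern get NA.
#' @noRd
prefix_mismatches <- function(reads, pattern) {
  plen <- nchar(pattern)
  out <- rep(NA_integer_, length(reads))
  ok <- !is.na(reads) & nchar(reads) >= plen
  if (!any(ok)) return(out)
  pref <- substr(reads[ok], 1L, plen)
  m <- matrix(.iupac_bits[utf8ToInt(paste(pref, collapse = ""))], nrow = plen)
  pb <- seq_bits(pattern)
  z <- bitwAnd(m, pb) == 0L
  dim(z) <- dim(m)
  out[ok] <- as.integer(colSums(z))
  out
}

# Hamming distance between two equal-length ACGT strings (raw-byte compare).
#' @noRd
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

#' @noRd
split_alleles <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(a) a[nzchar(a)])
}

#' @noRd
join_alleles <- function(x) {
  paste(sort(unique(x)), collapse = ";")
}

# report-style rounding: halves round up (62.5% -> 63%)
#' @noRd
round_pct <- function(x) {
  floor(x + 0.5)
}

#' @noRd
random_dna <- function(n, len) {
  vapply(
    seq_len(n),
    function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = ""),
    character(1)
  )
}
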