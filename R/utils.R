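DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over character DNA.
#'
#' @param x Character vector of A/C/G/T (and N) strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' dna_revcomp("GACCCTGG")
dna_revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# Fast scalar reverse complement (hot path; avoids XStringSet overhead).
revcomp1 <- function(x) {
  chartr("ACGTN", "TGCAN", rawToChar(rev(charToRaw(x))))
}

# Uniform random DNA string of length n (uses the current RNG stream).
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# 0-based half-open substring: sub0(seq, a, b) == seq[a, b)
sub0 <- function(seq, start0, end0) {
  substr(seq, start0 + 1L, end0)
}

# Replace seq[start0, start0 + nchar(replacement)) with `replacement` (0-based).
splice0 <- function(seq, start0, replacement) {
  paste0(
    substr(seq, 1L, start0),
    replacement,
    substr(seq, start0 + nchar(replacement) + 1L, nchar(seq))
  )
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# Vectorised mismatch count of each string in `x` against single string `pat`
# (all nchar(pat); strings in x must have that length).
hamming_vec <- function(x, pat) {
  k <- nchar(pat)
  mm <- integer(length(x))
  for (j in seq_len(k)) {
    mm <- mm + (substr(x, j, j) != substr(pat, j, j))
  }
  mm
}

# Mismatch profile: number of mismatches of pat against every length-k window
# of seq_raw (raw vectors). Returns integer vector of length n - k + 1.
mismatch_profile <- function(seq_raw, pat_raw) {
  n <- length(seq_raw)
  k <- length(pat_raw)
  L <- n - k + 1L
  if (L < 1L) return(integer(0))
  mm <- integer(L)
  for (j in seq_len(k)) {
    mm <- mm + (seq_raw[j:(j + L - 1L)] != pat_raw[j])
  }
  mm
}

pct <- function(num, den) {
  if (is.na(den) || den == 0) return(NA_real_)
  100 * num / den
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a decorrelated child seed (Lehmer step + salt, kept within 32-bit
# range) so components given the same user seed do not share RNG streams.
mix_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt) %% 2147483647)
}
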