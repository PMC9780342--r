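#' Amplicon indel rate around a cut site
#'
#' Aligns amplicon reads end to end against the amplicon reference (global
#' alignment via Biostrings) and reports the percentage of aligned reads
#' carrying an insertion or deletion overlapping `cut +/- window`. Reads
#' with more than `max_mismatch_frac` substitutions are treated as
#' unalignable and excluded from the denominator.
#'
#' @param reads Tibble with a `sequence` column (e.g. from
#'   [simulate_amplicon_reads()] or [read_fastq()]).
#' @param reference Amplicon reference sequence.
#' @param cut 0-based cut position within the amplicon.
#' @param window Half-width in bp of the indel-counting window (default 10).
#' @param max_mismatch_frac Maximum substitution fraction for an aligned
#'   read (default 0.10).
#' @param min_reads Below this number of aligned reads the result is flagged
#'   low-coverage (default 100).
#' @return One-row tibble: `indel_rate` (percent), `n_indel`, `n_aligned`,
#'   `n_reads`, `low_coverage`.
#' @export
amplicon_indel_rate <- function(reads, reference, cut, window = 10L,
                                max_mismatch_frac = 0.10, min_reads = 100L) {
  stopifnot(is.data.frame(reads), "sequence" %in% names(reads))
  n_reads <- nrow(reads)
  if (n_reads == 0L) {
    return(tibble::tibble(indel_rate = NA_real_, n_indel = 0L,
                          n_aligned = 0L, n_reads = 0L, low_coverage = TRUE))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(reads$sequence),
    subject = Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 1
  )
  nmm <- Biostrings::nmismatch(aln)
  aligned_len <- Biostrings::nchar(Biostrings::pattern(aln))
  ok <- nmm / pmax(aligned_len, 1L) <= max_mismatch_frac
  win_lo <- cut - window
  win_hi <- cut + window

  # Deletions in the read: gaps in the pattern, reported in subject
  # coordinates (1-based) -- convert to 0-based half-open.
  del <- Biostrings::deletion(aln)
  ins <- Biostrings::insertion(aln)
  has_indel <- vapply(seq_len(n_reads), function(i) {
    if (!ok[i]) return(FALSE)
    d <- del[[i]]
    if (length(d) > 0L) {
      ds <- IRanges::start(d) - 1L
      de <- IRanges::end(d)
      if (any(de > win_lo & ds < win_hi)) return(TRUE)
    }
    x <- ins[[i]]
    if (length(x) > 0L) {
      # Insertion positions are pattern coordinates; map to subject space by
      # removing the preceding inserted bases.
      ps <- IRanges::start(x)
      pw <- IRanges::width(x)
      prior <- cumsum(c(0L, pw))[seq_along(ps)]
      sp <- ps - 1L - prior
      if (any(sp >= win_lo & sp <= win_hi)) return(TRUE)
    }
    FALSE
  }, logical(1))

  n_aligned <- sum(ok)
  n_indel <- sum(has_indel)
  tibble::tibble(
    indel_rate = if (n_aligned > 0L) 100 * n_indel / n_aligned else NA_real_,
    n_indel = as.integer(n_indel),
    n_aligned = as.integer(n_aligned),
    n_reads = as.integer(n_reads),
    low_coverage = n_aligned < min_reads
  )
}
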