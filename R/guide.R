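#' Guide (sgRNA) specification
#'
#' Describes an SpCas9 target site on the reference: the 20-nt protospacer,
#' its NGG PAM, the genomic placement, the inferred blunt cut site (3 bp 5' of
#' the PAM, i.e. between protospacer positions 17|18), the bait-side nested
#' primer anchor, and the bait window used to separate local repair outcomes
#' from translocations.
#'
#' All coordinates are 0-based, half-open (BED convention). For a plus-strand
#' site starting at `start`, the 23-mer protospacer+PAM occupies
#' `[start, start + 23)` and the cut site is `start + 17`; for a minus-strand
#' site the cut site is `start + 6`.
#'
#' @param protospacer 20-nt DNA string (the spacer as it reads 5'->3' on the
#'   targeted strand).
#' @param pam 3-nt PAM (NGG for SpCas9).
#' @param chrom Chromosome name.
#' @param start 0-based start of the 23-mer protospacer+PAM on `chrom`.
#' @param strand `"+"` or `"-"`.
#' @param bait_offset Distance (bp) from the nested-primer anchor to the
#'   protospacer start; the bait primer sits this far upstream of the site.
#' @param bait_window Half-width (bp) of the window around the cut site within
#'   which junctions are treated as local repair (indels / large deletions).
#' @return A `guide_spec` object (list with the fields above plus `cut_site`
#'   and `anchor`).
#' @export
#' @examples
#' guide_spec("GACCCTGGTGGACATCTTCC", "AGG", "chr1", 30000)
guide_spec <- function(protospacer, pam, chrom, start,
                       strand = "+", bait_offset = 60L,
                       bait_window = 20000L) {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  stopifnot(nchar(protospacer) == 20L, nchar(pam) == 3L)
  if (!grepl("^[ACGT]+$", protospacer)) stop("protospacer must be A/C/G/T")
  if (!grepl("GG$", pam)) stop("PAM must end in GG (SpCas9 NGG)")
  stopifnot(strand %in% c("+", "-"), start >= 0)
  cut_site <- if (strand == "+") start + 17L else start + 6L
  if (strand != "+") {
    stop("only plus-strand target guides are supported for bait anchoring")
  }
  anchor <- start - as.integer(bait_offset)
  if (anchor < 0) stop("bait anchor falls before the chromosome start")
  structure(
    list(
      protospacer = protospacer,
      pam = pam,
      site_seq = paste0(protospacer, pam),
      chrom = chrom,
      start = as.integer(start),
      strand = strand,
      cut_site = as.integer(cut_site),
      anchor = as.integer(anchor),
      bait_offset = as.integer(bait_offset),
      bait_window = as.integer(bait_window)
    ),
    class = "guide_spec"
  )
}

#' @export
print.guide_spec <- function(x, ...) {
  cat("<guide_spec> ", x$site_seq, "\n", sep = "")
  cat("  ", x$chrom, ":", x$start, "-", x$start + 23L, " (", x$strand, ")",
      "  cut=", x$cut_site, "  anchor=", x$anchor,
      "  bait window=+/-", x$bait_window, " bp\n", sep = "")
  invisible(x)
}

# Cut site for an arbitrary 23-mer site (start 0-based) on either strand.
site_cut_site <- function(start, strand) {
  offs <- ifelse(strand == "+", 17L, 6L)
  as.integer(start + offs)
}
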