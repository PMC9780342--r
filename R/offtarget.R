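#' Find translocation hotspots by genome binning
#'
#' Tiles each chromosome in `bin_size` windows (plus a half-bin offset grid
#' to smooth bin-boundary splits) and reports merged windows supported by at
#' least `min_support` unique molecules.
#'
#' @param junctions Tibble of deduplicated translocation molecules with
#'   columns `chrom` (or `prey_ref`) and `pos` (or `prey_pos`).
#' @param bin_size Window size in bp (default 100).
#' @param min_support Minimum unique molecules per window (default 3).
#' @return Tibble of candidate windows: `chrom`, `start`, `end` (0-based
#'   half-open), `support`.
#' @export
find_hotspots <- function(junctions, bin_size = 100L, min_support = 3L) {
  if (!"chrom" %in% names(junctions) && "prey_ref" %in% names(junctions)) {
    junctions <- dplyr::rename(junctions, chrom = "prey_ref")
  }
  if (!"pos" %in% names(junctions) && "prey_pos" %in% names(junctions)) {
    junctions <- dplyr::rename(junctions, pos = "prey_pos")
  }
  stopifnot(all(c("chrom", "pos") %in% names(junctions)))
  junctions <- junctions[!is.na(junctions$pos), , drop = FALSE]
  empty <- tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), support = integer(0))
  if (nrow(junctions) == 0L) return(empty)

  half <- bin_size %/% 2L
  res <- list()
  for (ch in unique(junctions$chrom)) {
    pos <- junctions$pos[junctions$chrom == ch]
    iv <- list()
    # grid 1: [b*bin, (b+1)*bin); grid 2 shifted by half a bin
    for (off in c(0L, half)) {
      b <- (pos + off) %/% bin_size
      tab <- table(b)
      hit <- as.integer(names(tab))[tab >= min_support]
      if (length(hit)) {
        iv[[length(iv) + 1L]] <- IRanges::IRanges(
          start = hit * bin_size - off + 1L,  # 1-based for IRanges
          width = bin_size
        )
      }
    }
    if (length(iv) == 0L) next
    merged <- IRanges::reduce(do.call(c, iv), min.gapwidth = 1L)
    st <- IRanges::start(merged) - 1L
    en <- IRanges::end(merged)
    supp <- vapply(seq_along(st),
                   function(i) sum(pos >= st[i] & pos < en[i]), integer(1))
    keep <- supp >= min_support
    if (any(keep)) {
      res[[length(res) + 1L]] <- tibble::tibble(
        chrom = ch, start = pmax(st[keep], 0L), end = en[keep],
        support = supp[keep]
      )
    }
  }
  if (length(res) == 0L) return(empty)
  dplyr::arrange(dplyr::bind_rows(res), chrom, start)
}

#' Best guide match within a window
#'
#' Scans both strands of a window sequence for the 23-mer minimizing the
#' joint spacer+PAM mismatch count against the guide. Ties are broken by
#' proximity to the window centre, then plus strand first.
#'
#' @param window_seq Window DNA string (>= 23 nt).
#' @param guide A [guide_spec()] or 23-nt protospacer+PAM string.
#' @param max_mm Maximum joint mismatches (default 8).
#' @param require_pam If `TRUE`, additionally require an intact NGG PAM at
#'   the matched site (off by default: the similarity bound is read as a
#'   joint bound over the 23-mer).
#' @return One-row tibble `offset` (0-based within the window), `strand`,
#'   `n_mismatches`, or a zero-row tibble when no site is within `max_mm`.
#' @export
match_guide <- function(window_seq, guide, max_mm = 8L, require_pam = FALSE) {
  site <- guide_site_seq(guide)
  if (nchar(window_seq) < 23L) stop("window shorter than 23 nt")
  wraw <- charToRaw(toupper(window_seq))
  mm_f <- mismatch_profile(wraw, charToRaw(site))
  mm_r <- mismatch_profile(wraw, charToRaw(dna_revcomp(site)))
  cand <- tibble::tibble(
    offset = c(seq_along(mm_f), seq_along(mm_r)) - 1L,
    strand = rep(c("+", "-"), c(length(mm_f), length(mm_r))),
    n_mismatches = c(mm_f, mm_r)
  )
  if (require_pam) {
    ok <- vapply(seq_len(nrow(cand)), function(i) {
      w <- substr(window_seq, cand$offset[i] + 1L, cand$offset[i] + 23L)
      if (cand$strand[i] == "-") w <- dna_revcomp(w)
      substr(w, 22L, 23L) == "GG"
    }, logical(1))
    cand <- cand[ok, , drop = FALSE]
  }
  cand <- cand[cand$n_mismatches <= max_mm, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  centre <- (nchar(window_seq) - 23L) / 2
  cand <- cand[order(cand$n_mismatches, abs(cand$offset - centre),
                     cand$strand), , drop = FALSE]
  cand[1L, ]
}

guide_site_seq <- function(guide) {
  if (inherits(guide, "guide_spec")) return(guide$site_seq)
  site <- toupper(guide)
  stopifnot(nchar(site) == 23L)
  site
}

#' Brute-force enumeration of guide-similar sites
#'
#' Exhaustively scans every 23-mer on both strands of the genome and returns
#' all sites within `max_mm` joint spacer+PAM mismatches of the guide. This
#' is the enumeration oracle the hotspot-based discovery is validated
#' against.
#'
#' @param genome A [build_toy_genome()] object or named character vector of
#'   chromosome sequences.
#' @param guide A [guide_spec()] or 23-nt protospacer+PAM string.
#' @param max_mm Maximum joint mismatches (default 8).
#' @return Tibble sorted by (`n_mismatches`, `chrom`, `start`): `chrom`,
#'   `start`, `strand`, `n_mismatches`, `cut_site`.
#' @export
enumerate_offtargets_bruteforce <- function(genome, guide, max_mm = 8L) {
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes else genome
  site <- guide_site_seq(guide)
  pf <- charToRaw(site)
  pr <- charToRaw(dna_revcomp(site))
  res <- list()
  for (ch in names(chroms)) {
    sraw <- charToRaw(chroms[[ch]])
    for (st in c("+", "-")) {
      mm <- mismatch_profile(sraw, if (st == "+") pf else pr)
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        res[[length(res) + 1L]] <- tibble::tibble(
          chrom = ch, start = hit - 1L, strand = st,
          n_mismatches = mm[hit],
          cut_site = site_cut_site(hit - 1L, st)
        )
      }
    }
  }
  if (length(res) == 0L) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          strand = character(0), n_mismatches = integer(0),
                          cut_site = integer(0)))
  }
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out, n_mismatches, chrom, start)
}

#' Confirm junctions sit at the inferred cut site
#'
#' A candidate off-target passes when the median supporting junction
#' coordinate lies within `tol` bp of the cut site inferred from the matched
#' 23-mer (blunt cut 3 bp 5' of the PAM).
#'
#' @param cut_site Inferred cut-site coordinate of the matched site.
#' @param junction_pos Supporting junction coordinates.
#' @param tol Tolerance in bp (default 3).
#' @return Logical.
#' @export
confirm_cut_site <- function(cut_site, junction_pos, tol = 3L) {
  if (length(junction_pos) == 0L) return(FALSE)
  abs(stats::median(junction_pos) - cut_site) <= tol
}

#' Discover off-target sites from translocation junctions
#'
#' Implements the hotspot rule: translocation hotspots with a sequence
#' similar to the target site (at most `max_mm` joint spacer+PAM mismatches)
#' and with junctions at the presumable SpCas9 cut site are reported as
#' off-target sites.
#'
#' @param calls Junction-call tibble (molecule level); only translocation
#'   classes are used.
#' @param genome A [build_toy_genome()] object or named character vector.
#' @param guide A [guide_spec()] (defaults to the genome's guide).
#' @param bin_size,min_support Hotspot binning parameters (see
#'   [find_hotspots()]).
#' @param max_mm Similarity bound (default 8).
#' @param pad Window padding in bp for the guide scan (default 30).
#' @param cut_tol Cut-site confirmation tolerance in bp (default 3).
#' @param require_pam Require an intact NGG PAM in addition to the joint
#'   mismatch bound (default `FALSE`).
#' @return Off-target site tibble: `chrom`, `start`, `strand`,
#'   `n_mismatches`, `cut_site`, `support`.
#' @export
discover_offtargets <- function(calls, genome, guide = NULL,
                                bin_size = 100L, min_support = 3L,
                                max_mm = 8L, pad = 30L, cut_tol = 3L,
                                require_pam = FALSE) {
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes else genome
  if (is.null(guide) && inherits(genome, "toy_genome")) guide <- genome$guide
  tx <- calls[!is.na(calls$class) &
                calls$class %in% c("general_translocation",
                                   "offtarget_translocation") &
                !is.na(calls$prey_pos) & calls$prey_ref %in% names(chroms), ,
              drop = FALSE]
  empty <- tibble::tibble(chrom = character(0), start = integer(0),
                          strand = character(0), n_mismatches = integer(0),
                          cut_site = integer(0), support = integer(0))
  if (nrow(tx) == 0L) return(empty)
  hs <- find_hotspots(tx, bin_size = bin_size, min_support = min_support)
  if (nrow(hs) == 0L) return(empty)
  res <- list()
  for (i in seq_len(nrow(hs))) {
    ch <- hs$chrom[i]
    ws <- max(hs$start[i] - pad, 0L)
    we <- min(hs$end[i] + pad, nchar(chroms[[ch]]))
    m <- match_guide(sub0(chroms[[ch]], ws, we), guide, max_mm = max_mm,
                     require_pam = require_pam)
    if (nrow(m) == 0L) next
    start <- ws + m$offset
    cut <- site_cut_site(start, m$strand)
    sup <- tx[tx$prey_ref == ch &
                tx$prey_pos >= hs$start[i] & tx$prey_pos < hs$end[i], ,
              drop = FALSE]
    # Resolve each junction to the point of its microhomology interval
    # closest to the candidate cut before applying the median rule.
    hom <- if ("homology" %in% names(sup)) {
      dplyr::coalesce(sup$homology, 0L)
    } else rep(0L, nrow(sup))
    j_lo <- ifelse(sup$prey_strand == "-", sup$prey_pos, sup$prey_pos - hom)
    j_hi <- ifelse(sup$prey_strand == "-", sup$prey_pos + hom, sup$prey_pos)
    jpos <- pmin(pmax(cut, j_lo), j_hi)
    if (!confirm_cut_site(cut, jpos, tol = cut_tol)) next
    res[[length(res) + 1L]] <- tibble::tibble(
      chrom = ch, start = start, strand = m$strand,
      n_mismatches = m$n_mismatches, cut_site = cut,
      support = hs$support[i]
    )
  }
  if (length(res) == 0L) return(empty)
  dplyr::distinct(dplyr::arrange(dplyr::bind_rows(res), chrom, start))
}
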