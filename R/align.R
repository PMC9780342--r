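#' Build a seed index over a reference set
#'
#' Indexes every exact k-mer (default 20, the seed length used throughout the
#' pipeline) of a set of reference sequences for the seed-and-extend local
#' aligner. References are concatenated internally with `N` separators so a
#' single lookup table serves all of them; extensions can never cross a
#' separator because `N` never matches.
#'
#' @param refs Named character vector of sequences, or a
#'   [build_toy_genome()] / [build_aav_vector()] object.
#' @param k Seed length in nt (default 20).
#' @return A `seed_index` object.
#' @export
genome_index <- function(refs, k = 20L) {
  if (inherits(refs, "toy_genome")) refs <- refs$chromosomes
  if (inherits(refs, "vector_map")) refs <- setNames(refs$sequence, refs$name)
  stopifnot(is.character(refs), !is.null(names(refs)))
  k <- as.integer(k)
  sep <- strrep("N", 30L)
  concat <- paste(refs, collapse = sep)
  lens <- nchar(refs)
  offsets <- cumsum(c(0L, head(lens + 30L, -1L)))  # 0-based start in concat
  all_kmers <- character(0)
  all_pos <- integer(0)
  for (i in seq_along(refs)) {
    n <- lens[i]
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    all_kmers <- c(all_kmers, substring(refs[[i]], starts, starts + k - 1L))
    all_pos <- c(all_pos, starts - 1L + offsets[i])
  }
  env <- list2env(split(all_pos, all_kmers),
                  envir = new.env(hash = TRUE, parent = emptyenv(),
                                  size = length(all_pos)))
  structure(
    list(refs = refs, names = names(refs), lengths = lens,
         offsets = offsets, concat_raw = charToRaw(concat),
         env = env, k = k),
    class = "seed_index"
  )
}

#' @export
print.seed_index <- function(x, ...) {
  cat("<seed_index> k=", x$k, ", ", length(x$refs), " reference(s): ",
      paste0(x$names, " (", x$lengths, " bp)", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Seed-and-extend local alignment
#'
#' Aligns a query against an indexed reference set with exact `k`-mer seeds on
#' both strands, per-diagonal ungapped extension (best-scoring segment by a
#' maximum-subarray scan), and affine-gap chaining of colinear segments on
#' different diagonals. Scoring: match +1, mismatch -4, gap of length L costs
#' 6 + L (open 6, extend 1). For substitution-only differences the result is
#' the exact Smith-Waterman local optimum over the seeded diagonals.
#'
#' @param query DNA string (length >= seed size).
#' @param index A [genome_index()].
#' @param min_score Minimum reported score (default 30, i.e. at least ~30
#'   aligned nt for a clean hit).
#' @param max_candidates Maximum diagonals examined per strand.
#' @return Tibble of hits sorted by decreasing score (ties by reference name
#'   then coordinate): `query_start`, `query_end`, `ref`, `ref_start`,
#'   `ref_end` (all 0-based half-open, query interval in the original query
#'   orientation), `strand`, `score`, `n_mismatches`. Zero rows when nothing
#'   reaches `min_score`.
#' @export
seed_extend_align <- function(query, index, min_score = 30L,
                              max_candidates = 30L) {
  core <- seed_extend_core(query, index, min_score, max_candidates)
  if (is.null(core)) return(empty_hits())
  hits <- tibble::as_tibble(core)
  hits <- dplyr::distinct(hits)
  hits[order(-hits$score, hits$ref, hits$ref_start), ]
}

# Hot-path implementation on plain vectors; returns NULL or a list of
# parallel vectors (query_start, query_end, ref, ref_start, ref_end, strand,
# score, n_mismatches) sorted by decreasing score then (ref, ref_start).
seed_extend_core <- function(query, index, min_score = 30L,
                             max_candidates = 30L) {
  L <- nchar(query)
  k <- index$k
  if (L < k) stop("query shorter than seed length (", k, " nt); cannot seed")
  query <- toupper(query)
  total <- length(index$concat_raw)

  n_seg <- 0L
  sg_strand <- character(0); sg_diag <- integer(0)
  sg_qs <- integer(0); sg_qe <- integer(0)
  sg_score <- numeric(0); sg_mm <- integer(0)

  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp1(query)
    qraw <- charToRaw(q)
    nk <- L - k + 1L
    kmers <- substring(q, seq_len(nk), seq_len(nk) + k - 1L)
    hitlist <- mget(kmers, envir = index$env, ifnotfound = list(NULL))
    nhit <- lengths(hitlist)
    if (sum(nhit) == 0L) next
    qoff <- rep.int(seq_len(nk) - 1L, nhit)        # 0-based query offset
    gpos <- unlist(hitlist, use.names = FALSE)      # 0-based concat position
    dg <- gpos - qoff
    ud <- unique(dg)
    cnt <- tabulate(match(dg, ud))
    ord <- order(-cnt)
    diags <- ud[ord[seq_len(min(length(ud), max_candidates))]]
    for (d in diags) {
      lo <- max(0L, -d)                 # query index range valid on concat
      hi <- min(L - 1L, total - 1L - d)
      if (hi - lo + 1L < k) next
      m <- qraw[(lo + 1L):(hi + 1L)] ==
        index$concat_raw[(d + lo + 1L):(d + hi + 1L)]
      s <- ifelse(m, 1, -4)
      cs <- cumsum(s)
      prev <- c(0, cs[-length(cs)])
      cmin <- cummin(prev)
      gains <- cs - cmin
      j2 <- which.max(gains)
      best <- gains[j2]
      j1 <- which(prev[seq_len(j2)] == cmin[j2])[1L]
      n_seg <- n_seg + 1L
      sg_strand[n_seg] <- strand
      sg_diag[n_seg] <- d
      sg_qs[n_seg] <- lo + j1 - 1L      # 0-based within strand-oriented query
      sg_qe[n_seg] <- lo + j2           # half-open
      sg_score[n_seg] <- best
      sg_mm[n_seg] <- sum(!m[j1:j2])
    }
  }
  if (n_seg == 0L) return(NULL)

  # Affine-gap chaining: combine ordered, near-disjoint segment pairs on the
  # same strand (gap cost 6 + |diagonal shift|; query overlap charged at the
  # worst case of one match per overlapping base).
  if (n_seg > 1L) {
    o <- order(sg_strand, sg_qs)
    for (a in seq_len(n_seg - 1L)) {
      for (b in (a + 1L):n_seg) {
        i <- o[a]; j <- o[b]
        if (sg_strand[j] != sg_strand[i]) next
        gapd <- abs(sg_diag[j] - sg_diag[i])
        if (gapd == 0L || gapd > 50L) next
        overlap <- max(0L, sg_qe[i] - sg_qs[j])
        if (overlap > k) next
        gs_i <- sg_diag[i] + sg_qs[i]
        gs_j <- sg_diag[j] + sg_qs[j]
        if (gs_j + overlap <= gs_i) next  # reference order must agree
        sc <- sg_score[i] + sg_score[j] - overlap - (6L + gapd)
        if (sc > max(sg_score[i], sg_score[j])) {
          n_seg <- n_seg + 1L
          sg_strand[n_seg] <- sg_strand[i]
          sg_diag[n_seg] <- sg_diag[i]
          sg_qs[n_seg] <- sg_qs[i]
          sg_qe[n_seg] <- max(sg_qe[i], sg_qe[j])
          sg_score[n_seg] <- sc
          sg_mm[n_seg] <- sg_mm[i] + sg_mm[j]
        }
      }
    }
  }

  keep <- sg_score >= min_score
  if (!any(keep)) return(NULL)
  gs <- (sg_diag + sg_qs)[keep]
  ge <- (sg_diag + sg_qe)[keep]
  strand <- sg_strand[keep]
  qs <- sg_qs[keep]; qe <- sg_qe[keep]
  score <- sg_score[keep]; mm <- sg_mm[keep]

  # Map concat coordinates back to reference names; drop separator-spanning
  # artefacts (cannot occur: N never matches, but guard anyway).
  ri <- findInterval(gs, index$offsets)
  ok <- ge <= index$offsets[ri] + index$lengths[ri]
  if (!any(ok)) return(NULL)
  gs <- gs[ok]; ge <- ge[ok]; strand <- strand[ok]
  qs <- qs[ok]; qe <- qe[ok]; score <- score[ok]; mm <- mm[ok]
  ri <- ri[ok]

  minus <- strand == "-"
  out <- list(
    query_start = as.integer(ifelse(minus, L - qe, qs)),
    query_end = as.integer(ifelse(minus, L - qs, qe)),
    ref = index$names[ri],
    ref_start = as.integer(gs - index$offsets[ri]),
    ref_end = as.integer(ge - index$offsets[ri]),
    strand = strand,
    score = as.integer(score),
    n_mismatches = as.integer(mm)
  )
  o <- order(-out$score, out$ref, out$ref_start)
  lapply(out, `[`, o)
}

empty_hits <- function() {
  tibble::tibble(
    query_start = integer(0), query_end = integer(0), ref = character(0),
    ref_start = integer(0), ref_end = integer(0), strand = character(0),
    score = integer(0), n_mismatches = integer(0)
  )
}
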