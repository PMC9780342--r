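JUNCTION_CLASSES <- c("uncut", "indel", "large_deletion",
                      "offtarget_translocation", "general_translocation",
                      "aav_integration", "ambiguous")

# Options shared by locate/classify; single place for the declared defaults.
junction_opts <- function(min_score = 30L, d_large = 200L,
                          ot_window = 100L, max_small_insertion = 50L,
                          min_prey = 20L, min_past_cut = 10L,
                          anchor_mismatch = 2L) {
  list(min_score = as.integer(min_score),
       d_large = as.integer(d_large),
       ot_window = as.integer(ot_window),
       max_small_insertion = as.integer(max_small_insertion),
       min_prey = as.integer(min_prey),
       min_past_cut = as.integer(min_past_cut),
       anchor_mismatch = as.integer(anchor_mismatch))
}

#' Locate the bait-prey junction in one payload
#'
#' Anchors the payload at the nested-primer position (first 20 nt must match
#' the reference with at most 2 mismatches, else the read is from the wrong
#' locus and dropped), extends the bait colinearly along the reference
#' tolerating isolated substitutions, and takes the first sustained
#' divergence as the junction. The remainder (>= 20 nt required) is remapped
#' genome-first, then vector; an unaligned remainder prefix of >= 16 nt is
#' treated as an inserted segment and remapped the same way.
#'
#' @param payload Trimmed read payload (UMI and spacer removed).
#' @param guide A [guide_spec()].
#' @param gindex Genome [genome_index()].
#' @param vindex Vector [genome_index()] or `NULL`.
#' @param opts Internal options list.
#' @return One-row tibble: `status` (`uncut`, `junction`, `drop_anchor`,
#'   `ambiguous_short_colinear`, `ambiguous_short_prey`,
#'   `ambiguous_unmapped`, `ambiguous_long_insert`), `bait_end`, `prey_ref`,
#'   `prey_pos` (junction-proximal, 0-based), `prey_strand`, `prey_is_vector`,
#'   `insert_len`, `insert_is_vector`, `insert_vec_pos`, `insert_vec_strand`.
#' @export
locate_junction <- function(payload, guide, gindex, vindex = NULL,
                            opts = junction_opts()) {
  tibble::as_tibble(locate_junction_impl(payload, guide, gindex, vindex, opts))
}

locate_junction_impl <- function(payload, guide, gindex, vindex, opts) {
  ref <- gindex$refs[[guide$chrom]]
  a0 <- guide$anchor
  C <- guide$cut_site
  pl <- nchar(payload)
  avail <- min(pl, nchar(ref) - a0)
  pr <- charToRaw(toupper(payload))
  rr <- charToRaw(substr(ref, a0 + 1L, a0 + avail))
  mm <- pr[seq_len(avail)] != rr

  if (sum(mm[1:20]) > opts$anchor_mismatch) {
    return(raw_junction_row("drop_anchor"))
  }

  div <- find_divergence(mm)
  if (is.na(div)) {
    # Fully colinear: uncut if we see enough reference past the cut site.
    past_cut <- a0 + avail - C
    if (past_cut >= opts$min_past_cut) return(raw_junction_row("uncut"))
    return(raw_junction_row("ambiguous_short_colinear"))
  }

  bait_end <- a0 + div - 1L            # first divergent reference position
  remainder <- substr(payload, div, pl)
  if (nchar(remainder) < opts$min_prey) {
    return(raw_junction_row("ambiguous_short_prey"))
  }

  g1 <- top_hit(remainder, gindex, opts$min_score)
  if (!is.null(g1)) {
    ins <- classify_insert(remainder, g1$query_start, gindex, vindex, opts)
    if (identical(ins$status, "long_unmatched")) {
      return(raw_junction_row("ambiguous_long_insert"))
    }
    bk <- junction_backtrack(pr, div, mm, g1, gindex$refs[[g1$ref]])
    return(raw_junction_row(
      "junction", bait_end = bait_end - bk$shift,
      prey_ref = g1$ref,
      prey_pos = junction_proximal(g1) +
        if (g1$strand == "+") -bk$shift else bk$shift,
      prey_strand = g1$strand,
      prey_is_vector = FALSE,
      insert_len = ins$len,
      insert_is_vector = ins$is_vector,
      insert_vec_pos = ins$vec_pos,
      insert_vec_strand = ins$vec_strand,
      homology = bk$homology
    ))
  }
  if (!is.null(vindex)) {
    v1 <- top_hit(remainder, vindex, opts$min_score)
    if (!is.null(v1)) {
      bk <- junction_backtrack(pr, div, mm, v1, vindex$refs[[v1$ref]])
      return(raw_junction_row(
        "junction", bait_end = bait_end - bk$shift,
        prey_ref = v1$ref,
        prey_pos = junction_proximal(v1) +
          if (v1$strand == "+") -bk$shift else bk$shift,
        prey_strand = v1$strand,
        prey_is_vector = TRUE,
        insert_len = v1$query_start,
        homology = bk$homology
      ))
    }
  }
  raw_junction_row("ambiguous_unmapped")
}

# Canonicalize the junction position and measure its residual ambiguity.
#
# The junction of a bait-prey read is only defined up to the stretch over
# which bait reference and prey reference agree (microhomology); reads
# joining the target to guide-similar off-target sites can carry substantial
# homology on either side of the cut. Two quantities are derived by walking
# left from the sustained divergence while the payload matches the prey
# reference:
# * `shift` - how far the reported junction is pulled back across bait
#   positions that mismatched the bait reference (they were tolerated as
#   isolated substitutions but actually belong to the prey). Never crosses a
#   position that matched the bait reference cleanly.
# * `homology` - the remaining ambiguity: additional positions matching both
#   references, relative to the reported (post-shift) junction. Downstream
#   consumers (hotspot cut-site confirmation) resolve each junction to the
#   point of `[pos - homology, pos]` (plus strand; mirrored on minus)
#   closest to a candidate cut site.
junction_backtrack <- function(payload_raw, div, mm, hit, refseq, cap = 25L) {
  if (hit$query_start != 0L) {
    return(list(shift = 0L, homology = 0L))
  }
  reflen <- nchar(refseq)
  t_full <- 0L
  max_t <- min(cap, div - 21L)
  if (max_t >= 1L) {
    for (s in seq_len(max_t)) {
      pc <- rawToChar(payload_raw[div - s])
      if (hit$strand == "+") {
        rp <- hit$ref_start - s
        if (rp < 0L) break
        rc <- substr(refseq, rp + 1L, rp + 1L)
      } else {
        rp <- hit$ref_end - 1L + s
        if (rp >= reflen) break
        rc <- chartr("ACGT", "TGCA", substr(refseq, rp + 1L, rp + 1L))
      }
      if (pc != rc) break
      t_full <- s
    }
  }
  lo <- max(1L, div - 12L)
  steps <- 0L
  if (lo <= div - 1L) {
    win <- which(mm[lo:(div - 1L)])
    if (length(win) > 0L) steps <- div - (lo + win[1L] - 1L)
  }
  shift <- min(steps, t_full)
  list(shift = shift, homology = t_full - shift)
}

# Best-scoring hit as a plain list, or NULL.
top_hit <- function(query, index, min_score) {
  if (nchar(query) < index$k) return(NULL)
  core <- seed_extend_core(query, index, min_score)
  if (is.null(core)) return(NULL)
  lapply(core, `[`, 1L)
}

# First sustained divergence in a colinear mismatch vector: a mismatch is
# tolerated as an isolated substitution when fewer than 3 of the next 5
# positions also mismatch; mismatches within 3 nt of the read end never
# trigger a junction.
find_divergence <- function(mm) {
  n <- length(mm)
  for (i in which(mm)) {
    if (i + 3L > n) next
    la <- seq.int(i + 1L, min(i + 5L, n))
    if (sum(mm[la]) >= 3L) return(i)
  }
  NA_integer_
}

# Junction-proximal reference coordinate of a hit: the base matching the
# first (junction-side) query base.
junction_proximal <- function(hit) {
  if (hit$strand == "+") hit$ref_start else hit$ref_end - 1L
}

# Decide what an unaligned remainder prefix is: nothing (< 1 nt), a small
# untemplated insertion, a vector fragment (buried AAV), a genomic fragment,
# or a long unmatched insert (ambiguous).
classify_insert <- function(remainder, prefix_len, gindex, vindex, opts) {
  none <- list(status = "none", len = 0L, is_vector = FALSE,
               vec_pos = NA_integer_, vec_strand = NA_character_)
  if (prefix_len <= 0L) return(none)
  small <- list(status = "small", len = as.integer(prefix_len),
                is_vector = FALSE, vec_pos = NA_integer_,
                vec_strand = NA_character_)
  long_unmatched <- list(status = "long_unmatched", len = as.integer(prefix_len),
                         is_vector = FALSE, vec_pos = NA_integer_,
                         vec_strand = NA_character_)
  if (prefix_len < 16L) return(small)
  seg <- substr(remainder, 1L, prefix_len)
  thr <- min(opts$min_score, prefix_len - 5L)
  if (prefix_len >= gindex$k) {
    sg <- top_hit(seg, gindex, thr)
    if (!is.null(sg)) {
      # Genomic insertion (remap order: genome wins); treated like an
      # untemplated insert for classification purposes.
      if (prefix_len > opts$max_small_insertion) return(long_unmatched)
      return(small)
    }
  }
  if (!is.null(vindex) && prefix_len >= vindex$k) {
    sv <- top_hit(seg, vindex, thr)
    if (!is.null(sv)) {
      return(list(status = "vector", len = as.integer(prefix_len),
                  is_vector = TRUE,
                  vec_pos = junction_proximal(sv),
                  vec_strand = sv$strand))
    }
  }
  if (prefix_len > opts$max_small_insertion) return(long_unmatched)
  small
}

raw_junction_row <- function(status, bait_end = NA_integer_,
                             prey_ref = NA_character_,
                             prey_pos = NA_integer_,
                             prey_strand = NA_character_,
                             prey_is_vector = FALSE,
                             insert_len = 0L,
                             insert_is_vector = FALSE,
                             insert_vec_pos = NA_integer_,
                             insert_vec_strand = NA_character_,
                             homology = 0L) {
  list(
    status = status, bait_end = as.integer(bait_end),
    prey_ref = prey_ref, prey_pos = as.integer(prey_pos),
    prey_strand = prey_strand, prey_is_vector = prey_is_vector,
    insert_len = as.integer(insert_len),
    insert_is_vector = insert_is_vector,
    insert_vec_pos = as.integer(insert_vec_pos),
    insert_vec_strand = insert_vec_strand,
    homology = as.integer(homology)
  )
}

#' Classify a located junction into an editing-outcome class
#'
#' Applies the decision cascade, in order: (1) no junction -> `uncut`;
#' (2) inserted segment aligning to the vector -> `aav_integration` type
#' `buried`; (3) prey aligning to the vector -> `aav_integration` type
#' `fusion`; (4) prey inside the bait window (cut +/- 20 kb, plus strand):
#' deletion <= `d_large` -> `indel`, deletion in (`d_large`, 20 kb] ->
#' `large_deletion` (small non-vector insertions count as indels); (5) prey
#' within +/- `ot_window` (100 bp) of an off-target cut site ->
#' `offtarget_translocation`; (6) otherwise (other chromosome, > 20 kb away,
#' or an inversion inside the window) -> `general_translocation`.
#'
#' @param raw One-row tibble (or list) from [locate_junction()].
#' @param guide A [guide_spec()].
#' @param offtargets Off-target site tibble with `chrom` and `cut_site`
#'   columns (may have zero rows on a first pass).
#' @param opts Internal options list.
#' @return One-row tibble: `class`, `aav_type`, `prey_ref`, `prey_pos`,
#'   `prey_strand`, `deletion_size`, `insertion_size`, `bait_end`.
#' @export
classify_junction <- function(raw, guide, offtargets = NULL,
                              opts = junction_opts()) {
  if (is.data.frame(raw)) raw <- as.list(raw[1L, ])
  tibble::as_tibble(classify_junction_impl(raw, guide, offtargets, opts))
}

classify_junction_impl <- function(raw, guide, offtargets, opts) {
  out <- function(class, aav_type = "none", deletion_size = NA_integer_,
                  insertion_size = NA_integer_, prey_ref = raw$prey_ref,
                  prey_pos = raw$prey_pos, prey_strand = raw$prey_strand) {
    list(
      class = class, aav_type = aav_type,
      prey_ref = prey_ref, prey_pos = as.integer(prey_pos),
      prey_strand = prey_strand,
      deletion_size = as.integer(deletion_size),
      insertion_size = as.integer(insertion_size),
      bait_end = raw$bait_end,
      homology = raw$homology %||% 0L
    )
  }
  if (raw$status == "uncut") {
    return(out("uncut", prey_ref = NA_character_, prey_pos = NA_integer_,
               prey_strand = NA_character_))
  }
  if (raw$status != "junction") {
    return(out("ambiguous", prey_ref = NA_character_, prey_pos = NA_integer_,
               prey_strand = NA_character_))
  }
  if (isTRUE(raw$insert_is_vector)) {
    return(out("aav_integration", aav_type = "buried",
               insertion_size = raw$insert_len,
               prey_ref = "AAV", prey_pos = raw$insert_vec_pos,
               prey_strand = raw$insert_vec_strand))
  }
  if (isTRUE(raw$prey_is_vector)) {
    return(out("aav_integration", aav_type = "fusion"))
  }
  C <- guide$cut_site
  in_window <- raw$prey_ref == guide$chrom &
    abs(raw$prey_pos - C) <= guide$bait_window
  if (in_window && raw$prey_strand == "+") {
    d <- raw$prey_pos - raw$bait_end
    ins <- if (raw$insert_len > 0L) raw$insert_len else NA_integer_
    if (d <= opts$d_large) {
      return(out("indel", deletion_size = max(d, 0L), insertion_size = ins))
    }
    if (d <= guide$bait_window) {
      return(out("large_deletion", deletion_size = d, insertion_size = ins))
    }
  }
  if (!is.null(offtargets) && nrow(offtargets) > 0L) {
    near <- offtargets$chrom == raw$prey_ref &
      abs(offtargets$cut_site - raw$prey_pos) <= opts$ot_window
    if (any(near)) return(out("offtarget_translocation"))
  }
  out("general_translocation")
}

# Re-apply only the off-target window rule to already-classified calls:
# moves general translocations whose prey lies within +/- ot_window of a
# newly supplied off-target cut site into the off-target class (and back,
# when sites are withdrawn).
reclassify_with_offtargets <- function(calls, offtargets,
                                       opts = junction_opts()) {
  tx <- calls$class %in% c("general_translocation", "offtarget_translocation")
  if (!any(tx)) return(calls)
  near <- rep(FALSE, nrow(calls))
  if (!is.null(offtargets) && nrow(offtargets) > 0L) {
    for (i in seq_len(nrow(offtargets))) {
      near <- near | (!is.na(calls$prey_ref) &
                        calls$prey_ref == offtargets$chrom[i] &
                        abs(calls$prey_pos - offtargets$cut_site[i]) <= opts$ot_window)
    }
  }
  calls$class[tx & near] <- "offtarget_translocation"
  calls$class[tx & !near] <- "general_translocation"
  calls
}
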