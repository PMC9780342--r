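#' Build a toy genome with a planted on-target site and off-target lookalikes
#'
#' Generates a small multi-chromosome reference for exercising the junction
#' classifier end to end: a random A/C/G/T genome carrying exactly one copy of
#' the on-target protospacer+PAM and a configurable set of planted off-target
#' sites, each differing from the target 23-mer by an exact, recorded number
#' of mismatches. Any background 23-mer that falls at or below `max_mm`
#' mismatches from the guide by chance is scrubbed (mutated away), so a
#' brute-force enumeration of the returned genome at `max_mm` yields exactly
#' the on-target plus the planted sites.
#'
#' The default target context is the *Vegfa*-sg1 site
#' (`GACCCTGGTGGACATCTTCC` + `AGG`), with the nested bait-primer anchor 60 bp
#' upstream of the protospacer.
#'
#' @param seed Integer RNG seed; the same seed yields a byte-identical genome.
#' @param mismatch_counts Integer vector; one planted off-target per entry,
#'   each differing from the target 23-mer by exactly that many mismatches.
#'   Values must lie in 1..`max_mm` (0 would duplicate the on-target site and
#'   violate its uniqueness; more than `max_mm` could never pass the hotspot
#'   similarity filter and is rejected as a configuration error).
#' @param n_offtargets Number of planted sites; must equal
#'   `length(mismatch_counts)`.
#' @param chrom_lengths Named integer vector of chromosome lengths (each
#'   >= 10 kb; at least two chromosomes so the +/-20 kb window logic spans
#'   chromosomes).
#' @param protospacer,pam Target site sequence (20-nt spacer, NGG PAM).
#' @param target_chrom,target_start Placement of the target 23-mer.
#' @param max_mm Mismatch radius that must contain only the target and the
#'   planted sites (default 8, the hotspot similarity bound).
#' @return A `toy_genome` object: list with `chromosomes` (named character
#'   vector), `guide` (a [guide_spec()]), `offtargets` (tibble with columns
#'   `chrom`, `start`, `strand`, `n_mismatches`, `cut_site`, `site_seq`) and
#'   `seed`.
#' @export
#' @examples
#' g <- build_toy_genome(seed = 1, mismatch_counts = c(2, 3, 4))
#' g$offtargets
build_toy_genome <- function(seed = 1L,
                             mismatch_counts = c(2L, 3L, 4L),
                             n_offtargets = length(mismatch_counts),
                             chrom_lengths = c(chr1 = 60000L, chr2 = 50000L),
                             protospacer = "GACCCTGGTGGACATCTTCC",
                             pam = "AGG",
                             target_chrom = "chr1",
                             target_start = 30000L,
                             max_mm = 8L) {
  mismatch_counts <- as.integer(mismatch_counts)
  if (n_offtargets != length(mismatch_counts)) {
    stop("n_offtargets must equal length(mismatch_counts)")
  }
  if (any(mismatch_counts > max_mm)) {
    stop("mismatch counts > ", max_mm,
         " cannot pass the off-target similarity filter; rejected")
  }
  if (any(mismatch_counts < 1L)) {
    stop("mismatch count 0 would plant a second exact on-target site, ",
         "violating the uniqueness invariant")
  }
  if (length(chrom_lengths) < 2L || any(chrom_lengths < 10000L)) {
    stop("need >= 2 chromosomes, each >= 10 kb")
  }
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  site_seq <- toupper(paste0(protospacer, pam))

  # Generation can paint itself into a corner: a chance lookalike overlapping
  # the target or a planted footprint may be pinned at <= max_mm by bases we
  # must not edit. Deterministically retry the whole draw from a derived
  # child seed until the scrub succeeds (the same seed always walks the same
  # retry sequence, so outputs stay reproducible).
  built <- NULL
  for (attempt in 0:19) {
    seed_att <- if (attempt == 0L) as.integer(seed) else mix_seed(seed, 1000L + attempt)
    built <- withr::with_seed(seed_att, {
      chroms <- vapply(chrom_lengths, random_dna, character(1))

      # Embed the on-target 23-mer.
      chroms[[target_chrom]] <- splice0(chroms[[target_chrom]], target_start, site_seq)
      guide <- guide_spec(protospacer, pam, target_chrom, target_start)

      # Choose planted off-target positions: away from chromosome ends,
      # > 21 kb from the target cut site (outside the bait window with
      # margin), and pairwise separated.
      placements <- plant_positions(chrom_lengths, n_offtargets,
                                    target_chrom, guide$cut_site)
      ot <- vector("list", n_offtargets)
      for (i in seq_len(n_offtargets)) {
        k <- mismatch_counts[i]
        mut <- mutate_site(site_seq, k)
        st <- placements$strand[i]
        planted <- if (st == "+") mut else dna_revcomp(mut)
        ch <- placements$chrom[i]
        pos <- placements$pos[i]
        chroms[[ch]] <- splice0(chroms[[ch]], pos, planted)
        ot[[i]] <- tibble::tibble(
          chrom = ch, start = pos, strand = st,
          n_mismatches = k,
          cut_site = site_cut_site(pos, st),
          site_seq = mut
        )
      }
      offtargets <- dplyr::bind_rows(ot)

      # Scrub accidental lookalikes so the mismatch-<=max_mm neighbourhood
      # of the guide contains exactly the target and the planted sites.
      protected <- rbind(
        cbind(match(target_chrom, names(chroms)), target_start),
        cbind(match(offtargets$chrom, names(chroms)), offtargets$start)
      )
      chroms <- scrub_lookalikes(chroms, site_seq, max_mm, protected)
      if (is.null(chroms)) NULL
      else list(chroms = chroms, guide = guide, offtargets = offtargets)
    })
    if (!is.null(built)) break
  }
  if (is.null(built)) {
    stop("could not generate a genome free of accidental guide lookalikes")
  }
  chroms <- built$chroms
  guide <- built$guide
  offtargets <- built$offtargets

  # Independent verification before returning: recount planted mismatches
  # character by character, and confirm on-target uniqueness.
  for (i in seq_len(nrow(offtargets))) {
    w <- sub0(chroms[[offtargets$chrom[i]]],
              offtargets$start[i], offtargets$start[i] + 23L)
    w_on_strand <- if (offtargets$strand[i] == "+") w else dna_revcomp(w)
    got <- sum(strsplit(w_on_strand, "")[[1]] != strsplit(site_seq, "")[[1]])
    if (got != offtargets$n_mismatches[i]) {
      stop("internal error: planted site ", i, " has ", got,
           " mismatches, expected ", offtargets$n_mismatches[i])
    }
  }
  exact <- enumerate_offtargets_bruteforce(chroms, site_seq, max_mm = 0L)
  if (nrow(exact) != 1L) {
    stop("internal error: on-target site is not unique genome-wide")
  }

  structure(
    list(chromosomes = chroms, guide = guide, offtargets = offtargets,
         seed = as.integer(seed), max_mm = as.integer(max_mm)),
    class = "toy_genome"
  )
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("<toy_genome> ", length(x$chromosomes), " chromosomes (",
      paste0(names(x$chromosomes), ":", nchar(x$chromosomes), collapse = ", "),
      ")\n", sep = "")
  print(x$guide)
  cat("  planted off-targets: ", nrow(x$offtargets), " (",
      paste(x$offtargets$n_mismatches, collapse = ","), " mismatches)\n",
      sep = "")
  invisible(x)
}

# Sample n planting positions: >= 600 bp from chromosome ends, > 21 kb from
# the target cut when on the target chromosome, pairwise >= 2 kb apart.
plant_positions <- function(chrom_lengths, n, target_chrom, target_cut) {
  chosen_chrom <- character(0)
  chosen_pos <- integer(0)
  tries <- 0L
  while (length(chosen_pos) < n) {
    tries <- tries + 1L
    if (tries > 10000L) stop("could not place off-targets; genome too small")
    ch <- sample(names(chrom_lengths), 1L)
    pos <- sample.int(chrom_lengths[[ch]] - 1200L, 1L) + 600L - 1L
    if (ch == target_chrom && abs(pos - target_cut) <= 21000L) next
    same <- chosen_chrom == ch
    if (any(same) && any(abs(chosen_pos[same] - pos) < 2000L)) next
    chosen_chrom <- c(chosen_chrom, ch)
    chosen_pos <- c(chosen_pos, as.integer(pos))
  }
  list(chrom = chosen_chrom, pos = chosen_pos,
       strand = sample(c("+", "-"), n, replace = TRUE))
}

# Mutate exactly k positions of a site sequence to different bases.
mutate_site <- function(site_seq, k) {
  chars <- strsplit(site_seq, "")[[1]]
  idx <- sample(length(chars), k)
  for (j in idx) {
    chars[j] <- sample(setdiff(DNA_BASES, chars[j]), 1L)
  }
  paste(chars, collapse = "")
}

# Mutate away every 23-mer within max_mm mismatches of site_seq that is not a
# protected (target/planted) site. `protected` is a matrix of
# (chrom index, start) rows; the 23-bp footprints of protected sites are never
# edited.
scrub_lookalikes <- function(chroms, site_seq, max_mm, protected) {
  prot_key <- paste(protected[, 1], protected[, 2])
  prot_ranges <- lapply(seq_along(chroms), function(ci) {
    st <- protected[protected[, 1] == ci, 2]
    if (length(st) == 0) return(integer(0))
    unique(unlist(lapply(st, function(s) seq(s, s + 22L))))
  })
  site_raw_f <- charToRaw(site_seq)
  site_raw_r <- charToRaw(dna_revcomp(site_seq))
  for (iter in seq_len(50L)) {
    hits <- enumerate_offtargets_bruteforce(chroms, site_seq, max_mm)
    hits$ci <- match(hits$chrom, names(chroms))
    extra <- hits[!(paste(hits$ci, hits$start) %in% prot_key), , drop = FALSE]
    if (nrow(extra) == 0L) return(chroms)
    for (r in seq_len(nrow(extra))) {
      ci <- extra$ci[r]
      s <- extra$start[r]
      win <- seq(s, s + 22L)
      editable <- setdiff(win, prot_ranges[[ci]])
      if (length(editable) == 0L) next
      pat <- if (extra$strand[r] == "+") site_raw_f else site_raw_r
      cur <- charToRaw(sub0(chroms[[ci]], s, s + 23L))
      # Prefer positions currently matching the guide base: changing them is
      # guaranteed to add a mismatch.
      matching <- win[cur == pat]
      cand <- intersect(matching, editable)
      if (length(cand) == 0L) cand <- editable
      need <- min(length(cand), max(2L, max_mm + 1L - extra$n_mismatches[r]))
      for (p in cand[sample.int(length(cand), need)]) {
        guide_base <- rawToChar(pat[p - s + 1L])
        cur_base <- substr(chroms[[ci]], p + 1L, p + 1L)
        newb <- sample(setdiff(DNA_BASES, unique(c(guide_base, cur_base))), 1L)
        substr(chroms[[ci]], p + 1L, p + 1L) <- newb
      }
    }
  }
  NULL  # caller retries the whole draw from a fresh child seed
}
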