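#' Extract UMIs and trim reads to their payload
#'
#' Splits each read into `[UMI][6-nt spacer][payload]`. Reads whose spacer
#' carries more than one mismatch are dropped (they are not confidently
#' adapter-anchored), as are reads too short to contain a UMI, spacer and a
#' minimal payload; both drop classes are counted and surfaced as the
#' `"drop_counts"` attribute for the run report.
#'
#' @param reads Tibble with columns `read_id` and `sequence` (e.g. from
#'   [simulate_library()] or [read_fastq()]).
#' @param umi_length UMI length in nt.
#' @param spacer Expected 6-nt spacer sequence.
#' @param max_spacer_mismatch Maximum tolerated spacer mismatches (default 1).
#' @param min_payload Minimum payload length after trimming (default 30).
#' @return Tibble `read_id`, `umi`, `payload`; attribute `drop_counts` is a
#'   named integer vector (`too_short`, `spacer_mismatch`).
#' @export
extract_umi <- function(reads, umi_length = 12L, spacer = "ACGCGT",
                        max_spacer_mismatch = 1L, min_payload = 30L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  u <- as.integer(umi_length)
  sp_len <- nchar(spacer)
  min_len <- u + sp_len + min_payload
  len <- nchar(reads$sequence)
  long_enough <- len > min_len
  spacers <- substr(reads$sequence, u + 1L, u + sp_len)
  sp_mm <- hamming_vec(spacers, spacer)
  keep <- long_enough & sp_mm <= max_spacer_mismatch
  out <- tibble::tibble(
    read_id = reads$read_id[keep],
    umi = substr(reads$sequence[keep], 1L, u),
    payload = substr(reads$sequence[keep], u + sp_len + 1L, len[keep])
  )
  attr(out, "drop_counts") <- c(
    too_short = sum(!long_enough),
    spacer_mismatch = sum(long_enough & sp_mm > max_spacer_mismatch)
  )
  out
}

#' Collapse PCR duplicates by UMI and junction key
#'
#' Reads sharing a junction key whose UMIs lie within Hamming distance 1 are
#' collapsed to one molecule, greedily from the most frequent UMI down;
#' distinct junction keys never merge. The junction key is the outcome class
#' plus the prey reference, the prey position rounded to a +/-2 bp bucket,
#' and the prey strand.
#'
#' @param calls Tibble with a `umi` column and the key columns.
#' @param key_cols Character vector of column names forming the junction key.
#' @return Tibble with one row per molecule: `molecule_id`, the key columns,
#'   the representative (most frequent) `umi`, `n_reads`, and `read_ids`
#'   (list-column of member read ids when a `read_id` column is present).
#' @export
dedup_umis <- function(calls,
                       key_cols = c("kind", "prey_ref", "prey_bin", "prey_strand")) {
  stopifnot(is.data.frame(calls), "umi" %in% names(calls))
  key_cols <- intersect(key_cols, names(calls))
  if (length(key_cols) == 0L) stop("no junction key columns found")
  if (nrow(calls) == 0L) {
    out <- dplyr::mutate(calls, molecule_id = integer(0), n_reads = integer(0))
    return(out)
  }
  key <- do.call(paste, c(calls[key_cols], sep = "\r"))
  groups <- split(seq_len(nrow(calls)), key)
  has_ids <- "read_id" %in% names(calls)

  cluster_of <- integer(nrow(calls))
  rep_umi <- character(nrow(calls))
  mol_key <- character(nrow(calls))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    cl <- cluster_umis(calls$umi[idx])
    cluster_of[idx] <- cl$cluster
    rep_umi[idx] <- cl$representative[cl$cluster]
    mol_key[idx] <- paste0(gi, "_", cl$cluster)
  }

  first_idx <- which(!duplicated(mol_key))
  out <- calls[first_idx, setdiff(names(calls), c("umi", "read_id")), drop = FALSE]
  out <- tibble::as_tibble(out)
  out$umi <- rep_umi[first_idx]
  mol_of_read <- match(mol_key, mol_key[first_idx])
  out$n_reads <- tabulate(mol_of_read, nbins = length(first_idx))
  if (has_ids) {
    out$read_ids <- unname(split(calls$read_id, factor(mol_of_read,
                                                       levels = seq_along(first_idx))))
  }
  out$molecule_id <- seq_len(nrow(out))
  dplyr::relocate(out, molecule_id)
}

# Greedy Hamming<=1 clustering of a character vector of UMIs.
# Returns list(cluster = integer assignment per input element,
#              representative = character per cluster).
# Neighbour search uses the positional-mask trick: two equal-length strings
# are within Hamming distance 1 iff they share a masked key at some position.
cluster_umis <- function(umis) {
  tab <- sort(table(umis), decreasing = TRUE)
  uu <- names(tab)
  nu <- length(uu)
  if (nu == 1L) {
    return(list(cluster = rep(1L, length(umis)), representative = uu))
  }
  ul <- nchar(uu[1L])
  # masked key -> indices of unique UMIs sharing it
  masks <- character(nu * ul)
  for (p in seq_len(ul)) {
    masked <- uu
    substr(masked, p, p) <- "."
    masks[((p - 1L) * nu + 1L):(p * nu)] <- masked
  }
  map <- split(rep.int(seq_len(nu), ul), masks)
  lookup <- list2env(map, envir = new.env(hash = TRUE, parent = emptyenv(),
                                          size = length(map)))
  assign_of <- rep(NA_integer_, nu)
  reps <- character(0)
  cid <- 0L
  for (i in seq_len(nu)) {
    if (!is.na(assign_of[i])) next
    cid <- cid + 1L
    reps[cid] <- uu[i]
    assign_of[i] <- cid
    for (p in seq_len(ul)) {
      mk <- uu[i]
      substr(mk, p, p) <- "."
      nb <- lookup[[mk]]
      free <- nb[is.na(assign_of[nb])]
      if (length(free)) assign_of[free] <- cid
    }
  }
  list(cluster = assign_of[match(umis, uu)], representative = reps)
}
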