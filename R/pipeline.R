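#' Call junctions for a library of reads
#'
#' Runs the per-read stages of the pipeline: UMI extraction, bait-prey
#' junction location, UMI deduplication to molecules, and outcome
#' classification. Identical payloads are processed once and the results
#' fanned back out, so PCR duplicates cost almost nothing.
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param genome A [build_toy_genome()] object.
#' @param vector A [build_aav_vector()] object or `NULL`.
#' @param offtargets Off-target site tibble used for the +/-100 bp window
#'   rule; defaults to the genome's planted sites. Pass a zero-row tibble
#'   for a first (discovery) pass.
#' @param umi_length,spacer UMI layout (must match the library).
#' @param min_score Minimum prey alignment score (default 30).
#' @param d_large Indel vs large-deletion boundary in bp (default 200).
#' @param ot_window Off-target junction window half-width in bp (default 100).
#' @return Tibble of molecule-level junction calls: `molecule_id`, `class`,
#'   `aav_type`, `prey_ref`, `prey_pos`, `prey_strand`, `deletion_size`,
#'   `insertion_size`, `bait_end`, `umi`, `n_reads`, `read_ids`. The
#'   `"report"` attribute carries read-level drop counters.
#' @export
call_junctions <- function(reads, genome, vector = NULL,
                           offtargets = genome$offtargets,
                           umi_length = 12L, spacer = "ACGCGT",
                           min_score = 30L, d_large = 200L,
                           ot_window = 100L) {
  stopifnot(inherits(genome, "toy_genome"))
  opts <- junction_opts(min_score = min_score, d_large = d_large,
                        ot_window = ot_window)
  guide <- genome$guide
  gindex <- genome_index(genome)
  vindex <- if (!is.null(vector)) genome_index(vector) else NULL

  pr <- extract_umi(reads, umi_length = umi_length, spacer = spacer)
  drops <- attr(pr, "drop_counts")

  upay <- unique(pr$payload)
  nu <- length(upay)
  status <- character(nu)
  cls_list <- vector("list", nu)
  for (i in seq_len(nu)) {
    raw <- locate_junction_impl(upay[i], guide, gindex, vindex, opts)
    status[i] <- raw$status
    cls_list[[i]] <- classify_junction_impl(raw, guide, offtargets, opts)
  }
  col <- function(f, how) vapply(cls_list, function(x) x[[f]], how)
  per_payload <- tibble::tibble(
    payload = upay,
    status = status,
    class = col("class", character(1)),
    aav_type = col("aav_type", character(1)),
    prey_ref = col("prey_ref", character(1)),
    prey_pos = col("prey_pos", integer(1)),
    prey_strand = col("prey_strand", character(1)),
    deletion_size = col("deletion_size", integer(1)),
    insertion_size = col("insertion_size", integer(1)),
    bait_end = col("bait_end", integer(1)),
    homology = col("homology", integer(1))
  )

  per_read <- dplyr::left_join(pr, per_payload, by = "payload")
  dropped_anchor <- sum(per_read$status == "drop_anchor")
  per_read <- per_read[per_read$status != "drop_anchor", , drop = FALSE]

  # Junction key for deduplication: class kind + prey ref + position bucket
  # (+/-2 bp) + strand.
  per_read$kind <- per_read$class
  per_read$prey_bin <- per_read$prey_pos %/% 5L
  mols <- dedup_umis(per_read,
                     key_cols = c("kind", "prey_ref", "prey_bin", "prey_strand"))
  mols <- dplyr::select(mols, -dplyr::any_of(c("payload", "status", "kind",
                                               "prey_bin")))
  mols <- dplyr::relocate(mols, molecule_id, class)

  ambiguous <- sum(mols$class == "ambiguous")
  attr(mols, "report") <- c(
    n_reads = nrow(reads),
    dropped_too_short = unname(drops["too_short"]),
    dropped_spacer = unname(drops["spacer_mismatch"]),
    dropped_anchor = dropped_anchor,
    n_molecules = nrow(mols),
    n_ambiguous = ambiguous
  )
  mols
}

#' Run the full editing-outcome pipeline
#'
#' Chains junction calling, translocation-hotspot off-target discovery, a
#' reclassification pass applying the discovered +/-100 bp off-target
#' windows, and summary statistics.
#'
#' @inheritParams call_junctions
#' @param discover If `TRUE` (default), discover off-target sites from the
#'   data; otherwise use `offtargets` as supplied.
#' @param min_support Minimum hotspot support (default 3 molecules).
#' @param max_mm Maximum joint spacer+PAM mismatches for an off-target site
#'   (default 8).
#' @return A `pemseq_result`: list with `calls`, `offtargets`, `summary`
#'   (an [summarize_calls()] object) and `report`.
#' @export
run_pemseq <- function(reads, genome, vector = NULL, discover = TRUE,
                       offtargets = genome$offtargets,
                       umi_length = 12L, spacer = "ACGCGT",
                       min_score = 30L, d_large = 200L, ot_window = 100L,
                       min_support = 3L, max_mm = 8L) {
  first_pass_ot <- if (discover) genome$offtargets[0, ] else offtargets
  calls <- call_junctions(reads, genome, vector,
                          offtargets = first_pass_ot,
                          umi_length = umi_length, spacer = spacer,
                          min_score = min_score, d_large = d_large,
                          ot_window = ot_window)
  report <- attr(calls, "report")
  ot <- if (discover) {
    discover_offtargets(calls, genome, guide = genome$guide,
                        min_support = min_support, max_mm = max_mm)
  } else {
    offtargets
  }
  opts <- junction_opts(min_score = min_score, d_large = d_large,
                        ot_window = ot_window)
  calls <- reclassify_with_offtargets(calls, ot, opts)
  attr(calls, "report") <- report
  structure(
    list(calls = calls, offtargets = ot,
         summary = summarize_calls(calls), report = report),
    class = "pemseq_result"
  )
}

#' @export
print.pemseq_result <- function(x, ...) {
  cat("<pemseq_result> ", x$report[["n_molecules"]], " molecules from ",
      x$report[["n_reads"]], " reads; ", nrow(x$offtargets),
      " off-target site(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @method tidy pemseq_result
#' @export
tidy.pemseq_result <- function(x, ...) tidy(x$summary)

#' @method glance pemseq_result
#' @export
glance.pemseq_result <- function(x, ...) glance(x$summary)
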