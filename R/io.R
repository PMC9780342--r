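#' Read and write standard formats
#'
#' Thin wrappers over Biostrings/readr keeping the pipeline's tabular
#' containers: reads as tibbles (`read_id`, `sequence`, `quality`),
#' references as named character vectors, sites and calls as TSV/BED/BEDPE.
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `quality`.
#' @param path File path.
#' @name pemseq_io
NULL

#' @rdname pemseq_io
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality %||% strrep("I", nchar(reads$sequence))
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(qual)
  )
  # the quality mcol is carried explicitly; the drop note is expected
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(qs, path))
  invisible(path)
}

#' @rdname pemseq_io
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble::tibble(
    read_id = sub(" .*", "", names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(Biostrings::quality(x)))
  )
}

#' @rdname pemseq_io
#' @param seqs Named character vector of sequences, or a
#'   [build_toy_genome()] / [build_aav_vector()] object.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "toy_genome")) seqs <- seqs$chromosomes
  if (inherits(seqs, "vector_map")) seqs <- setNames(seqs$sequence, seqs$name)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname pemseq_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub(" .*", "", names(x)))
}

#' @rdname pemseq_io
#' @param sites Tibble with `chrom`, `start`, `strand` columns (e.g. planted
#'   or discovered off-target sites); written as BED6 (+ extra columns),
#'   0-based half-open.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- tibble::tibble(
    chrom = sites$chrom,
    start = sites$start,
    end = sites$start + 23L,
    name = sprintf("site_%d", seq_len(nrow(sites))),
    score = sites$n_mismatches %||% 0L,
    strand = sites$strand
  )
  extra <- setdiff(names(sites), c("chrom", "start", "strand"))
  bed <- dplyr::bind_cols(bed, sites[extra])
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname pemseq_io
#' @param truth Truth tibble from [simulate_library()].
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname pemseq_io
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname pemseq_io
#' @param calls Molecule-level junction-call tibble.
#' @export
write_calls_tsv <- function(calls, path) {
  flat <- dplyr::select(calls, -dplyr::any_of("read_ids"))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname pemseq_io
#' @export
read_calls_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(prey_ref = readr::col_character(),
                                          prey_strand = readr::col_character(),
                                          class = readr::col_character(),
                                          aav_type = readr::col_character()))
}

#' @rdname pemseq_io
#' @param guide A [guide_spec()] providing the bait side of each junction.
#' @export
write_translocations_bedpe <- function(calls, guide, path) {
  tx <- calls[calls$class %in% c("general_translocation",
                                 "offtarget_translocation"), , drop = FALSE]
  bedpe <- tibble::tibble(
    chrom1 = guide$chrom,
    start1 = ifelse(is.na(tx$bait_end), guide$cut_site, tx$bait_end),
    end1 = ifelse(is.na(tx$bait_end), guide$cut_site, tx$bait_end) + 1L,
    chrom2 = tx$prey_ref,
    start2 = tx$prey_pos,
    end2 = tx$prey_pos + 1L,
    name = sprintf("tx_%d", seq_len(nrow(tx))),
    score = 0L,
    strand1 = "+",
    strand2 = tx$prey_strand
  )
  readr::write_tsv(bedpe, path, col_names = FALSE)
  invisible(path)
}

#' Write a run report as TSV and JSON
#'
#' Emits all counts, normalized percentages, and a configuration echo for a
#' pipeline result.
#'
#' @param result A `pemseq_result` from [run_pemseq()].
#' @param path_prefix Output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param config Optional [sim_config()] or list echoed into the report.
#' @return Invisibly, the report list.
#' @export
write_run_report <- function(result, path_prefix, config = NULL) {
  s <- result$summary
  g <- glance(s)
  report <- list(
    counts = setNames(as.list(s$counts$n), s$counts$class),
    percentages = as.list(g[setdiff(names(g), c("total_events", "n_ambiguous"))]),
    total_events = s$total_events,
    n_ambiguous = s$n_ambiguous,
    read_report = as.list(result$report),
    offtargets = result$offtargets,
    config = if (!is.null(config)) unclass(config) else NULL
  )
  tsv <- dplyr::mutate(tidy(s),
                       pct_of_total = round(pct_of_total, 2))
  readr::write_tsv(tsv, paste0(path_prefix, ".tsv"))
  jsonlite::write_json(report, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Read chimeric alignments from a SAM/BAM file
#'
#' Optional alternative alignment source: converts primary alignments (and
#' their `SA` supplementary-alignment tags) into the internal hit layout so
#' externally mapped reads can enter the junction caller's downstream
#' contract.
#'
#' @param path SAM or BAM file path.
#' @return Tibble: `read_id`, `ref`, `ref_start` (0-based), `strand`,
#'   `cigar`, `sa_tag` (semicolon-separated supplementary alignments, `NA`
#'   when absent).
#' @export
read_sam_hits <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM/BAM input")
  }
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar"),
    tag = "SA"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(x$pos)
  tibble::tibble(
    read_id = x$qname[keep],
    ref = as.character(x$rname)[keep],
    ref_start = x$pos[keep] - 1L,
    strand = as.character(x$strand)[keep],
    cigar = x$cigar[keep],
    sa_tag = if (!is.null(x$tag$SA)) x$tag$SA[keep] else NA_character_
  )
}

#' Write simulated library artefacts to a directory
#'
#' Writes FASTQ reads, the truth TSV, genome and vector FASTA, and planted
#' sites BED for a simulated library.
#'
#' @param sim A `sim_library` from [simulate_library()].
#' @param genome A [build_toy_genome()] object.
#' @param vector A [build_aav_vector()] object or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_sim_library <- function(sim, genome, vector = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fastq = file.path(out_dir, "reads.fastq"),
    truth = file.path(out_dir, "truth.tsv"),
    genome = file.path(out_dir, "genome.fasta"),
    sites = file.path(out_dir, "planted_sites.bed")
  )
  write_fastq(sim$reads, paths["fastq"])
  write_truth_tsv(sim$truth, paths["truth"])
  write_fasta(genome, paths["genome"])
  write_sites_bed(genome$offtargets, paths["sites"])
  if (!is.null(vector)) {
    paths["vector"] <- file.path(out_dir, "vector.fasta")
    write_fasta(vector, paths["vector"])
  }
  invisible(paths)
}
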