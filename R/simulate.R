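SIM_CLASSES <- c("uncut", "indel", "large_deletion",
                 "offtarget_translocation", "general_translocation",
                 "aav_buried", "aav_fusion")

#' Default outcome-class mixture
#'
#' Per-molecule probabilities of each editing outcome used by
#' [sim_config()]: mostly uncut alleles, ~12% edited (indels, large
#' deletions, translocations) and 6% AAV vector capture, covering all seven
#' outcome classes.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_class_fractions <- function() {
  c(uncut = 0.82, indel = 0.10, large_deletion = 0.01,
    offtarget_translocation = 0.005, general_translocation = 0.005,
    aav_buried = 0.03, aav_fusion = 0.03)
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic PEM-seq library generator.
#' Reads are single-end, `read_length` nt:
#' `[umi_length-nt UMI][6-nt spacer][bait ... prey]`, with the bait starting
#' at the nested-primer anchor 60 bp upstream of the protospacer and running
#' through the cut site into a class-dependent prey.
#'
#' @param class_fractions Named per-molecule class probabilities over (a
#'   subset of) `uncut`, `indel`, `large_deletion`, `offtarget_translocation`,
#'   `general_translocation`, `aav_buried`, `aav_fusion`; must sum to 1.
#' @param n_molecules Number of original molecules to simulate.
#' @param pcr_duplication_rate Mean number of PCR duplicates per molecule
#'   (geometric); duplicates share the molecule's UMI and junction and get
#'   independent substitution errors.
#' @param umi_length UMI length in nt.
#' @param error_rate Per-base substitution probability (no indel errors).
#' @param itr_junction_bias Probability that an AAV-side breakpoint falls
#'   inside an ITR interval (otherwise uniform over the non-ITR remainder).
#' @param seed Integer RNG seed; a fixed seed yields byte-identical output.
#' @param read_length Total read length in nt.
#' @param spacer Fixed 6-nt spacer between UMI and bait.
#' @param indel_del_max Largest deletion still counted as an indel (bp);
#'   deletions in `(indel_del_max, large_del_max]` are large deletions.
#' @param large_del_max Largest simulated deletion (bp).
#' @param indel_ins_frac Fraction of indel molecules carrying an insertion
#'   (random non-vector nt) instead of a deletion.
#' @param indel_ins_max Largest simulated insertion (nt).
#' @param aav_frag_range Length range (nt) of buried AAV fragments.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(class_fractions = default_class_fractions(),
                       n_molecules = 20000L,
                       pcr_duplication_rate = 1,
                       umi_length = 12L,
                       error_rate = 0.001,
                       itr_junction_bias = 0.6,
                       seed = 7L,
                       read_length = 250L,
                       spacer = "ACGCGT",
                       indel_del_max = 200L,
                       large_del_max = 20000L,
                       indel_ins_frac = 0.3,
                       indel_ins_max = 20L,
                       aav_frag_range = c(20L, 500L)) {
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% SIM_CLASSES)) {
    stop("class_fractions must be named with classes among: ",
         paste(SIM_CLASSES, collapse = ", "))
  }
  if (any(class_fractions < 0 | class_fractions > 1)) {
    stop("class fractions must lie in [0, 1]")
  }
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class fractions must sum to 1 (got ", sum(class_fractions), ")")
  }
  if (n_molecules < 0) stop("n_molecules must be >= 0")
  stopifnot(error_rate >= 0, error_rate <= 1,
            itr_junction_bias >= 0, itr_junction_bias <= 1,
            pcr_duplication_rate >= 0,
            nchar(spacer) == 6L, umi_length >= 4L,
            read_length > umi_length + 6L + 100L)
  structure(
    list(class_fractions = class_fractions,
         n_molecules = as.integer(n_molecules),
         pcr_duplication_rate = pcr_duplication_rate,
         umi_length = as.integer(umi_length),
         error_rate = error_rate,
         itr_junction_bias = itr_junction_bias,
         seed = as.integer(seed),
         read_length = as.integer(read_length),
         spacer = toupper(spacer),
         indel_del_max = as.integer(indel_del_max),
         large_del_max = as.integer(large_del_max),
         indel_ins_frac = indel_ins_frac,
         indel_ins_max = as.integer(indel_ins_max),
         aav_frag_range = as.integer(aav_frag_range)),
    class = "sim_config"
  )
}

#' Simulate a truth-labelled PEM-seq library
#'
#' Draws `n_molecules` molecules from the configured class mixture, builds
#' each molecule's read through the bait-prey junction geometry of its class,
#' expands PCR duplicates, applies uniform substitution errors, and returns
#' both the reads and a per-read truth table.
#'
#' Junction geometry per class (cut site `C`, 0-based):
#' * `uncut` - colinear reference sequence through `C`.
#' * `indel` - deletion of 1..`indel_del_max` bp at `C`, or an insertion of
#'   random (non-vector) nt.
#' * `large_deletion` - deletion in `(indel_del_max, large_del_max]` bp.
#' * `offtarget_translocation` - prey resumes at a planted off-target cut
#'   site (random orientation).
#' * `general_translocation` - prey resumes at a uniform random genomic
#'   position > 20 kb from the target cut and >= 500 bp from every planted
#'   off-target cut.
#' * `aav_buried` - a 20-500 nt vector fragment inserted at `C`, then the
#'   target resumes (fragments too long for the read to show the return read
#'   out as fusions).
#' * `aav_fusion` - the read runs from the bait into the vector with no
#'   return.
#'
#' AAV-side breakpoints fall inside an ITR interval with probability
#' `itr_junction_bias`, otherwise uniformly over the non-ITR remainder.
#'
#' @param genome A [build_toy_genome()] object.
#' @param vector A [build_aav_vector()] object; required iff any AAV class
#'   fraction is positive.
#' @param config A [sim_config()].
#' @return A `sim_library`: list with `reads` (tibble `read_id`, `sequence`,
#'   `quality`), `truth` (tibble `read_id`, `molecule_id`, `umi`,
#'   `true_class`, `prey_ref`, `prey_pos`, `prey_strand`, `del_size`,
#'   `ins_size`) and the `config`.
#' @export
simulate_library <- function(genome, vector = NULL, config = sim_config()) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  fr <- config$class_fractions
  aav_frac <- sum(fr[intersect(names(fr), c("aav_buried", "aav_fusion"))])
  if (aav_frac > 0 && is.null(vector)) {
    stop("vector map required when AAV class fractions are positive")
  }
  if (any(fr[intersect(names(fr), "offtarget_translocation")] > 0) &&
      nrow(genome$offtargets) == 0L) {
    stop("offtarget_translocation fraction > 0 but genome has no planted sites")
  }

  guide <- genome$guide
  chroms <- genome$chromosomes
  tchr <- chroms[[guide$chrom]]
  C <- guide$cut_site
  a0 <- guide$anchor
  payload_len <- config$read_length - config$umi_length - nchar(config$spacer)
  bait <- sub0(tchr, a0, C)          # anchor .. cut (exclusive)
  bait_len <- nchar(bait)
  prey_len <- payload_len - bait_len # bases available after the junction
  uncut_payload <- sub0(tchr, a0, a0 + payload_len)
  vseq <- if (!is.null(vector)) vector$sequence else NULL
  vlen <- if (!is.null(vector)) nchar(vseq) else 0L

  empty <- list(
    reads = tibble::tibble(read_id = character(0), sequence = character(0),
                           quality = character(0)),
    truth = tibble::tibble(read_id = character(0), molecule_id = integer(0),
                           umi = character(0), true_class = character(0),
                           prey_ref = character(0), prey_pos = integer(0),
                           prey_strand = character(0), del_size = integer(0),
                           ins_size = integer(0)),
    config = config
  )
  if (config$n_molecules == 0L) return(structure(empty, class = "sim_library"))

  withr::with_seed(config$seed, {
    n <- config$n_molecules
    classes <- sample(names(fr), n, replace = TRUE, prob = fr)

    payload <- character(n)
    prey_ref <- rep(NA_character_, n)
    prey_pos <- rep(NA_integer_, n)
    prey_strand <- rep(NA_character_, n)
    del_size <- rep(NA_integer_, n)
    ins_size <- rep(NA_integer_, n)

    itr_pos <- if (!is.null(vector)) {
      unlist(lapply(seq_len(nrow(vector$itr_intervals)), function(i) {
        seq(vector$itr_intervals$start[i], vector$itr_intervals$end[i] - 1L)
      }))
    } else integer(0)
    nonitr_pos <- if (!is.null(vector)) setdiff(seq(0L, vlen - 1L), itr_pos) else integer(0)

    sample_breakpoint <- function() {
      if (runif(1) < config$itr_junction_bias) {
        itr_pos[sample.int(length(itr_pos), 1L)]
      } else {
        nonitr_pos[sample.int(length(nonitr_pos), 1L)]
      }
    }
    # Sequence read 5'->3' starting at breakpoint b in orientation st.
    vector_run <- function(b, st, len) {
      if (st == "+") sub0(vseq, b, min(b + len, vlen))
      else dna_revcomp(sub0(vseq, max(b - len + 1L, 0L), b + 1L))
    }
    feasible_strand <- function(b, len) {
      ok <- c("+", "-")[c(b + len <= vlen, b - len + 1L >= 0L)]
      if (length(ok) == 0L) ok <- if (b < vlen / 2) "+" else "-"
      if (length(ok) == 2L) sample(ok, 1L) else ok
    }
    genome_run <- function(ch, p, st, len) {
      s <- chroms[[ch]]
      if (st == "+") sub0(s, p, min(p + len, nchar(s)))
      else dna_revcomp(sub0(s, max(p - len + 1L, 0L), p + 1L))
    }

    ot <- genome$offtargets
    clens <- nchar(chroms)

    for (i in seq_len(n)) {
      cl <- classes[i]
      if (cl == "uncut") {
        payload[i] <- uncut_payload
      } else if (cl == "indel") {
        if (runif(1) < config$indel_ins_frac) {
          k <- sample.int(config$indel_ins_max, 1L)
          ins <- random_dna(k)
          payload[i] <- substr(paste0(bait, ins, sub0(tchr, C, C + prey_len)),
                               1L, payload_len)
          ins_size[i] <- k
          prey_ref[i] <- guide$chrom; prey_pos[i] <- C; prey_strand[i] <- "+"
        } else {
          d <- sample.int(config$indel_del_max, 1L)
          payload[i] <- paste0(bait, sub0(tchr, C + d, C + d + prey_len))
          del_size[i] <- d
          prey_ref[i] <- guide$chrom; prey_pos[i] <- C + d; prey_strand[i] <- "+"
        }
      } else if (cl == "large_deletion") {
        d <- config$indel_del_max +
          sample.int(config$large_del_max - config$indel_del_max, 1L)
        payload[i] <- paste0(bait, sub0(tchr, C + d, C + d + prey_len))
        del_size[i] <- d
        prey_ref[i] <- guide$chrom; prey_pos[i] <- C + d; prey_strand[i] <- "+"
      } else if (cl == "offtarget_translocation") {
        j <- sample.int(nrow(ot), 1L)
        st <- sample(c("+", "-"), 1L)
        p <- ot$cut_site[j]
        payload[i] <- paste0(bait, genome_run(ot$chrom[j], p, st, prey_len))
        prey_ref[i] <- ot$chrom[j]; prey_pos[i] <- p; prey_strand[i] <- st
      } else if (cl == "general_translocation") {
        repeat {
          ch <- sample(names(chroms), 1L)
          st <- sample(c("+", "-"), 1L)
          p <- sample.int(clens[[ch]] - 400L, 1L) + 200L - 1L
          if (st == "+" && p + prey_len + 5L > clens[[ch]]) next
          if (st == "-" && p - prey_len - 5L < 0L) next
          if (ch == guide$chrom && abs(p - C) <= 20500L) next
          near_ot <- ot$chrom == ch & abs(ot$cut_site - p) < 500L
          if (any(near_ot)) next
          break
        }
        payload[i] <- paste0(bait, genome_run(ch, p, st, prey_len))
        prey_ref[i] <- ch; prey_pos[i] <- as.integer(p); prey_strand[i] <- st
      } else if (cl == "aav_buried") {
        L <- config$aav_frag_range[1] +
          sample.int(config$aav_frag_range[2] - config$aav_frag_range[1] + 1L, 1L) - 1L
        b <- sample_breakpoint()
        st <- feasible_strand(b, L)
        frag <- vector_run(b, st, L)
        payload[i] <- substr(paste0(bait, frag, sub0(tchr, C, C + prey_len)),
                             1L, payload_len)
        ins_size[i] <- nchar(frag)
        prey_ref[i] <- vector$name; prey_pos[i] <- as.integer(b); prey_strand[i] <- st
      } else { # aav_fusion
        b <- sample_breakpoint()
        st <- feasible_strand(b, prey_len)
        payload[i] <- paste0(bait, vector_run(b, st, prey_len))
        prey_ref[i] <- vector$name; prey_pos[i] <- as.integer(b); prey_strand[i] <- st
      }
    }

    # UMIs and PCR duplication.
    umi_mat <- matrix(sample(DNA_BASES, n * config$umi_length, replace = TRUE),
                      nrow = n)
    umis <- do.call(paste0, as.data.frame(umi_mat))
    p_geo <- 1 / (1 + config$pcr_duplication_rate)
    n_reads_per_mol <- 1L + rgeom(n, p_geo)

    mol_of_read <- rep.int(seq_len(n), n_reads_per_mol)
    rep_idx <- sequence(n_reads_per_mol)
    read_id <- sprintf("M%06d_R%02d", mol_of_read, rep_idx)
    seqs <- paste0(umis[mol_of_read], config$spacer, payload[mol_of_read])

    # Uniform substitution errors across the whole read (UMI included).
    if (config$error_rate > 0) {
      lens <- nchar(seqs)
      n_err <- rbinom(length(seqs), lens, config$error_rate)
      for (r in which(n_err > 0L)) {
        pos <- sample.int(lens[r], n_err[r])
        for (p in pos) {
          old <- substr(seqs[r], p, p)
          substr(seqs[r], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
        }
      }
    }

    reads <- tibble::tibble(
      read_id = read_id,
      sequence = seqs,
      quality = strrep("I", nchar(seqs))
    )
    truth <- tibble::tibble(
      read_id = read_id,
      molecule_id = mol_of_read,
      umi = umis[mol_of_read],
      true_class = classes[mol_of_read],
      prey_ref = prey_ref[mol_of_read],
      prey_pos = prey_pos[mol_of_read],
      prey_strand = prey_strand[mol_of_read],
      del_size = del_size[mol_of_read],
      ins_size = ins_size[mol_of_read]
    )
    structure(list(reads = reads, truth = truth, config = config),
              class = "sim_library")
  })
}

#' @export
print.sim_library <- function(x, ...) {
  cat("<sim_library> ", nrow(x$reads), " reads from ",
      length(unique(x$truth$molecule_id)), " molecules\n", sep = "")
  print(table(x$truth$true_class[!duplicated(x$truth$molecule_id)]))
  invisible(x)
}

#' Simulate an amplicon deep-sequencing pool
#'
#' Generates full-length amplicon reads, a configured fraction of which carry
#' an insertion or deletion at the cut site, for exercising
#' [amplicon_indel_rate()].
#'
#' @param reference Amplicon reference sequence (character).
#' @param cut 0-based cut position within the amplicon.
#' @param n_reads Number of reads.
#' @param indel_fraction Fraction of reads carrying an indel at the cut.
#' @param seed RNG seed.
#' @param error_rate Per-base substitution probability.
#' @param del_sizes,ins_sizes Candidate indel sizes.
#' @param ins_frac Fraction of indel reads that are insertions.
#' @return Tibble with `read_id`, `sequence`, `quality` and truth column
#'   `has_indel`.
#' @export
simulate_amplicon_reads <- function(reference, cut, n_reads,
                                    indel_fraction, seed = 1L,
                                    error_rate = 0,
                                    del_sizes = 1:10, ins_sizes = 1:6,
                                    ins_frac = 0.3) {
  stopifnot(indel_fraction >= 0, indel_fraction <= 1, cut > 10,
            cut < nchar(reference) - 10)
  withr::with_seed(seed, {
    has_indel <- runif(n_reads) < indel_fraction
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      if (!has_indel[i]) {
        seqs[i] <- reference
      } else if (runif(1) < ins_frac) {
        k <- ins_sizes[sample.int(length(ins_sizes), 1L)]
        seqs[i] <- paste0(sub0(reference, 0L, cut), random_dna(k),
                          sub0(reference, cut, nchar(reference)))
      } else {
        k <- del_sizes[sample.int(length(del_sizes), 1L)]
        seqs[i] <- paste0(sub0(reference, 0L, cut),
                          sub0(reference, cut + k, nchar(reference)))
      }
      if (error_rate > 0) {
        ne <- rbinom(1L, nchar(seqs[i]), error_rate)
        if (ne > 0L) {
          for (p in sample.int(nchar(seqs[i]), ne)) {
            old <- substr(seqs[i], p, p)
            substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
          }
        }
      }
    }
    tibble::tibble(
      read_id = sprintf("A%06d", seq_len(n_reads)),
      sequence = seqs,
      quality = strrep("I", nchar(seqs)),
      has_indel = has_indel
    )
  })
}
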