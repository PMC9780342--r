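# Shared fixtures, built once per test run and memoized. All fixtures are
# generated in code under fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fix_genome <- function() {
  fixture("genome", function() build_toy_genome(seed = 1, mismatch_counts = c(2, 3, 4)))
}

fix_vector <- function() {
  fixture("vector", function() build_aav_vector(seed = 1))
}

fix_gindex <- function() {
  fixture("gindex", function() genome_index(fix_genome()))
}

fix_vindex <- function() {
  fixture("vindex", function() genome_index(fix_vector()))
}

# Small mixed library, error-free, with PCR duplicates.
fix_small_sim <- function() {
  fixture("small_sim", function() {
    simulate_library(fix_genome(), fix_vector(),
                     sim_config(n_molecules = 1500, error_rate = 0,
                                pcr_duplication_rate = 0.5, seed = 3))
  })
}

fix_small_calls <- function() {
  fixture("small_calls", function() {
    sim <- fix_small_sim()
    call_junctions(sim$reads, fix_genome(), fix_vector())
  })
}

# Default-mixture library at study scale (20k molecules, substitution
# errors on), plus an error-free twin for classifier truth recovery.
fix_big_sim_default <- function() {
  fixture("big_sim_default", function() {
    simulate_library(fix_genome(), fix_vector(), sim_config(seed = 7))
  })
}

fix_big_sim_errorfree <- function() {
  fixture("big_sim_errorfree", function() {
    simulate_library(fix_genome(), fix_vector(),
                     sim_config(seed = 7, error_rate = 0))
  })
}

fix_big_calls_errorfree <- function() {
  fixture("big_calls_errorfree", function() {
    sim <- fix_big_sim_errorfree()
    call_junctions(sim$reads, fix_genome(), fix_vector())
  })
}

# Map a truth class to the junction caller's class space (the two AAV
# integration types are combined for analysis).
truth_to_called <- function(true_class) {
  map <- c(uncut = "uncut", indel = "indel",
           large_deletion = "large_deletion",
           offtarget_translocation = "offtarget_translocation",
           general_translocation = "general_translocation",
           aav_buried = "aav_integration", aav_fusion = "aav_integration")
  unname(map[true_class])
}

# Truth rows matched to called molecules via each molecule's first read.
truth_for_calls <- function(calls, sim) {
  rep_read <- vapply(calls$read_ids, `[`, character(1), 1L)
  sim$truth[match(rep_read, sim$truth$read_id), ]
}

# Independent Smith-Waterman local alignment oracle over a reference set:
# best local score across all references and both strands, using the same
# scoring scheme as the seed-and-extend aligner (match +1, mismatch -4,
# gap open 6, gap extend 1).
sw_oracle_score <- function(query, refs) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                  baseOnly = TRUE)
  best <- 0
  for (ref in refs) {
    for (q in c(query, dna_revcomp(query))) {
      sc <- Biostrings::pairwiseAlignment(
        pattern = q, subject = ref, type = "local",
        substitutionMatrix = mat, gapOpening = 6, gapExtension = 1,
        scoreOnly = TRUE
      )
      best <- max(best, sc)
    }
  }
  best
}
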