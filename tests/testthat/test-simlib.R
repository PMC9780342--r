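test_that("toy genome plants off-targets with exact mismatch counts", {
  g <- fix_genome()
  guide_chars <- strsplit(g$guide$site_seq, "")[[1]]
  # independent character-by-character recount
  for (i in seq_len(nrow(g$offtargets))) {
    ot <- g$offtargets[i, ]
    w <- substr(g$chromosomes[[ot$chrom]], ot$start + 1, ot$start + 23)
    if (ot$strand == "-") w <- dna_revcomp(w)
    expect_identical(sum(strsplit(w, "")[[1]] != guide_chars),
                     as.integer(ot$n_mismatches))
  }
  expect_identical(g$offtargets$n_mismatches, c(2L, 3L, 4L))
})

test_that("toy genome respects its structural invariants", {
  g <- fix_genome()
  expect_true(all(grepl("^[ACGT]+$", g$chromosomes)))
  expect_gte(length(g$chromosomes), 2L)
  expect_true(all(nchar(g$chromosomes) >= 10000L))
  # on-target protospacer+PAM occurs exactly once genome-wide
  exact <- enumerate_offtargets_bruteforce(g, g$guide, max_mm = 0)
  expect_identical(nrow(exact), 1L)
  expect_identical(exact$start, g$guide$start)
  # no background lookalikes below the similarity bound
  all8 <- enumerate_offtargets_bruteforce(g, g$guide, max_mm = 8)
  expect_identical(nrow(all8), 1L + nrow(g$offtargets))
})

test_that("toy genome construction is deterministic and validates input", {
  g1 <- build_toy_genome(seed = 5, mismatch_counts = c(3, 5))
  g2 <- build_toy_genome(seed = 5, mismatch_counts = c(3, 5))
  expect_identical(g1$chromosomes, g2$chromosomes)
  expect_identical(g1$offtargets, g2$offtargets)
  expect_error(build_toy_genome(mismatch_counts = c(0)), "uniqueness")
  expect_error(build_toy_genome(mismatch_counts = c(2, 9)), "rejected")
  expect_error(build_toy_genome(mismatch_counts = c(2, 3),
                                n_offtargets = 3))
})

test_that("AAV vector map has terminal inverted repeats", {
  v <- fix_vector()
  iv <- v$itr_intervals
  expect_identical(nrow(iv), 2L)
  expect_true(all(iv$end - iv$start >= 100L))
  expect_identical(iv$start[1], 0L)
  expect_identical(iv$end[2], nchar(v$sequence))
  expect_lt(iv$end[1], iv$start[2])  # non-overlapping, at the two ends
  left <- substr(v$sequence, iv$start[1] + 1, iv$end[1])
  right <- substr(v$sequence, iv$start[2] + 1, iv$end[2])
  expect_identical(right, dna_revcomp(left))
})

test_that("simulator handles degenerate mixtures and bad configs", {
  g <- fix_genome()
  cfg <- sim_config(class_fractions = c(uncut = 1), n_molecules = 100,
                    error_rate = 0, pcr_duplication_rate = 0, seed = 2)
  sim <- simulate_library(g, NULL, cfg)
  expect_identical(nrow(sim$reads), 100L)
  expect_true(all(sim$truth$true_class == "uncut"))
  # all uncut payloads are colinear reference past the cut site
  payload <- substr(sim$reads$sequence[1], 12 + 6 + 1, 250)
  a0 <- g$guide$anchor
  expect_identical(payload,
                   substr(g$chromosomes[[g$guide$chrom]], a0 + 1,
                          a0 + nchar(payload)))

  empty <- simulate_library(g, NULL, sim_config(
    class_fractions = c(uncut = 1), n_molecules = 0, seed = 2))
  expect_identical(nrow(empty$reads), 0L)
  expect_identical(nrow(empty$truth), 0L)

  expect_error(sim_config(class_fractions = c(uncut = 0.5, indel = 0.4)),
               "sum to 1")
  expect_error(sim_config(n_molecules = -1))
  expect_error(simulate_library(g, NULL, sim_config(
    class_fractions = c(uncut = 0.5, aav_fusion = 0.5))), "vector")
})

test_that("simulated libraries are byte-identical under a fixed seed", {
  g <- fix_genome()
  v <- fix_vector()
  cfg <- sim_config(n_molecules = 300, seed = 9)
  s1 <- simulate_library(g, v, cfg)
  s2 <- simulate_library(g, v, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("PCR duplicates share molecule id, UMI and junction", {
  sim <- fix_small_sim()
  per_mol <- dplyr::summarise(
    dplyr::group_by(sim$truth, molecule_id),
    n_umi = dplyr::n_distinct(umi),
    n_class = dplyr::n_distinct(true_class),
    n_prey = dplyr::n_distinct(prey_pos, na.rm = TRUE)
  )
  expect_true(all(per_mol$n_umi == 1L))
  expect_true(all(per_mol$n_class == 1L))
  expect_true(all(per_mol$n_prey <= 1L))
})

test_that("truth labels are re-derivable from truth coordinates", {
  g <- fix_genome()
  v <- fix_vector()
  sim <- fix_small_sim()
  tm <- sim$truth[!duplicated(sim$truth$molecule_id), ]
  C <- g$guide$cut_site
  rederived <- character(nrow(tm))
  for (i in seq_len(nrow(tm))) {
    r <- tm[i, ]
    rederived[i] <- if (is.na(r$prey_ref)) {
      "uncut"
    } else if (r$prey_ref == "AAV") {
      r$true_class  # buried vs fusion distinguished by construction
    } else if ((r$prey_ref == g$guide$chrom && r$prey_strand == "+" &&
                  abs(r$prey_pos - C) <= 20000 && !is.na(r$del_size) &&
                  r$del_size <= 200) ||
               (!is.na(r$ins_size) && r$prey_ref != "AAV")) {
      "indel"
    } else if (r$prey_ref == g$guide$chrom && r$prey_strand == "+" &&
               abs(r$prey_pos - C) <= 20000) {
      "large_deletion"
    } else if (any(g$offtargets$chrom == r$prey_ref &
                     abs(g$offtargets$cut_site - r$prey_pos) <= 100)) {
      "offtarget_translocation"
    } else {
      "general_translocation"
    }
  }
  expect_identical(rederived, tm$true_class)
})

test_that("molecule classes follow the configured multinomial mixture", {
  sim <- fix_big_sim_default()
  fr <- sim$config$class_fractions
  tm <- sim$truth[!duplicated(sim$truth$molecule_id), ]
  obs <- table(factor(tm$true_class, levels = names(fr)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = fr))
  expect_gt(gof$p.value, 0.001)
})

test_that("the documented six-class example mixture is recovered end to end", {
  g <- fix_genome()
  v <- fix_vector()
  fr <- c(indel = 0.10, offtarget_translocation = 0.005,
          general_translocation = 0.005, aav_fusion = 0.03,
          aav_buried = 0.03, uncut = 0.83)
  n <- 4000
  sim <- simulate_library(g, v, sim_config(class_fractions = fr,
                                           n_molecules = n, seed = 13))
  calls <- call_junctions(sim$reads, g, v)
  called <- table(factor(calls$class, levels = c(
    "uncut", "indel", "large_deletion", "offtarget_translocation",
    "general_translocation", "aav_integration", "ambiguous")))
  got <- c(indel = called[["indel"]],
           offtarget_translocation = called[["offtarget_translocation"]],
           general_translocation = called[["general_translocation"]],
           aav = called[["aav_integration"]],
           uncut = called[["uncut"]])
  planted <- c(fr[c("indel", "offtarget_translocation",
                    "general_translocation")],
               aav = unname(fr[["aav_fusion"]] + fr[["aav_buried"]]),
               uncut = fr[["uncut"]])
  denom <- sum(called) - called[["ambiguous"]]
  for (k in seq_along(planted)) {
    se <- sqrt(planted[k] * (1 - planted[k]) / n)
    expect_lt(abs(got[k] / denom - planted[k]), 3 * se + 1e-9)
  }
})
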