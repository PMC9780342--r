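test_that("hotspot binning thresholds and merging behave as declared", {
  mk <- function(pos) tibble::tibble(chrom = "chr2", pos = pos)

  # 5 junctions within one 100-bp span
  one <- find_hotspots(mk(c(1000, 1010, 1020, 1040, 1060)), min_support = 3)
  expect_identical(nrow(one), 1L)
  expect_identical(one$support, 5L)

  # 10 junctions scattered >= 1 kb apart
  none <- find_hotspots(mk(seq(1000, 10000, by = 1000)), min_support = 3)
  expect_identical(nrow(none), 0L)

  # two clusters 120 bp apart merge after offset smoothing
  merged <- find_hotspots(mk(c(995, 1000, 1005, 1115, 1120, 1125)),
                          min_support = 3)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$support, 6L)
})

test_that("guide matching scans both strands with the joint mismatch bound", {
  g <- fix_genome()
  # exact on-target 23-mer
  win <- paste0(strrep("T", 30), g$guide$site_seq, strrep("T", 30))
  m <- match_guide(win, g$guide)
  expect_identical(m$n_mismatches, 0L)
  expect_identical(m$offset, 30L)
  expect_identical(m$strand, "+")

  # planted 4-mismatch site recovered at its planted position
  ot <- g$offtargets[g$offtargets$n_mismatches == 4L, ]
  win4 <- substr(g$chromosomes[[ot$chrom]], ot$start + 1 - 30, ot$start + 23 + 30)
  m4 <- match_guide(win4, g$guide)
  expect_identical(m4$n_mismatches, 4L)
  expect_identical(m4$offset, 30L)
  expect_identical(m4$strand, ot$strand)

  # a 9-mismatch lookalike is rejected
  site <- strsplit(g$guide$site_seq, "")[[1]]
  site[c(1, 3, 5, 7, 9, 11, 13, 15, 17)] <-
    vapply(site[c(1, 3, 5, 7, 9, 11, 13, 15, 17)],
           function(b) setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  win9 <- paste0(strrep("T", 30), paste(site, collapse = ""), strrep("T", 30))
  expect_identical(nrow(match_guide(win9, g$guide)), 0L)

  expect_error(match_guide("ACGTACGT", g$guide), "23")
})

test_that("brute-force enumeration is exact and strand-symmetric", {
  g <- fix_genome()
  sites <- enumerate_offtargets_bruteforce(g, g$guide, max_mm = 8)
  expect_identical(nrow(sites), 4L)  # on-target + three planted
  expect_identical(sites$n_mismatches, c(0L, 2L, 3L, 4L))

  only_target <- enumerate_offtargets_bruteforce(g, g$guide, max_mm = 0)
  expect_identical(nrow(only_target), 1L)

  # reverse-complementing the genome mirrors every site
  rc <- setNames(dna_revcomp(g$chromosomes), names(g$chromosomes))
  rc_sites <- enumerate_offtargets_bruteforce(rc, g$guide, max_mm = 8)
  expect_identical(nrow(rc_sites), nrow(sites))
  lens <- nchar(g$chromosomes)
  mirrored <- tibble::tibble(
    chrom = sites$chrom,
    start = as.integer(lens[sites$chrom] - sites$start - 23L),
    strand = ifelse(sites$strand == "+", "-", "+"),
    n_mismatches = sites$n_mismatches
  )
  expect_setequal(
    paste(rc_sites$chrom, rc_sites$start, rc_sites$strand, rc_sites$n_mismatches),
    paste(mirrored$chrom, mirrored$start, mirrored$strand, mirrored$n_mismatches)
  )
})

test_that("cut-site confirmation uses the median with monotone tolerance", {
  expect_true(confirm_cut_site(1000, c(998, 1000, 1001, 1002)))
  expect_false(confirm_cut_site(1000, c(1050, 1051, 1049)))
  # widening the tolerance never turns a pass into a fail
  withr::with_seed(41, {
    for (i in 1:20) {
      cut <- sample(10000, 1)
      jx <- cut + sample(-6:6, 5, replace = TRUE)
      if (confirm_cut_site(cut, jx, tol = 3)) {
        expect_true(confirm_cut_site(cut, jx, tol = 10))
      }
    }
  })
})

test_that("discovery finds planted sites and only guide-similar hotspots", {
  g <- fix_genome()
  # >= 5 error-free translocation molecules per planted site, plus a decoy
  # cluster at a scrubbed (guide-dissimilar) position
  jx <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(nrow(g$offtargets)), function(i) {
      tibble::tibble(
        class = "general_translocation",
        prey_ref = g$offtargets$chrom[i],
        prey_pos = g$offtargets$cut_site[i] + c(-1L, 0L, 0L, 1L, 0L, 2L),
        prey_strand = "+"
      )
    }),
    tibble::tibble(class = "general_translocation", prey_ref = "chr1",
                   prey_pos = rep(5000L, 8), prey_strand = "+")
  )
  found <- discover_offtargets(jx, g)
  expect_identical(nrow(found), nrow(g$offtargets))
  expect_setequal(paste(found$chrom, found$start, found$strand),
                  paste(g$offtargets$chrom, g$offtargets$start,
                        g$offtargets$strand))
  expect_identical(
    found$n_mismatches[order(found$start)],
    g$offtargets$n_mismatches[order(g$offtargets$start)]
  )

  # junctions clustered away from the matched cut site are rejected
  shifted <- dplyr::mutate(jx[1:6, ], prey_pos = prey_pos + 50L)
  expect_identical(nrow(discover_offtargets(shifted, g)), 0L)
})

test_that("amplicon indel rates follow the counting definition", {
  ref <- withr::with_seed(51, random_dna(300))
  reads <- simulate_amplicon_reads(ref, cut = 150, n_reads = 100,
                                   indel_fraction = 0.07, seed = 5)
  r <- amplicon_indel_rate(reads, ref, cut = 150)
  expect_identical(r$n_indel, sum(reads$has_indel))
  expect_equal(r$indel_rate, 100 * sum(reads$has_indel) / 100)
  expect_false(r$low_coverage)

  # all exact reads: 0%
  exact <- dplyr::mutate(reads, sequence = ref)
  expect_equal(amplicon_indel_rate(exact, ref, cut = 150)$indel_rate, 0)

  # low-coverage flag below 100 aligned reads
  expect_true(amplicon_indel_rate(reads[1:20, ], ref, cut = 150)$low_coverage)

  # simulation recovery at n = 5000 with sequencing errors
  big <- simulate_amplicon_reads(ref, cut = 150, n_reads = 5000,
                                 indel_fraction = 0.074, seed = 6,
                                 error_rate = 0.001)
  rb <- amplicon_indel_rate(big, ref, cut = 150)
  se <- 100 * sqrt(0.074 * (1 - 0.074) / 5000)
  expect_lt(abs(rb$indel_rate - 7.4), 3 * se)
})
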