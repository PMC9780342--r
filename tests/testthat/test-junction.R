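make_payload <- function(g, prey = NULL, insert = NULL, len = 232) {
  ref <- g$chromosomes[[g$guide$chrom]]
  bait <- substr(ref, g$guide$anchor + 1, g$guide$cut_site)
  C <- g$guide$cut_site
  resume <- substr(ref, C + 1, C + len)  # colinear continuation
  body <- paste0(bait, insert %||% "", prey %||% resume)
  substr(body, 1, len)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("junction location covers the colinear, deletion and fusion cases", {
  g <- fix_genome()
  v <- fix_vector()
  gindex <- fix_gindex()
  vindex <- fix_vindex()
  ref <- g$chromosomes[[g$guide$chrom]]
  C <- g$guide$cut_site

  # fully colinear payload through the cut: no junction (uncut candidate)
  raw <- locate_junction(make_payload(g), g$guide, gindex, vindex)
  expect_identical(raw$status, "uncut")

  # payload colinear to the cut, then resuming 57 bp downstream
  del57 <- make_payload(g, prey = substr(ref, C + 57 + 1, C + 57 + 160))
  raw <- locate_junction(del57, g$guide, gindex, vindex)
  expect_identical(raw$status, "junction")
  cls <- classify_junction(raw, g$guide, g$offtargets)
  expect_identical(cls$class, "indel")
  expect_identical(cls$deletion_size, 57L)

  # payload running from the bait into the vector with no return
  fus <- make_payload(g, prey = substr(v$sequence, 3001, 3160))
  raw <- locate_junction(fus, g$guide, gindex, vindex)
  expect_identical(raw$status, "junction")
  expect_true(raw$prey_is_vector)
  expect_identical(raw$prey_ref, "AAV")
  # up to 1 bp of chance microhomology at the breakpoint; bait and prey
  # coordinates must shift together
  expect_lte(abs(raw$prey_pos - 3000L), 1L)
  expect_identical(raw$prey_pos - 3000L, raw$bait_end - g$guide$cut_site)

  # anchor mismatch: wrong-locus read is dropped
  bad <- paste0(strrep("T", 20), substr(make_payload(g), 21, 232))
  expect_identical(locate_junction(bad, g$guide, gindex, vindex)$status,
                   "drop_anchor")
})

test_that("classification follows the decision cascade and its windows", {
  g <- fix_genome()
  v <- fix_vector()
  gindex <- fix_gindex()
  vindex <- fix_vindex()
  ref2 <- g$chromosomes[["chr2"]]
  C <- g$guide$cut_site
  ot <- g$offtargets[1, ]  # chr2 site

  # prey on a different chromosome with no off-target list: general
  far <- make_payload(g, prey = substr(ref2, 40001, 40160))
  raw <- locate_junction(far, g$guide, gindex, vindex)
  cls0 <- classify_junction(raw, g$guide, g$offtargets[0, ])
  expect_identical(cls0$class, "general_translocation")

  # 80 bp from a supplied off-target cut: off-target; 150 bp away: general
  p80 <- make_payload(g, prey = substr(ref2, ot$cut_site + 80 + 1,
                                       ot$cut_site + 80 + 160))
  r80 <- locate_junction(p80, g$guide, gindex, vindex)
  expect_identical(classify_junction(r80, g$guide, g$offtargets)$class,
                   "offtarget_translocation")
  p150 <- make_payload(g, prey = substr(ref2, ot$cut_site + 150 + 1,
                                        ot$cut_site + 150 + 160))
  r150 <- locate_junction(p150, g$guide, gindex, vindex)
  expect_identical(classify_junction(r150, g$guide, g$offtargets)$class,
                   "general_translocation")

  # deletion threshold D_large = 200: 3 nt -> indel, 5000 nt -> large deletion
  ref1 <- g$chromosomes[[g$guide$chrom]]
  d3 <- locate_junction(
    make_payload(g, prey = substr(ref1, C + 3 + 1, C + 3 + 160)),
    g$guide, gindex, vindex)
  expect_identical(classify_junction(d3, g$guide, g$offtargets)$class, "indel")
  d5k <- locate_junction(
    make_payload(g, prey = substr(ref1, C + 5000 + 1, C + 5000 + 160)),
    g$guide, gindex, vindex)
  cl5k <- classify_junction(d5k, g$guide, g$offtargets)
  expect_identical(cl5k$class, "large_deletion")
  expect_identical(cl5k$deletion_size, 5000L)

  # 60-nt inserted segment aligning to the vector ITR: buried AAV
  itr_seg <- substr(v$sequence, 31, 90)
  bur <- locate_junction(make_payload(g, insert = itr_seg),
                         g$guide, gindex, vindex)
  clb <- classify_junction(bur, g$guide, g$offtargets)
  expect_identical(clb$class, "aav_integration")
  expect_identical(clb$aav_type, "buried")
  expect_lte(abs(clb$prey_pos - 30L), 3L)  # breakpoint microhomology
  expect_true(clb$prey_pos >= 0 && clb$prey_pos < 145)

  # an inversion inside the bait window is a general translocation
  inv <- locate_junction(
    make_payload(g, prey = dna_revcomp(substr(ref1, C + 4841, C + 5000))),
    g$guide, gindex, vindex)
  expect_identical(inv$prey_strand, "-")
  expect_identical(classify_junction(inv, g$guide, g$offtargets)$class,
                   "general_translocation")
})

test_that("every deduplicated molecule gets exactly one class", {
  calls <- fix_small_calls()
  expect_true(all(calls$class %in% c(
    "uncut", "indel", "large_deletion", "offtarget_translocation",
    "general_translocation", "aav_integration", "ambiguous")))
  s <- summarize_calls(calls)
  expect_identical(sum(s$counts$n), nrow(calls))
  # local-repair classes carry prey inside the bait window; deletion sizes
  # appear exactly on deletion classes
  loc <- calls$class %in% c("indel", "large_deletion")
  expect_true(all(abs(calls$prey_pos[loc] - fix_genome()$guide$cut_site) <=
                    20000))
  expect_true(all(!is.na(calls$deletion_size[loc])))
  expect_true(all(is.na(calls$deletion_size[calls$class %in% c(
    "uncut", "general_translocation", "offtarget_translocation",
    "aav_integration")])))
  expect_true(all(calls$aav_type[calls$class == "aav_integration"] %in%
                    c("buried", "fusion")))
  expect_true(all(calls$aav_type[calls$class != "aav_integration"] == "none"))
})

test_that("classification recovers truth on an error-free library", {
  calls <- fix_small_calls()
  tr <- truth_for_calls(calls, fix_small_sim())
  agree <- calls$class == truth_to_called(tr$true_class)
  expect_gte(mean(agree), 0.995)
})

test_that("widening the off-target window only moves calls into the class", {
  calls <- fix_small_calls()
  g <- fix_genome()
  for (w in c(50L, 100L, 200L, 400L)) {
    narrow <- pemseqr:::reclassify_with_offtargets(
      calls, g$offtargets, pemseqr:::junction_opts(ot_window = w))
    wide <- pemseqr:::reclassify_with_offtargets(
      calls, g$offtargets, pemseqr:::junction_opts(ot_window = w + 100L))
    from_ot <- narrow$class == "offtarget_translocation"
    expect_true(all(wide$class[from_ot] == "offtarget_translocation"))
  }
})

test_that("removing genome references from the prey search only adds AAV calls", {
  g <- fix_genome()
  # vector whose payload embeds a genomic segment: with the genome indexed
  # the prey maps genome-first; without it, the same read becomes an AAV call
  shared <- substr(g$chromosomes[["chr2"]], 12001, 12160)
  vseq <- fix_vector()$sequence
  v2 <- fix_vector()
  v2$sequence <- paste0(substr(vseq, 1, 1000), shared,
                        substr(vseq, 1001 + nchar(shared), nchar(vseq)))
  vindex2 <- genome_index(v2)
  gindex_full <- fix_gindex()
  gindex_target_only <- genome_index(g$chromosomes["chr1"])

  payload <- make_payload(g, prey = shared)
  with_genome <- classify_junction(
    locate_junction(payload, g$guide, gindex_full, vindex2),
    g$guide, g$offtargets)
  without_genome <- classify_junction(
    locate_junction(payload, g$guide, gindex_target_only, vindex2),
    g$guide, g$offtargets)
  expect_identical(with_genome$class, "general_translocation")
  expect_identical(without_genome$class, "aav_integration")
})
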