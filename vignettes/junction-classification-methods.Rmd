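---
title: "Methods: junction classification for primer-anchored editing-outcome sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction classification for primer-anchored editing-outcome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

One-sided anchored junction sequencing interrogates a single CRISPR target
locus with a nested locus-specific primer placed a fixed distance upstream
of the SpCas9 cut site. Every sequenced molecule therefore starts with the
same *bait*: reference sequence running from the primer anchor toward the
cut. What follows the junction — the *prey* — identifies the repair
outcome:

* colinear reference past the cut → **uncut** allele;
* a deletion or small insertion at the cut → **indel**;
* a deletion larger than the indel boundary but still inside the local
  window → **large deletion**;
* resumption at a guide-similar site's cut → **off-target translocation**;
* resumption anywhere else in the genome (including inversions) →
  **general translocation**;
* vector sequence, either as an inserted fragment flanked by target
  sequence (**buried** AAV integration) or running to the end of the read
  (**fusion**).

Because the molecule — not the read — is the unit of biology, an
adapter-borne UMI tags each original fragment and PCR duplicates are
collapsed before counting.

`pemseqr` implements this model end to end together with a synthetic
generator that emits truth-labelled libraries with exactly this structure,
so the classifier can be validated against planted ground truth.

## Read layout and the synthetic generator

The digital read layout is a package decision (the wet-lab protocol does
not constrain it): single-end reads of 250 nt, `[12-nt UMI][ACGCGT
spacer][payload]`, payload beginning at the nested-primer anchor 60 bp
upstream of the protospacer. A 12-nt UMI makes duplicate collisions rare at
bench scale while keeping reads short; the spacer is matched with ≤1
mismatch so adapter identification itself is error-tolerant.

The toy genome (two chromosomes, 60 kb + 50 kb) carries the target
protospacer+PAM exactly once, plus planted off-target sites differing from
the 23-mer by exact, verified mismatch counts. Chromosomes are long enough
that the ±20 kb bait window can be exercised on the target chromosome
while cross-chromosome translocations exist. Two generation details
matter:

* **Lookalike scrubbing.** A random 110-kb genome contains, in
  expectation, dozens of chance 23-mers within 8 mismatches of the guide.
  The builder enumerates them exhaustively and mutates them away, so the
  ≤8-mismatch neighbourhood of the guide contains *exactly* the target and
  the planted sites; discovery can then be compared 1:1 against the
  enumeration oracle. When a chance lookalike overlaps a protected
  footprint and cannot be edited, the whole draw is retried from a derived
  child seed — deterministically, so a given seed always produces the same
  genome.
* **The vector.** The 4.7-kb synthetic AAV carries two 145-bp terminal
  repeats, the right one the reverse complement of the left (the defining
  property of ITRs; no palindromic secondary structure is modelled). A
  fragment wholly inside an ITR maps equally well to both copies; ties are
  broken deterministically and both positions are ITR, so ITR statistics
  are unaffected.

Class geometry at the cut site `C`: indel deletions are uniform on
1–200 bp and insertions (30% of indels) are 1–20 nt of untemplated
sequence; large deletions are uniform on 201 bp–20 kb; off-target
translocation preys resume exactly at a planted cut in random orientation;
general-translocation preys are uniform over positions >20 kb from the
target cut and ≥500 bp from planted cuts (so truth labels are unambiguous
under the classifier's own windows); buried AAV fragments are uniform
20–500 nt; AAV-side breakpoints fall inside an ITR with probability 0.6
by default, otherwise uniformly over the non-ITR remainder — so the
planted ITR fraction is the bias parameter itself.

The default mixture is 82% uncut, 10% indel, 1% large deletion, 0.5%
off-target and 0.5% general translocation, and 3% + 3% AAV capture —
roughly the regime of an efficiently edited in vivo sample with heavy
vector exposure, and covering all seven classes so classifier validation
exercises every branch. PCR duplication is geometric with mean 1 duplicate
per molecule; sequencing noise is substitution-only at 0.1% per base
(indel errors are excluded deliberately, so every classification edge case
in testing is attributable to junction structure rather than to read
noise).

Buried fragments longer than ~135 nt leave no room in a 250-nt read for
the genomic return segment; such molecules read out as fusions. The two
AAV types are combined for all rate reporting, so this affects the subtype
annotation only.

## Alignment

Prey segments are mapped with a self-contained seed-and-extend local
aligner: exact 20-bp seeds on both strands (the seed length standard
short-read mappers default to), per-diagonal ungapped extension solved
exactly as a maximum-scoring subarray, and affine-gap chaining of colinear
segments across diagonals. Scoring is match +1, mismatch −4, and a gap of
length L costs 6 + L. For substitution-only differences — the only kind
the generator emits — the per-diagonal scan *is* the Smith–Waterman local
optimum, which is why agreement with an exhaustive `pairwiseAlignment`
oracle under identical scoring is a tested invariant rather than an
aspiration. `min_score = 30` means a clean hit needs ~30 aligned
nucleotides; short inserted segments are matched against the vector with a
threshold of `min(30, length − 5)` so a 20-nt fragment needs a
near-perfect match — conservative against spurious vector calls.

The genome and vector are indexed together per reference set; references
are concatenated with `N` separators which can never match, so a single
k-mer table serves all chromosomes and extension cannot run across a
boundary.

## Junction location and microhomology

The bait is extended colinearly from the anchor, tolerating isolated
substitutions (a mismatch with fewer than 3 mismatches among the next 5
positions) so 0.1% sequencing noise does not fragment the bait. The first
sustained divergence is the junction; the remainder (≥20 nt required,
shorter divergent tails are counted `ambiguous` and excluded from every
denominator) is remapped genome-first, then vector — the declared remap
order, which also means a prey matching both is attributed to the genome.

A junction is only defined up to the stretch over which bait and prey
references agree. This matters precisely for the interesting reads:
translocations to guide-similar off-targets can carry several bases of
genuine homology on either side of the cut. Two mechanisms handle it:

* positions the bait extension tolerated as "isolated errors" but that
  match the prey reference are given back to the prey (they were prey all
  along), never crossing a position that matched the bait reference
  cleanly;
* the residual two-sided ambiguity is reported per call as a `homology`
  length, and the off-target cut-site confirmation resolves each junction
  to the point of its homology interval closest to the candidate cut
  before taking the median.

Without the second step, plus-orientation preys at sites whose PAM-
proximal bases match the target systematically report junctions a few
bases right of the cut and sound discovery fails its own ±3 bp rule; with
it, the median junction of a genuine site sits on the cut and the rule
works as stated.

## Classification windows and defaults

The decision cascade, in order: no junction → uncut (requires ≥10 colinear
nt past the cut; shorter reads are ambiguous); inserted segment aligning
to the vector → buried AAV; prey aligning to the vector → fusion AAV; prey
inside the ±20 kb bait window on the plus strand → indel or large
deletion by the deletion-size boundary; prey within ±100 bp of an
off-target cut → off-target translocation; anything else — other
chromosome, >20 kb away, or an inversion inside the window — general
translocation.

Parameters, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `bait_window` | ±20,000 bp | local-repair vs translocation boundary |
| `ot_window` | ±100 bp | off-target junction window |
| `d_large` | 200 bp | indel vs large-deletion boundary; the size cut is a package decision, configurable and echoed in run metadata |
| `min_score` | 30 | minimum prey alignment score |
| `max_small_insertion` | 50 nt | insertions up to this length with no vector match count as indels; longer unmatched inserts are ambiguous |
| cut-site convention | 17 | blunt cut between protospacer positions 17/18, 3 bp 5′ of the PAM (standard SpCas9 biochemistry); ±3 bp tolerance wherever "at the cut site" is tested |

Substitution-only reads (no indel at the cut) are classified uncut: the
method counts junctions, and a substitution produces none. Inversions are
counted as general translocations. All coordinates are 0-based, half-open,
BED-compatible.

## UMI deduplication

Reads collapse to one molecule when they share a junction key — outcome
class, prey reference, prey position rounded to a ±2 bp bucket, strand —
and their UMIs are within Hamming distance 1, clustered greedily from the
most frequent UMI down. Distinct junction keys never merge.

One property deserves honesty: "dedup recovers the simulated molecule
count exactly at zero error rate" is a statement about the *rule*, not
about 12-nt UMIs. All uncut molecules share one junction key, and among
~16,000 12-nt UMIs the expected number of Hamming-≤1 coincidences is in
the hundreds — even exact-match dedup would collide a few times. The
exactness tests therefore run with 24-nt UMIs, where the expected
collision count is ~10⁻³; the 12-nt default loses ~1.5% of molecules to
collisions at 20k scale, which cancels almost entirely in the reported
*fractions* (both are checked). The default stays 12 nt because that is
the realistic adapter regime.

## Off-target discovery

Translocation molecules are binned in 100-bp windows on two half-offset
grids (so a cluster straddling a bin boundary is not split); windows with
≥3 unique molecules merge into candidate hotspots. Each candidate, padded
±30 bp, is scanned on both strands for the 23-mer minimizing the joint
spacer+PAM mismatch count; sites above 8 mismatches are rejected — the
bound is read as a single joint budget over the 23-mer, with an optional
`require_pam` switch for the stricter reading (intact NGG in addition to
the bound), off by default. Finally the median (homology-resolved)
junction must lie within ±3 bp of the matched site's inferred cut.
Bin size and support minimum are package defaults recorded in output
metadata. Bulged (gapped) guide matches are not searched; the similarity
model is mismatch-only.

The brute-force enumeration of *all* guide-similar 23-mers on both strands
is part of the package, serving as the oracle: on toy genomes, discovery
must find exactly the enumeration's sites (minus the on-target, which by
construction receives no translocation junctions).

## Statistics and normalization

Three denominators coexist and are easy to confuse, so they are fixed in
one place: *editing events* exclude AAV integrations when reporting
editing efficiency and translocation rates, and include them when
reporting AAV rates; *total events* add uncut alleles; ambiguous molecules
appear in no denominator. The identity
`aav_pct_of_total / aav_pct_of_edited = (edited + AAV) / total` follows
and is asserted on every summary. Published companion numbers normalize
AAV rates "to indels" in one place and to indels+translocations+AAV in the
definitions; the definitional form is implemented, and the difference is
numerically negligible whenever translocations are rare relative to
indels. Large deletions are counted inside editing events by default
(switchable, recorded in metadata).

Group comparisons use the Welch unequal-variance form of the two-tailed
t-test — figure-legend groups have unequal n, and Welch is the safer
default when only "two-tailed Student's t-test" is specified; agreement
with an exhaustive 6-vs-6 permutation test is part of the test suite.
Zero-variance groups are handled explicitly (identical groups: t = 0,
p = 1). Fold changes are plain ratios reported to one decimal; a zero
denominator is undefined unless a pseudocount floor is requested. No
multiple-testing correction is applied anywhere.

## Problem sizes and what the tests show

The validation suite runs entirely on generated data: 20,000-molecule
libraries for classifier truth recovery (≥99.5% agreement, error-free) and
mixture recovery (every class fraction within 3 binomial standard errors,
with errors on), 20 independent toy genomes for discovery-vs-enumeration
equivalence, 1,000 AAV molecules for ITR-bias recovery, 500 random queries
for aligner-vs-oracle agreement, and 5,000 reads for amplicon indel-rate
recovery. These sizes give the binomial checks real statistical teeth
while keeping a full run inside a few minutes.

What passing does *not* show: the generator emits uniform substitution
errors, constant quality, no chimeric PCR artefacts, no indel sequencing
errors, single-end reads, and a vector without real ITR secondary
structure. Real libraries violate all of these to some degree; the
package's claims are about the correctness of the classification logic,
the window rules, the dedup rule and the normalization arithmetic — not
about robustness to artefacts the simulator does not model. Real-data
percentages from animal sequencing (which depend on biology and depth) are
out of reach of a desk-scale simulation and are not asserted anywhere in
the test suite.

## Known limitations

* No bulged guide matching in off-target discovery.
* No paired-end support and no BAM writing; SAM (with `SA` chimera tags)
  is accepted as an optional alignment source.
* Multi-fragment insertions beyond a single buried segment are not
  phased; long unmatched inserts land in the ambiguous bin.
* The aligner's gapped path is a chaining heuristic; it is exact only for
  the substitution-only reads the generator produces (which is what the
  oracle invariant covers).
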