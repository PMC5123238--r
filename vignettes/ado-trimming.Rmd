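---
title: "Managing allele drop-out in amplicon panels: the two-round trimming method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing allele drop-out in amplicon panels: the two-round trimming method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adotrim)
```

## The problem: allele drop-out

Amplicon-based targeted resequencing amplifies user-defined regions with
locus-specific primer pairs and sequences the products at high depth. Because
the assay is PCR at heart, it inherits PCR artifacts. Allele drop-out (ADO)
is the one this package addresses: when a heterozygous variant falls on a
primer hybridisation site, the primer binds the variant allele poorly and the
amplicon is synthesised almost exclusively from the wild-type allele. A
single 3'-proximal mismatch can reduce amplification yield by up to two
orders of magnitude; we model this worst case as a 100-fold yield reduction
(haplotype odds wild:mutated = 1:0.01 for the affected amplicon).

Two distinct artifacts follow:

1. **False homozygosity at the primer site.** Without primer removal, the
   primer bases of the biased amplicon are sequenced verbatim into every one
   of its reads and counted as reference support. On a two-amplicon design
   where the unbiased amplicon contributes ~37 % of reads, the variant's
   pileup fraction lands near `0.5 × 0.37 ≈ 18 %` — below the ~25 % fraction
   at which allele-fraction callers dismiss an allele — so a true
   heterozygote is reported as reference.
2. **A masked linked variant.** A second heterozygous variant sitting on the
   *same haplotype* a few bases downstream — inside both amplicons' inserts,
   outside every primer footprint — is also suppressed: the biased amplicon
   contributes only wild-type reads over that position, diluting the variant
   fraction to `0.45 × f_A` (with `f_A` the unbiased amplicon's read
   fraction and 0.9 the linkage probability). Primer trimming alone cannot
   fix this one.

## The two-round procedure

`run_two_step()` implements the remedy:

1. **Primer trimming.** Each read pair is assigned to an amplicon by prefix
   matching: read 1 against the upstream primer (ULSO), read 2 against the
   downstream primer (DLSO), each tolerating at most one mismatch and no
   gaps. Matched primers are cut from sequence and quality; pairs matching
   no primer pair are discarded whole.
2. **Round-one alignment and calling.** Trimmed reads are aligned to their
   amplicon's expected insert by local alignment; variants are called from
   pileup allele fractions.
3. **Read removal.** Every round-one variant whose reference span intersects
   a primer footprint marks the owning amplicons as ADO-affected; all their
   read pairs are removed. Exactly one removal round is run — the procedure
   is a two-step schematic, not a fix point iteration.
4. **Round-two calling and merge.** Pileup and calling are repeated on the
   remaining reads over all target regions, and the two rounds are merged by
   variant key with round-one precedence on collisions.

Round two is what recovers the masked linked variant: with the biased
amplicon gone, the downstream variant's fraction rises to ~45 % among the
remaining reads and is called heterozygous.

Two single-round baselines are provided by `run_single_round()`. The
`softclip` mode emulates the vendor workflow for amplicon kits — primer
identification with one mismatch, alignment to primer + insert + primer, and
soft-clipping of primer-overlapping bases so they stay in the record but out
of the pileup. It handles artifact 1 exactly as trimming does, but not
artifact 2: detection of the linked variant requires `0.45 f_A ≥ 0.25`,
i.e. `f_A` above ~55 %, a threshold effect that the benchmark grid shows as
detection only above the 50 % grid point. The `untrimmed` mode keeps primer
bases in the pileup and reproduces artifact 1.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_alt_fraction` | 0.25 | fraction below which an allele is dismissed; anchors the ADO failure mode |
| `hom_fraction` | 0.75 | at/above: homozygous call |
| `min_depth` | 30 | conventional minimum amplicon coverage (also the low-coverage threshold) |
| `min_alt_count` | 5 | absolute alternate support floor |
| `match/mismatch/gap open/extend` | +2/−2/−4/−1 | alignment scores; only tie cases depend on them at amplicon scale |
| `max_gap_fraction` | 1/3 | cumulative gap budget per read |
| `ado_yield_ratio` | 0.01 | mutated:wild yield of the ADO-affected amplicon |
| `het_fraction` | 0.5 | carrier haplotype probability on the unbiased amplicon |
| `second_mut_prob` | 0.9 | linkage probability of the downstream variant |
| `n_A`, `n_B` | 3186, 5484 | pool sizes; native composition ≈ 37:63 |

The caller is a deterministic allele-fraction gate rather than a genotype
likelihood model. This is a deliberate reduction: every outcome of the
benchmark lives far from the thresholds (fractions ≈ 0.01, 0.18, 0.45, 0.5),
except the deliberate `0.45 × 0.5 = 0.225 < 0.25` boundary case, which the
0.25 gate reproduces; likelihood modelling would add parameters without
changing any studied outcome.

## The synthetic benchmark

`build_fixture_panel()` draws a random ~600 bp reference and places two
250 bp amplicons (20-base primers, 210-base inserts) overlapping by 10
bases: A at insert `[100, 310)`, B at insert `[300, 510)` (all coordinates
0-based half-open). The planted variants:

* **m1** at position 297: inside B's upstream-primer footprint `[280, 300)`
  and inside A's insert. A substitution C>T in SD1; a single-base insertion
  in SD2. The insertion base is chosen to differ from both flanking
  reference bases (unique, left-normal placement) and such that the shifted
  primer prefix carries at least two mismatches — so the no-gap matcher
  must reject mutated-B reads deterministically rather than by luck.
* **m2** at position 302 (= m1 + 5): G>A, inside both inserts, outside all
  footprints, carried by mutated haplotypes with probability 0.9.

Reads are 2×150 bp from the amplicon ends, so mates overlap mid-insert;
read 1 starts with the ULSO, read 2 with the DLSO, which is how the trimmer
expects them. `mix_reads()` subsamples the two pools to a target A-fraction
at constant total (8670 pairs), so depth — and with it caller behaviour —
is comparable across the grid; draws are without replacement when the pool
allows, with replacement otherwise (flagged in the truth table).

What the generator does **not** emulate: sequencing-error and quality-score
profiles (qualities are constant `I`; `base_error_rate` defaults to 0 so
the planted variants are the only non-reference signal), chimera formation,
PhiX spike-in, and multi-sample panel structure. Passing the benchmark
therefore demonstrates the pipeline logic — assignment, trimming, removal,
re-calling, merging — not robustness to platform noise; the
`base_error_rate` knob exists for robustness experiments.

## Numerical and design choices

* **Alignment.** The aligner is an affine-gap Smith–Waterman over the full
  read × amplicon matrix (at 150 × 250 the full matrix is cheaper than band
  bookkeeping), with the gap budget enforced on the optimum: alignments
  whose cumulative inserted + deleted length exceeds
  `floor(read_len / 3)` are reported unaligned and dropped from the pileup.
  The "third of the read" budget is read as *cumulative* gap length, the
  stricter of the two possible readings. Traceback is deterministic
  (diagonal > deletion > insertion on ties); reported indels are
  left-aligned against the reference on output, the VCF convention.
  Identical (amplicon, sequence) alignments are memoised, which makes the
  highly redundant simulated pools cheap to process.
* **Tie-breaking at assignment.** When several primer pairs match a pair,
  the smallest total mismatch count wins, then manifest order. `N` matches
  any base on either side, never counting as a mismatch.
* **Coordinates.** 0-based half-open everywhere internally; a variant at
  `insert_start` is *not* in the upstream footprint. Conversion to 1-based
  happens only in the VCF writer.
* **Pileup accounting.** Soft-clipped bases contribute nothing; deleted
  reference bases count toward depth at the columns they span; insertions
  are tallied at their anchor base without adding depth. One alternate
  allele — the highest-fraction one — is reported per site.
* **Round-two scope.** The second round re-calls over *all* target regions
  and merges, rather than re-calling only affected intervals; this is the
  simplest semantics consistent with "merge the newly identified
  variants", and merging with round-one precedence makes the two
  equivalent in output.
* **Degenerate inputs.** Header-only manifests load as empty panels;
  empty FASTQ input yields zero-count statistics; an all-`N` read is
  assignable under the wildcard rule (manifest order breaks the tie);
  removal of every amplicon yields an empty round two. If removal leaves
  target bases covered by no amplicon, the loss is reported in the result
  statistics rather than silently ignored — regions covered by a single
  amplicon are an intrinsic design limitation no read-level method can
  recover.
* **QC gate arithmetic.** "Quality lower than 30 % of the reference" is
  applied literally (`q < 0.30 × reference`); the alternative reading
  (a 30 % drop below the reference) is available behind
  `interpretation = "below_reference"`.

## Problem sizes

The shipped tests and the acceptance script run the full native pools
(3186 + 5484 pairs), the 11-point mixing grid at constant 8670-pair depth
for both dataset modes, full-DP oracle comparisons on up to ~160 random
reads, and brute-force assignment checks on several hundred pairs. The
complete suite runs in about a minute on one CPU.

## Known limitations

* The emulated caller reproduces the benchmark's outcomes but not the
  internals of likelihood-based genotypers; in particular, the slight
  improvement a vendor pipeline shows on the insertion dataset at 30–40 %
  unbiased reads arises from caller internals that are out of scope here.
* Variant quality scores are not emitted; there is no defensible way to
  define them for a fraction-gate caller.
* ADO on regions covered by a single amplicon is detectable (the region
  goes uncovered after removal, and is reported) but not recoverable.
* The manifest dialect is a minimal TSV reconstruction, not the
  proprietary vendor manifest format.
```{r, eval = FALSE}
# the benchmark in one call
grid <- benchmark_grid(seed = 1)
grid[grid$mode == "SD1", ]
```
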