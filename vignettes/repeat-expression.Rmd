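---
title: "Quantifying repeat-family transcription against a uniform null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repeat-family transcription against a uniform null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retex)
```

## The problem

Repetitive elements — Alu and MIR SINEs, L1/L2/CR1 LINEs, LTR/ERV
elements, DNA transposons, satellites — cover nearly half of a mammalian
genome. In short-read RNA-seq their reads are intrinsically multi-mapping,
so the meaningful unit of quantification is the *family*, not the locus.
`retex` asks one question of such data: is each family transcribed more or
less than uniform background transcription of repeat sequence would
produce?

The analysis has five stages, each exposed as ordinary functions and
orchestrated by `run_pipeline()`.

## The repeat reference

`build_repeat_db()` extracts every annotated repeat with a flank of
`flank_bp` genomic bases on each side (default **50 bp**; enough to anchor
a 76 bp junction-spanning read while adding little unique sequence).
Flanks are clipped at chromosome ends; overlapping annotations yield
deliberately duplicated sequence (no merging), so `total_bp` may exceed
the distinct genomic coverage. Entries are stored genome-forward; strand
is handled at alignment. Coordinates are 0-based half-open internally and
1-based inclusive in human-readable output. Only A/C/G/T/N are accepted:
N never matches anything, other ambiguity codes are rejected at parse.

Class labels from RepeatMasker `.out` or BED6 input are collapsed to a
fixed 12-family taxonomy (`family_taxonomy()`) by ordered regular
expressions with `"Other"` as catch-all. The grouping of classes into
families is a configuration, not a fact of nature: the default puts
ERV ahead of the generic LTR rule and TcMar/hAT ahead of the generic DNA
rule, which is one reasonable reading of common annotation practice.

## Alignment

`align_reads()` implements seed-and-extend with the constraints that
define the analysis: **zero mismatches in the first 20 read bases** (the
seed), ungapped Hamming extension over the rest of the (76 bp-trimmed)
read, and a configurable total mismatch cap outside the seed
(`max_mismatches`, default **3** — the seed rule alone does not bound the
search, and 3 mismatches in 56 extension bases tolerates realistic
sequencing error plus residual divergence). One best alignment is kept
per read; ties are broken deterministically by (entry, + strand before −,
offset), which keeps family assignment stable and runs reproducible.
Base qualities are ignored; the constraints are purely sequence-based.
Indels are out of scope here — the LINE-1 module uses a gapped local
aligner instead.

The index is an exact-seed hash over every 20-mer of every entry
(forward; minus-strand placements are found by seeding the reverse
complement of the read). On databases up to ~100 kb the emitted best-hit
mismatch counts are verified against an exhaustive all-offsets,
both-strands scan built from independent Biostrings primitives; the test
suite requires 100% agreement on 5,000 reads.

`align_unique_genome()` retains reads with exactly one surviving
placement in an entire (toy) genome — the rule used for counting reads in
repeat-masked intronic/intergenic compartments
(`compartment_counts()`, which demands disjoint interval sets and counts
fully contained reads).

## The uniform-transcription null

`simulate_uniform_reads()` draws read start positions uniformly over all
valid (entry, offset) pairs of the database — an entry of length `L`
contributes `L − 75` starts — copies the sequence verbatim (no error
model; the null is about *where* reads come from, not read quality), and
assigns strand uniformly (unstranded cDNA libraries). `null_counts()`
aligns and counts each of `n_datasets` (default **100**) such datasets
exactly like observed samples; this is the point of simulating rather
than using analytic start-shares, since the simulated counts absorb any
bias the alignment process introduces. Dataset `i` uses subseed
`seed + i − 1`, making datasets independent and individually
reproducible. A coding-sequence database can be sampled the same way and
aligned against the repeat database, to ask whether uniform expression of
coding sequence explains observed repeat counts. Entries shorter than the
read length contribute no reads by design.

## The family-level test

`run_family_test()` compares observed samples (typically 10 pooled
biological samples) with the simulated datasets:

* **Size factors** (`estimate_size_factors()`): median-of-ratios against
  the per-family geometric mean, computed jointly across both conditions
  by default (configurable to per-condition; joint is the natural choice
  when both conditions share one count scale).
* **Dispersion** (`fit_dispersion()`): per condition, base mean `q_f` and
  variance `w_f` of normalized counts; the pooled relation `w(q)` is fit
  by isotonic regression — with only a dozen families a local regression
  is not identifiable, and NB variance is monotone in the mean. The raw
  (overdispersion) variance is `w(q) − q·mean(1/s_j)`, floored at zero:
  nothing is ever modeled as less variable than Poisson. By default each
  family uses the *larger* of its own and the fitted variance
  ("maximum" sharing), a conservative guard for families above the trend;
  measured type-I error at nominal 0.05 is ~0.07 over 12,000 same-law
  simulations in the acceptance suite.
* **Exact test** (`nb_exact_test()`): conditional on the two-condition
  total `S`, the p-value sums the probabilities of all splits no more
  likely than the observed one, under condition-specific NB laws whose
  means and variances come from the pooled base mean, size-factor sums
  and fitted dispersions. All masses are computed in log space and the
  full `0..S` range is enumerated (vectorized; exact at any desk-scale
  `S`), so `log10_p` stays meaningful long after `p` underflows to zero.
  A variance at or below the mean degenerates to the Poisson law;
  `S = 0` returns p = 1 with a flag.
* **Fold change** is simulated/observed, so overexpression reads as
  fold change < 1 — the orientation that makes the family-level table
  internally consistent (an overexpressed Alu-like family sits below 1
  while an underexpressed L1-like family sits above it).
* **BH adjustment** (`bh_adjust()`): textbook step-up, implemented
  directly and cross-checked against `p.adjust()`; an adjusted version of
  `log10_p` is computed with the same step-up on the log scale so that
  underflowed rows remain ordered.

## The LINE-1 5' profile

Most genomic L1 copies are 5'-truncated relics; only full-length copies
carry the internal promoter. `start_profile()` realigns L1-assigned reads
to a panel of full-length consensus sequences with Smith–Waterman local
alignment (match +1, mismatch −1, gap of length `L` costs `2 + L`;
minimum reported score **50** on 76 bp reads — a mostly matching read
with a few substitutions or a short indel). A read usually hits several
similar consensuses, so its position is summarized as the mean 1-based
start over its per-consensus best hits (ties resolve to the smallest
start) and histogrammed (default bin width **100 bp**). Observed mass in
the 5'-most bins above the uniform-null profile indicates promoter-driven
transcription of full-length elements. The dynamic programming is exact
(no heuristics) and is verified in the tests against an independent
quadratic implementation and against Biostrings' aligner scores.

## What the synthetic generator emulates — and what it does not

`make_genome()` builds a toy genome from i.i.d. background plus planted
families: a random consensus per family, copies mutated at the family's
divergence rate (default **5%** per base) and 5'-truncated
(full-length fraction **0.10** for the L1-like family; truncated copies
keep a 50 bp core plus a geometric number of 3' bases). Family bp budgets
are filled until the target repeat fraction (default **0.45**) is
realized; one full-length copy is always planted for truncating families
(an active source element always exists). Genes are planted too, a
configurable fraction carrying an embedded repeat copy — the mechanism by
which strongly expressed genes can drive family-level repeat signal,
which is what the coding-space null interrogates.

`make_reads()` draws each read from a three-part mixture: repeat
transcription (family weight ∝ multiplier × start-share; default repeat
fraction **0.08** of reads, matching repeat-derived shares reported for
poly-A brain libraries), log-normally expressed gene transcripts, and
uniform genomic background (default **0.02**). Repeat reads are drawn
from the *flank-extended* extent of each copy: repeat transcription in a
genomic context includes junction sequence, and this convention makes the
all-multipliers-at-1 configuration exactly the uniform null over the
repeat database — without it, short families would be systematically
deflated relative to the null by pure geometry. L1-like families emit
reads only from full-length copies (promoter-driven) while their family
weight still reflects the whole family. Substitution errors are applied
at **0.005** per base (Illumina-like). Mates of a pair are two
independent draws from the same law, reflecting their treatment as
technical replicates.

What the generator does **not** emulate: real repeat phylogenies and
subfamily structure, CpG-biased mutation, GC/coverage bias, RNA editing,
fragment-size correlation between mates, and position-dependent error
profiles. Passing tests on synthetic data therefore demonstrate that the
machinery recovers planted signal under the stated generative model, not
that any particular biological dataset will behave as cleanly.

## Null self-consistency as a design choice

The acceptance suite checks that data generated with all family
multipliers at 1 yields no significant family in ≥ 90% of 20 end-to-end
replicates. That check is run on a genome without embedded gene-repeat
copies and with the background component off: embedded copies under
log-normal gene expression, and whole-genome background (which weights
families by bp rather than start-share), are *genuine* departures from
uniform repeat transcription that the test is supposed to flag — leaving
them in would measure the generator's biology, not the test's type-I
behaviour.

## Problem sizes

Default desk scales, chosen so the whole suite runs comfortably on one
CPU: 400 kb two-chromosome genomes (~45% repeat), 10 observed samples of
2,000 reads, 100 null datasets of matching depth, 5,000-read
aligner-oracle comparisons on ≤ 100 kb databases, 100,000-read uniformity
checks, 250-read Smith–Waterman profiles, and 1,000-replicate type-I
simulations. Paper-scale settings (hundreds of thousands to millions of
reads per dataset) are reachable through the same configuration objects.

## Known limitations

* Family-level only: the one-best-hit strategy deliberately gives up
  locus-level resolution.
* The ungapped aligner ignores indels; reads spanning indel polymorphisms
  may be lost at the mismatch cap.
* With 12 families the dispersion fit pools little information; the
  "maximum" sharing mode trades power for type-I control.
* The uniform null models position, not sequence quality; systematic
  base-composition effects on sequencing itself are not separated from
  biology.
* Satellite-like families with few, long, internally repetitive entries
  give the exact test its weakest footing (few effective units per
  family).
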