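---
title: "Models and methods: stacking homoeologous deletions and sizing them by synteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: stacking homoeologous deletions and sizing them by synteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HomoeoDel)
```

## The problem

Allohexaploid bread wheat (*Triticum aestivum*) carries three subgenomes, A,
B and D. A typical gene exists as three homoeologous copies, one per
subgenome, sharing roughly 96–98% sequence identity, and two alleles of
each. Complete loss of function therefore requires combining homozygous
deletions at all three homoeoloci in one line — "stacking" — usually by
crossing single-locus deletion mutants recovered from a physically
mutagenized population and screening F2 progeny.

Three computations recur in such a programme, and this package implements
them with a synthetic-data generator so every stage runs, and is tested,
without external data:

1. expected F2 genotype-class ratios under a *hemizygote-blind* screen and
   chi-square tests of observed progeny counts against them (deviations
   signal incompatibility of stacked deletions);
2. calling which genes a mutagen-induced deletion removed, from amplicon
   sequencing of the mutant against wild-type and aneuploid controls;
3. converting per-marker intact/deleted calls along a synteny-anchored
   flanking panel into a minimum/maximum deletion-interval estimate.

## The segregation model

Genotypes are written as intact-allele dosages $(d_A, d_B, d_D)$ with
$d \in \{0, 1, 2\}$. The probe-based screen cannot distinguish one intact
allele from two: only loci with dosage 0 are reported
(`detectClass()`). The detected class is therefore the subset of
$\{A, B, D\}$ at which both homoeoalleles are gone.

Parents in a stacking cross are homozygous everywhere (dosage 0 or 2), so
the F1 dosage per locus is the parental mean (`f1Genotype()`). The three
homoeoloci sit on different homoeologous chromosomes and assort
independently; no recombination parameter is modelled. Selfing a locus of
F1 dosage $h$ yields an F2 offspring of dosage 0 with probability
$(1 - h/2)^2$: $1/4$ when hemizygous, $1$ when already deleted, $0$ when
intact. Class probabilities multiply across loci
(`f2ClassDistribution()`); the test suite pins this closed form against an
explicit gamete-enumeration oracle over all 27 possible F1 genotypes.

For a cross of an A-primary by a B-primary mutant the familiar ratios
emerge: 3/16 A-deletions, 3/16 B-deletions, 1/16 AB double deletions and
9/16 with nothing detected.

### Incompatibility testing

For each genotype class a screening table lists, we test observed against
expected counts with a 1-df goodness of fit on the two-cell split
\{class, not class\} with no continuity correction
(`perClassChiSquare()`):

$$X^2 = \frac{(O - np)^2}{np} + \frac{((n-O) - n(1-p))^2}{n(1-p)},$$

which for $O = 0$ reduces to $np/(1-p)$ exactly. Flags follow the
conventional two-level annotation: `*` for $p < 0.05$, `**` for $p < 0.01$
(configurable via `SignificanceConfig()`), with a bold marker when a class
was never observed and the deficit is significant. The source screening
tables say only that "chi-square contingency analysis" was performed in a
commercial GUI; we chose the per-class two-cell variant because it
reproduces the published flag pattern on the three-locus crosses (a missing
3/64 class among 252 progeny gives $X^2 = 12.4$, $p \approx 4\times10^{-4}$,
`**`; a missing 1/64 class gives $X^2 = 4$, $p \approx 0.0455$, `*`). The
discreteness of small counts makes the test mildly conservative; its exact
size at $np \ge 10$ stays within $\pm 0.01$ of nominal, and a seeded
simulation in the test suite verifies $\pm 0.02$.

Only classes *listed* in a table are tested. Screening tables omit classes
that were not scored — e.g. the 9/16 single-locus-deletion progeny of a
tetra-by-tetra cross — and treating an omitted class as a zero count would
manufacture wildly significant deficits the original analysis never
claimed. A zero must be printed to be tested.

`incompatibilityPower()` closes the loop: given a cross, a progeny count
and a hypothesized set of lethal classes, it simulates screens from the
renormalized distribution and reports how often every lethal class is
flagged — useful for judging whether "no double deletions among n progeny"
is evidence of incompatibility or just a small screen.

## The amplicon deletion caller

To size a deletion around a target gene, fragments of flanking genes are
PCR-amplified from the mutant and from controls, pooled and sequenced. The
controls are: wild-type accessions (two or more), and three
nullisomic-tetrasomic lines, aneuploid stocks that lack one homoeologous
chromosome pair and compensate with four copies of another — a genetic
"subtract one subgenome" experiment.

Reads are placed by exhaustive ungapped alignment against one mapping
reference per gene (in practice a diploid-progenitor scaffold), keeping the
placement with the fewest mismatches, mapped only above 85% identity
(`alignReads()`). Amplicons are short and the simulator substitution-only,
so gapless alignment is exact for what it models; the Rcpp inner loop is a
2-bit-packed branch-and-bound scan whose result is identical to the naive
scan (a pure-R brute-force oracle asserts this), with exact k-mer seeding
used purely to tighten the bound early.

SNPs are called per pileup column at $\ge 50\times$ coverage and $\ge 5\%$
allele frequency (`detectSnps()`, thresholds in `CallerConfig()`). The
logic that follows is set arithmetic on SNP keys (gene, position, allele):

1. **Consensus**: keep only SNPs present in *every* wild-type sample
   (`selectConsensusSnps()`); anything else is accession-specific or noise.
2. **Assignment**: a consensus SNP absent from exactly one
   nullisomic-tetrasomic control is specific to the subgenome that control
   lacks (`assignHomoeologueSnps()`). SNPs absent from zero controls
   (shared variation relative to the mapping reference) or from several
   (ambiguous) are logged unassigned. Whether "absence from two controls"
   occurs in real data is unknown to us; treating it as unassignable is a
   conservative choice.
3. **Calling**: a gene is *deleted* on a subgenome in a mutant when **all**
   of its subgenome-specific SNPs are absent from the mutant's SNP table,
   *intact* when all are present, and *unknown* otherwise
   (`callIntactness()`). "Consistently deleted" is read strictly: any
   partial pattern yields `unknown` with a conflict warning rather than a
   call, matching the three-state (green/red/white) reporting convention.
   Genes with no subgenome-specific SNP are inherently `unknown` — with a
   single-gene amplicon there is nothing to subtract — which is also how
   translocated genes manifest.

Presence in a control requires full threshold passage, the same criterion
as everywhere else; sub-threshold residual signal does not count. Monosomic
lines are not accepted as controls (one copy fluoresces like two in the
upstream screen, and here a one-dose control would shift frequencies
without removing the subgenome). PCR duplication is summarized as a
duplicate-start-position fraction (`duplicateStartFraction()`), never
filtered, mirroring the visual-inspection step it replaces. Quality
trimming is a pass-through: the simulator's substitution-only error model
carries no quality structure, and pre-trimmed FASTQ is accepted as is.

## Deletion-interval inference

Markers flank the anchor gene at signed offsets in kb ("Up" = negative =
toward the distal end of the short arm). The packaged panel
(`pft1FlankPanel()`) spans 2 Mb on each side at the published spacing; the
two anchor-adjacent markers have no published distance and carry ±10 kb
placeholder offsets (configurable).

Given a mutant's per-marker calls (`IntactnessProfile`),
`inferDeletionInterval()` reports:

* **minimum span** — from the outermost marker called deleted on the Up
  side to the outermost deleted marker Down;
* **maximum span** — extending on each side to the *nearest marker beyond
  the deleted run with a definite intact call*; `unknown` markers are
  skipped. The bound marker's own offset is the bound (a profile deleted
  from 400 kb Up to 100 kb Down with nearest intact markers at 700 kb Up
  and 200 kb Down gives 500–900 kb), following the published bracket
  arithmetic literally rather than treating the intact marker as an open
  endpoint.
* a side with no intact marker beyond the run is **open**: `maxSize = Inf`
  and the report renders "> min" with a `>` glyph.

A marker called deleted *beyond* an intervening intact marker is excluded
with a non-contiguous-deletion warning — with single-hit physical
mutagenesis that pattern indicates rearrangement or marker reordering
rather than one deletion, as observed on the D subgenome in the motivating
data. Sizes are in syntenic-reference kb: the estimate measures the
*syntenic model-grass region*, not physical wheat bases, which are several-
fold larger.

`classifySynteny()` and `estimateRegionSize()` implement the companion
rules for homology-hit tables: no hit on any target chromosome arm means
translocated; a target-arm best hit not matched-or-beaten off-target on
*both* identity and length means conserved; dominance everywhere means
uncertain. "Equal or greater identity and length" is evaluated on the
single best hit per arm (by e-value, ties by identity then length), since
hit tables carry many secondary HSPs. Region size sums each scaffold once,
however many conserved genes it carries.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, and
only that:

* **References** (`simulateHomoeologRefs()`): per gene, an ancestral
  amplicon (default 800 bp, within the 500–1500 bp design window) from
  which each subgenome copy diverges by substitutions at `divergence`/2
  (default 3% pairwise divergence, i.e. 97% identity). Site counts are
  fixed at `round(L * d/2)` per subgenome so realized pairwise identity is
  within 1% of target on every gene; positions are distinct across
  subgenomes and drawn uniformly with no transition/transversion bias. The
  ancestral sequence is the mapping reference, playing the role of the
  progenitor-genome scaffold; consequently each subgenome, including D,
  has its own specific sites relative to it, as cultivar D genomes do
  relative to the progenitor assembly.
* **Reads** (`simulateSampleReads()`): drawn per present gene-by-subgenome
  copy in proportion to copy number (nulli-tetra controls carry 0 and 4
  copies of the affected subgenomes), 200 bp at 60-fold per-copy coverage,
  i.i.d. substitution errors at 1% (the approximate post-trimming error
  of the emulated platform). Fragment starts may overhang either amplicon
  end and are clipped at a 50 bp minimum overlap, emulating the sheared
  amplicon pools actually sequenced; without this, amplicon ends sit far
  below the 50x coverage floor and edge divergence sites become
  systematically uncallable, which the real shearing protocol avoids. No
  homopolymer indels, quality decay, chimeras or coverage skew between
  amplicons are modelled — so passing tests demonstrate the threshold and
  set logic, not robustness to platform-specific artefacts.
* **Populations** (`simulateF2Population()`): locus-independent selfing
  draws with rejection of lethal detected classes, converging to the
  model's class distribution.

Everything stochastic takes an explicit integer seed; the same seed yields
byte-identical FASTQ.

## Problem sizes and numerical choices

The recovery property is exercised at the scale a study of this kind
actually has: the 21-marker panel, 5 control samples (2 wild type + 3
nulli-tetra) and 100 mutants with spans drawn uniformly up to 2.1 Mb per
side, each mutant fully re-sequenced and re-called (~17,000 reads per
sample). Bounded intervals bracket the true span in 100% of cases; spans
overrunning the panel produce open-sided intervals whose minimum bound is
still checked. Unit tests use smaller panels (3–6 genes, 300–400 bp
amplicons) for speed; thresholds, coverage and error rate stay at the
defaults unless a test is explicitly about the zero-error regime.

Class probabilities are exact rationals evaluated in double precision; the
distribution validity check tolerates 1e-12. Chi-square p-values come from
`stats::pchisq` upper tails. Alignment ties are broken deterministically
(first reference in input order, then lowest offset), and `detectSnps()`
output is sorted by scaffold and position, so the caller is invariant to
read input order.

## Known limitations

* The chi-square variant behind the published flags is not documented; one
  printed cell (18/164 at 3/16) is flagged where our default gives
  p ≈ 0.011, consistent with `*` but not uniquely so. The per-class
  two-cell test is a documented choice, not a reconstruction.
* The expected-ratio table the published index column refers to was not
  available; our index-to-cross map is derived from the cross structure
  and the stated expectation that tetra-by-tetra progeny all carry the
  shared deletion.
* Interval estimates are bounded by marker spacing: nothing between the
  outermost deleted marker and the bounding intact marker is observable.
* Real aneuploid stocks can carry background variation; the generator's
  controls differ from wild type only in dosage.
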