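# HomoeoDel

Deletion stacking genetics and homoeologue-specific deletion calling in
hexaploid wheat.

## The problem

Bread wheat (*Triticum aestivum*) is allohexaploid: most genes exist as
three homoeologous copies on the A, B and D subgenomes, at 96–98% mutual
identity, with two alleles each. Knocking a gene out therefore means
*stacking* homozygous deletions at all three homoeoloci, typically by
crossing single-locus deletion mutants from a physically mutagenized
population and screening F2 progeny with a probe assay that is
**hemizygote-blind**: it reports a locus only when *both* homoeoalleles are
gone. HomoeoDel is for geneticists running such a programme. It provides:

* **Segregation model + incompatibility tests.** With dosages
  $(d_A,d_B,d_D)\in\{0,1,2\}^3$ and independent assortment, an F1 locus of
  dosage $h$ selfs to a homozygous-deleted F2 locus with probability
  $(1-h/2)^2$; detected-class probabilities multiply across loci
  (`f2ClassDistribution()`). Observed per-class counts are tested with a
  1-df goodness of fit, $X^2 = (O-np)^2/np + ((n-O)-n(1-p))^2/n(1-p)$, no
  continuity correction, flagged `*` (p < 0.05) / `**` (p < 0.01)
  (`perClassChiSquare()`, `evaluateCrossTable()`), plus a Monte-Carlo power
  calculation for hypothesized lethal classes (`incompatibilityPower()`).
* **Amplicon deletion caller.** Exhaustive ungapped read alignment (85%
  identity floor), pileup SNP calling (≥ 50x coverage, ≥ 5% allele
  frequency), wild-type-consensus filtering, subgenome assignment by
  subtraction against nullisomic-tetrasomic controls, and three-state
  intact/deleted/unknown calls per gene and subgenome
  (`runDeletionCalling()`).
* **Synteny-anchored interval inference.** Per-marker intactness along a
  flanking panel → minimum span (outermost deleted markers) and maximum
  span (nearest definitely-intact markers; unknowns skipped; open sides
  reported) (`inferDeletionInterval()`), plus synteny-conservation
  classification of homology hit tables and unique-scaffold region sizing
  (`classifySynteny()`, `estimateRegionSize()`).
* **Synthetic data with ground truth.** Homoeologous reference triplets,
  control/mutant genotypes, seeded amplicon reads and F2 populations
  (`simulateHomoeologRefs()`, `simulateSampleReads()`,
  `simulateF2Population()`), so the entire pipeline runs and is tested
  offline.

## Worked example

Screen 316 F2 progeny of an A-primary x B-primary cross for the target
gene; 55 A-deletions and 51 B-deletions found, but no AB double deletions:

```r
library(HomoeoDel)
cross <- indexToCross(1, label = "tapft1-616-a x tapft1-157-b")
tab <- ObservedCrossTable(cross, n = 316,
                          counts = c(A = 55, B = 51, AB = 0),
                          gene = "TaPFT1")
evaluateCrossTable(tab)
#>   class observed expected statistic df  p_value flag  bold
#> 1     A       55     59.2     0.375  1 5.40e-01      FALSE
#> 2     B       51     59.2     1.414  1 2.34e-01      FALSE
#> 3    AB        0     19.8    21.067  1 4.44e-06   **  TRUE
```

The single-locus classes sit at their 3/16 expectations, but the missing
1/16 AB class (expected 19.75) is a 21-sigma-squared deficit — strong
evidence that this pair of deletions cannot be combined.

How much did that A mutant's deletion remove? From its amplicon-sequencing
intactness profile along the packaged 21-marker panel (markers deleted from
400 kb Up of the anchor through 100 kb Down; nearest intact markers at
700 kb Up and 200 kb Down):

```r
panel <- pft1FlankPanel()
m <- markers(panel)
calls <- structure(rep("unknown", nrow(m)), names = m$gene_id)
calls[m$offset_kb >= -400 & m$offset_kb <= 100] <- "deleted"
calls[m$offset_kb %in% c(-700, 200)] <- "intact"
iv <- inferDeletionInterval(IntactnessProfile("tapft1-616-a", "A", calls),
                            panel)
iv
#> DeletionInterval 'tapft1-616-a' [A]: min 500 kb, max 900 kb
#>   bounds: Bradi4g27117 (Up) / Bradi4g27880 (Down)
```

The deletion spans at least 500 kb and at most 900 kb of the syntenic
reference region (reference kb — the physical wheat span is several-fold
larger). `renderIntervalTrack(list(iv), panel)` draws it on the marker
grid:

```
mutant               -2M -1.5M   -1M  -700  -500  -400  -200 ...   100   200 ...
tapft1-616-a [A]       .     .     .     |     ~     ~     ~ ...     ~     | ...  min 500 kb, max 900 kb
```

The packaged cross tables (`exampleCrossTables("tetra")`,
`exampleCrossTables("hexa")`) carry the full two- and three-locus screening
data for three target genes (1237, 605 and 419 progeny screened);
`crossReport()` reproduces their per-cell flags and `summarizeScreening()`
their totals.

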