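---
title: "Rare-variant collapsing tests: model, conventions and design notes"
author: "rvCollapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant collapsing tests: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvCollapse)
```

## The model

Single-marker association tests have little power at minor allele
frequencies (MAF) of a few percent or below. The collapsing (burden)
approach pools the rare-variant content of a predefined region into one
composite "super-locus" and tests a per-individual summary. `rvCollapse`
uses the simplest such summary, a binary carrier indicator:

> an individual *carries* the region's rare variation if at least one
> minor allele is observed at at least one region marker with
> 0 < MAF ≤ *c*.

Carrier status is presence/absence, not an allele count: a homozygous
minor genotype, or minor alleles at several markers, still count once.
This sacrifices information relative to allele-count or weighted burden
scores but keeps the test a plain 2×2 contingency or two-group comparison,
robust and cheap at genome scale. Both analyses assume unrelated
individuals; no relatedness correction is applied.

For a binary trait the carrier × case/control table is tested with
Pearson's uncorrected chi-squared statistic (1 df). No Yates continuity
correction is applied — the statistic is the plain
$N(ad-bc)^2/(r_1 r_2 c_1 c_2)$. When the smallest *observed* cell count
falls below the minimum-cell threshold the asymptotic reference is
unreliable, and a two-sided Fisher's exact test (summing hypergeometric
probabilities no larger than the observed table's) is run in addition.
Permutation empirical p-values shuffle case/control labels among
individuals with defined carrier status and phenotype, preserving the
margins, and report the exceedance fraction with ties counted as
exceedances and no pseudocount: `0/10 = 0` is reported as written, which is
fine for screening but means small permutation counts cannot bound the p
away from zero.

For a quantitative trait the trait is regressed on the 0/1 indicator by
OLS. With a binary predictor the slope is exactly the carrier minus
non-carrier mean difference and the regression t equals the
pooled-variance two-sample t — an identity the test suite asserts to
machine precision. Carriers are coded 1, so a positive β means carriers
have the higher trait mean. (Published output of the historical
implementation of this method prints the opposite sign, consistent with
the reference level being coded the other way; the conventional coding is
used here and the sign difference is deliberate.)

## Regions and coordinates

Two region definitions are supported, mirroring field practice:

* **Gene-centric**: one region per gene record, extended by user flanks
  upstream/downstream and clamped at coordinate 0. Overlapping genes give
  overlapping regions and are analysed independently — adjacent genes
  often share identical carrier counts, which is expected, not a bug.
* **Sliding windows**: intervals `[k·step, k·step + window]` on a grid
  anchored at bp 0, for the smallest k-range covering the span of observed
  marker positions. Anchoring at 0 (rather than at the first marker) makes
  window identities reproducible across datasets sharing a build. The
  default step is half the window; a step larger than the window is
  allowed (with a warning) and leaves gaps. Windows with no markers are
  still reported, with `(0/0)` counts, so genome-wide bookkeeping is
  complete.

Coordinates are 1-based and interval membership is inclusive at both ends,
the linkage/MAP convention. A marker sitting exactly on a shared window
boundary therefore belongs to both adjacent windows.

## Conventions for awkward inputs

Decisions the file formats force, and the choices made:

* **Half-missing genotypes** (`0 A`) are treated as fully missing: one
  called allele cannot establish diploid carrier status.
* **Missing phenotype codes**: binary mode accepts both `0` and `-9`
  (configurable); quantitative mode defaults to `-9` only, because 0 is a
  legal trait value.
* **MAF reference sample**: frequencies are computed over all phenotyped
  individuals jointly (cases and controls together), so both groups share
  one rare-marker set and the 2×2 construction is symmetric. Computing MAF
  in controls only is a defensible alternative (cases are enriched for
  risk alleles) and is exposed as `mafGroup = "controls"`.
* **Frequency ties at 0.5** take the lexicographically smaller allele
  token as minor, making results independent of file order.
* **Monomorphic markers** have MAF 0 and are never selected as rare: with
  no minor allele present there is nothing to carry.
* **Partially missing rare genotypes**: an observed minor allele always
  makes a carrier; an individual whose observed rare genotypes are all
  major but who is missing at some markers is counted a non-carrier by
  default (the optimistic call — excluding such individuals would discard
  much of a genotyping-array panel), with `strictMissing = TRUE` switching
  to exclusion. Individuals missing at *every* rare marker are always
  excluded.
* **Degenerate tests**: a 2×2 table with a zero margin reports χ² = 0,
  p = 1; a QT region with an empty group, or zero residual variance, is
  written with empty statistic fields, flagged undefined and given p = 1
  (p = 0 if the groups separate exactly with zero noise) rather than being
  dropped, so every region defined on a chromosome appears in its output
  file exactly once.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `maf` | 0.05 | MAF cutoff (fraction) defining low-frequency/rare variants |
| `flankUp`, `flankDown` | 0 bp | gene extension beyond transcription start/stop |
| `windowBp`, `stepBp` | —, window/2 | sliding-window size and step (bp) |
| `minCell` | 30 | observed-cell threshold triggering Fisher's exact test |
| `perm`, `permTrigger` | 0, 0.05 | permutations per region, and the asymptotic-p gate |
| `sig` | 0.05 | threshold for summary files, SNP lists, highlighting |
| `pout` | 0.05 | regression-p threshold for per-region trait histograms |
| `seed` | 1 | global seed; per-region permutation streams derive from it |

The permutation stream for each region is seeded from the global seed and
the region name via a 31-bit polynomial string hash, so per-region results
are reproducible and independent of the order in which regions or
chromosomes are processed.

## Numerical choices

* Chi-squared and Fisher p-values come from the standard R tests
  (`chisq.test(correct = FALSE)`, `fisher.test`); the test suite
  cross-checks them against an independent closed-form oracle and a full
  hypergeometric enumeration on small margins.
* Label permutation with carrier status held fixed makes the case-carrier
  cell hypergeometric with the observed margins; replicates are therefore
  drawn directly with `rhyper` and scored with the closed-form statistic
  (in doubles, to avoid integer overflow at GWAS margins). An explicit
  label-shuffle oracle in the tests confirms the equivalence. Exceedance
  uses a `1e-12` absolute tie tolerance on the statistic.
* The 95% CI multiplier is the normal 1.96 rather than a t quantile:
  deterministic across df, and indistinguishable at the sample sizes this
  method targets.
* The two-sample t-test defaults to the pooled-variance form, preserving
  the regression identity; Welch's form is behind `welch = TRUE`.
  Published tables of the historical tool show t-test p-values about half
  the regression p-values, suggesting one-sided reporting there; this
  package reports two-sided p-values for both and makes no attempt to
  reproduce that halving.
* Output formatting rounds χ² to 2 decimals and p-values to 2 significant
  figures (scientific, upper-case E below 1e-3); files are tab-delimited
  and not byte-compatible with any earlier tool's layout.

## The synthetic-data generator

`genGenotypes()` draws alleles independently at the requested MAF —
Hardy–Weinberg proportions by construction — applies genotype-missingness
independently at a constant rate, and places markers on an evenly spaced
grid. `genCCPhenotypes()` samples affection from a logistic model on the
causal region's carrier indicator (the intercept solved so the expected
case fraction is met); `genQTPhenotypes()` adds a carrier mean shift δ to
Gaussian noise. Everything is deterministic given the seed, and
`writeFixture()` emits MAP/PED/gene files that round-trip the readers
exactly.

What the generator deliberately omits: linkage disequilibrium between
markers, population structure and relatedness, genotyping error, and
departures from HWE. The collapsing statistics operate only on carrier
status, so independent markers exercise every code path; but passing tests
on these fixtures demonstrates correctness of the computation, not
robustness of the scientific inference on real data, where LD between a
region's markers, stratification, and differential missingness between
cases and controls can all distort the carrier table. The data-quality
caveats usual for rare variants on genotyping arrays (poor clustering at
low MAF) apply entirely to the user's upstream QC.

Default simulation conditions used by the test and acceptance suites:
null calibration at n = 2,000 individuals with 10 rare markers drawn
uniformly from MAF 0.005–0.05 over 1,000 replicates (the acceptance script
uses 500); effect recovery with δ = 0.5, σ = 1 over 200 replicates of
n = 600 with 8 rare markers; end-to-end runs at n = 250–2,000 with 25–60
markers. These sizes put the carrier fraction in the few-percent range
typical of gene-level rare-variant pooling and keep a full run on one CPU
within minutes.

## Known limitations

* Binary carrier collapse only: no allele-count scores, no
  frequency/quality weighting, no covariates, no stratified tests, no
  family-based models.
* MAFs are estimated from the analysed sample itself; external reference
  frequencies are not consulted.
* Multi-allelic markers are rejected rather than decomposed.
* Permutation p-values are unadjusted exceedance fractions; genome-wide
  multiplicity is left to the user.
* The per-chromosome drivers process chromosomes serially; at desk scale
  this is adequate, and parallel scheduling is out of scope.
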