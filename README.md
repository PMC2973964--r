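# rvCollapse

Rare-variant collapsing (burden) association tests for case-control and
quantitative traits, on linkage-format genotype data.

## The problem

Genome-wide association studies are well powered for common variants but
not for low-frequency and rare ones (minor allele frequency, MAF ≤ 0.05):
single-marker tests at such frequencies need enormous samples. A collapsing
test recovers power by pooling the rare-variant content of a region — a
gene with optional flanks, or a sliding window — into a single composite
"super-locus" and testing a per-individual summary instead of each marker.

`rvCollapse` implements the binary-carrier form of that idea. Within each
region, markers with 0 < MAF ≤ *c* (default *c* = 0.05) are selected, and
every individual is classified as a **carrier** if at least one minor
allele is observed at at least one of those markers, as a **non-carrier**
if all observed rare genotypes are homozygous major, or **missing** if no
rare genotype was called. Then:

- **Binary traits (case-control).** The region is summarised by the 2×2
  table of carrier status × affection status and tested with Pearson's
  uncorrected chi-squared test,

  χ² = N(ad − bc)² / (r₁ r₂ c₁ c₂),   df = 1,

  where a…d are the cells and r, c the margins. When the smallest observed
  cell falls below a threshold (default 30), where the asymptotic test is
  unreliable, a two-sided Fisher's exact test is added. Empirical p-values
  are available by permuting case/control labels a preset number of times
  and reporting the exceedance fraction.
- **Quantitative traits.** The trait is regressed on the 0/1 carrier
  indicator by ordinary least squares; the slope β equals the carrier vs
  non-carrier mean difference, reported with its SE, 95% CI (β ± 1.96·SE)
  and two-sided p. A pooled-variance two-sample Student's t-test
  (Welch's form optional) can be added; for a binary predictor the pooled
  t equals β/SE exactly.

Inputs are the standard per-chromosome linkage files: a 3-column
(`chr marker bp`) or 4-column PLINK-style (`chr marker genetic-pos bp`) map
file, a pre-Makeped PED file (six identity/phenotype columns, then two
allele columns per marker, `0` = missing allele), and, for gene-centric
analysis, a 5-column gene coordinate file. A Hardy–Weinberg simulator
generates complete synthetic studies with planted effects, so the whole
pipeline is testable without external data.

## Worked example

Simulate a 2,000-individual case-control study (60 markers, six genes, a
carrier odds ratio of 3 planted in the first gene) and analyse it
gene-centrically:

```r
library(rvCollapse)

d <- tempfile()
paths <- simulateStudy(d, nIndividuals = 2000, nMarkers = 60,
                       effect = "cc", oddsRatio = 3, nGenes = 6, seed = 11)
res <- runCCRaVAT(paths["map"], paths["ped"], "demo_out",
                  genesFile = paths["genes"],
                  perm = 1000, permTrigger = 0.05, seed = 11, sig = 0.05)
#> chrom 1: 60 markers, 11 rare (MAF <= 0.05), 6 regions, 1 significant (p <= 0.05)
```

`demo_out/ccravat_chr1.txt` then contains one row per gene:

```
Gene/Wind  Chr  Start   End_Pos  N_SNPs  CaseRV  CaseNoRV  ContRV  ContNoRV  ChiSq  P-val     FisherExPval  Permutations
GENE1      1    100000  149166   (10/5)  266     728       112     894       79.66  4.45E-19  No < 30       Perm: 0/1000 = 0
GENE2      1    149167  198333   (10/0)  0       994       0       1006      0.00   1         1
GENE3      1    198334  247499   (10/3)  145     849       134     872       0.67   0.41      No < 30
...
```

Reading the GENE1 row: of its 10 markers, 5 are rare at MAF ≤ 0.05;
266 of 994 cases but only 112 of 1006 controls carry at least one rare
minor allele, giving χ² = 79.66 (p = 4.45e-19). Every cell is ≥ 30, so
Fisher's exact test is skipped (`No < 30`), and none of 1,000 label
permutations reached the observed statistic (`Perm: 0/1000 = 0`). GENE2
contains no rare markers, so its table is empty by construction and the
convention χ² = 0, p = 1 applies. The run also writes
`ccravat_summary.txt` (regions with p ≤ `sig` only),
`ccravat_permutations.txt`, a per-significant-region SNP list with MAFs
(`GENE1_snps.txt`), and a Manhattan plot of −log₁₀ p against genomic
position. `runQuTie()` is the quantitative-trait counterpart and adds the
trait histogram and per-significant-region carrier/non-carrier histograms.

Shell wrappers live in `inst/scripts/`:

```sh
Rscript inst/scripts/ccravat.R --map chr1.map --ped chr1.ped \
    --genes genes.txt --maf 0.05 --min-cell 30 --perm 1000 \
    --seed 1 --sig 0.05 --out results/
```

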