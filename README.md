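# TriadSeq

Gene expression is shaped by three successive layers of control:
transcription, mRNA turnover, and translation. When all three are
measured simultaneously — nascent transcription rate (TR, GRO-seq),
steady-state mRNA abundance (RA, RNA-seq) and translation activity
(TA, polysome-profiling RNA-seq) — systematic discrepancies between the
layers become quantifiable. TriadSeq is an R package for this kind of
matched three-parameter ("triad") analysis. It is aimed at
transcriptome biologists who have gene-level count or RPKM tables from
the three assays and want to quantify how mRNA stability couples to
translation, and what attenuates that coupling.

## The model and statistics at its core

Working on the log2 RPKM scale, the package defines two per-gene
indices:

- **stability index** = log2(RA/TR) — the discrepancy between mRNA
  abundance and its production rate; operationally a proxy for mRNA
  stability (stable mRNAs accumulate above their production rate), and
- **translation index** = log2(TA/RA) — polysome loading normalized to
  abundance.

Stabilization-by-translation — actively translated mRNAs being shielded
from degradation — predicts a *positive* correlation between the two
indices, even though RA enters them with opposite signs (which by
itself would drive the correlation negative). The package provides:

- **Pairwise log-log regression panel** (`pairwisePanel`,
  `fitLogLog`): OLS of log2 TR and log2 TA on log2 RA, with the
  replicate regression RA2~RA1 as the experimental-noise reference, and
  a **two-slope comparison test** (`slopeCI`, `compareSlopes`): paired
  97.5% Student-t intervals (tail 0.0125, a Bonferroni-style pair) and
  the normal-approximation statistic
  z = (β̂₂ − β̂₁)/√(σ̂²(β̂₁) + σ̂²(β̂₂)), with the two-sided p-value
  evaluated on the log scale so values below 1e-200 stay exact.
- **Permutation null** (`permutationNull`): TR and TA permuted across
  genes (RA fixed), 1000 replicates, reproducing the structural
  negativity of the null, centred at
  −Var(log₂RA)/√((Var RA + Var TR)(Var RA + Var TA)).
- **Standardization experiment** (`standardizeProfiles`): z-scoring
  each log2 profile and showing the index correlation collapses —
  evidence that the coupling lives in the distributional differences
  among the three parameters.
- **Dispersion analysis** (`dispersionSummary`, `histogramOverlay`):
  sd and value range increasing TR → RA → TA.
- **UTR stratification** (`annotateUtrFromGtf`,
  `utrBinnedAssociation`, `selectDefiers`, `utrShiftTest`,
  `groupUtrSummary`): the index coupling as a function of the UTR
  proportion (UTR5+UTR3)/mRNA length, and the UTR shift of "defier"
  mRNAs (stable yet poorly translated).
- **Similarity-stratified distances** (`stratifyDistances`,
  `stratumShiftTest`): Euclidean distances between genes in the
  (stability, translation) plane, stratified by GO-fingerprint
  similarity or protein-interaction confidence.
- **A calibrated synthetic-data generator** (`syntheticTruth`,
  `generateTriad`) — a Gaussian copula on the log2 scale with
  UTR-dependent coupling, replicate noise, functional groups and
  planted defiers — so every stage is testable against known ground
  truth. See the methods vignette for the generative model.

Data enter either as HTSeq-count two-column files (`readCounts` →
`rpkm` → `triadFromCounts`), as a precomputed RPKM matrix
(`readRpkmMatrix`), or from the generator. `runTriadPipeline` runs the
whole analysis from a YAML/list config and writes a manifest.

## Worked example

```r
library(TriadSeq)

truth <- syntheticTruth(seed = 1L)      # 12000 genes, defaults
sim   <- generateTriad(truth)
prof  <- filterExpressed(sim@experiment)  # RPKM >= 1 in >= 1 parameter
tab   <- computeIndices(prof)

indexAssociation(tab)$r
#> [1] 0.1063617
expectedCoupling(truth)                  # model-implied value
#> [1] 0.1119353

perm <- permutationNull(prof, nReps = 1000L, seed = 1L)
perm
#> PermutationResult: 1000 replicates (seed 1)
#>   observed r = 0.1064, slope = 0.1334
#>   null r: mean -0.5197, range (-0.5352, -0.5009); positive: 0

dispersionSummary(prof)
#>   parameter        sd value_range
#> 1        TR 0.9896879    7.024084
#> 2        RA 1.2937850   10.140738
#> 3        TA 1.4952696   12.686148
```

The observed index correlation (0.106) matches the generator's expected
coupling (0.112) within sampling error; not one of the 1000
permutation-null correlations is positive, so the observed positive
coupling is far outside the background model; and dispersion rises from
transcription to abundance to translation. On standardized profiles the
same correlation drops to −0.008 (`standardizeProfiles`), and
`utrBinnedAssociation(tab, sim@utr)` shows the per-bin correlation
falling from 0.38 in the lowest UTR bins to −0.26 in the highest.

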