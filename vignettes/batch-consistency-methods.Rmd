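---
title: "Sizing batch heterogeneity: from band profiles and fingerprints to HWEP and MQS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing batch heterogeneity: from band profiles and fingerprints to HWEP and MQS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BatchHWEP)
```

## The problem

Herbal materials are traded and dosed by batch, but a batch is a population
of plants, not a compound. Two sources of within-batch variability matter
for quality consistency: *genetic* admixture (a batch assembled from
genetically heterogeneous individuals) and *chemical* fluctuation (sample-
to-sample variation of the constituent profile). BatchHWEP quantifies both
on a common scale — information entropy — and converts the within-batch
entropy fluctuation into two operational numbers per batch:

* the **Hardy–Weinberg equilibrium population size** `n` (HWEP): how many
  1-g medicinal units a draw must cover before the within-batch
  fluctuation is balanced at the chosen confidence, and
* the **minimum quantity for one sampling** (MQS): `n` times the unit
  mass, in kilograms — a directly usable sampling prescription.

The motivating system is *Panax ginseng*: five market batches of decoction
pieces (PG01–PG05), cultivated garden ginseng (GG) and forest-grown
ginseng (FG), three samples per batch, genotyped with eight ISSR primers
(dominant markers, 92 scoreable bands) and fingerprinted by UPLC with six
common peaks (three of them the pharmacopoeia ginsenosides Rg1, Re, Rb1).
The package is not ginseng-specific: any dominant-marker binary matrix and
any aligned common-peak area table fit the containers.

## The model

### Entropy of a band profile

For a sample genotyped on a panel that can amplify `m1` bands in total, of
which the sample shows `m2`,

$$H = -C \, \ln(m_2 / m_1), \qquad C = 1/\ln 2 \text{ by default.}$$

`m1` is the *panel-wide* total (92 for the full eight-primer ginseng
panel), not a per-primer count; with `C = 1/ln 2` the entropy is in bits
and `H = -log2(m2/m1)`. A sample showing the full panel carries zero
entropy; `m2 = 0` is rejected as an infinite-entropy degenerate input.
`C` is exposed in `HwepConfig()` but there is no reason to change it: the
bits convention reproduces the reference per-sample entropies exactly to
their printed four decimals (e.g. `bandEntropy(70, 92)` = 0.3943).

### Entropy of a fingerprint

For one sample's common-peak areas $a_i$ (detector response units),

$$S_p = -\sum_i a_i \ln\!\big(a_i / \textstyle\sum_j a_j\big).$$

This is an area-*weighted* entropy (units: response × nats), so it scales
with the injected amount; only its *relative* spread within a batch enters
the sizing, which makes the statistic invariant to a common scale factor.
The sign is fixed so that $S_p \ge 0$; zero-area peaks contribute zero via
the $x\ln x \to 0$ limit.

### From entropy spread to a population size

Per batch, the entropy values of its samples give a relative standard
deviation `RSD = sd/mean` (sample sd, n−1 denominator). The HWEP size is

$$n = 100\,(t_{\alpha,n-1} + u_\beta)^2\, \mathrm{RSD}^2,$$

with the quantile sum fixed at 10.8 (α = β = 0.05) rather than re-derived
at run time. `n` is quadratic in RSD and zero for a perfectly homogeneous
batch. MQS is `n × unitMass / 1000` kg with a 1.000 g default unit.

An alternative printed formulation, `n = K · RSD²` with K = 25.6, is
available as `formulaMode = "eq5_literal"`. It is **not** the default for
either data type because it cannot reproduce the reference batch tables:
the two modes differ by the fixed factor `100·10.8²/K ≈ 455.6`, and only
the `table_consistent` form recovers both the genetic values
(e.g. PG01: RSD 6.16% → n 44.30) and the chemical ones (PG04: 5.66% →
37.37). The literal mode is kept as a regression-guarded code path and
announces itself with a message when used.

```{r}
ref <- ginsengReferenceData()
gen <- batchHwepReport(data.frame(batch = ref$bandCounts$batch,
                                  H = bandEntropy(ref$bandCounts$tnb, 92)))
formatHwepReport(gen)
```

Note the PG05 row: the reference table prints an MQS of 0.998 kg against
`n = 99.80`, which contradicts the 1 g unit used by every other row; the
package always recomputes (0.100 kg) and never copies printed summaries.

### Numerical sensitivity of the chemical table

The shipped reference fingerprint entropies are printed to three
significant figures. Because `n ∝ RSD²` and a batch RSD is a small spread
of three similar values, that rounding is amplified roughly five- to
ten-fold in `n`: recomputing from the printed entropies reproduces most
published chemical `n` values within about 1%, but deviates by 3–4% for
the tightest batches (PG01 six-peak panel, GG on both panels, PG04 on the
three-ginsenoside panel). The printed RSD column shows the original
computation used unrounded areas (GG: printed 8.97% vs 8.79% from the
rounded entropies). This is a property of the published precision, not of
the arithmetic; the genetic table, whose inputs (band counts) are exact
integers, reproduces essentially exactly.

## Similarity and clustering

Genetic similarity between binary profiles supports the Dice (default),
Jaccard and simple-matching coefficients; Dice is the default because it
is the prevalent choice for dominant-marker data, and the coefficient used
is carried in the object and every report. Distances are `1 − similarity`
with no further transformation. UPGMA (average linkage) produces an
ultrametric tree with merge height equal to half the merged average
distance; equal-height merge candidates are resolved by the
lexicographically smallest sorted leaf-id concatenation, which makes trees
bit-reproducible across platforms regardless of input order. Fingerprint
similarity is the congruence (cosine) coefficient of area vectors against
a generated reference — by default the cohort mean chromatogram, the
convention of the pharmacopoeia fingerprint-similarity software; the full
pairwise matrix is also returned for heatmaps.

Common peaks are matched on relative retention time (RRT; ratios to a
reference peak) with a default tolerance of 0.02, an order of magnitude
looser than the RRT repeatability a validated method achieves (< 0.3%),
and far tighter than typical peak spacing. The reference peak defaults to
the largest-area peak of the first sample and is overridable; raw-RT
matching is available by flag for instrument-stable cohorts.

## Cross-validation and correlation

`loocvGenetic()` re-runs the entire sizing once per excluded primer (eight
folds on the reference design), `loocvChemical()` once per excluded common
peak (six folds); summaries are means ± standard errors (`sd/√folds`)
per batch, matching how such error bars are conventionally reported. A
fold that leaves any sample with no band (or an all-zero area vector) has
no finite entropy; it is flagged, excluded from summaries, and warned
about rather than silently imputed.

Genetic and chemical heterogeneity are correlated with Spearman's rank
correlation on the per-batch full-data `n` values (seven batches). These
reproduce the published coefficient exactly (ranks are robust to
rounding): rho = 6/7 ≈ 0.857 for both the six-peak and three-ginsenoside
panels. With n = 7 pairs the p-value is computed by full enumeration of
all 5040 rank permutations (exact p = 0.0238 two-sided); the commonly
quoted p = 0.014 is the asymptotic t approximation, which the
implementation switches to above `exactMax = 9` (9! permutations being
the practical enumeration limit). Using LOOCV fold means instead of
full-data `n` is possible by passing those summaries, but full-data `n`
is the default input because it is exactly reproducible from the shipped
tables.

`groupCompare()` wraps the conventional contrasts (Welch's t, paired t,
one-way ANOVA with Fisher's-LSD pairwise t-tests and a compact letter
display); all-identical inputs report the exact-equality case (p = 1)
rather than erroring. Letters follow the standard semantics: groups
sharing a letter are not significantly different.

## The synthetic-data generators

Real band matrices and raw areas for the reference cohort are not
published, so the package ships generators whose defaults *are* the study
conditions:

* `bandDesign()`: eight primers with the published per-primer band counts
  (92 bands), seven batches of three samples. Each batch draws a founder
  profile (band present with probability set to the batch's observed band
  fraction) and derives each sample by independent per-band flips;
  `flip_prob` (0.01–0.07 across batches, graded GG-low to FG/PG03-high) is
  the single heterogeneity dial. Independent flips are the simplest
  mechanism producing the observed homogeneous-vs-admixed contrast;
  linkage between bands is deliberately not modelled.
* `peakDesign()`: six common peaks with mean areas on the 10⁴–10⁵
  response-unit scale, multiplicative log-normal noise parameterized by a
  per-batch CV (0.05–0.45, graded to the published chemical contrast).
  Log-normal noise guarantees positive areas and maps CV directly onto
  the RSD scale of the sizing model. Retention-time jitter (CV 0.002) is
  available for exercising peak matching.

Both generators take a mandatory seed and are bit-reproducible without
disturbing the caller's RNG stream. What passing tests on synthetic data
show is that the pipeline *recovers* heterogeneity orderings it is fed
(HWEP n monotone in `flip_prob` and in area CV over hundreds of seeded
replicates at the study's 3-samples-per-batch scale); they do not show
that real gels or chromatograms follow these noise models — real band
calls are correlated through linkage and scoring, and real peak areas
co-vary through extraction yield, neither of which is simulated.

## Numerical choices and edge cases

* Full precision is kept internally; rounding (entropy 4 dp, RSD 2 dp
  percent, n 2 dp, MQS 3 dp) happens only in `formatHwepReport()`.
* Two all-zero band profiles are defined as identical (similarity 1, with
  a warning) under Dice/Jaccard, whose denominators vanish.
* Singleton batches carry no pairwise similarity and are excluded from
  within-batch summaries with a warning.
* `batchRSD()` refuses a zero mean (a batch of all-full-panel samples has
  no relative scale) and fewer than two values.
* Monomorphic-absent bands (never observed) are legal but reported at
  construction, since a band that never appears would not have been
  scored from a gel.
* Test-suite and example problem sizes (200-replicate monotonicity runs,
  300-replicate dispersion-recovery runs, 2 × 3 × 30-band designs) were
  chosen as the smallest scales at which the monotonicity and recovery
  statements are stable across seeds.

## Limitations

* The sizing model takes the quantile sum 10.8 as a constant; it is not
  re-derived from α, β, or the fold sample size.
* Dominant markers carry no heterozygote information; "genetic entropy"
  here is a band-count statistic, not an allele-frequency one.
* Fingerprint similarity uses common-peak vectors, not full-curve
  correlation; raw chromatogram processing (baseline, peak picking) is
  out of scope, as are gel image analysis and band sizing.
* The published within-batch similarity means and LOOCV error bars depend
  on unpublished raw data and are treated as plausibility anchors for the
  generators, not as reproducible targets.
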