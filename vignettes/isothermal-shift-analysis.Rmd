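---
title: "Detecting drug-induced thermal stability shifts with isoshift"
author: "isoshift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting drug-induced thermal stability shifts with isoshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoshift)
```

## The two readouts of a thermal shift

When a small molecule binds a protein it usually stabilizes (or
occasionally destabilizes) the folded state, shifting the temperature at
which the protein denatures and aggregates out of solution. Two
proteome-wide experimental designs read this shift out by mass
spectrometry:

* **Thermal gradient (TPP / MS-CETSA).** Heat aliquots of a lysate to a
  ladder of temperatures, quantify the soluble fraction of every protein
  at every temperature, fit a melting curve per protein and condition,
  and compare melting temperatures: the effect size is a Tm shift
  (a horizontal difference between curves).
* **Isothermal shift assay (iTSA).** Heat all samples to one carefully
  chosen temperature and compare the soluble fraction between drug- and
  vehicle-treated replicates directly: the effect size is a solubility
  difference at that temperature (a vertical difference between curves).

For a fixed mass-spectrometry budget the isothermal design spends its
samples on replication rather than on temperatures: ten samples give
five replicates per condition, while a standard two-replicate,
ten-temperature gradient needs forty. The package exists to make the
statistical consequences of that trade-off concrete, testable and
reusable.

## The melting model

All simulated and fitted curves use a three-parameter sigmoid in
reciprocal temperature for the soluble fraction,

$$ f(T) = \frac{1 - \pi}{1 + e^{-(a/T - b)}} + \pi, $$

with steepness numerator $a > 0$ (on the Celsius scale), offset
$b > 0$ and high-temperature plateau $\pi \in [0, 1)$. The melting
temperature is the 0.5-crossing, available in closed form:

$$ T_m = \frac{a}{b + \log(1 - 2\pi)}, \qquad \pi < 0.5 . $$

The analytic slope at $T_m$ (the inflection slope when $\pi = 0$,
$-a/4T_m^2$) is the "curve slope" quantity used by the gradient
quality filter. Temperatures are degrees Celsius throughout; no Kelvin
conversion is applied inside the $a/T$ term, so $a$ and $b$ are
interpreted on that scale. A two-state thermodynamic model and
four-parameter logistic variants are deliberately out of scope.

The slope criterion is evaluated at the inflection point (the steepest
point of a plateau-free curve). An alternative convention evaluates the
minimal slope over the fitted range; for the curves this package fits
the two agree closely, and the closed form is exactly reproducible.

```{r melt}
mc <- MeltCurve(a = 520, b = 10, plateau = 0)
meltingTemperature(mc)
fractionSoluble(mc, c(45, 52, 60))
slopeAtTm(mc)
```

## What the simulator emulates -- and what it does not

`simConfig()` fixes the study conditions; `sampleProteome()` draws a
ground-truth proteome and `simulateIsothermal()` /
`simulateGradient()` assay it. The defaults encode:

* **Tm distribution**: normal with median 52 °C and IQR 8 °C
  (quartiles ~48/56 °C), truncated to [37, 70] °C -- the shape of a
  human leukemia-cell proteome. A normal is the simplest form matching
  the displayed quartiles; nothing in the analysis depends on the
  exact family.
* **Targets**: 1% of proteins (the rough prevalence of targets of a
  promiscuous kinase inhibitor in such a proteome), with true Tm shifts
  drawn from Normal(+4, 2) °C. The mean of +4 gives a mixture of easy
  and hard targets; negative draws produce destabilization, which
  occurs in practice.
* **Curve shape**: offset $b \sim U(12, 18)$ and plateau
  $\sim U(0, 0.15)$, giving melt transitions 10--15 °C wide whose
  inflection slopes straddle the -0.06 /°C quality threshold, as real
  proteome curves do.
* **Abundance and evidence**: log2 abundance ~ Normal(20, 2) (arbitrary
  reporter units); MS/MS and unique-peptide counts are Poisson with
  rates increasing in log-abundance, so low-abundance proteins fail
  identification filters more often -- the MS/MS sampling bias of
  data-dependent acquisition.
* **Noise**: multiplicative log-normal reporter noise with CV 5%.
  The within-group CV of real reporter intensities is a free parameter
  of the assay, not a published constant; 5% makes the 5v5 design at
  FDR 0.001 detect most +4 °C targets while leaving smaller shifts
  genuinely hard, which is the regime the method targets.
* **Missingness**: logistic dropout in log2 intensity (midpoint 14,
  scale 1.5), i.e. values are missing not at random, preferentially at
  low intensity, reproducing the abundance/detection confound.

The simulator works at the protein level. It does not model peptides,
TMT isotope-impurity ratio compression, multi-plex bridging, or
in-cell biology (dose, ATP competition, secondary effects); conclusions
drawn from it concern the statistical machinery only. Passing tests on
these simulations show the pipeline is calibrated and powered under the
stated noise model -- not that any particular real dataset satisfies
that model.

## The isothermal analysis pipeline

`runITSA()` chains the stages, each also exported on its own:

1. **Confidence filtering** (`filterHighConfidence()`): at least 1
   unique peptide, 2 MS/MS spectra and 2 valid reporter intensities;
   reverse-decoy and contaminant flags are dropped (standard practice
   for MaxQuant tables; the simulator emits none by default).
2. **log2 and quantile normalization** (`normalizeLog2()`): log2 first,
   then rank-based quantile normalization. Because the map is
   rank-based, the order of log2 and normalization affects only the
   reference scale; fixing log2-first makes the reference the mean of
   log2 order statistics. Missing values take no part in the reference
   distribution and stay missing; ties receive average ranks; columns
   with fewer than two present values are flagged and left out of the
   reference.
3. **Variance prior** (`estimateVariancePrior()`): the scaled-F model
   for per-protein variances fitted by digamma/trigamma moment
   matching; no excess dispersion of log-variances gives
   $d_0 = \infty$ (a common variance).
4. **Moderated t** (`moderatedTTest()`): pooled per-protein variance on
   present values, shrunk toward the prior; two-sided p-values on
   $d_0 + d$ degrees of freedom. Proteins with fewer than two present
   values per condition are reported untested; no imputation anywhere.
5. **BH and classification** (`bhAdjust()`, `classifyAndRank()`):
   strict q-value cutoff (matching "FDR < 0.001" semantics), optional
   absolute fold-change cutoff (default 0, since fold-change cutoffs
   are experiment-specific configuration).

```{r pipeline}
cfg <- simConfig(nProteins = 1000, seed = 7)
truth <- sampleProteome(cfg)
tq <- simulateIsothermal(truth, config = cfg)
tq
res <- runITSA(tq, qCutoff = 0.001)
head(as.data.frame(res[res$significant,
    c("protein_id", "log2_fc", "t_mod", "q_value")]))
sum(res$significant); sum(truth$is_target)
```

### Numerical corner cases

Fully noiseless data have zero within-group variance everywhere, so the
ensemble variance prior is undefined and `runITSA()` raises a
degenerate-data error; exact fold-change recovery on noiseless input is
available through `moderatedTTest()` with a fixed prior and
`normalize = FALSE` (quantile normalization is also counterproductive
there: with rank-stable columns it collapses replicate variation
entirely). p-values are clamped to the smallest positive double so that
underflow cannot produce an invalid 0. With very low noise and few
proteins, quantile normalization can return identical values for a
protein whose rank is stable across columns; such zero variances are
excluded from prior estimation.

## Gradient comparator

`fitMeltingCurves()` fits the sigmoid to every
(protein, condition, replicate) fold-change series by bounded
Levenberg--Marquardt with three deterministic restarts ($b$ started at
10, 7, 13 and $a = b\,T_{mid}$ from the series half-height, plateau 0);
sigmoid fits are initialization-sensitive and the restarts make the fit
reproducible without randomness. $R^2$ is computed on the fold-change
scale (the scale of fitting). Quality control keeps fits with
$R^2 > 0.8$, slope at $T_m < -0.06$ /°C and plateau $< 0.4$, all
strict, plus optimizer convergence. `buildTmLibrary()` averages
QC-passing vehicle Tm values per protein.

Two properties of the fold-change parameterization are worth knowing:

* Series are referenced to the lowest gradient temperature (37 °C).
  For proteins already melting at 37 °C the normalized curve's
  0.5-crossing sits above the raw-curve Tm -- an offset of the
  normalization itself, present even without noise, growing as Tm
  approaches the gradient edge (~+0.3 °C at Tm = 46 °C with the default
  curve shapes).
* Tm estimates from 5% multiplicative noise are accurate to a few
  tenths of a degree for centrally melting proteins (median absolute
  error well under 1 °C).

`tppSignificance()` calls a protein shifted when all four fits pass QC,
the two per-replicate Tm shifts share a sign, the smaller |shift|
exceeds the vehicle-vehicle Tm difference, and the smaller |shift|
exceeds 1 °C. The first three rules capture the replicate-concordance
logic of published gradient workflows; the 1 °C floor is this package's
addition, because the concordance rules alone compare noise against
noise -- about 20% of quality-concordant null proteins pass them
regardless of how precise the fits are -- and because ~1 °C shifts are
at the detection limit of a two-replicate gradient. The rule is a
deliberately simple surrogate: it is not a reimplementation of any
published gradient significance test, and counts produced with it are
comparable only within this package.

## Replicate subsampling and power

`runSubsampledAnalyses()` re-analyzes every paired k-replicate subset
of a 5v5 experiment exactly as a fresh experiment -- filtering with the
valid-value rule re-applied to the selected columns, normalization and
variance prior recomputed per subset -- at FDR < 0.1. With five
replicates per condition there are 25 paired 4-replicate comparisons
and 100 each at k = 3 and k = 2. Proteins significant in more than 80%
of comparisons form the powered set (a 0.8 power estimate at that
depth); `powerCurve()` tabulates how the powered count grows with k.

The Type-I check flags proteins significant in more than 10% of the
2- or 3-replicate comparisons yet significant neither in the full
design nor in any 4-replicate comparison
(`crossDepthTypeIFlags()`); on null simulations this set is empty in
the overwhelming majority of runs. All three thresholds are strict
inequalities.

```{r subsample}
rep3 <- runSubsampledAnalyses(tq, k = 3, fdr = 0.1)
rep3
```

## Design benchmarking

`compareDesigns()` simulates both designs from one ground-truth
proteome and scores them against the truth labels: the isothermal arm
via the full pipeline at FDR < 0.001, the gradient arm via curve
fitting and the surrogate call. Sensitivity is computed among
detectable proteins (those surviving filters / testable in that arm)
so coverage differences do not masquerade as power differences; the
detectable counts are reported alongside. Because the gradient arm
uses the surrogate rule, cross-design claims are directional (which
arm finds more of the truth under matched conditions), never
reproductions of published target counts. `temperatureSweep()` repeats
the isothermal arm at several assay temperatures on one proteome and
reports the overlap structure of the called sets; nearby temperatures
recover largely overlapping targets, distant ones diverge, and
sensitivity decays as the assay temperature moves away from a target's
Tm.

## Problem sizes and reproducibility

Every stochastic function takes its seed from `simConfig()` or an
explicit `seed` argument and is fully reproducible. The shipped test
suite and the acceptance script run simulations at 150--10,000 proteins
(10,000 for null-calibration checks, 3,000 x 20 seeds for
false-discovery calibration, 1,500 per seed for power curves, 800 per
seed for null Type-I checks, 600 x 10 seeds for the design comparison,
200 for curve-fit recovery) -- sizes chosen so the whole suite runs on
a laptop in minutes while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

* The generator's constant-CV noise makes per-protein variances nearly
  homogeneous; real reporter data show intensity-dependent variance.
  The pipeline deliberately omits an intensity-dependent variance
  trend and robust prior options.
* Melting temperatures near or below the lowest gradient temperature
  are biased by the fold-change reference (see above); gradient
  designs cannot measure what has already melted at their first
  temperature.
* Missing-not-at-random dropout interacts with small-replicate
  subsampling: proteins in the dropout zone carry fewer observed
  values and occasionally produce borderline calls at k = 2 or 3.
  This is a property of low replication under censoring that the
  subsampling procedure is designed to expose, not an artifact of the
  implementation.
* The proteinGroups reader/writer implements the single-plex,
  protein-level MaxQuant dialect (0 = missing, "+" flags); peptide
  tables, multi-plex layouts and raw spectra are out of scope.
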