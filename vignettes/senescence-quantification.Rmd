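---
title: "Quantifying replicative senescence in epithelial stem-cell cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying replicative senescence in epithelial stem-cell cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senesceq)
```

## The scientific setting

Primary human epithelial keratinocytes — from skin, limbus, conjunctiva or
oral mucosa — can be propagated in vitro only for a finite number of
passages before the culture senesces. Three kinds of quantitative readout
track this replicative ageing, and `senesceq` implements the machinery for
all three:

1. **Clonogenicity and lifespan.** At each passage a known inoculum is
   plated and the colony forming efficiency (CFE, the fraction of plated
   cells that found a colony) is scored, together with the cell yield at
   harvest and the fraction of *aborted* colonies (colonies of terminally
   differentiated cells). From these the package derives clonogenic cell
   numbers, per-passage and cumulative population doublings, and the
   passage at which half of all colonies are aborted.
2. **Expression trajectories.** Bulk RNA-seq FPKM values for every gene and
   isoform, measured in several independent cultures at successive
   passages, are filtered, normalized and screened for genes with a
   *constant* up- or down-regulation over time — candidate senescence
   drivers or markers. Candidate lists are then tested for annotation-term
   overrepresentation.
3. **Single-cell fluorescence.** Quantitative telomere FISH gives a
   per-cell relative telomere length (RTL); diffuse stains are quantified
   as corrected total cell fluorescence (CTCF).

Because such studies rarely deposit raw data, the package ships a seeded
synthetic-data module that generates every input with planted ground truth,
so the entire pipeline is testable end to end.

## Lifespan metrics

The clonogenic cells founding passage $p$ are $I_p = \mathrm{inoculum}_p
\times \mathrm{CFE}_p$. Population doublings within the passage are

$$\mathrm{PD}_p = \log_2\!\left(\frac{\mathrm{UCY}_p}{I_p}\right),$$

where UCY is the cell yield at harvest; the cumulative doublings are their
sum over the proliferative passages. The multiplier form
$\mathrm{PD} = (1/\log_{10} 2)\,\log_{10}(\mathrm{UCY}/I)$ with
$1/\log_{10}2 = 3.3219\ldots$ is the same quantity; `senesceq` computes the
exact binary logarithm rather than a truncated decimal constant (the
truncation to 3.322 would inflate every doubling count by about 0.006%).
By definition, doubling the yield at a fixed founder count adds exactly one
population doubling.

A passage with CFE $=0$ contributes zero doublings and *terminates* the
lifespan; records claiming renewed growth after exhaustion are rejected as
inconsistent rather than silently dropped. Whether cumulative doublings
should use each passage's own clonogenic count or the initial one is a
genuine modelling choice; the per-passage count is the default (each
passage's expansion is measured against the cells that actually founded
it), and `per_passage_clonogenic = FALSE` switches to the fixed-founder
convention.

qPCR support is deliberately minimal: absolute quantification is a
normalization the user performs; relative quantification is the
$2^{-\Delta\Delta C_t}$ method, with $\Delta C_t$ = target − reference
cycle threshold per sample and $\Delta\Delta C_t$ = sample − calibrator.
`marker_vs_passage_regression()` fits lifespan on an initial marker level
by ordinary least squares, the standard way of asking whether a stemness
marker (e.g. $\Delta N$p63$\alpha$) predicts replicative lifespan.

## The FPKM trend pipeline

`run_fpkm_pipeline()` applies, in a fixed order:

1. **Failure filter** — a feature whose FPKM status is `fail` in any
   culture is removed everywhere.
2. **Low-expression filter** — a feature is removed globally if in at
   least one culture the sum of its FPKM values over the time-points is
   below `sum_threshold` (default 5) *or* its first time-point is below
   `initial_threshold` (default 1). Both comparisons are strict, so
   boundary series (sum exactly 5, initial exactly 1) are kept.
3. **Housekeeping anomaly flagging** — a time-point whose housekeeping
   FPKM deviates from the median of its own series by more than
   `fold_limit` (default 3, `Inf` disables) is excluded from trend
   classification in that culture. An inflated housekeeping measurement
   would otherwise masquerade as coordinated down-regulation of every
   other gene; flagging formalizes the ad-hoc exclusion one would do by
   eye. The median is the reference because with as few as three
   time-points a single corrupted value must not drag the reference
   itself.
4. **Housekeeping normalization** — each value is divided by the
   housekeeping FPKM (default `GAPDH`) at the same time-point and culture,
   removing depth effects under the constant-dynamics assumption. The
   housekeeping series itself must be strictly positive at every retained
   time-point; a zero is an error naming the offending time-point.
5. **Baseline normalization and log2 evolution** — each series is divided
   by its first retained value (so every feature starts at 1) and
   log2-transformed (so it starts at 0 and later values are fold changes
   relative to time 0). Features with a zero first value are excluded with
   a logged reason rather than pseudocounted — the baseline is undefined
   and the low-expression filter removes almost all such series anyway; a
   `pseudocount` argument exists but defaults to 0.
6. **Trend classification** — a series is `up` when every consecutive
   log2 difference exceeds `min_step`, `down` when every difference is
   below `-min_step`, else `none`. `min_step = 0` by default: any strictly
   monotone change counts, and stringency is added explicitly, not
   implicitly. Classification is antisymmetric under time reversal and
   invariant under positive scaling of the raw series (scaling cancels in
   baseline normalization).
7. **Consensus** — a feature's consensus is the direction shared by *all*
   cultures; any disagreement or abstention gives `none`.

The coefficient of variation (sample SD over mean) of each raw series is
reported as a quality metric only; it does not filter, since a hard CV cut
would double-count the low-expression rule. Statistical significance of
candidate trends is the business of the slope test in the statistics
module (fit of log2 evolution on time pooled across cultures, BH-adjusted),
which `run_all()` applies to every consensus candidate.

## Statistics

* `fit_linear()` — ordinary least squares with slope standard error,
  residual variance and $R^2$ (defined as 1 for an exact fit, including
  constant series, where the usual ratio is 0/0).
* `compare_timeseries_ancova()` — the classical two-regression
  equality-of-slopes test: independent fits to each series, pooled
  residual variance $s^2 = (\mathrm{SSE}_a + \mathrm{SSE}_b)/(n_a+n_b-4)$,
  statistic $(b_a - b_b)/\sqrt{s^2(1/S_{xx,a} + 1/S_{xx,b})}$ on
  $n_a+n_b-4$ df, two-sided. The slope test is primary; the intercept
  comparison is reported secondarily. Two exactly identical perfect fits
  give $p = 1$ by convention (zero evidence of different dynamics); exact
  fits with different slopes give the $p \to 0$ limit.
* `bh_fdr()` — Benjamini–Hochberg step-up q-values. Note that the BH
  *adjustment as a whole* is not an idempotent map (reapplying it to
  q-values inflates them again by $m/i$); what is stable is the step-up
  monotone-enforcement stage, and fully tied adjusted vectors are fixed
  points. The package's tests check those true properties.
* `one_way_anova()`, `students_t()` — standard fixed-effects F and
  pooled-variance t. Degenerate inputs follow the limit conventions:
  identical group means give $F = 0,\ p = 1$; zero pooled variance with
  equal means gives $p = 1$, with unequal means $p = 0$ plus a warning.
  With two groups, $F = t^2$ exactly.
* `multiple_range_bonferroni()` — all $m = k(k-1)/2$ pairwise pooled
  t-tests, each judged at $\alpha/m$. This is the common reading of the
  "multiple range test with Bonferroni analysis" of legacy statistics
  packages; an LSD-style studentized-range variant is deliberately not
  offered.

## Overrepresentation

`fisher_overrepresentation()` tests one annotation term by the one-sided
hypergeometric upper tail $P(X \ge k)$ with $X \sim
\mathrm{Hypergeom}(N, K, n)$ — $k$ query hits among $n$ query genes, $K$
term members among $N$ background genes — and reports the fold enrichment
$(k/n)/(K/N)$ (0 when $k = 0$). Only over-representation is tested;
depletion is not analysed. `enrich_table()` runs a collection of terms,
adjusts by BH across all tested terms, and skips terms with no members in
the background. When no background is supplied, the union of all
annotation members plus the query is used — the query is included so the
containment precondition holds by construction; when the user supplies a
background, query genes outside it are an error, not silently dropped.
Terms are tested independently: no parent–child correction over an
ontology graph is attempted, so q-values for nested terms are correlated.

## Image quantification

Images are integer matrices (16-bit range), pixel coordinates 0-based and
row-major; rectangular ROIs use half-open bounds and arbitrary regions use
explicit pixel lists. For Q-FISH:

* `subtract_background()` removes a scalar level, or a level estimated as
  the median of a matched reference channel outside the nuclear ROIs, and
  clips at zero.
* `detect_spots()` thresholds within the cell ROI and labels 8-connected
  components; components smaller than `min_area` (default 2 px) are
  discarded as single-pixel noise. The default threshold — ROI mean plus
  three ROI standard deviations — is a conventional bright-spot heuristic;
  pass an explicit threshold for reproducible pipelines. The published
  procedures this mirrors delegate spot measurement to interactive tools
  without stating an algorithm, so the detection rule here is the
  package's own, stated formalization.
* `compute_rtl()` sums mean spot intensity × spot area over a cell's
  spots. "Intensity value" is read as the *mean* spot intensity, so the
  product is the spot's integrated intensity; summing raw pixel values
  directly gives the identical number by construction.

CTCF uses the standard definition: integrated density over the cell ROI
minus cell area × mean background-ROI intensity. It may legitimately be
negative (a cell dimmer than the chosen background) and is reported as-is.
`compare_rtl_groups()` feeds per-cell RTL values into the Bonferroni
multiple range test, mirroring how 10–20 per-cell RTL values per condition
are compared in practice.

## The synthetic-data module

The generators define the study conditions under which everything is
tested; their defaults are fixed once and mirror a four-culture,
three-passage design:

* **FPKM series** (`gen_fpkm_dataset()`): trending features follow an
  exact geometric law, expected value $b \cdot f^{\pm t}$ with
  `fold_per_step` $f = 2$ — i.e. a constant log2 slope of ±1 per step,
  matching the log2-evolution representation the pipeline works in.
  Directions are assigned deterministically (first block up, next block
  down, rest flat) so fractions are exact. Noise is multiplicative
  lognormal with mean 1 and coefficient of variation `noise_cv`: FPKM is
  positive and right-skewed, and no published variance model exists for
  these data, so `noise_cv = 0.1` is a convention chosen as a realistic
  bulk-RNA-seq replicate CV, not a literature value. Baselines are drawn
  log-uniformly from 5–100 FPKM so that planted trend features stay above
  the low-expression thresholds by construction — recovery tests then
  probe the classifier, while the filters are exercised by dedicated
  hand-built boundary fixtures. The housekeeping gene is appended with a
  constant expected value.
* **Colony series** (`gen_colony_series()`): expected CFE decays
  exponentially and is forced to 0 at the planted exhaustion passage;
  per-passage doublings decline linearly from `doublings0` (default 6, a
  vigorous early-passage expansion) to 0 at exhaustion — senescing
  cultures expand less each passage; the aborted-colony fraction ramps
  linearly to 1. None of these shapes is prescribed by published data;
  they are the simplest forms with the qualitatively correct monotonicity,
  and the planted per-passage doublings make the closed-form cumulative
  sum an exact oracle at zero noise.
* **FISH images** (`gen_fish_image()`): constant-intensity axis-aligned
  pixel blocks of exact area on a constant background, kept at least one
  pixel apart so they remain distinct 8-connected components. Realism
  (point-spread functions, intensity gradients) is explicitly not a goal:
  the design goal is an exact, integer ground truth.
* **Diffuse images** (`gen_diffuse_image()`): a single cell region of
  exact area on a uniform background, with planted CTCF
  $= \mathrm{area} \times (\mathrm{cell} - \mathrm{background})$.

All generators take a seed, restore the caller's RNG state, and are
byte-deterministic: identical configuration and seed give identical
output.

What the synthetic data does *not* emulate — and hence what passing tests
do not show about real data: library-size and gene-length biases upstream
of FPKM, overdispersed count noise and its mean–variance relationship,
batch and culture-adaptation effects, partially failed measurements,
optical blur and uneven illumination, and touching or out-of-focus
telomeric spots. The pipeline's correctness on its stated contracts is
tested; its robustness to those real-data pathologies is not claimed.

## Problem sizes and numerical checks

The test-suite simulations use sizes chosen to make the checked properties
sharp at desk scale: trend recovery on 1,000 features × 4 cultures at
noise CV 0.1 (sensitivity and false-direction rate over 200 planted
trends); slope-test calibration over 2,000 null replicates with n = 6
points per series (the rejection rate at $\alpha = 0.05$ is checked
against a [0.035, 0.065] band) and power against a slope offset of five
residual SDs; Fisher tail probabilities against exhaustive
binomial-coefficient enumeration for every 2×2 configuration with
$N \le 60$ (agreement to $10^{-10}$); and 20 noiseless plus 20 noisy FISH
images (4 cells each). For the noisy images the additive noise SD is one
tenth of the weakest spot intensity (SNR 10); with 5–10 spots of 16–36 px
per cell, the sampling error of a cell's RTL estimate is roughly
$\sigma/(\bar I \sqrt{A_{\mathrm{tot}}}) \lesssim 0.5\%$, so the 2%
recovery band is a property of the estimator, not of lucky seeds.

## Known limitations

* FPKM is taken as given; no alignment, quantification, isoform assembly
  or batch correction is performed, and no negative-binomial differential
  test is reimplemented — the slope test plus FDR is the package's
  significance surrogate for trend candidates.
* Three-point series make "monotone" a weak criterion (two sign
  conditions); `min_step` exists precisely to add stringency when the
  time-points are few.
* The multiple range test assumes approximate normality and common
  variance within groups; it is not a nonparametric procedure.
* Two-way ANOVA is out of scope; nothing in the artifact produces a
  factorial design.
* ROIs are inputs; the package does not segment nuclei or cells.
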