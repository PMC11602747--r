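---
title: "Methods: soil quality and yield sustainability indices for fertilization trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil quality and yield sustainability indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilqi)
```

## The problem

Long-term fertilization trials ask whether replacing part of a chemical
fertilizer dose with organic fertilizer improves the soil and stabilizes the
crop. `soilqi` models the canonical design for this question: a randomized
complete block experiment with five regimes — unfertilized control (CK),
chemical fertilizer only (CF), and 75/25, 50/50 and 25/75 chemical/organic
blends (M1, M2, M3) — six replicate blocks (30 plots), one seed-cotton yield
per plot and year over a decade, and a final-year soil panel of twelve
indicators: bulk density (BD), pH, organic matter (SOM), total N, ammonium N,
nitrate N, alkali-hydrolyzable N, available P, available K, and the urease,
catalase and alkaline-phosphatase activities.

Two composite statistics summarize the outcome. The **soil quality index**
compresses the twelve-indicator panel into one number per plot; the
**sustainable yield index** compresses each plot's ten-year yield series into
a high-and-stable measure. The package computes both, the inferential layer
around them, and a synthetic trial generator so the full analysis is testable
without any field data.

## Soil quality index

### Scoring

Each indicator is mapped to a score in $[0,1]$ by direction-aware min-max
scaling: $S_i = (X_i - X_{\min})/(X_{\max} - X_{\min})$ for "more is better"
indicators and $S_i = (X_{\max} - X_i)/(X_{\max} - X_{\min})$ for "less is
better". Design choices here:

* **Bounds are computed over all 30 plots jointly**, never per treatment: a
  single shared ruler is required for cross-treatment comparison. With
  data-derived bounds every indicator has at least one plot scoring 0 and one
  scoring 1. Fixed external bounds can be supplied instead (scores are then
  clipped into $[0,1]$); `predict()` on a fitted `soil_quality` object uses
  the stored bounds so new plots are measured on the fitted ruler.
* **Direction map.** BD and pH default to "less is better", the ten
  nutrient/enzyme indicators to "more is better". Dense soil impairs root
  function, which makes BD's direction uncontroversial; pH is genuinely
  ambiguous on calcareous soils near 7 (values rising toward 7.3 could count
  either way), so the direction map is an explicit argument
  (`soil_indicators(c(ph = "more_is_better"))`) rather than a constant.
* **Degenerate indicators** ($X_{\max}=X_{\min}$ with data-derived bounds)
  raise an error naming the indicator; an explicit option drops them with a
  warning instead. Silent behavior in either direction would corrupt the
  weight normalization unnoticed.

### Weighting

The indicator panel is standardized (z-scores) and the correlation matrix
eigendecomposed. Components are retained by the Kaiser rule (eigenvalue
$\ge 1$) by default, configurable to a fixed count or a cumulative-variance
threshold, because no single retention convention is universal. Each
indicator's communality $c_i$ — the sum of its squared loadings on the
retained components — measures how much of it the retained structure
explains, and the weights are $W_i = c_i / \sum_j c_j$, so $\sum W_i = 1$ by
construction. The per-plot index is $SQI = \sum_i W_i S_i \in [0,1]$.

Two conventions deserve note. PCA operates on the standardized **raw**
indicator values, not on the min-max scores: communalities are conventionally
extracted from standardized measurements, and scoring direction is irrelevant
to a correlation matrix anyway (a `pca_on = "scores"` switch exposes the
alternative). And eigenvalues below $10^{-10}$ are treated as numerical zero
(rank-deficient panels log a note), which only matters when indicators are
exact linear combinations.

Published analyses of this design sometimes print SQI values well above 1
(e.g. a range of 1.05–8.71), which is impossible under $\sum W_i = 1$ with
$S_i \in [0,1]$; such values imply an undocumented rescaling. This package
reports SQI on the canonical $[0,1]$ scale of the formula and leaves any
display rescaling to the user.

## Sustainable yield index

For a yield series $y_1,\dots,y_T$, $SYI = (\bar y - \sigma)/y_{\max}$. The
index is at most 1, equals 1 only for a constant positive series, is
invariant to rescaling the series, and falls as dispersion grows; it can go
negative when $\sigma > \bar y$, and such values are returned as-is with a
warning — clipping would hide exactly the pathology the index exists to
expose.

Two conventions are configurable because the literature leaves them
unstated:

* $\sigma$ defaults to the **sample** (n−1) standard deviation
  (`sd_mode = "population"` selects the alternative). Sample-sd SYI is never
  larger than population-sd SYI for the same series.
* SYI is computed **per plot** over that plot's own ten-year series, then
  analyzed across the six replicates. A treatment-level ANOVA of SYI (four
  degrees of freedom between groups) is only possible with replicate-level
  values, which settles the granularity; treatment means ± SE are reported
  alongside.

## Inferential layer

* **ANOVA** is the textbook one-way decomposition with explicit sums of
  squares ($SST = SSB + SSW$ is asserted in the test suite and exposed for
  audit). Zero within-group variance with nonzero between-group variance
  reports $F = \infty$, $p = 0$ and a flag rather than failing.
* **Assumptions**: Shapiro-Wilk per group, Levene's test across groups
  (mean-centered by default, matching the classic statistic; median centering
  — Brown-Forsythe — is the option), each with pass flags at $\alpha$.
  Groups smaller than 3 or constant are flagged not-assessable.
* **Compact letters** come from all pairwise comparisons (Tukey's
  studentized-range family by default; unadjusted LSD as the option) via the
  insert-and-absorb algorithm, implemented directly so that the letter
  semantics — two treatments share a letter *iff* their difference is
  nonsignificant at $\alpha$ — is a tested contract, not an import. The
  treatment with the largest mean gets "a".
* **Correlations** are pairwise Pearson with two-sided p-values and stars at
  0.05/0.01/0.001. No multiplicity correction is applied by default, matching
  common practice for descriptive correlation heatmaps; a flag enables
  Benjamini-Hochberg adjustment.
* **Regression** of SYI on SQI is ordinary least squares; $R^2$ equals the
  squared Pearson correlation (asserted in tests).
* **Random-forest importance** is out-of-bag permutation importance (%IncMSE)
  from 1000-tree regression forests. The significance procedure is defined
  exactly so it is reproducible: each predictor's null importance
  distribution is built by refitting the full forest on response-permuted
  data ($B = 99$ by default) and $p = (1 + \#\{null \ge obs\})/(1 + B)$, the
  add-one estimator, so p-values are never exactly zero. Predictor columns
  are sorted internally so results do not depend on column order. With only
  30 plots there is no train/test split; out-of-bag error is used throughout.

## The synthetic trial generator

The generator emulates the trial's statistical structure so every stage is
testable end-to-end.

**Soil panel.** Per-treatment indicator means default to the published
treatment effects for this design: control BD 1.35 g/cm³ vs 1.22 under M3,
pH 7.04 vs 7.30, nitrate-N 8.18 mg/kg vs 25.32 under CF, SOM/total-N/ammonium
increases of +99.56/+90.33/+156.35% under M1, urease +100.00/71.17/32.43% and
catalase +62.06/45.62/45.63% for M1/M2/M3, CF bulk density +9.74%, and the
pre-trial baseline panel (SOM 12.80 g/kg, TN 0.61 g/kg, alkali-N 49.00, AP
28.30, AK 191.00 mg/kg). Values not printed anywhere are set once to
plausible levels that respect every published ordering claim: control
ammonium 3.10 mg/kg and enzyme activities (urease 10.0, catalase 5.0,
alkaline phosphatase 2.0 units); fertilized nutrient means at fixed fractions
(CF 0.55, M3 0.70, M2 0.85) of the CK→M1 increment, so the 75/25 blend stays
the maximum. A literal interpolation in the organic fraction cannot hold here
— M2 and M3 carry more organic fertilizer than M1 yet the printed maxima
belong to M1 — hence the increment-fraction scheme. Plot values are treatment
means perturbed by correlated multiplicative noise (CV 0.05 by default):
$x = \mu(1 + cv\,z)$ with $z$ multivariate normal under an exchangeable
correlation ($\rho = 0.6$) across the ten nutrient/enzyme indicators, BD
coupled to that block at $-\rho/2$, pH independent; draws are truncated to
physical bounds. With CV = 0 every plot equals its treatment mean exactly.

**Yields.** Yield is `base + trend × (year − 2014) + block effect +
residual`, truncated at zero. Block effects (SD 80 kg/ha) are drawn once per
block and shared across treatments and years, mimicking a field block.
Absolute levels are implementer choices (no yield table is published):
first-year means 4400 (CK), 5300 (CF), 5800 (M3), 6100 (M2), 6400 (M1)
kg/ha. The treatment **trends** carry the sustainability signal: −160 (CK,
the published declining unfertilized trajectory), +150 (CF), +110 (M3), +65
(M2), +40 (M1) kg/ha/yr with a common residual SD of 100 kg/ha. This places
SYI separation in the deterministic trend component, which is shared by all
replicates of a treatment, so replicate-level SYI noise stays small relative
to the treatment spread — the configuration under which the published
qualitative pattern (ten-year mean yield M1 > M2 > M3 > CF > CK, SQI highest
for M1, a strongly positive SQI-SYI regression with $R^2$ above 0.9) is
reproduced robustly across seeds. A steeper organic-blend trend than M1's is
itself realistic: higher organic inputs build fertility more slowly but more
persistently.

**The 2019 shock.** A one-year multiplicative dip (default ×0.75 on M1 in
2019, off by default) reproduces the published inversion in which the 50/50
blend overtakes the 75/25 blend on SYI despite a lower mean yield: one bad
year inflates $\sigma$ and drops $(\bar y - \sigma)/y_{\max}$ sharply. It is
a config switch because the inversion is a property of that specific
trajectory, not of the design.

**What the generator does not emulate**: weather-driven year effects common
to all treatments, spatial autocorrelation beyond the additive block effect,
measurement error structure of individual assays, or any mechanistic
nutrient cycling. Passing tests therefore demonstrate correctness of the
*computations* and calibration of the *statistics* under a plausible data
model — not that any particular field result is reproduced.

## Reproducibility and the pipeline

`run_pipeline()` executes simulate → score → indices → stats → importance →
report, writing every intermediate as plain CSV (full precision, 17
significant digits, so downstream stages re-reading them lose nothing),
followed by `manifest.json` (resolved configuration, package version,
per-file MD5 checksums, collected warnings). One master seed drives
everything through a fixed split: yields use `seed`, the soil panel
`seed + 1`, the two forests `seed + 2000` and `seed + 3000`. Two runs with
the same configuration are byte-identical; stage wall-times go to a separate
`run.log` precisely so the artifact set can be checksummed. Stages are
individually rerunnable and fail fast with the name of the missing upstream
producer.

## Problem sizes used in the test suite

The suite exercises the formula layer against brute-force oracles on tables
of up to 6 plots × 6 indicators; property checks run over 1000 random tables
and series; ANOVA calibration uses 2000 simulated null datasets (5 groups ×
6 replicates); forest calibration uses 20 runs at n = 200 with 12 predictors,
99 response permutations and 100-tree forests (the floor of the configuration
contract, chosen so the whole suite runs in a few minutes); pipeline and
generator checks use the full 30-plot, 10-year default design.

## Known limitations

* Block structure enters the generator but not the inference: the ANOVA is
  strictly one-way, as is conventional for this trial's published analyses;
  there is no mixed-effects or repeated-measures option.
* Communality weighting inherits PCA's sensitivity to the indicator set:
  adding a redundant indicator raises its block's total weight. The weights
  table (with eigenvalue trail) is exported precisely so this can be audited.
* The min-max scores depend on the observed extremes; with 30 plots a single
  outlier plot stretches an indicator's ruler. Fixed bounds are the remedy
  when external reference values exist.
* `syi()` requires at least two years and a positive maximum; single-year
  designs get mean yield only.
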