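---
title: "Methods: element transfer in the soil-grapevine-wine system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: element transfer in the soil-grapevine-wine system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapetrace)
```

## The system and the model

`grapetrace` analyses element concentrations (Cu, Zn, Pb, Cd, Ni, Co, As,
Cr, Hg) measured in a vineyard system stratified into compartments: soil
sampled at four depths (0–20, 20–40, 40–60, 60–80 cm), grapevine roots,
canes, leaves and grapes, and the derived beverages must and wine. Soil and
tissue concentrations are on a dry-weight basis (mg/kg DW); beverages are
volume concentrations, canonically mg/L (µg/L columns are divided by 1000 on
load). Each record is a replicate mean with its standard deviation and
replicate count — the resolution at which such monitoring data are
published — so every downstream statistic operates on these per-cell means,
not on raw replicates.

The transfer model is a chain of concentration quotients. Translocation
factors compare adjacent compartments (root/soil, cane/root, leaf/cane,
grape/cane, must/grape, wine/must); note the grape branches off the cane,
with leaves a side branch. Mobility ratios compare each compartment against
topsoil (0–20 cm), the layer in closest exchange with the root zone. The
mean mobility ratio classifies the plant's behaviour: accumulator above the
indicator band, excluder below it, indicator inside. "Around 1" is not given
a number in the monitoring literature; the default band [0.75, 1.25] is a
symmetric 25% margin and is exposed as a parameter — conclusions about
elements far from 1 (e.g. Pb around 0.05, Cr around 2.9 for roots/soil) are
insensitive to it.

Two conventions matter for the quotients:

* **Censoring.** Below-LOQ values enter numerators as 0 (the measurement
  supports "at most LOQ", and the published averages treat them as 0) but
  make denominators undefined: the ratio is reported as `NA` with a warning,
  never as infinity. A compartment that is entirely censored (cobalt in must
  and wine) therefore truncates its chain.
* **Site handling.** Ratios are formed per site and then averaged across
  sites within a cultivar (`site_policy = "per_site_mean"`), because a ratio
  of cross-site average concentrations (`"pooled"`) would be dominated by
  the most polluted site. Both policies are available; the published
  per-variety ratios cannot be re-derived from the published aggregate
  tables under either policy (they evidently used unpublished per-replicate
  data), so validation of the chain rests on the internally consistent
  summary rows of the mobility tables and on synthetic ground truth, not on
  regenerating the published ratio tables from the concentration tables.

Soil enters the translocation chain as the depth average by default
(`soil_reference = "depth_average"`) and the mobility chain as topsoil
(`"topsoil_0_20"`); both are selectable.

## Regulatory grading

Soil is graded against tiered limits — normal value, alert threshold and
intervention threshold, the latter two split by land-use susceptibility —
shipped as an editable CSV (`thresholds_ro_order756.csv`). A tier is
assigned when its bound is *strictly* exceeded; a value exactly at a bound
stays in the lower tier, the natural reading of "threshold". Beverages are
graded against maximum permissible limits with matrix-specific rows: wine
limits (Cu 1, Zn 5, Pb 0.15, Cd 0.01, As 0.2 mg/L) and the higher must
limits for Cu, Zn (10 mg/L) and Pb (0.5 mg/L); Ni, Co, Cr and Hg carry no
limit and grade as `no_limit`. The As limit is stated in mg/L while As
itself is reported in µg/L; the canonical-unit conversion on load resolves
the comparison.

## Summary statistics and reporting

Grouped summaries use the arithmetic mean, the sample standard deviation
(n−1 denominator — confirmed by recomputing the published RSD% rows), and
RSD% = 100·SD/mean. When every value in a ratio set is zero the RSD is 0/0
and is reported as `NA`; with exactly one nonzero value among n it is the
pure number 100·sqrt(n) (173.2 for n = 3), which is why that figure recurs
in mobility tables of heavily censored elements. Computations run at full
precision; reports round half away from zero to 2 decimals
(`round_half_up()`), matching the tables' convention. Element rankings are
rendered in strictly descending order of the mean with alphabetical,
flagged tie-breaks.

Three cells of the bundled soil table deserve a note. One cell (Hg,
remote area, 40–60 cm) is printed as 0.57 ± 0.006 in the source but is
transcribed as 0.057: the printed column average (0.050), grand average
(0.055) and maximum row (0.070) are only consistent with 0.057. Conversely,
two printed area averages (remote-area Zn 59.99, smelter-area Co 22.57)
disagree with the average of their own printed members (58.99, 22.92); the
fixtures keep the printed members verbatim and the recomputed aggregates
stand — the tests assert these as documented mismatches rather than
silently matching the misprints.

## Pearson correlations and Duncan letters

Correlation cells carry the product-moment r with a two-tailed p from the t
transform and stars at 0.05/0.01. A zero-variance vector (an element fully
censored in one compartment) makes r undefined; it is reported as 0 with a
degeneracy flag, mirroring the zero rows of the published matrices. The
matrix builder pairs per-site-per-cultivar values across compartments plus
the distance to the pollution source; with three sites and three cultivars
that is n = 9 per cell, so these correlations are descriptive rather than
confirmatory, and no multiple-testing correction is applied across the
matrix (none is applied in the source analyses either).

Mean separation uses Duncan's multiple range test computed from the
studentized range distribution (`qtukey`), not printed tables, so any alpha
works — the letter displays are produced at 0.05 and can be rerun at 0.005.
The range spanning p ordered means is tested at the stage-wise level
alpha_p = 1 − (1 − alpha)^(p−1); once a range is non-significant everything
inside it is merged (the protection rule), and letters are the maximal
homogeneous intervals in descending-mean order. With two groups the
procedure reduces exactly to the pooled-variance t test. One property is
worth stating plainly: Duncan's guarantee is *comparison-wise* — under the
null the probability that a fixed pair separates stays at or below alpha,
but the probability that *some* pair among k > 2 groups separates
approaches alpha_k > alpha (0.0975 for three groups at alpha = 0.05). This
is a known, intended feature of the procedure, and the package's null
simulations check the comparison-wise rate (1000 replicates; two-group
familywise as the coinciding special case).

## Chemometrics

Geographic-origin discrimination fits Fisher linear discriminant axes on
z-scored element features with priors proportional to class counts
(`MASS::lda` underneath). Explained-variance percentages come from the
between-class eigenvalues; cross-validation (leave-one-out by default)
refits the standardization and the model inside every fold. The default
feature set excludes Co, which is entirely censored in beverages and would
contribute a constant column; for other partially censored cells the
feature builder imputes LOQ/2, the usual compromise that keeps scatter
matrices non-singular without inventing signal. Singular within-class
scatter is rejected with advice to drop collinear elements rather than
silently regularised. The published cross-validated membership percentages
for must and wine are not reproducible from published data (they require
per-replicate measurements), so the package validates the LDA stage by
construction: perfectly separated classes give 100%, shuffled labels give
chance.

Profile clustering standardizes each element to z-scores (otherwise Cu and
Zn, three orders of magnitude above Hg, dominate any distance), uses
Euclidean distance and Ward linkage by default — all configurable since the
source analyses name none — and exports Newick with branch lengths from the
merge heights. On the bundled soil profiles, cutting at k = 2 isolates the
remote area from the two smelter-adjacent areas, the qualitative structure
the monitoring question cares about.

## Analytical QC

Calibration fits are ordinary least squares on (level, response) points —
the default level series 2.5, 5, 10, 25, 50 matches the usual five-point
multielement calibration — with LoD = 3·SD/s and LoQ = 10·SD/s, where s is
the slope and SD the residual standard deviation. "SD of the regression
line" is read as the residual standard error with the n−2 denominator; the
ratio LoQ/LoD = 10/3 holds exactly and both limits are invariant to
rescaling the response, two properties the tests enforce. No weighting is
applied (the source methodology states none). The LOQ footnote constants of
the beverage table ship as data only; they cannot be recomputed without the
underlying calibration runs.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, with
known ground truth:

* **Gradient.** Soil concentration at distance d is S·exp(−k·d) per
  element — the simplest monotone decay consistent with the observed
  negative distance correlations. Defaults place three sites at 0, 5 and
  60 km (the source never states the real distances; these are plausible,
  user-configurable placeholders) with source strengths at the
  smelter-adjacent magnitudes (e.g. Cu 3500, Pb 3600 mg/kg) and faster
  decay for smelter-driven elements (Cu, Zn, Pb, Cd) than for geogenic ones
  (Ni, Co, As, Cr, Hg).
* **Partitioning.** Each downstream compartment mean is the upstream mean
  times a configured true ratio; the default partition vectors follow the
  observed mean translocation factors, including cobalt's complete blockage
  before the must (true ratio 0), so the default dataset exercises the
  censoring pathway exactly where the real data do.
* **Noise.** Replicates are the compartment mean times a lognormal factor
  with unit mean and configurable CV (default 0.1, i.e. 10% relative
  spread, the scale of the published replicate SDs): concentrations are
  positive and right-skewed, so multiplicative noise is the natural model;
  the source states none.
* **Censoring.** Values strictly below the per-element LOQ are emitted as
  censored records (value 0, flag set); the default LOQ of 0.001 censors
  Hg and Co in the beverage compartments, as observed.
* **Determinism.** Every record's draws are seeded from a hash of
  (seed, site, cultivar, compartment, depth, element), so subsetting the
  design does not shift the draws of the remaining records, and equal seeds
  give byte-identical datasets.

What the generator does *not* emulate: soil chemistry covariates (pH,
organic matter), element speciation, cultivar-specific uptake differences
(the partition is shared across cultivars), spatial heterogeneity within a
site, and temporal dynamics. Passing the recovery tests therefore shows the
chain computation is correct and unbiased under multiplicative noise — not
that real vineyards satisfy the proportional-transfer model.

## Validation sizes and numerical choices

The test suite and the acceptance script use problem sizes chosen to give
tight Monte-Carlo error at interactive runtimes: chain recovery at
cv = 0.1 over 200 seeds (median absolute relative error of every recovered
ratio stays below 5%; the observed maximum is about 2%), slope
unbiasedness over 500 calibration seeds, the Duncan null rate over 1000
replicates, and label-shuffled leave-one-out accuracy over 200 shuffles.
Noise-free recovery is exact to machine precision. Ratios whose ground
truth is 0, or that sit downstream of a zero compartment, are excluded from
relative-error summaries because relative error is undefined there.

Known limitations: the analysis operates on published cell means (mean, SD,
n), not raw replicates, so inferential statements inherit that resolution;
Duncan's familywise error exceeds alpha by design (see above); censored
values as hard zeros slightly bias means downward compared to interval
methods (e.g. Kaplan-Meier-type estimators for left-censored data), a
deliberate match to the source's own convention.
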