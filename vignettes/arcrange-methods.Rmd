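---
title: "Methods: home-range size, seasonal selection and landscape structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: home-range size, seasonal selection and landscape structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcrange)
```

## The scientific question

For a female grizzly bear, the home range is the area she traverses to
acquire the resources she needs; its size should depend on her
reproductive status (solitary, with cubs-of-the-year, with cubs at least
one year old) and on how the covers she prefers are arranged on the
landscape. On a low-heterogeneity Arctic landscape, where most covers are
widespread and only a few are strongly selected, the operative hypothesis
is that a female ranges farther when her seasonally preferred covers are
patchy and dispersed, and less far when they are aggregated — regardless
of offspring.

`arcrange` implements that analysis end to end: annual 95% fixed-kernel
home ranges from GPS fixes; a data-driven definition of seasons from
changing cover use; seasonal use–availability resource selection with the
bear as the unit of replication; reclassification of the landscape into
highly-selected / matrix / water; FRAGSTATS-style structure metrics of the
selected cover inside each home range; and an AICc comparison of candidate
models of log10 home-range size. Because no telemetry is distributed with
the package, a synthetic-data module generates landscapes and
cover-biased movement tracks with known ground truth, and the test suite
is built around recovering that truth.

## Home-range estimation

The utilization distribution is a fixed-kernel estimate with an isotropic
bivariate normal kernel and a single scalar bandwidth $h$ chosen by
least-squares cross-validation,
$$\mathrm{CV}(h) = \int \hat f_h^2 - \frac{2}{n}\sum_i \hat f_{h,-i}(x_i),$$
which reduces for Gaussian kernels to sums of
$\exp(-d_{ij}^2/4h^2)$ and $\exp(-d_{ij}^2/2h^2)$ over fix pairs. The
score is evaluated on 100 log-spaced candidates spanning 0.05–2 times the
bivariate normal-reference bandwidth
$\sigma n^{-1/6}$ and refined by golden-section search to a relative
tolerance of $10^{-3}$. LSCV famously loses its interior minimum on
strongly clustered data; when the grid minimum lands on the search
boundary the estimator falls back to the normal-reference bandwidth with
a warning, and duplicated coordinates are jittered by up to a tenth of a
raster cell before scoring. The UD is evaluated exactly (a separable
outer product of Gaussian factors, so the grid value *is* the kernel sum)
on a grid aligned to the cover raster; the home range is the smallest
density superlevel set holding 95% of the mass, kept as a union of grid
cells. We deliberately do not smooth the isopleth into a contour: cell
unions make areas, clips and metric extraction exact and testable. The
100% minimum convex polygon is the convex hull of all of an animal's
fixes pooled over years, and animals qualify for the selection analysis
only when at least 60% of their range lies in the study area.

The UD evaluation resolution and the LSCV search interval are not pinned
down by convention; both are configurable, with defaults of one raster
cell (28.5 m) and $[0.05, 2] \times h_{\mathrm{ref}}$.

## Defining seasons

Seasons are found, not imposed. Fixes are pooled over animals into
bi-weekly periods; each period's cover-use proportions are z-scored per
cover (so rare and common covers weigh equally) and the period rows are
clustered by Ward's minimum-variance method. Bi-weekly periods are paired
so that boundaries fall after odd calendar weeks, which is the break
style the seasonal structure is reported in (…-31, 32-39, 40-…).
Periods observed on fewer than 8 distinct days — partial periods at the
edges of the collaring window — are dropped: their proportion rows are
small-sample noise that the z-scoring then amplifies.

The number of seasons is decided by the Duda–Hart statistic. For the
split taking $k$ clusters to $k+1$, $Je(2)/Je(1)$ is the ratio of the
children's pooled within-cluster sum of squares to the parent's, and the
pseudo-$t^2$ is the equivalent $F$-style form. We compute both for every
split, but the stopping decision standardizes the ratio by its null mean
$1 - 2/(\pi d)$ and variance $2(1-8/(\pi^2 d))/(md)$ ($d$ = informative
profile dimensions, $m$ = parent size) and stops at the first split whose
standardized ratio is not below $-3.20$, the conventional critical value
for this index. The raw ratio is biased toward splitting small clusters —
chance alone removes much of the sum of squares of a 4-row cluster — and
an unstandardized "local extremum" read-off of the two statistics proved
unstable in exactly that way; the standardized rule recovers clean
2- and 3-regime structures essentially always and returns $k=1$ on pure
noise. Whether the chosen $k$ also sits at a local maximum of the ratio
and local minimum of pseudo-$t^2$ is reported as an `agreement` flag.

Ward clustering ignores time, so cluster labels are forced into
contiguous calendar blocks: runs of equal labels are formed and the
shortest island is merged into the neighbouring run with the closer
profile centroid until only $k$ runs remain. Profiles are pooled over
animals by default (one season structure for the population); per-animal
averaging is available behind a flag.

## Seasonal resource selection

Selection is modelled as use versus availability: GPS fixes (the 80%
per-animal training split, split off with round-half-up arithmetic and a
fixed seed) against random points sampled in each animal's multi-annual
100% MCP at 1 point/km² (floor of 30). The model is a random-intercept
logistic regression on cover-class dummies with water — the most common
cover, of marginal importance — as the reference level and the bear as
the random intercept, fitted with `lme4::glmer` (Laplace approximation;
a plain logistic fit is the tagged fallback if the mixed fit fails).
Covers observed on only one side of the use/availability contrast are
flagged as separated and excluded from the fit rather than allowed to
blow up; covers absent from the data are reported as matrix with a flag.

Each cover's relative selection index is the odds-ratio magnitude
$\mathrm{RSI} = e^{|\beta|}$, reported to one decimal. The magnitude
convention means an avoided cover can have a large RSI; the
"highly selected" class therefore requires both $\beta > 0$ and
$\mathrm{RSI} \ge 2$, water is always the reference class, and everything
else is matrix. The reclassified three-class map is validated with Manly
selection ratios on the held-out 20%: per animal,
$w_s = u_s / a_s$ with $u_s$ the proportion of test fixes on
highly-selected cells and $a_s$ the proportion of map cells with centres
inside the MCP that are highly selected; the mean ratio is compared to 1
by a Wald $F$ with $(1, n-1)$ degrees of freedom from an intercept-only
regression. Animals whose MCP contains no highly-selected cover are
excluded with a warning, and the per-cover rows are reported from one
multi-cover model by default (per-cover univariate fits are available
behind a flag).

## Landscape structure inside the home range

All metrics are computed on the cells whose centres fall inside the
annual kernel range. For the highly-selected class of each season's map:
the proportional amount; the landscape shape index
$\mathrm{LSI} = 0.25\,E/\sqrt{A}$ (1 for a single compact square, larger
as the class becomes patchy and dispersed), with 4-neighbour adjacency
and edges against the clip boundary counted (the FRAGSTATS landscape
boundary convention; both variants are implemented and tested); and edge
density in metres per hectare. Edge density is length per area — the
squared-metre unit that sometimes appears in print for this quantity is
treated as a typographical artefact. Water gets the same LSI and edge
density on the original covers, and overall cover diversity is
Shannon–Wiener $H = -\sum p_i \ln p_i$ in nats.

## Comparing models of home-range size

Annual areas are log10-transformed. Group structure is tested with a
pooled-variance t-test of solitary subadults against adults (pooling if
$P > 0.05$), one-way ANOVA across the three reproductive statuses, and
Tukey HSD pairwise comparisons (Tukey–Kramer under imbalance, as base R
computes). Candidate models are linear models of log10 area fitted by
maximum likelihood with a per-animal random intercept whenever an animal
contributes more than one annual range — ML, not REML, because AICc must
compare models with different fixed effects. Collinearity is screened
before modelling: of any covariate pair with $|r| \ge 0.6$, the member
with the weaker univariate association is excluded; models containing a
covariate with VIF > 10 are rejected. The "mean VIF considerably above
1" heuristic is reported but never used for exclusion, since it has no
defensible threshold.

AICc is $-2\log L + 2k + 2k(k+1)/(n-k-1)$ with the parameter-counting
convention that reproduces the published candidate tables: intercept 1,
each named term 1 more (a 3-level status factor counts 1, a quadratic
term counts 1), variance components uncounted. That convention is
non-standard — it underestimates the true parameter count for factors —
but it is required to reproduce the published $k$ column, so it is the
default with standard counting available. $R^2$ is the squared
correlation between the fixed-effect predictions and the observed log10
areas, which is well defined for every candidate and 0 for the null.
Akaike weights, the confidence set ($w \ge 0.10\,w_{best}$), per-term
importance weights (summed member weights), conditional model averaging
(weights renormalized over the models containing each coefficient) and
the quadratic-term check on the best model follow directly. The
random-intercept variance of the best model is tested by a REML
likelihood-ratio against the $0.5\chi^2_0 + 0.5\chi^2_1$ boundary
mixture; REML is used for this one test because the ML version is
anticonservative when few animals repeat, and the test is skipped when
no animal contributes multiple years.

## The synthetic study system

The generator supplies what the analysis needs and nothing more: a
categorical landscape and seasonally cover-biased tracks with known
preferences.

**Landscape.** A standard-normal field is smoothed by a Gaussian kernel
of length `aggregation` cells (0 = i.i.d.) and thresholded at the
cumulative target quantiles, so class proportions are hit essentially
exactly at any clumping. The default is the study system scaled down to a
tractable grid: 11 classes (10 vegetated covers + water), water at 35%,
28.5 m cells, 512×512 (tests mostly use 256×256), aggregation 6 cells.

**Movement.** Steps are proposed by a correlated random walk
(gamma step lengths with mean `step_scale` = 250 m per 4-h step,
wrapped-normal turns, concentration 1) and accepted by a Metropolis rule
on the potential
$W(x) = w_{s,\mathrm{cover}(x)} - \lVert x - c\rVert^2/2\rho^2$: the
seasonal log-weight of the destination cover plus a Gaussian home-range
envelope of scale $\rho = 4 \times$ step scale around the animal's
centre. One proposal is made per step and a rejection means the animal
stays put, which is exactly the Metropolis kernel: the walk's stationary
use is proportional to $e^{w}$ times the envelope — precisely the
structure the RSF assumes — and home-range size scales with the step
scale, which the per-status multipliers (0.7 for cubs-of-the-year, 1.2
for cubs ≥ 1 yr) act on. Two design points were learned the hard way and
are worth recording: retrying rejected proposals (a bounded multiple-try
scheme) systematically attenuates the programmed selection, because every
retry is another chance to leave a good cell; and applying the
home-range pull as a deterministic drift outside the acceptance rule
damps selection the same way. Both are avoided by folding everything
into the acceptance potential. A 120-step burn-in precedes recording so
tracks start near stationarity.

**Conditions.** Defaults mirror the study design: 30 females, 279–959
retained fixes each (sampled from the full 4-h slot sequence,
April–November, so every season is observed), three preference regimes
switching after weeks 31 and 39, and water strongly avoided year-round.
The regime weights keep the study's qualitative structure — spring
spreads preference over sparse vegetation, tall shrub, closed spruce,
low shrub upland and wet herbaceous; late summer concentrates on sparse
vegetation and low shrub lowland; autumn favours low shrub lowland,
closed spruce, tall shrub and sparse vegetation — with magnitudes capped
near $|w| = 2$. We deliberately did not program the published fitted
coefficients directly as weights: a log-weight near 4 on a rare cover
makes occupancy a slow two-state process (long dwell times in scarce
patches), which inflates between-period noise so much that adjacent
seasonal regimes blur into each other. The capped regimes produce
realized seasonal use in which the three regimes are distinct, which is
the property the field system evidently had.

**What the generator does not emulate.** Inter-annual range drift and
multi-year deployments (each synthetic animal has one year), fix-success
autocorrelation and habitat-dependent fix loss, GPS positional error,
denning-date variation beyond the fixed April–November window, and any
availability gradient beyond landscape patchiness. Passing
parameter-recovery tests on these data therefore shows the estimators
and the inference chain are correct, not that the field conclusions are
reproduced; the published group means and fitted $R^2$ depend on the
unreleased telemetry and are out of scope.

## Problem sizes used in the tests

The suite runs the season-recovery experiment at the study scale
(30 animals, 20 replicates), RSF recovery at 20 animals × 500–700 fixes,
the selection-ratio null at 200 replicates of a reduced two-month,
10-animal design (the test's level does not depend on the design size),
the candidate-model recovery at the published 43-range scale, and the
end-to-end pipeline once at full defaults on a 256×256 landscape. Oracle
checks (brute-force LSCV, hull, and edge counting) use n = 200–500
points and 64×64 rasters.

## Known limitations

Cell-union isopleths slightly overestimate areas relative to smoothed
contours at coarse grids; the Duda–Hart stopping rule assumes roughly
isotropic within-cluster scatter after z-scoring; the selection-ratio
test treats animals as exchangeable replicates and ignores the shared
landscape; and the table-reproducing parameter count makes AICc comparisons
reproducible rather than information-theoretically orthodox (the
standard count is one switch away).
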