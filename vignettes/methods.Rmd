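---
title: "Modelling extinction severity against climate velocity and hominin history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling extinction severity against climate velocity and hominin history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megapast)
```

## The scientific problem

Late Quaternary large-mammal faunas collapsed worldwide, and the two
candidate drivers — glacial–interglacial climate change and the expansion of
hominins — make distinct geographic predictions. If climate mattered most,
the proportion of a region's megafauna that went extinct should track the
magnitude or velocity of climate change there. If exposure history to
hominins mattered most, extinction severity should be lowest where hominins
and megafauna coevolved longest and highest where modern humans arrived as
the first hominin.

`megapast` implements the full analytical pathway for testing these
predictions at the resolution of ~229 country-scale analysis regions:
climate-change surfaces, curated extinct-species ranges, a richness-corrected
extinction proportion per region, competing regression models selected by
AIC, and spatial simultaneous autoregressive (SAR) error models with
correlogram diagnostics. A synthetic-world generator reproduces the
statistical structure the analysis assumes, so the entire pipeline is
testable offline.

## The response: richness-corrected extinction proportion

For region $i$, the response is

$$p_i = \frac{E_i}{E_i + \hat N_i},$$

where $E_i$ is the cumulative count of extinct (globally or continentally
extirpated) large-mammal species recorded or interpolated in the region, and
$\hat N_i$ is the *potential* extant large-mammal richness. $\hat N_i$
corrects observed richness for recent anthropogenic depletion: a
quasi-likelihood GLM (logit link, variance $\mu(1-\mu)$) of extant large
richness against small-mammal richness and a human-impact index is fitted per
continent, and where the impact coefficient is significant (gate
$\alpha = 0.10$, so continents just above the conventional 0.05 line are
still corrected) richness is re-predicted at the lowest impact recorded in
that continent. Because a $\mu(1-\mu)$ variance needs a response in (0, 1)
and the original analysis never states its denominator, the package models large
richness as a fraction of the regional pool (large + small richness) and
carries the pool scale to map predictions back to counts; this stand-in is a
documented design choice.

Modelling uses the variance-stabilizing arcsine square-root transform
$y_i = \arcsin\sqrt{p_i}$, which gives the halving of a four-species fauna
the same weight as the halving of a fifty-species fauna. The transform is
only invertible on $[0, \pi/2]$, so back-transformation clamps fitted values
to that interval before applying $\sin^2$; negative trends map to proportion
zero.

## Climate predictors

Four per-region scores: mean annual temperature anomaly and velocity and
annual precipitation anomaly and velocity between two epochs (Last Glacial
Maximum, ~21 000 yr BP, to present by default; Last Interglacial,
~130 000 yr BP, to LGM as the sensitivity pair, spans 21 000 and 109 000 yr
respectively). Anomaly is the cellwise absolute difference of
ensemble-averaged epoch grids. Velocity is the displacement rate

$$v = \frac{|\Delta| / T}{\lVert \nabla f \rVert},$$

the anomaly per year divided by the local spatial gradient — the speed at
which a species must move to track its climate. The gradient kernel is
central differences over the 3×3 neighbourhood (one-sided at edges); the
original analysis names only the map resolution, and this is the simplest scheme that
matches the velocity literature and is brute-force testable. Cells with
gradients below a floor of $10^{-6}$ units/m take the floor, so flat cells
get large finite velocities rather than infinities. Cell values are
aggregated to regions (zonal mean, plus zonal range as a within-region
heterogeneity diagnostic), then standardized by $\sqrt{v_i}/\max_j\sqrt{v_j}$
onto $[0, 1]$. Standardization after regional aggregation is a choice the
original analysis leaves open; the cell-level alternative remains available by
standardizing a grid before aggregation.

## Species curation

The acceptance filters retain a species iff it is taxonomically accepted
(uncertain species enter only the sensitivity configuration), has body mass
≥ 10 kg (≥ 44 kg in the sensitivity run; thresholds inclusive), has at least
one directly dated site, and its dated interval intersects the
132 000–1000 yr BP window — species lost in the last millennium are excluded.
Occurrence cleaning drops, with logged reason codes, records at (0, 0),
captive records, records on continents without a dated site for the species,
and extant-range records of continentally extirpated species; offshore
records snap to the nearest region within 50 km (configurable), with exact
ties broken to the smallest region id.

Fossil ranges are gappy, so presence maps are interpolated on the region
adjacency graph: (i) disjoint range fragments are connected along the
least-cost path, where entering a region costs the absolute difference
between its environmental score and the mean score of the directly occupied
regions — an operationalization of "the path that best reflects the
conditions where specimens were recovered"; (ii) interior holes (unoccupied
regions all of whose neighbours are occupied — the conservative "all"
reading) are filled to a fixed point; (iii) peripheral additions happen only
from an explicit per-species list, because the original analysis names examples rather
than a rule. Every fill is provenance-tagged `interpolated` and never
overwrites a `direct` record, and the primary analysis uses filled ranges
with a no-interpolation sensitivity toggle.

## Model families and selection

Candidate models come in three families. Climate-only: every non-empty
subset of the four climate scores in which the anomaly and the velocity of
the same variable never co-occur (velocity is computed from anomaly, so the
pair is collinear by construction) — per variable the choice is
none/anomaly/velocity, hence exactly $3 \times 3 - 1 = 8$ specifications.
Hominin-only: the five-class exposure coding (Homo-origin, Archaic-early,
-late, -peripheral, H. sapiens-only), the three-class lumped coding, and a
modern-human arrival-time covariate. Combined: the best climate and best
hominin specifications with hominin-by-climate interactions.

"GLM with arcsine transformation" is implemented as Gaussian-identity least
squares on the transformed response — the only reading with a defined AIC,
which the selection step requires. The AIC convention is the full Gaussian
log-likelihood including its $2\pi$ terms with the error variance counted as
a parameter (identical to `stats::AIC` on an `lm`), documented so
cross-implementation comparisons are exact. Ties break toward fewer
parameters. A quasi-binomial GLM (logit link, $\mu(1-\mu)$ variance, Pearson
dispersion) re-fits the selected model as a distribution-free consistency
check, and nested models are compared by partial $F$ with both degrees of
freedom reported explicitly (the original analysis prints only residual df).

The five exposure classes are reduced by an ordinal adjacent-contrast
procedure: fit the current grouping, test each contrast between adjacent
group means, merge the least significant pair whose $p$ exceeds
$\alpha = 0.05$, iterate to a fixed point. On data with a low/mid/mid/mid/high
mean structure this recovers the three-group coding (origin, archaic
combined, moderns-first) that the original analysis selects.

## Spatial structure

Spatial weights connect each region to its four nearest neighbours
(planar km in synthetic mode, great-circle on a 6371 km sphere for real
coordinates), row-standardized; k-NN adjacency is allowed to be asymmetric.
The SAR error model is

$$y = X\beta + u, \qquad u = \lambda W u + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2 I),$$

estimated by maximum likelihood on the concentrated (profile) likelihood in
$\lambda$: for each candidate the spatial filter $I - \lambda W$ is applied
to both sides, $\beta$ and $\sigma^2$ are profiled out by least squares, and
the log-determinant is computed by sparse LU factorization — robust for the
asymmetric k-NN matrix, whose eigenvalues may be complex. A 21-point grid on
$(-0.999, 0.999)$ brackets the optimum and golden-section/parabolic
refinement (via `stats::optimize`) polishes it; the interval restriction
substitutes for exact spectral bounds, which cost more than they are worth
for row-standardized weights. Standard errors come from the inverse
numerical Hessian of the full log-likelihood at the optimum (giving the
Z-statistic table), $\mathrm{AIC} = -2\ell + 2(p+2)$ counts $\lambda$ and
$\sigma^2$, and the reported pseudo-$R^2$ is the squared Pearson correlation
between the response and the trend $X\hat\beta$ — the original analysis never defines
its pseudo-$R^2$, so this common convention is fixed here and is not claimed
to reproduce the published value.

Residual spatial autocorrelation is diagnosed with Moran's I correlograms:
all region pairs binned into contiguous 500 km distance classes, binary
pair-membership weights per class, and a two-sided permutation test around
the permutation mean, with the same seeded permutations reused across
classes. Empty classes report `NA`, never zero.

## The synthetic world

`generate_regions()` partitions a planar lattice (default 40×60 cells of
100 km) into 229 contiguous regions grown from random seeds inside
contiguous continent blocks; each of the 6 blocks carries one hominin class,
mirroring the one-origin / three-archaic / two-moderns-first global
configuration. Planar geometry in km removes projection ambiguity from the
tests. Climate fields are Gaussian-kernel-smoothed white noise (correlation
length 300 km) over a north–south trend; epoch pairs share correlated
innovations (target $r = 0.9$, emulating the observed cross-epoch anomaly
consistency of 0.97/0.82) and the second epoch is offset by a latitudinally
graded glacial cooling of −2 °C (low latitudes) to −14 °C (high latitudes).
Polar amplification of glacial–interglacial change is the textbook pattern,
and it is what makes the standardized anomaly score genuinely span its
$[0, 1]$ range; a spatially uniform offset would leave the score nearly
constant and the climate coefficients unidentifiable.

Extinction outcomes follow the reference linear predictor on the arcsine
scale — intercept −0.353, H. sapiens-only +1.107, Archaic-combined +0.735,
temperature anomaly +1.504, with interactions −1.516 and −1.225 — plus SAR
errors $u = (I - \lambda W)^{-1}\varepsilon$ built on the same 4-NN weights
the analysis uses, with generator defaults $\lambda = 0.6$ and
$\sigma = 0.15$ chosen so simulated proportion spreads resemble the observed
interquartile ranges. These are generator defaults, not estimates. The
proportion is $\sin^2$ of the clamped predictor, and counts are
round-half-up of proportion × regional richness (drawn uniformly on 10–60
species) — round-half-up everywhere, a fixed testable convention. The
species-table generator emulates the curated-inventory schema (177 species,
log-normal masses, ~13% uncertain, a few records dated outside the window or
lacking direct dates) so every filter has work to do.

What a green test does establish: the estimators recover the parameters of
their own data-generating process, the oracles agree with the computational
path, and the pipeline's decisions are deterministic under a seed. What it
does not establish: agreement with the published coefficients, which depend
on external rasters, occurrence databases and range maps; the synthetic
world has no coastlines, islands, taphonomic geography, or non-stationary
spatial error structure, and its regions are statistically exchangeable
within continents in a way real countries are not.

## Numerical conventions and edge cases

* Round half away from zero for all count conversions (base R rounds half
  to even).
* Clamp to $[0, \pi/2]$ before $\sin^2$ back-transforms.
* Gradient floor $10^{-6}$ units/m before velocity division.
* Regions with zero valid climate cells raise a coverage error listing ids;
  all-zero score vectors are a degeneracy error, not silent `NA`.
* Regions with neither extinct nor extant species raise a classed error and
  are excluded with a log entry.
* Exact snap-distance ties break to the smallest region id; exact AIC ties
  break to fewer parameters.
* Duplicate region centroids (possible for symmetric cell sets) are
  separated by a deterministic sub-metre nudge so 4-NN weights exist.
* Permutation p-values use the add-one convention $(1 + \#\{\cdot\})/(B+1)$.
* The correlogram permutation count drops from 999 to 199 in the
  100-replicate acceptance runs: p-resolution 0.005 is ample for a 0.05
  decision at a fifth of the cost.

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline(run_config(seed = 1, n_perm = 199))
res$selection$combined$table   # AIC ranking of candidate models
print(res$sar)                 # SAR fit in the reference table schema
res$correlograms$glm[1:3, ]    # residual SAC before the SAR correction
res$correlograms$sar[1:3, ]    # ... and after
```

On the default synthetic world this selects a combined model carrying the
hominin coding, temperature anomaly and their interaction; the GLM
residuals' first 500-km correlogram class is permutation-significant while
the SAR innovations' is not, mirroring the analysis the package
re-implements.

## Known limitations

Real-data mode accepts the documented CSV/text-grid schemas but no GIS
formats; reprojection, raster resampling and genuine coastline handling are
out of scope. The quasi-logit richness correction's denominator is a
documented stand-in for an unrecoverable detail of the original analysis. The ordinal
lumping procedure operationalizes an unspecified "ordinal analysis" as
adjacent contrasts. SAR estimation assumes a row-standardized weight matrix
and $|\lambda| < 0.999$; spatial lag and CAR models, eigenvector filtering
and Bayesian variants are deliberately absent.
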