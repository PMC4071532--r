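# megapast

Macroecological analysis of late Quaternary megafauna extinctions: did
glacial–interglacial climate change or the geography of hominin expansion
drive the worldwide loss of large mammals?

`megapast` is an R package for researchers in macroecology and
palaeoecology. It re-implements, as a tested and fully synthetic-testable
pipeline, the analysis pathway that asks whether per-region extinction
severity tracks climate-change magnitude/velocity or hominin exposure
history:

* **Climate surfaces** — epoch-pair anomaly `|Δ|`, spatial gradient
  `‖∇f‖` (3×3 central differences), and climate-change velocity
  `v = (|Δ|/T)/‖∇f‖` in m/yr, aggregated to ~229 country-scale regions and
  standardized to `[0, 1]` scores by `√v / max √v`.
* **Species curation** — acceptance filters (mass ≥ 10 kg or ≥ 44 kg,
  direct dating, 132 000–1000 yr BP window), occurrence cleaning with
  logged reason codes, coastal snapping, and least-cost-path interpolation
  of gappy fossil ranges on the region adjacency graph.
* **Richness correction** — per-continent quasi-binomial GLMs (logit link,
  variance μ(1−μ)) of extant richness on small-mammal richness and human
  impact, re-predicted at each continent's minimum impact, giving the
  response `p = extinct / (extinct + estimated extant)`.
* **Model selection** — arcsine-square-root Gaussian models
  (`y = arcsin √p`), legal candidate enumeration (anomaly and velocity of
  the same variable never co-occur: exactly 8 climate specs), AIC selection
  with parsimony tie-breaks, ordinal lumping of the five hominin classes,
  quasi-binomial cross-checks, nested partial-F tests.
* **Spatial statistics** — 4-nearest-neighbour row-standardized weights,
  maximum-likelihood SAR error models (`u = λWu + ε`, sparse-LU
  log-determinants, concentrated likelihood in λ), Moran's I correlograms
  with 500 km classes and permutation tests, pseudo-R² as the squared
  correlation of response with trend.
* **Synthetic world** — a seeded generator producing the lattice
  tessellation, continent blocks with hominin classes, correlated epoch
  climate fields, and extinction outcomes from the reference linear
  predictor (intercept −0.353, H. sapiens-only 1.107, Archaic-combined
  0.735, temperature anomaly 1.504, interactions −1.516 / −1.225; λ = 0.6,
  σ = 0.15) so every stage is verifiable without downloads.

See `vignettes/methods.Rmd` for the model, its assumptions, every tunable
parameter, and the package's numerical conventions.

## Worked example

```r
library(megapast)
res <- run_pipeline(run_config(seed = 1, n_perm = 199))
print(res)
#> <pipeline_result>
#>   world: 229 regions, 6 continents, seed 1
#>   climate: lgm-present contrast over 21000 yr
#>   ranges: 121 of 177 species pass filters (>= 10 kg)
#>   ranges: gap filling applied (rules i-ii)
#>   richness: corrected continents:
#>   models: best climate [P_anom + T_anom], best hominin [hominin3],
#>           best combined [P_anom + T_anom + hominin3 + hominin3:climate]
#>   spatial: lambda = 0.560, pseudo-R2 = 0.452
```

The log reads bottom-up as the analysis: of 177 synthetic species, 121 pass
the acceptance filters; the best climate-only model (by AIC) carries
temperature anomaly and precipitation anomaly; the lumped three-class
hominin coding beats the five-class and arrival-time codings; the combined
model keeps hominin history, climate and their interaction; and the SAR
error model estimates residual spatial autocorrelation λ ≈ 0.56 with a
trend pseudo-R² ≈ 0.45. `print(res$sar)` shows the coefficient table
(estimate, s.d., Z, p plus λ, σ², logLik, AIC, pseudo-R²);
`res$correlograms$glm` and `res$correlograms$sar` show first-class Moran's I
significant before the SAR correction and non-significant after.

A command-line wrapper with subcommands (`simulate`, `climate`, `ranges`,
`richness`, `fit`, `spatial`, `all`) is installed at
`system.file("cli", "megapast.R", package = "megapast")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","megapast.R",package="megapast"))')" \
  all --seed 1 --min-mass 10 --out runs/demo
```

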