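# petalvision

Quantifying ozone effects on the visual attraction traits of flower petals:
spectral reflectance, pigment indices, and colour as seen by bees, flies and
butterflies.

## The problem

Tropospheric ozone damages plants at current ambient concentrations. Beyond
biomass and yield, ozone can alter the traits flowers use to attract
pollinators — petal size, pigmentation, and colour as perceived by insect
visual systems. Open-top-chamber (OTC) fumigation trials expose plants to a
gradient of ozone (charcoal-filtered air **CFA**, non-filtered ambient air
**NFA**, and ambient supplemented with 40 nL L⁻¹ ozone **FU+**, alongside a
chamber-less ambient plot **AMB**) and measure petal reflectance spectra,
petal areas, and chamber microclimate. `petalvision` packages the full
analysis chain for such trials, plus a synthetic-data generator so every
stage is testable without instrument data.

## What it computes

**Pigment and peak metrics.** From a petal's relative reflectance R(λ)
(white reference = 1, resampled to a 1-nm grid):

- anthocyanin reflectance index
  `ARI = (R800 / R550) − (R800 / R700)` — anthocyanins absorb near 550 nm,
  so deeper troughs raise ARI; the index is invariant to overall scaling;
- the maximum reflectance peak height in 325–600 nm (with its wavelength).

**Pollinator colour spaces.** Receptor quantum catches
`Q_i = ∫ R(λ) S_i(λ) I(λ) dλ` (trapezoidal, 325–700 nm) with sensitivities
S_i from an A1 visual-pigment template (Govardovskii form), CIE D65
illuminant in relative quanta, and von Kries adaptation
`q_i = Q_i / Q_i(green-leaf background)`:

- **bee colour hexagon** — excitations `E = q/(q+1)`,
  `x = (√3/2)(E_G − E_UV)`, `y = E_B − (E_UV + E_G)/2`, six 60° sectors;
- **fly categorical space** — opponent coordinates `q(R7p) − q(R8p)` and
  `q(R7y) − q(R8y)`; colour categories are the quadrants;
- **butterfly tetrahedron** — relative catches of u/s/m/l receptors mapped
  into a unit tetrahedron.

**Perceptibility.** Two petals differ perceptibly for a fly when their loci
fall in different quadrants; for a bee when hexagon distance ≥ 0.09; for a
butterfly when the colour-space axis difference (default the UV axis u)
≥ 0.03. Group comparisons score each treated petal against the control
centroid (default) or all control petals (strict).

**Statistics.** PERMANOVA (Anderson's pseudo-F on square-root-transformed
spectra with Bray–Curtis dissimilarity; seeded permutations or exhaustive
enumeration), planned single-df contrasts (`contr.poly` linear trend,
NFA-vs-rest `(−1, 2, −1)`, control-vs-rest `(2, −1, −1)`), one-way
ANOVA/ANCOVA with petal area as covariate, and a maximum-likelihood
random-intercept (plant) model selected against the fixed-only model by AIC.

**Ozone exposure.** AOT40 (accumulated exceedance over 40 nL L⁻¹ during the
07–15 h window), window and daily means, charcoal filtration efficiency,
chamber microclimate deltas, Magnus-form VPD (always computed per hour and
then averaged).

## Worked example

```r
library(petalvision)

cfg <- sim_config(plants_per_treatment = 6, petals_per_plant = 3, seed = 42)
sim <- simulate_dataset(cfg)
set1 <- spectrum_set(lapply(sim$set$spectra, resample, grid = 325:1075))

idx <- pigment_index_table(set1)
aggregate(cbind(ari, peak_height) ~ treatment, idx, mean)
#>   treatment      ari peak_height
#> 1       AMB 3.503010   0.4636612
#> 2       CFA 3.587320   0.4224564
#> 3       FU+ 3.496235   0.4703892
#> 4       NFA 7.243164   0.4306010
```

NFA petals carry the configured ARI bump (deeper anthocyanin trough at
ambient ozone), and peak height rises CFA → NFA → FU+ with the reflectance
scaling. Mapping the same petals into bee colour space:

```r
sys <- visual_system("bee")
#> visual_system 'bee': receptors UV(344 nm), B(436 nm), G(556 nm);
#> grid 325-700 nm; luminance receptor 'G'
head(colour_loci(set1, sys)$table[, c("petal_id", "x", "y", "distance", "sector")], 1)
#>             petal_id          x         y  distance  sector
#> 1 CFA_plant01_petal1 -0.1413747 0.0668505 0.1563835 UV-Blue
```

Petal areas and ozone exposure:

```r
estimate_area_reductions(sim$areas)          # % of the CFA mean
#>   treatment mean_area_cm2 percent_reduction
#> 2       CFA     0.8038257           0.00000
#> 4       NFA     0.5906629          26.51854   # configured 19.8 (n = 18/group)
#> 3       FU+     0.5334827          33.63204   # configured 25.0

s <- simulate_o3_series(days = 37, window_mean_target = 64.6)
aot40(s)$aot40_nl_l_h
#> 7281.6

chamber_effect_summary()[1:3, ]
#>                    quantity     value units
#> 1 filtration_efficiency_cfa 47.457627     %
#> 2             o3_nfa_vs_amb -2.905569     %
#> 3          o3_fuplus_vs_amb 56.416465     %
```

At 18 petals per treatment the recovered reductions scatter widely around
the configured 19.8%/25%; at 200 petals per treatment they land within a
couple of percentage points (see below). `run_pipeline()` chains all of the
above and writes tidy CSVs plus a JSON manifest echoing every threshold.

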