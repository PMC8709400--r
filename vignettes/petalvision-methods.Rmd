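---
title: "Methods: spectra, pollinator colour spaces, and ozone-exposure statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectra, pollinator colour spaces, and ozone-exposure statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petalvision)
```

`petalvision` analyses ozone effects on flower visual-attraction traits:
petal reflectance spectra, pigment indices, insect colour perception, petal
area, and the exposure and microclimate metrics of open-top-chamber (OTC)
fumigation trials. This vignette documents the models and procedures, the
parameters that matter, the synthetic-data generator, and the numerical and
design choices made where the design was genuinely open.

## 1. Spectra

A `petal_spectrum` stores relative reflectance (white reference = 1) on a
strictly increasing wavelength grid. Spectroradiometer output arrives at
~3-nm resolution over 325–1075 nm; all index arithmetic happens after
linear resampling to a 1-nm grid, because the pigment index addresses exact
wavelengths (550, 700, 800 nm). Reflectance is stored as a fraction
throughout; percent-scaled files are divided by 100 at the reader and
nowhere else, so a stray factor of 100 cannot leak into ratio indices.
Repeated scans of one petal are averaged pointwise (instrument protocols
average ~25 scans). No smoothing is applied by default — spectra are
analysed as measured — though a boxcar smoother is available
(`smooth_boxcar()`) for noisy instruments.

The peak metric `max_peak_height()` reports the maximum reflectance in a
window (default 325–600 nm, bracketing the short-wavelength peak of
anthocyanin-rich petals) together with its wavelength. Peak-finding tools
differ in whether "height" means the absolute maximum or the rise above a
local minimum; both are exposed (`above_min`), and the absolute maximum is
the default because it needs no baseline convention.

## 2. Anthocyanin reflectance index

`ARI = (R800/R550) − (R800/R700)`. Anthocyanins absorb around 550 nm;
R700 corrects for red-edge/scattering effects and R800 anchors the
near-infrared where pigments do not absorb. The index is invariant to a
common rescaling of the spectrum and strictly decreasing in R550 — both are
enforced as property tests. Ordinates are point values on the 1-nm grid by
default; a ±5-nm band mean is available behind a flag but is not the
default because the definition addresses point wavelengths. Petals with
non-positive R550 or R700 get an explicit undefined-index report rather
than silent removal. For statistics ARI is log-transformed (natural log,
applied in the analysis layer, not in `ari()`); non-positive ARI values
would be flagged per petal at that point.

## 3. Pollinator vision models

All vision computations trim inputs to 325–700 nm. Three ingredients:

- **Receptor sensitivities** come from the Govardovskii A1 visual-pigment
  template (`pigment_template()`): the standard three-exponential α-band
  plus a Gaussian β-band, peak-normalized. Each guild is fully specified by
  its receptor peak wavelengths, which are configuration, not code:
  bee UV 344 / B 436 / G 556 nm (honeybee-like); fly R7p 330 / R7y 350 /
  R8p 430 / R8y 530 nm; butterfly u 360 / s 440 / m 530 / l 600 nm. These
  defaults approximate published sensitivity curves that are not tabulated
  here; any receptor set can be substituted via `visual_system(lambda_max=)`.
- **Illuminant**: CIE standard daylight D65, embedded as the 10-nm relative
  power table, interpolated and converted to relative quanta (power × λ) —
  catches are photon counts.
- **Background**: a smooth synthetic green-foliage reflectance (low
  UV/blue, modest 550-nm bump, red trough, sigmoidal red edge to an NIR
  plateau). It plays only the role of the von Kries adapting background.

Quantum catch is the trapezoidal integral `Q = ∫ R S I dλ`; von Kries
adaptation divides by the background catch, so a petal spectrally identical
to the background has q = 1 in every receptor and maps to the neutral point
of every space — the hexagon centre, the fly origin, and the tetrahedron
centroid. This fixed point is verified to 1e-10 end-to-end.

**Bee hexagon.** Excitations `E = q/(q+1)` (hyperbolic transduction), then
`x = (√3/2)(E_G − E_UV)`, `y = E_B − (E_UV + E_G)/2`. All loci lie within
unit distance of the centre. Sectors are six 60° wedges centred on the
three receptor directions and their bisectors (Blue at 90°, then
Blue-Green, Green, UV-Green, UV, UV-Blue clockwise). No receptor-noise
model is used: the discrimination rule downstream is a plain Euclidean
threshold, so a noise-scaled space would change nothing but the units.

**Fly categorical space.** `cx = q(R7p) − q(R8p)`, `cy = q(R7y) − q(R8y)`;
flies are modelled as discriminating only across quadrants. The
quadrant→name map is a configuration table (`fly_category_map()`); the
default reads UV-rich stimuli (both R7 receptors above their R8 partners)
as Fly UV and both-negative as Fly Blue, with Fly Yellow and Fly Purple on
the mixed quadrants. The sign convention differs between sources, hence
config rather than code. Loci with a coordinate exactly zero are labelled
`boundary` and never silently assigned to a quadrant.

**Butterfly tetrahedron.** Relative catches `q_i/Σq` are the convex weights
of a regular tetrahedron with circumradius 1, centroid at the origin, and
the u (UV) vertex on +z. A receptor's "axis value" for a locus is the
projection onto the unit vector toward that vertex; for u this is simply
the z coordinate.

**Luminance** is the adapted catch of the guild's longest-wavelength
receptor (bee G, fly R8y, butterfly l).

## 4. Perceptibility

`perceptibility_rule()` encodes the discrimination criteria associated with
a ~60%-correct choice level: quadrant change (fly), Euclidean hexagon
distance ≥ 0.09 (bee), and axis difference ≥ 0.03 (butterfly, default axis
u — the receptor where petal variation concentrates; a
Euclidean-in-tetrahedron variant is available). Group-level scoring
(`cross_treatment_perceptibility()`) compares each treated petal with the
control group via one of two reference constructions:

- **centroid** (default): distance to the coordinate-wise mean of the
  control loci — this mirrors treating the control cloud as a single
  reference region;
- **strict**: the petal must be perceptible from every individual control
  petal.

Neither mode dominates the other as a theorem: a treated petal surrounded
by a ring of distant control petals is far from each control but close to
their centroid. In practice control clouds are compact relative to the
threshold, and then strict mode can only flag fewer petals; the test suite
asserts exactly that regime (compact control clouds, 100 seeded datasets).
Both modes ship because the choice materially affects reported fractions
and deserves a sensitivity analysis in any application.

## 5. Statistics

**PERMANOVA.** Spectra (petals × wavelengths) are square-root transformed
and converted to Bray–Curtis dissimilarities. The phrase "squared then root
transformed" in trial write-ups is read as the square-root transform: the
literal square-then-root composition is the identity on non-negative data
and cannot affect any dissimilarity, so it cannot describe a real
preprocessing step. Both `"sqrt"` and `"none"` are selectable, and a
regression-guard test asserts the two genuinely differ. The pseudo-F uses
Anderson's partition — `SS_total = Σ_{i<j} d²_ij / n`, within-group
analogues by group size — and significance comes from permuting group
labels with a required seed: `p = (1 + #{F* ≥ F}) / (1 + n_perm)`. For
small designs `exhaustive = TRUE` enumerates every distinct label
arrangement and returns the exact permutation p; on a 3+3 design this is
verified against an independent brute-force enumeration. The default
permutation count for applications is 9999; tests use fewer.

A note on test size: with very small balanced groups the permutation
distribution is coarse (complement splits tie), making the test visibly
conservative — with two groups of 5 the achievable size at α = 0.05 is
about 4.6%. Null-calibration checks therefore use groups of 10, where the
distribution is effectively continuous and the empirical size is ~5%.

**Planned contrasts.** Single-df tests of `Σ c_g μ_g = 0` inside the
one-way (or ANCOVA) model, with presets for the linear dose trend
(orthogonal polynomial scores), the NFA-vs-rest coding (−1, 2, −1), and the
control-vs-rest coding (2, −1, −1). The implementation uses the general
linear hypothesis on the cell-means parameterization; an independent
closed-form oracle `(Σ c_g ȳ_g)² / (MSW Σ c_g²/n_g)` confirms it to 1e-9,
and orthogonal contrasts are verified to decompose the between-group sum of
squares. Petal area enters reflectance-derived analyses as a covariate
(entered first, sequential SS) because petals may not cover the instrument
aperture. No multiplicity adjustment is applied; p-values are reported raw.

**Random-intercept model.** `y = treatment + plant + ε` with plants nested
in treatments, fitted by maximum likelihood — not REML — so AICs are
comparable across fixed-effect structures. The likelihood is profiled over
the variance ratio λ = σ²_plant/σ²_resid: for fixed λ the covariance is
block diagonal (`I + λJ` per plant), giving closed-form GLS estimates and
determinants, and a one-dimensional search over log λ (tolerance 1e-8,
explicit λ = 0 boundary check) finishes the fit. AIC counts both variance
parameters. The treatment statistic is a likelihood-ratio χ² (mixed model
with vs without treatment), labelled as such since Wald and LRT versions
differ in small samples. The fit matches `lme4::lmer(REML = FALSE)` to
1e-4 on shared quantities in the test suite. One caution from calibration:
with true σ²_plant = 0, the fixed-only model wins the AIC comparison ~98%
of the time in an 18-plant × 3-petal design, but the *estimated* plant
variance exceeds 5% of the residual variance in ~20% of such datasets —
variance components from 3 observations per plant are noisy, and claims
about them need ≥ ~10 observations per plant.

## 6. Ozone exposure and microclimate

AOT40 accumulates `max(0, c − 40)` nL L⁻¹ over hours whose start falls in
the 07:00–14:00 window — eight hourly values per day, matching an
8 h day⁻¹ (7:00–15:00) fumigation schedule. Missing hours are skipped and
counted; no gap filling. Window and daily means are plain arithmetic means.
Filtration efficiency is `100(1 − CFA/AMB)` on window means; chamber
effects are absolute deltas (temperature, RH) or relative percent
differences (VPD, PAR). VPD uses the Magnus form
`es = 0.6108·exp(17.27t/(t + 237.3))`, `VPD = es(1 − rh/100)`, applied per
hourly record and then averaged — never to period-mean T and RH, because
es is convex in temperature and the shortcut is biased. A bundled reference
table (`otc_reference_table()`) carries the per-treatment exposure and
microclimate summary of a 37-day OTC trial; `chamber_effect_summary()`
recomputes all seven comparison numbers from its cells.

## 7. The synthetic-data generator

The generator exists so the whole pipeline can be exercised and calibrated
without instrument data. It emulates anthocyanin-type petals:

`R(λ) = scale · [base(λ) − depth · G₅₅₀(λ) + uv bump] + noise`,

where `base` rises sigmoidally from a visible baseline (0.35) to an NIR
plateau (0.62) across a 640-nm red edge, the Gaussian trough (depth 0.22,
width 60 nm) sits on the 550-nm anthocyanin absorption, and a UV bump
(380 nm, amplitude 0.06) adds the short-wavelength component. The shape
guarantees a reflectance minimum near 550 nm and R(800) > R(550), so ARI is
positive. The noise-free ordinates are closed-form
(`model_reflectance()`), which the tests use to check ARI exactly.

Treatment effects: reflectance scale 1.00 (CFA) / 1.06 (NFA) / 1.12 (FU+)
— an overall reflectance increase with ozone; an extra trough depth of 0.06
for NFA only (the ARI bump at ambient ozone); mean-area multipliers 1.000 /
0.802 / 0.750 for CFA / NFA / FU+ (the 19.8% and 25% reductions the
generator is calibrated to), with AMB behaving like NFA. Petal areas take
mean-one lognormal noise with cv 0.25 — consistent with such reductions
being detectable at ~17 petals per treatment, as in the emulated design —
around a base area of 0.8 cm². Plant-to-plant variation is a single
standard-normal draw per plant scaled by `plant_sd = 0.08` (a modest,
realistic cv for clonal-age potted plants of one population): it acts
multiplicatively on area (after mean-one correction) and additively on the
reflectance scale. Each plant consumes its own RNG sub-stream derived from
the master seed, so enlarging the design does not perturb existing plants'
draws, and a fixed seed reproduces the dataset byte for byte.

What the generator does *not* emulate: wavelength-correlated instrument
noise, petal-to-petal shape (rather than scale) variation, specular
effects, and any real covariance between area and pigmentation. Passing
tests therefore demonstrate the pipeline's correctness and calibration on
data with the assumed structure, not the biology of any real species.

Sampling arithmetic worth knowing: at 200 petals per treatment with area
cv 0.25, the recovered percent reduction has a sampling sd of ≈2–2.7
percentage points, so single-dataset estimates routinely sit 1–2 points
from the configured 19.8/25 — the parameter-recovery checks run at exactly
this scale and tolerance.

The ozone series generator builds a sinusoidal diurnal cycle peaking at
13:00 and rescales it in closed form so the 07–15 h window mean equals the
target exactly, which pins AOT40 to an analytic expectation the tests
verify.

## 8. Problem sizes and determinism

Test and calibration runs use deliberately small designs: 3+3 petals for
exhaustive PERMANOVA (20 arrangements), 2000 seeded null datasets for the
size checks of the contrast test and PERMANOVA (199 permutations each, two
groups of 10), 200 replicates for the AIC selection calibration, and 200
petals per treatment for parameter recovery. Every stochastic step takes an
explicit seed; the pipeline writes a manifest recording the seed, the
configuration hash, and every threshold (0.09, 0.03, 40 nL L⁻¹, the 7–15 h
window) so published defaults are auditable.

## 9. Known limitations

- Receptor templates approximate, not reproduce, measured sensitivity
  curves; conclusions sensitive to exact λmax should re-run with measured
  curves supplied via configuration.
- The fly quadrant→name mapping is a convention; relabelling quadrants
  changes names, never the discrimination structure.
- The centroid/strict choice changes perceptibility fractions; report both
  when the control cloud is not compact.
- ML variance components from designs with few observations per plant are
  noisy; the AIC model choice is more stable than the variance estimates
  themselves.
- Bray–Curtis on reflectance treats wavelengths as exchangeable features;
  it ignores spectral smoothness entirely.
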