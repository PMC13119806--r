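---
title: "Methods: deriving and testing leaf drought-response traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and testing leaf drought-response traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafdrought)
```

## The experiment this package models

`leafdrought` analyses a factorial drought experiment on potted tree
seedlings during the autumn leaf-coloration window: four soil-water
treatments (CK = 100% of field capacity, T1 = 75–80%, T2 = 50–55%,
T3 = 35–40%), four sampling periods 20 days apart (S1–S4), and three
replicates per cell. At every sampling, leaves are measured for CIELAB
color (L*, a*, b*), pigment contents, anatomical thicknesses, gas
exchange, antioxidant enzyme activities and three families of hydraulic
traits. The package derives replicate-level traits from the raw
measurement streams, applies the matching one-way inference layer, and
quantifies which physiological traits statistically explain the color
coordinates with permutation-tested random-forest importance.

## Trait derivation

### Colorimetry

Color readings are taken on ten leaves per replicate, ten readings per
leaf. Leaves are the sampling unit, so `aggregate_color()` averages
readings within each leaf first and then averages leaf means,
unweighted, reporting the SE over leaves. This makes the aggregate
invariant to duplicating readings within a leaf — a pooled reading mean
is not.

### Anatomy

The palisade-to-spongy ratio is `compute_psr(pt, st) = pt/st`. When raw
per-leaf sections are available the ratio is computed per leaf and
averaged; when only cell means exist (as in published summary tables)
the ratio of means is used. The two conventions agree to the printed
two decimals on the reference table, so the package treats the
ratio-of-means as an adequate approximation in table-parity checks.

### Pigments

Chlorophyll and carotenoid contents come from absorbances of an 80%
acetone extract at 645/663 nm and 445 nm; anthocyanins from an
acidified-methanol extract at 530/657 nm. Because extinction
coefficient sets differ between solvents and labs and none are printed
with the protocol this package mirrors, the coefficients are
configuration (`default_pigment_coefficients()`), with Arnon-style
chlorophyll equations (total Chl = 20.2·A645 + 8.02·A663 mg L⁻¹) and a
carotenoid equation adapted to 445 nm as documented defaults.
Anthocyanins default to relative ΔA-based units
(ΔA = A530 − 0.25·A657, floored at zero and flagged when floored),
since molar-extinction conventions also vary; `ant_scale` switches to
absolute units if a lab's coefficient is known. Every content is
homogeneous of degree 1 in extract volume and dilution and degree −1 in
extracted mass — properties the test suite enforces.

### Hydraulics: anatomical Kmax

Petiole xylem vessels are treated as ideal capillaries. A vessel of
cross-section area `A_v` gets an equivalent circular radius
`r = sqrt(A_v/π)`, and its volumetric conductivity is the
Hagen–Poiseuille form `K_i = π r⁴ / (8 η ℓ)`. Two choices deserve
comment:

* **Conduit length.** The bare `π r⁴ / (8 η)` form sometimes quoted for
  single-vessel "conductivity" is not dimensionally a conductivity;
  a conduit length is required. The package includes the petiole length
  `ℓ` explicitly (default 0.02 m, configurable). Absolute Kmax
  magnitudes therefore depend on this choice; treatment contrasts do
  not, because `ℓ` enters every vessel identically.
* **Viscosity.** `water_viscosity()` uses the Vogel correlation
  (1.002×10⁻³ Pa·s at 20 °C, 0.890×10⁻³ at 25 °C); the default water
  temperature is 25 °C.

Leaf-level conductance scales the vessel sum by the total-to-counted
ratio `N/n` (the sizing protocol requires n ≥ 2N/3; smaller fractions
warn), divides by supported leaf area, and converts from
m³ s⁻¹ Pa⁻¹ m⁻² to mmol m⁻² s⁻¹ MPa⁻¹ via the molar volume of water
(1.8×10⁻⁵ m³ mol⁻¹), 10³ mmol/mol and 10⁶ Pa/MPa. The default
synthetic vessel configuration (40 vessels, radius 5.5 ± 0.8 μm,
leaf area 0.003 m², ℓ = 0.02 m) lands mid-range of field-plausible
angiosperm values; the acceptance suite checks the resulting Kmax
against the 9.7–22.5 mmol m⁻² s⁻¹ MPa⁻¹ span.

### Hydraulics: epidermal conductance

A saturated, darkened leaf first loses water through closing stomata
(steep phase), then through the epidermis alone (linear tail).
`detect_epidermal_phase()` fits every admissible two-segment
piecewise-linear model (each segment ≥ 3 points) and keeps the
breakpoint minimizing total squared error; the tail's OLS slope feeds
`epidermal_conductance()`:

> ge = 2.31×10⁶ · |Δw/Δt| · (1/A) · (1/Δe)

The 2.31×10⁶ conversion factor is taken as given with the equation it
comes from; its exact unit derivation is not stated there, so Δe is
consumed as a number in that equation's own units. A separate helper
(`absolute_humidity_difference()`) computes a leaf–air absolute
humidity difference in g m⁻³ from temperatures and relative humidity
via the Tetens formula, kept deliberately apart from the conductance
equation because of that unit ambiguity.

### Hydraulics: pressure–volume curves

Balance pressure P (water potential ψ = −P) is recorded against fresh
weight during a bench drydown. In the transformed plane
(x = 1 − RWC, y = 1/ψ), the purely osmotic region below the turgor
loss point is linear:

* ψ_sat = 1/intercept (osmotic potential at full saturation),
* apoplastic fraction = 1 − x₀ at the line's zero crossing,
* RWC_tlp = RWC of the wettest point still on the line,
* ψ_tlp = the osmotic line evaluated at RWC_tlp.

The linear region is selected automatically by growing the accepted
set from the driest observation towards wetter ones. The selection
criteria are this package's own choices (the classical programs'
internal criteria are not published), and three of them matter
numerically:

1. **Pressure-domain residual gate.** Chamber noise is approximately
   homoscedastic in pressure, but the 1/ψ transform inflates it at the
   wet end of the osmotic region. Residuals are therefore gated in the
   pressure domain: a candidate is accepted when its pressure residual
   is within `resid_k = 2.5` times the current fit's pressure RMSE.
2. **Prediction-variance scaling and a pilot scale.** The band is
   multiplied by the OLS prediction-standard-error factor
   `sqrt(1 + 1/k + (x−x̄)²/Sxx)` so that small, extrapolating regions
   are not miscalibrated, and the RMSE is floored by a pilot estimate
   from the six driest points (exactly linear there).
3. **Skip tolerance.** Isolated outliers are skipped; growth stops only
   on two consecutive rejections — the signature of systematic turgor
   onset rather than noise. An R² below `r2_min = 0.99` on the final
   line triggers a diagnostic warning, and a non-negative intercept
   (which would imply ψ_sat ≥ 0) is an error.

RWC_tlp is reported at the wettest accepted observation (the
discrete-departure convention of classical PV analysis); an
`interpolate = TRUE` flag reports the midpoint to the next wetter
observation instead.

## Inference layer

The reporting style mirrored here annotates each trait twice: lowercase
letters compare treatments within a period, uppercase letters compare
periods within a treatment, each from an independent one-way family. No
two-way model and no cross-trait multiplicity correction are applied,
because the reports this package mirrors use neither — a caveat worth
repeating when reading its outputs.

`anova_from_summary()` reconstructs the classical decomposition from
printed mean ± SE (n) rows, using n·SE² as the within-group variance;
it is provably identical to `anova_oneway()` on any raw data sharing
those sufficient statistics, and the suite checks the equivalence to
ten decimals on random instances.

Duncan's multiple range test computes the critical range for a
comparison spanning p ranks from the studentized-range quantile at
Duncan's protection level αₚ = 1 − (1 − α)^(p−1) — reproducing the
classical tables without shipping them — and applies the standard
containment rule (a pair inside a non-significant span is
non-significant). Compact letters come from the insert-and-absorb
algorithm, assigned in descending-mean order. Two sandwich properties
are enforced in tests: Duncan declares at least as many significant
pairs as Tukey's HSD and at most as many as unadjusted LSD.

## Random-forest importance

The forest learner is the `randomForest` package (bootstrap regression
trees, default `ntree = 500`); everything the analysis actually
specifies is implemented here:

* `permutation_importance()` — %IncMSE: permute a predictor, re-score
  every tree on its own out-of-bag rows, average the per-tree
  percentage MSE increase. One permutation is drawn per predictor and
  shared across trees (one prediction pass per predictor); a tiny-forest
  brute-force oracle in the tests walks the trees by hand to confirm
  the loop.
* `importance_significance()` — per-predictor permutation test: the
  null re-fits the forest on permuted responses
  (default 100 permutations), and p = (1 + #{null ≥ obs})/(n_perm + 1),
  so p is never exactly zero.
* `model_significance()` — the same construction on the out-of-bag R²,
  default 99 permutations (minimum attainable p = 0.01).
* `backward_select()` — iteratively drops the lowest-%IncMSE predictor
  and refits until the target count (default 14) remains. The drop
  criterion is this package's concrete choice; only the procedure's
  name and its retained count are specified by the analysis it mirrors.

With n = 48 observations (4×4×3) and ~14 predictors, importance
rankings are seed-sensitive; `importance_over_seeds()` (20 seeds by
default) is the recommended way to read them, and printed reports carry
the caveat. A related practical note: with a single informative
predictor among noise, the default `mtry = p/3` dilutes the signal and
caps the OOB R² well below what `mtry = p` (bagging) achieves; the
validation suite sets `mtry` explicitly where that matters.

## The synthetic experiment

`default_experiment_config()` fixes the study conditions: 4 treatments
× 4 periods × 3 replicates and 26 traits. Anatomical cell means and
SEs are the published table values; all figure-only traits (color,
pigments, enzymes, gas exchange, hydraulics) are plausible
reconstructions that honour every printed anchor number and percent
change and the qualitative temporal patterns described in the source
study's text — they are calibrations, not printed numbers, and are
documented as such in the code.

Replicate noise is Gaussian with sd = SE·√n where n = 3 is the
replicate count over which the SEs were computed, so sample SEs
reproduce the configured SEs in expectation even when more replicates
are generated for convergence checks. All draws flow from one master
seed through named substreams (`substream_seed()`), so each stage can
be regenerated independently and re-running one stage never perturbs
another; fixed seed means bit-identical output.

The generators for raw streams are exact inverses of the corresponding
estimators at zero noise, which the suite exploits as round-trip
identities: absorbance sets invert the pigment equations (a fixed
A663/A645 spectral shape closes the underdetermined system), drydown
series embed the tail slope implied by inverting the conductance
equation, and PV curves follow ψ(R) = ψ_sat(1−af)/(R−af) plus a turgor
component declining linearly from −ψ_sat at full hydration to zero at
the turgor loss point — the simplest turgor model consistent with the
classical osmometer framework and sufficient for recovery testing.

What the generator does **not** emulate: soil-water dynamics and
irrigation control, seedling growth, within-leaf spatial structure,
non-Gaussian replicate distributions (the source reports give no raw
distributions; Gaussian is an assumption), and any genuine biological
coupling between traits beyond what the cell-mean profiles induce.
Passing tests therefore demonstrate that the estimators recover known
truths under realistic noise and that the inference layer reproduces
published table annotations — not that the pipeline's scientific
conclusions would transfer to arbitrary real data.

## Validation problem sizes

The recovery and calibration checks run at desk scale, chosen to keep
the full suite in a few minutes while leaving comfortable statistical
margins: 100 simulated PV curves (30 points each, 0.02 MPa pressure
noise) for parameter recovery; 100 drydown series (0.002 g balance
noise) for conductance recovery; 100 seeds × 100 response permutations
with 100-tree forests on 30×8 feature matrices for the type-I and
power calibration of the importance test; 20 seeds × 500-tree forests
on the full 48×23 synthetic experiment for the predictor-set ranking
property.

## Known limitations

* Absolute Kmax values inherit the petiole-length and viscosity
  conventions above; only relative comparisons are calibration-free.
* The PV fit requires curves that genuinely span the post-turgor-loss
  region; it reports, but cannot repair, curves that stop near full
  turgor.
* Duncan's test assumes (near-)equal group sizes; unequal n falls back
  to the harmonic mean with a warning.
* The permutation tests refit forests under the null, which is honest
  but O(n_perm) in forest fits; reduce `ntree` for exploratory runs.
* Anthocyanin contents are in relative units unless a lab-specific
  extinction coefficient is supplied, so they compare within a study
  but not across instruments.
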