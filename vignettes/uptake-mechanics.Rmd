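---
title: "Substrate rigidity and particle uptake: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate rigidity and particle uptake: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uptakemech)
```

## The physical picture

Non-professional phagocytes — here, adherent cancer cells — internalize
micron-scale particles by deforming around them. The first, rate-limiting
step is passive: the particle must form a stable adhesive contact with the
membrane before active, cytoskeleton-driven engulfment can proceed. Substrate
rigidity ξ (the Young's modulus of the gel the cell sits on, in kPa) enters
twice, with opposing signs:

1. **Spreading.** Cells spread further on stiffer substrates; the relative
   spread area saturates, and we model it as `A(ξ) = tanh(α_A ξ)` with
   `α_A = 0.2 /kPa`. More spread area means more particles in contact per
   cell. (The anomalously high spreading sometimes seen on the softest
   0.5 kPa commercial substrates is deliberately *not* modelled; the tanh law
   describes the trend with that divergent point excluded.)

2. **Stiffening.** Cells also stiffen on stiffer substrates,
   `E(ξ) = E_max tanh(α_E ξ)` with `α_E = 0.05 /kPa`. A stiffer cell resists
   the local deformation that wrapping a particle requires.

The equilibrium wrapping (contact) angle balances the work of adhesion
`Δγ` (kPa·μm) against membrane bending `κ` (kPa·μm³) and cell compliance:

$$\theta(\xi) = \frac{3\pi}{4}\,
  \frac{\Delta\gamma - 4\kappa/R^2}{E(\xi)\,R}, \qquad
  \theta \in [0, \pi],$$

for a particle of radius `R` (μm). The printed form of this expression in the
source literature has ambiguous division bars; the grouping adopted here is
the unique one that is dimensionless and reproduces all stated trends
(θ decreasing in `E`, adhesion-promoted, bending-penalized). It is implemented
in one place (`contact_angle()`) so an alternative reading can be swapped in.
Values below 0 (adhesion cannot pay the bending cost — particles smaller than
the critical radius `R_c = sqrt(4κ/Δγ) ≈ 0.195 μm` at the defaults) clamp to
θ = 0; values above π mean full wrapping. The wrapped spherical-cap area is
`a = 2πR²(1 − cos θ)`, and the uptake propensity is the product

$$P(\xi) \propto A(\xi)\, a(\xi) \, g(\xi),$$

where `g(ξ) = 1 + β ξ/(ξ + ξ_half)` is an optional *functionality*
multiplier standing in for elevated biological activity on stiff substrates
(β = 0 by default: pure physics). Whether that correction is additive or
multiplicative is not established; a saturating multiplicative form was
chosen for boundedness and monotonicity, and is documented as this package's
choice, not as established mechanism. The superposition of the physical
rise-fall and biological corrections is what produces wave-like
("meandering") uptake-vs-rigidity curves.

## Parameters, units, defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| `delta_gamma` | work of adhesion per contact area | kPa·μm | 0.002 |
| `kappa` | membrane bending modulus | kPa·μm³ | 1.9e-5 |
| `alpha_A` | spreading saturation rate | 1/kPa | 0.2 |
| `alpha_E` | stiffening saturation rate | 1/kPa | 0.05 |
| `E_max` | cell-modulus prefactor | kPa | 0.0075 |
| `beta_func` | functionality amplitude | — | 0 |
| `xi_half` | functionality half-saturation | kPa | 16 |

**Calibration of `E_max`.** The stiffening law is stated in the literature
only as a proportionality; no prefactor is given. `E_max` is therefore a
calibration constant, not a literal cell modulus: on the scale on which
`Δγ` and `κ` are quoted, it absorbs every unstated proportionality constant
of the model. The default, `E_max = 0.0075` kPa, is derived by placing the
wrapping transition of an 0.8 μm bead — the point where θ leaves full
wrapping and the propensity peaks — at 8 kPa, the midpoint of the commercial
substrate panel {0.5, 2, 8, 16, 32, 64} kPa. This choice makes the model
reproduce its two documented signatures across the experimental window:
a single interior rise-fall peak for both bead sizes, and (with the default
event-generator calibration λ = 2) peak uptake fractions near 97%, matching
the observed regime in which ~95% of cells internalize at least one bead.
With a much larger `E_max` (for instance literal cell moduli of 0.5–5 kPa)
the transition migrates below 0.1 kPa and the curve is monotonically
decreasing over the whole physiological panel, contradicting those
signatures; users exploring that regime can simply pass their own value.

**Bead sizes.** The canonical particles are 0.8 and 2.4 μm diameter, i.e.
radii 0.4 and 1.2 μm. Size enters only through the contact area `a(R)`; in
the model (and in `fit_uptake_model()`) there is deliberately no per-size
calibration constant, which encodes the claim that size dependence is a
contact-area effect.

## Estimators

**Young's modulus.** Compression traces are converted with engineering
conventions (pre-compression cross-section and edge length, per the
measurement protocol), and the modulus is the zero-intercept least-squares
slope over the strain window (0, 0.10]. The protocol phrase "fitting the 10%
strain data point with a linear regression line" is ambiguous between a
single point and a window; a single point admits no regression, so the window
reading is used (configurable). The zero intercept follows from stress
vanishing at zero strain; it is also configurable in spirit — pass a curve
with a toe-region offset via `strain_offset`.

**Spreading area.** Channel thresholds default to Otsu's method per channel:
the original analysis chose thresholds manually per image, which is not
reproducible; Otsu is validated here against synthetic ground truth only.
"Stained fraction" is the share of pixels strictly above threshold (the
complement of the histogram mass below it). Nuclei are counted as 8-connected
above-threshold components of at least 20 px; touching nuclei merge (no
watershed), so counts are conservative on crowded fields. Per-cell areas are
stained area divided by nucleus count, with the nucleus-excluded variant
using the cell mask minus the nuclear mask.

**Gating and fractions.** Focused events require gradient RMS ≥ 50 (the
protocol's stated threshold). The singlet rule — high aspect ratio, low area —
is stated without numbers in the protocol; defaults here are aspect ratio
≥ 0.6 and area ≤ 1.5× the median event area, both configurable. The uptake
readout is the percentage of gated cells with at least one internalized bead.

**Zero-class link.** Per-cell bead counts are modelled as Poisson with mean
`λ·A·a·g`; the probability of internalizing any number of beads is then
`1 − exp(−λAag)`. This is the simplest generative bridge from a propensity
stated only up to proportionality to a fraction-of-cells readout, and it is
what `fit_uptake_model()` maximizes a binomial likelihood over (seeded
multistart, profile-likelihood intervals).

**Meandering test.** `detect_nonmonotonicity()` fits three
shape-constrained least-squares regressions to the per-rigidity replicate
means (weighted pool-adjacent-violators): monotone, rise-fall (umbrella with
free split) and fall-rise. The verdict is the smallest-RSS class, with ties
broken toward monotone because the umbrella class nests every monotone fit.
Significance comes from a bootstrap *under the monotone null*: within-rigidity
residuals (variance-corrected by n/(n−1)) are resampled around the monotone
fit and the RSS improvement of the best non-monotone shape is recomputed.
Resampling raw replicates would not impose the null and gives no type-I
control, which is why the null-residual form was chosen. The experimental
unit respected by the resampling is the replicate well, not the cell.

## The synthetic generators

The generators emulate the statistical structure the estimators assume — not
the optics or chemistry of the real assays:

- **events**: per-cell Poisson counts from the mechanics model
  (λ = 2 by default, chosen with the `E_max` calibration so fractions span
  ~30–97% across the panel, the regime the assays report); lognormal per-bead
  fluorescence (intensity is zero exactly when the count is zero); configured
  out-of-focus (10%) and doublet (5%) fractions; n = 3 replicates,
  1000 cells per condition by default (real per-condition cell counts are
  unreported; this default is statistical, not biological).
- **compression**: linear-elastic stress `E·strain` on a strain grid to 0.9
  (samples compressed to 90% of original size), multiplicative force noise
  (5% default), optional strain-stiffening beyond 10% strain to exercise the
  window choice.
- **images**: non-overlapping ellipses (10% area CV, axis ratio 0.6–1), one
  concentric nucleus per cell at 16% of cell area, unit foreground intensity,
  Gaussian noise of sd 1/SNR. No point-spread function, no instance-level
  shape realism: the generator supports area quantification, nothing more.
  Panel images follow `area_max·tanh(0.2ξ)` with `area_max = 1200 μm²`,
  giving ~120 μm² cells on 0.5 kPa and saturation above 16 kPa.

One global seed expands into fixed per-stream substreams (events, images,
compression), so identical configurations are bit-identical and modules can
be regenerated independently. Every generator returns a truth record
sufficient to score its downstream estimator.

Passing tests on these generators shows the estimators are correct under the
assumed structure; it does not certify performance on real micrographs
(uneven illumination, touching cells), on viscoelastic gels, or on real
ImageStream data (whose proprietary raw format is out of scope — bead counts
arrive as a column, and surface-bound versus internalized beads are not
discriminated).

## Numerical choices and degenerate inputs

- θ is clamped to [0, π]; `E = 0` is rejected as singular rather than clamped.
- The peak scan in `predict_uptake_curve()` uses 512 log-spaced grid points
  across the panel range, ties broken toward the softest rigidity.
- The modulus fit requires ≥ 3 points in the strain window; replicate
  summaries report sd = 0 with n = 1 for a single cube.
- Images whose cell channel is stained but whose nuclear channel yields no
  countable nucleus raise a degenerate-image error instead of dividing by
  zero; blank pairs report zero areas.
- All-zero uptake counts drive λ to its lower boundary and are flagged, as is
  an over-parameterised fit (all four parameters free with one bead size and
  fewer than five rigidities).
- Bootstrap p-values use the (1 + #{T* ≥ T}) / (B + 1) form, so they are
  never exactly zero.

## Problem sizes used in the checks

The packaged checks run the recovery studies at: 10 cubes per gel grade
(truths 1.59, 9.19, 31.34 kPa, 5% noise); 100 seeded event simulations of
1000 cells × 6 rigidities × 3 replicates × 2 bead sizes for calibration
recovery; 200 simulations each for the meandering test's type-I error
(monotone truth, binomial n = 300) and power (model truth, which rises and
falls across the panel); and 6-image panels of 15 cells at SNR 5 for the
area pipeline. Power for the meandering test is measured against the model's
rise-fall truth because power against a monotone stretch of the curve is
undefined.

## Known limitations

- The contact state is the closed-form equilibrium: no engulfment kinetics,
  no free-energy minimization, no 3D substrate penetration.
- The functionality correction is a phenomenological placeholder with an
  assumed (multiplicative, saturating) form.
- Nucleus counting has no watershed; merged nuclei undercount cells and
  inflate per-cell areas on crowded fields.
- The provenance of the 3π/4 prefactor in θ is inherited from prior work and
  not re-derived here.
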