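# uptakemech

Adherent cancer cells internalize micron-scale particles (0.8–2.4 μm) in a
phagocytosis-like process that requires substantial cell deformation, and the
rigidity of the substrate a cell is plated on tunes both how far the cell
spreads and how stiff it becomes. `uptakemech` implements a thermodynamic
model of this mechanically mediated uptake together with the quantification
steps the analysis rests on, so the whole pipeline — from raw-style inputs to
the uptake-vs-rigidity curve and its shape classification — runs end to end
on synthetic data or on user-supplied TIFF images and CSV tables.

It is aimed at mechanobiology and drug-delivery researchers who want to
reason about how substrate stiffness (0.5–64 kPa, the physiological range)
modulates particle engulfment, and at analysts reproducing imaging-flow-
cytometry uptake studies.

## The model

Two opposing effects control uptake on a substrate of rigidity ξ (kPa):

- spreading: cells spread more on stiffer substrates,
  `A(ξ) = tanh(0.2 ξ)`, so each cell exposes more area to particles;
- stiffening: cells stiffen on stiffer substrates,
  `E(ξ) = E_max tanh(0.05 ξ)`, which raises the energetic cost of wrapping a
  particle and shrinks the equilibrium contact angle

  `θ(ξ) = (3π/4) (Δγ − 4κ/R²) / (E(ξ) R)`, clamped to [0, π],

  with work of adhesion Δγ = 0.002 kPa·μm, membrane bending modulus
  κ = 1.9·10⁻⁵ kPa·μm³ and particle radius R. The wrapped (spherical-cap)
  contact area is `a = 2πR²(1 − cos θ)`. Below the critical radius
  `R_c = √(4κ/Δγ) ≈ 0.195 μm` adhesion cannot pay the bending cost and θ = 0.

The uptake propensity is `P(ξ) ∝ A(ξ) · a(ξ)`, optionally multiplied by a
saturating cell-functionality factor `g(ξ) = 1 + β ξ/(ξ + ξ_half)` describing
elevated biological activity on stiff substrates. The opposing trends give a
rise-then-fall of uptake across the rigidity panel; superposed biological
effects produce the observed wave-like ("meandering") dependence.

Around the model, the package provides:

- `fit_young_modulus()` / `summarize_moduli()` — Young's moduli of gel cubes
  from micro-compression force–displacement traces (engineering stress–strain,
  zero-intercept fit over the (0, 10%] strain window);
- `area_report()`, `count_nuclei()`, `pixel_fraction_above()` — threshold
  based cell spreading area from two-channel (cell body + nuclei)
  fluorescence images, with and without nuclear exclusion;
- `gate_events()`, `uptake_fraction()` — focus (gradient RMS ≥ 50) and
  singlet gating of flow-cytometry-like event tables and the per-condition
  percentage of cells internalizing at least one bead;
- `detect_nonmonotonicity()` — shape-constrained regression (monotone vs
  rise-fall vs fall-rise) with a bootstrap p-value for rejecting monotonicity;
- `fit_uptake_model()` — binomial maximum likelihood linking the propensity
  to measured uptake fractions through a Poisson zero-class model,
  `p(ξ) = 1 − exp(−λ A a g)`;
- `sim_uptake_events()`, `sim_compression_curves()`, `sim_image()`,
  `sim_rigidity_panel_images()` — seeded synthetic-data generators with
  machine-readable ground truth for every estimator.

## Worked example

```r
library(uptakemech)
panel <- c(0.5, 2, 8, 16, 32, 64)          # commercial substrate panel, kPa

curve <- predict_uptake_curve(panel, radius = 0.4)   # 0.8 um beads
print(curve, digits = 3)
#>   rigidity_kpa value value_kind radius_um
#> 1          0.5 0.200 propensity       0.4
#> 2          2.0 0.764 propensity       0.4
#> 3          8.0 1.853 propensity       0.4
#> 4         16.0 1.233 propensity       0.4
#> 5         32.0 0.736 propensity       0.4
#> 6         64.0 0.643 propensity       0.4
attr(curve, "peak_rigidity")
#> [1] 8.55
```

The propensity rises from soft substrates (spreading-limited) to a peak at
8.5 kPa and declines as cell stiffening suppresses wrapping. Simulated
flow-cytometry events follow the same model (λ = 2 beads per unit
propensity), and the analysis chain recovers it:

```r
sim   <- sim_uptake_events(n_cells = 1000, seed = 1)
gated <- gate_events(sim$events)
fr    <- uptake_fraction(gated)
detect_nonmonotonicity(fr[fr$radius_um == 0.4, ], n_boot = 999, seed = 2)
#> Meandering-uptake shape test
#>   verdict: unimodal_rise_fall (monotone direction: increasing)
#>   p-value for rejecting monotonicity: 0.001 (999 bootstrap draws)

fit_uptake_model(uptake_counts(gated), seed = 1)
#> Binomial fit of the uptake mechanics model
#>   log-likelihood: -8753.056  converged: TRUE
#>              estimate lower upper
#> lambda_scale    2.006 1.971 2.042
```

The uptake fractions span ~30% (0.5 kPa) to ~97% (8 kPa): monotonicity is
rejected (p = 0.001), the verdict is the model's rise-fall shape, and the
calibration constant is recovered at its true value 2 with a tight
profile-likelihood interval.

A thin command-line wrapper over the same functions ships in
`inst/cli/uptakemech.R` (`predict`, `simulate`, `fit-stiffness`,
`quantify-image`, `fit-uptake`, `test-meander`); each run writes a JSON
manifest of its inputs, seed and outputs.

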