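# relaxfit

Backbone ¹⁵N spin-relaxation analysis for proteins, as a tidy R pipeline:

- **Rate fitting** — mono-exponential fits of R₁/R₂ peak-intensity decays,
  steady-state {¹H}-¹⁵N NOE ratios with first-order error propagation, and
  R₂ᵉᶠᶠ dispersion profiles from constant-time CPMG intensities with
  duplicate-plane error pooling.
- **Lipari–Szabo model-free analysis** — rotational diffusion-tensor
  estimation from R₂/R₁ ratios (isotropic or axially symmetric, oblate or
  prolate), staged selection among the five standard motional models
  M1 (S²), M2 (S², τe), M3 (S², Rex), M4 (S², τe, Rex), M5 (S², τe, S²f),
  and Monte Carlo parameter errors.
- **CPMG relaxation dispersion** — two-state (A ⇌ B) exchange fitting of
  two-field dispersion profiles with a numerical Bloch–McConnell
  propagator (Carver–Richards closed form as an independent oracle),
  per-residue and clustered global fits sharing k_ex and p_A·p_B, and
  population algebra p_A = (1 + √(1 − 4 p_A p_B))/2.
- **pH titration** — composite chemical-shift perturbations
  √(Δδ_H² + (0.2·Δδ_N)²) and peak-status bookkeeping (missing peaks,
  first-appearance pH, multiple-conformation windows) across a pH series.
- **Synthetic data** — seeded generators that produce decay, NOE, CPMG and
  titration peak tables with the statistical structure the fitters assume,
  plus ground-truth sidecars, so every estimator can be exercised in
  closed-loop recovery studies.

The intended user measures protein dynamics by solution NMR — for example
µs–ms conformational exchange in an acid-stress chaperone dimer whose
activation is driven by loop dynamics rather than structural change — and
wants the full analysis chain, from peak-intensity tables to fitted
exchange and motional parameters, reproducible in one scripted pass.

## Models

Relaxation rates are the standard dipolar + CSA expressions in the
spectral density J(ω) evaluated at {0, ω_N, ω_H−ω_N, ω_H, ω_H+ω_N}. The
model-free spectral density (axially symmetric tumbling) is

    J(ω) = (2/5) Σᵢ Aᵢ(θ) [ S² τᵢ/(1+(ωτᵢ)²) + (S²f−S²) τᵢ′/(1+(ωτᵢ′)²) ]

with τ₁ = 1/(6D⊥), τ₂ = 1/(5D⊥+D∥), τ₃ = 1/(2D⊥+4D∥),
τᵢ′ = τᵢτe/(τᵢ+τe), and amplitudes Aᵢ set by the angle θ between the N–H
bond and the symmetry axis.

CPMG dispersion uses R₂ᵉᶠᶠ = −(1/T_relax)·ln(I(ν_CPMG)/I₀) and a two-state
Bloch–McConnell propagator: over one τ_cp–180°–2τ_cp–180°–τ_cp block the
evolution collapses to a fixed 2×2 complex matrix G = E₁·conj(E₂)·E₁
(a 180° pulse conjugates the transverse magnetisation), which is raised to
the block count analytically. The exchange-free rate r₂⁰ enters R₂ᵉᶠᶠ
additively and is profiled out of every fit exactly.

## Worked example

Simulate a four-residue cluster undergoing a concerted two-state exchange
(k_ex = 1822 s⁻¹, p_A·p_B = 0.026) at 800.2 and 600.13 MHz, convert the
intensities to dispersion profiles, and fit all residues globally:

```r
library(relaxfit)
library(dplyr)

set.seed(1)
cluster <- tibble(residue = c(27L, 43L, 53L, 71L),
                  dw_ppm  = c(2.1, 1.6, 3.0, 2.4))
sim <- simulate_cpmg(cluster, kex = 1822,
                     pa = population_from_product(0.026),
                     r20 = 17, noise = 0.02, seed = 1)
profiles <- r2eff_profile(sim$intensities, t_relax = 0.06)
fit <- fit_dispersion_global(profiles, n_mc = 20, seed = 1)
fit
#> <dispersion_fit:global> kex = 1731 +/- 77 /s, pApB = 0.0265 +/- 0.0016 (pA = 97.3%)
#>   4 residues, 96 points, chi-square 87.40
tidy(fit)
#> # A tibble: 4 × 6
#>   residue dw_ppm dw_sigma chisq r20_600.13 r20_800.2
#>     <int>  <dbl>    <dbl> <dbl>      <dbl>     <dbl>
#> 1      27   1.96   0.0574  19.4       17.1      17.9
#> 2      43   1.57   0.0384  23.5       16.8      17.2
#> 3      53   2.90   0.107   25.2       17.0      17.6
#> 4      71   2.34   0.0670  19.3       17.2      16.7
```

The shared exchange rate comes back within ~5% of the generating
1822 s⁻¹, the population product within ±0.002 of 0.026 (a 97.3% major /
2.7% minor state), and the per-residue ¹⁵N shift differences Δω (ppm,
field-independent) within their Monte Carlo errors. `autoplot(fit,
profiles)` overlays the fitted curves on the data;
`write_report(fit, "cpmg_report.tsv")` writes a deterministic TSV with
provenance (config hash, seed).

The model-free side is analogous: `simulate_relaxation()` →
`fit_decays()` → `relaxation_records()` → `estimate_diffusion()` →
`model_free_analysis()`, with `tidy()`/`glance()`/`autoplot()` at each
fitted object. See the vignette (`vignettes/relaxation-dynamics.Rmd`) for
the full methodology.

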