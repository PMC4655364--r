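---
title: "Backbone dynamics by NMR relaxation: models, fitting choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone dynamics by NMR relaxation: models, fitting choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxfit)
library(dplyr)
```

relaxfit implements the complete computational chain used to characterise
protein backbone dynamics from ¹⁵N relaxation experiments: rate
estimation, Lipari–Szabo model-free analysis under an anisotropic
rotational diffusion tensor, two-state CPMG relaxation-dispersion fitting,
and pH-titration chemical-shift bookkeeping. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not demonstrate about real data.

The motivating use case is a small acid-stress chaperone homodimer
(~10 kDa per subunit) whose chaperone activity at mildly acidic pH is
coupled to µs–ms conformational exchange at the dimer interface rather
than to a structural transition: the same pipeline quantifies the overall
tumbling, the per-residue motional amplitudes, and the exchange kinetics
across pH conditions.

## Spin system and constants

The rate expressions need the N–H dipolar coupling and ¹⁵N CSA constants.
These are rarely printed alongside relaxation studies, so `spin_system()`
defaults to the community-standard values for backbone amides:

* `r_nh = 1.02` Å (effective N–H bond length),
* `csa_ppm = -160` (¹⁵N chemical-shift anisotropy),
* `gamma_ratio = -9.8655` (γH/γN).

All three are arguments and can be overridden; every derived quantity
(ω_H, ω_N, the squared dipolar and CSA constants) follows from them and
the ¹H frequency. Two fields are used throughout the CPMG machinery,
800.2 and 600.13 MHz, matching the two-spectrometer design the dispersion
experiments assume.

## Rate estimation

R₁ and R₂ come from mono-exponential fits I(t) = I₀·e^(−Rt)
(Levenberg–Marquardt via minpack.lm, started from the log-linear
regression, so convergence is effectively global for decaying series).
Errors default to the scaled fit covariance; a Monte Carlo option
(`errors = "montecarlo"`) resamples residual-scale noise instead. The
heteronuclear NOE is the saturated/reference intensity ratio with
first-order error propagation. The default delay grids — eight points,
0.01–1.2 s for R₁ and 0.008–0.2 s for R₂ — sample roughly one and a half
decay constants of a ~10 ns tumbler at 800 MHz; they are generator
defaults, not constraints on user data.

For CPMG data, R₂ᵉᶠᶠ(ν_CPMG) = −(1/T_relax)·ln(I/I₀) with T_relax = 60 ms.
The per-point error is taken from the duplicated ν_CPMG plane:
σ_I = |I_a − I_b|/√2 per residue, pooled as a fractional error across
residues per field, with a configurable floor (`sigma_floor`, default
0.5%) that applies when the duplicates happen to agree unrealistically
well. Peak intensities, not volumes, are the measurement throughout.

## Overall tumbling

Under rigid local motion (model M1) the R₂/R₁ ratio is independent of S²,
so it isolates the rotational diffusion tensor. `estimate_diffusion()`

1. selects a rigid subset — NOE ≥ 0.65 and R₂/R₁ within 1.5 interquartile
   ranges of the median — to exclude flexible and exchange-broadened
   residues (the customary heuristic; the thresholds are arguments);
2. fits isotropic, axially symmetric oblate and prolate tensors to the
   ratios, the axial ones over (τ_m, D∥/D⊥, axis orientation) with
   multi-start local optimisation over several starting axes;
3. prefers the better axial branch over the isotropic fit by an F-test
   (3 extra parameters) at `alpha = 0.05`, with an exact-fit guard: when
   the isotropic χ² is already at the numerical floor (noise-free data)
   no anisotropy claim is made.

Axial fits need per-residue N–H orientations; `nh_orientations()` reads
them from a PDB file (first model), reconstructing amide protons from
backbone geometry when absent. Without orientations the function falls
back to an isotropic fit with a warning. `inertia_ratio()` provides the
customary sanity check that the fitted anisotropy is compatible with the
mass distribution of the structure.

## Model-free analysis

Each residue's (R₁, R₂, NOE) triple is fitted with the five standard
parameterisations M1–M5 by weighted least squares with the tensor fixed.
M5 is parameterised internally as (S²f, S²s, τe) with S² = S²f·S²s so the
constraint S² ≤ S²f is a box constraint; τe is bounded above by τ_m,
since slower internal motion is not identifiable from these data.

Selection is a staged protocol: M1 is kept if it passes a χ²
goodness-of-fit test (2 degrees of freedom) at `alpha`; otherwise the
two-parameter models are screened and the adequate one (χ² test, 1 df)
with the lower χ² wins; otherwise the better three-parameter model is
taken. With only three observables per residue the nested F-test has
(1, 1) degrees of freedom and essentially no power (the 5% critical value
is F ≈ 161), so adequacy is the operative stage-2 criterion; the F
statistic is still reported in the selection trace. A plain-AIC
alternative is available (`criterion = "aic"`); the small-sample AICc
correction is undefined here because n − p − 1 ≤ 0 for the larger models.
Parameter errors are Monte Carlo: refits of records resampled from
Normal(calculated, σ_obs), 500 draws by default, seeded.

Rex is treated as an additive constant at the measurement field; no field
scaling is applied, because the model-free data are single-field.

## CPMG dispersion fitting

The forward model is a numerical Bloch–McConnell propagation of two-state
transverse magnetisation through the echo train. Off-resonance effects,
finite pulse widths and R₁ during the relaxation period are neglected
(pure 2×2 complex transverse evolution), the idealised constant-time
regime. Three exact structural facts keep this fast and robust:

* a 180° pulse is complex conjugation, so the τ–180–2τ–180–τ block
  propagator collapses to the fixed matrix G = E₁·conj(E₂)·E₁;
* E(t) and Gᴺ are evaluated by closed-form 2×2 spectral decomposition,
  vectorised over the ν_CPMG grid;
* the exchange-free rate r₂⁰ shifts R₂ᵉᶠᶠ additively, so the optimal
  per-(residue, field) r₂⁰ is a weighted mean computed exactly at every
  objective evaluation ("variable projection"), removing 2R nuisance
  parameters from the search.

The number of 180° pulses at each ν_CPMG is rounded to the nearest even
integer; a realised frequency more than 1% from the requested one is an
error rather than a silent approximation. Model curves for plotting are
evaluated on the grid of realisable frequencies for the same reason.

The Carver–Richards closed form is provided as an independent oracle and
is used to anchor tests. It reproduces the exact dominant eigenvalue of
the echo-train propagator for equal intrinsic rates, but not the
finite-time mode-mixing amplitude of a constant-time measurement started
at equilibrium populations; the two models therefore agree to well under
1% in this package's study regime (p_B ≈ 2–3%) and can differ by up to
~3% in slow exchange with p_B near 10% at the lowest pulsing frequencies.
The numerical propagator is authoritative for all fitting.

Fitting minimises the σ-weighted χ² over (k_ex, p_A·p_B, Δω) — shared
(k_ex, p_A·p_B) plus one Δω per residue in the clustered global fit —
with the shared parameters optimised on a log scale so all coordinates
have comparable sensitivity. Initialisation is a coarse grid,
k_ex ∈ {200, 500, 1000, 2000, 4000} s⁻¹ × p_A·p_B ∈ {0.005, 0.02, 0.05},
with Δω seeded from the fast-exchange amplitude relation
R_ex ≈ p_Ap_B·Δω²/k_ex; the best few starts are refined and ties resolve
toward the smaller k_ex. Global fits are additionally seeded from the
medians of independent per-residue fits, the standard workflow. Δω is
stored as a magnitude in ppm (its sign is not identifiable from CPMG
data) and scales to rad/s with the field inside the model. Errors are
Monte Carlo around the fitted model. A fit whose dispersion amplitude is
within the data uncertainty is flagged degenerate — with Δω ≈ 0, k_ex is
undefined — and single-field fits carry an identifiability warning.

Cluster membership is declared by the caller. `suggest_cluster()` offers
a compatibility screen (per-residue k_ex agreeing within 2 combined σ)
but is never applied silently, because deciding that residues share one
exchange process is a scientific judgement, not a numerical one.

Single-residue fits at realistic noise deserve a caveat: with 24 points
and three strongly correlated parameters, the χ² surface has a shallow
valley along (k_ex, p_A·p_B, Δω) trade-offs, and the global minimum for
one noise realisation can sit 10–30% away from the generating k_ex even
when the optimiser provably finds it. This is intrinsic to the
experiment, and is exactly why shared-parameter cluster fits are the
reported quantity: the 10-residue, two-field global fit recovers k_ex to
within a few percent and p_A·p_B to ±0.001–0.003 at 2% intensity noise.

## Titration bookkeeping

Composite shift changes use √(Δδ_H² + (w·Δδ_N)²) with w = 0.2, the usual
¹⁵N scaling for amide HSQC data; w is an argument, and absolute CSP
magnitudes reported with a different convention differ by a global scale.
Residues missing at either endpoint of a comparison are flagged, never
zero-filled, and the status summary tabulates per-pH counts,
first-appearance pH (the highest pH at which a residue's major peak is
seen, matching the "becomes observable on acidification" bookkeeping) and
multiple-peak windows. Reversibility is supported as a direct comparison
of a forward and reverse series (`titration_reversibility()`), not as a
fitted quantity.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of (truth, design, seed):

* relaxation decays and NOE pairs with multiplicative Gaussian intensity
  noise (one fractional σ, default 2% — a stand-in: real per-residue
  noise levels vary and are rarely reported);
* constant-time CPMG intensities at both fields, including the 0 Hz
  reference and the duplicated 100 Hz plane with independent noise;
* titration trajectories as single-pKa sigmoids per residue, with
  missing-peak and multiple-peak flags driven by the truth table.

They deliberately do not simulate spectra: no lineshapes, no peak
overlap, no picking or assignment errors, no baseline artefacts, and no
correlated noise between experiments. Passing recovery tests therefore
demonstrates that the estimators invert their own forward models at
realistic noise — a necessary condition, and the only one testable
without deposited raw data — but not robustness to the pathologies of
real spectra. The titration sigmoid is generator-only structure: the
analysis code never fits a pKa.

Recovery studies use the published study conditions as generating truth:
τ_m = 10.8 ns with D∥/D⊥ = 0.89 (oblate) for the diffusion fit;
k_ex = 1822 s⁻¹ with p_Ap_B = 0.026 and k_ex = 1095 s⁻¹ with
p_Ap_B = 0.024 for the two dispersion regimes; a 45-residue motional
composition (28 M1 around S² ≈ 0.90, 8 M3, 4 M4, flexible termini as M5)
for model selection. Problem sizes in the test suite (10-residue
clusters, 44-residue rigid sets, a few hundred Monte Carlo draws) were
chosen as the smallest sets representative of those conditions.

## Numerical choices and degenerate inputs

* Optimisation is `nlminb` with box constraints everywhere; multi-start
  grids cover the physically plausible ranges, and a restart from the
  first solution guards against premature convergence.
* Exact ties in model selection resolve toward fewer parameters; ties in
  k_ex multi-starts resolve toward slower exchange.
* Duplicate CPMG planes that agree to machine precision would imply zero
  measurement error; the configurable σ floor prevents infinite weights.
* Collinear coordinates (zero principal moment), empty residue sets,
  sub-minimal delay grids, missing reference planes, non-positive
  intensities and unknown table schemas are errors with specific
  messages, not silent repairs.
* File output is deterministic (fixed column order and formatting, binary
  connection for newline stability) and embeds a config hash and seed, so
  identical analyses produce byte-identical reports.

## Known limitations

Fully anisotropic (rhombic) diffusion, per-residue τ_m, reduced
spectral-density mapping, three-state or off-resonance (R1ρ) exchange
models, CEST, proton-detected dispersion, and cross-correlated relaxation
are out of scope. The Bloch–McConnell model omits off-resonance and
finite-pulse effects; for the moderate shift differences (≤ 4 ppm ¹⁵N)
and fields modelled here that is the standard approximation. Minor peak
sets in multi-conformation pH windows are fitted independently via their
peak-set label; no automatic major/minor pairing is attempted.
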