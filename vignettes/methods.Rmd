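---
title: "WaterLOGSY epitope mapping: model, thresholds and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{WaterLOGSY epitope mapping: model, thresholds and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waterlogsy)
```

## The measurement and the factor protocol

WaterLOGSY transfers inverted bulk-water magnetisation to a ligand by
three routes: water immobilised in the binding site, chemical exchange
through protein labile protons, and the hydration layer of the
protein surface — all relayed through the protein–ligand complex. A
bound ligand therefore acquires a negative NOE with water (displayed as
a positive peak), while a free, fast-tumbling ligand picks up a weak
positive NOE (negative peak). Because the transfer is protein-mediated,
the *relative* intensities of a bound ligand's protons encode their
distance from the protein surface: a solvent-exposed proton receives
less transfer.

The protocol quantifies this by comparing, proton by proton, the
WaterLOGSY spectra with (`I+`) and without (`I-`) protein:

1. pick the reference proton = strongest peak of the free spectrum
   (ties broken lexicographically);
2. scale each spectrum by the magnitude of its own reference peak;
3. compute `factor = |I+ - I-| / |I-|` per proton;
4. normalise the set with its maximum at 100%.

A proton whose peak flips sign with unchanged relative magnitude scores
a raw factor of 2; an unchanged peak scores 0. The smallest normalised
factor marks the most solvent-exposed proton. STD factors
(`R = I_STD / I_1D x 100`, largest set to 100%) are the corresponding
quantity for saturation-transfer-difference spectra and should agree
with the WaterLOGSY reading; both are implemented in `wlogsy_factors()`
and `std_factors()`.

The per-spectrum rescaling (step 2) exists because experimental free
and bound spectra carry arbitrary overall gain. Simulated tables share
one absolute scale, so the simulator-driven analyses in this package
run in raw-intensity mode (`rescale = FALSE`); with near-uniform
free-ligand intensities the reference proton's own bound-state change
would otherwise propagate into every factor. Both modes are exposed to
users (`--no-rescale` on the command line).

## Case classification and exposure calls

`sign_pattern()` labels each proton `flipped`, `same` or `ambiguous`
(either magnitude below the noise floor), and `classify_case()` applies
the four-way partition described in the README. Ambiguous protons are
excluded from the predicates; an all-ambiguous pair refuses
classification rather than guessing.

The numeric thresholds are explicit configuration with these defaults,
chosen once so that the canonical worked examples (75% exposed, 25%
Case 3, 0% vs 100% Case 4, and a 10%-factor exposed proton on a small
receptor) classify correctly; none of them is fitted to data:

| parameter | default | meaning |
|---|---|---|
| `noise_floor` | 0.05 | fraction of reference magnitude; below it a sign is noise |
| `uniformity_tol` | 10 | percent window around 100% counting as "uniform" (Case 1 vs 2) |
| `exposed_cut` | 80 | normalised factor below which a proton is called exposed |
| `buried_cut` | 95 | normalised factor at or above which a proton is called buried |
| `agree_tol` | 20 | percentage points for STD/WaterLOGSY and analogue agreement |
| `trend_tol` | 0.15 | fractional mixing-time trend that flags exchange influence |

Case 1 is intrinsically ambiguous (nonspecific binding in several
orientations, complete burial, or a pose without any exposed proton);
the package reports the ambiguity and never resolves it. Case 4 uses
the same smallest-factor-is-exposed rule as Cases 2–3, which is
consistent across all four worked scenarios.

## Mixing-time series and labile protons

Protein-mediated transfer relies on spin diffusion and needs long
mixing times (the standard series is 1.5, 0.75, 0.25 s); exchange
transfer through a ligand OH/NH stays efficient at short mixing times
and contaminates protons within ~5 Å (the 1/r^6 reach of the NOE). The
artifact is therefore *directional*: the relative intensity of a
labile-adjacent proton rises as the mixing time drops.
`exchange_influence_flags()` encodes exactly that — the ratio to the
reference proton at the shortest mixing time must exceed the
longest-time ratio by more than `trend_tol` (fractionally). With only
three mixing times in the standard protocol, an endpoint comparison is
used rather than a regression slope. The recommended analysis mixing
time is always the longest available. Decreasing profiles are never
flagged: only the labile-driven increase pattern is the artifact.

In the Solomon model the artifact vanishes when the exchange rate drops
below roughly the inverse of the shortest mixing time (~4 s^-1 at
0.25 s): both the exchange and the protein pathways are then
lag-limited and build up quadratically, so no relative rise survives.
Property tests assert flagging for k_ex of 10–50 s^-1 and a monotone
growth of the short-mixing-time ratio across 1–50 s^-1; the default
demonstration fixture uses k_ex = 20 s^-1.

## The simulator

`simulate_waterlogsy()` integrates the Solomon equations
`dM/dt = -R M` for magnetisation deviations from equilibrium, by matrix
exponential (`Matrix::expm`; deterministic, verified in the tests
against a closed-form two-spin solution at 1e-10 and an adaptive ODE
solver at 1e-8 relative). The rate matrix combines homonuclear dipolar
cross-relaxation `sigma = K/r^6 (6J(2w) - J(0))` and auto-relaxation
`rho = K/r^6 (6J(2w) + 3J(w) + J(0))` with Lorentzian spectral
densities `J(w) = tau_c/(1 + (w tau_c)^2)`, plus chemical exchange
between labile sites and water. The dipolar prefactor is the physical
homonuclear constant `(mu0/4pi)^2 gammaH^4 hbar^2 / 10 = 5.6957e10
A^6 s^-2`, which yields O(1–10) s^-1 rates at 2–3 Å for complexes of
tens of ns — no empirical calibration is involved. The sign of `sigma`
flips at `w tau_c = sqrt(5)/2`, which is what converts the free
ligand's negative display peaks into the bound ligand's positive ones.

Modelling choices, in decreasing order of consequence:

* **Water is one pseudo-spin with a reservoir weight** (default 1e4):
  back-transfer into water is scaled by the inverse weight, so the
  water deviation is essentially clamped and decays only with
  `water_T1_s` (3 s). This reproduces sign and ordering behaviour at
  desk scale without a solvent lattice.
* **Water couplings are not taken at the state's correlation time.**
  Ligand–water pairs always use `tau_c_free`: the ligand–bulk-water
  interaction is motionally limited by water dynamics, not by the
  tumbling of the complex. In the free state every ligand proton sees
  water at one effective hydration distance (3.0 Å — a free ligand is
  isotropically solvated); in the bound state the geometric distance to
  the water site is used, so pocket protons lose their water contact.
  Protein–water couplings use the hydration distance at `tau_c_bound`,
  standing in for immobilised binding-site and surface water (the
  package deliberately merges these two mechanisms, which no
  WaterLOGSY observable separates). Without these rules a single water
  pseudo-site would make the free spectrum depend on where that site is
  drawn, and the protein would never polarise.
* **Fast-exchange population averaging**: the sample matrix is
  `p_b R_bound + (1 - p_b) R_free`, with `p_b` from the exact binding
  quadratic — valid for the µM–mM fragment regime the defaults target
  (400 µM ligand, 20:1 to 200:1 ligand:protein, K_D 10–1000 µM).
  Slow-exchange kinetics are out of scope.
* **The protein is 5–50 proxy protons** around a declared pocket;
  exposure ground truth in `random_toy_complex()` is geometric (one
  proton faces the water side, the rest are cradled by proxies placed
  2.5–4.5 Å away). This captures spin-diffusion ordering, not any real
  protein's proton density.
* STD is simulated by clamping protein spins at full saturation and
  relaxing the ligand/water subsystem to its driven steady state — a
  simplification that preserves the r^-6 proximity ordering used for
  epitope mapping.

What the simulator does *not* emulate: explicit bulk-water diffusion,
radiation damping, water-suppression artifacts, T1-relaxation biases of
intensities, peak overlap, or noise. Passing the end-to-end tests
therefore shows that the analysis pipeline recovers engineered exposure
under the stated transfer physics — not that it is robust to every
experimental imperfection of real spectra.

## Solvent accessibility cross-check

`shrake_rupley()` computes per-atom SASA with a deterministic
golden-spiral point set (960 points, probe 1.4 Å), accurate to ~1%
against single-sphere and two-sphere analytic areas. Per-proton SASA is
the hydrogen atom's own accessible area, matching the proton-level
granularity of the factors. `factor_vs_sasa()` reports the Spearman
rank correlation between normalised factors and SASA, which should be
negative for a consistent structure/factor pair; constant inputs are
reported as not applicable rather than as a correlation.

## Numerical details and degenerate inputs

* Integration of assigned peaks is signed trapezoidal over the closed
  window, with an optional edge-anchored linear baseline; a zero-width
  window yields the interpolated peak height. The method is linear and
  recovers injected areas of well-separated Lorentzians within 2%
  (half-width ≪ window).
* Denominator guards: factors error (naming the proton) when `|I-|`
  falls below 1e-12 of the reference magnitude; an all-zero raw factor
  set normalises to all-0% instead of erroring, so a no-binding sample
  does not crash the pipeline.
* Tied maxima all report 100%; reference-proton ties break
  lexicographically; the ppm axis is stored ascending and descending
  input is reversed on load.
* All randomised analyses are seeded; simulation problem sizes
  (200-draw recovery studies, 3–6-proton ligands, up to 50 proxy
  protons) are chosen so the full test suite and the acceptance script
  run in well under a minute each on a single CPU.

## Known limitations

* Thresholds are conventions, not fitted constants; data sets near a
  cut (for example a factor of 79% vs 81%) will change calls with the
  configuration.
* The four-case partition assumes the free and bound spectra cover the
  same protons; exchange-broadened or overlapped peaks must be resolved
  upstream.
* K_D estimation, build-up-curve fitting and docking are explicitly out
  of scope; the package validates binding-mode hypotheses, it does not
  generate poses.
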