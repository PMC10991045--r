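---
title: "Methods: multi-turnover RC kinetics and fluorescence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-turnover RC kinetics and fluorescence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcfluor)
```

## The kinetic model

`rcfluor` models light-driven electron transfer through the bacterial
photosynthetic reaction center (RC) when the cytochrome *bc*₁ cycle is
kinetically out of play and a finite periplasmic donor pool alone
re-reduces the photo-oxidized dimer P⁺.

**State space.** The scheme names reactions, not states, so a minimal
closed state space was chosen: the product of dimer redox state (P, P⁺),
primary quinone (Q_A, Q_A⁻) and secondary quinone site (Q_B, Q_B⁻,
Q_BH₂) — twelve states. Open (photochemically competent) states are the
three with P and Q_A; everything else is closed (P⁺ quenches, Q_A⁻ blocks
stable charge separation).

**Transitions.**

* *Photochemistry.* Every absorbed photon not lost as fluorescence closes
  an RC: the total closure flux is $k_I (1 - \varphi(x; p))$, distributed
  over the open states in proportion to their occupancy, each moving
  $(P, Q_A, b) \to (P^+, Q_A^-, b)$. If no RC is open the per-state flux
  is defined as zero. This rule reproduces the single-turnover limits
  exactly: the initial slope of $\varphi(t)$ is $(1-p)k_I$ and the
  supplementary area times $k_I$ is 1 (both are tested to 2–3%).
  Excitation acts only on open states — closed RCs are photochemically
  inert, and double reduction of Q_A is not modelled.
* *Donation.* Every P⁺ state returns to P at $D = k_2 [\mathrm{donor}]$;
  the donor concentration obeys mass action,
  $d[\mathrm{donor}]/dt = -k_2 [\mathrm{donor}] \cdot P^+_{tot} \cdot
  [\mathrm{RC}]$. Donation is treated as pure mass action; product
  inhibition of donor re-binding (plausible for tightly bound HiPIP) is
  not modelled.
* *Acceptor side.* First inter-quinone transfer $A_1$:
  $(d, Q_A^-, Q_B) \to (d, Q_A, Q_B^-)$; second transfer $A_2$:
  $(d, Q_A^-, Q_B^-) \to (d, Q_A, Q_{B}H_2)$; quinol/quinone exchange
  $E$: $(d, a, Q_BH_2) \to (d, a, Q_B)$. The membrane quinone pool is in
  large excess over the RC and is treated as unlimited — $E$ regenerates
  Q_B directly and no empty-site state exists.
* *No cyclic return.* Electrons leaving as quinol never come back: the
  *bc*₁ contribution is absent by construction, matching the
  myxothiazol-blocked experimental regime.

**Ferricyanide and terbutryn.** Slow chemical oxidation of the donors is
modelled solely as a reduced *initial* pool (the treatment lasts hours,
the measurement milliseconds, so oxidation during a run is ignored).
Terbutryn sets $A_1 = 0$, enforcing a single turnover.

## Parameters

| symbol | meaning | unit | typical |
|---|---|---|---|
| `k_I` | photochemical rate constant (∝ light intensity) | 1/s | 5×10³–2×10⁴ |
| `k2` | bimolecular donation rate constant | 1/M/s | ≤ 10¹⁰ (diffusion limit; exceeding it warns) |
| `rc_conc` | RC concentration | M | 3–8 µM |
| `A1`, `A2` | inter-quinone transfers | 1/s | 10³–10⁴ |
| `E` | quinol/quinone exchange | 1/s | 10² |
| `p` | inter-unit exciton hopping probability | – | 0–0.3 |
| `pool` | initial reduced donors per RC | – | 0–5 |

`preset_params("fig8A")` and `"fig8B"` carry the two published simulation
sets (multi-turnover correlation scan and reduced-quinone kinetics,
respectively).

## The two yield maps

Two φ(x) relations circulate for connected photosynthetic units: the
cluster mean-field polynomial
$\varphi = (1-p)x + (1-p)p x^2 + p^2(x^2/4 + 3x^3/4)$
(used by the simulator, `fluorescence_yield()`) and the Joliot-type
hyperbola $\varphi = x(1-p)/(1-px)$ whose inverse
$x = \varphi/(1 - p(1-\varphi))$ is the printed reconstruction formula
(`closed_fraction_from_yield()`, default map). They share endpoints and
the slope $(1-p)$ at the origin but differ at intermediate x for p > 0.
The package exposes **both** and never mixes them silently: reconstruction
defaults to the hyperbolic map as published, and a `yield_map = "cluster"`
switch exists for exact round trips against simulator output (tested to
10⁻⁶).

## Numerical choices

* **Integrator.** `deSolve::lsoda`, rtol 10⁻⁸, atol 10⁻¹⁰; rates span
  many orders of magnitude (up to k₂·[donor] ≈ 10⁵ s⁻¹ against E = 10²
  s⁻¹), so a stiff-capable adaptive method is required. Mass conservation
  of the twelve fractions is verified to 10⁻⁸ at every output point.
  Illumination switching is handled by integrating light-on and dark
  segments separately, never by a discontinuous right-hand side.
* **Output grid.** 2000 points by default, linear over the first 10 µs,
  log-spaced beyond — induction spans sub-µs photochemistry to seconds of
  donor-limited tails.
* **Saturation.** Areas and electron counts need φ → 1;
  `simulate_to_saturation()` doubles the window until φ ≥ 1 − 10⁻³
  (10⁻⁴ for curvature scans, where the (1,1) endpoint matters).
* **Initial slope.** A straight chord through the origin over φ < 0.15
  underestimates the tangent by several percent because the rise already
  curves inside the window; `initial_slope()` therefore fits
  $s t + c t^2$ through the origin and reports $s$.
* **F₀ / F_max.** F₀ is the t = 0 intercept of a line through the first
  five points. F_max is the mean over the trailing 5% of samples: the
  time plateau. Taking the top 5% *by value* instead biases F_max high
  under noise (order statistics), and that bias inflates the
  supplementary area by ε·T where T is the whole trace length — fatal on
  log-extended traces. For the same reason φ is clipped to [0, 1.05]
  rather than [0, 1]: symmetric plateau noise then cancels in ∫(1−φ)dt
  instead of accumulating one-sidedly.
* **Curvature score.** Pairs are sorted by P⁺, duplicates averaged, and
  the score is the trapezoidal integral of φ − P⁺ over P⁺. Positive =
  concave (curve above the bisectrix, the abundant-donor signature),
  negative = convex, |score| ≤ 0.01 = linear. The transition finder skips
  scores below 10⁻⁶ in magnitude when bracketing the sign change: a
  disconnected-unit (p = 0) panel sits at numerical zero for every pool
  and must not report a spurious transition.
* **Relaxation.** "Relaxation time" has no unique operational definition;
  both the half-time of the normalized decay (default) and a
  single-exponential τ (with τ·ln 2 reported alongside) are provided, and
  the two agree within 2% on exponential decays. Sparse flash-probe data
  are ordinary (time, value) samples; the probe flashes are assumed
  non-exciting, not modelled.
* **Stochastic oracle.** The Gillespie ensemble shares a token pool of
  `round(pool · n_rc)` donors; event times come from exponential clocks
  (ties are resolved by the time draws themselves, never by index order),
  and the clock is redrawn at the light-off boundary where propensities
  change discontinuously.

## The synthetic data generator

No raw traces from the original experiments are publicly deposited, so
validation datasets are generated from the model itself
(`generate_induction_dataset()`, `generate_relaxation_dataset()`), with a
ground-truth JSON sidecar accompanying every CSV.

* **Strain presets.** k_I and p per strain come from the published
  induction-derived table; acceptor rates A1 from the published
  re-opening half-times (A1 = ln 2 / t₁ᐟ₂); cycA's k₂ from its 500 ms
  donor-limited relaxation. Absolute donor-pool sizes are never printed
  anywhere, so pools are calibrated by inverting the simulated N(pool)
  curve to the published electron counts (wild-type *Rvx. gelatinosus*
  3.79, *Rba. sphaeroides* 2.4.1 1.39, *pufC* 1.18 donors/RC); cycA is
  set to 0.8, below *pufC*, to respect the strain ordering. The presets
  are therefore N-calibrated, not literature-calibrated.
* **Ferricyanide series.** Treatment duration maps to pool size as
  exp(−hours/1 h), which brings the electron count to ≈ 1 after about 4
  h. The exponential shape is a modelling choice; only the ≈ 4 h horizon
  is constrained.
* **Noise.** Multiplicative Gaussian, default σ = 1% (the original
  recordings report signal averaging but no noise figure). No photon shot
  noise or detector nonlinearity is modelled.
* **What passing tests show.** Recovery tests on these data demonstrate
  that the analysis chain is consistent with the generating model under
  realistic noise — they cannot detect model misspecification against
  real cells (baseline drift, multiphase antenna kinetics, detector
  nonlinearity are all absent from the generator).

## Known limitations

* Wild-type donation is represented by an effective pool and k₂, not by
  the four sequential hemes of the tetraheme subunit; no Marcus-type
  distance–rate calculation is attempted.
* No spatial diffusion or membrane confinement of carriers; donation is
  well-mixed mass action.
* Negative reconstructed P.Q_A⁻ values from noisy traces are clipped at
  zero (with a warning beyond −0.02); there is no published guidance for
  this case.
* Single-trace connectivity estimates at 1% noise scatter by roughly
  ±0.04; replicate averaging (`average_traces()`) is the intended remedy,
  matching experimental practice.

## Problem sizes

The test suite runs the ODE model at 600–2000 output points per
simulation, the stochastic cross-check at 10⁴ replicate RCs against the
mean field (agreement within 3·SEM pointwise on ≥ 95% of the grid), the
noisy recovery study at 20 seeds, and the pool scans over 5–7 pool values
— sizes chosen to make the statistical assertions sharp while keeping a
full run in the order of a minute.
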