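# rcfluor

Kinetic modelling and bacteriochlorophyll (BChl) fluorescence analysis of
multi-turnover electron transfer through the photosynthetic reaction center
(RC) of purple bacteria.

## The problem

Under intense continuous illumination the cytochrome *bc*₁ cycle of a purple
bacterium is kinetically bypassed, and the periplasmic pool of mobile
one-electron donors (cytochrome c₂/c₈, HiPIP) alone must re-reduce the
photo-oxidized dimer P⁺ while the two-electron quinone gate (Q_A → Q_B →
Q_BH₂) drains electrons on the acceptor side. Fluorescence induction and
relaxation of the BChl dimer, together with the P/P⁺ absorption change,
then report on how many electrons the donor pool can push through the RC,
how fast, and which side of the RC limits re-opening. `rcfluor` provides
the full analysis chain for such experiments, plus the kinetic model that
rationalizes them, for strains with and without donor-side cytochromes
(wild types, *cycA*, *pufC*).

## The model and statistics at its core

* **Twelve-state RC kinetics.** The RC state space is the product
  (P / P⁺) × (Q_A / Q_A⁻) × (Q_B / Q_B⁻ / Q_BH₂). Light closes open RCs at
  the total flux k_I·(1 − φ); donation P⁺ → P is second-order,
  D = k₂·[donor], against a finite, shrinking pool; the acceptor side
  cycles through the first (A1) and second (A2) inter-quinone transfers
  and quinol/quinone exchange (E). Solved as a stiff ODE system
  (`simulate_rc()`), cross-checked by an exact Gillespie ensemble
  (`simulate_rc_stochastic()`).
* **Yield maps.** Closed fraction x → fluorescence yield φ via the cluster
  mean-field polynomial φ = (1−p)x + (1−p)p·x² + p²(x²/4 + 3x³/4)
  (forward, simulation) or the Joliot-type hyperbola
  x = φ / (1 − p(1−φ)) (inverse, reconstruction), with the inter-unit
  exciton hopping probability p.
* **Induction analysis.** φ(t) = (F − F₀)/(F_max − F₀); the supplementary
  area A = ∫(1−φ)dt and initial slope give k_I = 1/A and p = 1 − A·Slope;
  the multiple/single turnover area ratio counts electrons per RC,
  N = A_m/A_s.
* **Correlation curvature.** The φ(P⁺) curve is scored by the signed area
  against the bisectrix: concave (above) for abundant donors, convex
  (below) for an exhausted pool with connected units;
  `find_curvature_transition()` locates the pool size where the sign
  flips.
* **Relaxation.** Post-pulse decay of φ gives the RC re-opening time
  (half-time or single-exponential τ), bottlenecked by the slower of the
  donor and acceptor sides.

## Worked example

Generate a synthetic *pufC*-like strain panel (the raw study traces are
not publicly deposited; the generator emulates them from the kinetic model
with ground-truth sidecars) and run the analysis chain:

```r
library(rcfluor)

dir <- tempdir()
# single-turnover reference (terbutryn blocks Q_A- -> Q_B) and full trace
single <- generate_induction_dataset(strain_preset("pufC", terbutryn = TRUE),
                                     noise_sigma = 0.01, seed = 42, dir = dir)
multi  <- generate_induction_dataset(strain_preset("pufC"),
                                     noise_sigma = 0.01, seed = 42, dir = dir)

ref <- analyze_induction(read_trace(single$trace_path, "raw_fluorescence"))
ref
#> <rc_induction>
#>   F0 = 1.006, Fmax = 3.998 (a.u.)
#>   slope = 7222 /s, area = 0.0001148 s
#>   k_I = 8714 /s, p = 0.171

feats <- analyze_induction(read_trace(multi$trace_path, "raw_fluorescence"),
                           single_turnover_area = ref$area_s)
feats$N
#> [1] 2.13
```

The single-turnover area (1.15 × 10⁻⁴ s) inverts to the photochemical rate
constant k_I ≈ 8.7 × 10³ s⁻¹, and the area ratio says the donor pool of
this tetraheme-deficient mutant supplies ≈ 2.1 electrons per RC before it
exhausts (generator truth: k_I = 8700 s⁻¹, p = 0.13, N = 2.17; a single
noisy trace carries p scatter of about ±0.04, which is why induction
experiments average replicate sweeps — see `average_traces()`).

Re-opening kinetics after a 50 µs pulse:

```r
relax <- generate_relaxation_dataset(strain_preset("pufC"),
                                     noise_sigma = 0.02, seed = 42, dir = dir)
extract_relaxation(read_trace(relax$trace_path, "phi", min_points = 6))
#> <rc_relaxation> half_time: 0.0004006 s (half-time 0.0004006 s)
```

The ≈ 400 µs half-time reflects the acceptor-side bottleneck (1/A1) of the
*pufC* preset. Every result object has `tidy()`, `glance()` and
`autoplot()` methods, and a command-line wrapper is available (see
`?rcfluor_cli`).

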