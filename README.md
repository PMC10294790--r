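# thyrodose

Model-based levothyroxine (LT4) dose guidance with robust discrete-time
control, in R.

Patients with autoimmune hypothyroidism depend on daily oral LT4, and
finding the right dose takes months of measure-adjust-wait cycles at the
clinic. `thyrodose` implements the computational chain for automating that
titration, end to end, for researchers working on closed-loop hormone
dosing:

* **Plant model** — a two-state linear model of free thyroxine (FT4)
  dynamics under impulsive daily dosing,

      dx1/dt = d − k_exc x1
      dx2/dt = v_max·TSH/(k_m + TSH) + k_reac x1 − k_sec x2

  with `x1` the exogenous serum T4 (µmol), `x2` the FT4 output (ng/L), and
  TSH acting as a Michaelis–Menten disturbance. Simulation uses exact
  closed-form propagation (no ODE solver), verified against an
  adaptive-step integrator to 1e-6 relative.
* **Identification** — bounded least-squares recovery of the
  patient-specific constants `(k_reac, k_m, v_max)` from hourly
  dose/TSH/FT4 records (log-space Nelder–Mead multistart plus a
  variable-projection polish).
* **Controller synthesis** — impulse-invariant discretization at the
  28-day visit interval, a first-order rate limiter `k_r/(z − Δ)`, and
  pole placement of the first-order controller
  `R(z) = (b1 z + b0)/(z + a0)` via the Diophantine identity
  `a(z)v(z) + b(z)µ(z) = (z − z0)^3`, all poles at `z0 = −0.01`.
* **Robust stability** — the four Jury–Pavlidis conditions for the
  closed-loop characteristic-polynomial family over the oral-elimination
  uncertainty `k_exc ∈ [0.16, 0.36]` 1/h, cross-checked by exhaustive root
  computation.
* **Dosing loop** — per-visit rate clipping (12.5–25 µg), 12.5 µg tablet
  quantisation, a hard 200 µg/day ceiling, and a euthyroid dead band
  (9.2–16 ng/L) that holds the dose once the patient is settled.
* **Virtual cohort** — a seeded synthetic patient surrogate (circadian FT4
  ripple, Hill-type TSH negative feedback, 17% residual secretion,
  bioavailability 0.64–0.83) and a 50-patient closed-loop cohort experiment
  with monthly mean/SD summaries.

## Worked example

```r
library(thyrodose)

params <- thyroid_params()                       # nominal fitted constants
plant  <- discretize_impulse_invariant(params)   # Td = 672 h (28 days)
ctrl   <- design_controller(plant)
ctrl
#> discrete dose controller R(z) = (b1 z + b0)/(z + a0)
#>   b1 = 0.191817, b0 = -0.0233791, a0 = 0.659644
#>   designed for z0 = -0.01 (triple), Td = 672 h, kr = 0.5

family_stability_check(charpoly_family(ctrl, params))
#> Jury-Pavlidis robust-stability report
#>   interval: [0.16, 0.36], nominal q0 = 0.26, grid 1001 points
#>   (i) nominal member Schur   PASS
#>   (ii) p(1, q) != 0           PASS
#>   (iii) p(-1, q) != 0          PASS
#>   (iv) det(X - Y) != 0        PASS
#>   verdict: robustly Schur-stable

run <- run_closed_loop(virtual_patient(params), ctrl)  # 12 visits, ref 13 ng/L
run$visits[, c("visit", "ft4", "ref", "dose", "in_band")]
#>    visit      ft4 ref dose in_band
#> 1      1 4.266952  13 12.5   FALSE
#> 2      2 5.344784  13 25.0   FALSE
#> 3      3 6.492315  13 37.5   FALSE
#> 4      4 7.605177  13 50.0   FALSE
#> 5      5 8.685125  13 62.5   FALSE
#> 6      6 9.744767  13 62.5    TRUE
#> 7      7 9.822959  13 62.5    TRUE
#> ...
#> 12    12 9.829081  13 62.5    TRUE
```

Reading the output: the untreated virtual patient presents overtly
hypothyroid (FT4 4.27 ng/L). The loop starts at one tablet quantum
(12.5 µg/day), climbs by exactly one quantum per monthly visit, and as soon
as the measured FT4 enters the euthyroid band (visit 6, 9.74 ng/L) the
dead band freezes the dose at 62.5 µg/day — the prescription then stays
constant, as steady-state dosing guidelines require.

A command-line wrapper ships in `inst/cli/lt4dose.R` with subcommands
`identify`, `design`, `stability`, `simulate`, `cohort`, reading JSON/YAML
configs and writing CSV/JSON results plus a reproducibility manifest.

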