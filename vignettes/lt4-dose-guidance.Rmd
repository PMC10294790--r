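---
title: "Model-based levothyroxine dose guidance: models, controller design, and the virtual cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based levothyroxine dose guidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrodose)
```

## The problem

Patients with autoimmune hypothyroidism (Hashimoto's thyroiditis) depend on
oral levothyroxine (LT4). Titrating the daily dose is slow: the physician
measures free thyroxine (FT4) every few weeks, nudges the dose by a tablet
quantum, and waits. `thyrodose` implements the full computational chain for
automating that loop: a control-oriented model of FT4 dynamics under oral
LT4, identification of its patient-specific constants, synthesis of a
discrete-time dose controller with clinically mandated rate and ceiling
constraints, a robust-stability certificate over the parameter uncertainty
seen across patients, and a seeded virtual-patient cohort for closed-loop
evaluation.

## The plant model

Two states: `x1`, the total exogenous T4 in serum (µmol), filled by
impulsive daily doses and drained at rate `kexc`; and `x2`, the FT4
concentration (ng/L), driven by `kreac * x1` plus a Michaelis–Menten
endogenous production term `vmax * TSH / (km + TSH)` and drained at rate
`ksec`:

    dx1/dt = d - kexc * x1
    dx2/dt = vmax * TSH / (km + TSH) + kreac * x1 - ksec * x2

TSH enters as a disturbance, not a second controlled output. The model is
linear in the state, so with TSH held piecewise-constant per hour
(zero-order hold) every hourly step has a closed-form solution;
`simulate_plant()` propagates it exactly (no ODE solver), which the test
suite verifies against an adaptive-step integrator to 1e-6 relative error.

Parameters and defaults:

| constant | meaning | default | unit |
|---|---|---|---|
| `kexc` | oral-compartment elimination | 0.26 | 1/h |
| `ksec` | FT4 elimination; ln 2 / (9.5 d) from the 9–10 d T4 half-life | 3.04e-3 | 1/h |
| `kreac` | exogenous-to-FT4 gain | 7.25 | "ppm" |
| `km` | Michaelis constant | 9.504e3 | µmol |
| `vmax` | maximal endogenous production | 2.19e-4 | µmol/h |

Two unit questions are genuinely open and are resolved as configurable
choices. First, doses are prescribed in µg but the model input is in µmol;
the package converts via the LT4 molar mass 776.87 g/mol and an oral
bioavailability multiplier. Second, "ppm" for `kreac` could mean a literal
1e-6 scaling or a plain label; the raw reading produces FT4 of the right
order (tens of ng/L at 100 µg/day) while the 1e-6 reading produces ~1e-5
ng/L, so `thyroid_params(kreac_scale = "raw")` is the default and `"1e-6"`
remains available.

## Identification

`identify_params()` fits the patient-specific triple (`kreac`, `km`,
`vmax`) by least squares against an hourly dose/TSH/FT4 record, with
`kexc`, `ksec` fixed from literature half-lives. The search is a
Nelder–Mead simplex in log-parameter space (positivity for free) with a
quadratic penalty above the upper bounds and three seeded jittered
restarts. Two numerical facts shaped the design:

* `km` and `vmax` are only separately identifiable when TSH varies: at
  constant TSH only the lumped production `vmax*TSH/(km+TSH)` is
  determined, and the function warns accordingly.
* even with varying TSH the (`km`, `vmax`) pair is near-degenerate
  (TSH ≪ km, so the production term is almost linear in TSH). A plain
  simplex stalls several orders of magnitude above the attainable optimum
  in that subspace. Because the model output is *linear* in `kreac` and
  `vmax` once `km` is fixed, the simplex result is refined by a
  variable-projection polish — a 1-D profiled search over `km` with an
  inner linear least-squares solve. On noiseless 90-day staircase records
  (50/80/110 µg/day) this recovers all three constants to better than 0.01%
  from 0.5x–2x perturbed starts.

Default bounds are 10x the nominal values ("realistic" positive bounds);
the default record is the 90-day staircase with the smooth elevated-TSH
trace `synthetic_tsh()`.

## Discretization and controller synthesis

Visits are 4–6-weekly, so the controller is discrete with sampling time
`Td = 672 h` (28 days; 30 days is a config option). Because dosing is one
tablet per day — an impulse train — the plant is discretized
impulse-invariantly:

    G(z) = A (q2 - q1) z / (z^2 - (q1 + q2) z + q1 q2),
    A = kreac/(ksec - kexc), q1 = e^(-ksec Td), q2 = e^(-kexc Td).

At visit-scale sampling `q1*q2 < 1e-6`, so the reduced first-order form
`G(z) = A p1 / (z - p2)` is used (`p1 = q2 - q1`, `p2 = q1 + q2`; with
`ksec < kexc` both `A` and `p1` are negative, the effective gain positive).

Sudden dose changes are clinically unacceptable, so a first-order rate
limiter `Krz(z) = kr/(z - Δ)`, `Δ = 1 - kr`, is placed in front of the
plant, and the controller `R(z) = (b1 z + b0)/(z + a0)` is designed against
the rate-limited total plant by pole placement: the Diophantine identity
`a(z) v(z) + b(z) mu(z) = vT(z)` is solved by direct coefficient matching
for the monic target `vT(z) = (z - z0)^3`. All three poles sit at
`z0 = -0.01`: close to the origin means deadbeat-fast (too aggressive for a
biological loop), close to ±1 means overshoot and fragile robustness, and
-0.01 is the compromise. The expansion `a v + b mu` reproduces `vT`
coefficient-wise to ~1e-17 in the tests; the *root* locations are only
checked to 5e-6 because a triple root has eps^(1/3) conditioning — no root
finder can do better from the coefficients.

One deliberate split: `kr` (default 0.5) is the smoothing gain of the
*linear* limiter used for design and stability analysis, while the literal
per-visit dose-change bound of 12.5–25 µg is enforced separately in the
dosing loop. A linear first-order lag cannot hard-bound increments, and the
quantised clinical increments cannot appear in a transfer function; the
split reconciles the two requirements.

## Robust stability

Across patients the oral elimination rate is the dominant uncertainty
(it absorbs, among other things, the 64–83% bioavailability range), taken
as `kexc ∈ [0.16, 0.36]` 1/h with the controller fixed at its nominal
design. `closed_loop_charpoly()` re-evaluates the closed-loop
characteristic cubic at each `kexc`, and `family_stability_check()` applies
the four Jury–Pavlidis conditions for a continuously parameterised
polynomial family: (i) the nominal member is Schur; (ii) `p(1,q) ≠ 0`;
(iii) `p(-1,q) ≠ 0`; (iv) `det(X(q) - Y(q)) ≠ 0`, with `X`/`Y` the banded
leading/trailing-coefficient matrices. Conditions (ii)–(iv) are verified on
a 1001-point grid with sign-change monitoring; "nonzero" uses the relative
tolerance `1e-12 * (1 + max|coefficient|)`. The tests cross-validate the
theorem against brute-force companion-matrix root checks at every grid
point, and `stability_margin()` reports the certified contiguous interval
around the design point — with the packaged defaults it covers the whole
probed grid 0.10–0.50 1/h, comfortably containing [0.16, 0.36].

## The dosing loop

`run_closed_loop()` realises the visit cycle: measure (the 24-h mean of
the patient's hourly FT4 — a deliberate convention, since circadian ripple
makes a single draw time-of-day dependent), advance the controller
recursion `u_k = b1 e_k + b0 e_{k-1} - a0 u_{k-1}`, then shape the raw
command through, in order: hard rate clip to ±`max_step` (default 12.5 µg)
around the previous dose, quantisation to the 12.5 µg tablet quantum (ties
rounded down), and saturation into [0, 200] µg/day. The block order is a
design decision; placing the quantiser after the clip keeps every
prescription a reachable tablet multiple.

The steady-state requirement — a constant dose once the patient is
euthyroid — cannot emerge from a non-integrating linear loop feeding a
quantiser (it would chatter), so it is implemented as a dead band: while
the measured FT4 lies inside [9.2, 16] ng/L *and* the reference has not
moved since the previous visit, the previous dose is held. At the first
visit the reference counts as unchanged, so a patient already settled at a
matched dose is left alone. The controller state keeps updating during the
hold, which is what lets a later reference drop produce an immediate,
correctly signed dose step.

Therapy starts from dose 0 with zero controller state; the raw first
command is far above the rate clip, so the first prescription is exactly
one quantum (12.5 µg), and the loop climbs by one quantum per visit until
the band is reached — the staircase behaviour expected clinically.

## The virtual patient and cohort

The surrogate patient is *not* a reimplementation of a full physiological
simulator; it emulates only the externally visible behaviours the dosing
loop interacts with:

* the two-state plant above, with residual thyroid secretion at 17% of a
  normal gland;
* TSH under negative feedback: a Hill function
  `TSH = tsh_max * 13^3/(13^3 + FT4^3)` fed back into the Michaelis–Menten
  term with a one-hour zero-order-hold lag (keeping per-step closed forms
  exact);
* a multiplicative circadian FT4 ripple (default amplitude 5%, random
  acrophase);
* oral bioavailability in [0.64, 0.83].

The absolute scales of the surrogate are fixed once, in closed form, by
two anchors (`patient_gain_calibration()`): a normal gland at TSH 5 mU/L
sustains 13 ng/L, and the nominal hypothyroid patient on 100 µg/day settles
at 13 ng/L. The pituitary ceiling `tsh_max = 10` mU/L was chosen so the
untreated nominal patient presents overt hypothyroidism (FT4 ≈ 4.3 ng/L,
TSH ≈ 9) and the treated loop shows a ~6-month dose staircase; these
constants are frozen package defaults, computed rather than hand-tuned.

`cohort_config()`/`run_cohort()` draw seeded patients — `kexc` uniform on
[0.16, 0.36], T4 half-life uniform on 9–10 days, (`kreac`, `km`, `vmax`)
log-normal around the nominal set with 30% CV, bioavailability uniform on
[0.64, 0.83] — and treat each with the shared nominal controller for 12
monthly visits at reference 13 ng/L, aggregating monthly means and
standard deviations of FT4 and dose. Patient `i` is deterministic under
`(master seed, i)` independently of the cohort size.

What the surrogate does **not** model — and hence what passing tests do
not show about real patients: T3/LT3 dynamics, antibody (TPOAb/TgAb)
effects, absorption variability day to day, meal interactions, missed
doses, irregular visit intervals, and measurement error in the FT4 assay.

## A known limitation, quantified

At the default seed the 50-patient cohort ends month 12 with 48 patients
in the euthyroid band. The two stragglers (final FT4 9.16 and 9.17 ng/L,
both still climbing) are low-gain patients — `kreac` about half nominal,
bioavailability near 0.64, fast `kexc` — whose maintenance dose exceeds
150 µg/day. With a 12.5 µg per-visit ramp starting from zero, no controller
of any kind can prescribe more than 150 µg by visit 12, so their month-12
shortfall is structural, not a tuning artefact; both enter the band at
months 13–14. Allowing the permitted 25 µg steps, or longer treatment,
removes the gap.

## Numerical choices and problem sizes

* Exact per-hour closed-form propagation everywhere; `stats::filter` for
  the linear recursions; no ODE solver in the package itself (deSolve is
  the independent oracle in the tests).
* Quantisation ties round down (the conservative clinical direction).
* Identification records: 90 days hourly (2161 samples); simplex
  `reltol 1e-14`, up to 4000 iterations, 3 restarts; variable-projection
  polish with `optimize()` at tolerance 1e-12 on log km.
* Stability grids: 1001 points on [0.16, 0.36] for the family check, 81
  points (step 0.005) on [0.10, 0.50] for the certified margin.
* Cohort: 50 patients x 12 visits x 672 hourly steps (~4 s on one core).
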