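---
title: "A steady-state kinetic model of plasma 1,5-anhydroglucitol across gestation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A steady-state kinetic model of plasma 1,5-anhydroglucitol across gestation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestag)
```

## The model and its assumptions

Plasma 1,5-anhydroglucitol (1,5-AG) is treated as a two-compartment
(plasma/tissue) system with rapid partitioning between the pools. The
plasma concentration `C` (mg/mL) at a frozen gestational week `t`
follows the fast-time mass balance

$$\frac{dC}{dt} \;=\; \frac{f(t)\,k_i}{V(t)}
\;-\; \frac{\mathrm{GFR}(t)\,C}{V(t)}\,\bigl(1 - r(t,[G])\bigr),$$

where `k_i` (mg/day) is the combined dietary and endogenous 1,5-AG
input, `f(t)` the fractional plasma mass partitioning that input into
the plasma pool, `V(t)` the plasma volume (mL), `GFR(t)` the glomerular
filtration rate, and `r(t,[G])` the tubular reabsorption fraction. The
assumptions:

* **Time-scale separation.** An individual's plasma pool equilibrates
  within days, while the gestational parameter curves move over weeks.
  Reported trajectories are therefore the steady state of the fast
  dynamics at each week, where plasma volume cancels:
  $C(t) = f(t)\,k_i / (\mathrm{GFR}_{day}(t)\,(1-r))$.
* **Glycemic state affects only `r`.** GFR, plasma volume and
  fractional plasma mass are taken to follow the same gestational
  curves in normal and diabetic (GDM/DM) pregnancy; the data needed to
  separate GDM from DM physiologically do not exist, so the two are
  pooled.
* **Steady glucose.** `[G]` is a mean-maximal summary of glycemia;
  minute-scale glucose fluctuations are assumed too fast to move
  1,5-AG, and the 24–72 h transient recovery after acute hyperglycemia
  is out of scope.

### Units

Gestational time is in weeks everywhere (week 0 = pre-pregnancy
baseline, range 0–42); GFR is stored in mL/min and converted by 1440
inside the ODE; `k_i` is mg/day; concentrations are computed in mg/mL
and reported ×1000 as µg/mL, the unit of the clinical 1,5-AG data.
These conventions make the mass balance dimensionally consistent.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `k_i` | 5 | mg/day | 1,5-AG input (ingestion + de-novo synthesis) |
| `[G]` | 5 (normal), 8.9 (GDM/DM) | mM | mean maximal plasma glucose |
| GFR `a2,a1,a0` | −0.077, 4.17, 99.04 | mL/min (per wk², wk, –) | quadratic GFR curve |
| `V(t)` | 796.2/(0.62 + 4.4 e^{0.21(t−9.2)}) + 2378 | mL | sigmoidal plasma volume |
| `f(t)` | −0.006 t + 0.32 | – | fractional plasma mass |
| `a` | 0.9984 | – | baseline reabsorption fraction |
| `b` | 0 | per week | post-week-25 reabsorption decline |
| `c` | 0.0026 | per mM | glucose sensitivity of reabsorption |
| `g_threshold` | 7.4 | mM | glucose threshold for inhibition |
| `t_break` | 25 | weeks | reabsorption breakpoint |

Any normal-pregnancy glucose below 7.4 mM behaves identically (the
glucose term is inactive); 5 mM is used as a representative value.
Two printed variants exist in the source literature for the baseline
reabsorption (0.998 vs 0.9984) and for the fractional-plasma-mass
intercept (0.3 vs 0.32); the package defaults to 0.9984 and 0.32 — the
values used in the sensitivity analysis and in the fitted-equation
forms — and exposes the alternatives through ordinary arguments.

### Reabsorption branches and tie-breaks

The glucose-only model is `0.9984` below threshold and
`−0.0026 [G] + 1.018` above it. The two branches disagree at exactly
7.4 mM (0.9984 vs 0.99876); the threshold point is assigned to the
constant branch. The gestational extension
`r = a − b(t − 25)[t>25] − c[G]\,[G>7.4]` is continuous in `t` at the
breakpoint by construction. Any evaluated `r` outside (0, 1) raises a
typed error rather than returning a non-physiological value, as do a
fractional plasma mass outside (0, 1] and a non-positive GFR or plasma
volume.

### The plasma-volume sign convention

As printed, the sigmoid's exponent makes plasma volume *decrease* with
gestation, contradicting the rising cohort data it was fitted to. The
curve object carries an explicit `sign` flag: `+1` (default) keeps the
printed form so its stated limits hold; `−1` gives the physiologically
rising orientation, and the synthetic plasma-volume cohort is generated
with `−1` because it emulates the real cohort. The steady state is
unaffected either way — `V` cancels — and the test suite checks that
invariance explicitly.

## Numerical choices

* **Steady state.** The closed form is the primary path. The
  ODE route ([deSolve::ode], lsoda, rtol 1e-10) integrates the fast
  dynamics in 30-day chunks up to a 365-day horizon and declares steady
  state when the relative derivative drops below 1e-9; at the default
  clearance (time constant ≈ 7 days) this agrees with the closed form
  to well under 1e-6 relative from any start.
* **Curve fitting.** The GFR quadratic and fractional-plasma-mass line
  are solved in closed form (QR normal equations); only the
  plasma-volume sigmoid needs iteration (Levenberg–Marquardt,
  [minpack.lm::nlsLM]). The printed six-parameter sigmoid is exactly
  over-parameterized — `num`, `d0`, `d1` share a common scale, and
  `t_mid` can be absorbed into `d1` — so the fitter profiles out the
  redundancy by holding `d0` and `t_mid` at their initialization and
  optimizing the four identifiable parameters, reporting the result in
  the full printed form. Week 0 is always excluded from the
  fractional-plasma-mass fit (the mass-gain ratio is 0/0 there).
* **Calibration.** Derivative-free Nelder–Mead simplex
  ([pracma::nelder_mead]) with function-value termination tolerance
  1e-5, matching the simplex-style tolerance language of the original
  workflow. Bounds (`k_i` ∈ [0.1, 50], `a` ∈ [0.9, 0.99999],
  `b` ∈ [0, 0.01], `[G]` ∈ [1, 30], `c` ∈ [0, 0.01] — wide margins
  around all published values) are enforced by a sine transform.
  Initialization is deterministic from `variant_defaults()`; for
  variants that free `b`, the initial `b` is 1e-4 rather than 0 so the
  simplex does not start pinned to a bound corner. One-parameter fits
  use golden-section/parabolic search (the simplex degenerates in 1-D).
  Two tie-breaks: if the initialization is already optimal to numerical
  noise the initialization is returned unchanged (the objective can
  have exactly flat directions, below), and an all-fixed specification
  is evaluated once rather than optimized.

## Identifiability

At steady state the trajectory is

$$C(t) \;\propto\; \frac{k_i}{(1-a) + b\,(t-25)_+ + c\,[G]\,\mathbf{1}_{[G]>7.4}},$$

which has exact flat directions in the parameter space:

* scaling `k_i`, `(1−a)` and `b` by a common factor leaves every
  trajectory unchanged — so the normal-pregnancy joint fits of
  {`k_i`, `a`} or {`k_i`, `a`, `b`} determine only `k_i/(1−a)` and
  `b/(1−a)`;
* `(1−a)` and `c[G]` enter only through their sum — so with `k_i`
  fixed, the diabetic fit determines `b` and `(1−a) + c[G]`, but `a`
  and `[G]` trade off exactly (and `c` and `[G]` only through their
  product, which is why `calibrate()` refuses specifications with both
  free).

Consequently a simplex fit from the nominal initialization drives the
objective to its floor but lands wherever the descent path first meets
the flat valley; the individual parameter values it reports are one
point on the ridge, reproducible but not unique. The test suite asserts
recovery of the *identified combinations* to tight tolerance and treats
individual-parameter agreement as what it is: attainable only for
parameters the data pin down (e.g. `a`, whose proximity to 1 makes its
relative error small along the whole ridge, or any single free
parameter fitted alone). This is worth keeping in mind when comparing
independently fitted values of `k_i` or `[G]` across studies: without
an external anchor for the scale, such comparisons are only meaningful
for the identified ratios.

## What the synthetic cohorts emulate

The generators reproduce the *design* of the literature cohorts the
model was built from, with Gaussian noise at the published average
standard deviations around the fitted curves:

| Kind | n | Visit weeks | Noise SD |
|---|---|---|---|
| `gfr` | 25 | 0, 16, 26, 36 | 21.2 mL/min |
| `plasma_volume` | 69 | 0, 8, 14, 20, 26, 32, 38 | 52.3 mL |
| `body_composition` | 27 | 0, 10, 20, 30 | 0.12 (fraction) |
| `ag_series` | 543 normal / 75 GDM-DM | 6, 8, …, 38 | 3 µg/mL |

Where the sources do not print a schedule, the defaults are the
package's own choice of a realistic design: seven equally spaced
plasma-volume visits; three pregnancy visits plus baseline for body
composition; biweekly 1,5-AG sampling with SD 3 µg/mL. The
body-composition generator draws a per-subject total-mass-gain slope
(10% spread around 0.31 kg/week, ≈ 12.4 kg at term) and applies the
noise to the plasma-mass *fraction*, so refitting the fractions
recovers the generating line — closing the ratio-then-regress loop the
fractional-plasma-mass curve comes from. Noise is independent across
subjects and weeks; each subject's draws come from a counter-derived
sub-seed, so cohorts are bit-for-bit reproducible and a subject keeps
its values when the visit schedule changes.

What the generators do **not** emulate: within-subject autocorrelation,
dropout, skewness, or the actual means of the clinical 1,5-AG cohorts
(which were never deposited). Passing parameter-recovery tests on these
cohorts therefore demonstrates correctness of the fitting machinery
under the model's own assumptions, not fidelity to any real population.
One structural caveat: all values are floored at 1% of the truth value
to keep measurements positive. Late in gestation the modelled 1,5-AG
falls to ~1 µg/mL, so at the default SD of 3 µg/mL the floor truncates
a substantial share of the noise distribution and biases late-gestation
sample means upward. The consistency tests therefore verify CLT
convergence at noise levels where the floor is inactive, plus monotone
improvement as the SD shrinks.

## Problem sizes in the test suite

The suite runs the full cohort sizes above (they are small), 100-seed
Monte-Carlo loops for the CLT checks, a 17-point week grid (6–38,
biweekly) for trajectory and calibration work, and noise-free
generate-and-refit oracles for every fitted object. The whole suite
completes in well under a minute on a single core.

## Known limitations

* Transient (non-steady-state) 1,5-AG dynamics are not modelled; the
  model cannot describe the days-scale recovery after an acute
  glycemic excursion.
* GDM and DM are pooled; the gestational physiology curves are from
  normal-pregnancy cohorts throughout.
* The candidate biological mechanisms for the post-week-25 reabsorption
  decline (nephron protein composition, endogenous production changes,
  fetal shunting, insulin requirements) are represented only through
  the phenomenological slope `b`.
* The goodness-of-fit values of the original physiology-curve fits
  depend on the digitized literature data points and cannot be
  reproduced from the published curve coefficients alone; the package
  verifies its fitting machinery on synthetic cohorts instead.
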