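---
title: "Dynamic box models of whole-body zinc isotope homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic box models of whole-body zinc isotope homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znbox)
```

## The model

Stable zinc isotope ratios, reported as δ⁶⁶Zn (the per-mil deviation of
⁶⁶Zn/⁶⁴Zn from the JMC-Lyon standard), fractionate systematically between a
mammal's diet and its tissues, which makes them a proxy for trophic ecology
and paleodiet. Interpreting tissue values, however, requires a quantitative
model of how dietary zinc propagates through the body and how fast each
pool re-equilibrates after the diet changes. `znbox` implements that model
as a first-order compartmental ("box") network.

Each finite compartment *i* is a well-mixed zinc pool of constant mass
$M_i$ (µg) with an evolving composition $\delta_i(t)$. A directed flux
$F_{ij}$ (µg/day) carries material of composition
$\delta_i + \Delta_{ij}$, where $\Delta_{ij} = 1000\,\ln\alpha_{ij}$ is the
per-mil expression of the flux's fractionation coefficient. The diet is an
infinite source with prescribed $\delta_D(t)$; waste is an infinite sink.
Mass balance at the physiological steady state ($\sum F_{in} = \sum
F_{out}$ per box, constant masses) gives the linear dynamics

$$ M_i\,\dot\delta_i \;=\; \sum_{j\to i} F_{ji}\,(\delta_j + \Delta_{ji})
   \;-\; \sum_{i\to k} F_{ik}\,(\delta_i + \Delta_{ik}), $$

i.e. $\dot{\boldsymbol\delta} = A\boldsymbol\delta + b + e\,\delta_D(t)$
with $A$ depending only on fluxes and masses. Three consequences organise
the whole package:

* **Steady state** is the solution of a nonsingular linear system
  (`steady_state()`); with every $\alpha = 1$ it collapses exactly to the
  diet value, and a dead-end pool exchanging with plasma alone sits at
  $\delta_{plasma} + \Delta_{in} - \Delta_{out}$.
* **Relaxation times** are the negative reciprocal eigenvalues of $A$
  (`relaxation_times()`): whole-system properties, each usually dominated
  by one box. The system is effectively equilibrated within five times the
  slowest mode.
* **Linearity** makes the response to any dietary forcing superposable:
  buffering and phase shift under sinusoidal forcing are independent of the
  forcing amplitude.

This per-mil ("delta") bookkeeping linearises the exact isotope-ratio
bookkeeping; the exact ratio formulation is also implemented
(`steady_state(..., formulation = "ratio")`) as a cross-check and differs
by $O(\Delta^2/10^3)$ per mil — two orders of magnitude below measurement
uncertainty here.

## The rat zinc cycle

The bundled reference model (`rat_model()`) describes a 370 g adult rat at
physiological steady state: diet → intestine → plasma, with plasma
exchanging with liver, red blood cells, muscle, bone, kidney and
integument, and losses through feces, urine and integument (desquamation).
Feces and urine are *accumulator* (day-loss) boxes: finite pass-through
pools whose efflux to waste equals their influx. Growth and ageing are
deliberately not modelled, nor are kidney fitting (the kidney acts as an
exchange interface and its observed composition is excluded from
calibration) or enamel formation (which needs secretion/maturation
geometry beyond a well-mixed pool).

Three variants are shipped:

* `"printed"` — the flux table as published, whose muscle efflux of
  900 µg/day breaks plasma and muscle mass balance by ±673 µg/day and
  contradicts the tabulated 8.6-day muscle residence time
  (1960 µg / 227 µg day⁻¹). It is kept for auditability; `mass_balance()`
  flags it.
* `"balanced"` — muscle efflux corrected to 227 µg/day and
  literature-style values for the unconstrained parameters (14-day bone
  residence, 70-day integument residence, neutral fractionation on the
  swept edges). The sweep starts here.
* `"fitted_final"` — the configuration reproducing the observed
  supplier-diet steady state *and* the diet-switch behaviour: bone
  exchange 3212/300.2 ≈ 10.70 µg/day each way, integument loss 4 µg/day,
  renal fractionation α = 1.00044, and the sweep-fitted absorption split
  (−0.025/+0.025 ‰) and integument-transport fractionation (−0.25 ‰).

A note on **residence times**: `residence_times()` returns mass divided by
total efflux — the mean residence time of first-order kinetics. The
physiology literature often labels these numbers $t_{1/2}$; no $\ln 2$
factor is applied, because the tabulated reference values (muscle
1960/227 = 8.6 d, red blood cells 320/35 = 9.1 d, bone 3212/10.70 =
300.2 d, integument 2787/4 = 696.8 d) are mass/efflux quantities. Plasma's
residence is 32/1588.7 ≈ 0.02 d, often printed as 0.0.

The fitted fractionation pairs follow the *split convention*: a
fractionation amplitude attributed half to the influx and half (with
opposite sign) to the efflux of a dead-end exchange, e.g. −0.42/+0.42 ‰
for plasma↔liver. At steady state the pair fixes the tissue−plasma spacing
exactly (liver = plasma − 0.84 ‰, RBC = plasma + 0.10 ‰), which is why
those spacings survive any re-fit of the remaining parameters.

## Dynamics

`simulate_diet()` integrates the linear system with `deSolve`'s `lsoda`,
which switches to an implicit backward-differentiation scheme on stiff
stretches — necessary here, since the rat network spans timescales from
0.02 to ~700 days. The default output step is 0.1 day; solver tolerances
are `rtol = 1e-8`, `atol = 1e-10`. Step forcings with a mid-run switch are
integrated piecewise so the discontinuity falls on a segment boundary.

After a step diet switch, `equilibration_progress()` reports the signed
fractional approach $100\,(\delta(t)-\delta(0))/(\delta(\infty)-\delta(0))$
— signed, so non-monotone boxes may transiently exceed 100 % —
and `time_to_progress()` takes the first crossing with linear
interpolation between grid points. On the fitted rat model this reproduces
the published milestones (plasma reaches 95 % in ~73 days; bone 50 % in
~231 days; every box except bone and integument is ≥ 90 % equilibrated by
day 60, the duration of the longest feeding experiments).

`sinusoid_response()` measures the transfer of a periodic (seasonal)
dietary signal: the simulation covers five times the slowest relaxation
time to shed transients, then the last full cycle is analysed — buffering
as the percentage of dietary amplitude lost, and phase shift as the lag of
the box's local maximum behind the diet's local maximum, following the
published definition. A Fourier-phase estimate would be less faithful to
that definition; the analytic one-pole filter (amplitude ratio
$1/\sqrt{1+(2\pi\tau/P)^2}$, lag $(P/2\pi)\arctan(2\pi\tau/P)$) serves as
the cross-check in the tests. The analysis cycle uses 2000 output points
per period, giving phase resolution well below the 0.1-day level that
matters.

## The parameter sweep and confidence-interval fit

Five rat parameters are poorly constrained: the intestinal
absorption/endogenous-loss fractionation pair, the plasma→integument
fractionation, the renal fractionation, and the plasma↔bone and
plasma→integument fluxes. `znbox` fits them the way the rat cycle was
originally calibrated — by **grid sweep + confidence-interval membership**,
not by continuous optimisation: a node is accepted iff its steady state lies within the
observed confidence half-width (2 SE) of *every* constrained compartment
(`sweep_steady()` + `ci_fit()`).

Axes preserve mass balance by construction: an exchange axis moves both
directions of a pair together, and the integument-loss axis co-adjusts
endogenous loss (plasma→intestine) and the fecal return so that plasma,
intestine and feces stay balanced — expressing the integument-loss /
endogenous-loss trade-off explicitly. Default resolutions (the ranges are
published; the resolutions are this package's choice): 0.05 ‰ steps in
split amplitude — i.e. 0.025 ‰ in the half-amplitude applied to each
direction — 0.05 ‰ steps for single-edge fractionations, and 15 log-spaced
points per flux axis. The half-step on the paired axis matters: the red
blood cell constraint (±0.03 ‰) maps to a window of about 0.03 ‰ in the
half-amplitude, and a 0.05 ‰ half-amplitude grid would straddle it,
leaving only fit solutions that lean entirely on large renal fractionation
— contradicting the finding, reproduced by `renal_sensitivity()`, that
renal fractionation shifts constrained steady states by < 0.03 ‰ per ‰ and
is therefore immaterial to the baseline fit.

The default five-axis grid has 25 × 11 × 21 × 15 × 15 = 1 299 375 nodes
(the sweep warns above 10⁶). It stays cheap because the linear structure
factorises exactly: $A$ depends only on fluxes, and the right-hand side is
affine in the per-mil fractionations, so one factorisation per flux-axis
combination (225 of them) is solved against all 5 775 fractionation
combinations at once. The full grid solves in seconds.

`ci_fit()` reports the accepted set, per-axis marginal accepted ranges,
per-node worst-violated observation (so an empty acceptance is
diagnosable), and a *representative* node: the coordinate-wise median of
the accepted nodes, snapped to the nearest accepted node in
normalised axis units, ties broken deterministically by node order.
Acceptance is monotone in the confidence widths, and refining a grid never
loses an accepted coarse node — both are tested properties.

Steady states cannot constrain a dead-end exchange flux (bone's steady
composition is flux-independent), so the bone residence time is calibrated
in a second stage against a diet-switch time series
(`calibrate_switch()`): with ~12 % bone equilibration after 54 days under
a 300-day residence versus ~95 % under 14 days, even noisy series separate
the two decisively. The shipped demonstration uses the synthetic
generator, since the underlying per-day measurements are not reproducible
here.

## The synthetic-data generator

`synthetic_spec()` + `generate_observations()` /
`generate_switch_series()` emulate the feeding experiments on a known
model: per-compartment Gaussian replicate noise (independent — measured
confidence intervals are 2 SE and carry no covariance information),
replicate counts, and a switch/sampling schedule bounded by the emulated
experiment length (54 days for the pelleted-diet experiments, 32 for the
natural-diet one). `rat_synthetic_spec()` fills the study's conditions:
noise σ equal to half the observed confidence half-width per compartment,
and the supplier-group replicate counts (plasma and integument 1, muscle
2, others 3). Feed compositions per group use the measured values where
printed (supplier 0.42 ‰, animal meal −0.09 ‰, bone addition 0.00 ‰) and
documented defaults spanning the observed ordering otherwise (lucerne
−0.30 ‰ lowest … vegetable mix 0.50 ‰ highest). An optional
between-individual σ exists but defaults to zero: the real data suggest
growth performance adds inter-individual spread, but provide no value to
adopt.

What passing synthetic-data tests do **not** show about real data: the
generator has no growth dilution (body-mass gain demonstrably lowers
tissue spacings), no hair-growth cycling (the integument box assumes
steady growth), and no diet-dependent zinc bioavailability. Parameter
recovery under the generator therefore validates the inference machinery,
not those biological simplifications.

## Numerical choices and degenerate inputs

* Mass-balance tolerance 10⁻⁶ µg/day; imbalance warns (and is reported)
  rather than errors, so published-but-inconsistent tables can be audited.
* Dense `eigen`/`solve` linear algebra — the networks are small.
* A finite box with zero efflux is rejected as a "dead-end finite box"
  before any solve; a non-negative eigenvalue raises "system not
  dissipative" naming the dominant box.
* Equal pre- and post-switch steady states make progress undefined and
  error explicitly.
* Axis grids must have at least two points and positive width; flux axes
  that would drive any rate negative, or leave any box unbalanced, are
  rejected at sweep time.
* Problem sizes used by the shipped checks: step simulations at dt = 0.1 d
  over 300 d (equilibration milestones) and dt = 0.5 d over 3 500 d (slow-
  box horizon); sinusoid analysis cycles of 2 000 points after a 5×-slowest-
  mode transient; the full default sweep grid; 100-replicate recovery and
  oracle batches. These sizes were chosen as the smallest that make the
  measured quantities grid-independent at the reported precision.

## Known limitations

The model is linear in δ by design; strongly nonlinear regimes (saturable
absorption kinetics) are out of scope. The accumulator convention
(pass-through excreta pools) makes the printed 1.0-day excreta residence a
reporting convention rather than a constraint, and the mode-to-row mapping
of the two fastest published relaxation values is not asserted — the
engine reports all modes with their dominant boxes instead. The fitted
absorption-split and integument fractionations are the representative node
of this package's own sweep; the originally fitted parameter set is not
published in full, so a slightly different accepted region is possible and
is flagged rather than reconciled.
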