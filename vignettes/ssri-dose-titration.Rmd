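---
title: "One-compartment SSRI kinetics and fluoxetine-matched dose titration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-compartment SSRI kinetics and fluoxetine-matched dose titration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssriload)
```

## The model

Every drug in this package is described by a one-compartment model with
first-order absorption. After oral doses $D_i$ (mg) at times $t_i$, the
amount still awaiting absorption, expressed on concentration scale
(ng/ml; one mg distributed into $V$ litres is $10^3/V$ ng/ml), is

$$A(t) = \sum_{t_i \le t} \frac{D_i \cdot 10^3}{V} e^{-k_a (t - t_i)},$$

and the plasma concentration obeys

$$\frac{dC}{dt} = k_a A(t) - \frac{V_m C}{K_m + C}.$$

When $C \ll K_m$ elimination is first-order with rate
$k_e = V_m/K_m$, and the model reduces to the classical biexponential,
which superposes across doses:

$$C(t) = \sum_{t_i \le t} \frac{D_i \cdot 10^3}{V}
  \frac{k_a}{k_a - k_e}\left(e^{-k_e (t-t_i)} - e^{-k_a (t-t_i)}\right).$$

`simulate_profile()` dispatches on the parameter class: `linear_pk`
profiles are computed from the closed form above (no integration error
beyond floating point), `mm_pk` profiles by adaptive stiff-capable
integration (`deSolve::ode`, lsoda, relative tolerance $10^{-8}$) of the
two-state (gut, plasma) system, with doses applied as bolus additions to
the gut state — identically the forcing sum $A(t)$. Because the linear
path never touches the ODE solver, it doubles as an independent oracle:
the test suite drives the Michaelis–Menten engine into the
$K_m \to \infty$ limit and checks agreement to $10^{-3}$, and checks the
linear engine against a separately written superposition loop to
$10^{-6}$.

Assumptions worth keeping in mind: a single well-stirred compartment, no
protein-binding or brain/CSF distinction, no inter-individual
variability, and absorption inputs that superpose even when elimination
saturates (elimination acts on the *total* concentration). Venlafaxine is
modelled as one combined moiety with its active metabolite
O-desmethylvenlafaxine, which is how its published daily means are
expressed.

## Parameters and their defaults

| Parameter | Units | Meaning | Typical range here |
|---|---|---|---|
| `volume` ($V$) | l | apparent volume of distribution | 426–1400 (bundled drugs) |
| `absorption_rate` ($k_a$) | 1/h | first-order absorption constant | 0.2–1.0 |
| `elimination_rate` ($k_e$) | 1/h | first-order elimination | ln 2 / t½ |
| `vmax` ($V_m$) | ng ml⁻¹ h⁻¹ | maximum elimination rate | 6.5 (fluoxetine) |
| `km` ($K_m$) | ng/ml | half-saturation concentration | 50–1000 |

Doses are absolute mg for a 70-kg adult (no per-kg scaling). The bundled
drug table (`ssri_assumptions()`) holds the published observables each
model is calibrated from; fluoxetine's constants
($V$ = 1033 l, $k_a$ = 0.53 h⁻¹, $V_m$ = 6.5, $K_m$ = 448) are used
verbatim because they were published in full, while paroxetine and
fluvoxamine — whose fitted constants were never published — are
re-fitted from their single-dose triples at package load.

## Which half-life?

For a saturable drug, "half-life" is ambiguous. The elapsed time from
Cmax to Cmax/2 after a single dose is *longer* than the terminal
elimination half-life $\ln 2 \cdot K_m / V_m$, for two reasons: drug still
being absorbed past the peak props the curve up, and near the peak the
elimination rate $V_m/(K_m + C)$ is depressed below its low-concentration
limit. For fluoxetine's constants the two definitions differ materially
at a 40-mg dose. Only the terminal definition is consistent with the
published fluoxetine triple (Cmax 35 ng/ml, Tmax 7 h, t½ 48 h): indeed
$\ln 2 \cdot 448 / 6.5 = 47.8$ h. `single_dose_metrics()` therefore
defaults to the terminal log-linear-slope estimate (fitted over the late
window where the concentration has fallen below Cmax/8), and offers the
peak-anchored definition as `half_life = "peak"` for sensitivity
analyses. Calibration and all reported half-lives use the terminal
definition.

## Calibration

Linear drugs are identified in closed form: $k_e = \ln 2 / t_{1/2}$ and
$k_a$ from the peak-time relation
$T_{max} = \ln(k_a/k_e)/(k_a - k_e)$, solved by bracketed root-finding
(`solve_absorption_rate()`); a solution exists only when
$T_{max} < 1/k_e$, which all bundled drugs satisfy comfortably.

Saturable drugs pose an under-determined problem: four constants
$(V, k_a, V_m, K_m)$ against three observables. With a supplied $K_m$ the
remaining three are identified; `calibrate_mm()` then polishes an
excellent analytic starting point (the low-concentration first-order
approximation) by Nelder–Mead least squares on the relative residuals of
a forward single-dose simulation, and refuses to return a fit whose worst
residual exceeds 1%. Without a $K_m$ prior it returns the
minimum-residual solution with an explicit non-identifiability warning.
This matters for interpretation: paroxetine and fluvoxamine regimens
generated here reproduce the *targets* exactly, but their dose columns
depend on the unidentifiable degree of saturation and should be read as
one consistent possibility, not a unique answer.

## The titration inverse problem

`build_reference()` simulates fluoxetine 40 mg once daily for 60 days and
records each day's 24-h trapezoidal mean. The steady-state mean is the
day-60 daily mean — by then the day-to-day relative change is ~$10^{-4}$
— and the loading fractions are the first 30 daily means divided by it
(0.208 on day 1, rising to 0.998 on day 30). Normalizing by the model's
own plateau, rather than any externally quoted steady-state figure, keeps
the fractions in $(0, 1]$ and makes the titration exactly self-matching.

Each titrated drug is anchored at the plateau of its standard maintenance
regimen (its published day-30 dose: sertraline 51 mg, citalopram 20.7 mg,
paroxetine 41.4 mg, venlafaxine 228.6 mg every 24 h; fluvoxamine 41 mg
every 12 h), simulated the same way. Day $d$'s dose is then the root of

$$\bar C_d(\text{dose} \mid \text{doses}_{1..d-1}) = f_d \cdot C_{ss}^{drug},$$

found by Brent's method on a $[0, 10\times$ standard dose$]$ bracket —
the daily mean is strictly increasing in the dose, so the root is unique.
Linear drugs use the exact analytic window integral inside the solve;
saturable drugs restart the ODE from the stored day-start state, so a
30-day schedule costs ~600 one-day integrations. Twelve-hour drugs give
the same amount at both intra-day doses, matching how twice-daily
regimens are actually prescribed. Optional rounding to a per-drug
increment (round half up) is applied *before* a dose enters the history,
so later solves compensate for the rounding of earlier days; by default
doses are left exact, since the heterogeneous granularity of published
dose tables follows no stated rule.

Two properties summarize correctness, and both are asserted in the test
suite: re-simulating a generated schedule reproduces its achieved daily
means to solver precision with every achieved/target residual below 0.1%,
and every drug's achieved loading shape (daily mean divided by day-30
mean) matches the fluoxetine fractions within 2%. Dose escalation is
monotone for the once-daily drugs; the twice-daily saturable drug
(fluvoxamine) shows a sub-mg wobble near its plateau, just as published
dose tables for it do.

## Agreement with the published table, and a caveat

Simulating the published escalating dose columns reproduces the published
day-1 daily means to ~1% (sertraline 11.66 vs 11.6, citalopram 10.53 vs
10.4) and the fluoxetine column throughout to better than 1%. The
published *day-30* values for the linear drugs, however, sit 2–3% below
what their own parameters force: at steady state the daily mean must
equal $D \cdot 10^3 / (V k_e \cdot 24)$ regardless of absorption model —
56.9 ng/ml for 51 mg of sertraline and 51.9 ng/ml for 20.7 mg of
citalopram, versus published values of 55.8 and 50.1. No solver or grid
choice can close that gap; this package reports the analytically forced
values. The venlafaxine column deviates further (~10%) and is treated as
indicative only.

## Numerical choices

* Output grid 0.1 h (0.02 h inside the synthetic-data generator, whose
  observables feed $10^{-4}$-level round-trip tests). Published daily
  means carry 3 significant figures; at 0.1 h the trapezoid error is
  orders of magnitude below that.
* ODE: lsoda with rtol $10^{-8}$, atol $10^{-10}$; dose events as state
  jumps, never smoothed.
* Steady state: successive daily means within $10^{-3}$ relative, capped
  at 60 days, error (with the last value attached) beyond the cap. Under
  this criterion fluoxetine converges shortly before the end of its
  fourth week.
* Cmax/Tmax refined by a parabola through the three grid points around
  the maximum; a profile whose maximum sits at the first grid point
  (bolus-like input) reports Tmax at that point unrefined.
* Degenerate inputs are rejected loudly: $k_a = k_e$ (flip-flop limit),
  non-positive parameters, unreachable targets (classed
  `ssriload_titration_infeasible`, naming the day), fewer than 3
  correlation records, zero-variance correlation inputs.

## Synthetic data: what it does and does not emulate

`gen_pk_drug()` draws $V$ from 100–2000 l, t½ from 5–60 h, Tmax from
2–10 h (truncated so $T_{max} < 0.6\, t_{1/2}/\ln 2$, keeping absorption
genuinely faster than elimination) and, for saturable drugs, $K_m$ from
50–1000 ng/ml with $V_m = k_e K_m$ — ranges that bracket every bundled
SSRI. Observables are *measured from a forward simulation*, so
calibration tests cannot cheat by inverting the same closed form that
generated the data. `gen_sre_records()` draws (ln t½, RR) from a
bivariate normal with a requested correlation (RR truncated positive by
resampling). Both are pure functions of their seed.

Passing round-trips on these generators demonstrates internal
consistency of simulator + calibrator under the model's own assumptions.
They say nothing about model misspecification in real patients:
multi-compartment disposition, active metabolites (beyond the venlafaxine
lumping), nonlinear absorption, adherence gaps, or pediatric scaling are
all outside the generator and the model.

## Problem sizes

The shipped tests use 100 random schedules for the superposition oracle,
50 linear and 20 saturable synthetic drugs for calibration recovery, 500
replicates at $n = 6$ for the correlation power check and $10^4$
permutations for the p-value cross-check; the acceptance script simulates
30-day regimens at the 0.1-h grid. All sizes were chosen so the complete
suite exercises every claimed tolerance while running in a few minutes on
one core.

## Known limitations

* Dose columns for drugs with unidentifiable $K_m$ are one consistent
  solution, not unique (targets and daily means are unaffected).
* The steady-state anchor convention (plateau of the published day-30
  dose) is a documented choice; other anchors rescale all targets
  proportionally.
* The bundled drug/SRE record table is a constructed illustration — the
  per-drug half-life/risk values used in the original correlation
  analyses were cited from regulatory meta-analyses, not republished —
  so inferential smoke tests on it validate machinery, not epidemiology.
* No pharmacodynamics: the 5-HT1A receptor mechanism motivates the
  loading-rate analysis but is not modelled.
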