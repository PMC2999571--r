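---
title: "Personalized dynamical models of prostate-cancer whole-cell vaccination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized dynamical models of prostate-cancer whole-cell vaccination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

psavax models the short-term effect of an allogeneic whole-cell vaccine on
androgen-independent prostate cancer, using serial PSA measurements as the
observable. This vignette documents the model, the numerical and
statistical choices behind each pipeline stage, what the virtual-patient
generator does and does not emulate, and the package's known limitations.

## The model

Seven compartments, all in cells, time in hours internally (all external
interfaces use days; 1 day = 24 h):

* $V$ — vaccine cells at the intradermal injection site,
* $D_m$ — antigen-bearing dermal dendritic cells (DCs),
* $D_C$ — mature antigen-presenting DCs in the draining lymph node,
* $D_R$ — "exhausted" DCs,
* $R$ — regulatory/inhibitory cells,
* $C$ — antigen-specific effector cells (e.g. cytotoxic T cells),
* $P$ — prostate-cancer cells.

$$
\begin{aligned}
\dot V &= -k_i V &
\dot D_m &= \tfrac{k_i}{n_V} V - k_m D_m &
\dot D_C &= \alpha_l k_m D_m + V_p - k_{CR} D_C \\
\dot D_R &= k_{CR} D_C - \mu_D D_R &
\dot R &= a_R D_R - \mu_R R &
\dot C &= a_C D_C - \mu_C C - k_R R C
\end{aligned}
$$
$$
\dot P = r P - a_p\, C\, P\, \frac{h_P}{h_P + P},
\qquad \mathrm{PSA}(t) = A\,P(t) + B .
$$

Each vaccination is an impulse $V \mapsto V + \text{dose}$. The cascade is
feed-forward: vaccine stimulates immunity, regulation suppresses it
(through $R$ inactivating $C$), and the tumor does not feed back on any
immune compartment. Killing saturates at high tumor burden through the
damping coefficient $h_P$; an alternative damping in effector number
($h_P/(h_P+C)$) is available via `model_options(killing_damping =
"effector")`.

Assumptions worth stating explicitly: no tumor-driven immunosuppression
beyond the generic regulatory arm, no androgen-axis dynamics, no spatial
or delay effects, no pharmacokinetics of vaccine spread, and PSA treated
as a (noisy, affine) surrogate of tumor burden.

### Parameters

Shared constants (`global_params()`, per hour unless noted):
$k_i=0.06$, $n_V=1$, $V_p=0$ cells/h, $k_m=0.027$, $\alpha_l=0.03$,
$k_{CR}=0.027$, $\mu_D=0.014$, $a_R=3\times10^{-3}$, $\mu_R=0.03$,
$a_C=0.38$, $\mu_C=0.007$, $k_R=6\times10^{-7}$ cell$^{-1}$h$^{-1}$,
$h_P=10^8$ cells. They are literature-derived population-level estimates
and are shipped as `inst/extdata/global_params.yaml` (any key
overridable).

Patient-specific (`patient_params()`): tumor growth rate $r$ (h$^{-1}$),
maximal killing efficacy $a_p$ (cell$^{-1}$h$^{-1}$), and the PSA map
pair $A$ ((ng/mL)/cell) and $B$ (ng/mL).

**The $P_0$ convention.** $A$ and the initial burden $P_0$ only appear as
the product $A\,P_0 e^{rt}$ plus $B$ in the observation, so they are not
separately identifiable. The package fixes $P_0 = h_P = 10^8$ cells and
lets $A$ absorb the scale: the fitted $A$ is a composite quantity, not an
absolute per-cell secretion rate. The PSA map is affine by default (two
parameters, sign-constrained, preserves log-linear pre-treatment growth);
a power law $A P^B$ sits behind `model_options(psa_map = "power")`.

## Simulation

`simulate_course()` integrates the system with `deSolve::lsoda` (the
right-hand side is compiled C), restarting the integration at every dose
event with a state jump on $V$ — impulses are never smoothed into narrow
continuous pulses. Default tolerances are `rtol = 1e-8`, `atol = 1e-6`
cells; compartment scales span $10^0$–$10^9$ cells, and halving the
tolerances moves reported PSA by far less than 0.1%. Solver-level
negative round-off (within `atol` of zero) is clamped to zero. Before day
0 there is no vaccine and no immune activity; the pre-treatment phase is
pure exponential growth initialized so that $P(0) = P_0$.

The standard schedule (`make_standard_protocol()`) is 14 doses of
$2.4\times10^7$ cells: days 0, 14, 28, then every 28 days to day 336,
with the course ending at day 364.

**The decoupled fast path.** The immune compartments do not depend on the
patient-specific parameters, so `immune_course()` solves them once per
protocol (output grid 6 h) and `simulate_psa()` then integrates only the
scalar tumor equation with $C(t)$ as an interpolated forcing. This agrees
with the whole-system solver to ~$10^{-5}$ relative and makes each
candidate parameter evaluation cost milliseconds — the basis for
multi-start fitting and regimen grid searches. The two routes are
cross-checked in the test suite, together with a matrix-exponential
solution of the linear immune cascade and an integrating-factor
quadrature for $C(t)$.

## Personalization

`classify_responder()` compares PSA velocity (OLS slope of $\ln$ PSA vs
time) before treatment (all points at day $\le 0$; the day-0 draw
precedes the first injection) against the first four treatment cycles.
With the trial spacing the fourth cycle ends at day 84 (14+14+28+28); the
boundary is derived from the protocol rather than hard-coded. Response is
a strict inequality: equal velocities do not count.

`fit_patient()` minimizes the plain (linear-scale) sum of squared PSA
residuals over the training set, subject to box constraints
(`default_fit_bounds()`): $r \in [10^{-5}, 5\times10^{-3}]$ h$^{-1}$
(PSA doubling ~6 days to ~8 years), $a_p \in [0, 10^{-3}]$,
$A \in [10^{-12}, 10^{-4}]$, $B \in [0, 50]$ ng/mL. $r$, $a_p$, $A$ are
searched in $\log_{10}$ space (their plausible ranges span orders of
magnitude); the zero lower bound of $a_p$ is represented by the floor
$10^{-12}$, dynamically indistinguishable from zero. A log-scale residual
option exists (`objective = "log"`), which is the statistically natural
choice under multiplicative noise; the linear scale is the default
because it is the plainest reading of "least squares" for this problem.

Three structural facts shape the optimizer:

1. **Variable projection.** With $P_0$ fixed, the tumor curve depends
   only on $(r, a_p)$, and the affine PSA map enters linearly; the
   optimal $(A, B)$ for any $(r, a_p)$ is an exact box-constrained linear
   least-squares solve. The nonlinear search is therefore 2-D.
2. **Multi-start.** One data-driven start (growth rate from the
   pre-treatment log-slope, PSA scale from the observation nearest day 0)
   plus `n_starts - 1` seeded Latin-hypercube starts, each descended with
   bounded Levenberg–Marquardt. The finite-difference step (`epsfcn =
   1e-12`) is set well above the ODE-solver noise floor; with the default
   machine-epsilon step the Jacobian is noise-dominated and the search
   stalls.
3. **Valley polish.** The objective has a curved, nearly flat valley —
   faster growth traded against stronger killing — in which LM stalls
   short of the floor. The top three endpoints are polished by a
   Nelder–Mead descent and a final four-parameter LM pass.

The procedure is deterministic given its seed, and the single-start run
shares its first start with the multi-start design, so the best
objective is non-increasing in `n_starts`. On 20 seeded noiseless virtual
patients all four parameters are recovered to better than 0.1%.

`predict_validation()` simulates the calibrated model at the held-out
times with the whole-system solver — no refitting — and
`goodness_of_fit()` is the ordinary $R^2 = 1 - SS_{res}/SS_{tot}$ about
the observed mean (possibly negative).

`iterative_training()` starts from all pre-treatment points plus two
in-treatment points and moves one observation per iteration from the
validation set into the training set until the mean absolute relative
prediction error on the remaining points is at most 10%. The 10%
threshold is a package choice (mirroring the 10% PSA-stabilization
tolerance used elsewhere in the pipeline); it is a tunable argument, and
the full iteration trace is returned because prediction accuracy need not
be monotone in training-set size. Each iteration's fit is independent
and identically seeded, so the result equals an exhaustive scan over all
split sizes (asserted against a brute-force oracle in the tests).

## Regimen intensification

`stabilization_ok()` encodes the clinical goal: predicted PSA at most 10%
above the pre-treatment level. Two variants exist because the goal can be
read two ways: `"max"` (default) requires the cap at every reported day
of the course, `"end"` only at the end of treatment. The default is the
stricter reading; both are arguments throughout.

`find_min_dose_factor()` scans factors 1.0, 1.1, ... (10% grid) of the
standard dose at the standard spacing up to 30×, returns the smallest
passing factor, and by default bisects the bracketing grid step to ~3
significant figures (recommendations like 1.47 or 5.08 are meaningful).
`find_max_interval()` scans 28, 27, ..., 1 days at the standard dose.
Two safeguards keep these searches honest:

* Stabilization is always evaluated through the end of the **standard**
  treatment span (day 364), so a compressed schedule cannot pass merely
  by ending before PSA has had time to rise.
* Interval reduction defaults to duration-preserving schedules (doses are
  added as the interval shrinks; daily dosing means daily for the year).
  With the dose count held at 14 instead (`preserve = "n_doses"`), the
  same cumulative dose is followed by a long untreated tail and shorter
  intervals essentially never help; that variant remains available.

An interesting consequence of the regulatory arm: under very frequent
dosing, $R$ accumulates until $k_R R \gg \mu_C$ and caps the effector
level, so interval-shortening saturates — some fast-growing tumors are
stabilizable only by large dose increases, or not at all. Patients with
$a_p = 0$ are never stabilizable, at any dose or interval.

## The virtual cohort

`cohort_spec()` + `generate_cohort()` emulate the statistical structure
of the trial data, not any actual patient: log-uniform patient parameters
with pre-treatment PSA doubling times of 1–24 months (asymptomatic
biochemical relapse), $a_p$ for responders in
$[10^{-10}, 2\times10^{-9}]$ cell$^{-1}$h$^{-1}$ (spanning barely
perceptible to strongly flattening velocity changes; realistic magnitudes
are not derivable from published data and are an engineering choice), $A$
such that baseline PSA falls in ~5–50 ng/mL, $B \in [1, 10]$ ng/mL.
Sampling: 4 monthly pre-treatment measurements, one at every vaccination,
sporadic mid-cycle draws up to 26 observations total; default training
split 12 points. Noise is multiplicative lognormal with unit mean
(PSA is positive; assay error roughly proportional), default CV 5%. A
configurable fraction of patients are non-responders with $a_p = 0$.
Everything is deterministic given `(seed, patient index)`.

What the generator does **not** emulate: the abrupt non-monotonic
late-course PSA breaks seen in a minority of real patients (the model
class cannot produce them, and fitting such patients fails by design),
assay drift or heteroscedasticity beyond the constant CV, correlated
measurement error, dropout, and inter-patient variability in the immune
constants (all immune heterogeneity is funneled into $a_p$). Passing
tests on this cohort therefore demonstrate internal consistency of the
pipeline under the model's own assumptions, not clinical validity.

## Identifiability: a known, quantified limitation

With 4 monthly pre-treatment points and 5% noise, the pre-treatment
log-slope that anchors $r$ has a standard error of roughly
$5.6\times10^{-4}$/day — more than half the true slope once the doubling
time exceeds about a year. The training objective also has the
$(r, a_p)$ compensation valley, so at a fixed 12-point split the
least-squares point estimate of $r$ carries a median relative error of
~20–25% across the default cohort, and its exponential extrapolation
degrades held-out predictions: the acceptance suite computes pooled
validation $R^2$ far below the oracle ceiling of ~0.997 for the true
parameters (≈0.76–0.83 on typical seeds, and occasionally driven to
large negative values by a single slow-growing patient whose training
optimum sits at the growth-rate bound). This is a statistical
floor of the study design, not an optimizer failure: the fitted SSE beats
the truth's SSE for every patient. The package's own remedy is the
iterative training-set expansion, which sizes each training set to the
patient: in the bundled analysis workflow the pooled validation $R^2$
rises from 0.29 at the fixed split to 0.97 at the individually sized
minimal training sets.

## Problem sizes

The test suite and acceptance script use cohorts of 20 patients for
calibration studies, 5 patients for the iterative-training and
regimen-search oracles, 50 random draws for closed-form solver checks,
and daily PSA grids for stabilization decisions; these sizes give stable
statistics while keeping a full run in the minutes range on one core.
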