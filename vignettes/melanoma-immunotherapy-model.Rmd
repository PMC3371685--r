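---
title: "A two-compartment DDE model of CTL + anti-CD137 immunotherapy against melanoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-compartment DDE model of CTL + anti-CD137 immunotherapy against melanoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melimm)
```

## The biological problem and the model

B16-OVA melanoma is poorly immunogenic: adoptively transferred, in vitro
activated OT1 cytotoxic T lymphocytes (CTLs) infiltrate the tumour but on
their own barely slow it down. Co-administration of anti-CD137 (4-1BB)
immunostimulatory antibodies boosts CTL duplication and tumour
infiltration, and in mice the combination — one bolus of both at day 3
after tumour inoculation — eradicates the tumour, while either component
alone is nearly ineffective.

`melimm` models this with seven delayed ordinary differential equations in
two compartments. The *injection point* holds the injected CTLs $E$ and
antibodies $Ab$, which decay (death rate $\alpha_8$, degradation
$\alpha_{10}$) and migrate to the skin at rate $\alpha_{11}$ with a delay
$\tau$. The *skin* holds the melanoma $C$, antigens $A$, naive CTLs $N$,
and the arrived CTLs $E_s$ and antibodies $A_s$:

$$
\begin{aligned}
E'   &= K_{in}(t,p) - (\alpha_{11}+\alpha_8)E \\
Ab'  &= K_{in}(t,q) - (\alpha_{11}+\alpha_{10})Ab \\
E_s' &= \alpha_7 \tfrac{A_s}{A_s+k_1} E_s + \alpha_{11} E(t-\tau)
        + \alpha_6 N A - \alpha_8 E_s \\
A_s' &= \alpha_{11} Ab(t-\tau) - \alpha_9 A_s E_s - \alpha_{10} A_s \\
N'   &= h (M - N) - \alpha_6 N A \\
C'   &= (\alpha_1 - \alpha_2 \ln C)\, C
        - \alpha_3 \tfrac{A_s+k_2}{A_s+k_3} E_s C \\
A'   &= \alpha_4\, \alpha_3 \tfrac{A_s+k_2}{A_s+k_3} E_s C
        - \alpha_5 A - \alpha_6 N A
\end{aligned}
$$

The tumour grows along a Gompertz law with plateau
$\exp(\alpha_1/\alpha_2) \approx 2.6\times 10^7$ cells at the default
calibration. Antibodies act twice: a Holling type II factor
$A_s/(A_s+k_1)$ gates CTL duplication, and $(A_s+k_2)/(A_s+k_3)$ scales
CTL killing between $k_2/k_3 = 1/50$ (no antibodies, poor infiltration)
and 1 (saturated). Antigen released by killed tumour cells
($\alpha_4$ per kill) recruits naive CTLs into the activated pool at rate
$\alpha_6 N A$; the naive pool relaxes back to its homeostatic size $M$ at
rate $h$. Antigen-presenting cells and T-helper signalling are deliberately
collapsed into the single $\alpha_6 N A$ term.

All rates are per $\Delta t$ = 8 hours (the shortest biologically
meaningful interval here, of the order of one cell division), and the
experiment spans $100\,\Delta t \approx 33$ days. `model_params()` carries
the full calibration with documentation of every unit; a YAML copy lives
in `inst/extdata/table2-params.yaml` and round-trips bit-exactly.

Design choices where the formulation left room:

* **Initial conditions.** Everything treatment-derived starts at 0;
  $N(0)=M$, $C(0)=C_0$. The pre-history (times $< 0$) equals the initial
  state.
* **The dosing function $K_{in}$** is realised as an instantaneous state
  jump (Dirac bolus) at the scheduled time — the in vivo protocol is one
  single boost — so the continuous-inflow arguments of the right-hand side
  default to zero and the RHS stays a pure function.
* **A single shared delay.** Both delayed migration terms use the same
  $\tau$; $\tau = 1$ is read in $\Delta t$ units (8 h), consistent with
  every other rate.
* **$\ln C$ below one cell.** The growth term is defined as 0 for
  $C < 1$: fractional cells cannot proliferate and the logarithm diverges
  at 0. Therapy can and does drive $C \to 0$; the floor keeps extinction
  absorbing.
* **Antigen and antibody "counts"** are abstract molecule counts; no
  physical concentration units are attached.

## Numerical integration: method of steps, stiffness, and the step size

`integrate_model()` advances the system with classical fixed-step RK4
organised as a method of steps: the grid step divides $\tau$ and every
event time, so delayed values at stage endpoints are stored grid nodes
(half-stages interpolate linearly between the two bracketing nodes — the
interpolation error is dominated by the RK4 truncation error at the steps
used). Two conventions matter at discontinuities:

* a bolus is applied to the node state *before* the step departing that
  node, so the stored state at an event time is the post-jump value;
* the delayed *echo* of a bolus at $t_{ev}+\tau$ is handled one-sidedly:
  a step *ending* at the echo reads the pre-jump left limit, the step
  *starting* there reads the post-jump value. Without this the onset node
  carries an $O(h)$ artifact that spoils step-refinement convergence.

States are floored at zero after every step; under the default calibration
the floor only engages as the tumour goes extinct (the count is kept in
the `clamp_count` attribute).

**Stiffness.** Once injected CTLs reach the skin and kill tumour cells,
antigen is cleared by naive-CTL activation at rate $\alpha_6 N \approx
0.1 \times 196000 \approx 2\times 10^4$ per $\Delta t$ — four orders of
magnitude above every other rate. The antigen pool is a fast
quasi-equilibrium (its level stays below a few hundred molecules), but an
explicit scheme is only stable while $h\,\alpha_6 N$ stays inside the RK4
stability interval ($\approx 2.79$ on the negative real axis). Treated
runs therefore need $h \sim 10^{-4}\,\Delta t$; untreated and
antibody-only runs never produce antigen (no CTLs in the skin) and are
non-stiff. With `hstep = NULL` the integrator picks
$h \approx 1.4/(\alpha_6 M)$ — rounded so that an integer multiple of
steps spans $\tau$ and the output grid — whenever the schedule injects
CTLs, and $h = 0.05$ otherwise. The compiled inner loop makes the fine
steps cheap (a full treated run costs a fraction of a second). Correctness
is established empirically rather than assumed: the suite checks
agreement with the closed-form untreated solution, exact exponential decay
of $E$ between impulses, self-convergence under 4-fold step refinement,
a hand-written first-order brute-force integrator across the bolus (on
$[0, 10]\,\Delta t$, where the system is provably non-stiff because the
delayed skin coupling only begins at day 3 + $\tau$), and an independent
adaptive stiff DDE solver (`deSolve::dede`) over the full combined
trajectory.

## From cell counts to melanoma surface

In vivo efficacy is read from the melanoma surface (mm²). Assuming only
radial growth and a disk-shaped monolayer, surface and cell count are
proportional: $S = C\,\pi (d/2)^2 / \phi$. The mean melanoma cell diameter
$d$ is **not** part of the published calibration; it is a configuration
parameter defaulting to 0.02 mm (a typical B16 cell scale) and documented
as an assumption — every test of the mapping uses roundtrip and linearity
properties, never an absolute surface. The packing fraction $\phi$
defaults to 1 (the minimal, self-consistent reading of the disk
construction). The comparison metric between simulated and measured
surfaces is the symmetric relative difference
$d(x,y) = |x-y| / \big((|x|+|y|)/2\big) \in [0,2]$, with $d(0,0)$ defined
as 0 (its limit along identical values).

## Fitting the growth parameters

`fit_gompertz()` estimates $(\alpha_1, \alpha_2)$ — and, unless supplied,
$C_0$ — by nonlinear least squares of the closed-form Gompertz curve
against **log**-counts: counts here derive from measured areas, so
multiplicative error is the natural noise model. Starting values are
deterministic: increments of $\log C$ decay like $e^{-\alpha_2 t}$, so
$\alpha_2$ comes from the slope of the log of successive log-count
increments, $\alpha_1 = \alpha_2 \log(\max \text{count})$, and $C_0$ is
back-extrapolated from the earliest observation. Confidence ranges are
95% normal-approximation intervals from the least-squares covariance;
they deliberately double as the $\alpha_1/\alpha_2$ sampling bounds of the
sensitivity analysis, mirroring how the in vivo fitting fed that analysis.
A fit with a singular covariance (e.g. all observations at the plateau,
where only the ratio $\alpha_1/\alpha_2$ is identified) is flagged
`wide_ci` with unbounded ranges rather than silently trusted.

## Sensitivity analysis: LHS + time-resolved PRCC

`prcc_timecourse()` samples the parameter space with a Latin hypercube
(uniform marginals, one point per equal-probability stratum per parameter
— the standard choice for LHS–PRCC studies), runs one integration of the
chosen arm per sample, and computes, at each output time, the partial rank
correlation of every parameter with the tumour burden $C(t)$: rank all
columns (average ranks on ties), regress out the other parameters' ranks
from both sides, and correlate the residuals. Rank-based partialling makes
the result invariant under any strictly monotone transformation;
significance is pointwise at $p < 0.01$ from the $t$ statistic with
$n - 2 - (k-1)$ degrees of freedom, with no correction across time points
(the time course is read as a profile, not as a family of tests). Two
degenerate situations are defined rather than crashed on: a constant
output (e.g. pre-treatment, when no sampled parameter can have acted)
yields `NA` coefficients, and a perfectly explained side yields a partial
correlation of 0.

The sampled ranges are a modelling choice, kept in configuration rather
than code: every rate and threshold varies ±50% around its nominal value;
the doses $p, q$ span 0.25×–2× nominal (the dose-reduction question);
$\alpha_1, \alpha_2$ take the confidence ranges of the growth fit when one
is supplied — the fallback ±50% lets the Gompertz plateau
$\exp(\alpha_1/\alpha_2)$ reach astronomically large values and is not
recommended for production runs. A `dummy` parameter on $[0,1]$ is sampled
like any other but never enters the model: it is the negative control
against which "no correlation" is judged. Failed integrations are dropped
with a warning (more than 10% failures aborts). The default is $n = 1000$
samples; $n = 200$ already gives a stable sign picture and is what the
test suite and the acceptance script use.

Findings worth stating because the tests compute them: the CTL dose $p$
and the killing rate $\alpha_3$ correlate strongly negatively with the
burden after treatment, CTL death $\alpha_8$ positively, duplication
$\alpha_7$ negatively but more weakly than $\alpha_3$; the naive pool size
$M$ weakly negatively; the thymic refresh rate $h$ and the antigen
half-life $\alpha_5$ show no significant correlation. The antibody dose
$q$ sits at the dummy's noise level in the first post-treatment days and
turns only weakly negative later: with the calibrated thresholds
($k_1 = 10$, $k_3 = 50$) the skin antibody count saturates both antibody
effects within a fraction of a time step at *any* dose in the sampled
range — which is precisely the model's clinical suggestion that the
antibody dose could be reduced without losing efficacy.

## The synthetic measurement cohort

`generate_cohort()` stands in for the in vivo measurement stream: five
mice (the in vivo group size) measured every third day from day 6 to 30
(the actual observation days are not on record, so the grid is a
configurable default), each following Gompertz kinetics from the
inoculated burden, converted to surface and perturbed by multiplicative
lognormal noise $e^{\sigma Z}$ with $\sigma = 0.05$ (areas are positive
and error scales with size; 5% is a realistic calliper-scale error).
Optional inter-mouse variability (default CV 5%) draws each mouse's
$(\alpha_1, \alpha_2)$ around the cohort truth; the per-mouse truth is
recorded in the output so the zero-noise identity is exact. The generator
does **not** emulate the detection delay of small early tumours (a real
melanoma takes days to become visible — the known early gap between
simulated and measured surfaces), measurement censoring, or treated-arm
kinetics. Passing tests therefore demonstrate correct recovery under this
noise model, not robustness to everything real measurements can do.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use: horizon 100 $\Delta t$
(≈33 days); output grid every 0.1 $\Delta t$; $n = 200$ LHS samples for
the sensitivity sign structure (≈40 s on one core) and $n = 500$ × 20
replicates for the dummy-control calibration; 100 noise replicates for
growth-parameter recovery; a 5-mouse cohort for the pipeline. Every
stochastic stage takes an explicit seed; `run_pipeline()` derives
per-stage sub-seeds deterministically from one master seed, so re-running
a configuration reproduces every artifact byte for byte.

## Known limitations

* No spatial structure and no vertical growth phase: the surface mapping
  is a monolayer disk, sensible only for the radial phase.
* Naive-CTL arms of the in vivo protocol are outside the model (there is
  no injected-naive pathway).
* The explicit fixed-step integrator buys exact delay alignment at the
  cost of very small steps in treated runs; a stiff implicit solver would
  be faster but would interpolate the delayed discontinuities.
* PRCC measures monotone association; strongly non-monotone responses
  (e.g. near the eradication threshold late in the time course, where many
  sampled runs tie at $C = 0$) compress towards zero.
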