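# melimm

Simulation and sensitivity analysis of immune-system–melanoma competition
under combined immunotherapy: adoptive transfer of in vitro activated OT1
cytotoxic T lymphocytes (CTLs) plus anti-CD137 (4-1BB) immunostimulatory
monoclonal antibodies, against B16-OVA melanoma in mice.

## The model

Two compartments are modelled: the **injection point**, holding the injected
activated CTLs `E` and antibodies `Ab`, and the **skin**, where the tumour
grows and the competition happens, holding skin-resident activated CTLs
`Es`, antibodies `As`, naive CTLs `N`, melanoma cells `C` and tumour
antigens `A`. Migration between compartments carries a delay τ, giving a
system of seven delay differential equations (rates per Δt = 8 h):

```
E'  = K_in(t, p) − α11 E − α8 E
Ab' = K_in(t, q) − α11 Ab − α10 Ab
Es' = α7 [As/(As+k1)] Es + α11 E(t−τ) + α6 N A − α8 Es
As' = α11 Ab(t−τ) − α9 As Es − α10 As
N'  = h (M − N) − α6 N A
C'  = (α1 − α2 ln C) C − α3 [(As+k2)/(As+k3)] Es C
A'  = α4 α3 [(As+k2)/(As+k3)] Es C − α5 A − α6 N A
```

The tumour grows Gompertz-like with plateau `exp(α1/α2)`; antibodies boost
CTL duplication (Holling type II in `As`) and CTL killing (the
`(As+k2)/(As+k3)` factor, `k2 ≪ k3`: killing is 50-fold weaker without
antibodies at the default thresholds); killed tumour cells release antigens
that recruit naive CTLs into the activated pool. Treatment is a single
bolus `K_in` at day 3, realised as an instantaneous state jump.

The package provides:

* `integrate_model()` — method-of-steps fixed-step RK4 integrator with
  impulsive dosing, delay-aligned grid, zero-flooring, and automatic
  stable-step selection (the antigen-clearance term `α6·N·A` makes treated
  runs stiff); compiled inner loop.
* `run_scenario()` / `run_scenarios()` — the four vaccination protocols
  (untreated, CTLs only, antibodies only, combined), all dosed at day 3.
* `cells_to_surface()` / `surface_to_cells()` / `surface_timeseries()` /
  `compare_surfaces()` — the disk-monolayer observable mapping between
  cell counts and measured melanoma surface (mm²), plus the symmetric
  relative-difference metric `d(x,y) = |x−y| / ((|x|+|y|)/2)`.
* `gompertz_closed_form()` / `fit_gompertz()` — the exact untreated
  solution and nonlinear least-squares estimation of (α1, α2) from noisy
  measurements, with confidence ranges.
* `lhs_sample()` / `prcc()` / `prcc_timecourse()` — Latin hypercube
  sampling and time-resolved partial rank correlation coefficients of every
  parameter against the tumour burden `C(t)`, with a dummy-parameter
  negative control and pointwise `p < 0.01` significance.
* `generate_cohort()` — synthetic per-mouse surface measurements (Gompertz
  kinetics, lognormal noise, optional inter-mouse spread), so the whole
  pipeline runs with no external data.
* `run_pipeline()` — config-driven end-to-end run writing tidy CSVs and a
  JSON manifest (thin CLI wrapper in `inst/scripts/run-pipeline.R`).

## Worked example

```r
library(melimm)

params <- model_params()      # the published calibration
runs   <- run_scenarios(params)             # four arms, horizon 100 dt
sapply(scenario_names(), function(nm) {
  x <- runs[runs$scenario == nm, ]; x$C[nrow(x)]
})
#> untreated  ot1_only   ab_only  combined
#> 6.365e+06 6.308e+06 6.365e+06 6.521e-11
```

Only the combined arm eradicates the tumour (`C < 1` cell by day 33);
antibodies alone change nothing (identical to untreated, node for node),
and CTLs alone shave off under 1%.

```r
cohort <- generate_cohort(params, seed = 1)   # 5 synthetic mice
fit    <- fit_gompertz(cohort_counts(cohort), C0 = params$C0)
tidy(fit)
#>   term   estimate std.error conf.low conf.high
#> 1 alpha1   0.199   0.00353    0.192     0.206
#> 2 alpha2   0.0108  0.000250   0.0104    0.0113
```

The growth parameters are recovered from the noisy cohort to within a few
percent; the confidence ranges then bound the α1/α2 sampling in the
sensitivity analysis, exactly as the fitting feeds the analysis for the in
vivo measurements.

```r
pt <- prcc_timecourse(params, ranges = default_ranges(params, fit),
                      n = 200, seed = 1)
dplyr::filter(tidy(pt), time_days == 10,
              parameter %in% c("p", "q", "alpha3", "alpha8", "dummy"))
#>   time_days parameter     prcc  p_value significant
#> 1        10    alpha3 -0.86501 8.41e-56        TRUE
#> 2        10    alpha8  0.64321 1.24e-22        TRUE
#> 3        10         p -0.91040 6.62e-71        TRUE
#> 4        10         q -0.00697 9.26e-01       FALSE
#> 5        10     dummy -0.09343 2.10e-01       FALSE
```

At day 10 the CTL dose `p` and killing rate `α3` correlate strongly and
negatively with the tumour burden, CTL death `α8` positively, while the
antibody dose `q` is indistinguishable from the dummy control — the model's
key clinical suggestion that the antibody dose could be reduced without
losing efficacy. `autoplot(pt)` draws the PRCC time courses with the dummy
overlay and significance marks.

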