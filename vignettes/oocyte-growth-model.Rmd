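---
title: "An oocyte growth dynamics model of fathead minnow fecundity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An oocyte growth dynamics model of fathead minnow fecundity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oocytedyn)
```

## The problem

Chemicals that disrupt endocrine function in fish — aromatase inhibitors and
other steroid-synthesis inhibitors among them — suppress the production of
vitellogenin (VTG), the egg-yolk precursor protein that growing oocytes
absorb from plasma. Because VTG uptake is the central process of oocyte
maturation, a female's plasma VTG concentration is a mechanistically
meaningful, cheaply measurable predictor of her egg output. `oocytedyn`
implements an individual-based model that turns a single per-fish plasma VTG
concentration (nmol·µL⁻¹) into predicted spawning: when batches of oocytes
are recruited, how fast they grow, when they are spawned and how many eggs
each spawn contains. Its intended users are ecotoxicologists interpreting
21-day fish short-term reproduction assays and modellers feeding fecundity
into population dynamics models.

## The model

A female recruits *batches* of oogonia into growth and development. For a
batch, the absorbed VTG mass $M_\mathrm{VTG}$ (nmol) and oocyte volume
$V_\mathrm{Ooc}$ (µL) obey

$$\frac{dM_\mathrm{VTG}}{dt} = \rho_\mathrm{VTG\_Ooc}\, C_\mathrm{VTG}\, V_\mathrm{Ooc},
\qquad
V_\mathrm{Ooc}(t) = 0.156\, R_\mathrm{VTG}\, M_\mathrm{VTG}(t) + V_\mathrm{Oog},$$

where $\rho_\mathrm{VTG\_Ooc}$ (h⁻¹) is the VTG absorption rate constant,
$C_\mathrm{VTG}$ (nmol·µL⁻¹) the plasma VTG concentration, 0.156 mg·nmol⁻¹
the molecular mass of VTG, $R_\mathrm{VTG}$ (µL·mg⁻¹) the oocyte volume
gained per mass of VTG absorbed (oocytes also take up water and nutrients),
and $V_\mathrm{Oog}$ the oogonium (initial) volume. Initial conditions are
$M_\mathrm{VTG}(0)=0$, $V_\mathrm{Ooc}(0)=V_\mathrm{Oog}$. All oocytes in a
batch grow at the same rate, and batches grow independently — the model has
no resource competition. A batch spawns the moment its volume reaches the
threshold $V^* = 0.52$ µL, derived from the diameter of mature oocytes.

Two empirical distributions supply the stochasticity, both truncated
lognormals fitted to control fathead minnows from paired-design studies:

* clutch size (oogonia per batch): $\mu = 4.11$, $\sigma = 0.96$, bounds
  $[1, 317]$;
* recruitment interval between batches (days): $\mu = 1.21$,
  $\sigma = 0.57$, bounds $[1, 25]$.

Each simulation covers an 81-day start-up (60 days of maturation from first
oogonia recruitment plus a 21-day acclimation window) followed by the
user-specified exposure window; start-up days are reported as negative study
days and exposure begins at day 0. Plasma VTG is piecewise constant: the
baseline concentration (default 0.1 nmol·µL⁻¹) before day 0 and the
fish's measured (or generated) exposure concentration thereafter. The switch
applies to all live batches at day 0; the alternative — growing
pre-exposure recruits to completion at the baseline — has no empirical
support we could anchor, and the switch-at-exposure rule is the conservative
reading of "concentration held constant during the modelled exposure".

## Parameters, units and calibration

| parameter | units | default | meaning |
|---|---|---|---|
| `w_vtg` | mg·nmol⁻¹ | 0.156 | VTG molecular mass |
| `v_threshold` | µL | 0.52 | spawning threshold volume |
| `v_oog` | µL | 5.236e-4 | oogonium volume (100 µm diameter sphere) |
| `r_vtg` | µL·mg⁻¹ | 1 | volume per VTG mass absorbed |
| `rho_vtg_ooc` | h⁻¹ | calibrated | VTG absorption rate constant |
| `c_vtg_pre_default` | nmol·µL⁻¹ | 0.1 | baseline (pre-exposure) plasma VTG |
| `startup_days` | d | 81 | pre-exposure window |
| `ode_rtol`, `ode_atol` | — | 1e-3, 1e-10 | numeric ODE tolerances |

The dynamics depend on $\rho_\mathrm{VTG\_Ooc}$ and $R_\mathrm{VTG}$ only
through their product, so spawning data cannot identify them separately;
neither value is part of the published evidence this package builds on.
`calibrate_rates()` therefore pins the product by a defining identity: at
the baseline concentration, maturation takes exactly one mean recruitment
interval,

$$\rho R = \frac{\ln(V^*/V_\mathrm{Oog})}{0.156\; C_\mathrm{ref}\; \bar\tau},
\qquad C_\mathrm{ref} = 0.1\ \mathrm{nmol\,\mu L^{-1}},$$

with $\bar\tau$ the truncated-lognormal mean interval, computed by
quadrature at parameter construction:

```{r}
p <- model_parameters()
trunc_lognormal_mean(p$interval_dist)  # mean interval, days
maturation_time(0.1, p)               # maturation at baseline, days
```

This choice makes a control female's steady-state spawn throughput equal to
the fitted clutch-size/interval throughput. $V_\mathrm{Oog}$ itself only
enters through $\ln(V^*/V_\mathrm{Oog})$ and is absorbed by the calibration;
its default (a 100 µm-diameter sphere, 5.236e-4 µL) is a conventional
oogonium size for a cyprinid and its exact value has no effect on calibrated
behaviour. The per-hour rate is converted to per-day exactly once, at
parameter construction.

## Numerical choices

* **Closed form first.** Within a constant-concentration segment the volume
  ODE is linear, $V(t) = V(t_0)\,e^{kC(t-t_0)}$ with
  $k = 0.156\,R\,\rho$, so the integrator propagates the exact solution
  segment by segment and solves the threshold crossing with a logarithm,
  not a root finder. A numeric path (`method = "ode"`,
  `deSolve::lsodar` with root-triggered stopping and the tolerances above)
  is kept for fidelity checks; the two agree on spawn times to relative
  error below 1e-6 when the numeric path is run at tight tolerances.
* **Tie-breaks.** A crossing exactly at the end of the window counts as a
  spawn. Spawn times are binned to integer study days by `floor()`, because
  eggs are collected daily in the assay.
* **Clutch integerization.** The clutch distribution was fitted to egg
  counts but is continuous; draws are rounded to the nearest integer and
  re-checked against the bounds (the published description does not state
  an integerization rule; rounding is unbiased to first order).
* **Truncation by rejection.** Both samplers reject draws outside the
  bounds; acceptance exceeds 95% for both shipped parameter sets, and the
  resulting distribution is exactly the truncated one.
* **Degenerate inputs.** Zero VTG freezes growth (maturation time
  `Inf`); zero spawns makes eggs-per-spawn an `NA` sentinel, converted to 0
  only at presentation (`undefined_as_zero()`), never in statistics.
* **Seeding.** `simulate_cohort()` derives one substream per
  (fish, replicate) from the master seed by a keyed hash, so adding or
  removing fish never perturbs another fish's draws and any single
  simulation can be reproduced in isolation.
* **First recruitment.** The first batch is recruited at the start of the
  start-up window (configurable); with an 81-day start-up and ~4-day
  maturation at baseline the steady state is reached long before day 0, so
  this choice does not affect exposure-window output.

## Reproduction metrics and group designs

For a window of $n_\mathrm{days}$ days, $n_\mathrm{female}$ females,
$n_\mathrm{egg\_total}$ eggs and $n_\mathrm{spawns}$ spawns:

$$\text{average fecundity} = \frac{n_\mathrm{egg\_total}/n_\mathrm{female}}{n_\mathrm{days}},\quad
\text{eggs per spawn} = \frac{n_\mathrm{egg\_total}}{n_\mathrm{spawns}},\quad
\text{spawns per female} = \frac{n_\mathrm{spawns}}{n_\mathrm{female}},$$

plus the cumulative fecundity series (running total of all groups' eggs by
day, optionally per female). The three scalars satisfy
$\text{avg fecundity} = \text{eggs/spawn} \times \text{spawns/female} / n_\mathrm{days}$
whenever eggs-per-spawn is defined.

In a *group* spawning design (typically four females and two males per
tank) the eggs collected on a day cannot be attributed to individual
females, so model-predicted events are compared after *binning*: all eggs
spawned by a group's females on the same study day count as one spawn whose
clutch is the day's sum. Binning conserves total eggs and average fecundity
exactly and only reduces spawn counts — which is precisely why it improves
agreement with observed eggs-per-spawn and spawns-per-female. Model and
data distributions are compared with a two-sample Kolmogorov–Smirnov test
(asymptotic p-values; exact small-sample p-values are out of scope). For the
group-design comparisons the tidy metrics table supports both fish-level and
replicate-level samples, since published practice does not fully specify
which level formed the samples.

## Synthetic cohorts: what they emulate and what they do not

`generate_cohort()` builds study-shaped VTG input tables: control
concentrations are lognormal with parameters fitted by maximum likelihood to
the packaged control column of measured fish (mean ≈ 0.086 nmol·µL⁻¹, range
≈ 0.02–0.21), and each treatment applies a multiplicative depression factor
in $[0,1]$ — the signature of steroid-synthesis inhibition. This emulates
the *input* structure of real studies. It deliberately does not emulate
dose–response shape, between-tank correlation, time-varying VTG (e.g. the
compensatory recovery seen under prolonged ketoconazole exposure) or
measurement error. Passing tests on synthetic cohorts therefore validate
the simulator and its bookkeeping, not the model's fidelity to any
particular chemical; the packaged ketoconazole-study VTG table
(`load_fixture("ketoconazole_table2")`) provides measured inputs for a
qualitative end-to-end run.

## Problem sizes used in the checks

The package's test suite runs the samplers at 10⁵ draws (CDF sup-distance
< 0.01 against the analytic truncated CDF), parameter recovery at 10⁴
draws (±0.05 on both log-scale parameters), conservation across all output
files on 100 random small cohorts, VTG-monotonicity of mean egg output on a
six-point concentration grid at 200 replicates per point, and the
control-cohort evaluation at the published replication level — 50
replicates of three tanks of four females (600 simulations). These sizes
were chosen so each check's Monte-Carlo error is comfortably below the
tolerance it asserts.

## Known limitations

* Plasma VTG is piecewise constant with a single step at exposure start;
  continuously time-varying VTG is out of scope, and chemicals that induce
  compensatory VTG recovery (ketoconazole-like) will be over- or
  under-predicted accordingly.
* The clutch and interval distributions are fathead minnow control-fish
  fits; other species (or other spawning modes) need refitted
  distributions.
* Recruitment never shuts down — no atresia, energetics or temperature
  effects; males, fertilization and hatching success are outside the model.
* Only the product $\rho R$ is calibrated; reported individual values of
  `rho_vtg_ooc` and `r_vtg` are a labelled decomposition, not estimates.
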