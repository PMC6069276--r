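---
title: "Modelling pediatric fluoride kinetics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pediatric fluoride kinetics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluopbpk)
```

## The problem

Children are exposed to fluoride from several media at once: fluoridated tap
water, food and beverages, swallowed toothpaste, ingested soil and dust, and
(negligibly) air. Population biomonitoring surveys report spot-urine fluoride
concentrations, which reflect the aggregate of all those sources. `fluopbpk`
connects the two directions of that problem for 4- and 8-year-old reference
children:

* **forward** — given per-source intakes, predict the steady-state urinary
  fluoride concentration a survey would observe; and
* **reverse** — given an observed urinary concentration, recover the absorbed
  total daily fluoride intake (TDFI, mg/kg/day) that would produce it, and
  compare it with dental-health guidance values (the suggested optimal
  absorbed dose of 0.04 mg/kg/day and absorbed tolerable daily intakes of
  0.08 and 0.16 mg/kg/day).

## Model structure

The kinetic core is a flow-limited (perfusion-limited) compartmental model
with amounts in mg and time in minutes. Compartments: well-mixed **blood**,
**liver**, **kidney**, **rest of body**, and **bone**; a cumulative **urine**
state closes the mass balance.

For each perfused soft tissue $t$ with blood flow $Q_t$ (L/min), volume $V_t$
(L) and tissue:plasma partition coefficient $P_t$:

$$\frac{dA_t}{dt} = Q_t\left(C_{art} - \frac{A_t}{V_t P_t}\right),$$

with the dose infusion added to the liver term. Ingested fluoride is absorbed
as a zero-order hepatic infusion: an absorbed daily dose $D$ (mg/day) enters
the liver at $D/1440$ mg/min, continuously over 24 h. There is no explicit
gastrointestinal compartment; oral absorption is folded into the source
bioavailability factors (water 0.83, toothpaste 1.0, diet and soil 0.40, air
1.0).

Elimination is split by age. Plasma clearance scales allometrically from an
adult reference value, $CL_p = CL_{ref}\,(BW/70)^{0.75}$, and is partitioned
into **bone clearance** and **renal clearance** along two straight lines in
age anchored at (0 y: 90%/10%) and (18 y: 50%/50%) — at age 4 the split is
81.1% bone / 18.9% renal, at age 8 it is 72.2% / 27.8%. Renal elimination is
$CL_r C_{art}$ into urine (the driving concentration is switchable to the
kidney-exit concentration via `renal_driver`).

### Bone handling

Bone is the decisive structural choice. Fluoride is avidly sequestered in
bone mineral, and in a growing child there is essentially no resorption
returning stored fluoride to blood, so no separate mobilization compartment
is modelled. Two behaviours are available through `bone_mode`:

* **`equilibrating`** (default): a single well-stirred exchangeable bone pool
  whose uptake is rate-limited by bone clearance,
  $dA_b/dt = CL_b\,(C_{art} - A_b/(V_b P_b))$, and whose *capacity* is set by
  the bone:plasma partition coefficient $P_b$. Early in exposure nearly all
  cleared fluoride is captured by bone; as the pool fills, net uptake decays
  and daily urinary excretion approaches the absorbed daily dose. The
  approach to that steady state is governed by the bone-fill time constant
  $\tau = V_b P_b\,(CL_r + CL_b)/(CL_r CL_b)$ — about 31 days for the
  4-year-old defaults, which puts the 1%-convergence day near 140 and the
  practical steady state at the conventional 150-day horizon.
* **`sink`**: irreversible uptake $CL_b C_{art}$ that never saturates. Here
  the steady-state urinary fraction of the infusion is the closed form
  $CL_r/(CL_r + CL_b)$ (about 0.19 at age 4), which the test suite uses as
  an independent oracle for the solver. This mode cannot reproduce the
  validation-cohort arithmetic — six published cohorts excrete 26–56% of
  their *intake* in urine, far above 19% of the absorbed dose — which is why
  the equilibrating pool is the default.

The whole system is linear in dose: every output (concentration, AUC,
excreted amount) is proportional to the absorbed daily dose. The package
exploits this for speed (a memoised unit-dose response) and the tests verify
it by superposition.

## Parameters, units, defaults

All physiology lives in a versioned YAML configuration
(`inst/extdata/config_default.yaml`); nothing anatomical is hard-coded. The
reference children are 16 kg / 103 cm at age 4 and 25 kg / 127 cm at age 8
(growth-chart 50th percentiles); intermediate validation ages interpolate
linearly.

| parameter | default | units | note |
|---|---|---|---|
| cardiac output | $0.235\,BW^{0.75}$ | L/min | sex-averaged allometric rule |
| blood volume | 8% of BW | L | 1 kg/L density |
| liver volume / flow | 2.6% BW / 25% CO | | |
| kidney volume / flow | 0.5% BW / 19% CO | | |
| bone volume / flow | 4% BW / 5% CO | | exchange is clearance-limited |
| rest-of-body volume / flow | 60% BW / 51% CO | | |
| partition coefficients | liver 0.85, kidney 1.2, rest 0.5, bone 250 | — | bone is the depot |
| reference plasma clearance | 0.07 at 70 kg | L/min | adult value, split 50/50 renal/bone at maturity |
| daily urine volume | 0.5 (age 4), 0.7 (age 8) | L/day | **calibration-sensitive** |

The compartment fractions and partition coefficients are transcriptions of
standard reference-child physiology and fluoride tissue-affinity values; the
bone partition coefficient in particular is an order-of-magnitude figure for
skeletal sequestration whose product with bone volume fixes the bone-fill
time constant above. The daily urine volumes deserve emphasis: the reported
urinary *concentration* is (excretion mg/day) / (urine L/day), so these two
numbers scale every concentration output and every reverse-dosimetry result.
They are deliberately exposed at the top of the configuration.

Solver settings: `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-12` mg,
daily (or finer) output checkpoints. Mass balance is checked on every run
and holds to machine precision, far inside the 0.1% guard.

## Calibration

Six published cohorts of 4–7-year-olds (Venezuela, Chile, UK, Germany)
provide estimated per-source intakes with measured 24-h urinary fluoride.
The uncalibrated model over-predicts urinary excretion for all six — as
expected when absorption fractions are generous and toothpaste
bioavailability is measured on an empty stomach. The empirical adjustment
factor is the arithmetic mean of the per-study measured/modeled ratios
(a geometric mean is available as an option), and is applied exactly once to
urinary outputs; outputs carry a `calibrated` attribute and a second
application is an error. Under the default configuration the factor computes
to about 0.415.

```{r calibration}
cal <- compute_adjustment_factor(validation_studies())
cal
```

The reverse direction divides by the factor implicitly: inversion solves the
*calibrated* forward model, so forward/inverse round trips close identically
regardless of the factor's value.

## Exposure scenarios

Presets reproduce the study design (`scenario_preset()`):
`"fluoridated-tap"` (water 0.7 mg/L, used for the source-contribution
analysis), `"ontario-s1"` (the population-equivalent 0.505 mg/L from 70%
coverage at 0.7 mg/L and 30% at the 0.05 mg/L detection limit),
`"quebec-s2"` (0.06 mg/L, the published equivalent for 2.5% coverage —
the exact weighted mean is 0.06625 mg/L, and the published rounded value is
preserved in the preset), and `"quebec-s3"` (scenario 2 with the dietary
source removed, reflecting that food prepared with fluoridated water carries
part of the water signal).

```{r scenarios}
report_scenarios(ages = 4)
```

## Reverse dosimetry

A biomonitoring concentration is converted to a daily excreted amount with
the configured urine volume and inverted through the calibrated model with a
bracketed scalar root finder (`uniroot` on
$f(d) = \widehat{A}_{exc}(d) - A_{target}$, initial bracket
$[10^{-6}, 1]$ mg/kg/day with geometric expansion, positivity enforced by
the bracket). Because the model is linear the closed-form solution
$d = A_{target}/\text{slope}$ exists; it is used as a cross-check in the
tests, while the root finder remains the primary path. Residual tolerance is
1e-10 mg/day, floored at the forward solver's relative accuracy
($2\times10^{-8} A_{target}$) when predictions come from fresh ODE solves.

```{r inversion}
invert_biomonitoring()[, c("region", "age_years", "urinary_concentration",
                           "absorbed_tdfi")]
```

## Sensitivity analysis

For parameter $P$ with output $O$ (24-h urinary excretion `Aexc` or 24-h
venous AUC `AUC_vc`, both at day 150), the index is the normalized one-sided
finite difference with a 2% parameter reduction:

$$SI_P = \frac{O_2 - O_i}{P_2 - P_i}\cdot\frac{P_i}{O_i},
\qquad P_2 = 0.98\,P_i .$$

The index is unit-free (invariant to parameter rescaling) and equals the
power-law exponent for outputs of the form $O \propto P^k$; the tests verify
$SI = 1$ for the dose multiplier and agreement within 2% with a
central-difference elasticity. `screen_parameters()` ranks the parameters
whose largest $|SI|$ across ages and metrics reaches 0.05: body weight, the
oral absorption fraction, renal clearance and the water/diet/toothpaste
intakes pass; reducing renal clearance raises blood levels (negative
`AUC_vc` index) while lowering excretion (positive `Aexc` index), and bone
volume carries a negative `AUC_vc` index. Soft-tissue volumes are inert at
steady state. Perturbed systems intentionally bypass the construction-time
physiological invariants — a perturbed physiology is a probe, not a
reference child.

## Synthetic data

Two generators support testing without any external data:

* `sample_urinary_concentrations()` draws lognormal spot-urine
  concentrations with prescribed geometric mean and geometric SD (default
  GSD 2.0, typical of biomonitoring spread); the 95th percentile closed form
  $GM \cdot GSD^{1.6449}$ is exposed on the specification object.
* `make_validation_cohort()` fabricates cohorts with ages 4–8 and intakes in
  the ranges spanned by the published cohorts, whose "measured" excretion is
  the model prediction times a known bias and lognormal noise; recovering
  the bias through `compute_adjustment_factor()` is the parameter-recovery
  test (within 5% at 200 studies, GSD 1.3).

What the generators do *not* emulate: survey weights and sampling design,
within-person spot-vs-24-h variability, creatinine correction, or seasonal
variation of water fluoride. Passing recovery tests therefore demonstrate
correctness of the estimator under the model's own assumptions, not survey
realism.

## Numerical choices and degenerate inputs

* Problem sizes: simulations run 150 days (300 for the convergence check) at
  daily checkpoints, hourly when an AUC is required; these solve in well
  under a second each.
* Zero dose short-circuits to exactly zero everywhere; zero intakes make
  source contributions undefined (an error, not `NaN`).
* The clearance split is computed as bone fraction and its complement, so
  the two fractions sum to 1 exactly in floating point.
* `time_to_steady_state()` compares each day's excretion with the final
  simulated day and returns `NA` (with a warning) when only the final day
  qualifies while the series is still moving.
* Bundled fixtures are checksum-verified on load.

## Known limitations

* The model is deterministic: it represents a theoretical average child per
  age and carries no inter-individual variability; probabilistic extensions
  (e.g. Monte-Carlo over physiology and intakes) are out of scope.
* Several anatomical constants are configuration transcriptions rather than
  measured quantities; the full-model outputs (adjustment factor, scenario
  concentrations, recovered doses) inherit that uncertainty, which is why
  the acceptance checks carry a ±25% band while the pure-arithmetic
  quantities are exact.
* Physiology is frozen at the reference age for the whole simulation — no
  growth over the 150-day span, consistent with the steady-state framing.
* Only direct water consumption is counted (indirect water is part of the
  dietary intake), toothpaste is the only dental-care source, and the
  urinary fluoride/creatinine monitoring ratio is not implemented.
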