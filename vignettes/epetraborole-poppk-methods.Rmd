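---
title: "Population pharmacokinetic methods for epetraborole"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetic methods for epetraborole}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebopk)
```

## Scope and model

`ebopk` implements a population pharmacokinetic (popPK) analysis pipeline
for epetraborole, an orally available bacterial leucyl-tRNA synthetase
inhibitor in clinical development for *Mycobacterium avium* complex (MAC)
lung disease. The drug is given both intravenously and orally, and dose
selection for MAC patients rests on simulations from a popPK model pooled
across Phase 1 studies in healthy volunteers and Phase 2 studies in
patients. The package provides every layer such an analysis needs — the
structural kinetics, the population (mixed-effects) layer, maximum-likelihood
estimation, model diagnostics, and a synthetic trial-program generator so
the whole pipeline is testable end to end without any confidential study
data.

### Structural kinetics

Disposition is a three-compartment mammillary model with linear elimination
from the central compartment: parameters `CL` (clearance), `V1` (central
volume), `Q2`/`V2` and `Q3`/`V3` (inter-compartmental clearances and
peripheral volumes). IV doses enter the central compartment, infusions as a
zero-order input over the recorded duration. Units are fixed: mg, L, h,
mg/L.

Oral absorption uses a transit-compartment chain: `n_transit` compartments
with a common rate `ktr` feed a depot that empties into the central
compartment at a first-order rate `ka`. Food status selects the rate —
`ka_fed` or `ka_fasted` — per dose, so crossover designs are expressed
naturally. An absolute bioavailability term `F` scales the amount entering
the chain; the fraction `1 - F` never reaches the systemic circulation.
Nonlinear (Michaelis-Menten) elimination is deliberately out of scope: the
model family implemented is the linear-elimination one, which was selected
over the nonlinear alternative during the original model development.

The system is linear, so the package evaluates it in closed form rather
than by numerical integration. The disposition block of a mammillary model
is similar to a symmetric matrix via a diagonal volume scaling, so its
eigenvalues are real and the block is never defective; the package computes
them from the disposition cubic in trigonometric closed form (falling back
to a symmetric eigendecomposition near a repeated rate). The oral input is
the convolution of an Erlang arrival density with the disposition impulse
response, evaluated through a numerically guarded continuation of the
regularized incomplete gamma function: a power series where cancellation is
bounded and a complementary finite sum elsewhere, with the one possible
confluence (`ka` equal to a disposition rate) handled by a symmetric
perturb-and-average step. The result is exact superposition over doses,
machine-precision dose linearity, and agreement with an adaptive-step ODE
oracle to better than 1e-6 relative error (tested on 100 random parameter
draws). We chose this over a literal matrix exponential of the full system
because the transit chain makes that matrix defective (the transit rate is
a repeated eigenvalue), and because the convolution form vectorizes over
observation times, which is what makes the estimation layer affordable in
pure R.

Number of transit compartments: the default is `n_transit = 3`, a model
setting rather than an estimated quantity, with the fed/fasted distinction
carried entirely by `ka` (shared `ktr`). `ktr` is an independent parameter
by default; users who prefer the common `ktr = ka` parameterization can
simply set both to the same value in the configuration. No lag time is
modeled.

### Population layer

Body weight enters through fixed-exponent allometric scaling:
clearance-type parameters (`CL`, `Q2`, `Q3`) are multiplied by
`(WT / ref_wt)^0.75` and volumes by `(WT / ref_wt)^1.0`, with
`ref_wt = 70` kg. Fixed theory-based exponents are the standard reading of
"allometric scaling" in this setting and accommodate the lower body weight
of MAC patients without extra estimated parameters; both exponents and the
reference weight are configuration-overridable. Absorption rates are not
weight-scaled.

Interindividual variability (IIV) is log-normal and, by default, on `CL`
and `F` — the two effects whose magnitudes the analysis quantifies — with a
diagonal covariance. IIV is reported as a coefficient of variation,
`CV% = 100 * sqrt(exp(omega^2) - 1)`. At the magnitudes involved
(7.9%, 32.7%) this differs from the alternative convention
`100 * omega` by well under a percentage point for CL and by about 1.7
points for F; the package standardizes on the log-normal formula and
`cv_percent_to_omega()` is its exact inverse. IIV on `F` is log-normal
without an upper truncation: the typical value stays at or below 1 while
individual values may exceed 1 in the tail. A logit-scale alternative would
bound individual bioavailability at 1 but cannot be matched to a single
reported CV% without further assumptions, so it was not adopted.

Residual error is combined proportional plus additive,
`DV = C * (1 + sigma_prop * eps1) + sigma_add * eps2`, shared across
routes and studies — the safest default for data pooling rich volunteer
profiles with sparse patient samples, and the additive floor keeps the
likelihood well-behaved near zero concentrations.

### Estimation

`fit_poppk()` maximizes a Laplace approximation to the marginal likelihood.
For each subject the joint log-density of data and random effects is
maximized over `eta` by a damped Gauss-Newton/Newton search (gradient
tolerance 1e-8), and the curvature at the mode uses the Gauss-Newton form
`J' W J + Omega^-1` with the residual variance evaluated at the individual
prediction — i.e. the interaction term is carried, giving
FOCE-with-interaction-like behaviour for the proportional error component
while remaining exact for additive-error linear models. The objective
function value (OFV) is minus twice the approximate marginal
log-likelihood.

The outer problem runs on transformed parameters — logs of the typical
values, the omega variances and the residual SDs — so positivity and
positive-semidefiniteness hold by construction; `stats::nlminb` is the
outer optimizer (single start from the user's initial estimates). The
bioavailability random effect is handled analytically in the inner
Jacobian (the model is linear in `exp(eta_F)`), the clearance effect by
finite differences. Parameters the design cannot inform — oral parameters
with IV-only data, an absorption rate with no doses in that food state, any
parameter starting at zero — are detected and frozen with a warning rather
than left to drift.

Empirical Bayes estimates (EBEs) are the conditional modes;
`ebe_and_shrinkage()` reports eta-shrinkage `100 * (1 - SD(eta_hat)/omega)`
per effect and epsilon-shrinkage `100 * (1 - SD(IWRES))`. Shrinkage is the
honest caveat of pooling patients with limited PK data: sparse designs pull
EBEs toward zero, and EBE-based diagnostics lose meaning as shrinkage
grows. A worth-knowing subtlety the tests encode: a "sparse" design with as
many informative observations as random effects does not shrink — it
overfits, and the EBE dispersion can exceed omega (negative shrinkage);
genuine shrinkage comes from designs like trough-only sampling that inform
fewer directions than there are effects.

Standard errors (finite-difference Hessian of the OFV, delta method to the
natural scale) are available with `control = list(se = TRUE)` and off by
default because they dominate runtime. Below-quantification-limit handling
is not implemented; observations flagged `MDV = 1` are simply excluded from
the likelihood.

### Diagnostics

`gof_residuals()` produces PRED/IPRED/IWRES/CWRES per observation, CWRES
from the first-order-conditional linearization about the EBE. On data
simulated from the same model, CWRES are calibrated (mean within ±0.1, SD
within [0.85, 1.15] — asserted in the tests).

`run_pcvpc()` implements the prediction-corrected visual predictive check:
observations and simulated replicates are normalized by
`pred_bin_ref / pred_ij` (proportional correction on the natural scale,
appropriate for a model without a lower bound), binned into quantile-based
time bins (default target 8, minimum 10 observations per bin, merged when
short, or explicit edges), and summarized as 5th/50th/95th percentiles with
90% inter-simulation bands. One quantile definition (type 7, linear
interpolation) is used on both the observed and simulated sides by sharing
the same code path. Results are data tables (CSV/JSON), not images: the
acceptance surface of a VPC is numeric.

## The synthetic trial program

`default_program()` reconstructs a pooled clinical program: five Phase 1
studies in healthy volunteers (three IV — single dose at two dose levels
and a 7-day q24h multiple-dose study — and two PO — a fed/fasted single-dose
crossover and a 14-day q24h fed multiple-dose study) with rich sampling,
and two Phase 2 studies in MAC patients (IV q24h, 500 mg) with 3-4 samples
each. The roster pools to exactly 138 subjects contributing 2637
concentration records. The per-study enrollments and schedules are explicit
synthetic choices — the public record gives only the pooled totals and the
qualitative design (study counts and routes, rich volunteer vs sparse
patient sampling) — and are constrained to reproduce those facts. Body
weights are log-normal with median 75 kg (healthy) and 55 kg (patients),
both 15% CV: magnitudes chosen once to express the documented lower weight
of MAC patients; they are not published values.

Generation is deterministic given a seed, with an independent random
substream per subject (hashed from the seed, study id and subject index) so
that editing one study of a roster does not change the subjects simulated
for another. What the generator does *not* emulate: dropout, BQL censoring,
dose adjustments, covariates beyond weight and food, between-occasion
variability, and model misspecification (the truth model is the fitted
family). Passing recovery tests on these data therefore demonstrates
estimator correctness under the stated design, not robustness to real-data
pathologies.

The truth model shipped as `default_truth_model()` uses synthetic,
pharmacologically plausible typical values (CL 15 L/h, V1 40 L, Q2 8 L/h,
V2 60 L, Q3 2.5 L/h, V3 220 L, ka_fed 0.7/h, ka_fasted 1.5/h, ktr 2/h,
F 0.8) — placeholders, because the published estimates exist only as an
image-format table — while its IIV magnitudes are set to the reported
CV values of 7.9% (CL) and 32.7% (F).

## Calibration experiments and problem sizes

`iiv_recovery_experiment()` is the package's main calibration: simulate
100 rich-sampled subjects (50 IV; 25 fed + 25 fasted PO; 12 samples each)
from the truth model, refit with displaced initial estimates — freeing
`CL`, `V1`, `F`, both omega variances and the proportional error SD, and
holding the peripheral/absorption constants at their known design values —
and report the recovered CV% of the CL and F IIV as the median over five
seeds. Medians over seeds separate estimator behaviour from
single-replicate noise; the experiment sizes (100 subjects, 12 samples,
5 seeds) were chosen as the smallest design in which the reported CL
variability is recoverable to within a few CV points. The same experiment
backs `scripts/acceptance.R`.

The pcVPC calibration check uses 100 PO subjects with 20 sampling times and
200 simulation replicates; a model with clearance misspecified two-fold
must push the observed medians outside the bands in most post-absorption
bins, while the correctly specified model keeps at least 80% of bins
covered.

Numerical choices collected in one place: inner Newton gradient tolerance
1e-8 (maximum 40 iterations, step halving up to 12 times); inner
finite-difference step 1e-6 on eta; outer relative OFV tolerance 1e-8 with
at most 150 iterations; residual variance floored at 1e-20; incomplete
gamma series switched to the complementary finite sum at |x| > 10;
confluence guard at a relative rate gap of 1e-8; steady-state metrics by
explicit superposition of up to 2000 doses (45 / (slowest rate × interval),
2001-point grid). Non-finite predictions during estimation return a large
penalty with a diagnostic flag instead of crashing the optimizer.

## Known limitations

* Laplace/FOCE-I is an approximation; at very sparse designs or extreme
  variances its omega estimates can be biased relative to adaptive
  quadrature. The test suite pins the objective against an exact
  linearized-model likelihood and against 1-D quadrature at a realistic
  variance.
* Only diagonal omega, effects on CL and F by default (others can be
  configured), one residual-error model for all routes and studies.
* No covariates other than body weight and food status; no
  between-occasion variability; no BQL handling.
* The estimated-allometric-exponent variant is a documented extension, not
  implemented: exponents are fixed settings.
* Typical values of the shipped truth model are synthetic placeholders; the
  package's claims are about recovering *known* simulation truths, not
  about reproducing confidential study estimates.
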