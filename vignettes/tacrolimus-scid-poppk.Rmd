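---
title: "Methods: population PK of tacrolimus in pediatric SCID-HSCT and initial-dose optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of tacrolimus in pediatric SCID-HSCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacropk)
```

## The problem

Tacrolimus prevents graft rejection after hematopoietic stem cell
transplantation (HSCT), but its pharmacokinetics in small children are highly
variable and the drug has a narrow therapeutic window (whole-blood troughs of
5–20 ng/ml). Therapeutic drug monitoring (TDM) adjusts later doses from
measured troughs, yet the *first* dose must be chosen before any
concentration exists. `tacropk` implements the complete model-based answer
for children with severe combined immunodeficiency (SCID) undergoing HSCT:
estimate a population PK model from sparse trough data, validate it, and use
Monte Carlo simulation to pick the initial weight-based dose that maximizes
the probability of landing in the target window.

## Structural and stochastic model

Concentrations follow a one-compartment model with first-order absorption and
elimination — the minimal structure consistent with reporting only CL/F, V/F
and a single absorption constant. For doses $D_d$ given at times $t_d$,

$$C(t) = \sum_{d:\,t_d \le t} \frac{D_d\,k_a}{V/F\,(k_a - k_e)}
  \left(e^{-k_e (t - t_d)} - e^{-k_a (t - t_d)}\right),
  \qquad k_e = \frac{CL/F}{V/F}.$$

Internally amounts are mg, volumes L and times h, so $C$ is mg/L; it is
reported ×1000 as µg/L = ng/ml, the whole-blood unit used in tacrolimus TDM.
$k_a$ is fixed at 4.48 h⁻¹ (literature value; troughs carry no absorption
information). No lag time is modelled — the source for the fixed $k_a$ does
not state one, and trough data could not inform it. Bioavailability is not
separable from oral data, so all parameters are apparent (CL/F, V/F) and no
explicit F exists anywhere in the code.

Body weight enters through fixed allometry against the 70 kg reference,

$$CL/F = \theta_{CL}\,(WT/70)^{0.75}, \qquad V/F = \theta_V\,(WT/70)^{1},$$

which reproduces the published per-kg clearance trend: 0.36 L/h/kg at 5 kg
falling to 0.26 L/h/kg at 20 kg for $\theta_{CL} = 13.1$ L/h.

Between-subject variability is log-normal, $P_i = TV \cdot e^{\eta_i}$ with
$\eta \sim N(0, \omega^2)$ independently on CL/F and V/F ($\Omega$ diagonal:
no covariance term was reported). Residual error is combined
proportional-plus-additive, $y = f\,(1+\varepsilon_1) + \varepsilon_2$, so
the conditional variance is $f^2\sigma_1^2 + \sigma_2^2$. The published
variability values (0.451, 0.592, 0.257, 1.265) are interpreted as
**standard deviations**, the dominant reporting convention for estimates of
this magnitude; both the generator and the likelihood use them as SDs, and
they are ordinary constructor arguments if a user disagrees.

Defaults of `population_model()` are the published final estimates, so the
default object *is* the final model.

## Likelihood: Laplace approximation with interaction

`foce_objective()` returns the NONMEM-style objective function value (OFV):
−2 × the approximate log marginal likelihood, all 2π constants dropped. Per
subject the conditional mode $\hat\eta$ minimizes

$$h(\eta) = \sum_j \left[\frac{(y_j - f_j(\eta))^2}{g_j(\eta)} +
  \log g_j(\eta)\right] + \eta^\top \Omega^{-1} \eta,$$

with $g = f^2\sigma_1^2 + \sigma_2^2$ evaluated at the *individual*
prediction — the "interaction". The marginal integral is then approximated by
the Laplace method using the exact (finite-differenced) 2×2 Hessian of $h$ at
$\hat\eta$. We deliberately use the full-Hessian Laplace flavour rather than
the strict first-order (Gauss–Newton) linearization: on toy datasets with
paper-scale variability the linearized OFV deviates from a dense-grid
quadrature of the exact marginal by up to ~0.4 units per subject, while
Laplace-with-interaction stays within ~0.1. Correctness is asserted against
that quadrature oracle (grid ±6ω, 241 points per dimension) in the test
suite, never against any external estimation software. In the $\omega \to 0$
limit (dimensions with $\omega < 10^{-8}$ are deactivated) the objective
reduces exactly to the fixed-effects weighted least-squares deviance.

Numerical choices: the inner mode search is a damped Newton iteration
cold-started at $\eta = 0$ (gradient tolerance $10^{-8}$, finite-difference
step $10^{-4}$, steepest-descent rescue if a Newton step fails); a
Gauss–Newton Hessian substitutes in the rare case the mode Hessian is not
positive definite. The outer problem optimizes log-transformed positive
parameters (plus covariate effects on the natural scale) with BFGS,
finite-difference step $10^{-4}$, relative tolerance $10^{-12}$. Standard
errors come from the inverse Hessian of the OFV at the optimum
(Var = 2 H⁻¹); that Hessian uses a *larger* step (0.01 on the log scale)
because the nested mode search leaves a ~$10^{-7}$ noise floor on the
objective that a small-step second difference would amplify
catastrophically. SE% of a log-parameter is 100 × its log-scale SE (delta
method).

**Known limitation — multimodality.** With trough-only sampling and a
terminal half-life around two weeks at these parameter values, short
sampling horizons (≲10 days) leave CL/F weakly identified; the likelihood
can then carry a second, degenerate mode (small CL/F, inflated ω). The fit
is deterministic from its starting values and the test suite asserts
multi-start consistency on the identifiable 15-day default design; for
weaker designs users should compare fits from perturbed starts.

## Covariate selection

Stepwise covariate modelling on OFV thresholds: forward inclusion requires an
OFV drop > 3.84 (χ², p < 0.05, 1 df), backward elimination removes any
included term whose deletion raises the OFV by ≤ 6.63 (p < 0.01). Continuous
covariates use the power form centred on the dataset median (computed per
fit); categorical covariates use the linear-shift form. Body weight enters
every model through the fixed allometric exponents and is never a candidate.
Candidates whose refit fails are skipped and recorded in the decision trace.
Under the null (no covariate effect in the generative model) the forward
step's false-inclusion rate is verified to stay within its nominal bound in
the acceptance suite.

## Synthetic cohort: the stated world

No patient-level data are distributable, so `simulate_cohort()` generates
cohorts with the published demographic and sampling structure, and all
estimation-side claims are tested as *parameter recovery* against this
generator:

* 18 subjects; body weight log-normal with median 7.50 kg (CV = 1.62/7.28),
  truncated by rejection to the observed 4.20–12.60 kg range.
* Fourteen continuous covariates (age, albumin, transaminases, bilirubins,
  hematology, ...) drawn as truncated normals from the published mean/SD and
  range; eight comedication flags Bernoulli with probability = published
  count/18. Covariates are sampled independently: only weight enters the
  final model, so their joint structure is immaterial downstream.
* Twice-daily oral dosing at 0.3 mg/kg/day (the pre-titration dose is never
  printed; this default is an assumption and a plain argument).
* Trough-only sampling on days 2, 4, 6, 8, 10, 13, 15 — the real TDM times
  are unknown; seven fixed days approximate the published mean of 7.2
  concentrations per subject, and the generator tops up
  `round(18 × 7.2) − 126 = 4` subjects with one extra day (continuing the
  grid in 2-day steps) so the default cohort has exactly 130 observations
  and a printed mean of 7.2.
* Observations are perturbed by the full residual model; negative draws are
  clamped to zero *at generation only* (never inside the likelihood), and
  values below the 2.0 ng/ml assay limit are flagged (`BLQ`) but kept — the
  source analysis does not describe BLQ handling, so the default fit uses
  all values.
* DVs are rounded to 0.001 ng/ml (far below assay precision) so that CSV
  round-trips are byte-identical.
* True per-subject random effects ride along as an attribute for recovery
  tests.

What a green test does **not** establish: the generator emulates the
published summary table, not the real joint distribution of covariates,
adherence, dose titration, or assay censoring. Recovery tests demonstrate
that the estimator finds the truth *of this stated world*; they cannot
validate the published estimates themselves, whose raw data are unavailable.

## Bootstrap and diagnostics

`bootstrap_model()` resamples subjects with replacement to the original
count, refits from the original estimates, and reports per-parameter median,
2.5th/97.5th percentile interval, and bias = (median − estimate)/estimate ×
100% (the published formula, reported to 3 decimals; all six published bias
cells reproduce exactly from the printed estimate/median pairs).
Non-converged replicates are dropped and counted — the dominant
pharmacometrics convention; >20% failures raises a warning flag.

`diagnostics()` emits the table behind the usual goodness-of-fit plots:
PRED (η = 0), IPRED (η at the conditional mode), iWRES = (DV −
IPRED)/√(IPRED²σ₁² + σ₂²), and CWRES from the first-order expansion at the
conditional mode (the conditional flavour, not the η = 0 one), decorrelated
by the Cholesky factor of V = diag(g) + GΩGᵀ. Plotting is left to the user;
headless test runs need no graphics device.

## Dose optimization and the evaluation-window decision

`pta_table()` simulates 1000 virtual subjects per weight-dose cell over the
published grid (5, 10, 15, 20 kg × 0.1–0.8 mg/kg/day, total daily dose split
q12h) and scores the probability that troughs fall inside 5–20 ng/ml.
Because the profile is linear in dose, the whole dose axis is evaluated by
rescaling one simulated cohort per weight (common random numbers); a
brute-force per-dose path exists and the suite asserts exact equality.
Residual (assay) noise is excluded by default — target attainment is about
true trough exposure — with a toggle for users who disagree.

**When to evaluate troughs is the decisive, under-determined choice.** At
the final parameters the terminal half-life is ≈ 350 h, so steady state is
never approached on clinical timescales and the PTA-optimal dose falls as
the evaluation window moves later. Deterministic integration over the
random-effect distribution gives, for pooled daily troughs:

| window (days) | PTA-optimal dose (mg/kg/day) |
|---|---|
| 1–4 | 0.7 |
| **1–5 (default)** | **0.6** |
| 1–7 | 0.4 |
| 1–15 | 0.2 |

The package default is days 1–5: the window an *initial* dose actually
owns, before the first TDM-guided adjustment takes over. Under it, 0.6
mg/kg/day maximizes mean PTA in every weight group, matching the published
recommendation — but the asymptotic margin over 0.5 mg/kg/day is only
≈ 0.007, so the acceptance check of the headline uses 20 000 virtual
subjects per cell (a Monte Carlo precision choice, not a model change), and
the recommendation must be read as configuration-dependent: any later or
longer evaluation window favours lower doses. `eval_times` is an ordinary
argument.

Ties in the recommendation break toward the lower dose (toxicity-averse
convention), and doses are rounded to 0.1 mg increments only in reports.

## Tunable parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `tv_cl`, `tv_v` | L/h, L at 70 kg | 13.1, 10900 | published final estimates |
| `ka` | 1/h | 4.48 (fixed) | literature value; not identifiable from troughs |
| `exp_cl`, `exp_v` | – | 0.75, 1 | fixed allometric theory values |
| `omega_cl`, `omega_v` | SD, log scale | 0.451, 0.592 | published IIV |
| `sigma_prop`, `sigma_add` | –, ng/ml | 0.257, 1.265 | published residual model |
| `dose_per_kg` (cohort) | mg/kg/day | 0.3 | assumed pre-titration dose (unreported) |
| `sampling_days` | day | 2,4,6,8,10,13,15 | ≈ 7.2 troughs/subject (real times unreported) |
| `eval_times` (PTA) | h | 24 × (1:5) | pre-TDM initial-dose window (see above) |
| `n_virtual` | – | 1000 | published simulation size per cell |
| include/exclude OFV bars | – | 3.84 / 6.63 | χ² 1-df thresholds, p = 0.05 / 0.01 |

## A worked example

```{r example, eval = FALSE}
model <- population_model()                      # published final model
cohort <- simulate_cohort(cohort_spec(), model, seed = 11)
summary(cohort)                                  # 18 subjects, 130 troughs, 7.2/subject
fit <- fit_popmodel(cohort, start = model)       # Laplace-with-interaction
boot <- bootstrap_model(cohort, fit, n = 200, seed = 3)
ptab <- pta_table(model, regimen_grid(), seed = 5)
recommend_dose(ptab)                             # 0.6 mg/kg/day overall
```

The same chain, with artifacts written to disk and one master seed, is
`run_pipeline(default_config(), out_dir)` or the `inst/cli/tacropk.R`
command-line surface.

## Design choices where the source was silent

* **Compartments:** one-compartment with first-order absorption — the
  minimal model consistent with the three reported parameters.
* **ω/σ as SDs**, not variances (see above); configurable.
* **ka ≈ ke degeneracy:** the closed form switches to the analytic limit
  $D k_a \tau / V\, e^{-k_a\tau}$ when $|k_a-k_e|\tau < 10^{-9}$; exact
  equality is rejected at construction (flip-flop).
* **Optimizer nesting:** inner Newton tolerance $10^{-8}$, outer BFGS; the
  conditional mode is cold-started at zero each outer evaluation, which
  affects step counts but not optima.
* **"1000 virtual patients"** is read as 1000 per weight × dose cell (the
  per-group simulation clouds imply per-group samples); configurable.
* **Provenance:** pipeline artifacts are deterministic given (config, seed);
  a `provenance.json` sidecar records the config hash, seed and package
  version rather than per-file headers, keeping every CSV plainly parseable.
* **Non-converged bootstrap replicates** are excluded and counted.

## Limitations

Beyond the synthetic-world caveats above: no inter-occasion variability, no
dose-titration feedback, no two-compartment or transit-absorption
alternatives, no CYP3A5 genotype effects (explicitly out of scope), and no
BLQ likelihood treatment. The bootstrap and recovery tolerances in the test
suite are calibrated to the scaled-down replicate counts they run at, not to
the reference analysis's full 1000 replicates.
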