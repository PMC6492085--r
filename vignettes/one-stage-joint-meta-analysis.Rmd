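---
title: "One-stage meta-analysis of joint longitudinal and time-to-event data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-stage meta-analysis of joint longitudinal and time-to-event data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In trials that record both a repeatedly measured biomarker (say, systolic
blood pressure) and a censored time-to-event outcome (death, myocardial
infarction), the two outcomes are rarely independent: subjects whose
trajectories run high may be at elevated risk, and subjects drop out of the
longitudinal schedule exactly when the event occurs.  Joint models handle
this by linking a linear mixed model for the biomarker with a proportional
hazards model for the event through shared random effects.  When individual
participant data (IPD) from several studies are pooled, the model must in
addition account for *between-study heterogeneity*: studies differ in their
baseline trajectories, in their treatment effects, and in their baseline
risk.

`metajoint` fits one-stage IPD meta-analytic joint models.  The data have
three nested levels — measurements within subjects within studies — and a
single hierarchical model is fitted to the pooled data.

# The model

For study $k = 1 \dots K$, subject $i = 1 \dots n_k$, measurement occasion
$j = 1 \dots m_{ki}$:

$$
\begin{aligned}
Y_{kij} &= X_1 \beta_1 + Z^{(2)}_{ki} b^{(2)}_{ki}
          + Z^{(3)}_{k} b^{(3)}_{k} + \varepsilon_{kij},\\
\lambda_{ki}(t) &= \lambda_0(t)\,
  \exp\!\bigl(X_2 \beta_2 + W_{2ki}(t)\bigr),\\
W_{2ki}(t) &= \alpha^{(2)}\bigl(b^{(2)}_{0ki} + b^{(2)}_{1ki} t\bigr)
            + \alpha^{(3)} Z^{(3)}_{ki} b^{(3)}_k,
\end{aligned}
$$

with $b^{(2)}_{ki} \sim N(0, D)$ (individual random intercept and slope),
$b^{(3)}_k \sim N(0, A)$ (study-level random effects),
$\varepsilon_{kij} \sim N(0, \sigma_e^2)$, all independent.  The association
parameters $\alpha^{(2)}$ (individual level) and $\alpha^{(3)}$ (study
level) carry the shared random effects into the hazard.  The baseline
hazard $\lambda_0(t)$ is left unspecified and estimated nonparametrically
(Breslow increments at the observed event times).  The time index of the
association is the hazard's risk time: in risk-set sums the individual
deviation is evaluated at the current event time, and in a subject's own
event-density contribution at their survival time $T_{S}$.

Six **model groups** encode the main strategies for between-study
heterogeneity (see `?mjm_spec`): none (group 0, naive pooling), fixed study
effects with or without treatment interactions (groups 1, 2), study-level
random effects shared between the sub-models (groups 2, 3, 5), and a
baseline hazard stratified by study (groups 4, 5).  Only time, a binary
treatment arm and study membership enter as covariates; an optional extra
basis in time (e.g. $\exp(-3t)$ for an early changepoint) can be added to
the longitudinal sub-model via `extra_basis`.

# Fitting: EM with pseudo-adaptive quadrature

`mjm()` maximizes the joint likelihood by EM, treating the random effects
as missing data.

**Starting values and comparators.**  Separate models of the same
specification — the linear mixed sub-model fitted by maximum likelihood
(`lme4`, ML not REML, because the estimates seed an ML algorithm) and the
Cox sub-model (`survival`, Breslow ties) — supply starting values.
`mjm_separate()` exposes these fits directly; they are the "separate
analysis" comparators, and their failure (singular random-effect
covariance, inestimable coefficients, no events) makes the joint fit a
counted failure rather than an error, so simulation grids can tally
success rates.

**E-step.**  Posterior expectations of functions of the random effects are
computed by pseudo-adaptive Gauss–Hermite quadrature: abscissae are centered
at the conditional modes of the random effects from the initial mixed-model
fit and scaled by the Cholesky factor of their conditional covariances, then
held fixed for the whole run.  Because the longitudinal data determine the
random effects sharply here (small $\sigma_e^2$, several measurements per
subject), few nodes per dimension suffice; the default is 5 per dimension
(`n_quad`, `n_quad_study`).  The study-level effects couple all subjects of
a study, so the study posterior is integrated on an outer grid with the
individual effects integrated conditionally within — the only arrangement
consistent with per-level centering.

**M-step.**  Given the posterior moments: $\beta_1$ by generalized least
squares; $\sigma_e^2$, $D$, $A$ from expected residual sums of squares and
second moments (positive semidefinite by construction); the baseline hazard
by the Breslow formula with expected risk scores; and $(\beta_2, \alpha)$
by damped Newton–Raphson on the expected survival log-likelihood with
$\lambda_0$ profiled out (a weighted Cox-type profile, concave, solved with
step-halving).  Association parameters start at 0.  One E-step plus these
conditional maximizations never decrease the observed log-likelihood; the
trace is stored (`loglik_trace`) and checked in the tests.

**Convergence.**  The fit stops when the mixed absolute–relative parameter
change $\max_j |\Delta\theta_j| / (|\theta_j| + 0.1)$ drops below
`tol_param` ($10^{-4}$) *and* the log-likelihood change is below
`tol_loglik` relative to $1 + |\ell|$; a purely relative criterion was
rejected because it stalls on fixed study effects that are genuinely near
zero.  `max_iter` defaults to 500: groups with a stratified hazard have a
slow EM tail (typically ~300 iterations) caused by the weakly identified
trade-off between study-specific baseline levels and the longitudinal study
effects; the other groups typically converge in well under 50 iterations.
Non-convergence, a singular covariance update or numerical overflow flag
the fit as failed — they do not throw.

**Standard errors.**  The reported model-based SEs are approximations: the
survival and association SEs invert the curvature of the profiled EM
objective, and the longitudinal SEs are taken from the initial mixed model
(the longitudinal point estimates of the separate and joint fits coincide
almost exactly in all scenarios examined).  With a nonparametric baseline
hazard such SEs understate sampling variability, so `mjm_boot()` implements
the recommended bootstrap: subjects are resampled with replacement *within*
each study, preserving the study structure, because inference is conditional
on the realized set of studies (resampling whole studies is available as a
sensitivity option).  Failed resamples are counted, never imputed.

**Pooling study-specific coefficients.**  Model groups with fixed
treatment-by-study interactions yield study-specific effects
($\beta_{12} + \beta_{14k}$ longitudinal, $\beta_{21} + \beta_{23k}$
survival).  `pool_study_effects()` combines them by DerSimonian–Laird
random-effects meta-analysis (moment estimator of $\tau^2$ truncated at
zero, inverse-variance weights); DL was chosen as the standard default
among the random-effects estimators.

# The simulator

`sim_scenario()` / `sim_joint_data()` generate multi-study joint data under
the group-3 structure (study-level random intercept and treatment effect):

* longitudinal outcome on the grid $0, 0.25, 0.5, 1, \dots, 4$ with
  $\beta_{10} = 1$, $\beta_{11} = 3$, $\beta_{12} = 2$,
  $D = \begin{pmatrix}1 & 0.5\\ 0.5 & 1.5\end{pmatrix}$,
  $A = \begin{pmatrix}1 & 0.5\\ 0.5 & 1.5\end{pmatrix}$,
  $\sigma_e^2 = 0.01$, and measurements kept only up to the survival time
  (informative truncation of the schedule);
* event times from a Gompertz baseline so that the time-varying
  random-slope term integrates in closed form:
  $T_E = \frac{1}{\alpha^{(2)} b_1 + \theta_1}\log\!\Bigl(1 +
  \frac{(\alpha^{(2)} b_1 + \theta_1)(-\log U)}{\exp(\theta_0 +
  \beta_{21}\,\text{treat} + \alpha^{(2)} b_0 + \alpha^{(3)} Z^{(3)}
  b^{(3)})}\Bigr)$, with shape $\theta_1 = \pi/(\sigma_0\sqrt 6) \approx
  2.5651$ and log-scale $\theta_0 = \log\theta_1 - \gamma - \mu_0\theta_1
  \approx -7.330517$ calibrated to event-time mean $\mu_0 = 3$ and SD
  $\sigma_0 = 0.5$;
* a *cure* check first: when the effective shape
  $\theta_1 + \alpha^{(2)} b_1$ is negative the cumulative hazard is
  bounded and a subject with $U$ below $\exp\!\bigl(e^{\eta}/(\theta_1 +
  \alpha^{(2)} b_1)\bigr)$ never experiences the event; the latent time is
  then `Inf` (represented explicitly, never a sentinel) and always resolves
  to censoring.  The default evaluates the cure probability with the full
  time-constant linear predictor $\eta$ — the form consistent with the
  inversion formula; a reduced form using only $\theta_0 + \alpha^{(2)}
  b_0$ is kept as `cure_condition = "reduced"` for comparison;
* independent exponential censoring with rate $\exp(-0.426)$, and
  $T_S = \min(T_E, T_C)$.  The event-time and censoring uniforms are
  independent draws (reusing one uniform for both is the only alternative
  reading and makes the outcomes artificially dependent);
* treatment allocated exactly 1:1 within each study of 500 subjects
  (5 studies by default; presets for 9 association scenarios, 5/10/15
  studies, and three heterogeneity levels ship as YAML files under
  `inst/extdata/scenarios/`).

Under these defaults the marginal event rate is just below 25% (about
23.5–25% across the association grid; the acceptance script reports the
realized value).  What the generator does *not* emulate about real
meta-analyses: unequal study sizes, study-specific measurement schedules,
non-normal biomarkers, informative censoring, and covariates beyond the
treatment arm — so passing recovery tests demonstrate internal consistency
of estimator and generator, not robustness to those features.

# The simulation-study harness

`run_scenario()` repeats simulate → fit (separate and joint, any subset of
groups) and summarizes each parameter as *mean estimate (SD of estimates
across replicates) [coverage]*, the display produced by
`summarize_sim()`/`render_sim_cell()`.  Coverage counts Wald intervals
(estimate $\pm z_{1-\gamma/2}$ SE, $\gamma = 0.05$) containing the
generating value, using the model-based SEs described above — bootstrap SEs
inside a full simulation grid are cluster-scale by nature, so coverage
here is indicative while *mean estimates* are the quantitative output.
Study-specific coefficients are pooled by DerSimonian–Laird before
summarizing.  Per-replicate seeds derive from one master seed, so grids are
exactly reproducible.

The package's own test suite runs the harness at reduced replication —
25 replicates of the base association scenario (groups 0, 1, 3) and 15 of
the no-heterogeneity scenario — sizes chosen so the whole suite runs on a
single desktop core in minutes while Monte-Carlo tolerances
($3\,\mathrm{SE}/\sqrt{R}$) remain meaningful.

# Numerical choices and edge cases

* Quadrature: product Gauss–Hermite rules (`pracma::gaussHermite`),
  log-sum-exp throughout; survival exponents above ~690 are treated as
  $-\infty$ likelihood contributions rather than overflowing.
* Ties in event times use the Breslow convention in both the separate Cox
  fit and the EM baseline update, so the two agree exactly when the
  association is zero.
* The reference study for fixed study effects defaults to the first label
  in sorted order and is overridable (`reference`); dummy coding with a
  documented column order keeps serialized results comparable.
* Degenerate inputs: subjects with no longitudinal records contribute only
  their survival factor; strata without events contribute no baseline
  increments (with a warning); an all-censored dataset is a flagged failed
  fit.
* `fix_alpha` pins association parameters (e.g. both to zero), which
  reduces the joint fit to the separate fits — asserted to $10^{-4}$ in the
  tests as a correctness property.

# Known limitations

Single continuous longitudinal outcome, binary time-fixed treatment, shared
zero-mean random-effects association only (no current-value or derivative
association), no competing risks, common association parameters across
studies.  Model-based SEs are known to be optimistic; use the bootstrap for
inference-grade intervals.  Fits that mix fixed study intercepts with a
study-level random intercept are intentionally outside the six shipped
groups.
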