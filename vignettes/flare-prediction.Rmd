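---
title: "Dynamic flare prediction during biologic tapering: model, assumptions, and design choices"
author: "flaretaper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic flare prediction during biologic tapering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flaretaper)
```

## The clinical problem

Rheumatoid arthritis patients in stable low disease activity on a biologic
DMARD are candidates for dose tapering: the drug is expensive and carries
adverse-event risk, and many patients keep low disease activity at a
reduced dose.  The established strategy — disease-activity-guided dose
optimisation (DGDO) — tapers stepwise until the disease flares, which makes
flares part of the protocol: the price of finding the lowest effective dose
by trial and error.  A *dynamic* flare prediction, recomputed at every
clinic visit from the information routine care already collects, lets the
decision "taper further or hold" be made per patient per visit, keeping
most of the dose reduction while avoiding a large share of the flares.

This package implements that pipeline end to end: DAS28 scoring and flare
detection from visit-level tables, a joint latent class mixed model of
disease-activity trajectories and flare hazard, landmark prediction of
3-month flare risk, validation metrics, a decision-rule simulator for
prediction-aided tapering, and synthetic cohort generators so that every
stage runs and is tested without access to clinical data.

## Clinical definitions

**DAS28.**  The 28-joint Disease Activity Score exists in four validated
variants (3- and 4-variable, with ESR or CRP as the inflammation marker).
Routine-care records rarely contain all components at every visit, so the
composite used throughout is the *mean of all variants computable from the
available components* (`das28()`), with components matched to a visit
within a ±4-week window (`match_components()`, nearest measurement, ties
toward the earlier one).  ESR values below 1 mm/h are floored at 1 before
the logarithm.

**Flare.**  A visit is a flare when DAS28 rose by more than 1.2 since the
previous visit, or by more than 0.6 to a value above 3.2; an increase in
the prescribed biologic dose also counts as a flare, so flares are captured
even when the DAS28 is incomputable at that visit.

**Course assembly.**  A biologic course enters the analysis at its
*baseline*: the first visit with DAS28 ≤ 3.2 reached after at least 24
weeks of treatment; the follow-up clock restarts there.  Eligible courses
have complete covariates and at least two DAS28 measurements per year.
Multiple courses per patient are treated as independent sampling units in
the likelihood; cross-validation folds are nevertheless split by patient to
prevent leakage.

## The joint latent class mixed model

Let $y_{ij}$ be the DAS28 of course $i$ at time $t_{ij}$ (years since
baseline) and $T_i$ the time to first flare (right-censored at the last
visit).  Each course belongs to an unobserved class $g \in \{1,\dots,G\}$
with prior probability $\pi_g$ (intercept-only multinomial; the published
model reports no membership covariates).

*Longitudinal submodel.*  Within class $g$,

$$y_{ij} = \beta_{g0} + \beta_{g1} t_{ij} + \dots + \beta_{gq} t_{ij}^q
  + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij},$$

with $(b_{0i}, b_{1i}) \sim N(0, B)$ (unstructured 2×2, shared across
classes) and $\varepsilon_{ij} \sim N(0, \sigma^2)$.  The random effects
are integrated analytically, giving a marginal multivariate normal per
course.

*Survival submodel.*  The class-$g$ flare hazard is

$$\lambda_g(t) = \kappa \rho^\kappa t^{\kappa - 1}
  \exp\!\big(\gamma_{1g} t + \gamma_{2g} t^2 + \beta_s^\top X_i
  + \delta\, 1[\text{dose}(t) \le 50\%]\big),$$

a Weibull baseline shared across classes with class-specific log-linear and
log-quadratic time effects — this matches a reported model whose
"trajectory class time coefficients" appear as hazard ratios, while a
shared parametric baseline keeps the mixture identifiable.  The fixed
covariates $X_i$ are time to reach low disease activity (weeks), baseline
DAS28, baseline dose fraction, swollen/tender-joint-count increase at
baseline, disease duration, seropositivity, and TNF-inhibitor class.  The
prescribed dose enters as a time-varying indicator dichotomised at 50% of
the full registered dose, because only one continuous time-dependent
variable (the trajectory) fits in this model family.  The cumulative hazard
is integrated by 15-node Gauss–Legendre quadrature within each
constant-dose segment; the segment touching $t=0$ is integrated under the
substitution $u = t^\kappa$, which removes the endpoint singularity of
$t^{\kappa-1}$ (and is exact when $\gamma_{1g}=\gamma_{2g}=0$).

*Joint likelihood and fitting.*  Conditional on class, the two submodels
are independent, so the observed-data log-likelihood is
$\sum_i \log \sum_g \pi_g \exp(\ell^{\text{long}}_{ig} +
\ell^{\text{surv}}_{ig})$, computed with log-sum-exp stabilisation.
`jlcm()` maximises it by BFGS on an unconstrained reparameterisation
(logits for $\pi$, Cholesky factor for $B$, logs for variances and Weibull
parameters) with an analytic gradient (the posterior-weighted score),
multiple starts (a data-driven initialisation from per-course OLS features
and k-means, then seeded random perturbations), relative tolerance
$10^{-8}$.  Class labels are made deterministic by ordering classes by
their trajectory value at the latest observed time, so "class 2" is always
the rising-activity class.  `jlcm_select()` fits a grid over $G \in 1{:}3$
and polynomial order $1{:}3$ and returns the lowest-BIC model, ties broken
toward the simpler one.

**Units.**  All public interfaces use weeks ("3 months" = 13 weeks, the
4-week component window = ±28 days); internally the model works in years
($t/52$) for numerical conditioning, so trajectory coefficients and hazard
time effects are per year and per year².  Hazard ratios around 4 per year²
are plausible; per week² they would not be.

## Landmark prediction

At a landmark $s$ where the course is in follow-up, the class posterior
combines prior, longitudinal history and event-free survival:

$$w_g(s) \propto \pi_g \, f\!\big(y_{i,\,t\le s} \mid g\big)\, S_g(s \mid X_i,
\text{dose history}),$$

and the predicted probability of a flare within the horizon $h$ (13 weeks)
is

$$\Pr(\text{flare in } (s, s+h]) = \sum_g w_g(s)\,
\frac{S_g(s) - S_g(s+h)}{S_g(s)} = \sum_g w_g(s)
\big(1 - e^{-(\Lambda_g(s+h) - \Lambda_g(s))}\big).$$

The future dose over $(s, s+h]$ defaults to the dose in force at $s$; the
simulator supplies the planned taper step explicitly.  With no DAS28
observations by $s$ the weights fall back to the prior tilted by survival.

Two choices deserve comment:

* **Post-flare predictions.**  The tapering simulator needs a risk at
  *every* 3-monthly visit, including after a flare, which the first-event
  survival model does not define.  We adopt a renewal reading: the at-risk
  clock restarts at the last flare (the survival factor in the weights
  spans only `[last flare, s]`), while the full DAS28 history stays in the
  longitudinal posterior.  Because the synthetic generator produces flares
  as an inhomogeneous Poisson process with the model's intensity, the
  conditional risk formula above is exact under this reading at any
  landmark.
* **Outcome labels.**  A prediction is labelled `flare` if the first flare
  falls inside $(s, s+h]$, `no-flare` if follow-up covers $s+h$ without a
  flare, and `indeterminate` if the course is censored inside the horizon;
  indeterminate rows are excluded from all metrics rather than counted as
  negatives, since their labels are unverifiable.  Development-style visits
  average ~22 weeks apart, so a no-flare label often relies on a later
  visit confirming event-free follow-up past $s+h$.

## Validation

`jlcm_cv()` partitions *patients* into five seeded folds, stratified by
whether any course of the patient flared (so no fold loses a label class),
fits on four folds and predicts the held-out visits; pooled out-of-fold
predictions feed `auc_roc()` (Mann–Whitney form, ties ½, pooled over all
landmarks — one row per prediction, with no per-patient reweighting),
`youden_cutoff()` (exhaustive scan over observed risks, rule
risk ≥ cutoff, ties toward the lower cutoff), `performance_at_cutoff()`
(2×2 metrics with patient-level percentile bootstrap, B = 1000 by default)
and `calibration()` (quartile groups of predicted risk against observed
flare frequency).

## The tapering decision simulator

`simulate_taper()` replays a protocolised tapering trial course under
prediction-aided decisions at a risk cutoff.  Conventions: visits sit on a
3-monthly grid over 18 months; the `dose_fraction` recorded at a visit is
the dose *prescribed there*, in force over the following interval; a flare
flag at a visit means the flare arose during the preceding interval (at the
dose prescribed at the previous visit).  The rules:

1. Flares observed before (or at) the first high-risk prediction are
   copied and the course follows the trial throughout — the prediction had
   no impact.
2. At the first high-risk prediction with no prior trial flare, the
   simulated dose freezes at the prescription current at that visit (at
   month 0, the pre-taper full dose) and later trial flares are
   suppressed…
3. …unless the trial course had already fully discontinued, in which case
   the simulated dose becomes and stays 50% of the full dose — the last
   tapering step.
4. A trial flare after the first high-risk prediction *is* copied when it
   arose at a trial dose at least the simulated dose (the simulated
   patient, on no more drug than the trial patient, would have flared
   too); from then on the simulated course follows the trial.

Under these conventions the invariants "simulated flares ⊆ observed
flares" and "simulated dose ≥ observed dose at every visit" hold by
construction for the four-level taper protocol: a freeze can only happen at
the full dose (month 0), the 50% step (month 3), or the 50% floor after
discontinuation, and any trial reinstatement that climbs back to the frozen
level produces a copied flare before it could exceed it.  Freezing instead
at the dose of the *preceding* interval would break the dose invariant in
rare double-flare sequences, which is why the prescription-at-visit reading
was adopted.

`taper_outcomes()` reports mean flares per course, the share of courses
with ≥1 flare, and the time-weighted mean dose (prescriptions persist over
their 3-month interval; the window is 18 months), with patient-level
bootstrap CIs.  `comparative_metrics()` forms the two trade-off ratios —
extra dose per flare prevented and extra flares per full dose saved —
which are invariant under swapping the arms; `cutoff_sweep()` tabulates
outcomes over a cutoff grid (15–45% by default).

## Synthetic cohorts: what they emulate, and what they do not

No development EHR or tapering-trial data are publicly available, so the
generators are first-class, tested code that define the study conditions.

**Development (EHR-style), `simulate_dev_cohort()`.**  Two latent classes
with shares 182/279 and 97/279; a stable trajectory (class 1) and a rising
one (class 2, reaching moderate disease activity within two years);
irregular visits with gamma-distributed intervals (mean 22.3, SD 12.3
weeks); log-normal follow-up (median 91 weeks, capped at 3 years);
covariate marginals matching the published cohort table (seropositivity
84.6%, disease duration log-normal with median 9 years, baseline DAS28
truncated-normal below 3.2, baseline dose Beta with mean ≈ 0.77, TNFi
share ≈ 0.80, tender/swollen-increase rates 17.6%/10.0%); survival
covariate effects set to the published hazard ratios (e.g. seropositivity
2.51, dose ≤ 50% 2.21, time-to-LDA 0.97 per week); 60% of courses taper
their dose in two multiplicative steps at random visits.  Flares arise as
an inhomogeneous Poisson (renewal) process with the class-specific
intensity, sampled by numerical inversion of the cumulative hazard, so the
first-event time has exactly the model's survival function.  The baseline
Weibull rate was calibrated once, by bisection with
`calibrate_flare_rate()`, so the visit-detected flare rate is ≈ 0.47 per
patient-year, and frozen as the default (ρ = 0.112/yr with κ = 1.1).

**Tapering trial, `simulate_trial_cohort()`.**  The tapering arm follows
the taper 100% → 67% → 50% → 0% prescribed at months 0/3/6 on a 3-monthly
grid over 18 months; on a flare the last effective dose is reinstated and
tapering stops; a persistent flare escalates to the full dose; the
routine-care arm keeps the full dose.  Covariates use trial-population
marginals (all TNFi at full baseline dose, baseline DAS28 2.15 ± 0.70,
joint-count-increase covariates set to "no" as in the external-validation
handling).  The baseline rate was likewise calibrated to ≈ 0.62 flares per
patient-year in the tapering arm (ρ = 0.171/yr).  DAS28 values at flare
visits are raised so the visit-to-visit flare criterion fires there as
well, keeping the two flare definitions consistent.

Deliberate idealisation, stated plainly: the generators hand the analysis
the *exact continuous first-flare time*, while real EHR data would only
interval-censor it between visits; trajectories and flares are exactly
conditionally independent given class; covariates are mutually independent
(only marginals are published); the routine-care arm never tapers (the
real-world comparator arm averaged 91% of full dose, not 100%); and
visit attendance is non-informative thinning.  Passing tests therefore
demonstrate the correctness of the machinery and the internal consistency
of the model — not that real tapering cohorts follow this model.

Class-2 time effects (γ = 1.10/yr, 0.30/yr²) were chosen so the rising
class separates early, as the published class-specific flare curves do;
with late-separating hazards nearly every high-risk prediction would
arrive after the course's first flare and a 35% decision cutoff would be
inert, which contradicts the reported behaviour of prediction-aided
tapering at that cutoff.

## Numerical choices and degenerate inputs

* Quadrature: 15-node Gauss–Legendre per constant-dose segment; the
  segment at $t=0$ uses the $u=t^\kappa$ substitution (above).  The same
  routine backs the likelihood, its gradient (which differentiates the
  quadrature formula itself, so likelihood and gradient agree to machine
  precision), prediction, and the generators' event sampling.
* Optimisation: 10 starts by default (2 suffice on well-separated
  synthetic data and are used in the test suite), BFGS, reltol $10^{-8}$,
  at most 500 iterations; non-finite or non-positive-definite proposals
  score $10^{10}$ and are stepped around.  Fits are bit-reproducible given
  the seed; the RNG state of the session is restored afterwards.
* Ties and boundaries: risk ≥ cutoff classifies as high (exact at the
  boundary); Youden ties break toward the lower cutoff within a $10^{-9}$
  float guard; component-window ties toward the earlier measurement;
  dose = 50% counts as low dose.
* Degenerate inputs: courses without a qualifying baseline are rejected
  (`"ineligible course"`); an all-missing dose path is taken as full dose;
  an all-identical risk vector yields a single flagged calibration group
  and Youden J = 0 at the common value; an empty predicted-positive set
  flags PPV as undefined; zero between-arm differences flag the
  comparative metrics as undefined rather than dividing by zero.

## Problem sizes in the shipped checks

The test suite and the acceptance script regenerate everything they
measure: cohorts of 150–500 courses for fitting checks (10 seeds for
recovery, a 3×3 BIC grid on 3 seeds), 1000 courses for the
cross-validation-versus-oracle comparison and the simulator invariant
sweep, 2000 for the calibration checks, and Monte-Carlo oracles with
$10^6$ draws for the longitudinal likelihood and $10^5$-step Riemann sums
for the cumulative hazard.  These sizes give stable verdicts for the
stochastic checks at fixed seeds while keeping a full run in the order of
a minute for the suite and under half a minute for the acceptance script.

## Known limitations

The Weibull-with-time-polynomials hazard is one defensible reading of the
published model (the original parameterisation is not fully specified);
absolute risk levels in the synthetic world are therefore calibrated, not
transcribed.  The landmark labels for sparsely visited courses depend on
later visits confirming event-free follow-up, which mildly under-uses
information compared to interval-censored likelihood approaches.  The
simulator inherits the published decision rules' strong assumptions —
frozen doses prevent all future flares except rule 4's copies — so its
outcome differences are best read as bounds on plausible impact, not
unbiased effect estimates.
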