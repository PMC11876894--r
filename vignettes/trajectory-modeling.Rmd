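---
title: "Modeling opioid dose trajectories and stimulant co-prescription from pharmacy claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling opioid dose trajectories and stimulant co-prescription from pharmacy claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Opioid prescribing in the United States co-occurs increasingly with central
nervous system stimulant prescribing — the so-called *twin epidemic*.  A
standard way to study long-term prescribing behaviour from insurance claims
is to (i) assemble a *new-user cohort* of opioid initiators, (ii) convert
every fill to a standardized dose (oral morphine milligram equivalents,
MME), (iii) summarize each patient's dosing as a monthly series, (iv) fit a
*group-based trajectory model* (GBTM) that partitions the cohort into a
small number of latent dose-trajectory groups, and (v) relate group
membership to patient characteristics — in particular stimulant exposure —
with rank tests and logistic regression.

`rxtraj` implements that entire pipeline, plus a synthetic-claims generator
with known latent-group structure so each stage can be validated exactly
without access to proprietary claims data.

## Cohort construction

The eligibility algorithm (`eligibility_rules()`, `build_cohort()`) encodes
the conventional new-user design:

* at least two oral opioid fills on distinct dates; the earliest defines
  the **index date** (non-oral opioid fills — patches, injections — are
  invisible to all counting rules);
* one continuous enrollment span covering the 365 days before the index
  date (the baseline window) and at least 60 days after it;
* age 18 or older at index;
* no cancer diagnosis at any time on or before the index date, and no
  buprenorphine fill strictly before it (buprenorphine marks treatment of
  opioid use disorder, not incident analgesic use);
* follow-up from the index date until the earlier of disenrollment and
  9 × 365 days.

Rules are evaluated in that fixed order, and `build_cohort()` reports the
count excluded at each rule (the attrition report partitions the input
population).  Two points were genuinely open and are configurable:

* *Cancer window.* "Ever diagnosed" has no natural window; the default
  excludes on any diagnosis on or before index.  A diagnosis dated exactly
  on the index date counts as post-index in the comorbidity *flags*
  (`comorbidity_flags()`), which describe rather than exclude; the
  exclusion rule is deliberately the more conservative on-or-before form.
* *Continuous enrollment.* Adjacent spans (gap ≤ `enrollment_grace_days`,
  default 0) are merged; overlapping spans are a data-quality error.

The follow-up cap is expressed in complete 30-day windows:
`floor(3285 × 12/365) = 108` windows.  Windows, not calendar years, drive
the model, and `n_windows ≤ 108` always holds.

## Dose series

Every opioid fill converts to a daily dose
`strength per unit × (quantity / days supplied) × MME conversion factor`
(`mme_daily_dose()`).  Conversion factors live in the drug catalog (a
configuration table), not in code, because published factor tables are
versioned externally.

Monthly dosing uses non-overlapping 30-day windows `[index + 30w,
index + 30(w+1))`.  Two windowing conventions are implemented
(`monthly_dose_series()`):

* **dispense_date** (default): window *w* receives the total MME dispensed
  on days inside it, divided by 30.  This is the natural reading of
  "all opioids dispensed in the period", and it conserves mass: the window
  totals sum to the total dispensed MME.
* **supply_spread** (sensitivity option): each fill contributes its daily
  dose on each covered day `[date, date + days_supply)`.

A partial terminal window (follow-up not divisible by 30) is dropped —
complete windows avoid denominator ambiguity.  Per-patient summaries
(`summarize_dosing()`) are the number of dispensing months (`prsc_no`), the
mean of positive-window doses (`avg_mme`), and the sum over all windows
(`total_mme`).

The time-varying stimulant covariate (`stimulant_covariates()`) at window
*w* is the cumulative count of stimulant fills from 365 days before index
through the end of window *w*; it is non-decreasing by construction.

## The trajectory model

Monthly mean daily MME is heavily right-skewed with many zero months, so
the outcome is modelled on the transformed scale `y* = log(1 + MME)` as a
**censored normal**: groups share a residual SD σ, and a zero-dose month
contributes the tail mass `Φ((0 − μ)/σ)` rather than a density value.  The
censored normal is the canonical GBTM family for semicontinuous dose
scales; the transform and the censor bound are configurable
(`model_spec()`), including `censor_lower = -Inf` for a plain normal model.

Group *j*'s mean at window *t* is

μ_jt = β_j0 + β_j1 s_t + β_j2 s_t² + α_j c_t,

with scaled time `s_t = t/107` (the 108-window horizon mapped onto [0, 1]
for conditioning), and `c_t` the cumulative stimulant covariate when the
opioid–stimulant model is requested.  The covariate coefficient α_j is
group-specific by default — the scientific question is precisely whether
stimulant exposure acts differently in different dose groups — with a
shared-σ, same-order-per-group parameterisation for parsimony.

Estimation (`fit_gbtm()`) is EM:

* **E-step**: posterior membership from the censored-normal patient
  likelihoods and mixture weights π;
* **M-step** (ECM): per-group Newton updates of (β_j, α_j) with
  step-halving on the weighted censored-normal objective, a safeguarded
  Newton step on the shared log σ, and closed-form π.  Every conditional
  step can only increase the expected complete-data objective, so the
  observed log-likelihood is non-decreasing across iterations (this is
  asserted, at tolerance 1e-8, throughout the test suite).

Numerical choices: the inverse Mills ratio is computed on the log scale
(`exp(log φ − log Φ)`) so deeply censored observations do not underflow;
Newton systems carry a 1e-10 ridge; EM stops when the relative
log-likelihood gain falls below `tol` (default 1e-6, threshold
`tol × (1 + |logLik|)`), or at `max_iter`.  Initialisation is k-means++ on
per-patient (mean, slope) summaries of the transformed series, with
`n_starts` (default 5) independent seedings; the best restart by
log-likelihood is kept, and a restart whose mixture weight falls below 1/N
is discarded as collapsed.  Fits are deterministic given the control seed.
Groups are reported in canonical order of ascending mean fitted dose, which
makes group indices comparable across restarts and models.

Model selection (`select_model()`) fits a grid over the number of groups
(and optionally polynomial order) and picks the converged candidate with
minimal BIC, using the convention `BIC = −2 logL + k log N` with **N = the
number of patients** (conventions differ; this one is fixed and documented
so results are reproducible).  Patients contribute only their observed
windows — series of different lengths mix freely, with no imputation.

Posterior assignment (`posterior_assign()`) is Bayes' rule with ties
broken toward the lower group index.  Predicted group curves
(`predicted_trajectory()`) back-transform μ_jt and, for a nonzero
confidence level, carry a delta-method band from the observed information
(`gbtm_vcov()`, a central-difference Jacobian of the analytic
Fisher-identity score).

## Association analyses

`membership_regression()` fits a binary logistic regression (IRLS via
`stats::glm.fit`) restricted to two trajectory groups, reporting odds
ratios with Wald confidence intervals.  Wald (not profile) intervals match
the symmetric-in-log intervals conventional in this literature.  The
time-varying stimulant covariate cannot enter a static regression as a
vector, so it is summarized as the cumulative count at end of follow-up
plus its binary form; the pre-index count is a separate predictor.  Age
enters linearly per year.  Separation and collinearity are detected and
reported as errors naming the offending predictors.  `subgroup_compare()`
uses Mann–Whitney U for two groups and Kruskal–Wallis otherwise, two-sided
with midranks, at the 0.05 level with **no multiplicity adjustment** — a
deliberate mirror of common practice in this literature, and a caveat for
interpretation.  `descriptive_table()` produces the usual n (%),
mean (SD), median (IQR) blocks by stratum.

## The synthetic-claims generator

`generate_population()` draws, per patient, a latent trajectory group and
emits claims whose monthly dispensed totals follow the group's trajectory:
the target mean daily MME in window *w* is the inverse transform of
(group polynomial in *w* + α_g × cumulative stimulant count + Gaussian
noise), floored at zero, and one opioid fill per active window (dated at
the window start) is emitted with the catalog quantity that best matches
the target total.  Zero-dose months arise when the target rounds below one
catalog unit.  Stimulant fills are Poisson per 30-day window — including
the 12 pre-index baseline windows — at a group-dependent rate, which is
what makes stimulant exposure informative about group membership
downstream.

Default conditions (chosen once, as the study conditions the package
emulates): five groups with proportions 77.5 / 10.2 / 8.5 / 2.4 / 1.4 %
(very low; low decreasing; low increasing; moderate increasing; high
sustained), `log(1+MME)`-scale trajectories starting at roughly 6, 14, 11,
34, 108 mg/day, residual SD 0.5, follow-up uniform on 6–84 months (mean
≈ 1350 days), age ≈ N(43.9, 13²) truncated to 18–85, 57 % female, regional
shares 12.8 / 20.2 / 49.7 / 16.2 %, and pre-/post-index comorbidity
prevalences typical of commercially insured opioid initiators.  The two
low groups' default polynomials decline through the zero-censor bound
within a few months: that is how discontinuation — and hence the sparse
dispensing typical of opioid initiators, whose median number of dispensing
months is low single digits — arises in this model family.  The
increasing and high-dose groups dispense continuously by construction; the
censored-normal trajectory family has no separate mechanism for
intermittent refills.  Stimulant rates (0.002 per window in the low
groups, 0.004 in the increasing/high groups, applied to pre-index windows
too) preserve the qualitative exposure pattern — roughly twice the
prevalence in increasing/high groups and a positive pre-index association
with escalation — although a single Poisson-per-window rate cannot
simultaneously match a realistic exposure prevalence and the heavy
per-user fill counts of chronic stimulant users.  The generator's
zero-month prevalence is not fixed a priori; it follows from the group
polynomials, σ, and the catalog quantization, all of which are parameters.

Two deliberate artifacts keep the generator aligned with the cohort rules:
every non-injected patient receives at least a minimum-quantity fill in
windows 0 and 1, so that the ≥ 2-distinct-dates rule is met by
construction and injected exclusion counts are exact; and each patient's
records are drawn from an RNG stream keyed by (seed, patient index), so a
patient's data do not change when more patients are generated.

Exclusion-triggering patients (minors, pre-index cancer, prior
buprenorphine, short pre- or post-index enrollment, single fill) are
injected independently at configurable fractions with all other features
intact, and the injected reasons are recorded in the dataset so attrition
can be checked exactly even when injections overlap.

What the generator does **not** emulate: real NDC semantics, claim
adjudication fields, inpatient records, dose titration within a month,
pharmacy shopping, or informative censoring — loss to follow-up is
independent of the dose path.  Passing tests therefore demonstrate that
the pipeline recovers the structure it is pointed at, not that real claims
satisfy the model's assumptions.

## Validation scale

The test suite exercises the pipeline at desk scale: dose-window
accounting against a day-level brute-force oracle; exact attrition on
1,000 patients with injected exclusions; parameter recovery from a
three-group truth (2,000 patients × 24 windows, intercepts ≥ 3σ apart);
BIC selection consistency over 20 replicates of 1,000 patients against a
1–5 group grid; single-group equivalence with pooled least squares and
with `survival::survreg`'s left-censored Gaussian; covariate-effect
recovery (α = 0.5 in the increasing group) with its membership odds
ratio; Type-I error and Wald-coverage calibration; and bit-identical
reruns of the full pipeline.  These sizes are the package's validation
conditions; larger populations simply scale linearly in patients.  The
reproduction script shipped with the repository runs the analysis itself
at 3,000 patients with a selection grid over 4–6 groups and 5 EM restarts
per candidate — enough restarts that the heavily dominated default mixture
(77.5 % in one group) is seeded correctly, and a scale at which the two
smallest groups (2.4 % and 1.4 %, about 2σ apart) may legitimately merge
under BIC.

## Known limitations

* The censored-normal family with shared σ is an assumption, not a
  finding; per-group σ is available behind a flag
  (`fit_gbtm`'s spec can be extended), and zero-inflated count families
  are out of scope.
* BIC selection among K values is consistent but can be indecisive when
  groups are weakly separated; the selection table should be inspected,
  not just the argmin.
* Membership regression is associational.  Nothing in this package
  supports causal claims about stimulant prescribing; the design cannot
  distinguish confounding by indication from effect.
* Group labels ("increasing", "decreasing") come from fitted start/end
  doses (`classify_trajectories()`) and depend on the fitted horizon.
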