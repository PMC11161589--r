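---
title: "Multistate modelling of lifetime coronary artery disease risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate modelling of lifetime coronary artery disease risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifemsm)
```

## The model

`lifemsm` estimates the remaining lifetime risk of coronary artery disease
(CAD) from longitudinal health-record-style data with a discrete-time,
time-inhomogeneous multistate Markov model.  A person occupies one of ten
states each year: `Health`; the seven non-empty combinations of
hypertension (`Ht`), hyperlipidemia (`HyperLip`) and diabetes (`Dm`);
`CAD`; and `Death`.  Risk factors accumulate monotonically (no recovery):
a state with $m$ risk factors can move in one year only to a superset
state with $m+1$ risk factors, to CAD, to Death, or stay put; CAD's only
exit is death; death is terminal.

For each age $a$ and each allowed non-self transition $j \to k$, the
one-year transition probability $\pi_{jka}(x)$ for covariates $x$ (sex,
polygenic risk score in SD units, smoking, statin use, antihypertensive
use) is a logistic regression fitted independently on the persons at risk
in state $j$ at age $a$:

$$\operatorname{logit} \pi_{jka}(x) = \beta_{jka0} + \beta_{jka1} x_1 +
\dots + \beta_{jkap} x_p.$$

The self transition is never fitted; it is the complement
$\pi_{jja} = 1 - \sum_{k \ne j}\pi_{jka}$, which keeps each annual row
stochastic without the cost of a polytomous fit.  Because every age gets
its own coefficient vector, covariate effects vary freely with age —
no proportional-hazards or parametric age-interaction assumption.

## Coefficient smoothing

Raw per-age coefficients are noisy where cells are small, so each
(transition, term) series is smoothed across age by locally weighted
least squares.  The weight of the raw estimate at distance
$D = |a_{\text{target}} - a_i|$ is

$$w_i = \Bigl(1 - \bigl(D/w\bigr)^3\Bigr)\cdot\frac{1}{\sigma_i^2},
\qquad D \le w,$$

the product of a distance taper and the inverse sampling variance of the
raw estimate.  The taper is deliberately the simple cubic $1-(D/w)^3$,
*not* the classical tricube $(1-(D/w)^3)^3$, and
a `classical_tricube` switch in `smoother_config()` provides the
conventional version for comparison.  Cells that could not be fitted
(no events, no non-events, fewer rows than parameters, separation,
non-convergence) carry an infinite-variance sentinel and therefore weight
exactly zero: sparse ages borrow strength from neighbours without
perturbing well-estimated ones.

Numerical choices worth knowing:

* **Window and degree.** Defaults are `window_width = 10` years and
  `degree = 2`, both configurable — the method's own presentation leaves
  them free.  The local polynomial is evaluated on an *age-centred* basis,
  so the smoothed value at a target age is simply the intercept of the
  local fit; this is algebraically identical for exact-fit cases and
  numerically better conditioned than powers of absolute age.
* **Boundary extension.** Within 5 years of either end of the age grid the
  window is widened by 5 years to mitigate boundary bias.  The *extended*
  width is also used in the taper's denominator; the unextended width
  there would give negative weights for $D$ between $w$ and $w+5$, and
  weights must stay nonnegative with the taper reaching zero at the
  window edge.
* **Sparse series.** If a target age has no positive-weight neighbour at
  all (a transition fitted at only a handful of ages), the window doubles
  until one is found.  This keeps the smoothed table total — every
  (transition, age, term) populated — which the risk engine requires.
  A transition with no successful fit at *any* age is marked unavailable
  and contributes probability zero, with a warning.
* **Rank deficiency.** If all weight concentrates on too few distinct ages
  for the requested degree, the degree is reduced for that target age with
  a warning.

## Risk composition

Given the smoothed table, the risk of reaching state $k$ from state $j$
between ages $A_1$ and $A_2$ is composed two ways:

* **Fixed-path** (the headline lifetime quantity):
  $1 - \prod_{a=A_1}^{A_2-1} (1 - \pi_{jka}(x))$, with lifetime risk using
  $A_2 = L = 80$.  This conditions on remaining in $j$ until the target
  transition occurs.
* **Marginal** (any path): the $(j,k)$ entry of the ordered product of
  annual $10\times10$ transition matrices, restricted to absorbing-side
  targets (CAD, Death).  Absorbing rows are unit vectors.

The two modes answer different questions and neither is silently
substituted for the other.  Note that the often-quoted intuition
"marginal $\ge$ fixed-path because extra paths only add probability" is
true only when no probability leaks to a competing absorbing state; with
death in the topology the marginal CAD risk can fall *below* the
fixed-path value.  Our tests assert dominance only on death-free chains,
where it is an algebraic identity.

Treatment is a constant per-year relative risk reduction, default
$RR = 0.20$ (the trial-estimated statin effect used as a parameter, not
re-estimated): each annual target probability is multiplied by $1 - RR$
before composition, and treated queries are refused for profiles already
on statins, since the imputed benefit applies to statin-free individuals
only.  The covariate profile is frozen at query time — age enters the
projection only through the age-specific coefficients; future medication
or smoking changes are not simulated.

Uncertainty comes from a person-level bootstrap: persons (not
person-years) are resampled with replacement, and the full
fit → smooth → project pipeline is re-run per replicate under a fixed
seed.  Replicates in which a needed transition cannot be fitted at any
age are recorded as missing and the count of valid replicates is
reported.

## Timeline construction

Raw person records (one row per person: diagnosis ages, death age, censor
age, first-observation age, enrollment age, medication start ages,
covariates) expand into person-year rows over the modelling window
$[40, 80)$.  Conventions:

* Ages are discretized to integer years; a diagnosis at age 39.6 takes
  effect at the transition into age 40 (half-open year $[a, a+1)$).
* Medication covariates are re-evaluated each year
  (`start_age <= a`) and treated as persistent.
* Persons with CAD at the window start are excluded entirely; rows stop
  at death; a death year is included so the terminal transition is
  observed, while a plain-censoring partial year is dropped.
* A year containing two same-age diagnoses jumps more than one
  risk-factor level.  Such rows are kept for trajectory bookkeeping but
  flagged `skip` and excluded from fitting, which respects the one-step
  topology.
* Left-censoring at the enrollment age is applied only in *evaluation*
  (to exclude person-time protected from death), never in fitting:
  evaluation must exclude immortal person-time, while fitting can safely
  use every observed transition.

## The synthetic cohort

Real training data for this class of model are access-controlled, so the
package ships a generator whose defaults emulate the published cohort's
structure: entry age $18 + \text{Exp}(\log 2 / 6.3)$ (median first
observation 24.3 years), follow-up $\mathcal N(29.4, 8^2)$ years, male
fraction 0.458, smoker fraction 0.105, standard-normal PRS, annual
medication-initiation hazards of 0.8%/1.0% from age 40, and age-constant
transition intercepts chosen to give roughly 40% lifetime hypertension,
24% hyperlipidemia, 10% diabetes and 11% CAD.  Covariate effects (log-odds
on CAD and death destinations: sex 0.5/0.3, PRS 0.3, smoker 0.4/0.5,
statin −0.2) are modest and plausible rather than calibrated to any real
population.  These values were fixed once from the cohort description and
are not tuned to test outcomes.

Trajectories are simulated year by year from the exact ground-truth
transition rows, so `ground_truth_risk()` gives the *exact* fixed-path or
marginal risk implied by the generating parameters, and end-to-end
parameter recovery can be tested: at $n = 50{,}000$ the fitted, smoothed
and projected lifetime risk from Health at 40 lands well within one
percentage point of truth.

What a green test does **not** establish: the generator draws states from
the same model family the pipeline fits (no model misspecification), uses
time-invariant covariates except medications, has no measurement error or
phenotype heterogeneity, and no calendar-time effects.  Agreement with
ground truth demonstrates the estimator and its plumbing are correct, not
that real-world risks would be this accurate.  Small cohorts
($n \lesssim 5000$) leave late ages sparse, and polynomial extrapolation
beyond the last well-estimated age can then be badly biased — visible in
the package's own small-$n$ smoke runs and expected behaviour, not a
defect the tests hide.

## Evaluation battery

* **Stratified calibration RMSE**: persons are stratified by sex × PRS
  group (<20th percentile, 20–80th, >80th, with breaks computed on the
  training split); the RMSE of (empirical incidence − mean predicted) over
  strata is reported in percent.
* **Net reclassification**: implemented exactly as the printed set
  algebra, including its asymmetric 5% threshold in the event
  down-classification term (`symmetric = TRUE` restores the symmetric
  variant); components carry $\sqrt{\hat p(1-\hat p)/n}$ standard errors.
* **Threshold ages**: first age a score strictly exceeds a threshold,
  with an infinite never-sentinel.
* **Interval expansion**: each trajectory is cut at every threshold age
  and the event age into consecutive inclusive-bound intervals,
  left-censored at enrollment, the event interval running to the horizon
  (80).
* **Time-dependent concordance**: Harrell's C where, at each event age,
  the failing person's *current* score is compared with the current scores
  of everyone still at risk; ties count one half; person-level bootstrap
  CI and a two-sided Z test for comparing two scores.
* **Cumulative AUROC / precision-recall**: rank-based AUROC (ties 0.5) and
  average precision against cumulative case status.

Comparator scores (30-year Framingham variants, pooled cohort equations)
are consumed as externally supplied columns; their published equations are
out of scope by design, which keeps the assessment machinery
comparator-agnostic.

## Known limitations

* The per-age one-vs-rest binary fits approximate a polytomous model; the
  complement rule plus over-unity rescaling guarantees row-stochasticity
  but is an approximation when annual probabilities are large.
* The bootstrap refits the entire pipeline per replicate and is expensive
  at scale; use modest `n_boot` for exploration.
* Smoothed-coefficient standard errors treat the combined
  tricube × inverse-variance weights as exact inverse variances; they are
  approximate and used only for reporting, never for the risk point
  estimates.
* `L = 80` caps all lifetime quantities; risks beyond the data's age
  support are extrapolations of the local polynomial and should be read
  with the sparse-data caveat above.
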