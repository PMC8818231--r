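---
title: "Weighted composite endpoints with recurrent events: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted composite endpoints with recurrent events: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrecs)
```

## The problem

Cardiovascular and oncologic trials often compare an intervention (I)
against a control (C) on a composite time-to-event endpoint, e.g. "time
to myocardial infarction or death".  Conventionally only the first
event per patient is analyzed, discarding recurrences of the non-fatal
component.  Using all observed events increases the information per
patient, but raises two issues: the event types differ in clinical
relevance (a myocardial infarction is not a death), and the analysis
must accommodate a recurrent non-fatal process terminated by a fatal
event.  `wrecs` implements three relevance-weighted analysis
approaches for this setting, a parametric simulator for recurrent-event
trial data, and a scenario runner for Monte-Carlo power and estimator
studies.

Throughout, data are two-armed with 1:1 allocation, one recurrent
non-fatal event type M and one terminal fatal type D, and the test
problem is one-sided: the null states that the control is at least as
good as the intervention.  All three test statistics are asymptotically
standard normal under their null and reject when the statistic falls at
or below $-z_{1-\alpha}$.

## Data representation

Input data are long-format event histories (`event_histories()`): one
row per event plus a terminal row per subject, with status codes 0
(censored), 1 (non-fatal), 2 (fatal).  All stratified analyses run on
the counting-process table produced by `to_counting_process()`: stratum
$j$ collects every subject's $j$-th composite event, on the calendar
(total-time) scale, so the interval for the $j$-th event starts at the
time of the $(j-1)$-th.  A subject whose last observed event is
non-fatal immediately re-enters the risk set of the next stratum; a
death as the $j$-th event belongs to stratum $j$.  This is the
total-time variant of the Prentice–Williams–Peterson conditional
model.  The calendar scale (rather than gap time) is used because the
parametric hazards of the simulation scenarios are functions of study
time and because the recurrent intensity is assumed not to change after
an event.

## The three approaches

### Wei–Lachin: weights on log hazard ratios

Cause-specific stratified proportional-hazards models
$\lambda_{c,j}(t) = \lambda_{c,0j}(t)\,e^{\beta_c X}$, $c \in \{D, M\}$,
with the binary group indicator $X$, strata $=$ event number, and the
other cause censored within its stratum, give estimates
$\hat\beta_D, \hat\beta_M$ (`fit_stratified_cox()`).  With relative
weights $w_D + w_M = 1$, $w_c > 0$, the weighted hazard ratio is

$$\theta^L = \exp(w_D \beta_D + w_M \beta_M),$$

estimated by plugging in the Cox estimates, with the one-sided
statistic

$$T^L = \frac{w_D\hat\beta_D + w_M\hat\beta_M}
{\sqrt{w_D^2\hat\sigma_D^2 + 2 w_D w_M \hat\sigma_{DM} + w_M^2\hat\sigma_M^2}}$$

and the $(1-2\alpha)$ interval obtained by exponentiating the normal
interval on the log scale (`wl_test()`, `wl_estimate_ci()`).  The
cross-cause covariance $\hat\sigma_{DM}$ comes from stacking the two
models in working-independence fashion: subjects' score residuals are
aggregated across their rows per cause, and
$\hat\sigma_{DM} = I_D^{-1} (\sum_i U_{iD} U_{iM}) I_M^{-1}$ with the
observed informations $I_c$ (`wl_covariance()`), following the
multivariate marginal-model construction of Wei, Lin and Weissfeld and
of Lachin and Bebu.  For coherence with this sandwich cross term, the
cause-specific variances default to the robust (score-residual
sandwich) form; the model-based inverse information is available via
`variance = "model"`.  Because the weights act on the log hazard
ratios, a cause with few events still carries its full weight — its
larger variance enters through the denominator instead.

### Rauch: weights on cause-specific hazards

The weighted all-cause hazard ratio evaluated at time $t$ is

$$\theta^R(t) = \frac{w_D \lambda^I_D(t) + w_M \lambda^I_M(t)}
{w_D \lambda^C_D(t) + w_M \lambda^C_M(t)}, \qquad w_D, w_M \ge 0,$$

the natural extension of the all-cause hazard ratio (recovered at unit
weights).  Weights multiply the hazards — hence, in estimation, the
event counts — so a highly weighted but rare event type has limited
influence.  `rauch_true_theta()` evaluates the estimand from parametric
hazards; with no strata-specific effects the average over strata equals
the single-stratum value.  The package evaluates at the end of study
(the administrative horizon) by default.

The non-parametric estimator (`rauch_estimate()`) replaces the hazards
by Nelson–Aalen cumulative hazards.  Two aggregations are offered:

* `combine = "pooled"` (default): cause-specific Nelson–Aalen
  estimates on the pooled risk set — a subject is at risk while under
  observation, every recurrence contributes a jump $d/Y$.  Under the
  equal-baseline-hazards assumption this is the Nelson–Aalen analogue
  of the Breslow baseline estimator of the stratified model, and it
  uses all events with stable risk sets.
* `combine = "strata"`: the average over strata of per-stratum weighted
  Nelson–Aalen ratios, each stratum estimated on its own risk set.
  Strata enter the average only when both group totals are strictly
  positive, and the averaging constant is the number of included
  strata, which avoids 0/0 cells late in follow-up.

The pooled form is the default because per-stratum risk sets for
second, third, ... events are small early and late, which makes the
per-stratum ratio estimator heavy-tailed: in simulations its log-scale
spread is roughly twice that of the pooled form, and the arithmetic
average of noisy ratios acquires a marked upward bias.  The pooled form
behaves like the other estimators in the package and converges, for
time-dependent hazards, to the ratio of weighted cumulative hazards at
$t$ (which coincides with the hazard-based estimand when the
cause-specific effects are time-constant).

No closed-form variance is available for $\hat\theta^R$, so confidence
intervals are percentile bootstrap intervals from subject-level
resampling, stratified by treatment group to preserve the allocation
(`rauch_bootstrap_ci()`).

The companion test (`rauch_test()`) is a stratified weight-based
log-rank statistic in which the relevance weights act multiplicatively
on the event counts: within stratum $j$, at each distinct event time
with risk sets $Y^I, Y^C$ and cause-specific event counts $dN_c$,

$$T^R = \frac{\sum_{j,k} \left( wO^I_{jk} - \tfrac{Y^I_{jk}}{Y_{jk}}\, wO_{jk} \right)}
{\sqrt{\sum_{j,k} \tfrac{Y^I_{jk} Y^C_{jk}}{Y_{jk}^2}\,
  \tfrac{Y_{jk} - dN_{jk}}{Y_{jk} - 1} \sum_c w_c^2\, dN_{c,jk}}}, \qquad
wO = \sum_c w_c\, dN_c.$$

At unit weights this is exactly the classical stratified all-cause
log-rank statistic (verified against an independent implementation in
the test suite), and its null distribution is standard normal (verified
by simulation).  Simultaneous events at one time are handled jointly
with the hypergeometric-style correction above.  Like every log-rank
statistic of this form it treats event contributions as conditionally
independent; a robust (within-subject) variance cannot currently be
incorporated, a known limitation of log-rank-type statistics for
recurrent events, so published power figures obtained with other
implementations of weight-based log-rank statistics in this setting may
exceed what a correctly calibrated statistic can achieve.

### Bakal: weights on individual scores

The Bakal approach defines no estimand and hence no effect estimator;
it provides weighted survival curves and a modified log-rank test.
Each subject starts with score $s_i = 1$ and, at each of its own events
at pooled event time $t_k$, loses the fraction given by the event-type
weight $w^B \in [0,1]$:

$$s_i(t_k) = s_i(t_{k-1}) - s_i(t_{k-1})\, w_i^B(t_k), \qquad s_i(t_0) = 1,$$

so a non-fatal event is a partial event and a fatal event (weight 1)
removes the subject.  Weighted event totals $e^B_k$ and risk masses
$n^B_k$ are sums of score drops and scores; the weighted product-limit
curve is $KM^B(t_k) = KM^B(t_{k-1})(1 - e^B_k / n^B_k)$ and the
modified log-rank statistic applies the usual
observed-minus-expected/hypergeometric form to these weighted totals
(`bakal_scores()`, `bakal_weighted_km()`, `bakal_test()`).

Conventions the original description leaves implicit, fixed here as
design choices: a subject with no own event at $t_k$ has weight 0 there
(its score is unchanged); the event-time grid is pooled across strata
and groups; simultaneous updates at one time are applied before
recomputing sums; a censored subject's remaining score leaves the risk
sums strictly after its censoring time while its earlier partial events
stay counted; grid times with pooled risk mass $n^B_k \le 1$ are
skipped in the test (they carry no variance).  At unit weights the
curves and test reduce exactly to the classical Kaplan–Meier estimate
and log-rank test on time-to-first-event data, which the test suite
checks against `survival`.

## Weight conventions

`weight_scheme()` validates the method-specific constraints: Wei–Lachin
weights are strictly positive and sum to 1; Rauch weights are
non-negative (scale-free, since they appear in numerator and
denominator — `rauch_estimate()` is invariant under joint rescaling)
with the convention that the most relevant event gets weight 1; Bakal
weights lie in $[0,1]$ with 1 for the fatal event.
`schemes_from_weights(w_fatal, w_nonfatal)` builds all three schemes
from one pair on the Rauch/Bakal convention, rescaling to sum to 1 for
Wei–Lachin so that the fatal/non-fatal weight ratio agrees across
methods.

## The simulation engine

`simulate_dataset()` generates one trial under a `scenario_spec()`:
per subject, the fatal time is drawn by inverting the cumulative hazard
at an Exp(1) deviate (the inversion method of Bender et al.), and
non-fatal events are drawn sequentially on the calendar scale by
conditional inversion, $\Lambda_M(t_{next}) = \Lambda_M(s) + \mathrm{Exp}(1)$
(as in Jahn-Eimermacher et al.), independent of the fatal process given
the group.  Death terminates observation; everyone else is
administratively censored at the horizon.  Three hazard shapes cover
the exponential and Weibull families used in the scenario catalog:
constant $a$, linear $a t$, and power $a t^b$, with closed-form
cumulative hazards and inverses (no root finding; the inverse is exact
to floating-point precision).

The built-in catalog (`scenario_catalog()`) holds 11 hazard
configurations crossed with 5 weight settings.  Defaults are the study
conditions: 100 subjects per arm, a 3-year horizon, analysis at 3
years, and a per-subject cap of 100 recorded events.  The cap is a
numerical guard, not a feature of the model: under the catalog's
hazards the probability of approaching it is negligible; a capped
subject keeps a censored terminal row at the horizon.

What the generator deliberately does **not** emulate: dependence
between the recurrent and the fatal process beyond the shared group
effect (no frailty), informative or staggered censoring, strata- or
history-dependent effects, covariates beyond the treatment indicator,
and tied event times (continuous hazards are tie-free almost surely;
the analysis code nevertheless handles ties for real data).  Passing
tests therefore demonstrate correctness under these conditions, not
robustness to, say, frailty-induced dependence — on real data with
strong within-patient clustering the log-rank-type tests in particular
inherit the calibration caveat above.

## Monte-Carlo workflow and numerical choices

`run_scenario()` simulates and analyzes replicates with all three
approaches; `replicate_table3()` maps over a scenario grid and writes a
summary CSV plus a run log.  Summaries follow the conventions of
`summarize_replications()`: power is the rejection fraction, the
estimator summary is the geometric mean (back-transformed mean of
logs), spread is the back-transformed log-scale standard deviation, and
the root-MSE is computed on the log scale against the estimand.  A
replicate whose stratified Cox fit is degenerate — no events of a
cause, all events of a cause in one arm (monotone likelihood), or
failed Newton convergence — is excluded from that method's summaries
only; exclusions are counted and reported.  Replication is sequential
from a single seeded stream, and per-scenario seeds in the grid runner
are fixed offsets of the base seed, so any subset of scenarios
reproduces exactly the rows of a full run.

Numerical details: Cox fits use Breslow tie handling, convergence
tolerance $10^{-10}$, at most 50 iterations, and flag
$|\hat\beta| \ge 15$ as divergent; Nelson–Aalen evaluation is
right-continuous with value 0 before the first jump; the one-sided
significance level defaults to $\alpha = 0.025$, the conventional
one-sided analogue of two-sided 5% testing in confirmatory trials; the
default evaluation time is the administrative horizon.

The package's own test suite runs the study at its original size
(2000 replicates per scenario) for the headline quantities and uses
10^4-draw distributional checks for the simulator, 200-replicate
coverage runs (bootstrap $B = 500$) for the percentile interval, and
100-dataset exact-reduction sweeps against independent oracles
(grid-search partial likelihood, brute-force log-rank, `survival`
estimates); `scripts/acceptance.R` recomputes the scenario-1 event
totals and the Wei–Lachin geometric-mean estimator from scratch.

## Known limitations

* Both effect estimators assume time-constant cause-specific effects;
  under non-proportional hazards the composite effect is
  time-dependent, the estimators target the weighted cumulative-hazard
  ratio at the evaluation time, and the hazard-based estimand and the
  estimator's limit separate — results at a single time point may be
  biased for other time points.
* The weight-based and modified log-rank statistics cannot currently
  use robust within-subject variances (see above).
* The Bakal approach has no estimand; only its test decision and
  curves are interpretable, and published descriptions of the score
  recursion leave several conventions unstated (fixed here as
  documented design choices).
* The applied example of the original methods literature (the
  colorectal-cancer readmission study shipped in the CRAN package
  `frailtypack`) is not redistributed; `analyze_dataset()` documents
  the export recipe for reproducing it.
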