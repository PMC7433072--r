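---
title: "Two-stage Bayesian safety monitoring: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Bayesian safety monitoring: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aesignal)
```

## The monitoring problem

During a randomized trial, investigators review safety reports with
treatment assignments concealed. Pooled (blinded) adverse-event counts can
reveal that *something* is off — the pooled incidence of an event is higher
than its pre-specified expectation — without revealing *which arm* is
responsible. Acting on blinded data alone is hard to justify; ignoring it
wastes the earliest available warning. The procedure implemented here
splits the decision in two:

1. **Stage 1 (blinded screen).** Compare each event's pooled incidence
   against its expected pooled rate $\pi_{M_j}$ and flag events whose
   posterior exceedance probability passes a critical value.
2. **Stage 2 (unblinded confirmation).** Unblind *only* the flagged
   events, fit a dose-response model to the per-arm counts, and confirm
   the signal if the dose slope is credibly positive.

The package provides both stages as model-fitting functions
(`blinded_safety()`, `unblinded_safety()`), an interim workflow that
enforces the blinding contract (`run_interim()`, `run_trial()`), and a
simulator (`run_oc()`) that measures frequency properties — per-event flag
and confirmation proportions and family-wise error rates (FWER) — under
configurable truth scenarios.

## Stage 1: blinded models

With $N$ subjects enrolled, $Y_j$ of whom experienced event $j$, both
stage-1 models start from $Y_j \sim \mathrm{Binomial}(N, \pi_j)$.

**Independent Beta-Binomial.** A conjugate $\mathrm{Beta}(a, b)$ prior
(default $a=b=1$) gives $\pi_j \mid Y_j \sim \mathrm{Beta}(Y_j + a,
N - Y_j + b)$ and the closed-form exceedance probability
$P(\pi_j > \pi_{M_j} \mid Y_j)$ (`beta_binomial_exceedance()`). Each event
is judged on its own; nothing is shared across events, so with many events
the family-wise false-flag rate is large.

**Hierarchical blinded model.** The pooled rate is written as the
randomization-weighted mixture
$\pi_j = Q_c\,\pi_{Ctr_j} + Q_T\,\pi_{Trt_j}$, where $Q_c$ is the
*protocol* control allocation (0.2 in the case study — deliberately not
the realized 11/53, since the protocol fraction is fixed across designs
and known without unblinding). Two assumptions make the treatment rate
identifiable from pooled data: the control rate is pinned at the expected
rate, $\pi_{Ctr_j} \equiv \pi_{M_j}$, and the treatment rate is an offset
on the log-odds scale,
$\mathrm{logit}(\pi_{Trt_j}) = \mathrm{logit}(\pi_{M_j}) + d_j$. The
offsets share a hierarchy, $d_j \sim N(\mu_d, \sigma_d^2)$ with
$\mu_d \sim N(\mu_{d0}, \sigma_{d0}^2)$ and
$\sigma_d \sim \mathrm{Unif}(U_a, U_b)$; defaults
$\mu_{d0}=0,\ \sigma_{d0}=2,\ (U_a,U_b)=(0,3)$ are weakly informative on
the log-odds scale. Shrinkage of the $d_j$ toward a common mean is what
controls multiplicity: a single noisy elevated count is partially
explained by the shared level rather than its own offset.

The decision statistic is $P_{jS1} = P(\pi_{Trt_j} > \pi_{M_j} \mid
\text{blinded data})$, computed as the fraction of retained draws with
$d_j > 0$ (the offset is a monotone transform, so the two events are
identical). An event is flagged when $P_{jS1} \ge P_{crit1}$; ties at the
boundary flag, at both stages, because the workflow's decision rules are
stated with $\ge$.

Degenerate counts $Y_j = 0$ and $Y_j = N$ are legal in both models: the
conjugate form handles them exactly, and the sampler's random walk on the
unconstrained scale never evaluates an infinite density.

## Stage 2: hierarchical logistic dose-response

For flagged events the per-arm counts become available:
$Y_{ij} \sim \mathrm{Binomial}(n_i, \pi_{ij})$ with
$\mathrm{logit}(\pi_{ij}) = \beta_{0j} + \beta_{1j} X_i$. Priors:
$\beta_{0j} \sim N(\mathrm{logit}(\pi_{M_j}), \sigma_{\beta_0}^2)$ — the
per-event prior mean lets baseline incidence differ across event types
while only the scale is shared and learned — and
$\beta_{1j} \sim N(\mu_{\beta_1}, \sigma_{\beta_1}^2)$ with
$\mu_{\beta_1} \sim N(0, 2^2)$,
$\sigma_{\beta_0}, \sigma_{\beta_1} \sim \mathrm{Unif}(0, 3)$.
Confirmation asks only whether the slope is positive:
$P_{jS2} = P(\beta_{1j} > 0 \mid \text{unblinded data}) \ge P_{crit2}$.
(The toxicity probability at the highest dose is deliberately not part of
the criterion.) A note on the prior as written for the intercept: its
stated mean is itself a logit, so the prior is taken as a normal on
$\beta_{0j}$ directly; a second logit transform of a real-valued
coefficient would be undefined.

**The dose covariate scale.** The fit uses the raw dose recorded in the
design (oxygen toxicity units in the case study), not dose/100, although
the scaled covariate is also stored on the design object
(`dose_scale = 100` reproduces the scaled analysis). This is a deliberate
choice: with doses compressed to $[0, 0.1]$, the slope needed to express a
realistic effect is of order 10–40, which the $\mathrm{Unif}(0,3)$ scale
prior effectively forbids — confirmation probabilities collapse toward
their prior value of one half regardless of the data, and none of the
operating characteristics the package is designed to reproduce (scenario-
dependent confirmation proportions, a two-stage null FWER near 5%) are
attainable. On the raw-dose scale the stated priors are weakly informative
relative to the likelihood, and the procedure behaves as intended.

**Joint versus one-at-a-time.** By default all flagged events enter one
joint fit so the hierarchy shares $\mu_{\beta_1}$, $\sigma_{\beta_0}$,
$\sigma_{\beta_1}$; a single flagged event is simply the degenerate case.
Joint fitting borrows strength across events — when several events truly
share a positive dose effect, each event's $P_{jS2}$ rises. Whether that
borrowing is wanted is a judgment call, so `joint = FALSE` fits each event
separately with its own hyperparameter draws. Events anticipated to be
flat in dose can alternatively be analyzed active-vs-control via
`two_arm_collapse()`; the model is unchanged, only the covariate becomes
the 0/1 active indicator.

## The sampler

Both hierarchical posteriors are sampled by a seeded adaptive random-walk
Metropolis-within-Gibbs engine (`mcmc_sample()`). Numerical choices:

* Bounded parameters (the uniform scales) are updated on an unconstrained
  transform — log for half-open, logit-affine for interval supports — with
  the Jacobian folded into the target.
* Conditionally-independent parameter blocks (the $d_j$ given the
  hyperparameters; the $\beta_{0j}$ and $\beta_{1j}$ rows given theirs)
  are proposed as vectors and accepted coordinate-wise from per-coordinate
  posterior terms. This is an exact blocked Metropolis-within-Gibbs scheme
  and is what makes replicated simulation affordable in pure R.
* Proposal scales adapt toward a per-coordinate acceptance rate of 0.44,
  in windows of 50 iterations, during burn-in only; retained draws come
  from a fixed kernel, preserving detailed balance.
* Initialization is prior-central ($d_j = \mu_d = 0$, scales at their
  support midpoints; $\beta_{0j}$ at $\mathrm{logit}(\pi_{M_j})$,
  $\beta_{1j} = 0$), which is always finite.
* One long chain by default, matching the simulation budget of the study
  the package reproduces (10,000 retained after 1,000 burn-in). Multi-chain
  runs exist for diagnostics: `mcmc_diagnose()` reports split-$\hat R$ and
  an autocorrelation ESS, and fits carry a non-fatal warning flag when the
  decision-bearing parameters mix poorly (ESS below 50) — reduced-budget
  replicate fits trip this routinely and the operating-characteristic
  summaries count them rather than discard them.
* Every decision-bearing probability carries its Monte Carlo standard
  error $\sqrt{p(1-p)/\text{draws}}$ (zero for the closed-form model).

Identical seed, settings, data and model give bitwise-identical draws.

## The scenario generator

`scenario_spec()` and `arm_rates()` translate a truth scenario into an
events-by-arms matrix of incidence rates for the eight-arm case-study
design (control 11 subjects, seven active regimens of 6, $N = 53$ at the
first interim); `simulate_trial()` draws independent per-arm binomial
counts from it, and pools row sums for the blinded stage. Patterns:

* `flat_at_pi_M` — all arms at the expected rate (no safety issue);
* `increasing_in_dose` — control pinned at $\pi_{M_j}$, treatment rates
  logistic-linear in dose, the slope solved by 1-D root finding so the
  sample-size-weighted pooled rate equals the scenario's stated pooled
  rate $\pi_0$;
* `flat_elevated` — every arm, control included, at the elevated $\pi_0$:
  a genuine safety problem with no dose-response signature, which stage 1
  should flag and stage 2 should usually fail to confirm.

Two rates in the pre-wired scenarios are rounding-degenerate: the
scenarios quote pooled rates to the whole percent, and for the rarest
event (expected rate 1%) the quoted pooled rate under the "same effect in
every event" scenarios equals the expected rate, which would force a zero
slope inside an all-increasing scenario. The generator's rule: an
increasing-pattern event whose stated $\pi_0 \le \pi_{M_j}$ receives the
mean calibrated slope of the scenario's other increasing events, keeping
the scenario's common-effect shape. The analogous flat-elevated row simply
stays at its stated rate.

The saturated-detection check uses a companion construction,
`hobit_rate_tiers()`: the case study's hypothetical observed rates come in
three joint severity tiers (expected / elevated / high), and all seven
events are simulated together at the tier rates. Simulating one elevated
event against six at expectation would instead let shrinkage pull the
elevated event's flag probability visibly below one.

What the generator does *not* emulate: enrollment over time and staggered
follow-up (counts appear at a single interim snapshot), correlated events
within subjects (counts are independent across events given the rates),
event recurrence and severity grades, and dropout. Passing operating-
characteristic checks therefore says the *decision procedure* behaves as
intended under the stated sampling model, not that real trial data meet
that model.

## Aggregating operating characteristics

`run_oc()` stores the per-replicate decision log and reports, per event:
the blinded flag proportion, the conditional confirmation proportion among
flagged replicates, and the overall proportion as their product — the same
multiplicative construction the case study uses. Family-wise summaries
come in two forms: the empirical share of replicates with at least one
flagged (or confirmed) event, and the independence-product aggregate
$1 - \prod_j(1 - \text{overall}_j)$, which is how the case study's
headline familywise proportions are assembled from its per-event tables.
The two differ when flags are correlated across events — and under the
hierarchical stage-1 model they are, through the shared $\mu_d$ — so both
are reported. Stage-2 critical values are applied *after* the fact to the
stored $P_{jS2}$, so a grid of `P_crit2` values is evaluated on identical
replicates and confirmation proportions are exactly monotone across the
grid.

Replicate fits default to a reduced budget (2,000 draws after 500
burn-in), a deliberate desk-scale choice: it roughly doubles the Monte
Carlo standard error of a posterior probability near the 0.9 threshold
(0.007 versus 0.003 at the full budget), which averages out across
replicates. The shipped checks use 300–500 replicates per scenario, giving
binomial standard errors of about 0.01–0.02 on proportions; the original
study ran 10,000 replicates at the full budget, so its printed values
carry far less noise than any single reduced run.

## Workflow semantics

`run_interim()` recomputes both stages from scratch on cumulative data at
each interim; a previously flagged but unconfirmed event returns to
blinded monitoring with no memory, and a confirmed event keeps being
monitored and re-reported (the procedure recommends, it does not stop
trials). No multiplicity is spent across interims — multiplicity is
handled within each stage by the hierarchy. The unblinded data source can
be an accessor function, in which case an interim that flags nothing
provably never reads per-arm data, and a source that returns events beyond
the flagged set raises an error rather than quietly widening the
unblinding.

## Limitations

* The blinded hierarchical model inherits its identifiability from two
  strong assumptions (known protocol allocation; control rate equal to
  the expected pooled rate). If the expected rates are mis-specified, the
  stage-1 flag probabilities shift accordingly — scenario V exists
  precisely to show the two-stage procedure's behaviour when the control
  arm itself is worse than expected: stage 1 flags, stage 2 rarely
  confirms, because there is no dose effect to find.
* Exposure-time (Poisson) modelling, covariate adjustment, severity
  grading, and nonlinear dose-response forms are out of scope.
* The sampler is a random-walk scheme; for much larger event families or
  hierarchies a gradient-based backend would be preferable. The engine's
  contract (seeded draws, supports, diagnostics) is deliberately small so
  such a backend can be swapped in behind it.
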