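---
title: "Simulating RDS data and evaluating regression validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating RDS data and evaluating regression validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdsregsim)
```

## The problem

Respondent-driven sampling (RDS) recruits members of hidden populations
-- groups without a sampling frame, such as people who inject drugs or
urban Indigenous communities -- along the social network itself: a
handful of *seeds* receive a small number of coupons and invite their
contacts, who in turn invite theirs, wave by wave.  Two features
separate the resulting data from a simple random sample: inclusion
probability grows with network degree, and observations are linked
through recruiter--recruit chains.  For estimating a *prevalence*, the
field has established degree-weighted estimators
(Salganik--Heckathorn's RDS-I, Volz--Heckathorn's RDS-II).  Whether the
same inverse-degree weights should enter *regression* models fitted to
RDS data is far less settled, and practice varies widely.

`rdsregsim` provides a complete Monte-Carlo laboratory for this
question: generate networked populations with controlled outcome
prevalence and homophily, draw RDS samples, fit a battery of weighted
and unweighted binomial and Poisson regressions with various clustering
controls, and score each variant on type-I error, confidence-interval
coverage, relative bias and predictive accuracy.

## The population model

A population holds $N$ individuals (default 10,000).  Each carries

* a binary group label $y_i$ ("G1" with prevalence $\pi$, the outcome);
* a continuous predictor $X_\text{predict} \sim N(2,1)$ in G1 and
  $N(0,1)$ in G2, so the true logit slope is
  $\Delta\mu/\sigma^2 = 2$ and the population odds ratio is near
  $e^2 \approx 7.39$;
* a pure-noise predictor $X_\text{NULL} \sim N(0,1)$ used to measure
  the type-I error;
* a network degree $d_i$ drawn from the mixture described below.

**Homophily.** With $T_{ii}$ within-group ties (both groups pooled) and
$T_{ij}$ between-group ties,
$$ Hx = 2\pi(1-\pi)\left(\frac{T_{ii}}{T_{ij}} + 1\right), $$
which equals 1 under proportionate mixing for any $\pi$.  Given a
target $Hx$ the edge total is split by inverting this expression
(`required_tie_counts()`); the inversion is infeasible when
$Hx < 2\pi(1-\pi)$, and the integer quota reproduces the target only to
the grid resolution $\approx Hx/T_{ij}$, not to $1/E$.

**Wiring.** `wire_network()` is a three-pool configuration model: the
$T_{ij}$ between-group edges pair random G1 stubs with random G2 stubs,
and each group's remaining stubs are paired internally.  Self-loops and
multi-edges are removed by degree-preserving swaps *within* each pool
(so tie quotas are preserved exactly); a proposed swap is rejected if it
would create a new conflict, which is what makes the repair converge
under a heavy-tailed degree sequence instead of hovering at the
configuration model's natural multi-edge rate.  Conflicts that are
structurally unresolvable -- a node needing more distinct same-pool
partners than the pool offers, which occurs when an extreme
degree-outcome assignment concentrates the hubs in a 1,000-member group
-- are dropped under an explicit repair budget (0.1% of edges for
primary populations, 1% for the extreme secondary populations) and
counted in the output.

**Relative activity.** The study design fixes $\omega$ (the ratio of
mean degree between groups) at 1.  With a heavy-tailed degree
distribution, simple random group assignment only achieves this in
expectation: at $\pi = 0.10$ the realized ratio fluctuates with a
standard deviation near 0.07, well past the declared 0.05 tolerance.
`build_population()` therefore balances the exact-count assignment
across consecutive blocks of ten in the degree-sorted order, which
pins $\omega \approx 1$ while remaining exchangeable with respect to
everything else.  The plain unbalanced assignment remains available via
`assign_groups_and_covariates(..., degrees = NULL)`.

### The degree mixture and how it was calibrated

The published account of the motivating survey constrains the degree
distribution qualitatively: modes near 10, 20, 50 and 100; median 20;
mean 47.5; a small set of very low reporters (smallest reported degree
2); and a heavy upper tail.  The exact generating mixture is not
available, so `default_degree_spec()` freezes a 7-component binomial
mixture (modes 3, 10, 20, 50, 100, 150, 1200 at weights 0.034, 0.276,
0.400, 0.057, 0.127, 0.101, 0.005), calibrated *once* against the exact
mixture distribution so that the generating law has median exactly 20
and mean exactly 47.5.  Two further facts printed in the reference
study pinned the tail shape *a priori*: the degree--outcome
correlations realized when G1 is assigned to the extreme degree deciles
($\rho \approx 0.53$ and $-0.13$), which jointly require an overall
degree standard deviation near 95.  Nothing about this mixture was
revisited after observing any downstream test result.

Two consequences of the mean-47.5 / median-20 combination are worth
stating because they bound what any reimplementation can reproduce:

1. Such a distribution necessarily has a strong tail (sd $\gtrsim 70$),
   and RDS inclusion rises with degree, so the mean degree *within
   samples* sits far above the population mean.  The reference tables
   print a mean sample degree *below* the population mean alongside a
   strongly positive frequency--degree correlation; those two numbers
   cannot both hold (the sample mean exceeds the population mean if and
   only if that covariance is positive).  This package reports the mean
   sample degree its sampler actually produces and asserts the
   mathematically coherent property (positive degree bias) instead.
2. How often very-low-degree participants enter a sample -- and hence
   how violently inverse-degree weights misbehave -- depends on the
   unpublished low end of the mixture.  The directional conclusions
   (weighted regression inflates error and destroys coverage; unweighted
   regression is valid) are robust to this; their precise magnitudes
   are not.

## The sampler

`rds_sample()` implements breadth-wise chain referral: ten uniform
seeds (wave 0), three coupons per participant, a target size of 500.
Each participant offers coupons to uniformly chosen *not-yet-sampled*
neighbours; each offer is accepted independently with probability 0.5
(identical in both groups).  Design choices that the published
description leaves open, and how they are resolved here:

* **Seed selection** is uniform over nodes.  Degree-proportional
  seeding is the main alternative; uniform is the plain reading of
  "randomly drawn" and the results are insensitive at 10 seeds of
  10,000 nodes.
* **A declined offer consumes the coupon** (each participant makes at
  most three offers), which is what lets 50% non-response lengthen
  chains: the expected branching factor drops to 1.5 and roughly eight
  waves are needed to reach 500.
* **A declined invitee stays eligible** for later offers from other
  recruiters; refusal is per-offer, not a permanent node trait.
* **Repeat recruitment is never allowed**; the recruitment graph is a
  forest and is validated as such in the test suite (single recruiter,
  wave arithmetic, coupon bound, edge membership).
* **Mid-wave truncation**: the final wave is enrolled in randomized
  order and truncated at the target size, so truncation is unbiased.
* **Stalled chains reseed by default** (a fresh uniform seed, logged in
  the sample metadata), so every run reaches its target; setting
  `allow_reseed = FALSE` turns a stall into a dead-chain error.
  "Waves" is the maximum wave index; "recruits per seed" divides
  non-seed participants by the number of seeds whose chains produced
  at least one recruit.

## Weights and prevalence estimators

RDS-II weights are inverse-degree weights normalized to mean one over
the sample, $w_i = (1/d_i) / \overline{(1/d)}$.  The printed formula in
the reference text has the normalization inverted (it would give mean
weights far below 1 and make every weighted test radically
conservative, contradicting the reported results); the mean-one
orientation matches the cited software's behaviour and is adopted
throughout.  The scale cancels in the Hajek prevalence ratio and in
weighted point estimates, but *matters* for weighted model-based
standard errors, where mean-one weights act as frequency-style
multipliers -- this is precisely the convention under which weighted
regression exhibits its leverage pathology.

`naive_prevalence()` (sample proportion, Wald interval),
`rds2_prevalence()` (Hajek ratio, design-robust interval) and the
optional `rds1_prevalence()` (Salganik--Heckathorn reciprocity
estimator with harmonic-mean degrees) all include seeds -- the seed
exclusion applies to regression, where the recruiter's outcome is
needed as a covariate and is undefined for seeds.
`prevalence_interval()` additionally offers a seed-chain bootstrap
(percentile interval over whole-chain resamples).

## The model battery

`model_spec()` declares a variant by family (`binomial_logit`,
`poisson_log`), weighting (`none`, `rds2`), clustering control and
variance estimator.  `fit_glm()` covers the unclustered and
recruiter-outcome-covariate variants; `fit_gee()` solves generalized
estimating equations with independence or exchangeable working
correlation within immediate-recruiter clusters, or AR(1) along seed
chains (correlation $\alpha^{|w_i - w_j|}$ in wave distance; same-wave
siblings receive $\alpha$, since a zero exponent would declare them
perfectly correlated and make the working covariance singular);
`fit_glmm_seed_intercept()` (optional, via lme4) adds a random
intercept per seed.  p-values are two-sided Wald on the link scale;
confidence intervals are Wald on the link scale and exponentiated --
no profile likelihood, so that all variants are strictly comparable.

Cluster-robust variances are implemented in-package (the environment
has no dedicated sandwich/GEE libraries), with four flavors validated
against a brute-force matrix oracle in the tests:

* `sandwich_classical`: $B^{-1} \left(\sum_c U_c U_c^\top\right) B^{-1}$
  with cluster scores $U_c$ and bread $B$;
* `sandwich_firores`: residual-level small-sample correction, replacing
  $e_c$ by $(I - H_{cc})^{-1} e_c$;
* `sandwich_firoeeq`: estimating-equation correction scaling $U_c$ by
  $(1 - \min(0.75, \text{leverage}))^{-1/2}$ per parameter;
* `sandwich_mbn`: the Morel--Bokossa--Neerchal inflation, a
  $\frac{n-1}{n-p}\frac{K}{K-1}$ factor plus a scaled model-based term,
  never below the classical estimator.

Non-convergent fits (including separation, detected as absent, zero or
explosive standard errors) carry no inference values, are excluded from
metric denominators, and are counted in the summaries.

## Evaluation

Every spec is fit twice per sample: with $X_\text{NULL}$ for the
type-I error (share of converged fits with $p \le 0.05$) and with
$X_\text{predict}$ for coverage (share of exponentiated 95% intervals
containing the population parameter -- each population's *own*
full-population odds ratio or relative risk from
`population_parameters()`), relative bias
$100\,(\text{center}(\hat\theta) - \theta)/\theta$ on the exponentiated
scale (mean and median), and in-sample accuracy
$\frac{1}{n}\sum I(p_i \ge 0.5 \wedge y_i = 1) + I(p_i < 0.5 \wedge
y_i = 0)$ (Poisson fitted rates thresholded identically; no holdout,
matching the reference design).  Pooled summaries aggregate replicates
across populations with equal weight, which coincides with averaging
population rates at equal replicate counts.  Accuracy is *reported*
only for models passing the validity gate (error $\le 0.05$ and
coverage $\ge 0.95$); the ungated value is retained in a separate
column.

## Secondary populations

`build_correlated_population()` fixes $\pi = 0.10$ and ties G1
membership to degree: the extreme modes assign the top or bottom decile
of degrees, the moderate modes walk deciles from the respective end,
assigning 50% more members per decile than independence would until
10% of the population is reached.  The realized correlation $\rho$ is
measured and recorded, never targeted.  For the negative modes the
declared homophily is provably unreachable: the between-group tie quota
implied by $Hx \in \{1.25, 1.5\}$ exceeds every stub the low-degree G1
owns, so the quota is clipped to the feasible boundary (all G1 stubs
between groups), the clip is flagged, and the realized homophily is
recorded.  The pooled-formula homophily of such a population is large
even though G1 itself is maximally heterophilous -- a known quirk of
the index under unequal group activity.

## What a green test establishes, and what it does not

The generator reproduces the *stated* world: exact prevalence, declared
homophily within 0.02 (primary populations), $\omega = 1$, a degree law
matching the published median/mean, and an RDS mechanism with the
published seed/coupon/response/size parameters.  It does not reproduce
unpublished specifics: the exact degree mixture, the internal
tie-placement of the original generator, or its handling of the
infeasibilities documented above.  Monte-Carlo quantities that depend
only on the stated world (population odds ratios and relative risks,
unweighted-model error and coverage, accuracy, the direction and
rough size of every weighted-model pathology, the secondary-population
error pattern) reproduce at the published values.  Quantities that
depend on the unpublished low-degree mass -- the precise magnitudes of
the weighted models' error inflation and coverage collapse -- are
qualitatively reproduced (strongly inflated error, coverage far below
nominal) but can sit short of the exact printed figures; the acceptance
suite asserts the printed values at their stated tolerances and leaves
honest failures visible rather than retuning the generator toward them.

## Numerical choices

* IRLS via `stats::glm.fit` with tightened tolerance (`epsilon =
  1e-12`), verified against an independent Newton--Raphson oracle to
  $10^{-8}$.
* GEE Fisher scoring stops at a $10^{-8}$ step norm, capped at 25
  iterations; the moment estimate of $\alpha$ outside $[0, 0.95)$
  falls back to independence with a flag.
* Integer tie quotas choose the best of floor/ceiling by the implied
  homophily; stub parity is repaired by moving a single tie between
  pools.
* Exact-count group assignment uses cumulative rounding, so realized
  prevalence equals $\text{round}(N\pi)/N$ always.
* Root seed determinism: per-population and per-replicate seeds are
  derived from the root seed and recorded in the manifest; reruns are
  numerically identical.

## Known limitations

* Seeds never expire and coupon timing is not modelled; response is
  homogeneous across groups (differential activity by response is a
  non-goal).
* The RDS-I estimator uses the plain reciprocity form with
  harmonic-mean degrees, not the data-smoothed iterative variant.
* Survey-package strata/class constructions, the declining-correlation
  PQL model and the Morel adjustment are out of scope by design.
* Populations are fixed per experiment; variability across population
  realizations is not part of the reported Monte-Carlo error (matching
  the reference design, which holds each population constant).
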