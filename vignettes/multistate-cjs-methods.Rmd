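---
title: "Multistate Cormack-Jolly-Seber models for polar bear mark-recapture data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate Cormack-Jolly-Seber models for polar bear mark-recapture data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscjs)
```

## The problem

Southern Beaufort Sea polar bears are sampled from helicopters each spring:
bears are physically captured and permanently marked, or identified from
biopsy-dart tissue samples, and a subset carries satellite telemetry.
Recapture probability is strongly heterogeneous in space — search effort
concentrates nearshore, and bears that summer far offshore or outside the
study area cannot be seen at all.  Ignoring that heterogeneity biases
survival and abundance estimates.  `mscjs` addresses it with a multistate
Cormack-Jolly-Seber (CJS) model: the study area is partitioned into four
geographic states (Nearshore-west, Nearshore-east, Offshore-west,
Offshore-east) plus a fifth state, *Elsewhere*, where a bear is alive but
unobservable, and bears move among states with first-order Markovian
transition probabilities.

## Spatial-state design

The state geometry is fixed by three quantities: a nearshore band out to
43.246 km from the mainland coast (the 67th quantile of coast distances of
search-flight locations), an offshore band out to 104.606 km (the 99.5th
quantile, enclosing all capture locations), and an east/west split at
-151.0 degrees longitude.  `derive_boundaries()` recomputes band edges from
search distances using linear-interpolation quantiles (type 7); the paperwork
of turning raw flight tracks into effort is handled by
`filter_search_points()` (steps under 10 m or over 2,083 m in 30 s are
incompatible with searching, and the leading record is dropped) and
`compile_effort()` (searching step lengths summed by state and year, then
inflated multiplicatively by the fraction of flight time with missing
tracks; an inverse convention `d/(1-p)` is available as a switch).
Three conventions are declared rather than inherited, because the source
material leaves them open: boundary locations belong to the nearer-shore /
western state; telemetry annual assignment gives *Elsewhere* only a strict
majority of daily locations, with ties among states 1-4 broken to the
lowest id; and quantiles interpolate linearly between order statistics.

## The model

Let $\phi_{ijk}$ be the probability that a bear of sex $i$ and age class
$j$ survives from spring of year $k$ to spring of year $k+1$, $\tau_{mn}$
the probability of moving from state $m$ to $n$ between springs, and
$\rho_{nk}$ the probability a bear alive in state $n \le 4$ in year $k$ is
observed.  Age classes are A0 (cubs), A1 (yearlings), A2 (first year
independent), A3-4 (subadults), A5-19 (adults), A20+ (old adults), and
Unknown.  Survival is parameterized on the logit scale relative to adult
males,
$$\phi_{M5k} = \left(1 + e^{\alpha_{T5k}}\right)^{-1},\qquad
  \phi_{F0k} = \left(1 + e^{\alpha_F + \alpha_{A0} + \alpha_{A1} +
  \alpha_{T5k}}\right)^{-1},\ \ldots$$
with $\alpha_{Aj} \sim U(0,5)$, so that cub $\le$ yearling $\le$ adult,
age-2 $\le$ subadult $\le$ adult, and old-adult $\le$ adult hold in every
posterior draw by construction.  The *interactive* survival submodel frees
the cub and age-2 classes to vary independently through time
($\alpha_{T0k}, \alpha_{T2k} \sim U(0,5)$ replacing $\alpha_{A0},
\alpha_{A2}$).  Unknown-age survival is a mixture of the three adult-class
survivals with stick-breaking weights $U(0,1)$.

Transition rows are stick-breaking products of twenty $U(0,1)$ parameters,
so each row is a proper probability vector with every entry in $(0,1)$.
Recapture is either *State + Time* ($\rho_{1k} = (1+e^{\beta_{1k}})^{-1}$
with state offsets $\beta_2 \sim U(-5,5)$, $\beta_3, \beta_4 \sim U(0,5)$
imposing nearshore $\ge$ offshore within each east/west region) or *State +
Distance* ($\rho_{1k} = \omega(1+e^{\beta_1 + \theta_1 d_{1k}})^{-1}$ with
$\omega \sim U(0.01, 1)$ a detection ceiling and $\theta_m \sim U(-50,0)$
coefficients on effort distance).  The four pairwise submodel combinations
have 61, 89, 52, and 80 free parameters (`count_parameters()`).

Two choices deserve flagging.  First, the displayed State + Distance prior
indexes its baseline by year, but the published parameter counts (52, 80)
are only consistent with a single time-constant $\beta_1$; the counts win
here, and `time_varying_beta1 = TRUE` restores the annual form.  Second,
effort distances are divided by 10,000 km (configurable `effort_scale`)
before meeting $\theta$, so that the stated $(-50, 0)$ support spans useful
effect sizes for annual state-level effort of a few thousand km.

Note the nearshore $\ge$ offshore recapture ordering is a structural
guarantee only under State + Time; with distance effects the state-specific
$\theta_m d_{mk}$ terms can locally reverse it, which is the point of that
submodel.

## Likelihood

The latent state of a marked bear each year is one of $\{1,\ldots,5,
\text{dead}\}$ and is only partially observed.  Rather than imputing latent
states by Gibbs sampling (the route a BUGS/JAGS implementation takes), the
package marginalizes them with the hidden-Markov forward algorithm:
conditioning on the first observation, the six-state chain propagates with
$\phi_{ijk}\tau_{mn}$ (alive to alive) and $1-\phi_{ijk}$ (alive to dead,
absorbing), and each later occasion contributes $\rho_{nk}$ if the bear was
seen in state $n$, or the non-detection mass ($1-\rho_{nk}$ for states 1-4,
1 for *Elsewhere* and dead) otherwise.  Both formulations target the same
posterior; marginalization makes desk-scale fitting feasible and is checked
exactly against brute-force enumeration over all latent-state sequences on
short histories (tolerance 1e-10).  Telemetry bears are known alive, so
their annual state sequences contribute only transition terms; a gap of $g$
years contributes the $(m,n)$ entry of $\tau^g$.  For speed, bears with
identical likelihood profiles (sex, entry year, age-class sequence,
encounter row) are collapsed to weighted profiles — an exact rewrite of the
same sum.

## Sampling

`fit_mscjs()` runs adaptive Metropolis-within-Gibbs: each scalar gets a
Gaussian random-walk proposal (rejected outside its uniform support), with
proposal scales adapted toward 44% acceptance in batches of 50 iterations
during burn-in only, so the post-burn-in kernel is fixed and the chains
target the exact posterior.  Because the annual baseline parameters trade
off against the effects added to them (every recapture probability shares
its year's baseline), each sweep also makes a handful of joint translation
moves — shifting a whole annual block by a common amount, optionally with
an opposed shift of a companion state effect.  These symmetric proposals
leave the target unchanged and cut the autocorrelation of the
baseline/effect ridges by an order of magnitude.  Chains start from independent prior draws and
run sequentially from one seeded RNG stream; a seed fully reproduces a fit.
The full-analysis configuration (5 chains, 200,000 burn-in, 100,000 further
iterations thinned by 25, i.e. 20,000 stored draws) is encoded in
`mcmc_config()`; testing and examples use `mcmc_config_reduced()` and the
problem sizes below.  In models where both survival and recapture vary
freely through time, the final survival and recapture parameters are
confounded (only their product is identified); they are sampled but flagged,
and `posterior_summary()` excludes them by default.

## Abundance

Within-area abundance is Horvitz-Thompson:
$\hat N^*_k = \sum_{m=1}^4 C_{mk} / \hat\rho_{mk}$, with $C_{mk}$ the
bears observed in state $m$ in year $k$.  Total abundance divides by the
proportion of living marked bears occupying states 1-4, taken from one
exact latent-state realization per posterior draw obtained by
forward-filtering / backward-sampling (a marginalized sampler must
reconstruct the latent states a Gibbs implementation has for free; whether
the original analysis used a realization or a within-draw expectation is
not stated, and the per-draw realization is used here).  Abundance is
reported for every year except the first (no recapture probability) and
last (confounded).  No floor is imposed on $\rho$ — tiny offshore recapture
probabilities genuinely destabilize the estimator, and that instability is
part of the method's behavior — but `rho_floor` exists for diagnostic runs,
and divisions below 1e-4 warn.

## Assessment

`gelman_rubin()` is the basic between/within-chain potential scale
reduction factor ($R_c < 1.1$ taken as convergence; cross-checked against
coda in the test suite), `dic()` the standard deviance information
criterion with $p_D$ = mean deviance minus deviance at the posterior mean —
computed on the marginalized (observed-data) deviance, which is stabler
than, and not numerically identical to, a latent-state implementation's
conditional deviance.  Goodness of fit is a posterior predictive check on
Freeman-Tukey discrepancies $\sum (\sqrt{x} - \sqrt{e})^2$.  The exact cell
structure behind the published check is not recoverable from the text, so
the partition is declared here: annual detection counts by spatial state
(4 states x recapture years), with expected counts from each draw's
parameters by forward recursion over the marked bears, and replicate data
simulated conditional on each bear's first observation.  Ties count toward
the numerator of the Bayesian p-value.

## Synthetic data

`mscjs_truth()` + `simulate_dataset()` generate data with exactly the
structure the model assumes, for parameter-recovery and calibration tests.
The defaults emulate the study design: 16 annual occasions, ~80 newly
marked bears per year with a realistic sex/age mix, adult survival near
0.92 dipping to ~0.80 for a mid-study block of years, diagonal-dominant
movement with a persistent *Elsewhere* state, nearshore recapture near
0.35 and lower offshore, ~10% of subadult-or-older entrants with hidden age
(mirroring biopsy sampling), and ~8 telemetry deployments per year each
contributing three annual states.  Two recruitment modes exist: `"cohort"`
(first captures injected, guaranteeing the marked sample size — CJS
conditions on first capture, so recruitment need not be modeled) and
`"population"` (every capture, including the first, is a Bernoulli($\rho$)
detection from a latent population, so capture counts satisfy
$E[C_{mk}] = \rho_{mk} N_{mk}$ exactly — the mode the Horvitz-Thompson
calibration uses).  What the generator does *not* emulate: movement
geometry (states are sampled directly, not from locations), litter
dependence (cub fates are independent of mothers, matching the model rather
than biology), density dependence, and age/sex structure in movement.
Passing recovery tests therefore demonstrate correctness of the estimation
machinery under the model's own assumptions, not robustness to their
violation in real data.

## Projection

As a consistency check between survival estimates and the abundance trend,
`project_population()` projects an initial set of family groups (an adult
female plus a litter of random size and age) forward 14 years, one
trajectory per posterior survival draw, with Bernoulli survival per
individual per year.  The reproduction rules are deliberately simple and
explicitly configurable — available females (breeding ages, no dependent
cubs) litter with a fixed annual probability; litter sizes 1-3 with
configurable weights; cubs wean at 2 — because the original appendix
detailing them is not available.  The projection supports trend comparison
(`projection_trend()`), not absolute abundance.

## Problem sizes used by the test suite

The full analysis configuration is impractical for a test suite (the
original model runs took 87-153 hours each), so the suite works at reduced,
fixed scales chosen once: a shared synthetic fit of 300 marked bears over
8 occasions (3 chains, 2,500 burn-in + 2,000 stored draws; max $R_c$
~1.03) for constraint, convergence, goodness-of-fit, and abundance checks;
5 parameter-recovery replicates of 600 marked bears, 8 occasions, ~40
telemetry bears at the same chain configuration; and 50 simulation-only
replicates for the Horvitz-Thompson calibration.  At these scales the
recovery checks use group-level mean error (adult-survival years, and the
25 transition entries, averaged): individual weakly informed entries — the
*Elsewhere* row sees only a handful of observed transitions per replicate,
and Offshore-west data are sparse by design — carry visible shrinkage
toward the stick-breaking prior, the small-sample analogue of the
instability the original analysis reports for offshore recapture
probabilities.

## Limitations

Transition probabilities are constant through time and shared across sex
and age classes; survival covariates (sea ice, body condition) are out of
scope by design; the likelihood conditions on first capture, so the
package estimates apparent survival and cannot separate permanent
emigration from death beyond what the *Elsewhere* state absorbs; and GPS
track regularization expects already-regularized inputs (linear
interpolation at most), not a movement model.
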