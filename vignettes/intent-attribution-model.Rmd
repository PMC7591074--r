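---
title: "A grid-based Bayesian observer model of intent attribution in serial dictator games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A grid-based Bayesian observer model of intent attribution in serial dictator games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intentgame)
```

## The task and the modelling problem

In a serial dictator game a participant is endowed with a small sum
(£0.10) and watches a partner — the dictator — decide how much of it to
return, over 6 trials. After each observed split the participant rates, on
1–100 scales, how much the decision was driven by *harmful intent* (HI, a
threat-related attribution: "they wanted to reduce my bonus") and by
*self-interest* (SI, a non-threat attribution: "they wanted to earn more").
Each participant meets three dictators in counterbalanced order: a *fair*
one who always returns half, an *unfair* one who always keeps everything,
and a *partially fair* one who does either with equal probability. That
yields 18 trials and 36 ratings per participant. Pre-existing paranoid
ideation is measured beforehand with the Green Paranoid Thoughts Scale
(GPTS; totals range 32–160).

The package models the participant as an approximately ideal Bayesian
observer of the dictator's latent attributes, and asks which latent
quantities — prior strength, prior uncertainty, assumed consistency of the
partner's behaviour, carry-over of beliefs between partners — vary with
paranoia.

## The generative model

**Belief representation.** Both attributes are discretised into 9 levels,
index 0 ("totally altruistic") to 8 ("totally antisocial"). The
participant's belief is a joint probability grid $p_t(HI, SI)$ over the
$9\times 9$ lattice.

**Sharpened binomial family.** Marginals and policy rows all come from one
two-parameter family: a binomial pmf over $k = 0..8$ raised elementwise to
a power and renormalized,

$$\mathrm{NB}(k; p, u, n) \;\propto\; \mathrm{Bin}(k; p, n)^u .$$

Exponents above 1 sharpen the distribution around its (unchanged) mode;
exponents below 1 blunt it; $u = 0$ gives the uniform. `sharpened_binomial()`
implements this in log space so extreme exponents cannot overflow.

**Priors.** The initial belief is the outer product of two such marginals:
mode `pHI0` with exponent `1/uHI0` for harmful intent, and `pSI0`, `1/uSI0`
for self-interest. The uncertainties enter inverted so that *larger* `uHI0`
means a *flatter* marginal — reduced confidence — matching their
interpretation throughout: in the limit `uHI0, uSI0 -> Inf` the prior tends
to uniform `1/81`.

**Policy map.** The participant holds a map from attributes to behaviour:
for each lattice cell, a distribution over the 9 possible return bins
($r = 1$: nothing returned, $r = 5$: half, $r = 9$: everything). The raw
template is built from fixed constants ($n_\pi = 9$, $p_{init} = 0.05$,
$u_{init} = 2.5$, $\delta_p = (1 - 2p_{init})/(n_\pi - 1) = 0.1125$): level
$a$ of either attribute contributes a sharpened binomial with success
probability $1 - p_{init} - \delta_p a$ and exponent
$u_{init} - 2\delta_p(a+1)$, and the joint row is the normalized product of
the two attribute contributions. A fully altruistic cell peaks at $r = 9$,
a fully antisocial cell at $r = 1$. A note on support: with 9 return bins
the binomial is taken over $r - 1 \in \{0..8\}$, i.e. 8 trials, which is
the only reading consistent with both the 9-bin scale and the corner modes.

The participant-level *policy uncertainty* `u_pi` then flattens every row
(elementwise power $1/u_\pi$), and a small fixed lapse
$\xi = 0.02/n_\pi^2 = 0.02/81$ is added before renormalization. Large
`u_pi` makes each observed return nearly uninformative; the lapse keeps
every bin strictly positive so updates never degenerate.

**Updating and carry-over.** Each observed return triggers an exact
Bayesian update of the full joint grid (`bayes_update()`). When a dictator
block ends, the prior for the next dictator is the convex mixture
$(1-\eta)\,\text{prior}_b + \eta\,\text{posterior}_b$ of the block's
*starting* prior and its final posterior, chained across the three blocks.
The learning rate $\eta \in [0,1]$ is "how much I expect the next partner
to resemble what I just learned".

**Response model.** Reported ratings are treated as a *joint* draw of one
(HI, SI) cell from the belief grid, mapped between the lattice and the
1–100 scale by equal-width bins (`rating_to_bin()`, centres for the
inverse). The joint-draw convention is pinned down by the chance floor: a
model hedging uniformly over all possible responses scores
$\ln(1/81) = -4.394$ per trial, the reference value every diagnostic is
compared against. Ratings are scored against the belief *after* that
trial's update by default (participants rate after seeing the split); the
pre-update convention is available via `fit_config(score = "pre")` since
the original timing convention is not recoverable.

## Fitting

Each participant is characterised by six parameters
(`pHI0, uHI0, pSI0, uSI0, u_pi, eta`), estimated by MAP: the session
log-likelihood plus a weak regularizing prior — uniform over the box bounds
for the probabilities and the learning rate, log-normal(0, 1.5) on the
three uncertainty scales as a soft pull to order-1 values (untruncated; the
truncation constant is irrelevant to the optimum). Neither grid resolution,
optimizer, prior form nor bounds are dictated by the model itself, so the
defaults are chosen for determinism and tractability and are all
overridable through `fit_config()`:

* a factorial scan of 5 values per parameter (15,625 points; probabilities
  linear on [0.05, 0.95], uncertainty scales geometric on [0.05, 20],
  learning rate linear on [0, 1]), ties broken lexicographically;
* the best 3 grid points each seed a BFGS ascent on a transformed,
  unconstrained scale (scaled logits for bounded parameters, scaled logit
  of the log for the uncertainty scales), `maxit = 100`,
  `reltol = 1e-8`;
* the reported optimum never falls below the best grid seed, per-trial
  cell probabilities are floored at $10^{-30}$ before logs, and identical
  data + configuration reproduce the fit bit for bit.

The hot paths (session log-likelihood and the factorial scan) are compiled
(Rcpp), exploiting the fact that within a block the posterior after $t$
trials is the prior times a running product of policy slices, so each trial
costs one dot product over the 81 cells. The exported R operations are the
definitional implementation; the test suite holds the two to $10^{-12}$
agreement and checks both against an independently written brute-force
oracle.

## Simulation and the synthetic population

`simulate_participant()` runs the same belief recursion forward, sampling
one joint cell per trial; `simulate_population()` counterbalances dictator
orders cyclically and gives every participant an independent seeded RNG
substream. Dictator behaviour follows the task design exactly (fair: all
half; unfair: all nothing; partially fair: iid fair/unfair coin flips,
realized independently per participant). Observed return sequences can be
replayed instead (`simulate(fit, replay = TRUE)`) when comparing simulated
with fitted sessions.

Because the original behavioural dataset is an external deposit, the
package ships a generator (`population_spec()`, `generate_population()`)
that emulates the population structure the analysis assumes rather than
estimating it: GPTS totals are drawn as `32 + 128 * Beta(1.2, 4)` (rounded)
— a right-skewed marginal typical of general-population paranoia — and the
six parameters are linear in z-scored GPTS on their link scales with
Gaussian noise, clipped to the fitting bounds. Coupling defaults take the
reported standardized coefficients as link-scale magnitudes: +0.09 on
log `u_pi`, +0.04 on log `uHI0`, +0.03 on log `uSI0`, zero on the learning
rate; the harmful-intent prior mode loading (+0.35 on the logit) mirrors
the magnitude of the reported harmful-intent effect. The noise scales
(sd 1.0 on the logit modes, 0.3 on the log uncertainty scales, 0.75 on the
logit learning rate) were fixed once from power reasoning at the study's
n = 200 validation size: wide enough spread for rank-based recovery to be
meaningful, narrow enough that an 0.09-per-z coupling remains detectable.
These are generator settings that emulate reported directions, not
estimates of any population.

What the generator does *not* emulate: item-level GPTS responses and
subscales, age/sex structure (optional covariates are out of its scope),
response perseveration, and any non-Bayesian response styles (e.g.
alternating or anchored raters). Tests passing on this synthetic population
therefore validate the machinery — identifiability, directions of effect,
absence of fitting artefacts — not the empirical claims about human data,
which require the original deposit.

## Validation workflow

* `run_diagnostics()` recomputes per-trial log-likelihoods at fitted
  parameters and aggregates by trial, dictator type and GPTS quantile
  (4 quantiles by default; the original quantile scheme is unstated),
  flagging any stratum below the $-4.394$ floor.
* `summarize_attributions()` gives descriptive direction-of-effect
  summaries (mean HI/SI by dictator type, GPTS rank correlations). This
  deliberately replaces cumulative-link and mixed-model machinery with
  descriptives; model-averaged coefficients are out of scope.
* `run_recovery()` simulates from known parameters, refits, and reports
  per-parameter Spearman rho, bias and RMSE. At n = 200 the prior modes
  recover at rho ≈ 0.9 and policy uncertainty at rho ≈ 0.75–0.8; with only
  18 trials the prior uncertainties and the learning rate are
  information-poor (rho ≈ 0.4–0.5), which is expected rather than a defect.
* `parameter_network()` is a deliberately simple stand-in for
  graphical-model machinery: unregularized partial correlations via
  precision-matrix inversion of the z-scaled parameters (ridge fallback
  with a logged regularizer when singular), percentile bootstrap intervals,
  and moderation by nodewise regressions with moderator-by-parameter
  interactions (an edge's moderation coefficient averages its two directed
  interaction terms). EBIC-glasso model selection, stability bootstraps and
  centrality analyses are intentionally not reimplemented.
* `run_cluster_control()` is the artefact control: three populations drawn
  uniformly inside the printed low/medium/high `pHI0`/`pSI0` density
  cluster ranges, with the remaining parameters from one shared dense range
  and *no* coupling anywhere, are refitted and their network edge signs
  tabulated against a structured reference network. Edges that the
  unstructured clusters reproduce are candidates for fitting artefacts
  (parameter trade-offs); edges they do not are attributable to population
  structure.

## Numerical choices and degenerate inputs

* All pmf powers are computed in log space with a max-shift, so exponents
  up to the bound (1/0.05 = 20) cannot overflow; cells can underflow to
  exactly zero for hyper-sharp priors, in which case the $10^{-30}$
  probability floor bounds per-trial log-likelihoods below by
  $\ln 10^{-30} \approx -69$.
* Grid ties in the scan are broken by lexicographic parameter order, so
  fits are reproducible across platforms to the extent floating point is.
* Constant rating columns make rank correlations undefined; summaries
  report them as `NA` rather than warn or error.
* Two regional, numerically verified facts about the printed construction
  are worth knowing. First, the per-cell renormalization of the product
  template makes the likelihood of an extreme return non-monotone in one
  attribute at fixed levels of the other, so "observing a take-all split
  never lowers the harmful-intent mean" holds from the uniform prior and
  for the large majority — but not the entirety — of product priors.
  Second, the information carried by one observation (posterior–prior KL)
  decreases monotonically in `u_pi` only on the flattening side
  (`u_pi` ≳ 1.5); below that, the fixed lapse caps the likelihood ratios a
  hyper-sharpened policy can produce. The property tests assert exactly
  these regional versions.

## Problem sizes

The validation studies in the test suite and the acceptance script use
n = 200 pseudo-participants per population (the size of each cluster
dataset in the artefact control), 20 replicates for sign-recovery rates,
and 200–500 bootstrap resamples for network intervals; the full behavioural
cohort (n = 1754) is emulated only in direction, not in precision. These
sizes are the package's validation recipe and can be scaled up through the
same functions.

## Known limitations

* With 18 trials per participant the likelihood is nearly flat in `eta`
  and in the prior uncertainties for many response patterns; point
  estimates of those parameters should be interpreted at the population
  level (rank correlations), not individually.
* The response model has no separate reporting-noise parameter: participant
  noisiness and assumed partner inconsistency are absorbed jointly by
  `u_pi` and the prior uncertainties, and cannot be distinguished with this
  amount of data.
* The network stage quantifies linear conditional associations only, and
  its moderation model assumes a linear moderator effect.
* The per-partner "overall" attributions (the 42nd rating of the original
  task) are not part of the fitted likelihood.
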