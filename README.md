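# intentgame

Bayesian modelling of harmful-intent and self-interest attributions in
serial dictator games.

## The problem

When a partner keeps most of a shared endowment, was it malice or just
greed? In the serial dictator game a participant watches three partners
(fair, partially fair, unfair) split £0.10 over 6 trials each, and after
every split rates the partner's *harmful intent* (HI) and *self-interest*
(SI) on 1–100 scales. Paranoia research uses this task because harmful
intent is the live, threat-related attribution: the question is which
latent cognitive quantities — prior beliefs, their uncertainty, assumed
partner consistency, carry-over of learning between partners — drive those
ratings, and how they vary with pre-existing paranoid ideation (GPTS).

This package implements the full modelling pipeline for researchers in
computational psychiatry and social decision-making: the observer model,
per-participant MAP fitting, forward simulation, synthetic-population
generation, fit diagnostics, parameter recovery, and a partial-correlation
network over fitted parameters with paranoia-moderated edges.

## The model

Beliefs live on a 9×9 lattice over (HI, SI), updated by exact Bayes. All
distributions come from a sharpened binomial family
NB(k; p, u, n) ∝ Bin(k; p, n)^u. Each participant is characterised by six
parameters:

| parameter | meaning |
|---|---|
| `pHI0`, `pSI0` | modes of the initial HI / SI beliefs |
| `uHI0`, `uSI0` | prior uncertainties (larger = flatter prior, exponent 1/u) |
| `u_pi` | policy uncertainty: how loosely attributes map onto observed returns |
| `eta` | learning rate mixing one dictator's posterior into the next prior |

A fixed policy template maps every attribute cell to a distribution over
the 9 return bins (altruist cell peaks at returning everything, antisocial
cell at returning nothing; constants p_init = 0.05, u_init = 2.5,
δp = 0.1125, lapse ξ = 0.02/81). Ratings are scored as a joint draw of one
lattice cell from the belief grid, so a model hedging uniformly scores
ln(1/81) = −4.394 per trial — the chance floor all diagnostics reference.
Fitting is MAP (weak log-normal regularizer on the uncertainty scales) via
a 15,625-point factorial grid scan plus BFGS ascent, with the hot paths
compiled. See the vignette (`vignettes/intent-attribution-model.Rmd`) for
the full account.

## Worked example

```r
library(intentgame)

pars <- participant_params(pHI0 = 0.3, uHI0 = 1, pSI0 = 0.6, uSI0 = 1,
                           u_pi = 1.2, eta = 0.5)
sess <- simulate_participant(pars, seed = 42, gpts = 80)
fit  <- fit_intent(sess)
print(fit)
#> Intent-attribution model fit (MAP)
#> Parameters:
#>   pHI0   uHI0   pSI0   uSI0   u_pi    eta
#> 0.3610 0.9101 0.5913 1.2719 2.9994 0.5203
#> log-posterior: -60.064   log-likelihood: -54.604  (chance floor per trial: -4.394)
#> converged: TRUE   posterior evaluations: 16242
```

The refit recovers the generating prior modes closely (0.36 vs 0.30, 0.59
vs 0.60) from a single 18-trial session; the scale parameters are
information-poor at this size, which is why validation works at the
population level. The mean per-trial log-likelihood (−54.6/18 ≈ −3.0) sits
well above the −4.394 chance floor, i.e. the model predicts this
participant far better than hedging.

Population-level recovery:

```r
rec <- run_recovery(population_spec(n = 200, seed = 11), seed = 12)
print(rec)
#> Parameter recovery over 200 simulated participants (0 failed fits)
#>  parameter   rho   bias  rmse
#>       pHI0 0.906  0.040 0.096
#>       uHI0 0.522 -0.213 0.410
#>       pSI0 0.921  0.018 0.079
#>       uSI0 0.450 -0.271 0.465
#>       u_pi 0.782 -0.101 0.256
#>        eta 0.423 -0.098 0.309
```

Spearman rho is between true and refitted values; with 18 trials the prior
modes and policy uncertainty are well identified, the remaining scales
only moderately — expected for this design.

A thin command line covers the same workflow
(`inst/cli/intentgame.R simulate | fit | recover | report | network`).

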