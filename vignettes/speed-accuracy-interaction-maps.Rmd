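---
title: "Modeling conditional dependence between responses and response times with latent space interaction maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling conditional dependence between responses and response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cognitive-test models usually assume that, given a person's ability and an
item's difficulty, the response and its response time are independent.
Empirically they often are not: responses given faster or slower than
expected for that person and item differ systematically in accuracy, and the
direction and strength of that *conditional dependence* varies across items
and across respondents. `lsirtmap` implements a pipeline that makes this
heterogeneity visible and quantifiable:

1. **Speed classification.** A cross-classified random-effects model for
   natural-log response times,
   $\ln RT_{pi} = \beta_0 + u_p + u_i + e_{pi}$, removes the person's
   general speed ($u_p$) and the item's time intensity ($u_i$). The sign of
   the conditional residual $e_{pi}$ classifies each response: slow when
   $e_{pi} \ge 0$, fast when $e_{pi} < 0$.
2. **Expansion.** Slow and fast responses to item $i$ are treated as
   responses to distinct pseudo-items $i$ and $I+i$ in a $P \times 2I$
   matrix; the sibling cell is structurally missing, so every respondent has
   exactly half of the potentially observable expanded entries missing.
3. **Latent space Rasch model.** The correctness probability is
   $\mathrm{logit}\, P(Y_{pj} = 1) = \theta_p + c_j - \gamma\, d(a_p, b_j)$
   with Euclidean distance $d$ in a $k$-dimensional space (default $k = 2$).
   The weight $\gamma \ge 0$ measures how strongly residual person–item
   interactions depress accuracy. Two variants are fitted: a *constrained*
   model with easiness tied across an item's two pseudo-items, and an
   *unconstrained* model with free easiness per pseudo-item.
4. **Summaries.** After Procrustes alignment of the posterior position
   draws, the *interaction map* of point estimates supports the reported
   quantities: mean item–respondent distances $\bar d_j$, slow–fast
   separations $d(b_i, b_{I+i})$, relative easiness vs distance-difference
   comparisons, and nearest-respondent accuracy contrasts.

## Model assumptions and priors

The reference prior set is $\theta_p \sim N(0, \sigma^2)$,
$c_j \sim N(\mu_c, \sigma_c^2)$, $\gamma \sim N(0, 3^2)$ truncated to
$\gamma \ge 0$, position rows $a_p, b_j \sim MVN(0, I_k)$, $\mu_c \sim
N(0, 5^2)$, and half-Cauchy(0, 5) priors for $\sigma$ and $\sigma_c$. All
are configurable through `lsirt_priors()`, but the defaults are the analysis
contract and the tested configuration.

Two modeling decisions deserve explicit statement:

- **Crossed, not nested, random effects.** The log-RT model is additive in
  crossed person and item intercepts; it is fitted by REML (via lme4) with
  BLUP random effects, and the classification residual is the *conditional*
  residual $\ln RT_{pi} - \hat\beta_0 - \hat u_p - \hat u_i$. Marginal
  residuals (fixed effects only) would ignore the person/item centering that
  the classification is defined by. With shrinkage the residuals are only
  approximately double-centered: per-person and per-item residual means are
  near but not exactly zero.
- **Ties.** A residual of exactly zero is classified slow ($e \ge 0$).
  Responses exactly at the slow-response-time filter limit are kept; only
  strictly longer times are removed (the limit's treatment at equality is a
  convention, stated here because the filter is a data-cleaning contract).

## Identifiability and post-processing

The likelihood depends on positions only through distances, so it is
invariant under any common rotation, reflection or translation of all
positions. The isotropic $MVN(0, I_k)$ position prior is exactly invariant
under rotations and reflections but **not** under translations (a translated
configuration has lower prior density), so the unnormalized posterior is
exactly rotation/reflection-invariant and only approximately
translation-invariant. In practice the posterior is an equivalence class of
configurations; chains wander across isometries even when every distance has
converged.

Consequently:

- **Convergence is diagnosed on distances**, not coordinates: the classic
  (non-split, non-rank-normalized) Gelman–Rubin factor
  $\hat R = \sqrt{\widehat{var}^+ / W}$ with
  $\widehat{var}^+ = \frac{n-1}{n} W + B/n$ is computed per observed
  person–pseudo-item distance and per non-position scalar, with a 1.05
  threshold. Chains of identical constants return $\hat R = 1$ by
  convention.
- **Procrustes alignment** maps every draw's stacked $(P + 2I) \times k$
  configuration onto the highest-log-posterior draw (pooled over chains) by
  the optimal translation plus rotation/reflection. Scaling is *not*
  included: it would change distances and hence the likelihood. Alignment
  preserves every within-draw distance and the likelihood exactly; the
  log *posterior* of a draw can change by the (small) translation effect on
  the position prior, which is why the stored per-draw log posteriors are
  those of the original draws.

## Sampling

The posterior is explored with Hamiltonian Monte Carlo over an analytic
gradient (compiled core). Chains start from a shared data-informed
configuration — rough Rasch estimates for abilities and easiness, a
spectral embedding (top-$k$ singular vectors of the centered residual
matrix) for positions, refined by a short penalized optimization with the
scale hyperparameters pinned at unit values — plus chain-specific jitter.
The data-informed start matters: from an arbitrary configuration the
position gradients vanish as $\gamma \to 0$, and chains can lodge in a
Rasch-limit basin (diffuse positions, $\gamma \approx 0$) that the
distance-PSRF diagnostic flags but cannot repair. Because all chains start
near one basin, the between-chain diagnostic is a within-basin check; the
posterior predictive comparison is the guard against settling in a
basin that misfits the data. The distance weight and the scale
hyperparameters
are sampled on the log scale with Jacobians, making positivity constraints
automatic. Warm-up uses dual-averaging step-size adaptation targeting 0.8
acceptance, with one diagonal mass-matrix update mid warm-up; after warm-up
the step size is fixed. The leapfrog count per iteration is drawn uniformly
up to `traj_length / step_size` (default trajectory length 4 integrator
units, capped at 96 steps) — long trajectories matter here because the
$\gamma$–scale ridge of the posterior mixes slowly under short ones.
Trajectories whose energy error explodes or whose log posterior becomes
non-finite count as divergences and are rejected; a collapsed step size or a
near-zero post-warm-up acceptance rate raises an error rather than
returning a silently broken chain.

Every random ingredient (initial values, momenta, leapfrog counts,
acceptance decisions) derives from the single `seed` argument, so runs are
bit-reproducible on the same platform. The desk-scale default is 2 chains
of 2000 iterations (first half warm-up); the reference configuration of
2 × 10,000 is a `n_iter` away but is not the tested scale.

## The synthetic-data generator

`generate_dataset()` emulates exactly what the pipeline assumes: crossed
person/item log-normal response times; a slow/fast label that is the sign of
the *true* RT residual; and Bernoulli responses from the latent space logit
with condition-specific easiness ($c_{i,\text{slow}}, c_{i,\text{fast}}$)
and condition-specific item positions. Dependence between response and
speed is planted only through those condition-specific quantities, so
whatever the fitted models recover is attributable. Defaults: $P = 300$,
$I = 30$, $k = 2$, $\gamma = 1.2$, $\sigma_\theta = 1$, $\mu_c = 0$,
$\sigma_c = 1$, log-RT grand mean 3.5 (≈ 33 s) with person/item/residual
SDs 0.4/0.5/0.5 — values a timed cognitive test plausibly produces. By
default each item's slow and fast positions are drawn independently from
the standard-normal position distribution — exactly the fitted model's
prior, which is the condition under which Bayesian credible intervals are
calibrated and recovery studies are meaningful. Planted constructions
(`slow_fast_displacement`) instead place the slow position at a chosen
distance from the fast one; they create the canonical qualitative
signatures but make the truth *atypical* under the model's
independent-position priors. Two consequences worth knowing: a planted
displacement of 0 (both conditions share one position) is a measure-zero
configuration for which the position prior's Occam penalty legitimately
pulls the posterior of $\gamma$ toward zero, and large planted
displacements push items so far from all respondents that accuracy
saturates and the item's direction is no longer identified — which is why
the signature preset uses a moderate displacement on a longer test. The
signature preset (`signature_config()`: $P = 300$, $I = 40$, mean slow–fast
displacement 1.0, difficulty-linked) plants larger slow-position
displacements for harder items, the structure behind the canonical
qualitative findings.

What the generator does **not** emulate: multiple-choice guessing floors,
varying item discrimination, curvilinear accuracy–speed dependence,
speededness at test end, or any cognitive process model. Passing recovery
tests therefore show the pipeline is consistent on its own model class —
not that real tests satisfy that class.

## Numerical choices

- Linear predictors are clipped at ±35 before the inverse logit; at
  realistic parameter scales the clip is never active, it only prevents
  `log(0)`.
- The gradient of a distance at $d = 0$ is regularized by
  $\max(d, 10^{-12})$ in the denominator (measure-zero event under the
  continuous posterior).
- REML convergence in the log-RT fit uses lme4 defaults; constant log-RT
  tables short-circuit to the exact degenerate answer (all variances and
  residuals zero, with a warning) rather than invoking an optimizer on a
  singular problem.
- Ties in nearest-respondent selection break by person ordering, which is
  fixed lexicographically at load time.

## Problem sizes used by the test suite

The suite runs desk-scale versions of every statistical claim: the
parameter-recovery check fits the default generator preset ($P = 300$,
$I = 30$, full design) with 2 × 2000 iterations, and the
qualitative-signature check fits the signature preset ($P = 300$, $I = 40$)
with constrained and unconstrained models at 2 × 1500. A 10-replicate
coverage suite for the $\gamma$ credible interval is a long-running job; the
bundled tests run single replicates at fixed seeds. Smaller property tests
(isometry invariance, Procrustes optimality, PSRF oracles, the
mixed-model residual oracle) are exact-tolerance checks on hand-sized
problems.

## Known limitations

- Distances enter only linearly in the logit; a two-parameter
  (discrimination) latent space model is out of scope.
- Dichotomizing speed at the residual's sign discards within-condition RT
  information; median splits or multi-category classifications are only
  available as threshold overrides in `classify_speed()`.
- At the desk-scale design ($\approx 30$ expanded observations per person)
  person positions carry substantial posterior uncertainty; posterior-mean
  distances are therefore shrunk relative to true distances, and
  point-estimate summaries of individual persons should be read against the
  full posterior spread. Accuracy of the recovered *map* grows with items
  per person, which is exactly why the empirical studies this mirrors used
  longer tests.
- The sampler is a static-trajectory HMC, not a dynamic-length NUTS;
  convergence must be (and is) checked through the distance-PSRF report
  rather than assumed.
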