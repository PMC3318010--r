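---
title: "Testing directional body-size trends with trait-dependent birth-death models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing directional body-size trends with trait-dependent birth-death models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftshift)
```

## The question

Does body size in a clade drift in a preferred direction over evolutionary
time?  Cope's rule posits a within-lineage tendency toward larger size;
miniaturization is the opposing trend.  With only extant species available,
the question has to be answered from the shape of a time-calibrated
phylogeny together with the trait values of its tips.  `driftshift`
implements the two-step analysis this calls for:

1. **Phylogenetic signal.**  Is the trait structured by the phylogeny at
   all?  Pagel's lambda, estimated under a generalized-least-squares (GLS)
   model, answers this; lambda near 1 licenses tree-based trait models,
   lambda near 0 says ancestry does not predict the trait.
2. **Trait-dependent diversification with drift.**  A birth-death process
   in which the speciation rate is a function of a continuously diffusing
   character (a QuaSSE-type model).  Directionality enters through a drift
   term in the character process; comparing drift against no-drift models
   tests Cope's rule against the null of undirected diffusion.

## The trait model

The character `x` (here: natural log of maximum head-body length in mm)
evolves along each lineage as a Brownian diffusion with rate `sigma2`
(ln-mm²/Myr) plus a deterministic drift `theta` (ln-mm/Myr); `theta > 0`
is a positive (Cope's-rule) trend.  Lineages speciate at rate
`lambda_S(x)` and go extinct at rate `mu`.  Four speciation families are
supported:

| kind      | form                                        | free parameters |
|-----------|---------------------------------------------|-----------------|
| constant  | `c`                                         | 1               |
| linear    | `max(0, a + b x)`                           | 2               |
| sigmoidal | `y0 + (y1 - y0) / (1 + exp(-(x - m)/r))`    | 4               |
| hump      | `y0 + (y1 - y0) exp(-(x - m)^2 / (2 w^2))`  | 4               |

Adding `mu` and `sigma2` to every model, and `theta` to the drift
variants, reproduces the conventional degrees-of-freedom accounting:
Full (constant) 3, Linear 4, Sigmoidal 6, Hump 6, and 5/7/7 for the drift
variants.  The root state is integrated out rather than counted as a
parameter.

## The likelihood engine

Let `D(x, t)` be the probability density of the data observed in the clade
descending from a lineage that has character value `x` at time `t` before
the present, and `E(x, t)` the probability that such a lineage leaves no
extant descendants.  Backward in time,

```
dE/dt = mu - (lambda(x) + mu) E + lambda(x) E^2 + (sigma2/2) E_xx - theta E_x
dD/dt = -(lambda(x) + mu) D + 2 lambda(x) E D  + (sigma2/2) D_xx - theta D_x
```

The advection sign is fixed so that `theta > 0` means the trait increases
in *forward* time; a simulation-recovery test locks the convention, since
a sign error here is the classic failure mode of this model class.

The solver discretizes `x` on a uniform power-of-two grid and advances
each branch by operator splitting: the birth-death part is applied
pointwise with its *exact* constant-rate solution over the step, and the
diffusion-advection part is applied spectrally, multiplying the FFT of
`(D, E)` (packed as one complex vector; the kernel is real) by the
characteristic function of a Gaussian with variance `sigma2 * dt` and mean
`-theta * dt`.  At interior nodes daughters combine as
`D = D_left * D_right * lambda(x)`; at the root `D` is integrated against
either its own normalized shape (`root_mode = "obs"`, the default) or a
flat weight, optionally conditioning on survival of the two root lineages
by dividing by the weighted `lambda(x) (1 - E)^2`.  Defaults (obs root,
conditioning on) are recorded in every fit's metadata because published
analyses rarely state them.

### Numerical choices that matter

* **Grid.**  Default 1024 points spanning the trait range plus a pad of
  `5 * sqrt(sigma2_max * depth) + |theta_max| * depth + 10 * tip_sd`.
  During ML fitting the same grid (sized from the search bounds, drift
  allowance included even for no-drift models) is shared by every model
  compared on a tree, so discretization bias cancels exactly in AIC and
  chi-square differences.  Density outside the grid is treated as absorbed;
  a guard converts real probability mass reaching the outermost cells into
  a hard "grid too narrow" error.  The guard ignores values below 1e-3 of
  the density peak: sub-resolution spectral ringing is orders of magnitude
  smaller than any truncation that could move the likelihood.
* **Time step.**  Default `0.01 * tree depth` per splitting step.  With a
  constant speciation rate the splitting is exact (the two operators
  commute); with trait-dependent rates the refinement-oracle tests pin the
  error below 1e-3 log-units on the fixture sizes used.
* **Tip conditioning.**  Each tip contributes a Gaussian density centred
  on its observed value with the measurement standard deviation (default:
  1/100 of the observed trait range).  The effective sd is floored at 1.5
  grid cells: a narrower density cannot be represented on the grid, and
  the floor is identical across models sharing a grid.
* **Sibling extinction vectors** are compared at every node (they describe
  the same process below the node and must agree); the tolerance inside
  full-tree traversals is 2e-3 by default, absorbing the operator-splitting
  jitter of branches discretized with different step counts, and the two
  vectors are averaged.
* **Optimization.**  Subplex (via nloptr; Nelder-Mead fallback) on a
  log/identity-transformed scale, from several seeded moment-based starts;
  drift models additionally start from deterministic positive and negative
  drift values because `theta = 0` is a saddle whenever the speciation
  slope is near zero.  Fits warm-start along the model hierarchy
  (constant feeds the trait-dependent models; each no-drift fit feeds its
  drift variant), and one polish restart is run from the incumbent.
  `mu` is fitted (bounded below at zero), matching the published
  degrees-of-freedom accounting.

## Phylogenetic signal stage

The GLS model places the trait vector in a multivariate normal with mean
`alpha * 1` and covariance `sigma2 * V_lambda`, where `V` holds shared
root-to-tip path lengths and lambda multiplies the off-diagonal of `V`.
`fit_lambda()` profiles the closed-form GLS likelihood over lambda in
`[0, 1]` (values above 1 are not considered), with a likelihood-ratio
interval, or samples the posterior by random-walk MCMC under a uniform
prior on lambda and bounded uniform priors on `ln sigma2` and `alpha`
(proposals adapted toward 20-40% acceptance during burn-in).  Marginal
likelihoods for the observed model and for lambda forced to 0 or 1 use the
harmonic-mean estimator, mirroring the "Ln Harmonic mean" reporting
convention of the analyses this package reproduces — with the caveat,
printed in the result, that the estimator has notoriously high variance; a
stepping-stone option (`marginal = "stepping-stone"`, power posteriors
with `beta = (k/K)^3`) is provided for when the number itself matters.
Bayes factors are reported on the `2 * delta-ln` scale, where 3 is the
conventional positive-support threshold.

No drift parameter is estimated at this stage: on an ultrametric tree a
drift term shifts every tip mean equally and cannot be separated from the
root state.  Drift is identified only through the interaction of the
character process with speciation in the birth-death stage.

## Diagnostics

**Substitution saturation.**  The observed index is the mean per-site
Shannon entropy divided by the entropy expected under full saturation
(columns i.i.d. from the overall base composition, estimated by seeded
randomization with the same number of sequences, so the small-sample bias
of the plug-in entropy cancels).  The critical index for the alignment's
size is calibrated by simulation: Jukes-Cantor alignments are evolved on a
balanced tree across a divergence ladder, and the critical value is the
index at which neighbour-joining stops recovering the generating topology
for 95% of replicates.  The comparison is a z-test combining the
site-bootstrap error of the observed index with the calibration error.
This is a reimplementation of an entropy-based saturation test from its
published description; exact numerical agreement with the original tool is
not claimed, and the calibration table is attached to every result.

**Node-density artifact.**  Sparse taxon sampling inflates the curvature
of the relation between the number of nodes and the path length from root
to tip.  `node_density_test()` fits `n = beta * x^delta` by nonlinear
least squares (log-log regression start; the regression itself on exactly
degenerate surfaces), tests `beta > 0` by permutation of node counts
against path lengths, and declares "no artifact" when beta is
significantly positive and `delta <= 1`.  Tips share ancestors and are not
independent; the permutation test inherits this approximation from the
original method.  Perfectly ultrametric trees (all path lengths equal)
return "not applicable" rather than an error, and a sample-level wrapper
reports the percentage of trees in each (beta significant) x (delta <= 1)
cell so the joint criterion can be read either way.

## Tree samples and phylogenetic uncertainty

`fit_over_sample()` runs the battery independently on every tree of a
Bayesian posterior sample (per-tree failures are recorded, not fatal) and
the aggregation stage reports, per drift model, the mean and shortest 95%
interval of the per-tree drift estimates, plus a pairwise model ranking.
The published analyses this mirrors do not state how per-tree maximum
likelihoods were combined into their sample-level Bayes factors; this
package uses `2 * (mean lnL_1 - mean lnL_2)` as the primary statistic and
also reports the fraction of trees each model wins by AIC, so the
sample-level conclusion can be checked both ways.  Reproducing any
specific published sample-level Bayes-factor value is therefore not
claimed; the qualitative ranking is.

## What the synthetic generators emulate

`simulate_quasse_forward()` is a forward-time Euler implementation of the
exact process the likelihood models: per step, traits drift and diffuse,
lineages speciate with probability `lambda(x) dt` and die with `mu dt`
(steps refined so no event probability exceeds 0.1), extinct lineages are
pruned, and the reconstructed tree of extant tips is returned —
ultrametric by construction, which is what all fitted models condition on.
`simulate_traits()` draws tip traits from the exact lambda-structured
multivariate normal, and `simulate_alignment()` evolves sites under
Jukes-Cantor.

Features of real data deliberately *not* emulated: measurement error in
the generator (added only in the likelihood's tip conditioning),
incomplete taxon sampling, fossil calibration uncertainty, among-site rate
variation, and cladogenetic (speciational) trait jumps.  Passing the
round-trip tests therefore shows the estimator is consistent with its own
model assumptions on clean trees of the stated size — not that those
assumptions hold for any particular empirical clade.

### Study conditions of the validation experiments

The parameter-recovery experiments (`drift_recovery_replicate()`)
simulate a linear-speciation process with drift —
`lambda(x) = max(0, -2 + 0.5 x)`, `mu = 0`, `sigma2 = 0.15 ln-mm²/Myr`,
`theta = 0.3 ln-mm/Myr`, root state `x0 = 4.7 ln mm` (about 110 mm, the
middle of a rodent-like size range) — grown to 100 extant tips.  These
values give contemporaneous lineages a realistic spread of speciation
rates (roughly 0.3-1.3 events/Myr across the simulated trait range), so
the trait-diversification coupling the model is built to detect is
genuinely present in the data, with a drift-model likelihood improvement
of the same order of magnitude as empirical analyses of this kind report.
The null experiments use a constant rate of 0.5 events/Myr with the same
diffusion.  Replicate fits use a 256-point grid, a splitting step of 2.5%
of tree depth, and fixed search bounds (`sigma2` up to 0.45, `|theta|` up
to 0.5) so every replicate shares one discretization scale — coarser than
the analysis defaults, chosen to keep the replicate sets of the
validation suite at desk scale; the refinement oracle pins the residual
discretization error on fixtures of this size.  The drift point estimate
is read from the fit of the generating model class (extinction fixed at
its generating value of zero): with extinction free, `theta` and `mu` sit
on a nearly flat likelihood ridge — re-optimizing the remaining
parameters at different fixed drift values leaves the log-likelihood
essentially unchanged — so the free-extinction point estimate is
arbitrary along the ridge and only the model comparison is meaningful
there.  The free-extinction fit is still run in every replicate (it is
what the AIC contest uses), and the generating-class solution is offered
to it as an extra starting point, which it must dominate by nesting.

## Known limitations

* Drift (`theta`) is weakly identified in this model class: on an
  ultrametric tree its trait-level signature is absorbed by the root
  state, so identification rests entirely on the interaction between the
  drifting character and the speciation-rate function, and it competes
  with extinction (`mu`) in explaining the acceleration of lineage
  accumulation toward the present.  Expect wide intervals on `theta`, and
  treat the drift-vs-no-drift *model comparison* as the primary readout
  rather than the point estimate.
* The harmonic-mean marginal likelihood is retained for comparability and
  is unreliable as an absolute number; use stepping-stone for real model
  choice.
* Extinction-variable models are out of scope (extinction-rate signal in
  molecular phylogenies is notoriously weak).
* The likelihood treats sampling as complete; there is no sampling
  fraction correction.
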