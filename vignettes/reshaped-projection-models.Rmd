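---
title: "Reshaped random-projection models of neural population activity"
author: "reshapeRP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reshaped random-projection models of neural population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reshapeRP)
```

## The model

A population of $n$ neurons, binned into small time windows (20 ms by
convention), produces binary activity patterns
$\vec{x} \in \{0,1\}^n$. The random-projection (RP) maximum-entropy model
describes the distribution of these patterns through a set of sparse
nonlinear *projections*

$$ f_i(\vec{x}) = \sigma\Big(\sum_j a_{ij} x_j - \theta_i\Big), $$

where most coefficients $a_{ij}$ are zero (the sparse synaptic mask), the
thresholds are $\theta_i = 1$, and $\sigma$ is either the Heaviside step or
a logistic sigmoid $\sigma(u) = 1/(1+e^{-\beta u})$ with slope $\beta$. The
model itself is the maximum-entropy distribution consistent with the
observed projection means $\langle f_i \rangle$:

$$ p(\vec{x}) = \frac{1}{Z} \exp\Big(-\sum_i \lambda_i f_i(\vec{x})\Big), $$

with Lagrange multipliers $\lambda_i$ and partition function $Z$. The model
maps onto a shallow feed-forward circuit: input neurons connect through
sparse weights $a_{ij}$ to an intermediate layer of projection neurons,
whose outputs are weighted by $\lambda_i$ at a readout whose activation is
the pattern's log-likelihood up to a constant.

The package implements three ways of fitting this model to a spike raster,
under five synaptic-constraint regimes, together with exact and sampled
inference, evaluation metrics, and a synthetic-data generator.

## Sign conventions and gradients

With the energy written as $E(\vec{x}) = \sum_i \lambda_i f_i(\vec{x})$ and
$p \propto e^{-E}$, the derivative of the mean training log-likelihood is

$$ \frac{\partial \mathcal{L}}{\partial \lambda_i}
   = \langle f_i \rangle_{\text{model}} - \langle f_i \rangle_{\text{data}}, $$

so `lambdaGradient()` returns exactly this ascent direction; its fixed
point is marginal matching and small steps increase the training
likelihood (the problem is convex in $\lambda$). The reshape rule tunes
the nonzero weights with $\lambda$ held fixed:

$$ \Delta a_{ij} \propto \lambda_i \Big(
   \Big\langle \tfrac{\partial \sigma}{\partial a_{ij}} \Big\rangle_{\text{model}}
 - \Big\langle \tfrac{\partial \sigma}{\partial a_{ij}} \Big\rangle_{\text{data}}
   \Big), \qquad
   \frac{\partial \sigma}{\partial a_{ij}} = \beta\, \sigma(u_i)(1-\sigma(u_i))\, x_j. $$

Both directions are verified against finite differences of the exact
enumeration likelihood in the test suite (tolerance $10^{-5}$, and in
practice they agree to $\sim 10^{-10}$). Reshaping requires the sigmoid:
the Heaviside step has zero derivative almost everywhere and is rejected
with an explicit error. Joint ("backpropagation-style") training applies
both updates in the same step; with either step size set to zero it
reproduces the corresponding single-mode trainer exactly, because all
three modes share one training core.

Two conventions are fixed once and used everywhere:

* **Heaviside boundary**: $H(0) = 1$. For continuous weight draws the
  event $u = 0$ has measure zero; any fixed convention works, but it must
  be consistent between enumeration, sampling, and training.
* **Units**: natural logarithms throughout; likelihoods are reported in
  nats per sample. The uniform model on $n$ neurons scores
  $-n \ln 2$.

## Synaptic constraints

Reshaping can be run under five regimes (`ConstraintSpec`):
unconstrained; *bounded*, $|a_{ij}| \le \omega$; and three *homeostatic
normalization* schemes that fix a sum of absolute synaptic weights to a
budget $\phi$ — per projection's inputs ($\sum_j |a_{ij}| = \phi$), per
input neuron's outputs ($\sum_i |a_{ij}| = \phi$), or circuit-wide
($\sum_{ij} |a_{ij}| = \phi$).

The homeostatic kinds are implemented by reparameterization: the optimizer
works on unconstrained parameters $\tilde{a}$ and the model always sees
$a = \phi\,\tilde{a} / \sum |\tilde{a}|$ (row-wise, column-wise, or
globally), so the constraint surface holds *exactly* — to machine
precision — after every iteration, not approximately at convergence.
Gradients are pulled back through the reparameterization by the chain
rule, with the subgradient of $|\cdot|$ at 0 taken as 0. A projection (or
input neuron, or circuit) whose unconstrained weights sum to zero absolute
weight cannot be normalized and raises a degenerate-configuration error;
the same applies to homeostatic-output normalization when some input
neuron has no outgoing synapses at all.

The bounded regime uses projected gradient ascent: after each optimizer
step the parameters are clipped to $[-\omega, \omega]$. A literal clip
reparameterization would have zero derivative wherever the unconstrained
parameter escapes the box, permanently freezing that synapse; projection
keeps the ceiling exact while letting boundary synapses re-enter the
interior. Inside the box the two formulations coincide, which is where
the finite-difference checks are performed.

## Convergence

Multiplier training stops when every projection's model marginal falls
inside the two-sided Clopper–Pearson interval around its empirical
marginal, computed from the Beta-quantile closed form with
$N = $ number of training samples. The default level 0.6827 reads "one
standard deviation" as the Gaussian two-sided 1-SD coverage. Sigmoid
projection means are not binomial counts; the interval is applied to them
regardless, with fractional success counts (the Beta quantiles accept
continuous arguments). The calibration of the rule is itself tested: at
$p = 0.3$, $N = 1000$, the true marginal is accepted in
$68.3\% \pm 2\%$ of 10,000 simulated draws. Reshaping, whose stationary
point is not marginal matching, instead declares a projection converged
when its gradient row falls below `gradTol` in infinity norm; otherwise it
runs to `maxIters`.

## Exact inference, sampling, and partition functions

For $n \le 20$ the package enumerates all $2^n$ patterns
(`enumerateDistribution`), which serves as the exact oracle for every
sampler and trainer. Above the cap, `mhSample()` provides
Metropolis–Hastings sampling with uniformly chosen single-neuron flip
proposals, accepted with probability $\min(1, e^{E(x)-E(x')})$; default
burn-in and thinning are $10n$ and $n$ proposed flips (one expected update
per neuron between retained samples), and chains are bit-reproducible from
their seed. The log-partition function is estimated by annealed importance
sampling (`estimateLogPartitionAIS`) along a geometric inverse-temperature
ladder from the uniform model ($\ln Z_0 = n \ln 2$) to the target, with a
bootstrap standard error over chains. The flip kernels are implemented in
C++ for throughput but draw from R's RNG, so seeding behaves like any
base-R simulation.

Model expectations during training come either from enumeration
(`expectationSource = "exact"`) or from a bank of persistent MH chains
advanced a little every iteration (`"mcmc"`, persistent contrastive
divergence style), initialized at random data rows.

## The synthetic-data generator

No recordings ship with the package; `makeGroundTruthModel()` constructs
generators emulating 20 ms-binned cortical rasters: low per-bin firing
probabilities (default target band 0.01–0.15 per neuron), weak pairwise
correlations induced by shared sparse projections (in-degree 5,
$\mathcal{N}(1,1)$ weights, $\theta_i = 1$), and positive multipliers.
Because a global multiplier scale cannot place every heterogeneous
neuron's rate inside a band, the generator adds one single-input "bias"
projection per neuron (weight 1, threshold 1/2) whose multiplier acts as a
per-neuron field, tuned by a damped logit-matching loop on probe rasters —
the same role per-neuron rate terms play when such models are fitted to
real recordings. Per-neuron targets are drawn from the central 60% of the
band, so rates are heterogeneous but safely inside it.
`sampleSyntheticRaster()` then draws disjoint train/test rasters from one
chain (default proportion 4:1, mirroring standard 160k/40k splits).

What the generator does *not* emulate: stimulus structure, trial
alignment, slow nonstationarities, refractoriness, and the spatial
correlation structure of real arrays. Passing tests therefore demonstrate
correctness of the machinery and reproduction of the qualitative
phenomena under a known ground truth, not performance claims about any
particular biological dataset.

## Study conditions at desk scale

The experiment drivers (`runReshapeComparison`, `runBudgetComparison`,
`runRateHomeostasis`, `runConnectivityComparison`) reproduce the main
result classes at sizes where the exact oracle is available, rather than
at the original scale of 50-neuron groups with 150 projections. Choices,
made once:

* **Geometry.** 10 neurons; 12 projections for the training-mode and
  budget comparisons; 30 projections (the projection-rich ratio
  $n_{\text{proj}}/n = 3$ of the original setting) for the rate-homeostasis
  and connectivity experiments, where the effects strengthen with the
  number of projections. In-degree 5; 20,000 training and 5,000 test
  samples; exact expectations.
* **Sigmoid slope.** $\beta = 2$ by default. The rate-homeostasis
  experiment uses $\beta = 4$: with a shallow slope the activation floor
  $\sigma(-\beta)$ compresses all projection rates into a narrow band and
  different normalization budgets cannot produce the widely different
  *initial* rates whose convergence under reshaping is the phenomenon of
  interest. $\beta$ is always an explicit parameter, never hard-coded.
* **Budgets.** The homeostatic-vs-bounded comparison matches available
  budgets at 35% of the initial set's total absolute weight (the scarce
  regime, where the redistribution advantage of normalization is
  expressed); `phi = budget / n_{proj}` and
  `omega = budget / n_{synapses}`. The rate-homeostasis experiment spans
  $\phi \in \{3, 8, 20\}$, from scarce to ample; the connectivity
  experiment uses $\phi = 1.4$ per projection, scarce but trainable.
* **Connectivity experiment.** The generator with known connectivity is
  itself a fitted sparse RP model (multiplier training on a warm-up
  raster), following the fit-then-sample route; reshaping then starts
  from the generator's own mask, an independent sparse draw, or full
  connectivity, with fresh $\mathcal{N}(1,1)$ weights on each, and
  comparisons are made between seed-averaged held-out likelihoods, as the
  underlying claims concern means over many models.
* **Projection firing rates** in the rate-homeostasis experiment are
  empirical means of $f_i$ over the training raster (the quantity visible
  during learning); `projectionFiringRates()` also offers the exact model
  expectation, and both converge on the fixtures.

## Numerical choices

* Enumeration cap $n \le 20$ ($2^{20} \approx 10^6$ states); larger
  populations must use the AIS path, and `enumerateDistribution` refuses
  them explicitly.
* Data-side expectations collapse the raster to unique patterns with
  counts before any training loop, so per-iteration cost scales with the
  number of distinct observed patterns, not raw samples.
* Optimizers: ADAM (default; learning rate 0.05 for weights, 0.1 for
  multipliers in the shipped experiments) or gradient ascent with
  momentum. Momentum with coefficient 0 recovers plain gradient ascent,
  which is provably monotone for multiplier training at small steps.
* Empty projection rows in random masks are redrawn (a projection with no
  inputs is a constant); the ground-truth generator additionally redraws
  until every neuron feeds at least one projection, since a fully
  disconnected neuron is pinned at rate 1/2.
* Model files serialize with 17 significant digits, making round-trips
  lossless and file checksums platform-stable.
* Threshold tuning ($\theta_i$, gradient
  $\partial\sigma/\partial\theta_i = -\beta\sigma(1-\sigma)$) is available
  via `tuneThresholds` but off by default; it has little effect on the
  fitted likelihood in this regime.
* `lambda = 1` for all projections is the reshaping default. The best
  fixed multiplier interacts with the number of projections (large
  multipliers with many projections aggravate the non-convexity), so the
  value is a constructor default, not a constant.

## Known limitations

* Reshaping is non-convex; trainers accept local optima, and
  repeated-seed experiments are the unit of evidence for the qualitative
  orderings.
* The Clopper–Pearson stopping rule applied to continuous sigmoid
  marginals is a heuristic carried over from the binary case.
* AIS standard errors are bootstrap estimates over chains; for
  pathological multiplier magnitudes the sampler warns when acceptance
  falls below 1% but does not adapt.
* Desk-scale geometries reproduce orderings and invariances, not the
  absolute likelihood values of 50-neuron cortical groups.

## A worked example

```{r example, eval = FALSE}
nl <- Nonlinearity("sigmoid", beta = 2)
gt <- makeGroundTruthModel(10, 12, 5, nl, seed = 1)
d  <- sampleSyntheticRaster(gt, 20000, 5000, seed = 2)

P0 <- buildSparseProjections(10, 12, 5, nl, seed = 3)
M  <- RPModel(P0)               # all multipliers 1

rp <- trainLambdas(M, d$train, OptimizerConfig(learningRate = 0.1,
                                               maxIters = 1000))
rs <- trainReshape(M, d$train, OptimizerConfig(learningRate = 0.05,
                                               maxIters = 600),
                   ConstraintSpec("homeo_input", phi = 2))

exactMeanLogLikelihood(rp$model, d$test)
exactMeanLogLikelihood(rs$model, d$test)
rotationAngles(P0, projections(rs$model))
synapticBudget(projections(rs$model), P0,
               ConstraintSpec("homeo_input", phi = 2))
```

The README shows this example with the numbers it prints.
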