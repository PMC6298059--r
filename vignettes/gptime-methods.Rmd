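---
title: "Pseudotime inference with capture-time priors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudotime inference with capture-time priors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gptime)
```

## The model

Single-cell expression profiles are snapshots of cells progressing through
a dynamic process at unknown rates. **Pseudotime** is a latent scalar
$t_c$ per cell $c$ summarising that progress. gptime models the
log-transformed expression $y_{g}$ of each gene $g$ as a noisy nonlinear
function of pseudotime,
$$ y_{g} = f_g(t) + \epsilon, \qquad \epsilon \sim N(0, \sigma^2_{noise}), $$
with a zero-mean Gaussian-process prior on the mapping,
$$ f_g(t) \sim \mathcal{GP}\!\left(0,\; \sigma^2 k(t, t')\right). $$
The covariance function $k$ is shared across genes, which is the model's
smoothness constraint: one latent ordering must make *all* genes smooth.
Genes are centred before fitting (the zero-mean prior) and the centres are
added back in predictions.

The assumption that makes pseudotime identifiable here is that **capture
times are informative**: each cell's pseudotime receives a Gaussian prior
centred on the experimental time point $\tau_c$ at which the cell was
captured,
$$ t_c \sim N(\tau_c, \sigma_t^2). $$
The prior variance $\sigma_t^2$ (squared capture-time units) controls how
far cells may move from their nominal capture time; it is the single most
consequential user parameter. Small values effectively sort cells within
capture batches; large values let the expression data override the design.

Three covariance families are provided, with $r = \lVert t_1 - t_2 \rVert / l$:

* RBF: $k = \exp(-r^2)$ — smooth aperiodic trajectories;
* Matérn-3/2: $k = (1 + \sqrt{3}r)\exp(-\sqrt{3}r)$ — rougher trajectories;
* periodic (for cell-cycle-like data, known period $\lambda$):
  $k = \exp\{-\tfrac{1}{2}(\sin(\pi(t_1-t_2)/\lambda)/l)^2\}$.

The latent space can have $Q > 1$ dimensions: dimension 1 carries the
capture-time prior and is interpreted as pseudotime; the remaining
dimensions get standard-normal priors and are free to absorb other
structure, such as the divergence of cell fates after a branch point. The
kernel acts on the full latent vector through the scaled Euclidean
distance with a single shared lengthscale; per-dimension lengthscales
exist as a fixed-hyperparameter extension (`kernel_spec(lengthscale =
c(l1, l2))` with `optimize_hyperparams = FALSE`) but are off by default,
because a shared scale is what the isotropic-kernel formulation implies
and it keeps the extra dimension comparable with the pseudotime axis.

## Sparse inference: VFE and FITC

Exact GP inference costs $O(C^3)$ per gene-shared covariance; sparse
approximations summarise the posterior through $M \ll C$ inducing inputs
$Z$ at cost $O(CM^2)$. Both supported approximations can be written as a
Gaussian log-density with covariance $Q_{NN} + G$, where
$Q_{NN} = K_{NM} K_{MM}^{-1} K_{MN}$ is the Nyström approximation of the
full kernel matrix:

* **VFE** (variational free energy): $G = \beta^{-1} I$, plus a trace
  penalty $-\tfrac{\beta}{2}\mathrm{tr}(K_{NN} - Q_{NN})$ per gene. The
  total is a true lower bound on the marginal likelihood; adding inducing
  points can only tighten it, and the trace term measures exactly the
  error introduced by sparsification.
* **FITC**: $G = \mathrm{diag}(K_{NN} - Q_{NN}) + \beta^{-1} I$ and no
  trace term. This is equivalent to modifying the GP prior itself, so it
  is *not* a bound and can overestimate the evidence — which is the
  documented overfitting risk of FITC and the reason VFE is the default.

`vfe_objective()` and `fitc_objective()` return the decomposition as
`data_fit + complexity + trace_term - kl_prior = total`, each term stored
with its signed contribution. When $Z$ equals the latent points and
$M = C$, both objectives collapse to the exact dense GP log marginal
likelihood plus the log prior; the test suite verifies this equality to
$10^{-8}$ relative error and the bound property on random configurations.

### Latent-variable treatment: two modes

* `variational` (default for VFE): a factorised Gaussian
  $q(t) = \prod_n N(t_n \mid \tau^*_n, \sigma^{*2}_n)$ is optimised
  through the collapsed bound
  $\mathbb{E}_{q}[\log p(Y \mid t)] - \mathrm{KL}[q \,\|\, p]$, which
  requires the kernel expectations
  $\psi_0 = \sum_n \mathbb{E}_q[k(t_n,t_n)]$,
  $\Psi_1 = \mathbb{E}_q[K_{NM}]$ and
  $\Psi_2 = \sum_n \mathbb{E}_q[k(Z,t_n)k(t_n,Z)]$.
* `map` (required for FITC): the latent means are optimised directly with
  the log prior density as regulariser. This pathway is faster, supports
  all kernels without quadrature, and produces the same posterior-mean
  orderings that the headline statistics are computed from; what it lacks
  is the per-cell posterior variance.

With $q$ variances driven to zero, $\Psi_1 \to K_{NM}$ and
$\Psi_2 \to K_{MN}K_{NM}$ and the variational bound collapses onto the map
objective (minus the divergent entropy), which the tests check via the
degenerate $\psi$-statistics.

### Kernel expectations

The $\psi$-statistics have closed forms for the RBF kernel (products of
1-D Gaussian convolutions per latent dimension). For the Matérn-3/2 and
periodic kernels they are computed numerically. In one latent dimension
the integrals use **Gauss–Legendre panels split at the inducing inputs**,
truncated at $\pm 8.5$ posterior standard deviations: the Matérn kernel
has a derivative kink at $r = 0$, so a single global rule (such as
Gauss–Hermite in the Gaussian measure) converges only polynomially across
the kink, while piecewise panels are spectrally accurate — doubling the
panel order changes the result by less than $10^{-6}$ at the default
order 20, which is the self-consistency the tests demand. For $Q > 1$ a
tensor Gauss–Hermite rule is used (the kink is then a measure-zero cone,
and the smooth RBF case — the one used for branching — has closed forms
anyway).

### Gradients

All objectives provide hand-derived analytic gradients with respect to
the latent means (and log-variances in variational mode), the inducing
inputs, and the log-transformed kernel variance, lengthscale and noise
precision. In the panel-quadrature pathway the nodes are fixed given $Z$,
so mean/variance gradients flow only through the Gaussian density
weights, making the gradient of the discretised objective exact up to
quadrature error. Every gradient path is verified against central finite
differences at relative error $<10^{-4}$ in the test suite.

## Optimisation

A quasi-Newton method (L-BFGS-B via `optim`) minimises the negative
objective over all unconstrained parameters; positive parameters are
log-transformed. Convergence is declared at relative objective change
below `tol` (default $10^{-6}$) or `max_iter` (default 2000) iterations.
Restarts are seeded: the first uses the configured initialisation
exactly, later ones jitter the initial means by half a prior standard
deviation; the restart with the best final objective is returned, and the
recorded trace of accepted objective values is non-decreasing.

**Initialisation.** Good orderings depend on initialising the latent
means sensibly. `capture_time` (the default) starts dimension 1 at
$\tau$; `pca` uses the leading principal component rescaled to the
capture-time range and sign-aligned to correlate positively with capture
time; `tsne_hook` accepts any embedding callback (t-SNE itself is
deliberately not reimplemented — it is an injected interface). Extra
dimensions start at subsequent components scaled to unit variance.
Initial variational variances are $\sigma_t^2/2$: strictly inside the
prior scale, so the KL term neither vanishes nor explodes at the start.

**Inducing-point policy.** `choose_inducing()` places $M$ points at
equally spaced type-1 empirical quantiles of the initial latent means,
per dimension. When the means sit on a coarse grid — exactly what the
`capture_time` initialisation produces with a handful of capture times —
the quantiles collide and the effective number of inducing points would
silently collapse to the number of capture times; in that case the
dimension falls back to an equally spaced grid over the initial range,
padded by twice the initial posterior standard deviation, which is the
scale over which cells diffuse away from their capture times during
optimisation. With this policy, fixed inducing points reach objectives
within a fraction of a percent of jointly optimised ones on the synthetic
study data, so `fix_inducing = TRUE` is the default.

**Numerical safeguards.** $K_{MM}$ receives a relative jitter of
$10^{-6}\sigma^2$ before factorisation (configurable); on Cholesky
failure the jitter escalates tenfold up to $10^{-2}\sigma^2$ before a
numerical error is raised. Map-mode prediction uses the projected-process
identity $\mu_* = Q_{*N}(Q_{NN}+\Lambda)^{-1}y$ rather than the
$K_{MM} + K_{MN}\Lambda^{-1}K_{NM}$ form, which stays well conditioned as
the noise variance approaches zero. The `float32` precision mode rounds
the stored expression and kernel/$\psi$ matrices to IEEE single precision
(accumulation remains in double), emulating the memory-bound behaviour of
reduced-precision fitting; `float64` is the default and is used for all
quantitative checks.

## The synthetic-data generator

`simulate_expression()` draws data from exactly the model's assumptions:
pseudotimes $t_c \sim N(\tau_c, \sigma_t^2)$ around a capture grid (cells
split evenly, remainder to the earliest times), gene profiles drawn from
the GP prior with the chosen kernel at the true latent coordinates, plus
i.i.d. Gaussian noise. Identical `sim_spec()`s give bit-identical output.
Default study conditions: 100 cells, 20 genes, capture grid $0,1,2,3$,
$\sigma_t^2 = 0.25$, RBF kernel with $\sigma^2 = 1$, $l = 1$, noise
variance $0.1$.

The **branching** scenario is this package's own construction (no
generative branching model exists to copy): each cell carries a fate
label; the second latent coordinate is 0 before the branch point (the
capture-grid midpoint) and ramps linearly to $\pm d$ (default $d = 2$
lengthscales) over one lengthscale of pseudotime, staying there — fates
commit and remain separated, so branch variation genuinely competes with
temporal variation instead of being collinear with it. For the 1-D-vs-2-D
comparison the fits use a capture-time prior variance of $0.1$, the value
used in the qPCR branching analysis that this scenario mirrors.

What the generator deliberately does **not** emulate: count-level
sampling (negative binomial, dropout), library-size and batch artefacts,
gene-specific mean functions, or non-Gaussian noise. Passing tests on
these simulations therefore demonstrate correctness of the inference
machinery under the model's own assumptions, not robustness to the full
messiness of real scRNA-seq data — on real data the log transform and
gene filtering (`select_variable_genes()`, normalized dispersion with
binned z-scoring, 20 bins by default, fewer when genes are scarce) are
doing real work that the simulations bypass.

## Evaluation statistics

* `spearman()` — rank correlation between inferred pseudotime and capture
  time (ties by average ranks). Pseudotime is identifiable only up to a
  monotone transformation in the absence of a prior; with the capture-time
  prior no post-hoc alignment is applied, and comparisons report $|\rho|$
  where sign ambiguity matters.
* `roughness()` — the per-gene roughness statistic under an ordering:
  profiles are z-scored (sample standard deviation) and the
  root-mean-square of consecutive differences is returned; constant
  profiles give 0 by convention. The z-scoring makes the statistic
  scale-free and comparable across genes; this normalisation is an
  explicit convention of this package, chosen because the statistic's
  original reference does not restate one. Held-out evaluation orders
  genes excluded from fitting by the fitted posterior means.
* `adjusted_rand_index()` — chance-corrected partition agreement
  (permutation model), used to compare k-means clusterings of the latent
  space with reference labels; 1 for identical partitions.
* `peak_time()` — for periodic fits, the argmax of the posterior
  predictive mean over one period on a uniform grid (default 128 points),
  refined by a three-point quadratic interpolation on the circular
  neighbourhood and reported modulo $\lambda$.

## Problem sizes and runtime

The shipped tests and the acceptance script use desk-scale problems
chosen to exercise every code path at tight tolerances: objective
exactness and bound checks on 6–12 cells, gradient checks on 10 cells,
recovery studies on 100 cells × 20 genes with $M = 10$ (10 seeded
replicates), branching comparisons on 80 cells × 16 genes, and cyclic
phase recovery on 60 cells × 6 genes. A single 100-cell variational fit
takes on the order of a second; the complete acceptance computation runs
in well under a minute. Cost scales as $O(GCM^2)$ per objective
evaluation, so the same code handles much larger matrices by keeping $M$
fixed while $C$ grows.

## Known limitations

* The factorised Gaussian $q(t)$ can understate posterior uncertainty,
  particularly when several orderings explain the data comparably;
  variational posterior variances should be read as lower bounds on the
  true spread.
* The optimiser sees a multimodal landscape (cell orderings are discrete
  relabelings); restarts mitigate but do not eliminate local optima.
  Branching fits are the most affected, which is why multiple restarts
  and informative priors matter there.
* FITC is provided for comparison, not recommendation: it can exceed the
  exact evidence and jointly optimising its inducing points invites
  overfitting.
* The periodic kernel is one-dimensional; cyclic-plus-branching latent
  spaces are out of scope.
* Raw counts are not modelled; inputs are assumed variance-stabilised
  (e.g. `log1p`), with `transform = "log1p"` available at read time.
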