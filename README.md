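# gptime

Scalable Bayesian pseudotime inference for single-cell expression data,
using a Gaussian-process latent variable model (GPLVM) with an
**informative capture-time prior** and **sparse variational inference**.

## The problem

Cells profiled in a single-cell experiment are snapshots of a dynamic
process — differentiation, infection response, the cell cycle — taken at
unknown points of progress. *Pseudotime* assigns each cell a latent
coordinate `t_c` recovering that progress from expression similarity.
When the experiment is a time course, the capture time of each cell is
informative about its pseudotime, and a Bayesian model can use it as a
prior rather than discard it.

gptime models each gene's log-expression as a GP-distributed function of
pseudotime,

    y_g = f_g(t) + eps,   f_g ~ GP(0, sigma^2 k(t, t')),   eps ~ N(0, sigma_noise^2),

with a per-cell prior `t_c ~ N(tau_c, sigma_t^2)` centred on the capture
time `tau_c`. Inference maximises an exact sparse variational bound (VFE)
over a factorised Gaussian posterior `q(t)` — or, for comparison, the
FITC objective — at cost `O(G C M^2)` for `C` cells, `G` genes and
`M << C` inducing points, so the same model scales from plates to
droplet-scale matrices. Extra latent dimensions (without the capture-time
prior) let the model separate pseudotime from branching structure, and a
periodic kernel handles cell-cycle data, including per-gene peak-time
estimation.

The package is aimed at analysts of time-course single-cell (or bulk)
expression data who want probabilistic pseudotime with uncertainty, and
at method developers who need a reference implementation of the
VFE/FITC sparse objectives with informative latent priors, their
kernel expectations, and analytic gradients — all tested against
independent oracles.

## Worked example

Simulate a 100-cell time course captured at days 0–3 (25 genes drawn from
a smooth GP with observation noise), fit on 20 genes, and evaluate:

```r
library(gptime)

sim   <- simulate_expression(sim_spec(n_cells = 100, n_genes = 25, seed = 42))
prior <- capture_time_prior(sim$capture_times, prior_var = 0.25)
fit   <- gp_fit(sim$Y[, 1:20], prior, kernel = kernel_spec("rbf"),
                config = fit_config(n_inducing = 10, seed = 42))
fit
#> <gp_fit> VFE/variational: 100 cells, 20 genes, Q = 1, M = 10
#>   bound = -1125.3786  (restart 1/1, converged: TRUE)
#>   kernel: rbf  noise_var = 0.1053
```

The one-row model summary shows the recovered hyperparameters (the
generator used `sigma^2 = 1`, `l = 1`, noise `0.1`) and the rank
agreement between inferred pseudotime and capture time:

```r
glance(fit)[, c("objective", "variance", "lengthscale", "noise_var",
                "spearman_vs_capture")]
#> # A tibble: 1 × 5
#>   objective variance lengthscale noise_var spearman_vs_capture
#>       <dbl>    <dbl>       <dbl>     <dbl>               <dbl>
#> 1    -1125.    0.806       0.943     0.105               0.912
```

`tidy()` gives one row per cell with the posterior mean and variance of
its pseudotime — cells captured at the same day are spread out along the
trajectory, which is the point of the exercise:

```r
head(tidy(fit), 4)
#> # A tibble: 4 × 4
#>   cell_id capture_time pseudotime pseudotime_var
#>   <chr>          <dbl>      <dbl>          <dbl>
#> 1 cell_1             0      0.659        0.00198
#> 2 cell_2             0     -0.176        0.00275
#> 3 cell_3             0      0.280        0.00290
#> 4 cell_4             0      0.238        0.00272

spearman(tidy(fit)$pseudotime, sim$cell_info$true_pseudotime)
#> [1] 0.9985719
```

The inferred ordering tracks the *true* (simulated) pseudotime almost
perfectly (Spearman 0.999) even though its agreement with the coarse
4-level capture time is necessarily lower (0.912). The five held-out
genes are smooth under the inferred ordering:

```r
evaluate_ordering(tidy(fit)$pseudotime, sim$capture_times,
                  heldout_Y = sim$Y[, 21:25])
#> <ordering_evaluation> Spearman vs capture = 0.912; mean held-out roughness = 0.739 (5 genes)
```

`autoplot(fit)` plots pseudotime against capture time;
`plot_gene_profiles(fit)` overlays posterior predictive gene curves
(from `posterior_predict()`) on the data. For branching data, fit with
`latent_dims = 2` and compare 1-D and 2-D fits with
`branching_recovery_check()`; for cell-cycle data use
`kernel_spec("periodic", period = ...)` and recover per-gene peak times
with `peak_time()`.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
GPTIME=$(Rscript -e 'cat(system.file("exec", "gptime.R", package = "gptime"))')
Rscript $GPTIME simulate --n-cells 100 --n-genes 20 --seed 1 --out sim/
Rscript $GPTIME fit --expression sim/expression.csv --metadata sim/metadata.tsv \
        --prior-var 0.25 --n-inducing 10 --seed 1 --out fit/
Rscript $GPTIME evaluate --pseudotime fit/pseudotime.tsv --metadata sim/metadata.tsv --out eval/
```

Each run writes a `run_manifest.json` (resolved options, input digests,
versions) before computing; exit codes are 0/1/2 for
success/runtime/usage errors.

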