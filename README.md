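# dynocov

Bayesian estimation of **dynamic covariance** — an input-dependent covariance
matrix Σ(x) for multivariate series — with **generalised Wishart processes**,
for researchers in neuroscience, computational psychiatry and econometrics
who need more than a sliding-window estimate: a full posterior distribution
over the covariance process, on possibly unevenly spaced inputs, with a
principled test for whether any pair of variables is dynamically correlated.

## The model

For d variables and v degrees of freedom, draw d·v independent latent
Gaussian processes f_jl ~ GP(0, κ_θ) and set, at every input x_i,

    Σ(x_i) = Σ_{l=1..v} L f_l(x_i) f_l(x_i)' L',      y_i ~ N_d(0, Σ(x_i)),

with L the lower Cholesky factor of a scale matrix V = LL'. When
κ(x, x) = 1 the marginal of Σ(x) is Wishart(V, v). The kernel κ_θ sets the
character of the dynamics (RBF: smooth; Matérn-1/2: rough; periodic /
locally periodic: repeating; an RBF + Matérn-1/2 sum for mixed time scales).
Free entries of L get standard-normal priors; kernel hyperparameters get
log-normal priors.

Three inference backends share one interface:

* `run_smc()` — **adaptive-tempering Sequential Monte Carlo** (the
  recommended sampler): particles start at the prior (β = 0), and each
  iteration re-weights by the likelihood raised to an increment Δβ chosen so
  the effective sample size hits a target fraction, resamples, and mutates
  every particle with tempered Gibbs cycles until β = 1. Robust to the
  multimodal posteriors composite kernels induce, and returns a log-evidence
  estimate.
* `run_mcmc()` — Gibbs MCMC: elliptical slice sampling for the latent GPs,
  random-walk Metropolis for hyperparameters and scale, PSRF-monitored
  burn-in over multiple chains.
* `fit_vi()` — a simplified variational baseline (whitened full-rank
  Gaussian posteriors per latent GP, point-estimated hyperparameters, Adam).

Plus: synthetic-data generators with known ground truth
(`simulate_gwp_prior()`, `simulate_state_switching()`), evaluation metrics
(`evaluate_fit()`: covariance MSE of the posterior mean and of posterior
samples, average predictive log-likelihood, Gaussian KL), and
`test_dynamics()`, which classifies each variable pair as uncorrelated,
statically correlated (S) or dynamically correlated (D) from per-input 95%
highest-density intervals expanded by a ±0.005 region of practical
equivalence.

## Worked example: recovering a switching covariance

The state-switching benchmark draws 600 observations of three variables
whose true covariance alternates every 50 observations between uncorrelated
and equicorrelated (ρ = 0.8, unit variances); the first 300 observations
(inputs on [0, 1), so one on/off cycle spans 1/3 input units) are used for
inference with a periodic kernel.

```r
library(dynocov)

bundle <- simulate_state_switching(seed = 101)
split  <- train_test_split(bundle, n_train = 300)

model <- gwp_model(d = 3, v = 3, kernel = gwp_kernel("periodic"))
fit <- run_smc(split$train$data, model,
               smc_control(n_particles = 300, mutation_steps = 15,
                           rw_step = 0.05, seed = 5101))

glance(fit)
tidy(fit)
evaluate_fit(fit, split$train$truth)
test_dynamics(fit)
```

A run of the above prints (about four minutes on one core):

```
#> # A tibble: 1 × 10
#>   backend n_draws n_obs     d     v log_evidence n_iterations psrf_max converged
#>   <chr>     <int> <int> <int> <int>        <dbl>        <int>    <dbl> <lgl>
#> 1 smc         300   300     3     3       -1115.           19       NA TRUE
#> # A tibble: 8 × 5
#>   term               estimate  std.error conf.low conf.high
#>   <chr>                 <dbl>      <dbl>    <dbl>     <dbl>
#> 1 period                0.337 0.00000137    0.337     0.337
#> 2 period_lengthscale    3.09  0.00459       3.09      3.09
#> 3 L[1,1]                0.655 0.222         0.318     1.08
#> # ... (remaining scale-Cholesky terms)
#> # A tibble: 1 × 4
#>   mse_sigma mse_samples avg_loglik    kl
#>       <dbl>       <dbl>      <dbl> <dbl>
#> 1    0.0435      0.0589      -3.53 0.156
#> # A tibble: 3 × 5
#>   var1  var2  label   intersection_low intersection_high
#>   <chr> <chr> <chr>              <dbl>             <dbl>
#> 1 y1    y2    dynamic            0.382            0.257
#> 2 y1    y3    dynamic            0.485            0.103
#> 3 y2    y3    dynamic            0.453            0.0919
```

Read it as: the posterior mean of the period hyperparameter is ≈ 0.337 input
units — the design value is 1/3 — the posterior-mean covariance process
deviates from the truth by a mean squared error of ≈ 0.04 over all inputs
and unique matrix entries, and every variable pair is classified as
dynamically correlated (an empty intersection of the per-input posterior
intervals: `intersection_low > intersection_high`). At this desk scale the
period posterior has collapsed onto the correct mode but understates its
own spread — the tiny standard errors reflect surviving-lineage coalescence,
not genuine certainty. `autoplot(fit)` draws the posterior band of every
Σ_ij(x); `predict(fit, x_star)` propagates the posterior to the held-out
inputs for out-of-sample evaluation.

At this desk scale the period posterior is found by particle selection, and
occasionally a run settles in a long-period mode instead (the posterior is
sharply multimodal); the particle count is the reliability lever. The
reference-scale configuration (1000 particles, thousands of mutation steps)
is available via the `"reference"` preset of `run_experiment()`.

## Command line

A thin CLI over the same functions lives at `inst/cli/dynocov.R`
(subcommands: `simulate`, `fit`, `evaluate`, `test-dynamics`,
`run-experiment`; YAML configs). See the methods vignette
(`vignettes/wishart-process-methods.Rmd`) for the model, the samplers, every
tunable parameter, and the design decisions behind them.
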