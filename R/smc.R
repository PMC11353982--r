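# Adaptive-tempering Sequential Monte Carlo over Wishart-process states:
# initialise particles from the prior, then iterate incremental likelihood
# weighting, ESS-targeted temperature selection, resampling, and Gibbs
# mutation until the tempering exponent reaches 1.

#' Control settings for the SMC backend
#'
#' @param n_particles Number of particles `s`.
#' @param ess_fraction Target fraction `a` of `s` for the effective sample
#'   size when choosing the next temperature; larger values take smaller,
#'   safer temperature increments.
#' @param mutation_steps Gibbs cycles applied to every particle after each
#'   resampling. The reference configuration for full-scale runs is in the
#'   low thousands; the default here is a desk-scale value.
#' @param resampler `"systematic"` (default, lower variance) or
#'   `"multinomial"`.
#' @param rw_step Random-walk Metropolis step size inside the mutation
#'   cycles.
#' @param jitter Diagonal jitter for Gram factorisations.
#' @param max_iter Safety cap on the number of tempering iterations.
#' @param beta_schedule Optional fixed increasing temperature schedule ending
#'   at 1, overriding the adaptive choice (e.g. `1` forces a single-jump
#'   sampler, which is plain importance sampling from the prior).
#' @param seed Master seed; particles receive independent sub-seeds.
#' @return A list of class `smc_control`.
#' @export
smc_control <- function(n_particles = 1000, ess_fraction = 0.5,
                        mutation_steps = 20,
                        resampler = c("systematic", "multinomial"),
                        rw_step = 0.01, jitter = 1e-6, max_iter = 1000,
                        beta_schedule = NULL, seed = NULL) {
  resampler <- match.arg(resampler)
  stopifnot(n_particles >= 2, ess_fraction > 0, ess_fraction < 1,
            mutation_steps >= 0, rw_step > 0, max_iter >= 1)
  if (!is.null(beta_schedule)) {
    stopifnot(all(diff(c(0, beta_schedule)) > 0),
              abs(tail(beta_schedule, 1) - 1) < 1e-12)
  }
  structure(list(n_particles = as.integer(n_particles),
                 ess_fraction = ess_fraction,
                 mutation_steps = as.integer(mutation_steps),
                 resampler = resampler, rw_step = rw_step, jitter = jitter,
                 max_iter = as.integer(max_iter),
                 beta_schedule = beta_schedule, seed = seed),
            class = "smc_control")
}

#' Draw an initial particle set from the prior
#'
#' @param model A [gwp_model()].
#' @param x Input locations.
#' @param n_particles Number of particles.
#' @param seed Optional master seed (each particle gets an independent
#'   sub-seed).
#' @param jitter Diagonal jitter.
#' @return List with `states` (prior draws), uniform `log_weights`, and
#'   `beta = 0`.
#' @export
init_particles <- function(model, x, n_particles, seed = NULL,
                           jitter = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- next_subseed(n_particles)
  states <- lapply(seeds, function(s)
    sample_prior_state(model, x, seed = s, jitter = jitter))
  list(states = states,
       log_weights = rep(-log(n_particles), n_particles), beta = 0)
}

#' Effective sample size of importance weights
#'
#' `1 / sum(w^2)` over normalised weights; ranges from 1 (degenerate) to the
#' number of particles (uniform).
#'
#' @param log_weights Unnormalised log-weights.
#' @return A single numeric ESS.
#' @export
effective_sample_size <- function(log_weights) {
  if (all(!is.finite(log_weights)))
    stop("all particle weights are zero; cannot normalise")
  lw <- log_weights - max(log_weights)
  w <- exp(lw)
  w <- w / sum(w)
  1 / sum(w^2)
}

#' Incremental log-weights for a temperature increase
#'
#' Under likelihood tempering the weight ratio between successive tempered
#' targets reduces to `likelihood^delta_beta`, so the log-increment for each
#' particle is `delta_beta` times its data log-likelihood.
#'
#' @param loglik Vector of particle log-likelihoods at the full data.
#' @param delta_beta Non-negative temperature increment.
#' @return Vector of incremental log-weights.
#' @export
incremental_log_weights <- function(loglik, delta_beta) {
  stopifnot(delta_beta >= 0)
  out <- delta_beta * loglik
  out[is.nan(out)] <- -Inf
  out
}

#' Choose the next tempering exponent by effective-sample-size bisection
#'
#' Finds the largest admissible temperature increment such that the ESS of
#' the incremental weights equals `ess_fraction * s`; if even the full jump
#' to `beta = 1` keeps the ESS above the target, returns 1.
#'
#' @param loglik Particle log-likelihoods.
#' @param ess_fraction Target ESS fraction `a` in (0, 1).
#' @param current_beta Current exponent, below 1.
#' @param tol Bisection tolerance on the increment.
#' @return The new exponent, strictly greater than `current_beta`.
#' @export
next_temperature <- function(loglik, ess_fraction = 0.5, current_beta = 0,
                             tol = 1e-6) {
  stopifnot(ess_fraction > 0, ess_fraction < 1, current_beta < 1)
  if (all(!is.finite(loglik)))
    stop("no particle has a finite likelihood")
  s <- length(loglik)
  target <- ess_fraction * s
  ess_at <- function(delta) effective_sample_size(
    incremental_log_weights(loglik, delta))
  hi <- 1 - current_beta
  if (ess_at(hi) >= target) return(1)
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ess_at(mid) >= target) lo <- mid else hi <- mid
  }
  delta <- (lo + hi) / 2
  current_beta + max(delta, tol)
}

#' Resample particle indices in proportion to weights
#'
#' Systematic resampling (default) places `s` evenly spaced points on the
#' cumulative weight scale with one common uniform offset, so with uniform
#' weights every particle is kept exactly once; multinomial resampling draws
#' independently. Both are unbiased: the expected copy count of particle `i`
#' is `s * w_i`.
#'
#' @param weights Normalised weights (any non-negative vector is renormalised).
#' @param method `"systematic"` or `"multinomial"`.
#' @return Integer vector of `length(weights)` resampled indices.
#' @export
resample_indices <- function(weights,
                             method = c("systematic", "multinomial")) {
  method <- match.arg(method)
  if (any(weights < 0) || sum(weights) <= 0 || any(!is.finite(weights)))
    stop("weights must be non-negative, finite, and not all zero")
  s <- length(weights)
  w <- weights / sum(weights)
  if (method == "multinomial")
    return(sample.int(s, s, replace = TRUE, prob = w))
  u <- runif(1) / s
  pts <- u + (seq_len(s) - 1) / s
  findInterval(pts, cumsum(w)) + 1L
}

#' Mutate particles by tempered Gibbs cycles
#'
#' Each particle is advanced independently by `n_steps` Gibbs cycles with the
#' likelihood tempered to exponent `beta`, using per-particle sub-seeds so
#' results are identical whether particles are processed sequentially or
#' concurrently.
#'
#' @param states List of `gwp_state` particles.
#' @param data Data (first column x) the model is conditioned on.
#' @param model A [gwp_model()].
#' @param beta Tempering exponent in (0, 1].
#' @param n_steps Gibbs cycles per particle.
#' @param control An [smc_control()] (step size and jitter are read from it).
#' @param seeds Optional integer vector of per-particle sub-seeds.
#' @return List with mutated `states`, per-particle `loglik`, and mean
#'   acceptance rates.
#' @export
mutate_particles <- function(states, data, model, beta, n_steps,
                             control = smc_control(n_particles =
                                                     length(states)),
                             seeds = NULL) {
  dat <- as_gwp_data(data)
  Yc <- center_observations(model, dat$Y)$Yc
  if (is.null(seeds)) seeds <- next_subseed(length(states))
  stopifnot(length(seeds) == length(states))
  acc_t <- acc_L <- ll <- numeric(length(states))
  if (n_steps > 0) {
    for (i in seq_along(states)) {
      set.seed(seeds[i])
      res <- run_cycles(states[[i]], dat$x, Yc, beta, n_steps,
                        control$rw_step, control$jitter)
      states[[i]] <- res$state
      ll[i] <- res$loglik
      acc_t[i] <- res$acc_theta
      acc_L[i] <- res$acc_L
    }
  } else {
    ll <- vapply(states, function(st)
      gwp_loglik_cpp(Yc, st$F, st$L, control$jitter), numeric(1))
    acc_t[] <- NA_real_
    acc_L[] <- NA_real_
  }
  list(states = states, loglik = ll, acc_theta = mean(acc_t),
       acc_L = mean(acc_L))
}

#' Fit a Wishart process by adaptive-tempering SMC
#'
#' Initialises particles from the prior, then repeats: weight by the
#' incremental tempered likelihood, pick the next temperature so the
#' effective sample size hits `ess_fraction * n_particles`, resample, and
#' mutate every particle with tempered Gibbs cycles. On reaching `beta = 1`
#' the final (post-resampling, post-mutation) particles are returned as
#' posterior draws together with the log-evidence estimate accumulated from
#' the incremental weights.
#'
#' @param data Data frame whose first column is the input location.
#' @param model A [gwp_model()].
#' @param control An [smc_control()].
#' @return A `gwp_fit`; `glance()` reports the number of tempering
#'   iterations, the log-evidence estimate, and the final-iteration ESS; the
#'   realised temperature ladder is in `fit$history`.
#' @export
run_smc <- function(data, model, control = smc_control()) {
  stopifnot(inherits(model, "gwp_model"), inherits(control, "smc_control"))
  dat <- as_gwp_data(data)
  cen <- center_observations(model, dat$Y)
  if (!is.null(control$seed)) set.seed(control$seed)
  s <- control$n_particles

  init_seed <- next_subseed(1)
  loop_seed <- next_subseed(1)
  part <- init_particles(model, dat$x, s, seed = init_seed,
                         jitter = control$jitter)
  states <- part$states
  set.seed(loop_seed)
  loglik <- vapply(states, function(st)
    gwp_loglik_cpp(cen$Yc, st$F, st$L, control$jitter), numeric(1))

  beta <- 0
  log_evidence <- 0
  history <- list()
  iter <- 0L
  collapsed <- FALSE
  while (beta < 1 && iter < control$max_iter) {
    iter <- iter + 1L
    beta_new <- if (!is.null(control$beta_schedule)) {
      control$beta_schedule[min(iter, length(control$beta_schedule))]
    } else {
      next_temperature(loglik, control$ess_fraction, beta)
    }
    delta <- beta_new - beta
    incr <- incremental_log_weights(loglik, delta)
    mx <- max(incr)
    log_evidence <- log_evidence + mx + log(mean(exp(incr - mx)))
    ess <- effective_sample_size(incr)
    if (ess < 2) collapsed <- TRUE
    w <- exp(incr - mx)
    idx <- resample_indices(w / sum(w), control$resampler)
    states <- states[idx]
    loglik <- loglik[idx]
    mut_seeds <- next_subseed(s)
    mut <- mutate_particles(states, dat, model, beta_new,
                            control$mutation_steps, control, mut_seeds)
    states <- mut$states
    loglik <- mut$loglik
    history[[iter]] <- tibble::tibble(
      iteration = iter, beta = beta_new, delta_beta = delta, ess = ess,
      acc_theta = mut$acc_theta, acc_L = mut$acc_L)
    beta <- beta_new
  }
  if (beta < 1)
    warning("SMC stopped before beta reached 1 (max_iter hit)")

  new_gwp_fit(states = states, backend = "smc", data = dat, model = model,
              control = control, mu = cen$mu,
              diagnostics = list(
                log_evidence = log_evidence, n_iterations = iter,
                final_ess = if (iter) history[[iter]]$ess else s,
                collapsed = collapsed, reached_posterior = beta >= 1),
              history = dplyr::bind_rows(history))
}
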