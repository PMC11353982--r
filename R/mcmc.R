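# Gibbs MCMC backend: elliptical slice sampling for the latent GPs,
# random-walk Metropolis (step 0.01) on log-hyperparameters and on the free
# entries of the scale Cholesky, with PSRF-monitored burn-in.

# Thin R wrapper around the compiled Gibbs cycle. `collect_every` > 0 keeps a
# draw every that many cycles.
run_cycles <- function(state, x, Yc, beta, n_cycles, rw_step = 0.01,
                       jitter = 1e-6, collect_every = 0L,
                       blocks = c("latent", "theta", "scale")) {
  kern <- state$kernel
  pr <- kernel_prior_mat(kern)
  res <- gwp_cycles_cpp(Yc, x, state$F, log(unname(kern$params)),
                        kernel_kind_code(kern$kind), pr$meanlog, pr$sdlog,
                        state$L, beta, rw_step, jitter, as.integer(n_cycles),
                        !kern$fixed && "theta" %in% blocks,
                        as.integer(collect_every),
                        "latent" %in% blocks, "scale" %in% blocks)
  wrap_state <- function(F, logtheta, L) {
    k <- kern
    k$params[] <- exp(logtheta)
    structure(list(F = F, kernel = k, L = L), class = "gwp_state")
  }
  draws <- NULL
  if (collect_every > 0 && length(res$draws_F))
    draws <- purrr::pmap(list(res$draws_F, res$draws_theta, res$draws_L),
                         wrap_state)
  list(state = wrap_state(res$F, res$logtheta, res$L),
       loglik = res$loglik, acc_theta = res$acc_theta, acc_L = res$acc_L,
       draws = draws, draws_ll = res$draws_ll)
}

#' One Gibbs cycle over a model state
#'
#' Applies the three block updates in order: elliptical slice moves on each of
#' the `d * v` latent GP rows (targeting `p(Y|F,L)^beta * p(F|theta)`), a
#' random-walk Metropolis step on the log kernel hyperparameters (whose
#' conditional `p(F|x,theta) p(theta)` never involves `Y`), and a joint
#' random-walk Metropolis step on the free entries of the scale Cholesky.
#'
#' @param state A `gwp_state`.
#' @param data Data frame (first column x) or list with `x` and `Y`.
#' @param model The [gwp_model()].
#' @param beta Likelihood tempering exponent in `[0, 1]`; `beta = 0` leaves
#'   the joint prior invariant.
#' @param n_cycles Number of cycles to apply.
#' @param rw_step Random-walk step size.
#' @param jitter Diagonal jitter for Gram factorisations.
#' @return The updated `gwp_state` (acceptance rates in attributes
#'   `acc_theta`, `acc_L`, log-likelihood in `loglik`).
#' @export
gibbs_cycle <- function(state, data, model, beta = 1, n_cycles = 1,
                        rw_step = 0.01, jitter = 1e-6) {
  stopifnot(beta >= 0, beta <= 1)
  dat <- as_gwp_data(data)
  Yc <- center_observations(model, dat$Y)$Yc
  res <- run_cycles(state, dat$x, Yc, beta, n_cycles, rw_step, jitter)
  out <- res$state
  attr(out, "acc_theta") <- res$acc_theta
  attr(out, "acc_L") <- res$acc_L
  attr(out, "loglik") <- res$loglik
  out
}

#' Single-block Gibbs updates
#'
#' The three conditional updates that make up one [gibbs_cycle()], exposed
#' individually: `update_latent_gps()` applies one elliptical slice move to
#' each of the `d * v` latent GP rows against the tempered likelihood times
#' the GP prior; `update_hyperparams()` applies one random-walk Metropolis
#' step on the log kernel hyperparameters against `p(F | x, theta) p(theta)`
#' (a no-op for fixed kernels; the data enter only through `F`);
#' `update_scale_cholesky()` applies one joint random-walk Metropolis step
#' on the free entries of the scale Cholesky. Each update leaves the other
#' two components of the state untouched.
#'
#' @inheritParams gibbs_cycle
#' @return The updated `gwp_state`.
#' @name gibbs_blocks
NULL

#' @rdname gibbs_blocks
#' @export
update_latent_gps <- function(state, data, model, beta = 1, n_cycles = 1,
                              jitter = 1e-6) {
  gibbs_block(state, data, model, beta, n_cycles, 0.01, jitter, "latent")
}

#' @rdname gibbs_blocks
#' @export
update_hyperparams <- function(state, data, model, beta = 1, n_cycles = 1,
                               rw_step = 0.01, jitter = 1e-6) {
  gibbs_block(state, data, model, beta, n_cycles, rw_step, jitter, "theta")
}

#' @rdname gibbs_blocks
#' @export
update_scale_cholesky <- function(state, data, model, beta = 1, n_cycles = 1,
                                  rw_step = 0.01, jitter = 1e-6) {
  gibbs_block(state, data, model, beta, n_cycles, rw_step, jitter, "scale")
}

gibbs_block <- function(state, data, model, beta, n_cycles, rw_step, jitter,
                        block) {
  stopifnot(beta >= 0, beta <= 1, rw_step > 0)
  dat <- as_gwp_data(data)
  Yc <- center_observations(model, dat$Y)$Yc
  res <- run_cycles(state, dat$x, Yc, beta, n_cycles, rw_step, jitter,
                    blocks = block)
  out <- res$state
  attr(out, "acc_theta") <- res$acc_theta
  attr(out, "acc_L") <- res$acc_L
  attr(out, "loglik") <- res$loglik
  out
}

#' Control settings for the Gibbs MCMC backend
#'
#' Defaults mirror a long-run configuration: four chains, random-walk step
#' 0.01, thinning 1000, 250 retained samples per chain, and burn-in determined
#' automatically by the potential scale reduction factor dropping below 1.1
#' for all monitored scalars. Reduce `thinning` and use a numeric `burn_in`
#' for quick exploratory runs.
#'
#' @param n_chains Number of independent chains (at least 2 when PSRF is
#'   used).
#' @param rw_step Random-walk Metropolis step size for hyperparameters and the
#'   scale Cholesky.
#' @param thinning Keep one draw per `thinning` Gibbs cycles.
#' @param burn_in Either a number of cycles to discard, or `"auto"` to extend
#'   the run in batches until the PSRF criterion is met (or `burn_in_cap`
#'   cycles are reached, in which case the result is flagged non-converged).
#' @param samples_per_chain Number of retained draws subsampled uniformly
#'   without replacement from each chain after burn-in.
#' @param psrf_threshold Convergence rule: maximum PSRF over monitored scalars
#'   (covariance elements, hyperparameters, scale entries) must fall below
#'   this.
#' @param burn_in_cap Upper bound on cycles per chain under `burn_in =
#'   "auto"`.
#' @param auto_batch Draws collected per chain between PSRF checks under
#'   automatic burn-in.
#' @param jitter Diagonal jitter for Gram factorisations.
#' @param seed Master seed; chains receive independent sub-seeds.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 4, rw_step = 0.01, thinning = 1000,
                         burn_in = "auto", samples_per_chain = 250,
                         psrf_threshold = 1.1, burn_in_cap = 200000,
                         auto_batch = 50, jitter = 1e-6, seed = NULL) {
  stopifnot(n_chains >= 1, rw_step > 0, thinning >= 1, samples_per_chain >= 1,
            psrf_threshold > 1, burn_in_cap >= 1, auto_batch >= 2)
  if (identical(burn_in, "auto") && n_chains < 2)
    stop("automatic (PSRF-based) burn-in needs at least 2 chains")
  structure(list(n_chains = as.integer(n_chains), rw_step = rw_step,
                 thinning = as.integer(thinning), burn_in = burn_in,
                 samples_per_chain = as.integer(samples_per_chain),
                 psrf_threshold = psrf_threshold,
                 burn_in_cap = as.integer(burn_in_cap),
                 auto_batch = as.integer(auto_batch),
                 jitter = jitter, seed = seed),
            class = "mcmc_control")
}

# monitored scalars for one retained draw: unique Sigma elements at every
# input, hyperparameters, free scale entries
monitor_scalars <- function(state) {
  Sig <- construct_sigma(state)
  d <- dim(Sig)[1]
  keep <- which(lower.tri(matrix(0, d, d), diag = TRUE))
  sig_flat <- apply(Sig, 3, function(S) S[keep])
  c(as.numeric(sig_flat), unname(state$kernel$params),
    state$L[lower.tri(state$L, diag = TRUE)])
}

# max PSRF over columns of per-chain draw matrices (list of draws x scalars)
psrf_max <- function(chain_mats) {
  n <- nrow(chain_mats[[1]])
  if (n < 2) return(Inf)
  means <- sapply(chain_mats, colMeans)
  vars <- sapply(chain_mats, function(m) apply(m, 2, var))
  W <- rowMeans(vars)
  B <- n * apply(means, 1, var)
  r <- sqrt(((n - 1) / n * W + B / n) / W)
  r[W == 0 & B == 0] <- 1
  r[W == 0 & B > 0] <- Inf
  max(r)
}

#' Gelman–Rubin potential scale reduction factor
#'
#' Computed over parallel chains of a scalar quantity as
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain variance and
#' `B` `n` times the variance of the chain means. Values near 1 indicate the
#' chains are sampling the same distribution; the conventional convergence
#' rule used throughout this package is PSRF below 1.1.
#'
#' @param chains A list of equal-length numeric vectors (one per chain), or a
#'   matrix with one chain per column.
#' @return A single numeric PSRF (`Inf`, with a warning, when the within-chain
#'   variance is zero but the chains disagree).
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(i) chains[, i])
  m <- length(chains)
  if (m < 2) stop("psrf needs at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal lengths")
  if (n < 2) stop("chains must contain at least two samples")
  W <- mean(vapply(chains, var, numeric(1)))
  B <- n * var(vapply(chains, mean, numeric(1)))
  if (W == 0) {
    if (B == 0) return(1)
    warning("zero within-chain variance; PSRF is infinite")
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a Wishart process by Gibbs MCMC
#'
#' Runs `n_chains` independent chains from prior-drawn initialisations, thins,
#' discards burn-in (fixed or PSRF-determined), and merges
#' `samples_per_chain` uniformly subsampled retained draws per chain into one
#' posterior sample.
#'
#' @param data Data frame whose first column is the input location and whose
#'   remaining columns are the observed variables.
#' @param model A [gwp_model()].
#' @param control An [mcmc_control()].
#' @return A `gwp_fit` object; `glance()` reports the maximum PSRF, whether
#'   the convergence rule was met, and acceptance rates.
#' @export
run_mcmc <- function(data, model, control = mcmc_control()) {
  stopifnot(inherits(model, "gwp_model"), inherits(control, "mcmc_control"))
  dat <- as_gwp_data(data)
  cen <- center_observations(model, dat$Y)
  if (!is.null(control$seed)) set.seed(control$seed)
  chain_seeds <- next_subseed(control$n_chains)
  pick_seed <- next_subseed(1)

  chains <- lapply(chain_seeds, function(s) {
    set.seed(s)
    list(state = sample_prior_state(model, dat$x, jitter = control$jitter),
         rng = .Random.seed, draws = list(), acc_theta = c(), acc_L = c(),
         cycles = 0L)
  })

  advance <- function(ch, n_cycles, collect_every) {
    .Random.seed <<- ch$rng
    res <- run_cycles(ch$state, dat$x, cen$Yc, beta = 1, n_cycles = n_cycles,
                      rw_step = control$rw_step, jitter = control$jitter,
                      collect_every = collect_every)
    ch$rng <- .Random.seed
    ch$state <- res$state
    ch$draws <- c(ch$draws, res$draws)
    ch$acc_theta <- c(ch$acc_theta, res$acc_theta)
    ch$acc_L <- c(ch$acc_L, res$acc_L)
    ch$cycles <- ch$cycles + as.integer(n_cycles)
    ch
  }

  converged <- TRUE
  psrf_val <- NA_real_
  if (is.numeric(control$burn_in)) {
    if (control$burn_in > 0)
      chains <- lapply(chains, advance, n_cycles = control$burn_in,
                       collect_every = 0L)
    chains <- lapply(chains, advance,
                     n_cycles = control$samples_per_chain * control$thinning,
                     collect_every = control$thinning)
    windows <- lapply(chains, `[[`, "draws")
    if (control$n_chains >= 2) {
      mats <- lapply(windows, function(d) t(sapply(d, monitor_scalars)))
      psrf_val <- psrf_max(mats)
      converged <- psrf_val < control$psrf_threshold
    }
  } else {
    # PSRF-determined burn-in: extend in batches, monitor the last half
    repeat {
      chains <- lapply(chains, advance,
                       n_cycles = control$auto_batch * control$thinning,
                       collect_every = control$thinning)
      total <- length(chains[[1]]$draws)
      half <- seq.int(floor(total / 2) + 1L, total)
      mats <- lapply(chains, function(ch)
        t(sapply(ch$draws[half], monitor_scalars)))
      psrf_val <- psrf_max(mats)
      enough <- length(half) >= control$samples_per_chain
      if (psrf_val < control$psrf_threshold && enough) break
      if (chains[[1]]$cycles >= control$burn_in_cap) {
        converged <- FALSE
        warning("burn-in cap reached with max PSRF ", round(psrf_val, 3),
                "; result flagged non-converged")
        break
      }
    }
    windows <- lapply(chains, function(ch) {
      total <- length(ch$draws)
      ch$draws[seq.int(floor(total / 2) + 1L, total)]
    })
  }

  avail <- length(windows[[1]])
  if (control$samples_per_chain > avail)
    stop("samples_per_chain (", control$samples_per_chain,
         ") exceeds the ", avail, " retained draws per chain")
  set.seed(pick_seed)
  states <- list()
  chain_id <- integer(0)
  for (c_i in seq_along(windows)) {
    keep <- sort(sample.int(avail, control$samples_per_chain))
    states <- c(states, windows[[c_i]][keep])
    chain_id <- c(chain_id, rep(c_i, control$samples_per_chain))
  }

  new_gwp_fit(states = states, backend = "mcmc", data = dat, model = model,
              control = control, mu = cen$mu,
              diagnostics = list(
                psrf_max = psrf_val, converged = converged,
                cycles_per_chain = chains[[1]]$cycles,
                acc_theta = mean(unlist(lapply(chains, `[[`, "acc_theta"))),
                acc_L = mean(unlist(lapply(chains, `[[`, "acc_L"))),
                chain = chain_id))
}
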