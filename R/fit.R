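# The gwp_fit container shared by all backends, plus broom-style accessors,
# prediction of the covariance process and observations at new inputs, and
# ggplot2 display methods.

new_gwp_fit <- function(states, backend, data, model, control, mu,
                        diagnostics = list(), history = NULL) {
  structure(list(states = states, backend = backend, x = data$x, Y = data$Y,
                 x_name = data$x_name %||% "x",
                 y_names = data$y_names %||%
                   paste0("y", seq_len(ncol(data$Y))),
                 model = model, control = control, mu = mu,
                 diagnostics = diagnostics, history = history),
            class = "gwp_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a generalised Wishart process
#'
#' Front door to the three inference backends. `backend = "smc"` (the
#' recommended default) runs the adaptive-tempering Sequential Monte Carlo
#' sampler; `"mcmc"` runs Gibbs MCMC with PSRF-monitored burn-in; `"vi"` runs
#' the simplified variational baseline.
#'
#' @param data Data frame whose first column is the input location and whose
#'   remaining columns are the observed variables (see [read_gwp_csv()]).
#' @param model A [gwp_model()].
#' @param backend One of `"smc"`, `"mcmc"`, `"vi"`.
#' @param control A matching control object ([smc_control()],
#'   [mcmc_control()], [vi_control()]); defaults to the backend's defaults.
#' @return A `gwp_fit` with posterior draws of the full model state. Use
#'   [posterior_sigma()] for covariance draws, [tidy()] for hyperparameter
#'   summaries, [glance()] for one-row diagnostics, [predict.gwp_fit()] for
#'   out-of-sample prediction, and [autoplot.gwp_fit()] to plot the estimated
#'   covariance process.
#' @export
fit_gwp <- function(data, model, backend = c("smc", "mcmc", "vi"),
                    control = NULL) {
  backend <- match.arg(backend)
  switch(backend,
         smc = run_smc(data, model, control %||% smc_control()),
         mcmc = run_mcmc(data, model, control %||% mcmc_control()),
         vi = fit_vi(data, model, control %||% vi_control()))
}

#' @export
print.gwp_fit <- function(x, ...) {
  cat(sprintf("<gwp_fit> %s backend: %d posterior draws, d = %d, v = %d, n = %d\n",
              x$backend, length(x$states), x$model$d, x$model$v,
              length(x$x)))
  print(glance(x))
  invisible(x)
}

#' Posterior draws of the covariance process
#'
#' @param fit A `gwp_fit`.
#' @param draws Optional number of posterior states to use (defaults to all).
#' @return A `d x d x n x draws` array of covariance matrices at the training
#'   inputs.
#' @export
posterior_sigma <- function(fit, draws = NULL) {
  stopifnot(inherits(fit, "gwp_fit"))
  states <- fit$states
  if (!is.null(draws)) states <- states[seq_len(min(draws, length(states)))]
  d <- fit$model$d; n <- length(fit$x)
  out <- array(0, c(d, d, n, length(states)))
  for (k in seq_along(states)) out[, , , k] <- construct_sigma(states[[k]])
  dimnames(out) <- list(fit$y_names, fit$y_names, NULL, NULL)
  out
}

#' Posterior mean of the covariance process
#'
#' @param fit A `gwp_fit`.
#' @return A `d x d x n` array, the entrywise posterior mean of `Sigma(x_i)`.
#' @export
posterior_mean_sigma <- function(fit) {
  sig <- posterior_sigma(fit)
  apply(sig, c(1, 2, 3), mean)
}

#' Predict the covariance process and observations at new inputs
#'
#' For each posterior state the latent GPs are propagated to `x_star` by the
#' noiseless GP conditional, a latent draw is taken, the covariance is
#' reconstructed, and (optionally) new observations are sampled from the
#' multivariate normal observation model.
#'
#' @param object A `gwp_fit`.
#' @param x_star Numeric vector of new input locations.
#' @param draws Number of posterior states to propagate (default all).
#' @param sample_y Also draw predictive observations.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List with `sigma` (`d x d x m x draws` array) and, when
#'   `sample_y`, `y` (`m x d x draws` array).
#' @export
predict.gwp_fit <- function(object, x_star, draws = NULL, sample_y = FALSE,
                            seed = NULL, ...) {
  stopifnot(is.numeric(x_star))
  if (!is.null(seed)) set.seed(seed)
  states <- object$states
  if (!is.null(draws)) states <- states[seq_len(min(draws, length(states)))]
  d <- object$model$d; v <- object$model$v; m <- length(x_star)
  jitter <- object$control$jitter %||% 1e-6
  sig <- array(0, c(d, d, m, length(states)))
  ystar <- if (sample_y) array(0, c(m, d, length(states))) else NULL
  if (m == 0)
    return(list(sigma = sig, y = ystar))
  for (k in seq_along(states)) {
    st <- states[[k]]
    pl <- predict_latent(st, object$x, x_star, jitter)
    ch <- tryCatch(chol(pl$cov + diag(jitter, m)), error = function(e) NULL)
    if (is.null(ch)) ch <- chol(pl$cov + diag(1e-4, m))
    Fs <- array(0, c(d, v, m))
    for (j in seq_len(d))
      for (l in seq_len(v))
        Fs[j, l, ] <- pl$mean[j, l, ] + as.numeric(t(ch) %*% rnorm(m))
    Sg <- construct_sigma(Fs, st$L)
    sig[, , , k] <- Sg
    if (sample_y) {
      for (i in seq_len(m)) {
        S <- Sg[, , i] + diag(jitter, d)
        ystar[i, , k] <- as.numeric(t(chol(S)) %*% rnorm(d))
      }
    }
  }
  list(sigma = sig, y = ystar)
}

#' @rdname fit_gwp
#' @param x A `gwp_fit`.
#' @method tidy gwp_fit
#' @export
tidy.gwp_fit <- function(x, ...) {
  kern_names <- names(x$states[[1]]$kernel$params)
  as_rows <- function(v) if (is.matrix(v)) t(v) else matrix(v, ncol = 1)
  theta <- as_rows(vapply(x$states, function(s) unname(s$kernel$params),
                          numeric(length(kern_names))))
  colnames(theta) <- kern_names
  d <- x$model$d
  lt <- which(lower.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
  Lmat <- as_rows(vapply(x$states,
                         function(s) s$L[lower.tri(s$L, diag = TRUE)],
                         numeric(nrow(lt))))
  colnames(Lmat) <- sprintf("L[%d,%d]", lt[, 1], lt[, 2])
  all <- cbind(theta, Lmat)
  purrr::map_dfr(colnames(all), function(nm) {
    v <- all[, nm]
    h <- hdi(v, 0.95)
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = h[1], conf.high = h[2])
  })
}

#' @rdname fit_gwp
#' @method glance gwp_fit
#' @export
glance.gwp_fit <- function(x, ...) {
  dg <- x$diagnostics
  tibble::tibble(
    backend = x$backend,
    n_draws = length(x$states),
    n_obs = length(x$x),
    d = x$model$d,
    v = x$model$v,
    log_evidence = dg$log_evidence %||% NA_real_,
    n_iterations = dg$n_iterations %||% dg$cycles_per_chain %||%
      dg$iterations %||% NA_integer_,
    psrf_max = dg$psrf_max %||% NA_real_,
    converged = dg$converged %||% dg$reached_posterior %||% NA,
    elbo = dg$elbo %||% NA_real_)
}

#' Tidy posterior summary of the covariance process
#'
#' @param fit A `gwp_fit`.
#' @param mass Credible mass for the highest-density intervals.
#' @return A tibble with one row per input location and variable pair
#'   (`i <= j`): posterior mean, HDI bounds.
#' @export
tidy_sigma <- function(fit, mass = 0.95) {
  sig <- posterior_sigma(fit)
  d <- dim(sig)[1]; n <- dim(sig)[3]
  pairs <- which(lower.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
  purrr::map_dfr(seq_len(nrow(pairs)), function(p) {
    i <- pairs[p, 2]; j <- pairs[p, 1] # i <= j
    draws <- sig[i, j, , , drop = TRUE]
    if (is.null(dim(draws))) draws <- matrix(draws, nrow = n)
    hh <- t(apply(draws, 1, hdi, mass = mass))
    tibble::tibble(x = fit$x,
                   var1 = fit$y_names[i], var2 = fit$y_names[j],
                   mean = rowMeans(draws),
                   conf.low = hh[, 1], conf.high = hh[, 2])
  })
}

#' Plot the estimated covariance process
#'
#' Posterior mean and highest-density band of every unique covariance element
#' as a function of the input, facetted by variable pair.
#'
#' @param object A `gwp_fit`.
#' @param mass Credible mass of the shaded band.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gwp_fit
#' @export
autoplot.gwp_fit <- function(object, mass = 0.95, ...) {
  df <- tidy_sigma(object, mass)
  df$pair <- paste0("Sigma(", df$var1, ", ", df$var2, ")")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = object$x_name, y = "covariance",
                  title = sprintf("Posterior covariance process (%s backend)",
                                  object$backend)) +
    ggplot2::theme_minimal()
}
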