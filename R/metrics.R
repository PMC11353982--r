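# Evaluation metrics for covariance-process estimates, and the HDI + ROPE
# hypothesis test that classifies variable pairs as uncorrelated, statically
# correlated, or dynamically correlated.

# mean over inputs and unique (lower-triangle-with-diagonal) entries
unique_entry_mean <- function(arr_fun, d, n) {
  keep <- lower.tri(matrix(0, d, d), diag = TRUE)
  tot <- 0
  for (i in seq_len(n)) tot <- tot + mean(arr_fun(i)[keep])
  tot / n
}

#' Mean squared error between two covariance processes
#'
#' Squared differences averaged over all inputs and over the `d(d+1)/2`
#' unique (lower-triangle-with-diagonal) matrix entries, so symmetric
#' off-diagonal entries are not double-counted.
#'
#' @param estimate,truth `d x d x n` covariance arrays of equal shape.
#' @return A single non-negative number.
#' @export
mse_sigma <- function(estimate, truth) {
  stopifnot(identical(dim(estimate), dim(truth)))
  d <- dim(truth)[1]; n <- dim(truth)[3]
  unique_entry_mean(function(i) (estimate[, , i] - truth[, , i])^2, d, n)
}

#' Mean squared error of posterior covariance samples
#'
#' The average of [mse_sigma()] over posterior samples of the covariance
#' process, evaluating the accuracy of the full posterior distribution rather
#' than just its mean.
#'
#' @param samples Either a list of `d x d x n` arrays or a `d x d x n x m`
#'   array of posterior draws.
#' @param truth `d x d x n` ground-truth covariance array.
#' @return A single non-negative number.
#' @export
mse_samples <- function(samples, truth) {
  if (is.array(samples) && length(dim(samples)) == 4)
    samples <- lapply(seq_len(dim(samples)[4]), function(k) samples[, , , k, drop = TRUE])
  if (!length(samples)) stop("no posterior samples supplied")
  samples <- lapply(samples, function(s) {
    if (length(dim(s)) != 3) array(s, dim(truth)) else s
  })
  mean(vapply(samples, mse_sigma, numeric(1), truth = truth))
}

#' Average predictive log-likelihood
#'
#' Log-likelihood of observations under the (zero-mean by default)
#' multivariate normal observation model with a given covariance process,
#' divided by the number of observations.
#'
#' @param Y `n x d` observation matrix.
#' @param Sigma `d x d x n` covariance array (typically the posterior-mean
#'   covariance process).
#' @param mean Optional `n x d` mean matrix.
#' @return Average log-likelihood per observation.
#' @export
avg_loglik <- function(Y, Sigma, mean = NULL) {
  Y <- as.matrix(Y)
  log_likelihood(Y, Sigma, mean) / nrow(Y)
}

#' Kullback–Leibler divergence between zero-mean Gaussians
#'
#' `KL(N(0, Sigma_a) || N(0, Sigma_b)) =
#' 0.5 (tr(Sigma_b^{-1} Sigma_a) - d + log det Sigma_b - log det Sigma_a)`.
#'
#' @param Sigma_a,Sigma_b Symmetric positive-definite matrices of equal size.
#' @return A single non-negative number.
#' @export
kl_mvn <- function(Sigma_a, Sigma_b) {
  Sigma_a <- as.matrix(Sigma_a); Sigma_b <- as.matrix(Sigma_b)
  d <- nrow(Sigma_a)
  stopifnot(identical(dim(Sigma_a), dim(Sigma_b)))
  cb <- chol(Sigma_b)
  ca <- chol(Sigma_a)
  tr <- sum(backsolve(cb, backsolve(cb, Sigma_a, transpose = TRUE)) *
              diag(1, d)) # tr(Sigma_b^{-1} Sigma_a)
  0.5 * (tr - d + 2 * sum(log(diag(cb))) - 2 * sum(log(diag(ca))))
}

#' Predictive Kullback–Leibler divergence of a covariance posterior
#'
#' Mean over posterior samples and inputs of the per-input Gaussian KL
#' divergence between the sampled covariance and the true covariance. With
#' `moment_match = TRUE` the posterior predictive mixture is first collapsed
#' to its moment-matched Gaussian (per input) and a single KL per input is
#' computed instead.
#'
#' @param samples List of `d x d x n` arrays or `d x d x n x m` array of
#'   posterior covariance draws at the evaluation inputs.
#' @param truth `d x d x n` true covariance array at those inputs.
#' @param moment_match Collapse the sample mixture before the divergence.
#' @return A single non-negative number.
#' @export
predictive_kl <- function(samples, truth, moment_match = FALSE) {
  if (is.array(samples) && length(dim(samples)) == 4)
    samples <- lapply(seq_len(dim(samples)[4]), function(k) samples[, , , k, drop = TRUE])
  if (!length(samples)) stop("no posterior samples supplied")
  d <- dim(truth)[1]; n <- dim(truth)[3]
  samples <- lapply(samples, function(s) array(s, dim(truth)))
  if (moment_match) {
    avg <- Reduce(`+`, samples) / length(samples)
    return(mean(vapply(seq_len(n), function(i)
      kl_mvn(avg[, , i], truth[, , i]), numeric(1))))
  }
  mean(vapply(samples, function(s)
    mean(vapply(seq_len(n), function(i)
      kl_mvn(s[, , i], truth[, , i]), numeric(1))), numeric(1)))
}

#' Highest density interval of a sample
#'
#' The shortest contiguous interval containing `ceiling(mass * m)` of the `m`
#' sorted samples.
#'
#' @param samples Numeric vector (at least 2 values).
#' @param mass Credible mass in (0, 1).
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  samples <- sort(samples[is.finite(samples)])
  m <- length(samples)
  if (m < 2) stop("hdi needs at least two samples")
  k <- ceiling(mass * m)
  if (k >= m) return(c(samples[1], samples[m]))
  widths <- samples[seq.int(k, m)] - samples[seq.int(1, m - k + 1)]
  i <- which.min(widths)
  c(samples[i], samples[i + k - 1])
}

# classify one pair from an m x n matrix of posterior draws of Sigma_ij(x)
dynamics_label <- function(draws, mass = 0.95, rope = 0.005) {
  his <- apply(draws, 2, hdi, mass = mass)
  lo <- his[1, ] - rope
  hi <- his[2, ] + rope
  if (all(lo <= 0 & hi >= 0)) return(list(label = "uncorrelated",
                                          lo = lo, hi = hi))
  int_lo <- max(lo); int_hi <- min(hi)
  if (int_lo <= int_hi) list(label = "static", lo = lo, hi = hi)
  else list(label = "dynamic", lo = lo, hi = hi)
}

#' Hypothesis test for dynamic covariance
#'
#' For every variable pair, the per-input 95% highest-density intervals of
#' the posterior covariance are expanded by the region of practical
#' equivalence (`rope`). A pair is *uncorrelated* if zero lies in every
#' expanded interval; otherwise *static* (`"S"`) if some single constant lies
#' in all of them (their intersection is nonempty); otherwise *dynamic*
#' (`"D"`). The uncorrelated check takes precedence over static, zero being a
#' valid constant.
#'
#' @param fit A `gwp_fit`, or a `d x d x n x m` array of posterior covariance
#'   draws.
#' @param mass Credible mass of the intervals.
#' @param rope Half-width of the region of practical equivalence.
#' @param detail Also return the per-input ROPE-expanded interval bounds as
#'   list columns `hdi_low` and `hdi_high`.
#' @return A tibble with one row per pair (`i < j`; diagonals excluded):
#'   `var1`, `var2`, `label`, and the intersection bounds where defined.
#' @export
test_dynamics <- function(fit, mass = 0.95, rope = 0.005, detail = FALSE) {
  sig <- if (inherits(fit, "gwp_fit")) posterior_sigma(fit) else fit
  stopifnot(length(dim(sig)) == 4)
  d <- dim(sig)[1]
  nms <- dimnames(sig)[[1]] %||% paste0("y", seq_len(d))
  out <- list()
  for (i in seq_len(d - 1)) {
    for (j in seq.int(i + 1, d)) {
      draws <- t(sig[i, j, , , drop = TRUE]) # m x n
      res <- dynamics_label(draws, mass, rope)
      row <- tibble::tibble(
        var1 = nms[i], var2 = nms[j], label = res$label,
        intersection_low = max(res$lo), intersection_high = min(res$hi))
      if (detail) {
        row$hdi_low <- list(res$lo)
        row$hdi_high <- list(res$hi)
      }
      out[[length(out) + 1]] <- row
    }
  }
  dplyr::bind_rows(out)
}

#' Evaluate a fit against a known covariance process
#'
#' Computes the standard report for simulation studies: mean squared error of
#' the posterior-mean covariance process, the sample-averaged MSE over
#' posterior draws, the average log-likelihood of the observations under the
#' posterior-mean covariance, and the predictive KL divergence.
#'
#' @param fit A `gwp_fit`.
#' @param truth `d x d x n` true covariance array at the training inputs.
#' @param Y Optional observations for the log-likelihood (defaults to the
#'   training data stored in the fit).
#' @param draws Number of posterior draws to use for the sample-based
#'   metrics.
#' @return A one-row tibble with columns `mse_sigma`, `mse_samples`,
#'   `avg_loglik`, `kl`.
#' @export
evaluate_fit <- function(fit, truth, Y = NULL, draws = NULL) {
  stopifnot(inherits(fit, "gwp_fit"))
  sig <- posterior_sigma(fit, draws)
  est <- apply(sig, c(1, 2, 3), mean)
  if (is.null(Y)) Y <- fit$Y
  tibble::tibble(
    mse_sigma = mse_sigma(est, truth),
    mse_samples = mse_samples(sig, truth),
    avg_loglik = avg_loglik(Y, est, mean = fit$mu),
    kl = predictive_kl(sig, truth))
}
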