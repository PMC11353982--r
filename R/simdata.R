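# Synthetic-data generators with known ground-truth covariance processes:
# draws from the Wishart-process prior itself, and a rapid state-switching
# design used to probe periodic kernels and out-of-sample prediction.

new_gwp_sim <- function(x, truth, Y, params) {
  d <- ncol(Y)
  data <- tibble::tibble(x = x)
  for (j in seq_len(d)) data[[paste0("y", j)]] <- Y[, j]
  structure(list(data = data, truth = truth, params = params),
            class = "gwp_sim")
}

#' @export
print.gwp_sim <- function(x, ...) {
  cat(sprintf("<gwp_sim> %s: n = %d, d = %d\n",
              x$params$design, nrow(x$data), ncol(x$data) - 1))
  invisible(x)
}

mvn_rows <- function(truth, jitter = 1e-10) {
  d <- dim(truth)[1]; n <- dim(truth)[3]
  Y <- matrix(0, n, d)
  for (i in seq_len(n))
    Y[i, ] <- as.numeric(t(chol(truth[, , i] + diag(jitter, d))) %*% rnorm(d))
  Y
}

#' Simulate datasets with a covariance process drawn from the prior
#'
#' Each dataset draws `d * v` latent GPs with an RBF kernel over `n` evenly
#' spaced inputs on `[0, 1]`, constructs the covariance process with scale
#' matrix `V`, and samples one observation row per input from
#' `MVN(0, Sigma(x_i))`. The kernel lengthscale and `V` are held fixed across
#' datasets; only the latent draws and observations differ. The defaults
#' (ten datasets, `n = 300`, `d = 3`, `v = 4`, lengthscale 0.35, `V = I`)
#' give slowly varying covariance relative to the unit input range.
#'
#' @param n_datasets Number of independent datasets.
#' @param n Observations per dataset.
#' @param d Number of variables.
#' @param v Degrees of freedom.
#' @param lengthscale RBF lengthscale of the latent GPs.
#' @param V Scale matrix (defaults to the identity).
#' @param seed Optional master seed.
#' @param jitter Diagonal jitter for the Gram factorisation.
#' @return A list of `gwp_sim` bundles, each holding `data` (tibble with
#'   columns `x`, `y1..yd`), `truth` (`d x d x n` array) and generator
#'   metadata.
#' @export
simulate_gwp_prior <- function(n_datasets = 10, n = 300, d = 3, v = 4,
                               lengthscale = 0.35, V = NULL, seed = NULL,
                               jitter = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(V)) V <- diag(d)
  stopifnot(nrow(V) == d, ncol(V) == d, lengthscale > 0, n >= 1, v >= 1)
  L <- t(chol(V))
  x <- seq(0, 1, length.out = n)
  kern <- gwp_kernel("rbf", lengthscale = lengthscale, fixed = TRUE)
  Lk <- chol_gram(kern, x, jitter)$lower
  lapply(seq_len(n_datasets), function(ds) {
    F <- array(0, c(d, v, n))
    for (j in seq_len(d))
      for (l in seq_len(v))
        F[j, l, ] <- as.numeric(Lk %*% rnorm(n))
    truth <- construct_sigma(F, L)
    Y <- mvn_rows(truth)
    new_gwp_sim(x, truth, Y,
                params = list(design = "wishart-prior", dataset = ds,
                              n = n, d = d, v = v,
                              lengthscale = lengthscale, V = V,
                              seed = seed))
  })
}

#' Simulate a state-switching covariance process
#'
#' The true covariance alternates every `block` observations between an
#' uncorrelated regime (all off-diagonals 0, starting regime) and an
#' equicorrelated regime (all off-diagonals `rho`); variances are 1
#' throughout. Inputs are evenly spaced on `[0, 2)` at the default `n = 600`,
#' so a full on/off cycle of 100 observations spans 1/3 input units — the
#' period a periodic kernel should recover. The first `n/2` observations are
#' conventionally used for inference and the rest for out-of-sample
#' prediction (see [train_test_split()]).
#'
#' @param n Total observations (must be a multiple of `block`).
#' @param block Observations per regime block.
#' @param rho Off-diagonal covariance in the correlated regime; must keep the
#'   equicorrelation matrix positive definite (`rho < 1`, `rho > -1/(d-1)`).
#' @param d Number of variables.
#' @param first_correlated Start in the correlated regime instead.
#' @param x_max Upper end of the (half-open) input range.
#' @param seed Optional seed.
#' @return A `gwp_sim` bundle.
#' @export
simulate_state_switching <- function(n = 600, block = 50, rho = 0.8, d = 3,
                                     first_correlated = FALSE, x_max = 2,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n %% block == 0, d >= 2)
  if (rho >= 1 || rho <= -1 / (d - 1))
    stop("rho = ", rho, " makes the equicorrelation matrix non positive ",
         "definite for d = ", d)
  x <- seq(0, x_max, length.out = n + 1)[seq_len(n)]
  on_block <- matrix(rho, d, d); diag(on_block) <- 1
  off_block <- diag(d)
  truth <- array(0, c(d, d, n))
  for (i in seq_len(n)) {
    b <- (i - 1) %/% block
    correlated <- if (first_correlated) b %% 2 == 0 else b %% 2 == 1
    truth[, , i] <- if (correlated) on_block else off_block
  }
  Y <- mvn_rows(truth)
  new_gwp_sim(x, truth, Y,
              params = list(design = "state-switching", n = n, block = block,
                            rho = rho, d = d,
                            first_correlated = first_correlated,
                            x_max = x_max, seed = seed))
}

#' Split a simulation bundle into contiguous train and test parts
#'
#' @param bundle A `gwp_sim`.
#' @param n_train Number of leading observations assigned to the training
#'   part; the remainder is the test part.
#' @return List with elements `train` and `test`, each a `gwp_sim`.
#' @export
train_test_split <- function(bundle, n_train = 300) {
  stopifnot(inherits(bundle, "gwp_sim"))
  n <- nrow(bundle$data)
  stopifnot(n_train >= 0, n_train <= n)
  take <- function(idx, tag) {
    dat <- bundle$data[idx, , drop = FALSE]
    Y <- as.matrix(dat[, -1, drop = FALSE])
    tr <- bundle$truth[, , idx, drop = FALSE]
    p <- bundle$params
    p$split <- tag
    new_gwp_sim(dat$x, tr, Y, p)
  }
  list(train = take(seq_len(n_train), "train"),
       test = take(seq.int(n_train + 1, length.out = n - n_train), "test"))
}
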