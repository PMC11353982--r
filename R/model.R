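#' Specify a generalised Wishart process model
#'
#' The generalised Wishart process places a nonparametric prior on an
#' input-dependent covariance matrix. Each of the `d * v` latent functions
#' `f_jl` is an independent zero-mean Gaussian process with kernel
#' `kernel`; at every input `x_i` the covariance is constructed as
#' `Sigma(x_i) = sum_l (L f_l(x_i)) (L f_l(x_i))'`, where `L` is the lower
#' Cholesky factor of the scale matrix `V = L L'`. When the kernel satisfies
#' `k(x, x) = 1`, the marginal law of `Sigma(x)` is Wishart with scale `V` and
#' `v` degrees of freedom. Observations are `y_i ~ MVN(mean_i, Sigma(x_i))`.
#'
#' The free entries of `L` (the lower triangle, diagonal included and
#' sign-unconstrained) carry independent standard-normal priors.
#'
#' @param d Number of observed variables.
#' @param v Degrees of freedom: the number of latent GP columns summed in the
#'   construction. `v < d` is allowed but yields rank-deficient covariance
#'   slices and triggers a warning.
#' @param kernel A [gwp_kernel()].
#' @param mean `"zero"` (default) or `"ema"`. With `"ema"` the exponential
#'   moving average [ema_mean()] of each column is subtracted from the data
#'   before inference (the likelihood stays zero-mean internally) and can be
#'   added back for fitted values.
#' @param ema_k Window length for the EMA mean (only used when
#'   `mean = "ema"`); the smoothing weight is `alpha = 2 / (ema_k + 1)`.
#' @return An object of class `gwp_model`.
#' @examples
#' gwp_model(d = 3, v = 4, kernel = gwp_kernel("rbf", lengthscale = 0.35))
#' @export
gwp_model <- function(d, v, kernel, mean = c("zero", "ema"), ema_k = 10) {
  mean <- match.arg(mean)
  stopifnot(is.numeric(d), d >= 1, is.numeric(v), v >= 1, ema_k >= 1,
            inherits(kernel, "gwp_kernel"))
  d <- as.integer(d); v <- as.integer(v)
  if (v < d)
    warning("v < d: covariance slices are rank-deficient (singular); ",
            "likelihood evaluations rely on diagonal jitter")
  structure(list(d = d, v = v, kernel = kernel, mean = mean,
                 ema_k = as.integer(ema_k)),
            class = "gwp_model")
}

#' @export
print.gwp_model <- function(x, ...) {
  cat(sprintf("<gwp_model> d = %d, v = %d, mean = %s\n", x$d, x$v, x$mean))
  print(x$kernel)
  invisible(x)
}

# Validate tabular input: first column is the input location x, the remaining
# columns the observed variables. Returns x, the n x d matrix Y and names.
as_gwp_data <- function(data) {
  if (is.list(data) && !is.data.frame(data) &&
      all(c("x", "Y") %in% names(data)))
    return(data)
  data <- as.data.frame(data)
  if (ncol(data) < 2)
    stop("data must have an input column followed by at least one variable")
  x <- as.numeric(data[[1]])
  Y <- as.matrix(data[, -1, drop = FALSE])
  storage.mode(Y) <- "double"
  if (any(!is.finite(x))) stop("non-finite values in the input column")
  if (any(!is.finite(Y))) stop("non-finite values in the observations")
  list(x = x, Y = Y, x_name = names(data)[1], y_names = colnames(Y))
}

# centred observations according to the model's mean function
center_observations <- function(model, Y) {
  mu <- if (model$mean == "ema") ema_mean(Y, model$ema_k) else
    matrix(0, nrow(Y), ncol(Y))
  list(Yc = Y - mu, mu = mu)
}

#' Draw a model state from the prior
#'
#' Samples kernel hyperparameters from their log-normal priors (unless the
#' kernel is fixed), the `d * v` latent GP rows from `MVN(0, K_theta)`, and
#' the free entries of the scale Cholesky from independent standard normals.
#'
#' @param model A [gwp_model()].
#' @param x Numeric vector of input locations.
#' @param seed Optional integer seed for reproducibility.
#' @param jitter Diagonal jitter for the Gram factorisation.
#' @return A `gwp_state`: list with latent array `F` (`d x v x n`), the
#'   kernel carrying the drawn hyperparameters, and the scale Cholesky `L`.
#' @export
sample_prior_state <- function(model, x, seed = NULL, jitter = 1e-6) {
  stopifnot(inherits(model, "gwp_model"))
  if (!is.null(seed)) set.seed(seed)
  kern <- model$kernel
  if (!kern$fixed) {
    pr <- kernel_prior_mat(kern)
    kern$params[] <- exp(rnorm(length(kern$params), pr$meanlog, pr$sdlog))
  }
  n <- length(x)
  Lk <- chol_gram(kern, x, jitter)$lower
  d <- model$d; v <- model$v
  F <- array(0, dim = c(d, v, n))
  for (j in seq_len(d))
    for (l in seq_len(v))
      F[j, l, ] <- as.numeric(Lk %*% rnorm(n))
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- rnorm(d * (d + 1) / 2)
  structure(list(F = F, kernel = kern, L = L), class = "gwp_state")
}

#' Build the covariance process from a latent state
#'
#' `Sigma(x_i) = sum_l (L f_l(x_i)) (L f_l(x_i))'` for every input; each slice
#' is symmetric positive semi-definite by construction.
#'
#' @param F Latent array of dimension `d x v x n` (or a `gwp_state`).
#' @param L Lower-triangular `d x d` scale Cholesky (ignored when `F` is a
#'   state).
#' @return A `d x d x n` array of covariance matrices.
#' @export
construct_sigma <- function(F, L = NULL) {
  if (inherits(F, "gwp_state")) {
    L <- F$L
    F <- F$F
  }
  stopifnot(length(dim(F)) == 3, is.matrix(L),
            nrow(L) == dim(F)[1], ncol(L) == dim(F)[1])
  gwp_sigma_cpp(F, L)
}

#' Log-likelihood of observations under a covariance process
#'
#' `sum_i log MVN(y_i | mean_i, Sigma(x_i))`. Slices that fail to factorise
#' get diagonal jitter escalated by factors of 10 up to `1e-2` before the
#' function errors.
#'
#' @param Y `n x d` observation matrix.
#' @param Sigma `d x d x n` covariance array.
#' @param mean Optional `n x d` mean matrix (defaults to zero).
#' @param jitter Initial diagonal jitter used when a slice is singular.
#' @return A single numeric log-likelihood.
#' @export
log_likelihood <- function(Y, Sigma, mean = NULL, jitter = 0) {
  Y <- as.matrix(Y)
  n <- nrow(Y); d <- ncol(Y)
  stopifnot(length(dim(Sigma)) == 3, dim(Sigma)[1] == d, dim(Sigma)[2] == d,
            dim(Sigma)[3] == n)
  if (is.null(mean)) mean <- matrix(0, n, d)
  stopifnot(nrow(mean) == n, ncol(mean) == d)
  tot <- 0
  for (i in seq_len(n)) {
    S <- Sigma[, , i, drop = TRUE]
    if (d == 1) S <- matrix(S, 1, 1)
    j <- jitter
    repeat {
      ch <- tryCatch(chol(S + diag(j, d)), error = function(e) NULL)
      if (!is.null(ch)) break
      j <- if (j == 0) 1e-8 else j * 10
      if (j > 1e-2)
        stop("covariance slice ", i, " singular even after jitter escalation")
    }
    z <- backsolve(ch, Y[i, ] - mean[i, ], transpose = TRUE)
    tot <- tot - 0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  tot
}

#' Predict the latent Gaussian processes at new inputs
#'
#' Standard noiseless GP conditional applied independently to each of the
#' `d * v` latent rows: mean `K_*x K_xx^{-1} f`, covariance
#' `K_** - K_*x K_xx^{-1} K_*x'` (shared across rows, since all latents use
#' the same kernel).
#'
#' @param state A `gwp_state` (e.g. one posterior draw).
#' @param x Training input locations the state was fitted on.
#' @param x_star New input locations.
#' @param jitter Diagonal jitter for the training Gram factorisation.
#' @return List with `mean` (`d x v x m` array) and `cov` (`m x m` matrix).
#' @export
predict_latent <- function(state, x, x_star, jitter = 1e-6) {
  stopifnot(inherits(state, "gwp_state"))
  m <- length(x_star)
  d <- dim(state$F)[1]; v <- dim(state$F)[2]
  if (m == 0)
    return(list(mean = array(0, c(d, v, 0)), cov = matrix(0, 0, 0)))
  kern <- state$kernel
  Lk <- chol_gram(kern, x, jitter)$lower
  Ksx <- outer(x_star, x, function(a, b) evaluate_kernel(kern, a, b))
  Kss <- gram_matrix(kern, x_star, jitter = 0)
  # A = K_xx^{-1/2} K_*x' via one triangular solve; then
  # mean row = A' (K_xx^{-1/2} f), cov = K_** - A'A
  A <- forwardsolve(Lk, t(Ksx))
  cov <- Kss - crossprod(A)
  mean <- array(0, c(d, v, m))
  for (j in seq_len(d))
    for (l in seq_len(v)) {
      z <- forwardsolve(Lk, state$F[j, l, ])
      mean[j, l, ] <- as.numeric(crossprod(A, z))
    }
  list(mean = mean, cov = cov)
}

#' Exponential moving average mean function
#'
#' Row `i + 1` of the output is the weighted history
#' `alpha * y_i + (1 - alpha) * y_{i-1} + ... + (1 - alpha)^{k-1} * y_{i-k+1}`
#' per column, with `alpha = 2 / (k + 1)`. The weights are used exactly as
#' written — `alpha` multiplies only the newest term and the older terms carry
#' unnormalised geometric weights — so for `k > 2` they do not sum to one;
#' `normalise = TRUE` divides each row's weights by their sum. Early rows use
#' whatever history is available (truncated weights); the first row, having no
#' history, is 0.
#'
#' @param Y `n x d` observation matrix (a data frame is accepted).
#' @param k Window length (`k = 1` reduces to the previous observation).
#' @param normalise Normalise the truncated weights to sum to one.
#' @return An `n x d` matrix of smoothed means.
#' @export
ema_mean <- function(Y, k, normalise = FALSE) {
  Y <- as.matrix(Y)
  stopifnot(k >= 1)
  k <- as.integer(k)
  n <- nrow(Y)
  alpha <- 2 / (k + 1)
  w <- c(alpha, (1 - alpha)^seq_len(k - 1))
  out <- matrix(0, n, ncol(Y))
  for (i in seq_len(n - 1)) {
    take <- min(k, i)
    ww <- w[seq_len(take)]
    if (normalise) ww <- ww / sum(ww)
    idx <- i - seq_len(take) + 1L
    out[i + 1, ] <- ww %*% Y[idx, , drop = FALSE]
  }
  out
}
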