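#' Gaussian-process covariance functions for the Wishart process
#'
#' A kernel specification bundles the kernel family, its positive
#' hyperparameters, and an independent log-normal prior for each
#' hyperparameter. The available families are
#'
#' * `"rbf"` — squared exponential, `exp(-(x - x')^2 / (2 * lengthscale^2))`;
#' * `"periodic"` — `exp(-2 sin^2(pi |x - x'| / period) / period_lengthscale^2)`;
#' * `"locally_periodic"` — the product of the periodic and RBF kernels, so a
#'   repeating structure whose shape may drift over the input range;
#' * `"matern12"` — exponential kernel in the squared-lengthscale
#'   parameterisation `exp(-|x - x'| / (2 * matern_lengthscale^2))`, giving
#'   rough, quickly-decorrelating sample paths;
#' * `"sum_rbf_matern12"` — the sum of the RBF and Matérn-1/2 kernels, used to
#'   capture slow and fast covariance changes simultaneously. Note this kernel
#'   is deliberately not normalised: `k(x, x) = 2`, and the Wishart-process
#'   scale matrix absorbs the factor.
#'
#' Hyperparameters are supplied on their natural (positive) scale. Samplers
#' propose them in log space, which preserves positivity; the log-normal prior
#' on the natural scale is exactly a normal prior on the log scale.
#'
#' @param kind Kernel family, one of `"rbf"`, `"periodic"`,
#'   `"locally_periodic"`, `"matern12"`, `"sum_rbf_matern12"`.
#' @param ... Named hyperparameters for the family (see Details); any omitted
#'   parameter defaults to 1.
#' @param prior Named list of length-2 numeric vectors `c(meanlog, sdlog)`
#'   giving the log-normal prior of each hyperparameter. Unnamed entries
#'   default to `c(0, 1)`.
#' @param fixed If `TRUE` the hyperparameters are held at their supplied
#'   values during inference (no prior draws, no Metropolis updates).
#'
#' @return An object of class `gwp_kernel`.
#' @examples
#' k <- gwp_kernel("rbf", lengthscale = 0.35)
#' evaluate_kernel(k, 0, 0.35) # exp(-1/2)
#' @export
gwp_kernel <- function(kind = c("rbf", "periodic", "locally_periodic",
                                "matern12", "sum_rbf_matern12"),
                       ..., prior = NULL, fixed = FALSE) {
  kind <- match.arg(kind)
  wanted <- kernel_param_names(kind)
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == "")))
    stop("kernel hyperparameters must be named")
  extra <- setdiff(names(dots), wanted)
  if (length(extra))
    stop("unknown hyperparameter(s) for kind '", kind, "': ",
         paste(extra, collapse = ", "))
  params <- setNames(rep(1, length(wanted)), wanted)
  for (nm in names(dots)) params[[nm]] <- as.numeric(dots[[nm]])
  if (any(!is.finite(params)) || any(params <= 0))
    stop("all kernel hyperparameters must be finite and strictly positive")
  pr <- rep(list(c(meanlog = 0, sdlog = 1)), length(wanted))
  names(pr) <- wanted
  if (!is.null(prior)) {
    bad <- setdiff(names(prior), wanted)
    if (length(bad)) stop("prior given for unknown parameter(s): ",
                          paste(bad, collapse = ", "))
    for (nm in names(prior)) {
      p <- as.numeric(prior[[nm]])
      if (length(p) != 2 || !all(is.finite(p)) || p[2] <= 0)
        stop("prior for '", nm, "' must be c(meanlog, sdlog) with sdlog > 0")
      pr[[nm]] <- c(meanlog = p[1], sdlog = p[2])
    }
  }
  structure(list(kind = kind, params = params, prior = pr,
                 fixed = isTRUE(fixed)),
            class = "gwp_kernel")
}

kernel_param_names <- function(kind) {
  switch(kind,
         rbf = "lengthscale",
         periodic = c("period", "period_lengthscale"),
         locally_periodic = c("period", "period_lengthscale", "lengthscale"),
         matern12 = "matern_lengthscale",
         sum_rbf_matern12 = c("lengthscale", "matern_lengthscale"),
         stop("unknown kernel kind: ", kind))
}

kernel_kind_code <- function(kind) {
  match(kind, c("rbf", "periodic", "locally_periodic", "matern12",
                "sum_rbf_matern12"))
}

#' @export
print.gwp_kernel <- function(x, ...) {
  cat("<gwp_kernel> ", x$kind, if (x$fixed) " (fixed)", "\n", sep = "")
  for (nm in names(x$params)) {
    pr <- x$prior[[nm]]
    cat(sprintf("  %s = %g  [log-normal prior: meanlog %g, sdlog %g]\n",
                nm, x$params[[nm]], pr[1], pr[2]))
  }
  invisible(x)
}

#' Evaluate a kernel pointwise
#'
#' Vectorised over `x` and `x_prime` (recycled to a common length).
#'
#' @param spec A [gwp_kernel()].
#' @param x,x_prime Numeric input locations.
#' @return Numeric vector of covariance values.
#' @export
evaluate_kernel <- function(spec, x, x_prime) {
  stopifnot(inherits(spec, "gwp_kernel"))
  r <- abs(x - x_prime)
  p <- spec$params
  rbf <- function(ell) exp(-r^2 / (2 * ell^2))
  per <- function(pp, lp) exp(-2 * sin(pi * r / pp)^2 / lp^2)
  m12 <- function(ell) exp(-r / (2 * ell^2))
  switch(spec$kind,
         rbf = rbf(p[["lengthscale"]]),
         periodic = per(p[["period"]], p[["period_lengthscale"]]),
         locally_periodic = per(p[["period"]], p[["period_lengthscale"]]) *
           rbf(p[["lengthscale"]]),
         matern12 = m12(p[["matern_lengthscale"]]),
         sum_rbf_matern12 = rbf(p[["lengthscale"]]) +
           m12(p[["matern_lengthscale"]]))
}

#' Gram matrix of a kernel over a set of inputs
#'
#' @param spec A [gwp_kernel()].
#' @param x Numeric vector of input locations.
#' @param jitter Non-negative value added to the diagonal for numerical
#'   stability.
#' @return The `length(x)` square covariance matrix.
#' @export
gram_matrix <- function(spec, x, jitter = 1e-6) {
  stopifnot(inherits(spec, "gwp_kernel"), is.numeric(x), length(x) >= 1,
            jitter >= 0)
  gwp_gram_cpp(kernel_kind_code(spec$kind), unname(spec$params), x, jitter)
}

# Lower Cholesky factor of the Gram matrix, escalating the jitter by factors
# of 10 (up to max_jitter) if the factorisation fails.
chol_gram <- function(spec, x, jitter = 1e-6, max_jitter = 1e-2) {
  j <- max(jitter, 1e-12)
  repeat {
    K <- gram_matrix(spec, x, j)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (!is.null(ch)) return(list(lower = t(ch), jitter = j))
    if (j >= max_jitter)
      stop("Gram matrix not positive definite even at jitter ", j,
           "; the input grid is numerically degenerate")
    j <- j * 10
  }
}

#' Log-density of the hyperparameter prior
#'
#' Sum of independent log-normal log-densities over the kernel's
#' hyperparameters, evaluated on the natural scale. Non-positive parameter
#' values return `-Inf` rather than erroring, so samplers reject them
#' naturally.
#'
#' @param spec A [gwp_kernel()].
#' @param params Optional named vector of parameter values to evaluate at;
#'   defaults to the values stored in `spec`.
#' @return A single numeric log-density.
#' @export
log_hyperprior <- function(spec, params = NULL) {
  stopifnot(inherits(spec, "gwp_kernel"))
  if (is.null(params)) params <- spec$params
  if (any(!is.finite(params)) || any(params <= 0)) return(-Inf)
  tot <- 0
  for (nm in names(spec$params)) {
    pr <- spec$prior[[nm]]
    tot <- tot + dlnorm(params[[nm]], pr[1], pr[2], log = TRUE)
  }
  tot
}

kernel_prior_mat <- function(spec) {
  mu <- vapply(spec$prior, `[[`, numeric(1), 1)
  sd <- vapply(spec$prior, `[[`, numeric(1), 2)
  list(meanlog = unname(mu), sdlog = unname(sd))
}
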