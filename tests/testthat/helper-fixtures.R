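# Shared fixtures built in code: small datasets with known covariance.

# constant-covariance observations for a d-variate toy
make_constant_data <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  d <- nrow(Sigma)
  Y <- t(t(chol(Sigma)) %*% matrix(rnorm(d * n), d, n))
  df <- data.frame(x = seq(0, 1, length.out = n))
  for (j in seq_len(d)) df[[paste0("y", j)]] <- Y[, j]
  df
}

# a tiny fixed model with known hyperparameters (no hyperparameter updates)
fixed_rbf_model <- function(d = 1, v = 1, lengthscale = 0.5) {
  gwp_model(d, v, gwp_kernel("rbf", lengthscale = lengthscale, fixed = TRUE))
}
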