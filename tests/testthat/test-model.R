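test_that("prior state draws are reproducible and correctly shaped", {
  m <- gwp_model(2, 3, gwp_kernel("rbf", lengthscale = 0.5))
  x <- seq(0, 1, length.out = 7)
  s1 <- sample_prior_state(m, x, seed = 99)
  s2 <- sample_prior_state(m, x, seed = 99)
  expect_identical(s1, s2)
  expect_equal(dim(s1$F), c(2, 3, 7))
  # d = 2: exactly 3 free scale entries, upper-right fixed at zero
  expect_identical(s1$L[1, 2], 0)
  expect_equal(sum(s1$L != 0), 3)
  # hyperparameters redrawn from the prior (differ across seeds)
  s3 <- sample_prior_state(m, x, seed = 100)
  expect_false(s1$kernel$params[["lengthscale"]] ==
                 s3$kernel$params[["lengthscale"]])
})

test_that("at a single input the latent draws are marginally standard normal", {
  m <- fixed_rbf_model(d = 1, v = 1)
  draws <- vapply(seq_len(5000), function(s)
    sample_prior_state(m, x = 0.5, seed = s)$F[1, 1, 1], numeric(1))
  ks <- suppressWarnings(stats::ks.test(draws, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("construct_sigma matches the outer-product definition", {
  # scalar case: d = v = 1, L = 1, f constant
  F <- array(3, c(1, 1, 4))
  expect_equal(as.numeric(construct_sigma(F, matrix(1))), rep(9, 4))
  # zero scale kills everything
  F2 <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
  expect_equal(construct_sigma(F2, matrix(0, 2, 2)), array(0, c(2, 2, 5)))
  # brute-force oracle: explicit sum of outer products
  L <- matrix(c(1.2, -0.4, 0, 0.8), 2, 2, byrow = FALSE)
  L[upper.tri(L)] <- 0
  S <- construct_sigma(F2, L)
  for (i in 1:5) {
    ref <- matrix(0, 2, 2)
    for (l in 1:3) {
      u <- L %*% F2[, l, i]
      ref <- ref + u %*% t(u)
    }
    expect_equal(S[, , i], ref)
    expect_equal(S[, , i], t(S[, , i]))
  }
})

test_that("construct_sigma is invariant to permuting the latent columns", {
  set.seed(5)
  F <- array(rnorm(3 * 4 * 6), c(3, 4, 6))
  L <- matrix(rnorm(9), 3, 3)
  L[upper.tri(L)] <- 0
  expect_equal(construct_sigma(F, L),
               construct_sigma(F[, c(3, 1, 4, 2), , drop = FALSE], L))
})

test_that("prior covariance marginals match direct Wishart sampling", {
  # at one input with k(x,x) = 1 the constructed Sigma is Wishart(V, v);
  # oracle: stats::rWishart first moments (v * V)
  set.seed(77)
  d <- 3; v <- 4; n_draws <- 20000
  L <- matrix(rnorm(d * d), d, d)
  L[upper.tri(L)] <- 0
  V <- L %*% t(L)
  F <- array(rnorm(d * v * n_draws), c(d, v, n_draws))
  S <- construct_sigma(F, L) # each slice: one prior draw at a single input
  emp_mean <- apply(S, c(1, 2), mean)
  wis <- stats::rWishart(n_draws, df = v, Sigma = V)
  oracle_mean <- apply(wis, c(1, 2), mean)
  se <- apply(S, c(1, 2), sd) / sqrt(n_draws)
  se_o <- apply(wis, c(1, 2), sd) / sqrt(n_draws)
  expect_true(all(abs(emp_mean - v * V) < 3 * se))
  expect_true(all(abs(emp_mean - oracle_mean) < 3 * sqrt(se^2 + se_o^2) +
                    1e-12))
})

test_that("log-likelihood matches univariate closed forms", {
  expect_equal(log_likelihood(matrix(0), array(1, c(1, 1, 1))),
               -0.5 * log(2 * pi))
  # residual zero: only the normalising constant remains
  set.seed(8)
  n <- 6; d <- 2
  Sig <- array(0, c(d, d, n))
  for (i in 1:n) {
    A <- matrix(rnorm(4), 2)
    Sig[, , i] <- A %*% t(A) + diag(0.5, 2)
  }
  M <- matrix(rnorm(n * d), n, d)
  ll <- log_likelihood(M, Sig, mean = M)
  ref <- -0.5 * sum(vapply(1:n, function(i)
    d * log(2 * pi) + determinant(Sig[, , i])$modulus, numeric(1)))
  expect_equal(ll, ref)
  # doubling a 1-d covariance at y = mean costs 0.5 log 2 per observation
  S1 <- array(1, c(1, 1, 10)); S2 <- array(2, c(1, 1, 10))
  Y0 <- matrix(0, 10, 1)
  expect_equal(log_likelihood(Y0, S2) - log_likelihood(Y0, S1),
               -0.5 * log(2) * 10)
})

test_that("log-likelihood is invariant to joint row permutations", {
  set.seed(9)
  n <- 8
  Y <- matrix(rnorm(n * 2), n, 2)
  Sig <- array(0, c(2, 2, n))
  for (i in 1:n) {
    A <- matrix(rnorm(4), 2)
    Sig[, , i] <- A %*% t(A) + diag(2)
  }
  p <- sample(n)
  expect_equal(log_likelihood(Y, Sig),
               log_likelihood(Y[p, ], Sig[, , p]))
})

test_that("compiled likelihood agrees with the R reference", {
  set.seed(10)
  d <- 3; v <- 4; n <- 12
  F <- array(rnorm(d * v * n), c(d, v, n))
  L <- matrix(rnorm(d * d), d, d); L[upper.tri(L)] <- 0
  Y <- matrix(rnorm(n * d), n, d)
  Sig <- construct_sigma(F, L)
  expect_equal(dynocov:::gwp_loglik_cpp(Y, F, L, 1e-6),
               log_likelihood(Y, Sig, jitter = 1e-6), tolerance = 1e-8)
})

test_that("latent prediction interpolates, reverts, and has a closed 1-point form", {
  # rough (well-conditioned) kernel: interpolation is exact to jitter level
  mm <- gwp_model(2, 2, gwp_kernel("matern12", matern_lengthscale = 0.6,
                                   fixed = TRUE))
  x <- seq(0, 1, length.out = 9)
  stm <- sample_prior_state(mm, x, seed = 3)
  plm <- predict_latent(stm, x, x)
  expect_equal(plm$mean, stm$F, tolerance = 1e-5)
  expect_lt(max(diag(plm$cov)), 1e-5)
  # far away (>= 20 lengthscales) the prior takes over
  m <- fixed_rbf_model(d = 2, v = 2, lengthscale = 0.4)
  st <- sample_prior_state(m, x, seed = 3)
  pf <- predict_latent(st, x, 30)
  expect_lt(max(abs(pf$mean)), 1e-6)
  expect_equal(pf$cov[1, 1], 1, tolerance = 1e-6)
  # single training point closed form
  st1 <- sample_prior_state(m, 0, seed = 4)
  k <- evaluate_kernel(st1$kernel, 0.3, 0)
  p1 <- predict_latent(st1, 0, 0.3, jitter = 1e-6)
  expect_equal(p1$mean[1, 1, 1], k * st1$F[1, 1, 1] / (1 + 1e-6),
               tolerance = 1e-9)
  # empty prediction grid
  p0 <- predict_latent(st, x, numeric(0))
  expect_equal(dim(p0$mean), c(2, 2, 0))
})

test_that("EMA mean follows the stated weighting scheme", {
  set.seed(12)
  Y <- matrix(rnorm(20), 10, 2)
  # k = 1 (alpha = 1): output row i+1 is input row i, first row zero
  e1 <- ema_mean(Y, 1)
  expect_equal(e1[2:10, ], Y[1:9, ])
  expect_equal(e1[1, ], c(0, 0))
  # k = 2 (alpha = 2/3): weights alpha and 1 - alpha sum to one, so a
  # constant column is reproduced exactly
  C <- matrix(5, 10, 1)
  expect_equal(ema_mean(C, 2)[3:10, 1], rep(5, 8))
  # k = 10: alpha = 2/11, verbatim truncated weights
  k <- 10; alpha <- 2 / (k + 1)
  expect_equal(alpha, 2 / 11)
  w <- c(alpha, (1 - alpha)^(1:9))
  e10 <- ema_mean(Y, 10)
  i <- 9 # row 10 uses rows 9..1 (9 terms available)
  expect_equal(e10[10, 1], sum(w[1:9] * Y[9:1, 1]))
  # normalised variant reproduces constants for every k
  expect_equal(ema_mean(C, 7, normalise = TRUE)[2:10, 1], rep(5, 9))
})
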