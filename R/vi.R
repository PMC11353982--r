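# Simplified variational baseline. Each latent GP row is given a full-rank
# Gaussian variational posterior in *whitened* coordinates: with K = Lk Lk'
# the latent is f = Lk w and q(w) = N(m_w, C C') with C lower triangular,
# so KL(q(f) || GP prior) = KL(N(m_w, CC') || N(0, I)) in closed form and
# the objective stays well conditioned even for very smooth kernels.
# Kernel hyperparameters, the scale Cholesky and a diagonal observation
# noise are point-estimated. The evidence lower bound
#   E_q[log p(Y | F, L, Lambda)] - sum_r KL_r + log p(theta) + log p(L)
# is estimated with a small number of reparameterised Monte Carlo draws and
# maximised with Adam.

#' Control settings for the variational baseline
#'
#' @param learning_rate Adam step size.
#' @param n_mc Monte Carlo draws per ELBO/gradient estimate.
#' @param patience Stop when the best ELBO has not improved for this many
#'   iterations.
#' @param max_iter Hard iteration cap.
#' @param restarts Independent random restarts; the run with the highest
#'   ELBO is returned.
#' @param n_posterior_draws Covariance-process draws taken from the fitted
#'   variational posterior.
#' @param lambda_init Initial diagonal observation noise.
#' @param jitter Diagonal jitter for Gram factorisations.
#' @param seed Master seed.
#' @return A list of class `vi_control`.
#' @export
vi_control <- function(learning_rate = 0.001, n_mc = 3, patience = 10000,
                       max_iter = 300000, restarts = 4,
                       n_posterior_draws = 200, lambda_init = 0.001,
                       jitter = 1e-6, seed = NULL) {
  stopifnot(learning_rate > 0, n_mc >= 1, patience >= 1, max_iter >= 1,
            restarts >= 1, lambda_init > 0)
  structure(list(learning_rate = learning_rate, n_mc = as.integer(n_mc),
                 patience = as.integer(patience),
                 max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts),
                 n_posterior_draws = as.integer(n_posterior_draws),
                 lambda_init = lambda_init, jitter = jitter, seed = seed),
            class = "vi_control")
}

# latent row index: r = (l - 1) * d + j  <->  F[j, l, ]
vi_nlatent <- function(model) model$d * model$v

vi_build_C <- function(Clow, clogd) {
  C <- Clow
  diag(C) <- exp(clogd)
  C
}

vi_pack_F <- function(model, fmat, n) {
  # fmat: (d*v) x n -> cube d x v x n
  array(t(fmat), c(n, model$d, model$v)) |> aperm(c(2, 3, 1))
}

# fresh variational state (one restart)
vi_init <- function(model, x, Yc, control) {
  n <- length(x)
  d <- model$d; v <- model$v; dv <- d * v
  kern <- model$kernel
  if (!kern$fixed) {
    pr <- kernel_prior_mat(kern)
    kern$params[] <- exp(rnorm(length(kern$params), pr$meanlog, pr$sdlog))
  }
  Sy <- cov(Yc) + diag(1e-6, d)
  L0 <- t(chol(Sy / v)) + matrix(rnorm(d * d, 0, 0.01), d, d)
  L0[upper.tri(L0)] <- 0
  list(mw = matrix(rnorm(dv * n, 0, 0.3), dv, n),
       Clow = replicate(dv, matrix(0, n, n), simplify = FALSE),
       clogd = matrix(log(0.5), dv, n),
       logtheta = log(unname(kern$params)),
       L = L0,
       loglam = rep(log(control$lambda_init), d),
       kernel = kern)
}

# whitened KL summed over latent rows, with gradients; closed form against
# the standard normal
vi_kl <- function(vstate, grad = TRUE) {
  n <- ncol(vstate$mw)
  dv <- nrow(vstate$mw)
  kl <- 0
  gClow <- if (grad) vector("list", dv) else NULL
  for (r in seq_len(dv)) {
    C <- vi_build_C(vstate$Clow[[r]], vstate$clogd[r, ])
    kl <- kl + 0.5 * (sum(C^2) + sum(vstate$mw[r, ]^2) - n -
                        2 * sum(vstate$clogd[r, ]))
    if (grad) {
      G <- C
      diag(G) <- 0
      gClow[[r]] <- G
    }
  }
  out <- list(kl = kl)
  if (grad) {
    out$gmw <- vstate$mw
    out$gClow <- gClow
    # d/d clogd of 0.5 * Cii^2 - clogd = Cii^2 - 1 (with Cii = exp(clogd))
    out$gclogd <- exp(2 * vstate$clogd) - 1
  }
  out
}

# log prior of the point-estimated hyperparameters (normal in log space) and
# scale Cholesky entries
vi_param_prior <- function(vstate) {
  kern <- vstate$kernel
  lp <- 0
  if (!kern$fixed) {
    pr <- kernel_prior_mat(kern)
    lp <- lp + sum(dnorm(vstate$logtheta, pr$meanlog, pr$sdlog, log = TRUE))
  }
  free <- vstate$L[lower.tri(vstate$L, diag = TRUE)]
  lp + sum(dnorm(free, log = TRUE))
}

#' Estimate the evidence lower bound of a variational state
#'
#' The expected log-likelihood is estimated with `n_mc` reparameterised
#' draws; the KL term between each (whitened) Gaussian variational factor
#' and its GP prior is exact. Deterministic given `seed`.
#'
#' @param vstate A variational state as produced by [fit_vi()] (component
#'   `vstate` of the fit's diagnostics): fields `mw` (`(d*v) x n` whitened
#'   means), `Clow`/`clogd` (whitened covariance factors: strict lower part
#'   and log-diagonal), `logtheta`, `L`, `loglam`, `kernel`.
#' @param data Data (first column x).
#' @param model A [gwp_model()].
#' @param n_mc Monte Carlo draws.
#' @param seed Optional seed.
#' @param include_likelihood Set to `FALSE` to return only the negative KL
#'   plus the parameter priors, e.g. to verify that `q` equal to the prior
#'   (zero whitened mean, identity factor) gives exactly zero KL.
#' @return A single numeric ELBO estimate.
#' @export
elbo_estimate <- function(vstate, data, model, n_mc = 3, seed = NULL,
                          include_likelihood = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  dat <- as_gwp_data(data)
  Yc <- center_observations(model, dat$Y)$Yc
  out <- -vi_kl(vstate, grad = FALSE)$kl
  if (include_likelihood) {
    kern <- vstate$kernel
    kern$params[] <- exp(vstate$logtheta)
    Lk <- chol_gram(kern, dat$x, 1e-6)$lower
    n <- length(dat$x)
    dv <- nrow(vstate$mw)
    lik <- 0
    for (mc in seq_len(n_mc)) {
      fmat <- matrix(0, dv, n)
      for (r in seq_len(dv)) {
        C <- vi_build_C(vstate$Clow[[r]], vstate$clogd[r, ])
        fmat[r, ] <- as.numeric(Lk %*% (vstate$mw[r, ] + C %*% rnorm(n)))
      }
      F <- vi_pack_F(model, fmat, n)
      lik <- lik + gwp_vi_likgrad_cpp(Yc, F, vstate$L,
                                      exp(vstate$loglam))$value / n_mc
    }
    out <- out + lik
  }
  out + vi_param_prior(vstate)
}

# one Adam ascent run; returns the final state and ELBO trace
vi_optimise <- function(model, x, Yc, control) {
  vs <- vi_init(model, x, Yc, control)
  n <- length(x); dv <- nrow(vs$mw); d <- model$d
  lr <- control$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  pr <- kernel_prior_mat(vs$kernel)
  ltri <- lower.tri(vs$L, diag = TRUE)
  n_theta <- if (vs$kernel$fixed) 0L else length(vs$logtheta)

  flatten <- function(v) c(v$mw, unlist(v$Clow), v$clogd,
                           if (n_theta) v$logtheta, v$L[ltri], v$loglam)
  p <- flatten(vs)
  m1 <- numeric(length(p)); m2 <- numeric(length(p))

  chol_of <- function(logtheta) {
    kern <- vs$kernel
    kern$params[] <- exp(logtheta)
    chol_gram(kern, x, control$jitter)$lower
  }

  best <- -Inf; best_iter <- 0L; trace <- numeric(0)
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    Lk <- chol_of(vs$logtheta)
    klres <- vi_kl(vs, grad = TRUE)
    lam <- exp(vs$loglam)

    gmw <- -klres$gmw
    gClow <- lapply(klres$gClow, function(g) -g)
    gclogd <- -klres$gclogd
    gL <- matrix(0, d, d)
    gloglam <- numeric(d)
    lik <- 0
    Ws <- vector("list", control$n_mc) # whitened draws, reused for theta FD
    for (mc in seq_len(control$n_mc)) {
      epsm <- matrix(rnorm(dv * n), dv, n)
      W <- vs$mw
      Cs <- vector("list", dv)
      for (r in seq_len(dv)) {
        Cs[[r]] <- vi_build_C(vs$Clow[[r]], vs$clogd[r, ])
        W[r, ] <- W[r, ] + as.numeric(Cs[[r]] %*% epsm[r, ])
      }
      Ws[[mc]] <- W
      fmat <- W %*% t(Lk) # row r: (Lk %*% W[r, ])'
      F <- vi_pack_F(model, fmat, n)
      res <- gwp_vi_likgrad_cpp(Yc, F, vs$L, lam)
      if (!is.finite(res$value)) return(list(diverged = TRUE))
      lik <- lik + res$value / control$n_mc
      gfmat <- matrix(aperm(res$gF, c(3, 1, 2)), n, dv) |> t()
      gw <- gfmat %*% Lk # chain rule through f = Lk w
      gmw <- gmw + gw / control$n_mc
      for (r in seq_len(dv)) {
        gc <- tcrossprod(gw[r, ], epsm[r, ]) / control$n_mc
        gc[upper.tri(gc)] <- 0
        dgc <- diag(gc)
        diag(gc) <- 0
        gClow[[r]] <- gClow[[r]] + gc
        gclogd[r, ] <- gclogd[r, ] + dgc * diag(Cs[[r]])
      }
      gLmc <- res$gL
      gLmc[upper.tri(gLmc)] <- 0
      gL <- gL + gLmc / control$n_mc
      gloglam <- gloglam + res$glambda * lam / control$n_mc
    }
    gL <- gL - vs$L * ltri # N(0,1) prior on free entries

    gtheta <- NULL
    if (n_theta) {
      # the kernel enters the bound only through f = Lk(theta) w; finite
      # differences reuse the same whitened draws
      h <- 1e-4
      lik_at <- function(logtheta) {
        Lkh <- chol_of(logtheta)
        tot <- 0
        for (mc in seq_len(control$n_mc)) {
          F <- vi_pack_F(model, Ws[[mc]] %*% t(Lkh), n)
          tot <- tot + gwp_vi_likgrad_cpp(Yc, F, vs$L, lam)$value /
            control$n_mc
        }
        tot
      }
      gtheta <- vapply(seq_len(n_theta), function(k) {
        up <- vs$logtheta; up[k] <- up[k] + h
        dn <- vs$logtheta; dn[k] <- dn[k] - h
        (lik_at(up) - lik_at(dn)) / (2 * h)
      }, numeric(1))
      gtheta <- gtheta - (vs$logtheta - pr$meanlog) / pr$sdlog^2
    }

    g <- c(gmw, unlist(gClow), gclogd, gtheta, gL[ltri], gloglam)
    m1 <- b1 * m1 + (1 - b1) * g
    m2 <- b2 * m2 + (1 - b2) * g^2
    step <- lr * (m1 / (1 - b1^it)) / (sqrt(m2 / (1 - b2^it)) + eps)
    p <- p + step

    off <- 0L
    take <- function(k) {
      out <- p[(off + 1):(off + k)]
      off <<- off + k
      out
    }
    vs$mw <- matrix(take(dv * n), dv, n)
    for (r in seq_len(dv)) {
      M <- matrix(take(n * n), n, n)
      M[upper.tri(M, diag = TRUE)] <- 0
      vs$Clow[[r]] <- M
    }
    vs$clogd <- matrix(take(dv * n), dv, n)
    if (n_theta) vs$logtheta <- take(n_theta)
    Lnew <- matrix(0, d, d)
    Lnew[ltri] <- take(sum(ltri))
    vs$L <- Lnew
    vs$loglam <- take(d)

    elbo <- lik - klres$kl + vi_param_prior(vs)
    trace <- c(trace, elbo)
    if (elbo > best) {
      best <- elbo
      best_iter <- it
    }
    if (it - best_iter >= control$patience) break
  }
  list(vstate = vs, elbo = best, trace = trace, iterations = it,
       diverged = FALSE)
}

#' Fit a Wishart process by variational inference
#'
#' Runs `restarts` independent Adam optimisations of the ELBO and keeps the
#' run with the highest bound. Hyperparameters and the scale Cholesky are
#' point-estimated (the variational posterior over them is a point mass);
#' the covariance-process uncertainty comes from the Gaussian variational
#' posteriors over the latent GPs. Note that the learned diagonal
#' observation noise takes part in the observation covariance
#' (`Sigma(x) + Lambda`), so on data whose covariance is nearly constant
#' part of the diagonal variance may be explained by the noise term rather
#' than the covariance process.
#'
#' @param data Data frame whose first column is the input location.
#' @param model A [gwp_model()].
#' @param control A [vi_control()].
#' @return A `gwp_fit` whose states are draws from the fitted variational
#'   posterior; `fit$diagnostics$vstate` holds the variational parameters,
#'   `$elbo` the best bound and `$lambda` the learned noise diagonal.
#' @export
fit_vi <- function(data, model, control = vi_control()) {
  stopifnot(inherits(model, "gwp_model"), inherits(control, "vi_control"))
  dat <- as_gwp_data(data)
  cen <- center_observations(model, dat$Y)
  if (!is.null(control$seed)) set.seed(control$seed)
  rseeds <- next_subseed(control$restarts)
  draw_seed <- next_subseed(1)

  runs <- lapply(rseeds, function(s) {
    set.seed(s)
    vi_optimise(model, dat$x, cen$Yc, control)
  })
  ok <- !vapply(runs, `[[`, logical(1), "diverged")
  if (!any(ok)) stop("all variational restarts diverged (non-finite ELBO)")
  runs <- runs[ok]
  bestrun <- runs[[which.max(vapply(runs, `[[`, numeric(1), "elbo"))]]
  vs <- bestrun$vstate

  # posterior draws from q
  set.seed(draw_seed)
  n <- length(dat$x); dv <- vi_nlatent(model)
  kern <- vs$kernel
  kern$params[] <- exp(vs$logtheta)
  Lk <- chol_gram(kern, dat$x, control$jitter)$lower
  Cs <- lapply(seq_len(dv), function(r)
    vi_build_C(vs$Clow[[r]], vs$clogd[r, ]))
  states <- lapply(seq_len(control$n_posterior_draws), function(k) {
    fmat <- matrix(0, dv, n)
    for (r in seq_len(dv))
      fmat[r, ] <- as.numeric(Lk %*% (vs$mw[r, ] + Cs[[r]] %*% rnorm(n)))
    structure(list(F = vi_pack_F(model, fmat, n), kernel = kern, L = vs$L),
              class = "gwp_state")
  })

  new_gwp_fit(states = states, backend = "vi", data = dat, model = model,
              control = control, mu = cen$mu,
              diagnostics = list(
                elbo = bestrun$elbo, iterations = bestrun$iterations,
                elbo_trace = bestrun$trace, vstate = vs,
                lambda = exp(vs$loglam),
                n_restarts = length(runs), converged = TRUE))
}
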