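# Dataset reading/writing, posterior serialisation (plain-text CSV plus a
# JSON sidecar), and the experiment driver that chains simulate -> fit ->
# evaluate -> test-dynamics.

#' Read a dataset from CSV
#'
#' Expects a header row; the first column is the input location, the
#' remaining columns the observed variables.
#'
#' @param path Path to a CSV file.
#' @return A tibble whose first column is the input.
#' @export
read_gwp_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2)
    stop("expected an input column plus at least one variable column in ",
         path)
  if (anyDuplicated(names(df)))
    stop("duplicate column names in ", path)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]]))
      stop("non-numeric values in column '", names(df)[j], "' of ", path)
    if (anyNA(df[[j]])) {
      row <- which(is.na(df[[j]]))[1]
      stop("missing value at row ", row, ", column '", names(df)[j],
           "' of ", path)
    }
  }
  tibble::as_tibble(df)
}

#' Write a dataset to CSV
#'
#' @param data Data frame (first column x).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gwp_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Serialise posterior covariance draws
#'
#' Writes `sigma.csv` (long format: draw, input index, input location, row,
#' col, value over the unique lower-triangle entries) and `meta.json`
#' (backend, model settings, seeds, axis description) into `dir`. The format
#' is identical across backends, so downstream evaluation code does not care
#' which sampler produced it.
#'
#' @param fit A `gwp_fit`.
#' @param dir Output directory (created if missing).
#' @param draws Optional cap on the number of draws written.
#' @return `dir`, invisibly.
#' @export
write_posterior <- function(fit, dir, draws = NULL) {
  stopifnot(inherits(fit, "gwp_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig <- posterior_sigma(fit, draws)
  d <- dim(sig)[1]; n <- dim(sig)[3]; m <- dim(sig)[4]
  lt <- which(lower.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(m), function(k) {
    do.call(rbind, lapply(seq_len(nrow(lt)), function(p) {
      data.frame(draw = k, input = seq_len(n), x = fit$x,
                 row = unname(lt[p, 1]), col = unname(lt[p, 2]),
                 value = unname(sig[lt[p, 1], lt[p, 2], , k]))
    }))
  }))
  utils::write.csv(rows, file.path(dir, "sigma.csv"), row.names = FALSE)
  meta <- list(backend = fit$backend,
               d = fit$model$d, v = fit$model$v,
               kernel = list(kind = fit$model$kernel$kind,
                             params = as.list(fit$model$kernel$params)),
               mean = fit$model$mean,
               n_draws = m, n_inputs = n,
               variables = fit$y_names,
               seed = fit$control$seed,
               axes = "long format over draw, input, lower-triangle (row, col)",
               diagnostics = fit$diagnostics[
                 vapply(fit$diagnostics, function(z)
                   is.numeric(z) && length(z) == 1 || is.logical(z),
                   logical(1))])
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read serialised posterior covariance draws
#'
#' @param dir Directory written by [write_posterior()].
#' @return List with `sigma` (`d x d x n x m` array, symmetric slices),
#'   `x`, and the metadata list.
#' @export
read_posterior <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  rows <- utils::read.csv(file.path(dir, "sigma.csv"))
  d <- meta$d; n <- meta$n_inputs; m <- meta$n_draws
  sig <- array(0, c(d, d, n, m))
  for (r in seq_len(nrow(rows))) {
    sig[rows$row[r], rows$col[r], rows$input[r], rows$draw[r]] <- rows$value[r]
    sig[rows$col[r], rows$row[r], rows$input[r], rows$draw[r]] <- rows$value[r]
  }
  x <- rows$x[rows$draw == 1 & rows$row == 1 & rows$col == 1]
  list(sigma = sig, x = x, meta = meta)
}

default_run_config <- function() {
  list(design = "state-switching", backend = "smc", scale = "desk",
       seed = 1, d = 3, v = 4,
       kernel = list(kind = "periodic", params = list()),
       mean = "zero", ema_k = 10, n_train = 300)
}

known_config_keys <- c("design", "backend", "scale", "seed", "d", "v",
                       "kernel", "mean", "ema_k", "n_train", "out",
                       "n_particles", "mutation_steps", "ess_fraction",
                       "n_chains", "thinning", "burn_in", "samples_per_chain",
                       "rw_step", "learning_rate", "max_iter", "patience",
                       "restarts", "force")

validate_run_config <- function(config) {
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(default_run_config(), config)
  stopifnot(cfg$backend %in% c("smc", "mcmc", "vi"),
            cfg$scale %in% c("desk", "reference"))
  cfg
}

backend_control <- function(cfg) {
  full_scale <- cfg$scale == "reference"
  pick <- function(key, desk, full) cfg[[key]] %||% if (full_scale) full else desk
  switch(cfg$backend,
         smc = smc_control(
           n_particles = pick("n_particles", 200, 1000),
           mutation_steps = pick("mutation_steps", 10, 2000),
           ess_fraction = cfg$ess_fraction %||% 0.5,
           rw_step = cfg$rw_step %||% 0.01, seed = cfg$seed),
         mcmc = mcmc_control(
           n_chains = cfg$n_chains %||% 4,
           thinning = pick("thinning", 20, 1000),
           burn_in = pick("burn_in", 2000, "auto"),
           samples_per_chain = pick("samples_per_chain", 100, 250),
           rw_step = cfg$rw_step %||% 0.01, seed = cfg$seed),
         vi = vi_control(
           learning_rate = cfg$learning_rate %||% 0.001,
           max_iter = pick("max_iter", 2000, 300000),
           patience = pick("patience", 500, 10000),
           restarts = pick("restarts", 1, 4), seed = cfg$seed))
}

#' Run a simulation experiment end to end
#'
#' Simulates a dataset with a known covariance process, fits the requested
#' backend, evaluates the fit (covariance MSEs, average log-likelihood,
#' predictive KL — for the state-switching design both in-sample and
#' out-of-sample), runs the dynamics hypothesis test, and writes every
#' artifact (data CSV, posterior draws, metrics, a summary table) into the
#' output directory. The `"desk"` scale preset keeps run times short; the
#' `"reference"` preset uses the full-scale sampler settings (1000 particles,
#' thinning 1000, 250 kept per chain) and takes hours.
#'
#' @param config A named list or the path to a YAML file. Recognised keys:
#'   `design` (`"state-switching"` or `"wishart-prior"`), `backend`, `scale`
#'   (`"desk"`/`"reference"`), `seed`, `d`, `v`, `kernel` (`kind`, `params`),
#'   `mean`, `n_train`, plus backend-specific overrides
#'   (`n_particles`, `mutation_steps`, `n_chains`, `thinning`, ...).
#' @param out Output directory.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, a list with the fit, the metrics tibble, and the
#'   dynamics table.
#' @export
run_experiment <- function(config = list(), out, force = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config)
  if (dir.exists(out) && length(dir(out)) && !force)
    stop("output directory ", out, " is not empty; use force = TRUE")
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  set.seed(cfg$seed)
  sim_seed <- next_subseed(1)
  fit_seed <- next_subseed(1)

  if (cfg$design == "state-switching") {
    bundle <- simulate_state_switching(seed = sim_seed, d = cfg$d)
    split <- train_test_split(bundle, cfg$n_train)
    train <- split$train; test <- split$test
  } else {
    bundle <- simulate_gwp_prior(n_datasets = 1, d = cfg$d, v = cfg$v,
                                 seed = sim_seed)[[1]]
    train <- bundle; test <- NULL
  }
  write_gwp_csv(train$data, file.path(out, "train.csv"))

  kern <- do.call(gwp_kernel,
                  c(list(kind = cfg$kernel$kind), cfg$kernel$params))
  model <- gwp_model(cfg$d, cfg$v, kern, mean = cfg$mean, ema_k = cfg$ema_k)
  ctrl <- backend_control(cfg)
  ctrl$seed <- fit_seed
  fit <- fit_gwp(train$data, model, backend = cfg$backend, control = ctrl)
  write_posterior(fit, file.path(out, "posterior"))

  metrics <- dplyr::mutate(evaluate_fit(fit, train$truth), split = "train")
  if (!is.null(test) && nrow(test$data)) {
    write_gwp_csv(test$data, file.path(out, "test.csv"))
    pred <- predict(fit, test$data$x, seed = next_subseed(1))
    est <- apply(pred$sigma, c(1, 2, 3), mean)
    Yte <- as.matrix(test$data[, -1])
    metrics <- dplyr::bind_rows(metrics, dplyr::mutate(tibble::tibble(
      mse_sigma = mse_sigma(est, test$truth),
      mse_samples = mse_samples(pred$sigma, test$truth),
      avg_loglik = avg_loglik(Yte, est),
      kl = predictive_kl(pred$sigma, test$truth)), split = "test"))
  }
  utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)

  dyn <- test_dynamics(fit)
  utils::write.csv(dyn, file.path(out, "dynamics.csv"), row.names = FALSE)

  summary_lines <- c(
    sprintf("design: %s | backend: %s | scale: %s | seed: %d",
            cfg$design, cfg$backend, cfg$scale, cfg$seed),
    utils::capture.output(print(as.data.frame(metrics), row.names = FALSE)),
    utils::capture.output(print(as.data.frame(dyn), row.names = FALSE)))
  writeLines(summary_lines, file.path(out, "summary.txt"))
  jsonlite::write_json(cfg, file.path(out, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fit = fit, metrics = metrics, dynamics = dyn))
}
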