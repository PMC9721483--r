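#' Generate a value-fitting dataset of random experiments over the prior
#'
#' For each of `n_param` parameter draws from the uniform prior box, one
#' episode is simulated under uniformly random discrete grid actions; every
#' step contributes one record holding everything any observation
#' formulation needs (scaled measurement, step index, accumulated
#' information matrix, full history, action index) together with the
#' return-to-go `G(o_tau) = sum_{i >= tau} r_i`, which telescopes to the
#' remaining D-optimality gain. Episodes whose integration fails are
#' resampled.
#'
#' @param model a [chemostat_model()].
#' @param n_param number of parametrisations (episodes).
#' @param grid an [action_grid()].
#' @param episode an [episode_config()].
#' @param scaling a [scaling_scheme()]; the default uses sqrt-mode
#'   measurement scaling, appropriate over the prior where populations
#'   span an order of magnitude.
#' @param seed RNG seed.
#' @return object of class `value_dataset`: list of episodes, each with
#'   `meas` (scaled measurements), `actions` (scaled), `a_idx`, `fims`,
#'   `rewards`, `returns`, `params`.
#' @export
generate_value_dataset <- function(model, n_param, grid = action_grid(),
                                   episode = episode_config(),
                                   scaling = scaling_scheme(
                                     sqrt_mode = TRUE, sqrt_divisor = 7.5e5),
                                   seed = 1) {
  set.seed(seed)
  env <- oed_env(model, episode, obs_spec("IIIa"), scaling,
                 mode = "sample_prior")
  episodes <- vector("list", n_param)
  i <- 1L
  n_resampled <- 0L
  while (i <= n_param) {
    env_reset(env)
    a_idx <- integer(0)
    fims <- list(env$aug$fim)
    ok <- TRUE
    for (tau in seq_len(episode$n_steps)) {
      ai <- sample.int(grid$n_actions, 1)
      res <- env_step(env, grid$joint[ai, ])
      if (res$failed) { ok <- FALSE; break }
      a_idx <- c(a_idx, ai)
      fims[[tau + 1]] <- env$aug$fim
    }
    if (!ok) { n_resampled <- n_resampled + 1L; next }
    rec <- episode_record(env)
    rewards <- vapply(rec$transitions, `[[`, numeric(1), "r")
    episodes[[i]] <- list(meas = rec$meas, actions = rec$actions,
                          a_idx = a_idx, fims = fims, rewards = rewards,
                          returns = rev(cumsum(rev(rewards))),
                          params = rec$params_used$theta[model$params$focal])
    i <- i + 1L
  }
  # max-calibrate the information normalisers from the generated episodes
  # themselves (floored at 1) so formulation-I observations are scaled
  if (all(scaling$fim_divisors == 1)) {
    mx <- matrix(0, 3, 3)
    for (ep in episodes) for (f in ep$fims) mx <- pmax(mx, abs(f))
    scaling$fim_divisors <- pmax(mx, 1)
  }
  structure(list(episodes = episodes, grid = grid, episode = episode,
                 scaling = scaling, n_resampled = n_resampled),
            class = "value_dataset")
}

# render a value dataset under an observation formulation into regression
# arrays: flat matrix for families I/II, padded sequence arrays for III
value_dataset_inputs <- function(ds, spec, scaling = ds$scaling) {
  n_steps <- ds$episode$n_steps
  recs_per <- n_steps
  n <- length(ds$episodes) * recs_per
  G <- numeric(n); a_idx <- integer(n)
  flat <- spec$family != "III"
  Xf <- NULL; X <- NULL; lengths <- NULL; extra <- NULL
  k <- 0L
  for (ep in ds$episodes) {
    for (tau in seq_len(n_steps)) {
      k <- k + 1L
      hist <- list(tau = tau, meas = ep$meas, actions = ep$actions,
                   fim = ep$fims[[tau]], n_steps = n_steps)
      o <- build_observation(spec, hist, scaling)
      if (flat) {
        if (is.null(Xf)) Xf <- matrix(0, n, length(o))
        Xf[k, ] <- o
      } else {
        if (is.null(X)) {
          X <- array(0, c(n, n_steps, 3))
          lengths <- integer(n)
          extra <- matrix(0, n, length(o$current))
        }
        X[k, seq_len(tau), ] <- o$history
        lengths[k] <- tau
        extra[k, ] <- o$current
      }
      G[k] <- ep$returns[tau]
      a_idx[k] <- ep$a_idx[tau]
    }
  }
  if (flat) list(flat = TRUE, X = Xf, G = G, a_idx = a_idx)
  else list(flat = FALSE, X = X, lengths = lengths, extra = extra, G = G,
            a_idx = a_idx)
}

#' Fit a value function to returns and score it on a test split
#'
#' Regresses the formulation's value network (recurrent for family III) on
#' the training returns and reports the mean squared prediction error on
#' the test split, in unscaled return units, repeated over several seeds.
#'
#' @param train,test [generate_value_dataset()] objects from independent
#'   parameter draws.
#' @param spec an [obs_spec()].
#' @param hidden dense hidden widths (families I/II).
#' @param gru_units,head_units recurrent network widths (family III).
#' @param epochs,batch_size,lr regression settings.
#' @param repeats number of independent fits.
#' @param seed base RNG seed (repeat i uses `seed + i - 1`).
#' @return list with `mse` (mean over repeats), `sd`, and `per_repeat`.
#' @export
fit_and_score_value <- function(train, test, spec, hidden = c(100, 100),
                                gru_units = c(64, 64),
                                head_units = c(128, 128), epochs = 10,
                                batch_size = 256, lr = 1e-3, repeats = 5,
                                seed = 1) {
  tr <- value_dataset_inputs(train, spec)
  # the test split is rendered under the training scaling, as at deployment
  te <- value_dataset_inputs(test, spec, scaling = train$scaling)
  q_div <- train$scaling$q_target_divisor
  n_actions <- train$grid$n_actions
  mses <- vapply(seq_len(repeats), function(i) {
    set.seed(seed + i - 1)
    if (tr$flat) {
      net <- mlp(c(ncol(tr$X), hidden, n_actions))
      fit <- mlp_train(net, tr$X, tr$G / q_div, target_col = tr$a_idx,
                       epochs = epochs, batch_size = batch_size, lr = lr)
      pred <- mlp_forward(fit$net, te$X)[cbind(seq_along(te$G), te$a_idx)]
    } else {
      net <- rnet(3, ncol(tr$extra), gru_units, head_units,
                  out_dim = n_actions)
      fit <- rnet_train(net, tr$X, tr$lengths, tr$extra, tr$G / q_div,
                        target_col = tr$a_idx, epochs = epochs,
                        batch_size = batch_size, lr = lr)
      pred <- rnet_forward(fit$net, te$X, te$lengths,
                           te$extra)[cbind(seq_along(te$G), te$a_idx)]
    }
    mean((pred * q_div - te$G)^2)
  }, numeric(1))
  list(mse = mean(mses), sd = stats::sd(mses), per_repeat = mses)
}

#' Simulate a noisy measurement series under a design
#'
#' Integrates the model under the design, samples the population at the
#' interval boundaries (including t = 0) and perturbs each sample with
#' independent zero-mean Gaussian noise whose variance follows the model's
#' noise convention; negative draws are floored at zero.
#'
#' @param design an [experiment_design()].
#' @param model a [chemostat_model()] (its `noise` drives the variance).
#' @param step_duration interval length (h).
#' @param seed RNG seed.
#' @return data.frame with columns `t`, `N_true`, `N_obs`, `sd`.
#' @export
simulate_noisy_dataset <- function(design, model, step_duration = 2,
                                   seed = 1) {
  sim <- simulate_experiment(design, model, step_duration)
  N <- sim$trajectory$N
  sd <- noise_sd(N, model$noise)
  set.seed(seed)
  N_obs <- pmax(N + stats::rnorm(length(N), sd = sd), 0)
  data.frame(t = sim$trajectory$t, N_true = N, N_obs = N_obs, sd = sd)
}

# measurement standard deviation (absolute, cells/L) implied by the
# noise convention
noise_sd <- function(N, noise) {
  u <- noise$measurement_unit
  switch(noise$sigma_mode,
         quadratic = sqrt(noise$cv) * pmax(N, noise$nfloor),
         linear = sqrt(noise$cv * u * pmax(N, noise$nfloor)),
         constant = rep(sqrt(noise$cv) * u, length(N)))
}

# model-implied population at the sample times for given focal values
predicted_population <- function(log10_focal, design, model,
                                 step_duration) {
  mm <- model
  mm$params <- set_focal(mm$params, 10^log10_focal)
  sol <- fast_integrate(design_matrix(design), mm, step_duration,
                        full = TRUE)
  sol[, 4]   # column order: time, C0, C1, N, ...
}

#' Fit the focal parameters to a noisy measurement series
#'
#' Weighted nonlinear least squares over `(mu_max, K0, K1)` inside the
#' prior box, on a log10 parameter scale (the parameters span four orders
#' of magnitude), using bounded Levenberg-Marquardt with multistart
#' (box midpoint plus random interior starts). Residuals are weighted by
#' the model-implied measurement standard deviation.
#'
#' @param series data.frame from [simulate_noisy_dataset()].
#' @param design the [experiment_design()] that generated it.
#' @param model a [chemostat_model()].
#' @param step_duration interval length (h).
#' @param n_restarts multistart count.
#' @param seed seed for the random restarts.
#' @return list with `estimate` (named vector), `converged`, `ssr`.
#' @export
fit_parameters <- function(series, design, model, step_duration = 2,
                           n_restarts = 4, seed = 1) {
  pr <- parameter_prior(model$params)
  lo <- log10(pr["min", ]); hi <- log10(pr["max", ])
  resid_fn <- function(lp) {
    Nm <- try(predicted_population(lp, design, model, step_duration),
              silent = TRUE)
    if (inherits(Nm, "try-error")) return(rep(1e6, nrow(series)))
    (Nm - series$N_obs) / noise_sd(Nm, model$noise)
  }
  starts <- list((lo + hi) / 2)
  if (n_restarts > 1) {
    rs <- withr_seed(seed, matrix(stats::runif((n_restarts - 1) *
                                                 length(lo)),
                                  ncol = length(lo)))
    for (i in seq_len(nrow(rs)))
      starts[[i + 1]] <- lo + rs[i, ] * (hi - lo)
  }
  fits <- list()
  for (s in starts) {
    # tolerances are tight because weakly identified directions leave a
    # nearly flat sum of squares that default stopping rules abandon early
    fit <- try(minpack.lm::nls.lm(par = s, lower = lo, upper = hi,
                                  fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 500, ftol = 1e-15,
                                    ptol = 1e-15, gtol = 0,
                                    # finite-difference steps must clear
                                    # the ODE-solver noise floor
                                    epsfcn = 1e-6)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.finite(ssr))
      fits[[length(fits) + 1]] <- list(par = fit$par, ssr = ssr,
                                       converged = fit$info %in% 1:4)
  }
  if (length(fits) == 0)
    return(list(estimate = stats::setNames(rep(NA_real_, length(lo)),
                                           model$params$focal),
                converged = FALSE, ssr = NA_real_))
  fits <- fits[order(vapply(fits, `[[`, numeric(1), "ssr"))]
  best <- fits[[1]]
  # quasi-Newton polish of the leading solutions: the Levenberg-Marquardt
  # bound projection can pin a weakly identified parameter against the box
  # edge in a local basin short of the optimum
  ssr_fn <- function(lp) sum(resid_fn(lp)^2)
  for (cand in fits[seq_len(min(2, length(fits)))]) {
    # start strictly inside the box: line searches from a pinned bound fail
    p0 <- pmin(pmax(cand$par, lo + 1e-3), hi - 1e-3)
    pol <- try(stats::optim(p0, ssr_fn,
                            method = "L-BFGS-B", lower = lo, upper = hi,
                            control = list(maxit = 300, factr = 1e2,
                                           ndeps = rep(1e-5, length(lo)))),
               silent = TRUE)
    if (!inherits(pol, "try-error") && is.finite(pol$value) &&
        pol$value < best$ssr)
      best <- list(par = pol$par, ssr = pol$value, converged = TRUE)
  }
  # refinement rounds: Levenberg-Marquardt from the polished point (its
  # trust region re-expands there), then another quasi-Newton descent;
  # repeated while the flat valley keeps yielding
  for (round in 1:3) {
    ssr_before <- best$ssr
    ref <- try(minpack.lm::nls.lm(par = pmin(pmax(best$par, lo + 1e-3),
                                             hi - 1e-3),
                                  lower = lo, upper = hi, fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 500, ftol = 1e-15,
                                    ptol = 1e-15, gtol = 0,
                                    epsfcn = 1e-6)),
               silent = TRUE)
    if (inherits(ref, "try-error")) break
    ssr_ref <- sum(ref$fvec^2)
    if (is.finite(ssr_ref) && ssr_ref < best$ssr)
      best <- list(par = ref$par, ssr = ssr_ref, converged = TRUE)
    p1 <- pmin(pmax(best$par, lo + 1e-3), hi - 1e-3)
    pol <- try(stats::optim(p1, ssr_fn, method = "L-BFGS-B",
                            lower = lo, upper = hi,
                            control = list(maxit = 300, factr = 1e2,
                                           ndeps = rep(1e-5, length(lo)))),
               silent = TRUE)
    if (!inherits(pol, "try-error") && is.finite(pol$value) &&
        pol$value < best$ssr)
      best <- list(par = pol$par, ssr = pol$value, converged = TRUE)
    if (best$ssr > 0.99 * ssr_before) break
  }
  list(estimate = stats::setNames(10^best$par, model$params$focal),
       converged = best$converged, ssr = best$ssr)
}

#' Inference quality metrics over fit replicates
#'
#' Truth-normalised metrics over converged replicates: the normalised mean
#' squared error `mean(((theta_hat - theta)/theta)^2)` over replicates and
#' focal parameters, and the log-determinant of the sample covariance of
#' the truth-normalised estimate vectors `theta_hat/theta`.
#'
#' @param estimates matrix of fitted focal parameters, one row per
#'   converged replicate.
#' @param truth named vector of true focal values.
#' @return list with `normalised_mse`, `logdet_cov`, `n_replicates`.
#' @export
inference_metrics <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 2)
    stop("at least 2 converged replicates are required")
  rel <- sweep(estimates, 2, truth, `/`)
  nmse <- mean((rel - 1)^2)
  cv <- stats::cov(rel)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  logdet <- if (min(ev) <= 0) -Inf else sum(log(ev))
  list(normalised_mse = nmse, logdet_cov = logdet,
       n_replicates = nrow(estimates))
}

#' Full inference study of one design
#'
#' Simulates `n_replicates` independently noise-corrupted datasets under
#' the design, refits the focal parameters to each, and summarises with
#' [inference_metrics()].
#'
#' @param design an [experiment_design()].
#' @param model a [chemostat_model()].
#' @param n_replicates number of simulated datasets.
#' @param step_duration interval length (h).
#' @param n_restarts per-fit multistart count.
#' @param seed base seed; replicate i uses `seed * 1000 + i`.
#' @return list with `metrics`, `estimates` (converged replicates),
#'   `n_failed`.
#' @export
inference_study <- function(design, model, n_replicates = 30,
                            step_duration = 2, n_restarts = 4, seed = 1) {
  fits <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    series <- simulate_noisy_dataset(design, model, step_duration,
                                     seed = seed * 1000 + i)
    fits[[i]] <- fit_parameters(series, design, model, step_duration,
                                n_restarts = n_restarts,
                                seed = seed * 1000 + i)
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  est <- do.call(rbind, lapply(fits[ok], `[[`, "estimate"))
  truth <- model$params$theta[model$params$focal]
  list(metrics = inference_metrics(est, truth), estimates = est,
       n_failed = sum(!ok))
}
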