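#' Episode protocol configuration
#'
#' An experiment is a fixed number of sample-and-hold intervals; the default
#' protocol is ten two-hour intervals (a 20 h experiment).
#'
#' @param n_steps number of intervals T.
#' @param step_duration interval length in hours.
#' @export
episode_config <- function(n_steps = 10, step_duration = 2) {
  stopifnot(n_steps >= 1, step_duration > 0)
  structure(list(n_steps = n_steps, step_duration = step_duration),
            class = "episode_config")
}

#' Observation formulation
#'
#' The six observation formulations differ in what the agent sees at each
#' step:
#' * `I`: scaled measurement, the nine scaled Fisher-information entries,
#'   and (variant a) the scaled step index — a positive control that assumes
#'   knowledge of the parameters via the information matrix.
#' * `II`: scaled measurement and (variant a) the step index only — a
#'   negative control.
#' * `III`: scaled measurement (+ step index for variant a) plus the full
#'   history of scaled measurements and inputs, consumed by a recurrent
#'   network; no parameter knowledge needed.
#'
#' @param formulation one of `"Ia"`, `"Ib"`, `"IIa"`, `"IIb"`, `"IIIa"`,
#'   `"IIIb"`.
#' @export
obs_spec <- function(formulation = c("Ia", "Ib", "IIa", "IIb",
                                     "IIIa", "IIIb")) {
  formulation <- match.arg(formulation)
  structure(list(formulation = formulation,
                 family = substr(formulation, 1, nchar(formulation) - 1),
                 include_time = substr(formulation, nchar(formulation),
                                       nchar(formulation)) == "a"),
            class = "obs_spec")
}

#' Input/output scaling for the neural agents
#'
#' Network inputs are divided by fixed constants so they lie approximately
#' in \[0, 1\]: the population measurement by `population_divisor` (or, in
#' `sqrt_mode`, its square root by `sqrt_divisor`), the step index by
#' `time_divisor`, each Fisher-information element by its entry of
#' `fim_divisors`, and regression targets for the value networks by
#' `q_target_divisor`. Actions are mapped affinely from the input box onto
#' \[0, 1\].
#'
#' @param population_divisor population normaliser (cells/L).
#' @param time_divisor step-index normaliser.
#' @param fim_divisors 3 x 3 positive matrix of per-element normalisers
#'   (see [calibrate_fim_divisors()]); defaults to 1.
#' @param q_target_divisor divisor applied to value-regression targets.
#' @param sqrt_mode use `sqrt(N)/sqrt_divisor` as the scaled measurement
#'   (prior-distribution training).
#' @param sqrt_divisor normaliser in `sqrt_mode` (sqrt cells/L).
#' @export
scaling_scheme <- function(population_divisor = 50e9, time_divisor = 10,
                           fim_divisors = NULL, q_target_divisor = 100,
                           sqrt_mode = FALSE, sqrt_divisor = 1e5) {
  if (is.null(fim_divisors)) fim_divisors <- matrix(1, 3, 3)
  stopifnot(population_divisor > 0, time_divisor > 0, q_target_divisor > 0,
            sqrt_divisor > 0, all(fim_divisors > 0))
  structure(list(population_divisor = population_divisor,
                 time_divisor = time_divisor,
                 fim_divisors = fim_divisors,
                 q_target_divisor = q_target_divisor,
                 sqrt_mode = sqrt_mode, sqrt_divisor = sqrt_divisor),
            class = "scaling_scheme")
}

scale_measurement <- function(N, scaling) {
  if (scaling$sqrt_mode) sqrt(N) / scaling$sqrt_divisor
  else N / scaling$population_divisor
}

scale_action <- function(u, bounds) {
  (u - bounds[1]) / (bounds[2] - bounds[1])
}

#' Episodic RL environment over the chemostat simulator
#'
#' Wraps the augmented dynamics as an episodic environment: [env_reset()]
#' reinitialises the experiment (optionally drawing focal parameters from
#' the uniform prior), [env_step()] applies one sample-and-hold input and
#' returns the D-optimality *gain* over the interval as the reward. Because
#' the log-determinant baseline at the start of an episode is defined as 0,
#' the episode return telescopes to the final D-optimality exactly.
#'
#' @param model a [chemostat_model()].
#' @param episode an [episode_config()].
#' @param obs an [obs_spec()].
#' @param scaling a [scaling_scheme()].
#' @param mode `"fixed_nominal"` (episodes use `model$params`) or
#'   `"sample_prior"` (focal parameters drawn uniformly per episode).
#' @return an environment object of class `oed_env` with mutable episode
#'   state; interact through [env_reset()] and [env_step()].
#' @export
oed_env <- function(model, episode = episode_config(),
                    obs = obs_spec("Ia"), scaling = scaling_scheme(),
                    mode = c("fixed_nominal", "sample_prior")) {
  mode <- match.arg(mode)
  e <- new.env(parent = emptyenv())
  e$model <- model; e$episode <- episode; e$obs <- obs
  e$scaling <- scaling; e$mode <- mode
  e$active <- FALSE
  class(e) <- "oed_env"
  e
}

#' @export
print.oed_env <- function(x, ...) {
  cat("OED environment (", x$mode, "), T =", x$episode$n_steps,
      "steps of", x$episode$step_duration, "h; observation",
      x$obs$formulation, "\n")
  invisible(x)
}

#' Reset the environment and obtain the first observation
#'
#' @param env an [oed_env()].
#' @return the step-1 observation (see [build_observation()]).
#' @export
env_reset <- function(env) {
  params <- env$model$params
  if (env$mode == "sample_prior")
    params <- set_focal(params, as.numeric(sample_prior(params, 1)))
  env$params_used <- params
  env$sim_model <- env$model
  env$sim_model$params <- params
  env$aug <- augmented_init(env$sim_model)
  env$tau <- 1L
  env$logdet_prev <- 0          # baseline: log|I_0| := 0
  env$active <- TRUE
  env$failed <- FALSE
  env$meas <- scale_measurement(env$aug$state[["N"]], env$scaling)
  env$actions <- matrix(numeric(0), 0, 2)   # scaled actions applied so far
  env$transitions <- list()
  build_observation(env$obs, env_history(env), env$scaling)
}

# snapshot of everything observable up to the current step
env_history <- function(env) {
  list(tau = env$tau, meas = env$meas, actions = env$actions,
       fim = env$aug$fim, n_steps = env$episode$n_steps,
       bounds = env$model$input_bounds)
}

#' Advance the environment by one sample-and-hold interval
#'
#' @param env an [oed_env()].
#' @param a input pair `c(C0_in, C1_in)` in g/L, inside the input bounds.
#' @return list with `r` (D-optimality gain), `o_next`, `done`, and
#'   `failed` (TRUE when the integrator broke down; the episode is then
#'   flagged discarded and terminated).
#' @export
env_step <- function(env, a) {
  if (!isTRUE(env$active)) stop("environment must be reset first")
  check_input(a, env$model)
  o_prev <- build_observation(env$obs, env_history(env), env$scaling)
  out <- try(integrate_interval(env$aug, a, env$episode$step_duration,
                                env$sim_model), silent = TRUE)
  if (inherits(out, "try-error")) {
    env$failed <- TRUE
    env$active <- FALSE
    return(list(r = NA_real_, o_next = NULL, done = 1L, failed = TRUE))
  }
  env$aug <- out
  logdet <- d_optimality(env$aug$fim)
  r <- logdet - env$logdet_prev
  env$logdet_prev <- logdet
  env$meas <- c(env$meas, scale_measurement(env$aug$state[["N"]],
                                            env$scaling))
  env$actions <- rbind(env$actions,
                       scale_action(a, env$model$input_bounds))
  env$tau <- env$tau + 1L
  done <- as.integer(env$tau > env$episode$n_steps)
  o_next <- build_observation(env$obs, env_history(env), env$scaling)
  env$transitions[[length(env$transitions) + 1]] <-
    list(o = o_prev, a = a, r = r, o_next = o_next, done = done)
  if (done == 1L) env$active <- FALSE
  list(r = r, o_next = o_next, done = done, failed = FALSE)
}

#' Build the agent observation from an episode history
#'
#' Renders the current episode history under a given formulation (see
#' [obs_spec()]). Formulations `I`/`II` return a flat numeric vector of
#' length 11/10 (`Ia`/`Ib`) or 2/1 (`IIa`/`IIb`). Formulation `III` returns
#' a list with `current` (scaled measurement, + scaled step index for
#' variant a) and `history`, a `tau x 3` matrix whose row i holds the i-th
#' scaled measurement and the scaled input pair applied *before* it (zeros
#' for the first row), for consumption by a recurrent network.
#'
#' @param spec an [obs_spec()].
#' @param history list with elements `tau`, `meas` (scaled measurements so
#'   far), `actions` (scaled input pairs so far), `fim` (accumulated
#'   information matrix or NULL), `n_steps`, `bounds`.
#' @param scaling a [scaling_scheme()].
#' @export
build_observation <- function(spec, history, scaling) {
  tau <- history$tau
  y <- history$meas[tau]
  t_scaled <- (tau - 1) / scaling$time_divisor
  if (spec$family == "I") {
    if (is.null(history$fim))
      stop("formulation I requires the Fisher information in the history")
    fim_scaled <- as.numeric(history$fim / scaling$fim_divisors)
    o <- c(y, fim_scaled)
    if (spec$include_time) o <- c(o, t_scaled)
    o
  } else if (spec$family == "II") {
    if (spec$include_time) c(y, t_scaled) else y
  } else {
    hist <- cbind(history$meas[seq_len(tau)],
                  rbind(c(0, 0), history$actions[seq_len(tau - 1), ,
                                                 drop = FALSE]))
    colnames(hist) <- c("y", "u1", "u2")
    list(current = if (spec$include_time) c(y, t_scaled) else y,
         history = hist)
  }
}

#' Run one episode under a policy function
#'
#' @param env an [oed_env()].
#' @param policy function of (observation, tau) returning an input pair in
#'   g/L; defaults to uniformly random inputs.
#' @return an episode record: list with `params_used`, `transitions`,
#'   `return` (sum of rewards), `final_logdet`, `discarded`.
#' @export
run_episode <- function(env, policy = NULL) {
  b <- env$model$input_bounds
  if (is.null(policy))
    policy <- function(o, tau) stats::runif(2, b[1], b[2])
  o <- env_reset(env)
  repeat {
    res <- env_step(env, policy(o, env$tau))
    if (res$done == 1L) break
    o <- res$o_next
  }
  episode_record(env)
}

episode_record <- function(env) {
  rs <- vapply(env$transitions, `[[`, numeric(1), "r")
  list(params_used = env$params_used,
       transitions = env$transitions,
       return = if (env$failed) NA_real_ else sum(rs),
       final_logdet = if (env$failed) NA_real_ else env$logdet_prev,
       meas = env$meas, actions = env$actions,
       discarded = env$failed)
}

#' Write an episode record as CSV
#'
#' One row per step: step index, reward, done flag, the scaled measurement
#' at the start of the step and the scaled input pair applied.
#'
#' @param record an episode record from [run_episode()].
#' @param path output file.
#' @export
write_episode <- function(record, path) {
  n <- length(record$transitions)
  df <- data.frame(step = seq_len(n),
                   r = vapply(record$transitions, `[[`, numeric(1), "r"),
                   done = vapply(record$transitions, `[[`, numeric(1),
                                 "done"),
                   meas = record$meas[seq_len(n)],
                   u1_scaled = record$actions[, 1],
                   u2_scaled = record$actions[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Instability filter for prior-distribution training
#'
#' Under `sqrt_mode` scaling, an episode is discarded when any scaled
#' observation exceeds 1 (the network inputs would leave their design
#' range, indicating a parametrisation whose population outgrew the
#' normaliser) or when the integrator failed.
#'
#' @param record an episode record from [run_episode()].
#' @param scaling a [scaling_scheme()] with `sqrt_mode = TRUE`.
#' @return TRUE to keep, FALSE to discard.
#' @export
stability_filter <- function(record, scaling) {
  if (!scaling$sqrt_mode)
    stop("the instability filter applies to sqrt-mode scaling")
  if (record$discarded) return(FALSE)
  all(record$meas <= 1)
}

#' Calibrate per-element Fisher-information normalisers
#'
#' Runs random-input episodes at the environment's parameter setting and
#' returns, for each of the nine information-matrix elements, the largest
#' absolute value observed (floored at 1), for use as
#' `scaling_scheme(fim_divisors = )`.
#'
#' @param env an [oed_env()].
#' @param n_trial_episodes number of random episodes.
#' @param seed RNG seed (deterministic given the seed).
#' @export
calibrate_fim_divisors <- function(env, n_trial_episodes = 100, seed = 1) {
  set.seed(seed)
  mx <- matrix(0, 3, 3)
  for (i in seq_len(n_trial_episodes)) {
    env_reset(env)
    for (tau in seq_len(env$episode$n_steps)) {
      a <- stats::runif(2, env$model$input_bounds[1],
                        env$model$input_bounds[2])
      res <- env_step(env, a)
      if (res$failed) break
      mx <- pmax(mx, abs(env$aug$fim))
    }
  }
  pmax(mx, 1)
}

#' Calibrate the sqrt-mode measurement normaliser over the prior
#'
#' Runs random-input episodes with prior-sampled parameters and returns
#' `margin` times the maximum sqrt-population observed, so that only the
#' most extreme few percent of episodes trip the instability filter.
#'
#' @param env an [oed_env()] in `sample_prior` mode.
#' @param n_episodes pilot episode count.
#' @param margin multiplier above the pilot maximum.
#' @param quantile_keep quantile of per-episode maxima used as the
#'   reference (guards against a single runaway episode).
#' @param seed RNG seed.
#' @export
calibrate_sqrt_divisor <- function(env, n_episodes = 200, margin = 1.1,
                                   quantile_keep = 0.975, seed = 1) {
  set.seed(seed)
  maxima <- numeric(0)
  for (i in seq_len(n_episodes)) {
    rec <- run_episode(env)
    if (!rec$discarded) maxima <- c(maxima, max(rec$meas))
  }
  # meas are sqrt(N)/sqrt_divisor under the env's current scaling
  ref <- stats::quantile(maxima, quantile_keep, names = FALSE)
  margin * ref * env$scaling$sqrt_divisor
}
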