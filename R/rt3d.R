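#' Configuration for the recurrent TD3 agent
#'
#' Hyperparameters of the twin-delayed deterministic policy-gradient agent.
#' Actions are handled internally on the scaled \[0, 1\] box (affine image
#' of the input bounds), so `smoothing_sigma` and `smoothing_clip` are in
#' scaled action units.
#'
#' @param gamma discount factor (1: undiscounted finite horizon).
#' @param rho Polyak rate for the target networks.
#' @param smoothing_sigma std of the target-policy smoothing noise.
#' @param smoothing_clip bound on the absolute smoothing noise.
#' @param batch_size replay mini-batch size.
#' @param update_frequency environment steps between network updates.
#' @param policy_delay critic updates per actor/target update.
#' @param buffer_capacity maximum stored transitions.
#' @param actor_lr,critic_lr Adam learning rates.
#' @param gru_units,head_units recurrent encoder and dense-head widths.
#' @param explore_sigma std of the greedy-action exploration noise at
#'   explore rate 1 (scaled units; the applied std is
#'   `explore_sigma * eps`).
#' @export
rt3d_config <- function(gamma = 1, rho = 0.99, smoothing_sigma = 0.1,
                        smoothing_clip = 0.25, batch_size = 256,
                        update_frequency = 1, policy_delay = 2,
                        buffer_capacity = Inf, actor_lr = 3e-4,
                        critic_lr = 1e-3, gru_units = c(64, 64),
                        head_units = c(128, 128), explore_sigma = 0.2) {
  stopifnot(rho >= 0, rho <= 1, smoothing_clip > 0, policy_delay >= 1,
            update_frequency >= 1)
  structure(list(gamma = gamma, rho = rho,
                 smoothing_sigma = smoothing_sigma,
                 smoothing_clip = smoothing_clip, batch_size = batch_size,
                 update_frequency = update_frequency,
                 policy_delay = policy_delay,
                 buffer_capacity = buffer_capacity, actor_lr = actor_lr,
                 critic_lr = critic_lr, gru_units = gru_units,
                 head_units = head_units, explore_sigma = explore_sigma),
            class = "rt3d_config")
}

#' Initialise an RT3D agent
#'
#' Twin recurrent critics (history encoder + head consuming the candidate
#' action), a recurrent deterministic actor (bounded by a sigmoid squashing
#' onto the scaled action box), and Polyak-averaged target copies of all
#' three.
#'
#' @param cfg an [rt3d_config()].
#' @param current_dim length of the non-sequential observation part
#'   (scaled measurement and step index).
#' @param seq_dim features per history step.
#' @return object of class `rt3d_agent`.
#' @export
rt3d_agent <- function(cfg = rt3d_config(), current_dim = 2, seq_dim = 3) {
  # output layers start near zero (micro-initialisation): the actor then
  # opens at the centre of the action box instead of a saturated corner,
  # and critic values start small, which stabilises early bootstrapping
  micro_init <- function(net, scale = 3e-3) {
    L <- length(net$head$layers)
    net$head$layers[[L]]$W <- net$head$layers[[L]]$W * 0 +
      matrix(stats::runif(length(net$head$layers[[L]]$W), -scale, scale),
             nrow(net$head$layers[[L]]$W))
    net$head$layers[[L]]$b <- net$head$layers[[L]]$b * 0
    net
  }
  critic <- function() micro_init(rnet(seq_dim, current_dim + 2,
                                       cfg$gru_units, cfg$head_units,
                                       out_dim = 1))
  actor <- micro_init(rnet(seq_dim, current_dim, cfg$gru_units,
                           cfg$head_units, out_dim = 2))
  q1 <- critic(); q2 <- critic()
  agent <- list(cfg = cfg, current_dim = current_dim, seq_dim = seq_dim,
                actor = actor, q1 = q1, q2 = q2,
                actor_targ = actor, q1_targ = q1, q2_targ = q2,
                opt_actor = adam(rnet_params(actor), lr = cfg$actor_lr),
                opt_q1 = adam(rnet_params(q1), lr = cfg$critic_lr),
                opt_q2 = adam(rnet_params(q2), lr = cfg$critic_lr),
                update_count = 0)
  class(agent) <- "rt3d_agent"
  agent
}

# actor forward: returns scaled actions in (0, 1); optionally the cache
actor_forward <- function(net, X, lengths, extra, cache = FALSE) {
  out <- rnet_forward(net, X, lengths, extra, cache = cache)
  a <- sigmoid(out)
  if (cache) attr(a, "raw") <- out
  a
}

#' Smoothed target action
#'
#' `clip(pi_targ(o') + clip(xi, -c, c), 0, 1)` with `xi` zero-mean Gaussian
#' of std `smoothing_sigma`, independent per batch element and channel
#' (scaled action units).
#'
#' @param agent an [rt3d_agent()].
#' @param X,lengths,extra next-observation batch (see [rnet_forward()]).
#' @export
smoothed_target_action <- function(agent, X, lengths, extra) {
  a <- actor_forward(agent$actor_targ, X, lengths, extra)
  if (agent$cfg$smoothing_sigma > 0) {
    xi <- matrix(stats::rnorm(length(a), sd = agent$cfg$smoothing_sigma),
                 nrow(a), ncol(a))
    xi <- pmin(pmax(xi, -agent$cfg$smoothing_clip), agent$cfg$smoothing_clip)
    a <- a + xi
  }
  pmin(pmax(a, 0), 1)
}

#' Critic regression targets
#'
#' `y = r + gamma (1 - d) min(Q1_targ, Q2_targ)(o', a')` at the smoothed
#' target action; rewards arrive already divided by the Q-target
#' normaliser, so targets are on the scaled value scale throughout.
#'
#' @param agent an [rt3d_agent()].
#' @param batch a batch as assembled by the replay buffer (fields
#'   `Xn, lengths_n, extran` for the next observation and `r, d`).
#' @export
critic_targets <- function(agent, batch) {
  a2 <- smoothed_target_action(agent, batch$Xn, batch$lengths_n,
                               batch$extran)
  ex <- cbind(batch$extran, a2)
  q1 <- rnet_forward(agent$q1_targ, batch$Xn, batch$lengths_n, ex)
  q2 <- rnet_forward(agent$q2_targ, batch$Xn, batch$lengths_n, ex)
  batch$r + agent$cfg$gamma * (1 - batch$d) * pmin(q1[, 1], q2[, 1])
}

#' One gradient step on both critics
#'
#' Mean-squared error of each critic against the (constant) targets `y`.
#'
#' @param agent an [rt3d_agent()].
#' @param batch replay batch.
#' @param y targets from [critic_targets()].
#' @return list with the updated agent and losses `l1`, `l2`.
#' @export
update_critics <- function(agent, batch, y) {
  ex <- cbind(batch$extra, batch$a)
  losses <- numeric(2)
  for (i in 1:2) {
    nm <- if (i == 1) "q1" else "q2"
    out <- rnet_forward(agent[[nm]], batch$X, batch$lengths, ex,
                        cache = TRUE)
    resid <- out[, 1] - y
    losses[i] <- mean(resid^2)
    if (!is.finite(losses[i])) stop("non-finite critic loss")
    bw <- rnet_backward(agent[[nm]], out, matrix(2 * resid / length(y)))
    stepped <- adam_step(agent[[paste0("opt_", nm)]],
                         rnet_params(agent[[nm]]), bw$grads)
    agent[[nm]] <- rnet_set_params(agent[[nm]], stepped$params)
    agent[[paste0("opt_", nm)]] <- stepped$opt
  }
  list(agent = agent, l1 = losses[1], l2 = losses[2])
}

#' One ascent step on the actor
#'
#' Maximises the batch mean of `Q1(o, pi(o))`; only actor parameters move.
#'
#' @param agent an [rt3d_agent()].
#' @param batch replay batch.
#' @return list with the updated agent and the (negated objective) `loss`.
#' @export
update_actor <- function(agent, batch) {
  n <- length(batch$r)
  a <- actor_forward(agent$actor, batch$X, batch$lengths, batch$extra,
                     cache = TRUE)
  ex <- cbind(batch$extra, a)
  qout <- rnet_forward(agent$q1, batch$X, batch$lengths, ex, cache = TRUE)
  loss <- -mean(qout[, 1])
  if (!is.finite(loss)) stop("non-finite actor loss")
  bwq <- rnet_backward(agent$q1, qout, matrix(-1 / n, n, 1))
  da <- bwq$dExtra[, agent$current_dim + 1:2, drop = FALSE]
  draw <- da * a * (1 - a)                  # through the sigmoid squashing
  bwa <- rnet_backward(agent$actor, attr(a, "raw"), draw)
  stepped <- adam_step(agent$opt_actor, rnet_params(agent$actor),
                       bwa$grads)
  agent$actor <- rnet_set_params(agent$actor, stepped$params)
  agent$opt_actor <- stepped$opt
  list(agent = agent, loss = loss)
}

#' Polyak target-network update
#'
#' `theta_targ <- rho * theta_targ + (1 - rho) * theta` for actor and both
#' critics.
#'
#' @param agent an [rt3d_agent()].
#' @param rho averaging rate (defaults to the agent's configured rate).
#' @export
polyak_update <- function(agent, rho = agent$cfg$rho) {
  mix <- function(targ, live)
    param_map2(targ, live, function(a, b) rho * a + (1 - rho) * b)
  agent$actor_targ <- rnet_set_params(
    agent$actor_targ, mix(rnet_params(agent$actor_targ),
                          rnet_params(agent$actor)))
  agent$q1_targ <- rnet_set_params(
    agent$q1_targ, mix(rnet_params(agent$q1_targ), rnet_params(agent$q1)))
  agent$q2_targ <- rnet_set_params(
    agent$q2_targ, mix(rnet_params(agent$q2_targ), rnet_params(agent$q2)))
  agent
}

# assemble an observation (formulation III) into network inputs
rt3d_inputs <- function(obs, n_steps_max) {
  h <- obs$history
  X <- array(0, c(1, n_steps_max, 3))
  X[1, seq_len(nrow(h)), ] <- h
  list(X = X, lengths = nrow(h),
       extra = matrix(obs$current, 1))
}

#' Choose an action from an episode history
#'
#' Epsilon-greedy over the continuous box: with probability `eps` a
#' uniformly random input pair; otherwise the actor output perturbed by
#' zero-mean Gaussian noise of std `explore_sigma * eps` and clipped to the
#' box. Deterministic at `eps = 0`.
#'
#' @param agent an [rt3d_agent()].
#' @param obs a formulation-III observation (see [build_observation()]).
#' @param eps explore rate.
#' @param bounds input bounds in g/L.
#' @param n_steps_max episode horizon (padding length).
#' @return input pair in g/L.
#' @export
rt3d_act <- function(agent, obs, eps, bounds = c(0.01, 1),
                     n_steps_max = 10) {
  if (eps > 0 && stats::runif(1) < eps) {
    a <- stats::runif(2)
  } else {
    inp <- rt3d_inputs(obs, n_steps_max)
    a <- as.numeric(actor_forward(agent$actor, inp$X, inp$lengths,
                                  inp$extra))
    if (eps > 0)
      a <- a + stats::rnorm(2, sd = agent$cfg$explore_sigma * eps)
    a <- pmin(pmax(a, 0), 1)
  }
  bounds[1] + a * (bounds[2] - bounds[1])
}

# ---- replay buffer ---------------------------------------------------------

# transitions are stored with padded history arrays so batches assemble by
# simple indexing
rt3d_buffer <- function(capacity = Inf) {
  structure(list(store = list(), capacity = capacity), class = "rt3d_buffer")
}

buffer_add <- function(buf, transitions) {
  buf$store <- c(buf$store, transitions)
  n <- length(buf$store)
  if (is.finite(buf$capacity) && n > buf$capacity)
    buf$store <- buf$store[(n - buf$capacity + 1):n]
  buf
}

buffer_sample <- function(buf, batch_size, n_steps_max) {
  n <- length(buf$store)
  idx <- sample.int(n, min(batch_size, n))
  tr <- buf$store[idx]
  nb <- length(tr)
  # next-observation histories after the terminal step carry T + 1 rows
  n_steps_max <- n_steps_max + 1L
  X <- array(0, c(nb, n_steps_max, 3))
  Xn <- array(0, c(nb, n_steps_max, 3))
  lengths <- integer(nb); lengths_n <- integer(nb)
  extra <- matrix(0, nb, length(tr[[1]]$current))
  extran <- matrix(0, nb, length(tr[[1]]$current))
  a <- matrix(0, nb, 2); r <- numeric(nb); d <- numeric(nb)
  for (i in seq_len(nb)) {
    t1 <- tr[[i]]
    lengths[i] <- nrow(t1$hist); lengths_n[i] <- nrow(t1$hist_next)
    X[i, seq_len(lengths[i]), ] <- t1$hist
    Xn[i, seq_len(lengths_n[i]), ] <- t1$hist_next
    extra[i, ] <- t1$current; extran[i, ] <- t1$current_next
    a[i, ] <- t1$a_scaled; r[i] <- t1$r_scaled; d[i] <- t1$done
  }
  list(X = X, lengths = lengths, extra = extra, Xn = Xn,
       lengths_n = lengths_n, extran = extran, a = a, r = r, d = d)
}

#' Train an RT3D agent in an OED environment
#'
#' Runs the twin-delayed deterministic policy-gradient loop: per
#' environment step, store the transition; every `update_frequency` steps,
#' sample a replay batch and update the critics, with the actor and target
#' networks updated every `policy_delay`-th critic update. In
#' `sample_prior` mode with sqrt scaling, episodes tripping the
#' instability filter are excluded from the buffer and replaced.
#'
#' @param env an [oed_env()] with a formulation-III observation.
#' @param agent an [rt3d_agent()] (a fresh one is created when NULL).
#' @param n_episodes kept-episode count to train for.
#' @param schedule an [explore_schedule()] (default over `n_episodes`).
#' @param seed RNG seed; the run is deterministic given it.
#' @param verbose print a progress line every 100 episodes.
#' @return list with trained `agent`, `curve` (episode, return, epsilon),
#'   and `n_discarded`.
#' @export
rt3d_train <- function(env, agent = NULL, n_episodes = 1000,
                       schedule = explore_schedule(n_episodes), seed = 1,
                       verbose = FALSE) {
  set.seed(seed)
  if (is.null(agent)) agent <- rt3d_agent()
  cfg <- agent$cfg
  Tmax <- env$episode$n_steps
  q_div <- env$scaling$q_target_divisor
  buf <- rt3d_buffer(cfg$buffer_capacity)
  curve <- data.frame(episode = integer(0), return = numeric(0),
                      epsilon = numeric(0))
  n_discarded <- 0L
  step_count <- 0L
  e <- 0L
  while (e < n_episodes) {
    eps <- epsilon(e, schedule)
    o <- env_reset(env)
    ep_tr <- list()
    repeat {
      a <- rt3d_act(agent, o, eps, env$model$input_bounds, Tmax)
      res <- env_step(env, a)
      if (res$failed) break
      ep_tr[[length(ep_tr) + 1]] <- list(
        hist = o$history, current = as.numeric(o$current),
        a_scaled = scale_action(a, env$model$input_bounds),
        r_scaled = res$r / q_div,
        hist_next = res$o_next$history,
        current_next = as.numeric(res$o_next$current),
        done = res$done)
      o <- res$o_next
      step_count <- step_count + 1L
      if (length(buf$store) >= cfg$batch_size &&
          step_count %% cfg$update_frequency == 0L) {
        batch <- buffer_sample(buf, cfg$batch_size, Tmax)
        y <- critic_targets(agent, batch)
        agent <- update_critics(agent, batch, y)$agent
        agent$update_count <- agent$update_count + 1L
        if (agent$update_count %% cfg$policy_delay == 0L) {
          agent <- update_actor(agent, batch)$agent
          agent <- polyak_update(agent)
        }
      }
      if (res$done == 1L) break
    }
    rec <- episode_record(env)
    keep <- !rec$discarded &&
      (!env$scaling$sqrt_mode || stability_filter(rec, env$scaling))
    if (keep) {
      buf <- buffer_add(buf, ep_tr)
      curve <- rbind(curve, data.frame(episode = e, return = rec$return,
                                       epsilon = eps))
      e <- e + 1L
      if (verbose && e %% 100 == 0)
        message("episode ", e, " return ",
                round(mean(tail(curve$return, 50)), 2), " eps ",
                round(eps, 3))
    } else {
      n_discarded <- n_discarded + 1L
    }
  }
  list(agent = agent, curve = curve, n_discarded = n_discarded)
}

#' Next input for a partially run experiment
#'
#' Deployment entry point: given the measurements observed so far and the
#' inputs already applied (a CSV with columns `N`, `C0_in`, `C1_in`; the
#' last row's inputs may be `NA` since the next pair is what is being
#' requested), returns the trained agent's next input pair in g/L. The
#' forward pass takes well under a second.
#'
#' @param agent a trained [rt3d_agent()].
#' @param history_csv path to the partial-experiment CSV.
#' @param scaling the [scaling_scheme()] the agent was trained with.
#' @param bounds input bounds (g/L).
#' @param n_steps episode horizon.
#' @export
rt3d_next_input <- function(agent, history_csv,
                            scaling = scaling_scheme(),
                            bounds = c(0.01, 1), n_steps = 10) {
  h <- utils::read.csv(history_csv)
  stopifnot(all(c("N", "C0_in", "C1_in") %in% names(h)), nrow(h) >= 1)
  tau <- nrow(h)
  meas <- scale_measurement(h$N, scaling)
  acts <- cbind(scale_action(h$C0_in[-tau], bounds),
                scale_action(h$C1_in[-tau], bounds))
  obs <- build_observation(
    obs_spec("IIIa"),
    list(tau = tau, meas = meas,
         actions = matrix(acts, ncol = 2), fim = NULL,
         n_steps = n_steps, bounds = bounds), scaling)
  rt3d_act(agent, obs, eps = 0, bounds, n_steps)
}

#' Run one greedy episode under a trained RT3D agent
#'
#' @param env an [oed_env()] with formulation-III observations.
#' @param agent a trained [rt3d_agent()].
#' @return episode record (see [run_episode()]).
#' @export
rt3d_greedy_episode <- function(env, agent) {
  Tmax <- env$episode$n_steps
  run_episode(env, policy = function(o, tau)
    rt3d_act(agent, o, eps = 0, env$model$input_bounds, Tmax))
}
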