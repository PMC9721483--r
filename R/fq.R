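#' Discrete action grid
#'
#' Linearly spaced levels per input channel between the input bounds
#' (endpoints included); joint actions are the Cartesian product.
#'
#' @param n_levels levels per input (default 10, i.e. 100 joint actions).
#' @param bounds `c(low, high)` input bounds in g/L.
#' @export
action_grid <- function(n_levels = 10, bounds = c(0.01, 1)) {
  stopifnot(n_levels >= 2, bounds[1] < bounds[2])
  levels <- seq(bounds[1], bounds[2], length.out = n_levels)
  joint <- as.matrix(expand.grid(C0_in = levels, C1_in = levels))
  structure(list(n_levels = n_levels, levels = levels, joint = joint,
                 n_actions = nrow(joint), bounds = bounds),
            class = "action_grid")
}

#' Exploration schedule
#'
#' Epsilon-greedy decay `eps(e) = clip(1 - log10(e / A), 0, 1)` over
#' 0-based episode index `e`, with `eps(0) = 1`: full exploration at the
#' start, zero from episode `10 A` onward. The default `A = E/11` places
#' the zero before the end of an `E`-episode run.
#'
#' @param n_episodes total episodes E.
#' @param decay_constant the constant A (default `E/11`).
#' @export
explore_schedule <- function(n_episodes, decay_constant = n_episodes / 11) {
  stopifnot(n_episodes >= 1, decay_constant > 0)
  structure(list(n_episodes = n_episodes, A = decay_constant),
            class = "explore_schedule")
}

#' Explore rate at an episode
#'
#' @param e 0-based episode index.
#' @param schedule an [explore_schedule()].
#' @export
epsilon <- function(e, schedule) {
  ifelse(e <= 0, 1, pmin(1, pmax(0, 1 - log10(e / schedule$A))))
}

#' Epsilon-greedy action selection over the grid
#'
#' With probability `eps` a uniformly random joint action; otherwise the
#' argmax of the Q-values with ties broken toward the lowest index.
#'
#' @param q_values numeric vector of Q-values, one per joint action.
#' @param eps explore rate in \[0, 1\].
#' @return integer action index.
#' @export
select_action <- function(q_values, eps) {
  if (stats::runif(1) < eps) sample.int(length(q_values), 1)
  else which.max(q_values)
}

#' Q-learning regression targets from a transition memory
#'
#' `target = r + gamma * (1 - d) * max_a Q(o', a)`, divided by the
#' Q-target normaliser before regression. A `NULL` network values every
#' future state at zero.
#'
#' @param memory list of transitions `(o, a_idx, r, o_next, done)` with
#'   flat observation vectors.
#' @param net an [mlp()] Q-network or NULL.
#' @param gamma discount factor.
#' @param q_divisor target normaliser (see [scaling_scheme()]).
#' @return numeric vector of scaled targets, one per transition.
#' @export
q_targets <- function(memory, net, gamma, q_divisor = 100) {
  r <- vapply(memory, `[[`, numeric(1), "r")
  d <- vapply(memory, `[[`, numeric(1), "done")
  fut <- numeric(length(memory))
  live <- which(d == 0)
  if (length(live) > 0 && !is.null(net) && gamma != 0) {
    Onext <- do.call(rbind, lapply(memory[live], `[[`, "o_next"))
    q <- mlp_forward(net, Onext)
    fut[live] <- apply(q, 1, max)
  }
  (r / q_divisor) + gamma * (1 - d) * fut
}

#' One fitted-Q iteration
#'
#' Re-initialises the Q-network from scratch (from the current RNG state)
#' and regresses it on the whole memory against targets bootstrapped from
#' the previous network.
#'
#' @param memory transition memory (see [q_targets()]).
#' @param prev_net previous Q-network (NULL on the first iteration).
#' @param obs_dim observation vector length.
#' @param grid an [action_grid()].
#' @param gamma discount factor.
#' @param hidden hidden-layer widths of the Q-network.
#' @param epochs,batch_size,lr inner regression settings.
#' @param q_divisor Q-target normaliser.
#' @return the newly fitted [mlp()].
#' @export
fq_iteration <- function(memory, prev_net, obs_dim, grid, gamma = 1,
                         hidden = c(100, 100), epochs = 10,
                         batch_size = 256, lr = 1e-3, q_divisor = 100) {
  stopifnot(length(memory) > 0)
  y <- q_targets(memory, prev_net, gamma, q_divisor)
  O <- do.call(rbind, lapply(memory, `[[`, "o"))
  a_idx <- vapply(memory, `[[`, integer(1), "a_idx")
  net <- mlp(c(obs_dim, hidden, grid$n_actions))
  fit <- mlp_train(net, O, y, target_col = a_idx, epochs = epochs,
                   batch_size = batch_size, lr = lr)
  fit$net
}

#' Episodic neural fitted Q-learning
#'
#' Runs `n_episodes` epsilon-greedy episodes in the environment, appending
#' every transition to a growing memory and refitting the Q-network from
#' scratch on the full memory after each episode.
#'
#' @param env an [oed_env()] with a flat (formulation I or II) observation.
#' @param n_episodes number of training episodes E.
#' @param grid an [action_grid()].
#' @param schedule an [explore_schedule()] (default over `n_episodes`).
#' @param gamma discount (1: undiscounted finite horizon, so values equal
#'   expected final D-optimality).
#' @param hidden,epochs,batch_size,lr passed to [fq_iteration()].
#' @param refit_every run the (quadratically growing) refit only every
#'   k-th episode; 1 reproduces the every-episode protocol.
#' @param seed RNG seed; the whole run is deterministic given it.
#' @return list with `net`, `curve` (data.frame episode/return/epsilon)
#'   and `memory_size`.
#' @export
fq_learning <- function(env, n_episodes, grid = action_grid(),
                        schedule = explore_schedule(n_episodes),
                        gamma = 1, hidden = c(100, 100), epochs = 10,
                        batch_size = 256, lr = 1e-3, refit_every = 1,
                        seed = 1) {
  set.seed(seed)
  q_div <- env$scaling$q_target_divisor
  memory <- list()
  net <- NULL
  obs_dim <- NULL
  curve <- data.frame(episode = integer(0), return = numeric(0),
                      epsilon = numeric(0))
  for (e in seq_len(n_episodes) - 1L) {
    eps <- epsilon(e, schedule)
    o <- env_reset(env)
    if (is.null(obs_dim)) obs_dim <- length(o)
    repeat {
      qv <- if (is.null(net)) rep(0, grid$n_actions)
            else as.numeric(mlp_forward(net, matrix(o, 1)))
      ai <- select_action(qv, eps)
      res <- env_step(env, grid$joint[ai, ])
      if (res$failed) break
      memory[[length(memory) + 1]] <-
        list(o = o, a_idx = ai, r = res$r, o_next = res$o_next,
             done = res$done)
      o <- res$o_next
      if (res$done == 1L) break
    }
    rec <- episode_record(env)
    curve <- rbind(curve, data.frame(episode = e, return = rec$return,
                                     epsilon = eps))
    if ((e + 1L) %% refit_every == 0 || e == n_episodes - 1L)
      net <- fq_iteration(memory, net, obs_dim, grid, gamma, hidden,
                          epochs, batch_size, lr, q_div)
  }
  list(net = net, curve = curve, memory_size = length(memory),
       grid = grid, obs_dim = obs_dim)
}

#' Run one greedy (epsilon = 0) episode under a trained Q-network
#'
#' @param env an [oed_env()].
#' @param net trained [mlp()] Q-network.
#' @param grid the [action_grid()] the network was trained over.
#' @return episode record (see [run_episode()]).
#' @export
fq_greedy_episode <- function(env, net, grid) {
  run_episode(env, policy = function(o, tau) {
    qv <- as.numeric(mlp_forward(net, matrix(o, 1)))
    grid$joint[which.max(qv), ]
  })
}
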