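#' Experiment designs
#'
#' An experiment design is an ordered sequence of input pairs
#' `(C0_in, C1_in)`, one per sample-and-hold interval, together with a
#' provenance tag recording which designer produced it.
#'
#' @param inputs T x 2 numeric matrix (or data.frame) of input pairs (g/L).
#' @param provenance one of `"rational"`, `"osao"`, `"mpc"`, `"agent"`,
#'   `"random"`.
#' @export
experiment_design <- function(inputs,
                              provenance = c("rational", "osao", "mpc",
                                             "agent", "random")) {
  provenance <- match.arg(provenance)
  u <- as.matrix(inputs)
  if (ncol(u) != 2 || any(!is.finite(u)))
    stop("inputs must be a finite T x 2 matrix of (C0_in, C1_in) pairs")
  colnames(u) <- c("C0_in", "C1_in")
  structure(list(inputs = u, provenance = provenance),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design (", x$provenance, "), T = ", nrow(x$inputs),
      " intervals\n", sep = "")
  print(round(x$inputs, 4))
  invisible(x)
}

design_matrix <- function(design) {
  if (inherits(design, "experiment_design")) design$inputs
  else {
    u <- as.matrix(design)
    stopifnot(ncol(u) == 2)
    colnames(u) <- c("C0_in", "C1_in")
    u
  }
}

#' Wrap and validate a user-supplied (rational) design
#'
#' @param inputs T x 2 matrix of input pairs.
#' @param model a [chemostat_model()] providing the input bounds.
#' @param n_steps required number of intervals.
#' @export
rational_design <- function(inputs, model, n_steps = 10) {
  u <- design_matrix(inputs)
  if (nrow(u) != n_steps)
    stop("design has ", nrow(u), " rows; expected ", n_steps)
  apply(u, 1, check_input, model = model)
  experiment_design(u, "rational")
}

#' A placeholder staircase design for smoke tests
#'
#' Ramps both inflows up the input box in `n_steps` equal increments; stands
#' in for a hand-chosen design when none is supplied.
#'
#' @inheritParams rational_design
#' @export
staircase_design <- function(model, n_steps = 10) {
  b <- model$input_bounds
  lev <- seq(b[1], b[2], length.out = n_steps)
  rational_design(cbind(lev, lev), model, n_steps)
}

#' Uniformly random design
#'
#' @param model a [chemostat_model()].
#' @param n_steps number of intervals.
#' @export
random_design <- function(model, n_steps = 10) {
  b <- model$input_bounds
  experiment_design(matrix(stats::runif(2 * n_steps, b[1], b[2]),
                           ncol = 2), "random")
}

#' Score a design by its final D-optimality
#'
#' Integrates the augmented system over the full design and returns the
#' final log-determinant of the accumulated Fisher information matrix.
#' Deterministic for fixed solver tolerances.
#'
#' @param design an [experiment_design()] or T x 2 matrix.
#' @param model a [chemostat_model()].
#' @param step_duration interval length in hours.
#' @return list with `score` (log-det units), `trajectory` and `final`
#'   augmented state.
#' @export
evaluate_design <- function(design, model, step_duration = 2) {
  sim <- simulate_experiment(design, model, step_duration)
  list(score = sim$logdet, trajectory = sim$trajectory, final = sim$final)
}

#' Nonlinear-programme settings for the classical designers
#'
#' @param maxit iteration cap per solver call.
#' @param multistart number of restarts for the full-horizon problem
#'   (uniform interior points plus the box midpoint and the greedy
#'   one-step-ahead solution).
#' @param grid_n per-axis resolution of the coarse grid that seeds each
#'   greedy one-step optimisation.
#' @param factr L-BFGS-B convergence factor.
#' @param seed seed for the random restart points.
#' @export
#' @param inner_rtol,inner_atol solver tolerances used inside the
#'   optimisation loop (the final design is rescored at the model's full
#'   tolerances).
nlp_config <- function(maxit = 100, multistart = 8, grid_n = 8,
                       factr = 1e7, seed = 1, inner_rtol = 1e-6,
                       inner_atol = 1e-8) {
  stopifnot(multistart >= 1, grid_n >= 2)
  structure(list(maxit = maxit, multistart = multistart, grid_n = grid_n,
                 factr = factr, seed = seed, inner_rtol = inner_rtol,
                 inner_atol = inner_atol), class = "nlp_config")
}

# loosened-tolerance copy of the model for use inside optimisers
inner_model <- function(model, nlp) {
  model$rtol <- max(model$rtol, nlp$inner_rtol)
  model$atol <- max(model$atol, nlp$inner_atol)
  model
}

# objective for a single committed interval: logdet after appending one
# interval with input u to the augmented state aug
step_objective <- function(u, aug, model, step_duration) {
  out <- try(integrate_interval(aug, u, step_duration, model,
                                check_bounds = FALSE), silent = TRUE)
  if (inherits(out, "try-error")) return(-1e6)
  d_optimality(out$fim)
}

#' Greedy one-step-ahead optimal design
#'
#' Sequentially maximises the information gained over each upcoming interval:
#' at step `tau` the input pair for that interval alone is chosen to maximise
#' `log |I_(tau+1)|` given the trajectory committed so far. Each step is
#' seeded by a coarse grid over the input box and refined by a bounded
#' quasi-Newton search.
#'
#' @param model a [chemostat_model()].
#' @param n_steps number of intervals.
#' @param step_duration interval length (h).
#' @param nlp an [nlp_config()].
#' @return list with `design` (provenance `"osao"`), `score` and the
#'   per-step running log-determinants.
#' @export
osao_design <- function(model, n_steps = 10, step_duration = 2,
                        nlp = nlp_config()) {
  b <- model$input_bounds
  im <- inner_model(model, nlp)
  lev <- seq(b[1], b[2], length.out = nlp$grid_n)
  grid <- as.matrix(expand.grid(lev, lev))
  aug <- augmented_init(model)
  u_opt <- matrix(NA_real_, n_steps, 2)
  logdets <- numeric(n_steps)
  for (tau in seq_len(n_steps)) {
    vals <- apply(grid, 1, step_objective, aug = aug, model = im,
                  step_duration = step_duration)
    best <- grid[which.max(vals), ]
    opt <- stats::optim(best, step_objective, aug = aug, model = im,
                        step_duration = step_duration,
                        method = "L-BFGS-B", lower = b[1], upper = b[2],
                        control = list(fnscale = -1, maxit = nlp$maxit,
                                       factr = nlp$factr))
    if (opt$value < max(vals))  # refinement must not lose to its seed
      opt <- list(par = best, value = max(vals))
    u_opt[tau, ] <- opt$par
    aug <- integrate_interval(aug, opt$par, step_duration, model)
    logdets[tau] <- d_optimality(aug$fim)
  }
  list(design = experiment_design(u_opt, "osao"),
       score = logdets[n_steps], logdets = logdets)
}

# full-horizon objective over the flattened 2T input vector
horizon_objective <- function(x, model, n_steps, step_duration) {
  u <- matrix(x, ncol = 2)
  aug <- augmented_init(model)
  for (k in seq_len(n_steps)) {
    out <- try(integrate_interval(aug, u[k, ], step_duration, model,
                                  check_bounds = FALSE), silent = TRUE)
    if (inherits(out, "try-error")) return(-1e6)
    aug <- out
  }
  d_optimality(aug$fim)
}

# same objective through the single-call episode integrator (optimiser path)
horizon_objective_fast <- function(x, model, step_duration) {
  fast_design_logdet(matrix(x, ncol = 2), model, step_duration)
}

#' Full-horizon model-predictive (open-loop) optimal design
#'
#' Solves one nonlinear programme over all `2 * n_steps` input variables,
#' maximising the final log-determinant of the Fisher information matrix,
#' with multistart restarts (box midpoint, the greedy one-step-ahead design,
#' and uniform random interior points). Returns the best restart, so the
#' score dominates the greedy design by construction.
#'
#' @inheritParams osao_design
#' @param osao optional precomputed result of [osao_design()] to use as a
#'   restart seed (computed internally when `NULL`).
#' @return list with `design` (provenance `"mpc"`), `score` and the
#'   per-restart scores.
#' @export
mpc_design <- function(model, n_steps = 10, step_duration = 2,
                       nlp = nlp_config(), osao = NULL) {
  b <- model$input_bounds
  if (is.null(osao)) osao <- osao_design(model, n_steps, step_duration, nlp)
  starts <- list(rep(mean(b), 2 * n_steps),
                 as.numeric(osao$design$inputs))
  n_random <- max(0, nlp$multistart - length(starts))
  if (n_random > 0) {
    rs <- withr_seed(nlp$seed, matrix(stats::runif(2 * n_steps * n_random,
                                                   b[1], b[2]),
                                      ncol = n_random))
    starts <- c(starts, lapply(seq_len(n_random), function(j) rs[, j]))
  }
  im <- inner_model(model, nlp)
  fits <- lapply(starts, function(x0) {
    opt <- try(stats::optim(x0, horizon_objective_fast, model = im,
                            step_duration = step_duration,
                            method = "L-BFGS-B", lower = b[1], upper = b[2],
                            control = list(fnscale = -1, maxit = nlp$maxit,
                                           factr = nlp$factr)),
               silent = TRUE)
    if (inherits(opt, "try-error")) NULL else opt
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all MPC restarts failed")
  # rescore every restart at the model's full tolerances
  scores <- vapply(fits, function(f)
    horizon_objective(f$par, model, n_steps, step_duration), numeric(1))
  best <- fits[[which.max(scores)]]
  best_score <- max(scores)
  # the greedy design itself is a feasible point; never return worse
  if (best_score < osao$score) {
    best <- list(par = as.numeric(osao$design$inputs))
    best_score <- osao$score
  }
  list(design = experiment_design(matrix(best$par, ncol = 2), "mpc"),
       score = best_score, restart_scores = scores)
}

# evaluate expr under a temporary seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Write / read a design as CSV
#'
#' Schema: `step, C0_in, C1_in`; round-trips exactly at full precision.
#'
#' @param design an [experiment_design()].
#' @param path file path.
#' @export
write_design <- function(design, path) {
  u <- design_matrix(design)
  utils::write.csv(data.frame(step = seq_len(nrow(u)), u), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @param provenance provenance tag to attach on read.
#' @export
read_design <- function(path, provenance = "rational") {
  d <- utils::read.csv(path)
  experiment_design(as.matrix(d[, c("C0_in", "C1_in")]), provenance)
}
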