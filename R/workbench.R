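# Orchestration: serialisable run configurations, a single `run()` entry
# point dispatching to the training / design / evaluation pipelines,
# portable JSON agent snapshots, and the design comparison table.

#' Serialise a network or agent snapshot to JSON
#'
#' Parameters, architecture and (for an agent) configuration are written as
#' plain JSON so snapshots survive across platforms and sessions without
#' binary formats.
#'
#' @param object an [mlp()], [rnet()] or [rt3d_agent()].
#' @param path output file.
#' @export
save_snapshot <- function(object, path) {
  ser <- serialise_obj(object)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

serialise_obj <- function(object) {
  if (inherits(object, "mlp")) {
    list(kind = "mlp", sizes = object$sizes, params = mlp_params(object))
  } else if (inherits(object, "rnet")) {
    list(kind = "rnet", seq_dim = object$seq_dim,
         extra_dim = object$extra_dim, out_dim = object$out_dim,
         gru_units = vapply(object$gru, function(l) length(l$b_c),
                            numeric(1)),
         head_sizes = object$head$sizes, params = rnet_params(object))
  } else if (inherits(object, "rt3d_agent")) {
    list(kind = "rt3d_agent", cfg = unclass(object$cfg),
         current_dim = object$current_dim, seq_dim = object$seq_dim,
         nets = lapply(object[c("actor", "q1", "q2", "actor_targ",
                                "q1_targ", "q2_targ")], serialise_obj))
  } else stop("cannot serialise objects of class ",
              paste(class(object), collapse = "/"))
}

#' Load a snapshot written by [save_snapshot()]
#'
#' @param path JSON snapshot file.
#' @export
load_snapshot <- function(path) {
  deserialise_obj(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE))
}

as_param_list <- function(p) {
  # jsonlite returns matrices for 2-d arrays and vectors otherwise
  if (is.list(p)) lapply(p, as_param_list) else p
}

deserialise_obj <- function(ser) {
  if (ser$kind == "mlp") {
    net <- mlp(ser$sizes)
    mlp_set_params(net, as_param_list(ser$params))
  } else if (ser$kind == "rnet") {
    net <- rnet(ser$seq_dim, ser$extra_dim, ser$gru_units,
                utils::head(ser$head_sizes[-1], -1), ser$out_dim)
    rnet_set_params(net, as_param_list(ser$params))
  } else if (ser$kind == "rt3d_agent") {
    cfg <- do.call(rt3d_config, ser$cfg[names(ser$cfg) %in%
                                          names(formals(rt3d_config))])
    agent <- rt3d_agent(cfg, ser$current_dim, ser$seq_dim)
    for (nm in names(ser$nets))
      agent[[nm]] <- deserialise_obj(ser$nets[[nm]])
    agent
  } else stop("unknown snapshot kind: ", ser$kind)
}

#' Load a run configuration from YAML or JSON
#'
#' @param path configuration file; see the packaged example under
#'   `system.file("extdata", "example_run.yaml", package = "rloed")`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  required <- c("task", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0)
    stop("run config is missing field(s): ", paste(missing, collapse = ", "))
  tasks <- c("design_osao", "design_mpc", "design_rational", "train_fq",
             "train_rt3d", "eval_inference")
  if (!cfg$task %in% tasks)
    stop("unknown task '", cfg$task, "'; expected one of ",
         paste(tasks, collapse = ", "))
  cfg
}

# build the model from the config's optional model block
config_model <- function(cfg) {
  mb <- cfg$model
  if (is.null(mb)) return(chemostat_model())
  params <- do.call(chemostat_params,
                    mb[names(mb) %in% names(formals(chemostat_params))])
  noise <- if (is.null(mb$noise)) noise_model()
  else do.call(noise_model, mb$noise)
  args <- list(params = params, noise = noise)
  if (!is.null(mb$fim_noise))
    args$fim_noise <- do.call(noise_model, mb$fim_noise)
  for (nm in c("initial_state", "input_bounds", "rtol", "atol"))
    if (!is.null(mb[[nm]])) args[[nm]] <- unlist(mb[[nm]])
  do.call(chemostat_model, args)
}

#' Execute a configured run
#'
#' Dispatches on `config$task`, seeds all randomness from `config$seed`,
#' writes artifacts (design CSV, training-curve CSV, metrics JSON) under
#' `config$out_dir` when given, and returns a manifest containing the
#' resolved configuration and the task's headline numbers.
#'
#' @param config list from [read_run_config()] (or constructed in code).
#' @export
run <- function(config) {
  config <- validate_run_config(config)
  model <- config_model(config)
  set.seed(config$seed)
  episode <- episode_config(
    n_steps = config$n_steps %||% 10,
    step_duration = config$step_duration %||% 2)
  out <- switch(
    config$task,
    design_osao = {
      r <- osao_design(model, episode$n_steps, episode$step_duration)
      list(design = r$design, score = r$score)
    },
    design_mpc = {
      r <- mpc_design(model, episode$n_steps, episode$step_duration)
      list(design = r$design, score = r$score)
    },
    design_rational = {
      d <- read_design(config$design_file, "rational")
      d <- rational_design(d$inputs, model, episode$n_steps)
      list(design = d,
           score = evaluate_design(d, model, episode$step_duration)$score)
    },
    train_fq = {
      env <- oed_env(model, episode, obs_spec(config$formulation %||% "Ia"),
                     scaling_scheme(), config$mode %||% "fixed_nominal")
      r <- fq_learning(env, config$n_episodes %||% 500, seed = config$seed)
      rec <- fq_greedy_episode(env, r$net, r$grid)
      list(curve = r$curve, net = r$net, grid = r$grid,
           score = rec$final_logdet,
           design = experiment_design(
             un_scale_action(rec$actions, model$input_bounds), "agent"))
    },
    train_rt3d = {
      env <- oed_env(model, episode, obs_spec("IIIa"),
                     scaling_scheme(sqrt_mode = isTRUE(config$sqrt_mode)),
                     config$mode %||% "fixed_nominal")
      r <- rt3d_train(env, n_episodes = config$n_episodes %||% 1000,
                      seed = config$seed)
      rec <- rt3d_greedy_episode(env, r$agent)
      list(curve = r$curve, agent = r$agent, score = rec$final_logdet,
           design = experiment_design(
             un_scale_action(rec$actions, model$input_bounds), "agent"))
    },
    eval_inference = {
      d <- read_design(config$design_file, "rational")
      st <- inference_study(d, model,
                            n_replicates = config$n_replicates %||% 30,
                            step_duration = episode$step_duration,
                            seed = config$seed)
      list(metrics = st$metrics, estimates = st$estimates)
    })
  manifest <- list(config = config, task = config$task,
                   score = out$score %||% NULL,
                   metrics = out$metrics %||% NULL,
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$design))
      write_design(out$design, file.path(config$out_dir, "design.csv"))
    if (!is.null(out$curve))
      utils::write.csv(out$curve,
                       file.path(config$out_dir, "training_curve.csv"),
                       row.names = FALSE)
    if (!is.null(out$agent))
      save_snapshot(out$agent, file.path(config$out_dir, "agent.json"))
    if (!is.null(out$net))
      save_snapshot(out$net, file.path(config$out_dir, "qnet.json"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  c(out, list(manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

un_scale_action <- function(a_scaled, bounds) {
  bounds[1] + as.matrix(a_scaled) * (bounds[2] - bounds[1])
}

#' Compare designs in a single table
#'
#' One row per design: provenance, final D-optimality and (optionally, when
#' `inference = TRUE`) the downstream inference metrics; rows are sorted by
#' D-optimality, best first.
#'
#' @param designs named list of [experiment_design()] objects.
#' @param model a [chemostat_model()].
#' @param inference also run [inference_study()] per design (slow).
#' @param n_replicates replicates per inference study.
#' @param step_duration interval length (h).
#' @param seed seed for the inference studies.
#' @export
compare_designs <- function(designs, model, inference = FALSE,
                            n_replicates = 30, step_duration = 2,
                            seed = 1) {
  stopifnot(length(designs) >= 1)
  rows <- lapply(names(designs), function(nm) {
    d <- designs[[nm]]
    score <- evaluate_design(d, model, step_duration)$score
    row <- data.frame(design = nm, provenance = d$provenance,
                      d_optimality = score)
    if (inference) {
      st <- inference_study(d, model, n_replicates, step_duration,
                            seed = seed)
      row$normalised_mse <- st$metrics$normalised_mse
      row$logdet_cov <- st$metrics$logdet_cov
    }
    row
  })
  tab <- do.call(rbind, rows)
  tab[order(-tab$d_optimality), , drop = FALSE]
}
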