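#' Chemostat model parameters
#'
#' Constructs the parameter vector of the auxotroph chemostat model: Monod
#' double-substrate growth at maximal rate `mu_max` with half-saturation
#' constants `K0` (auxotrophic nutrient) and `K1` (carbon source), yields
#' `gamma0`/`gamma1` (cells per gram of each substrate) and dilution rate `q`.
#' The Fisher information matrix is accumulated over the `focal` parameters
#' only; the yields are practically unidentifiable from population
#' measurements and `q` is an experimentally controlled setting, so none of
#' them may be focal.
#'
#' @param mu_max maximal specific growth rate (1/h).
#' @param K0 half-saturation concentration of the auxotrophic nutrient (g/L).
#' @param K1 half-saturation concentration of the carbon source (g/L).
#' @param gamma0,gamma1 yields on the two substrates (cells/g).
#' @param q chemostat dilution rate (1/h).
#' @param bounds named list of `c(min, max)` prior bounds for the focal
#'   parameters; defaults to the nominal prior box.
#' @param focal ordered character vector of focal parameter names.
#' @return an object of class `chemostat_params`.
#' @export
chemostat_params <- function(mu_max = 1, K0 = 6.8e-5, K1 = 4.9e-4,
                             gamma0 = 4.8e11, gamma1 = 5.2e11, q = 0.5,
                             bounds = list(mu_max = c(0.5, 2),
                                           K0 = c(1e-5, 1e-4),
                                           K1 = c(1e-4, 1e-3)),
                             focal = c("mu_max", "K0", "K1")) {
  theta <- c(mu_max = mu_max, K0 = K0, K1 = K1,
             gamma0 = gamma0, gamma1 = gamma1, q = q)
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("all chemostat parameters must be finite and strictly positive")
  if (any(focal %in% c("gamma0", "gamma1", "q")))
    stop("gamma0, gamma1 and q cannot be focal parameters")
  if (!identical(focal, c("mu_max", "K0", "K1")))
    stop("the compiled sensitivity system is specialised to the focal set ",
         "(mu_max, K0, K1)")
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || b[1] >= b[2])
      stop("bounds for ", nm, " must be c(min, max) with min < max")
  }
  structure(list(theta = theta, focal = focal, bounds = bounds),
            class = "chemostat_params")
}

#' @export
print.chemostat_params <- function(x, ...) {
  cat("Chemostat parameters (focal:", paste(x$focal, collapse = ", "), ")\n")
  print(x$theta)
  invisible(x)
}

#' Replace focal parameter values
#'
#' Returns a copy of `params` with the focal entries set to `values`
#' (in focal order). Used when sampling episodes from the prior and when
#' refitting parameters to data.
#'
#' @param params a [chemostat_params()] object.
#' @param values numeric vector, one value per focal parameter.
#' @export
set_focal <- function(params, values) {
  stopifnot(inherits(params, "chemostat_params"),
            length(values) == length(params$focal))
  params$theta[params$focal] <- values
  params
}

#' Uniform prior over the focal parameters
#'
#' @param params a [chemostat_params()] object carrying the bounds.
#' @return matrix with rows `min`, `max` and one column per focal parameter.
#' @export
parameter_prior <- function(params) {
  b <- vapply(params$focal, function(nm) params$bounds[[nm]], numeric(2))
  rownames(b) <- c("min", "max")
  b
}

#' Sample focal parameters uniformly from the prior box
#'
#' @param params a [chemostat_params()] object.
#' @param n number of draws.
#' @return an `n` x `length(focal)` matrix of draws.
#' @export
sample_prior <- function(params, n = 1) {
  pr <- parameter_prior(params)
  draws <- vapply(seq_len(ncol(pr)),
                  function(j) stats::runif(n, pr[1, j], pr[2, j]),
                  numeric(n))
  matrix(draws, nrow = n, dimnames = list(NULL, params$focal))
}

#' Measurement noise model
#'
#' Gaussian observation error on the measured population, expressed on a
#' reference measurement scale of `measurement_unit` cells/L (populations in
#' this system are naturally counted in units of 1e9 cells/L). Three
#' variance conventions are supported, with `N_u = N / measurement_unit`:
#' * `"linear"` (default): variance `cv * N_u` on the measurement scale —
#'   the variance equals a fixed fraction of the measured quantity.
#' * `"quadratic"`: variance `cv * N_u^2`, i.e. a fixed relative variance;
#'   this convention makes the Fisher information invariant to the
#'   population unit.
#' * `"constant"`: variance `cv`, independent of the signal.
#'
#' @param cv variance parameter on the measurement scale (default 0.05).
#' @param sigma_mode `"linear"`, `"quadratic"` or `"constant"`.
#' @param measurement_unit reference population unit (cells/L).
#' @param nfloor population floor (cells/L) applied inside the information
#'   increment so that a washed-out culture cannot make the noise variance
#'   singular.
#' @export
noise_model <- function(cv = 0.05,
                        sigma_mode = c("linear", "quadratic", "constant"),
                        measurement_unit = 1e9, nfloor = 1e3) {
  sigma_mode <- match.arg(sigma_mode)
  if (!is.finite(cv) || cv <= 0) stop("cv must be > 0")
  if (!is.finite(measurement_unit) || measurement_unit <= 0)
    stop("measurement_unit must be > 0")
  structure(list(cv = cv, sigma_mode = sigma_mode,
                 measurement_unit = measurement_unit, nfloor = nfloor),
            class = "noise_model")
}

#' Chemostat model specification
#'
#' Bundles parameters, initial conditions, input bounds, the noise model and
#' solver settings into the single object the simulator, the designers and
#' the RL environment all consume.
#'
#' @param params a [chemostat_params()] object.
#' @param initial_state named vector `c(C0, C1, N)` at the start of every
#'   experiment (g/L, g/L, cells/L).
#' @param input_bounds `c(low, high)` bounds on both inflow concentrations
#'   (g/L).
#' @param noise a [noise_model()] describing the measurement error used
#'   when simulating experimental data (default: variance equal to 5% of
#'   the measured population on the 1e9 cells/L scale).
#' @param fim_noise a [noise_model()] giving the variance weighting inside
#'   the Fisher-information integrand. The default is a unit constant
#'   variance on the 1e9 cells/L measurement scale, the weighting under
#'   which the optimality scores of the classical designers sit on the
#'   scale reported for this system; see the methods vignette for why this
#'   is configured separately from the data noise.
#' @param rtol,atol relative and absolute solver tolerances passed to the
#'   stiff-capable variable-step integrator.
#' @export
chemostat_model <- function(params = chemostat_params(),
                            initial_state = c(C0 = 1, C1 = 0, N = 20e9),
                            input_bounds = c(0.01, 1),
                            noise = noise_model(),
                            fim_noise = noise_model(cv = 1,
                                                    sigma_mode = "constant"),
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "chemostat_params"),
            inherits(noise, "noise_model"),
            inherits(fim_noise, "noise_model"),
            length(input_bounds) == 2, input_bounds[1] < input_bounds[2],
            all(initial_state >= 0))
  structure(list(params = params,
                 initial_state = initial_state[c("C0", "C1", "N")],
                 input_bounds = input_bounds, noise = noise,
                 fim_noise = fim_noise,
                 rtol = rtol, atol = atol),
            class = "chemostat_model")
}

#' @export
print.chemostat_model <- function(x, ...) {
  cat("Chemostat model: initial (C0, C1, N) =",
      paste(signif(x$initial_state, 4), collapse = ", "),
      "\n input bounds [", x$input_bounds[1], ",", x$input_bounds[2], "] g/L;",
      "noise cv =", x$noise$cv, "(", x$noise$sigma_mode, ")\n")
  print(x$params)
  invisible(x)
}

#' Monod growth rate
#'
#' Specific growth rate `mu = mu_max * C1/(K1+C1) * C0/(K0+C0)`; zero when
#' either substrate is exhausted, `mu_max/4` at joint half-saturation.
#'
#' @param state named vector or list with `C0`, `C1`.
#' @param params a [chemostat_params()] object.
#' @return growth rate in 1/h.
#' @export
growth_rate <- function(state, params) {
  th <- params$theta
  C0 <- state[["C0"]]; C1 <- state[["C1"]]
  unname(th[["mu_max"]] * C1 / (th[["K1"]] + C1) * C0 / (th[["K0"]] + C0))
}

#' Validate an input pair against the model bounds
#'
#' @param u numeric `c(C0_in, C1_in)` in g/L.
#' @param model a [chemostat_model()].
#' @keywords internal
check_input <- function(u, model) {
  if (length(u) != 2 || any(!is.finite(u)))
    stop("input must be a finite pair (C0_in, C1_in)")
  b <- model$input_bounds
  if (any(u < b[1]) || any(u > b[2]))
    stop("input (", paste(signif(u, 4), collapse = ", "),
         ") outside bounds [", b[1], ", ", b[2], "]")
  invisible(u)
}

# pack the 11-element parameter vector consumed by the compiled RHS; the
# variance is converted to absolute (cells/L)^2 units so the C code is
# unit-agnostic: quadratic cv*N^2, linear (cv*unit)*N, constant cv*unit^2
rhs_parms <- function(model, u) {
  th <- model$params$theta
  fn <- model$fim_noise
  cv_abs <- switch(fn$sigma_mode,
                   quadratic = fn$cv,
                   linear = fn$cv * fn$measurement_unit,
                   constant = fn$cv * fn$measurement_unit^2)
  c(th[["mu_max"]], th[["K0"]], th[["K1"]], th[["gamma0"]], th[["gamma1"]],
    th[["q"]], u[1], u[2], cv_abs, fn$nfloor,
    switch(fn$sigma_mode, quadratic = 1, linear = 2, constant = 3))
}
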