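#' Initial augmented state
#'
#' The augmented state bundles everything that is integrated jointly over an
#' experiment: the chemostat state `(C0, C1, N)`, the 3x3 block of log-scaled
#' sensitivities `S[i, j] = theta_j dX_i/dtheta_j` of the full state with
#' respect to the focal parameters, and the accumulated 3x3 scaled Fisher
#' information matrix of the measured output `N`. Sensitivities and
#' information start at zero: initial conditions are fixed, so their
#' parameter sensitivity vanishes, and no information has been collected.
#'
#' @param model a [chemostat_model()].
#' @return object of class `augmented_state` with fields `state`, `sens`
#'   (3x3 matrix, rows = states, cols = focal parameters), `fim` (3x3
#'   symmetric matrix) and `t` (hours).
#' @export
augmented_init <- function(model) {
  focal <- model$params$focal
  structure(list(
    state = model$initial_state,
    sens = matrix(0, 3, 3, dimnames = list(c("C0", "C1", "N"), focal)),
    fim = matrix(0, 3, 3, dimnames = list(focal, focal)),
    t = 0), class = "augmented_state")
}

# flatten to the 18-vector layout of the compiled RHS
aug_pack <- function(aug) {
  f <- aug$fim
  c(aug$state, as.numeric(aug$sens), f[upper.tri(f, diag = TRUE)])
}

aug_unpack <- function(y, aug) {
  aug$state[] <- y[1:3]
  aug$sens[] <- y[4:12]
  f <- matrix(0, 3, 3)
  f[upper.tri(f, diag = TRUE)] <- y[13:18]
  f <- f + t(f) - diag(diag(f))
  dimnames(f) <- dimnames(aug$fim)
  aug$fim <- f
  aug
}

#' Time derivatives of the augmented system
#'
#' Right-hand side of the joint ODE system: the three chemostat state
#' equations, the forward log-sensitivity equations
#' `dS[,j]/dt = theta_j dF/dtheta_j + (dF/dX) S[,j]` propagated for the full
#' state vector, and the information increment
#' `dI[j,k]/dt = S[N,j] S[N,k] / Sigma(N)` restricted to the measured output.
#'
#' @param aug an `augmented_state`.
#' @param u input pair `c(C0_in, C1_in)` (g/L).
#' @param model a [chemostat_model()].
#' @return list with components `state`, `sens` and `fim` holding the
#'   derivatives in the same shapes as the augmented state.
#' @export
augmented_derivatives <- function(aug, u, model) {
  check_input(u, model)
  if (aug$state[["N"]] <= 0 && model$noise$nfloor <= 0)
    stop("degenerate noise variance: N = 0 with no population floor")
  yd <- .Call(C_chem_rhs, aug_pack(aug), rhs_parms(model, u))
  f <- matrix(0, 3, 3)
  f[upper.tri(f, diag = TRUE)] <- yd[13:18]
  f <- f + t(f) - diag(diag(f))
  list(state = stats::setNames(yd[1:3], c("C0", "C1", "N")),
       sens = matrix(yd[4:12], 3, 3, dimnames = dimnames(aug$sens)),
       fim = f)
}

#' Integrate the augmented system over one sample-and-hold interval
#'
#' Advances state, sensitivities and Fisher information by `duration` hours
#' under a constant input pair, using the stiff-capable variable-step
#' integrator over the compiled right-hand side. The information added over
#' any interval is a time-integral of weighted outer products and is
#' therefore symmetric positive semidefinite, so the accumulated matrix is
#' non-decreasing in the Loewner order.
#'
#' @param aug an `augmented_state`.
#' @param u input pair `c(C0_in, C1_in)` (g/L).
#' @param duration interval length in hours (> 0).
#' @param model a [chemostat_model()].
#' @param check_bounds validate `u` against the model input bounds
#'   (disabled inside optimisers that already enforce box constraints).
#' @return the advanced `augmented_state`.
#' @export
integrate_interval <- function(aug, u, duration, model, check_bounds = TRUE) {
  if (check_bounds) check_input(u, model)
  stopifnot(duration > 0)
  y0 <- aug_pack(aug)
  sol <- try(deSolve::lsoda(
    y = y0, times = c(0, duration), func = "chemostat_derivs",
    parms = rhs_parms(model, u), dllname = "rloed",
    initfunc = "chemostat_init",
    rtol = model$rtol, atol = model$atol, maxsteps = 20000), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < 2 ||
      any(!is.finite(sol[nrow(sol), -1]))) {
    stop("integration failure over [", aug$t, ", ", aug$t + duration, "] h",
         call. = FALSE)
  }
  out <- aug_unpack(as.numeric(sol[nrow(sol), -1]), aug)
  # negative concentrations/population at solver-noise level are clipped
  out$state[out$state < 0 & out$state > -1e-9 * max(abs(out$state))] <- 0
  out$t <- aug$t + duration
  out
}

#' D-optimality score of a Fisher information matrix
#'
#' The log-determinant `log |I|`. A singular matrix (no strictly positive
#' determinant) returns the finite `sentinel` instead of `-Inf`, which
#' keeps first-interval rewards finite. Eigenvalues that are non-positive
#' only through round-off (tiny relative to the largest) are clamped at
#' `rel_floor` times the largest eigenvalue, so a nearly-singular but
#' genuine information matrix keeps a finite, continuous score.
#'
#' @param fim symmetric positive semidefinite matrix.
#' @param sentinel value returned for a singular matrix.
#' @param rel_floor relative eigenvalue clamp.
#' @export
d_optimality <- function(fim, sentinel = -1e6, rel_floor = 1e-18) {
  if (!isSymmetric(unname(fim), tol = 1e-8))
    stop("Fisher information matrix must be symmetric")
  ev <- eigen(fim, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(sentinel)
  sum(log(pmax(ev, max(ev) * rel_floor)))
}

#' Simulate a full experiment and export the trajectory
#'
#' Runs the augmented system through a sequence of sample-and-hold intervals
#' and returns one row per interval boundary: time, states, applied inputs,
#' the nine sensitivity entries, the six unique Fisher-information entries
#' and the running D-optimality.
#'
#' @param design an [experiment_design()] or a T x 2 matrix of input pairs.
#' @param model a [chemostat_model()].
#' @param step_duration interval length in hours.
#' @return list with `trajectory` (data.frame), `final` (`augmented_state`)
#'   and `logdet` (final D-optimality).
#' @export
simulate_experiment <- function(design, model, step_duration = 2) {
  u <- design_matrix(design)
  aug <- augmented_init(model)
  rows <- vector("list", nrow(u) + 1)
  rows[[1]] <- trajectory_row(aug, c(NA, NA))
  for (k in seq_len(nrow(u))) {
    aug <- integrate_interval(aug, u[k, ], step_duration, model)
    rows[[k + 1]] <- trajectory_row(aug, u[k, ])
  }
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  list(trajectory = traj, final = aug,
       logdet = d_optimality(aug$fim))
}

trajectory_row <- function(aug, u) {
  s <- aug$sens; f <- aug$fim
  data.frame(t = aug$t,
             C0 = aug$state[["C0"]], C1 = aug$state[["C1"]],
             N = aug$state[["N"]], C0_in = u[1], C1_in = u[2],
             S_C0_mu = s[1, 1], S_C1_mu = s[2, 1], S_N_mu = s[3, 1],
             S_C0_K0 = s[1, 2], S_C1_K0 = s[2, 2], S_N_K0 = s[3, 2],
             S_C0_K1 = s[1, 3], S_C1_K1 = s[2, 3], S_N_K1 = s[3, 3],
             I_11 = f[1, 1], I_12 = f[1, 2], I_13 = f[1, 3],
             I_22 = f[2, 2], I_23 = f[2, 3], I_33 = f[3, 3],
             logdet = d_optimality(f, sentinel = NA_real_))
}
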