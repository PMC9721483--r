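test_that("Monod growth rate has its analytic limits and values", {
  p <- chemostat_params()
  expect_equal(growth_rate(c(C0 = 0, C1 = 0.5), p), 0)
  expect_equal(growth_rate(c(C0 = p$theta[["K0"]], C1 = p$theta[["K1"]]),
                           p), p$theta[["mu_max"]] / 4)
  # independent hand evaluation of the product at C0 = C1 = 1
  th <- p$theta
  by_hand <- th[["mu_max"]] * 1 / (th[["K1"]] + 1) * 1 / (th[["K0"]] + 1)
  expect_equal(growth_rate(c(C0 = 1, C1 = 1), p), by_hand)
  expect_lte(growth_rate(c(C0 = 50, C1 = 50), p), th[["mu_max"]])
})

test_that("parameter constructor enforces positivity and the focal set", {
  expect_error(chemostat_params(mu_max = -1), "positive")
  expect_error(chemostat_params(focal = c("mu_max", "K0", "q")), "focal")
  expect_error(chemostat_params(bounds = list(mu_max = c(2, 0.5))),
               "min < max")
})

test_that("washout state is absorbing in N and consumption vanishes", {
  m <- nominal_model()
  aug <- augmented_init(m)
  aug$state[["N"]] <- 0
  d <- augmented_derivatives(aug, c(0.5, 0.5), m)
  expect_equal(d$state[["N"]], 0)
  th <- m$params$theta
  # pure dilution: dC/dt = q (C_in - C)
  expect_equal(d$state[["C0"]], th[["q"]] * (0.5 - aug$state[["C0"]]))
  expect_equal(d$state[["C1"]], th[["q"]] * (0.5 - aug$state[["C1"]]))
})

test_that("with zero sensitivities the sensitivity RHS is the direct
           parameter derivative of the state RHS", {
  m <- tight_model(nominal_model())
  aug <- augmented_init(m)
  u <- c(0.7, 0.3)
  d <- augmented_derivatives(aug, u, m)
  # oracle: theta_j dF/dtheta_j by central differences on the state RHS
  state_rhs <- function(params) {
    mm <- m; mm$params <- params
    a <- augmented_init(mm); a$state <- aug$state
    augmented_derivatives(a, u, mm)$state
  }
  h <- 1e-6
  for (j in seq_along(m$params$focal)) {
    nm <- m$params$focal[j]
    up <- m$params; up$theta[[nm]] <- up$theta[[nm]] * (1 + h)
    dn <- m$params; dn$theta[[nm]] <- dn$theta[[nm]] * (1 - h)
    fd <- (state_rhs(up) - state_rhs(dn)) / (2 * h)
    expect_equal(unname(d$sens[, j]), unname(fd), tolerance = 1e-6)
  }
})

test_that("propagated log-sensitivities of N match a finite-difference
           oracle over a 20 h trajectory", {
  m <- tight_model(nominal_model())
  u_seq <- varied_design()
  n_at <- function(params) {
    mm <- m; mm$params <- params
    aug <- augmented_init(mm)
    sapply(seq_len(10), function(k) {
      aug <<- integrate_interval(aug, u_seq[k, ], 2, mm)
      aug$state[["N"]]
    })
  }
  aug <- augmented_init(m)
  sens_traj <- matrix(NA_real_, 10, 3)
  for (k in seq_len(10)) {
    aug <- integrate_interval(aug, u_seq[k, ], 2, m)
    sens_traj[k, ] <- aug$sens[3, ]
  }
  h <- 1e-3   # +/- 0.1% log-parameter perturbation
  for (j in 1:3) {
    nm <- m$params$focal[j]
    up <- m$params; up$theta[[nm]] <- up$theta[[nm]] * exp(h)
    dn <- m$params; dn$theta[[nm]] <- dn$theta[[nm]] * exp(-h)
    fd <- (n_at(up) - n_at(dn)) / (2 * h)
    expect_equal(sens_traj[, j], fd, tolerance = 1e-3)
  }
})

test_that("interval integration is consistent under splitting", {
  m <- nominal_model()
  aug <- augmented_init(m)
  one <- integrate_interval(aug, c(0.4, 0.8), 2, m)
  two <- integrate_interval(integrate_interval(aug, c(0.4, 0.8), 1, m),
                            c(0.4, 0.8), 1, m)
  expect_equal(one$state, two$state, tolerance = 1e-6)
  expect_equal(one$sens, two$sens, tolerance = 1e-6)
  expect_equal(one$fim, two$fim, tolerance = 1e-6)
})

test_that("every information increment is symmetric positive semidefinite
           and D-optimality is non-decreasing once nonsingular", {
  m <- nominal_model()
  aug <- augmented_init(m)
  prev_logdet <- NULL
  set.seed(7)
  for (k in 1:10) {
    u <- runif(2, 0.01, 1)
    nxt <- integrate_interval(aug, u, 2, m)
    inc <- nxt$fim - aug$fim
    expect_equal(inc, t(inc), tolerance = 1e-9)
    expect_gte(min(eigen(inc, symmetric = TRUE,
                         only.values = TRUE)$values),
               -1e-10 * max(1, max(abs(inc))))
    ld <- d_optimality(nxt$fim)
    if (!is.null(prev_logdet) && prev_logdet > -1e5)
      expect_gte(ld, prev_logdet - 1e-8)
    prev_logdet <- ld
    aug <- nxt
  }
})

test_that("relative-noise information is invariant to the population
           unit", {
  m1 <- relative_noise_model()
  # same system with N counted in units 10x smaller (numbers 10x larger)
  p2 <- chemostat_params(gamma0 = 4.8e12, gamma1 = 5.2e12)
  m2 <- chemostat_model(params = p2,
                        initial_state = c(C0 = 1, C1 = 0, N = 200e9),
                        fim_noise = noise_model(cv = 0.05,
                                                sigma_mode = "quadratic"))
  u <- varied_design()
  f1 <- simulate_experiment(u, m1)$final$fim
  f2 <- simulate_experiment(u, m2)$final$fim
  expect_equal(f1, f2, tolerance = 1e-6)
  expect_equal(d_optimality(f1), d_optimality(f2), tolerance = 1e-6)
})

test_that("D-optimality is the log-determinant with a singular sentinel", {
  expect_equal(d_optimality(diag(3)), 0)
  expect_equal(d_optimality(2 * diag(3)), 3 * log(2))
  set.seed(3)
  A <- crossprod(matrix(rnorm(9), 3))
  expect_equal(d_optimality(A),
               sum(log(eigen(A, symmetric = TRUE)$values)))
  expect_equal(d_optimality(matrix(0, 3, 3)), -1e6)
  expect_error(d_optimality(matrix(1:9, 3)), "symmetric")
})

test_that("with no consumers the substrates relax exponentially to the
           inflow at rate q", {
  m <- nominal_model(initial_state = c(C0 = 1, C1 = 0, N = 0))
  u <- c(0.25, 0.75)
  aug <- integrate_interval(augmented_init(m), u, 3, m)
  q <- m$params$theta[["q"]]
  expect_equal(aug$state[["C0"]], u[1] + (1 - u[1]) * exp(-q * 3),
               tolerance = 1e-6)
  expect_equal(aug$state[["C1"]], u[2] + (0 - u[2]) * exp(-q * 3),
               tolerance = 1e-6)
})

test_that("trajectory export carries states, inputs, sensitivities,
           information entries and the running score", {
  m <- nominal_model()
  sim <- simulate_experiment(const_design(n_steps = 3), m)
  expect_equal(nrow(sim$trajectory), 4)
  expect_true(all(c("t", "C0", "C1", "N", "C0_in", "C1_in", "S_N_mu",
                    "I_11", "logdet") %in% names(sim$trajectory)))
  expect_equal(sim$trajectory$t, c(0, 2, 4, 6))
  expect_equal(sim$logdet, sim$trajectory$logdet[4])
})

test_that("out-of-bounds inputs are rejected", {
  m <- nominal_model()
  aug <- augmented_init(m)
  expect_error(integrate_interval(aug, c(0.005, 0.5), 2, m), "bounds")
  expect_error(integrate_interval(aug, c(0.5, 1.2), 2, m), "bounds")
})
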