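test_that("reset produces the expected initial observation under nominal
           scaling", {
  env <- oed_env(nominal_model())
  o <- env_reset(env)
  expect_length(o, 11)              # measurement + 9 FIM entries + time
  expect_equal(o[1], 20e9 / 50e9)   # scaled initial population
  expect_equal(o[11], 0)            # scaled step index at the start
  expect_true(all(o[2:10] == 0))    # information starts at zero
})

test_that("observation vectors have the documented lengths for all six
           formulations at every step", {
  lens <- c(Ia = 11, Ib = 10, IIa = 2, IIb = 1)
  for (f in names(lens)) {
    env <- oed_env(nominal_model(), obs = obs_spec(f))
    o <- env_reset(env)
    for (tau in 1:10) {
      expect_length(o, lens[[f]])
      res <- env_step(env, c(0.5, 0.5))
      o <- res$o_next
    }
  }
  # formulation III carries exactly tau measurements and tau - 1 actions
  env <- oed_env(nominal_model(), obs = obs_spec("IIIb"))
  o <- env_reset(env)
  for (tau in 1:4) {
    expect_equal(nrow(o$history), tau)
    expect_length(o$current, 1)     # no time index in variant b
    expect_true(all(o$history[1, 2:3] == 0))  # no action before step 1
    o <- env_step(env, c(0.3, 0.9))$o_next
  }
  env2 <- oed_env(nominal_model(), obs = obs_spec("IIIa"))
  o2 <- env_reset(env2)
  expect_length(o2$current, 2)
})

test_that("the episode return telescopes exactly to the final
           D-optimality for any policy", {
  env <- oed_env(nominal_model())
  set.seed(21)
  for (rep in 1:3) {
    rec <- run_episode(env)
    expect_false(rec$discarded)
    expect_equal(rec$return, rec$final_logdet, tolerance = 1e-12)
    expect_length(rec$transitions, 10)
  }
})

test_that("episodes terminate exactly at the tenth step and out-of-bounds
           actions are rejected", {
  env <- oed_env(nominal_model())
  env_reset(env)
  for (tau in 1:9) expect_equal(env_step(env, c(0.5, 0.5))$done, 0L)
  expect_equal(env_step(env, c(0.5, 0.5))$done, 1L)
  expect_error(env_step(env, c(0.5, 0.5)), "reset")
  env_reset(env)
  expect_error(env_step(env, c(0.005, 0.5)), "bounds")
})

test_that("environment episodes are reproducible from the seed", {
  env <- oed_env(nominal_model(), mode = "sample_prior")
  set.seed(33); r1 <- run_episode(env)
  set.seed(33); r2 <- run_episode(env)
  expect_identical(r1$params_used$theta, r2$params_used$theta)
  expect_identical(r1$return, r2$return)
  expect_identical(r1$actions, r2$actions)
})

test_that("prior sampling stays inside the bounds box with uniform
           marginals", {
  p <- chemostat_params()
  set.seed(5)
  draws <- sample_prior(p, 1e4)
  pr <- parameter_prior(p)
  for (j in 1:3) {
    expect_true(all(draws[, j] >= pr[1, j] & draws[, j] <= pr[2, j]))
    width <- pr[2, j] - pr[1, j]
    se <- width / sqrt(12) / sqrt(1e4)
    expect_lt(abs(mean(draws[, j]) - mean(pr[, j])), 3 * se)
  }
})

test_that("the instability filter discards exactly the episodes whose
           scaled observations exceed one", {
  sc <- scaling_scheme(sqrt_mode = TRUE, sqrt_divisor = 1e5)
  keep_rec <- list(meas = c(0.2, 0.8, 1.0), discarded = FALSE)
  spike_rec <- list(meas = c(0.2, 1.2, 0.4), discarded = FALSE)
  failed_rec <- list(meas = c(0.2), discarded = TRUE)
  expect_true(stability_filter(keep_rec, sc))
  expect_false(stability_filter(spike_rec, sc))
  expect_false(stability_filter(failed_rec, sc))
  expect_error(stability_filter(keep_rec, scaling_scheme()), "sqrt")
})

test_that("episode records export one CSV row per step", {
  env <- oed_env(nominal_model())
  set.seed(44)
  rec <- run_episode(env)
  path <- tempfile(fileext = ".csv")
  write_episode(rec, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 10)
  expect_equal(sum(df$r), rec$final_logdet, tolerance = 1e-10)
})

test_that("the sqrt-scaling normaliser calibrates above the pilot maxima
           over the prior", {
  env <- oed_env(nominal_model(),
                 scaling = scaling_scheme(sqrt_mode = TRUE,
                                          sqrt_divisor = 1e6),
                 mode = "sample_prior")
  div <- calibrate_sqrt_divisor(env, n_episodes = 10, seed = 3)
  expect_gt(div, sqrt(20e9))    # above the initial population's scale
  expect_lt(div, 1e7)           # and of the populations' order
})

test_that("information normalisers are calibrated as seeded maxima with a
           unit floor", {
  env <- oed_env(nominal_model())
  d1 <- calibrate_fim_divisors(env, n_trial_episodes = 30, seed = 9)
  d2 <- calibrate_fim_divisors(env, n_trial_episodes = 30, seed = 9)
  expect_identical(d1, d2)
  expect_true(all(d1 >= 1))
  # the dominant diagonal element exceeds the floor under random inputs
  expect_gt(max(d1), 1)
  # a fresh random run stays within the calibrated scale almost surely
  env2 <- oed_env(nominal_model(),
                  scaling = scaling_scheme(fim_divisors = d1))
  set.seed(10)
  scaled <- c()
  for (i in 1:3) {
    env_reset(env2)
    for (tau in 1:10) {
      env_step(env2, runif(2, 0.01, 1))
      scaled <- c(scaled, as.numeric(abs(env2$aug$fim / d1)))
    }
  }
  expect_gte(mean(scaled <= 1), 0.99)
})
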