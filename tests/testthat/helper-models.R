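# shared fixtures: models and small designs built in code

nominal_model <- function(...) chemostat_model(...)

# relative-noise (unit-invariant) information weighting, used by the
# invariance checks
relative_noise_model <- function(...) {
  chemostat_model(fim_noise = noise_model(cv = 0.05,
                                          sigma_mode = "quadratic"), ...)
}

# very tight solver settings for finite-difference oracles
tight_model <- function(model) {
  model$rtol <- 1e-12
  model$atol <- 1e-12
  model
}

const_design <- function(u1 = 1, u2 = 1, n_steps = 10) {
  matrix(c(rep(u1, n_steps), rep(u2, n_steps)), ncol = 2)
}

# deterministic "varied" design exercising both channels
varied_design <- function(n_steps = 10) {
  cbind(seq(0.01, 1, length.out = n_steps),
        rev(seq(0.01, 1, length.out = n_steps)))
}

# hand-built deterministic 2-step, 2-action decision problem; the exact
# values come from exhaustive backward induction done inline where used
toy_mdp_memory <- function(reps = 25) {
  o0 <- c(0, 0); oA <- c(1, 0); oB <- c(0, 1)
  base <- list(
    list(o = o0, a_idx = 1L, r = 1, o_next = oA, done = 0),
    list(o = o0, a_idx = 2L, r = 0, o_next = oB, done = 0),
    list(o = oA, a_idx = 1L, r = 2, o_next = oA, done = 1),
    list(o = oA, a_idx = 2L, r = 0, o_next = oA, done = 1),
    list(o = oB, a_idx = 1L, r = 5, o_next = oB, done = 1),
    list(o = oB, a_idx = 2L, r = 1, o_next = oB, done = 1))
  rep(base, reps)
}
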