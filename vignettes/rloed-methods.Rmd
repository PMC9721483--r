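---
title: "Designing informative chemostat experiments: models, agents and conventions"
author: "rloed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing informative chemostat experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design problem

An auxotrophic bacterial strain grows in a chemostat at dilution rate $q$
on two substrates: a carbon source and the nutrient the strain cannot
synthesise. With Monod kinetics in both substrates the model is

$$
\mu = \mu_{\max}\,\frac{C_1}{K_1 + C_1}\,\frac{C_0}{K_0 + C_0},\qquad
\begin{aligned}
\dot C_0 &= q\,(C_{0,in} - C_0) - \mu N / \gamma_0\\
\dot C_1 &= q\,(C_{1,in} - C_1) - \mu N / \gamma_1\\
\dot N   &= (\mu - q)\,N.
\end{aligned}
$$

Only the population $N$ is measured. An experiment is ten two-hour
sample-and-hold intervals: before each interval the experimenter (or an
agent) picks the two inflow concentrations within $[0.01, 1]$ g/L, and the
goal is to choose them so that the resulting time series pins down
$(\mu_{\max}, K_0, K_1)$ as tightly as possible. The yields
$\gamma_0, \gamma_1$ are practically unidentifiable from population data
and $q$ is set by the experimenter, so none of them is a target of
inference.

Informativeness is scored by D-optimality: the log-determinant of the
Fisher information matrix (FIM) of the measured output with respect to the
focal parameters. The package propagates log-scaled forward sensitivities
$\bar X_{ij} = \theta_j\, \partial X_i / \partial \theta_j$ of the *full*
state jointly with the state — the sensitivity system only closes over all
states, because the vector field depends on the hidden substrate
concentrations — and accumulates
$\dot I_{jk} = \bar N_j \Sigma^{-1} \bar N_k$ along the trajectory, all as
one compiled 18-dimensional ODE system integrated by a stiff-capable
variable-step solver (`deSolve::lsoda`, `rtol = 1e-8`, `atol = 1e-10`).
Substrate relaxation near the half-saturation constants is orders of
magnitude faster than the dilution timescale, so a stiff-capable method is
not optional. Correctness of the sensitivities is established against a
central finite-difference oracle on $N(t)$, and every information
increment is checked to be symmetric positive semidefinite.

## Noise and scale conventions

Two distinct variance conventions live in the model object, and they are
deliberately separate:

* `noise` — the *measurement error* used when simulating data for
  inference: Gaussian with variance equal to 5% of the measured output on
  the $10^9$ cells/L measurement scale (`noise_model(cv = 0.05,
  sigma_mode = "linear", measurement_unit = 1e9)`). This is the literal
  error model for this experimental setup, and it also provides the
  weights for the nonlinear least-squares fits.
* `fim_noise` — the variance weighting $\Sigma$ inside the information
  integrand: by default a *constant unit variance on the same
  $10^9$ cells/L scale*.

Why two? No single convention reproduces both halves of the study this
package implements. We scanned the three families (relative, proportional,
constant variance, each over a range of measurement units): the designers'
achievable optimality scores shift by an additive constant within each
family, and only the constant-unit-variance weighting places the
full-horizon optimum near 20 log-det units, the scale on which optimality
scores for this system are conventionally reported. The relative-variance
weighting (which has the theoretical appeal of making the score invariant
to the population unit — a property the test suite verifies under that
switch) puts the same optimum near 2.6. All conventions remain one
argument away; the default is the one under which scores are comparable
to the published scale.

A related loose end is the population scale itself: with the Table-of-
parameters yields ($\gamma \approx 5\times 10^{11}$ cells/g) and inflow
up to 1 g/L, the steady-state population approaches
$5\times 10^{11}$ cells/L, an order of magnitude above the
$50\times 10^9$ normaliser that supposedly maps all measurements into
$[0,1]$. We keep the Table yields and treat all normalisers as
configuration (`scaling_scheme()`), with a square-root measurement scaling
for prior-distribution training whose divisor can be calibrated from a
pilot run (`calibrate_sqrt_divisor()`) rather than fixed at a constant
that would discard every episode.

## Classical designers

`osao_design()` implements the greedy one-step-ahead optimiser: at each
interval it maximises the log-det gain of that interval alone, seeding a
bounded quasi-Newton search from the best point of a coarse grid, so each
step's optimum matches a dense grid search (a property the tests assert).
`mpc_design()` solves the full-horizon problem over all 20 input variables
with L-BFGS-B multistart (box midpoint, the greedy design, and seeded
random interior points); including the greedy design among the starts
makes the dominance MPC $\ge$ OSAO structural. Gradients are central
finite differences over the compiled ODE objective; the inner loop runs at
loosened solver tolerances (`1e-6`/`1e-8`) and every candidate is rescored
at the model's full tolerances before designs are compared — agreement
between the two paths is itself under test at $4\times10^{-5}$ log-det
units.

Two caveats a user should know. First, greedy scores are *fragile*:
because the per-step objective is multimodal and greedy is myopic, two
solvers that differ only in which near-tie they pick can follow greedy
trajectories several log-units apart; a per-step *global* greedy is not
the best greedy. Our exact greedy lands at 14.2 on the nominal model.
Second, the multistart MPC reliably reaches 20.5–20.6; reported
full-horizon scores for this system in the literature are a few percent
lower, consistent with a single local solve.

## The reinforcement-learning agents

The episodic environment (`oed_env()`) defines the reward as the
D-optimality *gain* per interval, with the start-of-episode baseline
$\log|I_0| := 0$, so the return telescopes exactly to the final
D-optimality for every policy (asserted in the tests). Observations come
in six formulations — measurement + FIM elements (+ step index),
measurement (+ step index) alone, or measurement plus the full history of
measurements and inputs for recurrent agents — with all network inputs
scaled into roughly $[0,1]$.

`fq_learning()` is neural fitted Q-iteration over the discretised action
grid: after every episode the Q-network is re-initialised and regressed on
bootstrapped targets over the entire transition memory. The discount is 1
(finite horizon; values then equal expected final D-optimality), targets
are divided by 100, and the inner regression (10 epochs, batch 256, Adam
at $10^{-3}$) is deliberately modest since it restarts every episode. The
exploration schedule is $\epsilon(e) = \mathrm{clip}(1 - \log_{10}(e/A),
0, 1)$ with $A = E/11$ — the unique common form that starts at 1 and
reaches 0 at $10A$, i.e. before training ends. Correctness is anchored by
a hand-enumerable two-step decision problem whose exact backward-induction
values the fitted network must reproduce to $10^{-2}$.

`rt3d_train()` is a recurrent twin-delayed deterministic policy gradient:
twin recurrent critics with min-target bootstrapping, clipped
target-policy smoothing, delayed actor updates and Polyak-averaged
targets. The encoder is a two-layer GRU over the (measurement, input)
history; heads are dense ReLU networks; the actor squashes its output onto
the scaled action box with a sigmoid. All networks, including
backpropagation through time, are implemented in vectorised base R and
verified against numerical gradients. Three choices matter in practice and
differ from what a large-compute setting would tolerate: output layers are
micro-initialised ($\pm 3\times10^{-3}$; otherwise the actor saturates at
an action-box corner within the first hundred episodes and its gradient
dies), the actor learning rate is $3\times10^{-4}$, and the target-network
rate is $\rho = 0.99$ so that target lag fits runs with thousands rather
than hundreds of thousands of updates.

## Evaluation pipelines

The value-fitting study asks a simpler question than control: can a
network of each observation formulation *predict the return* of random
experiments run on prior-sampled parametrisations? `generate_value_dataset()`
builds train/test splits of episodes under uniformly random grid actions
(records satisfy the suffix-sum identity exactly), and
`fit_and_score_value()` reports test mean squared error in unscaled return
units over repeated seeded fits. Time-blind memoryless agents (formulation
IIb) fail dramatically here, which is the point of the negative control.

The inference study closes the loop: `simulate_noisy_dataset()` corrupts
the model trajectory at the eleven interval boundaries with the
measurement noise model, `fit_parameters()` refits the focal parameters by
weighted nonlinear least squares on a log scale inside the prior box
(bounded Levenberg–Marquardt with multistart, finite-difference steps set
above the ODE-solver noise floor, and a quasi-Newton polish because the LM
bound projection can stall against a box edge short of the optimum), and
`inference_metrics()` summarises truth-normalised error and the
log-determinant of the estimate covariance. The truth-normalised
convention ($\hat\theta/\theta$) is the only one that makes parameters
spanning four orders of magnitude commensurable. Noiseless data from an
informative design are recovered to better than 0.1%; with 5% noise, the
likelihood genuinely fails to constrain $K_0$ from eleven samples, so the
bounded maximum-likelihood estimate concentrates at a box edge — the
reported metrics are properties of the estimation problem, not of the
optimiser.

## Problem sizes and what the tests show

The packaged checks run at desk scale, chosen once: value fitting uses
1,000 parametrisations per split with five repeated fits (the study design
also supports 10,000); the fitted-Q learning-progress check uses 500
episodes on a 2×2 action grid (learning over the full 100-action grid is
slow and high-variance — the small grid isolates "does the agent learn"
from "is the action space hard"); the recurrent TD3 check uses 1,000
episodes with a 32-unit encoder, 64-unit heads, batch 128, updates every
third environment step and a $5\times10^{-4}$ actor step; inference uses
30 replicates. Training at these sizes
demonstrates learning progress and qualitative orderings, not the
asymptotic scores of multi-hour full-scale runs (50,000 FQ episodes,
17,500 TD3 episodes with 64/128-unit networks, ten repeats), which the
configuration surface supports but nothing here asserts.

The synthetic-data generator *is* the study: all data are simulated from
the chemostat model, so passing tests show correctness of the machinery
and behaviour of the methods under the model's own assumptions — perfectly
known structure, Gaussian output error, fixed initial conditions. They say
nothing about structural mismatch, non-Gaussian noise, input actuation
error, or biological drift in a real bioreactor.

## Known limitations

* Design optimisation uses finite-difference gradients through the ODE
  solver; an adjoint or automatic-differentiation path would scale better
  in the number of inputs.
* The greedy designer's printed-score fragility discussed above.
* Recurrent training is single-threaded R; it is adequate for the
  desk-scale protocols and two orders of magnitude short of a GPU
  implementation, which changes what "full scale" means in practice.
* The instability filter and sqrt-scaling calibration target this model's
  prior box; other models plugged into the same environment surface will
  need their own calibration pass.
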