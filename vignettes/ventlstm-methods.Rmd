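---
title: "Methods: metaheuristic-tuned LSTM prediction of ventilator airway pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metaheuristic-tuned LSTM prediction of ventilator airway pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A pressure-controlled mechanical ventilator drives air into a patient's
lungs through an inspiratory solenoid valve (opening fraction `u_in`,
0–100) and releases it through a binary expiratory valve (`u_out`).  The
clinically relevant state variable is the airway pressure in the
respiratory circuit (cmH2O).  Predicting that pressure from the valve
commands and the patient's lung mechanics — airway resistance `R`
(cmH2O/L/s) and compliance `C` (mL/cmH2O) — is a sequence-regression
problem: pressure at consecutive time steps is strongly autocorrelated,
and the response to a valve change is delayed, so a recurrent model with
memory is the natural fit.

`ventlstm` implements this pipeline end to end: a long short-term memory
(LSTM) regressor built from its gate equations, a Chimp Optimization
Algorithm (ChoA) that selects the LSTM's hyperparameters, three baseline
metaheuristics (PSO, GWO, WOA) behind the same optimizer contract, a
single-compartment lung simulator that emulates the public
ventilator-pressure dataset schema, and a repeated-run ANOVA protocol for
comparing the optimizers.

## The LSTM regressor

Each memory cell applies, at every time step, with `[h, x]` the
concatenation of the previous hidden state and the current input:

* forget gate `f_t = sigmoid(W_f [h_{t-1}, x_t] + B_f)`
* input gate `i_t = sigmoid(W_i [h_{t-1}, x_t] + B_i)`
* candidate `c~_t = tanh(W_c [h_{t-1}, x_t] + B_c)`
* output gate `o_t = sigmoid(W_o [h_{t-1}, x_t] + B_o)`
* cell state `c_t = f_t * c_{t-1} + i_t * c~_t`
* hidden state `h_t = o_t * tanh(c_t)`

Layers stack by feeding `h_t` of one layer as `x_t` of the next; a linear
readout maps the top hidden state to one pressure value per time step.
The training cost is the mean squared error (MSE) over all time steps.
Gradients are exact reverse-mode backpropagation through time,
implemented in compiled code and verified against central finite
differences (relative error below `1e-4` in the test suite); the forward
pass is verified against an independent scalar-loop implementation of the
equations above to `1e-12`.

Choices the gate equations do not fix, and how this package makes them:

* **Weight training rule.** Only the hyperparameters of training are
  searched; the update rule itself is Adam (`beta1 = 0.9`,
  `beta2 = 0.999`, `eps = 1e-8`) by default, with plain SGD available.
  Adaptive steps are the standard choice for LSTMs and make the fitness
  landscape far less sensitive to the learning-rate coordinate.
* **Initialization.** Uniform in `+/- 1/sqrt(fan_in)`, seeded; biases
  zero.
* **Readout.** A single linear layer on the top hidden state per step
  (the target is one scalar pressure per sample).
* **Standardization.** Input features are z-scored with statistics of
  the training split only; the pressure target is likewise z-scored for
  conditioning and predictions are mapped back to cmH2O.  Fold-internal
  statistics are used inside cross-validation.
* **Batching.** Whole breaths (about 80 samples) are the batching unit;
  at this sequence length no truncated backpropagation is needed.

## The Chimp Optimization Algorithm

ChoA is a population metaheuristic whose four best individuals — the
attacker, barrier, chaser and driver — steer the rest.  For a chimp at
`x` and a leader at `L`, a candidate move is

```
d = | c * L - m * x |,      x' = L - a * d
```

with `c = 2 r2` in `[0, 2]`, `m` a chaotic-map value, and the attack
coefficient `a` derived from a coefficient `l` that decays linearly from
2.5 to 0 over the iterations.  With probability `Pr = 0.5` a chimp moves
to the mean of the four leader-directed candidates (each leader drawing
its own `r1`, `r2`, `m`); otherwise it relocates chaotically around the
attacker with the move scaled by a fresh chaotic value,
`x' = attacker - a * m * d`.

Three points in the printed method are ambiguous, and the package
resolves them explicitly:

* **The attack coefficient.**  The printed form is `a = 2 l r1 - 1`,
  which does not shrink to zero as `l` decays; the form used in the
  original ChoA literature is `a = 2 l r1 - l`.  Both are implemented
  behind `a_formula` (`"paper"` is the default for fidelity;
  `"original"` converges more tightly, and the test suite documents that
  its median final sphere fitness beats the `"paper"` variant).
* **The branch condition.**  The two-branch position update prints the
  same condition for both branches; the package reads it as the
  narrative describes: below the threshold the prey-directed
  (leader-mean) move, at or above it the chaotic relocation.
* **The chaotic map.**  Unspecified; the logistic map `x <- 4x(1-x)` is
  the default with a tent map as the alternative, both seedable through
  `map_init` (default 0.7, away from the logistic map's fixed points).

Boundary handling is clamping (idempotent), leaders are refreshed from
the pool of previous leaders plus the new population with a stable
fitness-then-index order (so the attacker never worsens and ties resolve
deterministically), and every random draw comes from one seeded stream
in a fixed, documented order (`phi`, then per-leader `r1`, `r2`, with the
chaotic map advancing once per pair) so a scripted-generator oracle can
reproduce a step exactly.  Whether `phi` is drawn per chimp or per
dimension is unstated in the source method; per chimp is used.

The baselines use their canonical published update rules with the
standard parameterization adopted here: PSO with 30 particles, cognitive
and social factors 0.75, and linearly decaying inertia 0.9 to 0.4 (the
inertia schedule is unstated in the source and is the common default);
GWO with population 10 (the "gene mutation / crossover" entries listed
alongside it in the source are genetic-algorithm parameters inapplicable
to canonical GWO and are ignored); WOA with 50 whales and spiral constant
`b = 1`.  All share 200 iterations and best-so-far elitism, so every
trace is non-increasing.

## Hyperparameter search space

The optimizer works in the unit box `[0, 1]^4`; coordinates decode to
the four searched hyperparameters: epochs `N_I` (integer,
round-half-up), learning rate `L_R` (exponential map, i.e. uniform in
log space), hidden units `N_HU` (integer) and layers `N_L` (integer).
The source method never prints its bounds; the package defaults —
`N_I` in [5, 50], `L_R` in [1e-4, 1e-1], `N_HU` in [4, 128], `N_L` in
[1, 3] — cover the magnitudes its text implies and are overridable in
`hyperparam_space()`.  Out-of-bounds positions are clamped before
decoding, never rejected.  The fitness of a decoded configuration is the
training MSE by default (the fitness the tuning loop states), with
five-fold breath-level cross-validation (`"cv5"`) recommended and used in
this package's own end-to-end tests because it guards against degenerate
overfit selections.  A diverging training run scores `+Inf` (logged, and
fed to the optimizer as a large finite sentinel) so the search survives
bad regions.  Decoded configurations are cached within one tuning run;
since fitness is deterministic given the seed, re-visiting a rounded
point costs nothing.

## The breath simulator

The public ventilator dataset cannot be redistributed here, so the
package ships a generator that emulates its schema and physiology from a
single-compartment linear lung model — the standard textbook
representation of a test lung on a bench circuit:

* net flow `dV/dt = q_in (1 - leak) - q_out`, with
  `q_in = Q_max u_in / 100` (default `Q_max` = 1 L/s) and passive
  exhalation `q_out = u_out * (P - PEEP) / R`; because the outflow and
  the pressure it creates are coupled, each step on the 80-sample,
  3-second grid solves them self-consistently — with
  `a = 1000 dt / C + R` and `b = 1000 V / C` the within-step outflow is
  `q_out = (b + a q_in) / (R + a)` — which keeps the exhalation decay
  smooth, the volume non-negative (and exactly equal to the discrete
  integral of net flow), and the pressure at or above PEEP while the
  expiratory valve is open;
* observed pressure `P = PEEP + 1000 V / C + R dV/dt + noise`, with
  volume in litres, compliance in mL/cmH2O, additive Gaussian noise
  (default sd 0.05 cmH2O) on the observation only — the latent state
  stays clean so oracle checks are exact;
* breaths draw `(R, C)` from the 3x3 grid R in {5, 20, 50} x C in
  {10, 20, 50}, with a randomized ramp-to-plateau inspiratory profile
  (~1 s, boundary jittered +/-10 %) followed by exhalation;
* PEEP defaults to 5 cmH2O (a typical bench setting; the source never
  states its value) and a 1 % inspiratory-flow leak emulates the slight
  expiratory-valve leak visible in the source's pressure distributions.

The simulator reproduces the qualitative findings the exploratory
analysis reports — open-valve pressures concentrate below closed-valve
pressures, distinct `(R, C)` pairs produce distinct pressure
distributions, and pressure correlates more strongly with `u_in` than
with `R` — and those properties are asserted in the test suite.  What it
does **not** emulate: patient effort (spontaneous breathing), nonlinear
or multi-compartment mechanics, sensor quantization, and the
idiosyncrasies of the real bench hardware.  Passing tests on simulated
breaths therefore demonstrate that the pipeline's machinery is correct
and that the search improves the model under known physics; they do not
certify accuracy on real ventilator data.

## Engineered features

Within each breath: the lung setting `delta = R * C`; `cisv`, the
cumulative sum of `u_in`; `integral`, the inter-sample time difference;
and `differential`, the inter-sample `u_in` difference (both difference
features are 0 at the first sample so lengths stay aligned).  The
selection step keeps `delta`, `cisv` and `integral` and drops
`differential`, which fails to separate the pressure distributions; the
selection is configurable.  Two readings in the source are ambiguous:
"integral" is taken literally as the time difference, and "differential"
differences `u_in` (pressure is the target and unavailable at inference).
Spearman's rank correlation is computed from the rank-difference formula
with average ranks for ties (the printed formula assumes no ties); the
exploratory correlation matrix defaults to Spearman with Pearson
available, since the source's text and its figure caption disagree on
which was used.

## Statistical comparison

Each optimizer is re-run on the same split with independent seeds; each
run's test MSE fills a run-by-method matrix, and a classical one-way
ANOVA at the 95 % confidence level tests equality of the method means,
with two-group ANOVAs against the reference method as the pairwise
report.  The source reports a p-value per run per method pair — a
construction it does not explain — so this package implements the
standard protocol its text describes (one test across the runs) instead.
The test suite checks the implementation against a hand sums-of-squares
oracle and verifies its type-I error calibration by simulation
(3 equal-mean Gaussian groups of 10, 2000 replicates, empirical
rejection rate required to fall in [0.03, 0.07] at the nominal 0.05
level).

## Problem sizes used by the tests and the acceptance script

Training hundreds of LSTMs at the source's full scale (125,000 breaths,
200-iteration searches, 20 repetitions) is a multi-hour exercise; this
package's own experiments are scaled-down versions chosen once and used
everywhere:

* end-to-end tuning runs on 200 simulated breaths with a search budget
  of population 4 and 10 iterations, hyperparameter bounds `N_I` in
  [5, 12], `L_R` in [3e-3, 1e-1], `N_HU` in [4, 32], `N_L` in [1, 2],
  batch size 64, five-fold cross-validated fitness, five independent
  seeds, and a baseline of eight uniformly random configurations;
* the optimizer benchmark uses the 5-dimensional sphere function with
  each method's standard population over 20 seeds;
* the acceptance script's optimizer comparison uses three runs per
  method with the training-MSE fitness (the tuning loop's stated cost)
  and reports the test-set MSEs and their ANOVA.

At these sizes the comparison demonstrates the pipeline's operational
claim — the metaheuristic search finds configurations at least as good
as random sampling at equal budget, with ChoA competitive among the four
methods — while the printed full-scale MSE values of the source remain
out of reach by construction (different data, different compute scale).

## Numerical notes and limitations

* Everything is deterministic given a seed: optimizers draw from one
  seeded stream, fitness caches are keyed on decoded configurations,
  CSV writers emit 17-significant-digit values, and serialized JSON
  artifacts omit wall-clock fields, so identical seeds give
  byte-identical files.
* Ties: leader refresh is stable (fitness, then index); grid search
  breaks ties by grid order; KNN breaks distance ties by training-row
  index.
* Degenerate inputs: constant feature columns get unit scale (no
  division by zero); constant columns in correlation matrices are
  flagged `NA` with a warning; an all-divergent tuning run raises an
  error advising narrower learning-rate bounds.
* The LSTM is CPU-only, double precision, and unidirectional;
  bidirectional/GRU variants and multi-objective search are out of
  scope.
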