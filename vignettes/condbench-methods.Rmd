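---
title: "Methods: conditioning benchmarks and online TD learners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditioning benchmarks and online TD learners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

condbench packages three diagnostic prediction problems from the
animal-learning tradition -- trace conditioning, noisy patterning, and
trace patterning -- as seeded discrete-time simulators, together with the
online learners customarily benchmarked on them. This vignette is the
package's account of the models, the parameters that matter, the
numerical choices, and what the tests do and do not establish.

## The prediction problem

At each step the agent observes a binary vector `o_t` (conditioned
stimulus channels, one unconditioned-stimulus channel, distractor
channels) and must output a prediction `V_t` of the discounted return of
the US channel,

    G_t = sum_{k >= 0} gamma^k US_{t+k+1},

learned online: the prediction is updated on every step, before the
outcome is available, as in temporal-difference learning. The discount
factor is tied to the trial timing by `gamma = 1 - 1/E(ISI)` so the
horizon of the return matches the inter-stimulus interval; with the
noisy-patterning ISI of 4 this gives `gamma = 0.75`, and the short,
medium, and long trace-conditioning settings (ISI uniform on {7..13},
{14..26}, {20..40}) give 0.9, 0.95, and 0.9667. Performance is the mean
squared return error (MSRE): the squared gap between the online
prediction and the retrospectively computed return, averaged over all
steps (inter-trial intervals included). Returns at the very end of a
finite stream are biased by truncating the infinite sum, so the last
`H = ceiling(log(tol)/log(gamma))` steps are masked out of the average
(`tol = 1e-8` by default); nothing else is excluded, including any
warm-up period.

## Environments

**Trace conditioning.** Each trial: a single CS for 4 steps, a stimulus-
free trace interval, then the US for 2 steps, `ISI` steps after CS onset.
The ITI (US onset to next CS onset) is integer-uniform on {80..120}. All
"uniform on (a, b)" ranges are read as discrete uniform on the inclusive
integer range, which makes the stated expected ISIs (10, 20, 30) exact.
Ten free-running binary distractor channels with mean onset intervals 10,
20, ..., 100 steps run throughout (ITIs included): each inactive channel
draws a Bernoulli(1/mean) candidate onset every step; an onset holds the
channel active for 4 steps; candidates arriving while active are ignored.
This is the simplest discrete-time rendering of Poisson-scheduled
distractors, and it implies a long-run active fraction of
`duration/(duration + mean)` -- a renewal-process identity the tests
check against generated streams.

**Noisy patterning.** `n` CSs appear simultaneously for 4 steps at trial
onset. `k` activation patterns, each with exactly `n/2` active CSs, are
drawn without replacement at construction. Half of all trials present an
activation pattern (uniformly chosen); the other half present a uniform
draw from the complement of the activation set over all `2^n`
configurations (their composition is not prescribed by the protocol; the
uniform-complement choice is ours). The US fires 4 steps after CS onset
iff the configuration is an activation pattern, except that a single
noise mechanism flips the outcome in `noise_pct`% of trials (covering
both "pattern but no US" and "no pattern but US"). Distractor channels
are trial-locked -- i.i.d. Bernoulli(0.5) per trial, co-occurring with the
CSs -- and are absent during the ITI (a choice we made where the protocol
is silent). The defaults (8 CSs, 8 patterns, 10 distractors, 10% noise)
follow the one fully printed configuration; the easy/medium/hard presets
in `noisy_patterning_preset()` are this package's own labeled choices.

**Trace patterning** combines the two: pattern logic, stochastic ISI,
and free-running distractors, so a learner must simultaneously bridge
the trace interval and identify which configurations predict the US.

The environment state machine is trial-granular: each trial's ISI,
pattern, outcome flip, ITI, and distractor draws happen in a fixed order,
then the step block is emitted. `env_step()` iterates over exactly the
buffer `generate_stream()` fills, so the two access paths cannot
diverge. Every environment owns its RNG state (swapped in and out around
buffer extensions), making streams bit-reproducible from `(config, seed)`
regardless of interleaved R RNG use. Trial annotations (pattern
membership, noise flips, phase) ride on an evaluation-only side channel
that learners never see.

## Fixed representations

All fixed representations append a bias feature (always 1, last element)
and treat every channel identically (CS, US, and distractors all get
traces/features). The stimulating trace of a channel is set to 1 at a
rising edge and decays multiplicatively by `tau` every step -- including
while the stimulus remains on (onset-triggered, per the protocol). The
default `tau = 1 - 1/E(ISI)`: the phrase "decay parameter set according
to the ISI: 1/E(ISI)" is ambiguous between a per-step decay *amount* and
a time constant, so the decay rate `1/E(ISI)` per step (i.e.,
`tau = 1 - 1/E(ISI)`) is the default and `tau` is exposed as a knob.

* `rep_presence()` -- the observation bits themselves. During the trace
  interval only the bias is active, so the representation cannot carry
  the prediction across the gap; this is the diagnostic baseline.
* `rep_tilecoded()` -- tile coding of each channel's trace: 2 tilings of
  8 tiles, offsets evenly spaced (`j/(n_tilings*n_tiles)`), deterministic
  rather than hashed since the input is a scalar in [0, 1]; exactly one
  active tile per tiling per channel, clamped at the boundaries.
* `rep_microstimulus()` -- per channel, 8 Gaussians of the trace with
  centers equally spaced in (0, 1] and standard deviation 0.8 (in trace
  units, the printed value), each scaled by the trace height
  (`f_i = y * exp(-(y - c_i)^2 / (2 sigma^2))`), so features rise and
  fall in sequence across the trial.
* `rep_esn()` -- an echo state network: fixed two-point (+/-
  `input_scaling`) input and prediction-feedback weights, sparse internal
  matrix rescaled to spectral radius < 1 (echo-state property; the
  feedback carries the *previous step's own prediction*, keeping the
  construction causal), tanh units, only the linear readout learned. The
  defaults (40 hidden units, scaling 0.5, radius 0.9, density 0.1) are
  mid-range values of the customary sweep grids; the protocol's own
  values are figure-only, so these are package choices.

## Linear TD(lambda)

The learner is semi-gradient TD(lambda) with accumulating eligibility
traces over any fixed representation:

    delta_t = US_{t+1} + gamma V_{t+1} - V_t      (pre-update weights)
    z_t     = gamma lambda z_{t-1} + x_t
    w      <- w + alpha delta_t z_t               (plain-SGD mode)

`lambda = 0.9` for fixed representations. The benchmarks train with Adam
(beta1 0.9, beta2 0.999, eps 1e-8); how Adam should interact with
eligibility traces is not prescribed anywhere we know of, so the package
feeds the pseudo-gradient `-delta_t z_t` to the standard bias-corrected
moment updates, with `alpha` as Adam's learning rate. Plain SGD mode is
retained because it is exactly the textbook update, and it is what the
convergence oracle tests use: on a 5-state Markov reward chain with
known transitions, tabular TD(0) under a Robbins-Monro step-size
schedule (`1/(5 + N(s))^0.5` per-state) with Polyak tail averaging
recovers the analytic `v = (I - gamma P)^{-1} P c` to 1e-3 at gamma =
0.9 -- a demanding absolute tolerance that requires tens of millions of
steps, which is why that loop is compiled (`run_td_tabular()`, asserted
step-for-step identical to `td_update()`).

Non-finite TD errors abort a run with a diagnostic rather than silently
poisoning the log.

## Recurrent learners

Vanilla RNN, LSTM (forget-gate bias initialized to 1), and GRU
(candidate input `[o_t; r * h_prev]`), one hidden layer, linear value
head, trained on semi-gradient TD(0) targets (`lambda = 0` for all
recurrent learners). Weights initialize uniform on
`(-1/sqrt(n_hidden), 1/sqrt(n_hidden))`; the value head starts at zero
(predictions start exactly at 0, and an all-zero US stream provably
leaves the parameters untouched). No gradient clipping by default.

**T-BPTT.** At step t the network is unrolled `T` steps from the stored
hidden state `x_{t-T-1}` -- stored when it was computed online, never
recomputed, hence deliberately stale -- over `o_{t-T} .. o_{t-1}`. The
window's TD(0) losses `0.5 (US_{k+1} + gamma stopgrad(V_{k+1}) - V_k)^2`
are *summed* and the newest loss bootstraps on the *online* prediction
`V_t` (two points the protocol leaves open; these are our choices,
fixed and documented here). One Adam update per step over overlapping
windows; a `update_stride` option trades fidelity for speed. The online
hidden state that drives behavior is computed incrementally with the
current parameters and is never revised by updates.

**RTRL.** The influence matrix `J_t = d(state_t)/d(theta_rec)` is
propagated forward each step (`J <- A J + B` with `A`, `B` evaluated at
the parameters that produced that step's forward pass) and the TD(0)
update is applied every step from `J_{t-1}`; `J` is *not* reset after
parameter updates -- the stale-Jacobian protocol. The per-step cost is
`O(state_dim x n_recurrent_params)` (quartic in the hidden size), which
is why the hidden sizes here stay modest. The TD error uses the stored
previous prediction `V_{t-1}` (computed under the previous parameters),
the natural fully online rule.

Gradient correctness is established by two independent routes: with
parameters frozen, the RTRL-accumulated gradient of the summed losses
equals full-unroll backprop from the origin to relative 1e-6 (they agree
to machine precision in practice), and the T-BPTT window gradient
matches central finite differences of a fixed-target window loss to
relative 1e-4. The targets must be frozen in that check because the
bootstrap term is stop-gradient -- differencing the raw loss would
measure the full gradient instead, which is a different quantity.

**Stimulating-trace augmentation.** `augment_with_traces()` concatenates
the per-channel traces to the observation (`[o_t; y_t]`, doubling the
input dimension, default `tau = 1 - 1/E(ISI)`); the learner is otherwise
unchanged. This gives a T-BPTT learner with even `T = 1` an input that
spans the trace interval.

## Protocols, sweeps, seeds

`run_many()` runs an agent for `n_runs` seeds (`seed_base + i`), scoring
each run by MSRE and aggregating mean and standard error across runs;
within a run the environment stream uses `seed` and weight
initialization uses `seed + 500000` as separate substreams.
`sweep_agents()` tabulates a list of agents under identical seeds and
`select_best()` picks the lowest mean MSRE, ties going to the earliest
(order grids from smallest hyperparameter up). The full-scale protocol
(2M-5M steps, 30 runs, the complete step-size/size grids) is expressible
with the same functions; the package's own test protocol is the scaled
version below.

## Scaled study sizes and what the tests show

The test suite replicates the benchmark findings at desk scale -- the
package's chosen sizes, stated here once:

* linear fixed representations: short-ISI trace conditioning, 200k
  steps, step size swept over `2^{-6, -8, -10, -12}` per representation,
  2 seeds per cell. Finding reproduced: with swept step sizes,
  microstimulus and tile-coded traces each reach at most half the
  presence-representation MSRE, and the presence prediction through the
  trace interval equals its (small) bias weight.
* recurrent learners: LSTM, 16 hidden units, 150k steps, 5 seeds.
  T-BPTT truncations T in {1, 5, 10, 20} with step size swept over
  `2^{-11, -12}` per T inside the test; RTRL and the trace-augmented
  T = 1 variant use `2^-9`, selected once by the same
  lowest-mean-MSRE sweep protocol during development and fixed as
  defaults. Findings reproduced: T = 10 at most halves the T = 1 error
  on E(ISI) = 10; mean MSRE is non-increasing in T up to one standard
  error; RTRL matches the best truncation window; trace augmentation
  brings T = 1 within 1.5x of un-augmented T = 10.

What these scaled tests show is the *ordering and ratio structure* of
the methods under the stated trial statistics, not the asymptotic error
levels of multi-million-step training; absolute MSREs here are higher
than at full scale because learning is still progressing. The synthetic
streams realize the protocol's stated distributions exactly (integer
ISIs/ITIs, Bernoulli-thinned distractors, balanced activation patterns);
they do not emulate sensor noise, continuous stimulus intensities,
overlapping (delay-conditioning) stimulus arrangements, or
action-conditional dynamics, so passing tests say nothing about those
regimes.

## Numerical notes and limitations

* Returns are computed by a reverse recursive filter (exact backward
  recursion), not naive summation; the recursion identity is asserted at
  every valid index of generated streams.
* Tile-coding indices are `floor((y + offset) * n_tiles)` clamped to the
  last tile, so `y = 1` (a fresh onset) lands in the top tile rather
  than overflowing.
* Distractor episodes last exactly `duration` steps, but an onset landing
  exactly at expiry concatenates episodes, so observed run lengths are
  multiples of `duration`.
* The R reference engine (`engine = "r"`) and the compiled fast path of
  the linear agent agree to 1e-10 over every representation; tiny
  differences trace to libm rounding, not logic.
* RTRL is exact (no approximation beyond the stale-Jacobian protocol
  itself); its memory is one `state_dim x n_recurrent_params` matrix.
* Parameter-sweep selection is a pure function of the summary table;
  re-running a configuration reproduces summaries bit-for-bit.
* Known limitations: no true-online TD(lambda) or dutch traces; no
  hashed or multi-dimensional tile coding; single recurrent layer only;
  no UORO/SnAp-style RTRL approximations.
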