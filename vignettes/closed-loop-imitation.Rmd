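---
title: "Closed-loop decoder training as online imitation learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop decoder training as online imitation learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imitatebci)
```

## The model

A brain-computer interface decoder maps neural activity and the current
effector state to a kinematic update.  When the user cannot move overtly,
there is no supervised label for what they intended; training instead uses
an *intention oracle* — a goal-aware model of the user's instantaneous
intent — and the learning loop becomes online imitation: execute the
current decoder (possibly blended with the oracle), query the oracle at
every visited state, aggregate, refit.

Concretely, one session runs `K` reach trials.  In trial `k` with goal `g`:

1. the oracle supplies the intended velocity `o_t` (the training label);
2. the signal actually driving the neurons is `u_t`, equal to `o_t` unless
   an intention mismatch is configured;
3. neural activity is `n_t = A u_t + c_t`, `c_t ~ N(0, σ²I)`;
4. the decoder proposes `a_t = F_v n_t + b_v + G_v v_t`;
5. the executed velocity is `β_k o_t + (1 − β_k) a_t` (assisted decoding),
   and the pose advances with the *current* velocity,
   `p_{t+1} = p_t + dt·v_t` — the commanded velocity takes effect one step
   later, exactly as the block structure of the steady-state velocity
   Kalman filter prescribes;
6. the triple `(v_t, n_t, o_t)` is recorded; the trial ends at goal
   tolerance `ε` or at the horizon `T`.

After each trial one of three update rules produces the next decoder:

* **OGD** — one gradient step on the newest trial's loss with rate
  `1/η_k`;
* **MA (smoothBatch)** — `(1 − λ)·old + λ·(ridge fit on the newest trial)`;
* **FTL** — ridge refit on everything aggregated so far, executed exactly
  online by recursive least squares (Sherman–Morrison rank-1 updates of the
  inverse Gram matrix).

The surrogate loss everywhere is the squared error between the decoder
output and the oracle action.  Learning quality is summarized by per-trial
SSE (which folds per-step error together with acquisition time), by
acquisition time itself, and by empirical regret: the cumulative excess
loss of the sequence of held decoders over the single best decoder fit in
hindsight on the same realized samples.

## Assumptions

* Neural tuning is linear in intended velocity, Gaussian, and stationary
  within a session; activity is real-valued (binned rates), not spikes.
* The decoder family is the steady-state velocity Kalman filter treated
  directly as a parameterized policy; no Kalman recursion is run, the
  regression fit determines the gain.
* The oracle is deterministic given the state and goal; mismatch between
  the oracle and the signal driving the neurons is modeled explicitly (see
  below), not left implicit.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `K`, `T_max` | 100, 200 (cursor); 50, 150 (arm) | reaches per session; steps per reach |
| `epsilon` | 0.5 (cursor); 0.2 (arm) | goal tolerance, task units; the arm value bounds the worse fingertip error |
| `speed` | 0.5 | cursor oracle speed, task units/step |
| workspace | `[-10, 10]^3` | cursor goal cube |
| `N`, SNR | 10, 1 (cursor); 75, 1 (arm) | neurons; per-neuron signal power / noise variance |
| `beta` | `1, 0, 0, …` | assistance schedule: one fully assisted reach, then none |
| `exec_noise_pct` | 5 | % intention noise on the *executed* (never the labeled) oracle action while `β > 0` |
| `ridge` | 5 | shared ℓ2 coefficient of all batch fits and the RLS prior; OGD uses `ridge/K` per update |
| `lr0` | 300 | OGD schedule base, `η_k = lr0·k` |
| `lambda` | 0.9 | MA weight on the newest batch fit |
| `mu`, `omega_max`, `delta` | 0.01, 0.1, 0.3 | chain oracle damping; per-joint speed cap (rad/step); wrist radius switching to the touch phase |

Notes on the less obvious choices:

* **dt = 1.** Time is measured in simulation steps (a step corresponds to
  one decoder bin, order 10–50 ms in hardware); all speeds are per step.
* **Ridge = 5.** Regularization exists here to keep closed-loop training
  stable: an early fit can hand `G_v` a spectral radius above 1, and the
  velocity feedback loop then diverges.  We scanned ridge values over every
  study condition shipped with the package (plain cursor sessions across 40
  seeds, rotated-intention, noise and arc mismatch sweeps) and kept the
  smallest value with zero diverged reaches.  As a second line of defense
  the trial runner ends a reach (as a failure) if pose or velocity exceeds
  1e8, so one unstable reach cannot overflow downstream Gram products.
* **lr0 = 300.** OGD needs hand tuning; `tune_ogd_rate()` reproduces the
  grid search (mean cumulative SSE over short sessions).  Values below
  ~150 diverge, values above ~1000 learn needlessly slowly.
* **Bias is never penalized**, so noiseless identifiable data is recovered
  exactly at ridge 0.  The RLS prior therefore has a singular direction;
  the inverse Gram is formed by a direct solve at the first streamed sample
  (provably nonsingular from then on) and updated rank-1 afterwards.
* **Initial decoder** is small random (`scale = 0.01`) with `G_v` rescaled
  below unit spectral radius: stable but uninformative, and not exactly
  zero, which would make the first trial's regression design degenerate.
* **Seeds.**  Each session derives three independent streams (encoding
  model + initial decoder, goal sequence, noise) from one master seed, so
  mismatch studies can share the encoding realization and goal sequence
  across conditions.

## The effectors and oracles

The cursor oracle is the optimal controller for a quadratic cost with a
speed budget: equal-length velocities pointed at the target, shortened on
the final approach so the goal is never overshot.

The arm is a serial 8-joint chain (two "shoulder" joints, an "elbow", two
"wrist" joints, three "finger" joints on short distal links) with `wrist`,
`thumb_tip` and `mid_tip` markers.  Its oracle is a one-step
damped-least-squares resolved-rate controller,
`Δθ = Jᵀ(JJᵀ + μI)⁻¹ e`, on the active marker errors — the standard
closed-form incremental step for a spring-like end-effector penalty.
Reaches have two phases: the wrist approaches the wand; within radius `δ`
the objective switches to touching the two wand points with the two
fingertip markers.  This chain is an intentionally simplified stand-in for
a full musculoskeletal arm model driven by an iterative optimal-control
solver; it preserves the property that matters for the learning dynamics —
strongly uneven task relevance across joints — not anatomical fidelity.
Arm sessions reset the pose between reaches; cursor sessions continue from
the previous endpoint.

Arm noise calibration measures a representative oracle action norm on a
deterministic pilot reach (pure oracle control to a fixed wand) and plugs
its RMS into the same spherical-action SNR formula used for the cursor.

## Intention mismatch

Three wrappers model discrepancy between the oracle and the signal that
actually drives the neurons:

* **noise** — add a uniformly directed vector of norm `pct/100 · ‖o‖`;
* **linear** — apply a fixed invertible operator `M`; training can learn to
  undo a consistent linear bias, so the loss is expected to be unchanged
  when `M` preserves the signal scale (a rotation is the canonical case —
  a pure gain instead changes the effective SNR);
* **arc** — rotate the intention by the same angle in the xy, yz and zx
  planes (applied in that fixed order), with the angle a logistic function
  of goal distance (`phi_max · σ((d − midpoint)/slope)`, defaults midpoint
  3, slope 1): far from the goal the user "intends" an arcing path, near
  the goal the discrepancy vanishes.  No fixed decoder can undo a
  distance-dependent rotation, so residual error grows with `phi_max`.

## What the synthetic generator does and does not emulate

The generator reproduces the *statistical structure* of closed-loop decoder
training: decoder-induced (non-i.i.d.) state sampling, goal-directed
intention labels, linear-Gaussian tuning at a realistic SNR, and trial
termination coupled to performance.  It does not emulate spiking
statistics, tuning drift or nonstationarity, sensory feedback delays, user
co-adaptation, or arm dynamics (inertia, contact).  Passing tests therefore
certify the algorithmic claims — update-rule orderings, regret growth
rates, robustness trends under mismatch — on this generative family, not
decoding performance on any real neural recording.

## Numerical choices and degenerate inputs

* Regression solves assembled normal equations; a singular design at
  ridge 0 is an error instructing positive ridge rather than a silent
  pseudo-inverse.
* RLS re-symmetrizes the inverse Gram each update against drift and
  verifies positive diagonal entries.
* Zero-length trials (goal already inside tolerance) contribute no samples
  and leave the decoder unchanged; the update count still advances.
* `trials_to_recover()` reports `Inf` when a joint's recovery correlation
  never crosses the threshold within a session.
* The "asymptotic" loss of a session is the mean per-trial SSE over the
  final 20% of trials, everywhere.

## Design choices that were genuinely open

* **Regression target.**  The decoder is fit to predict the *oracle
  action* from `[n_t; 1; v_t]` with `v_t` the realized closed-loop
  velocity.  The alternative (predict the realized next velocity) would
  reproduce the executed dynamics rather than imitate intention and cannot
  reduce the imitation loss below the blend it was recorded under.
* **Returned decoder.**  A session reports both the final decoder and a
  "best" decoder: the one held during the lowest-MSE trial of the final
  20% of trials.
* **Problem sizes.**  Shipped analyses use 20 repeats per condition for the
  cursor comparisons and arm recovery and 10 repeats per mismatch level,
  at K = 100 (cursor) / 50 (arm) reaches; these sizes give stable medians
  and orderings while keeping a full reproduction run in minutes on one
  core.

## Known limitations

* **The plateau statistic is fragile.**  The headline "reaches to plateau"
  measure (first trial at which the median-across-repeats SSE curve enters
  and stays within ±25% of its tail level) conflates two things: genuine
  convergence of the learner and sampling noise of a median of 20 values
  whose underlying distribution varies with goal distance.  Under the
  default conditions about a quarter of asymptotic trials sit outside the
  ±25% band, so the "stays" clause is satisfied only late even though the
  curve visibly settles within roughly ten reaches (e.g. the worked example
  in the README drops from ~198 to under 5 by reach 7).  A band wider than
  the median's sampling noise, or a smoothed curve, would measure
  convergence; we report the statistic as defined and flag it here.
* **Early-session transient.**  With a single fully assisted first reach
  (~24 samples), the first fit can push the mean oracle velocity of that
  reach into the unpenalized bias; the second reach then drives at a
  roughly constant wrong velocity and, because cursor sessions continue
  across reaches, the cursor can leave the goal region by tens of task
  units before reaches 3–7 recover it.  Longer assisted reaches, a
  decaying β schedule, or resetting the cursor between reaches all remove
  the transient; the defaults keep the abrupt schedule.
* Neural encoding is stationary by construction; none of the update rules
  shipped here track drifting tuning (MA would be the natural starting
  point, its weakness on stationary data notwithstanding).
* The chain oracle is a one-step controller; it can stall in deep local
  minima of the marker cost for contorted poses (not observed under the
  shipped presets, whose reaches start from a fixed benign pose).
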