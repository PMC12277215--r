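---
title: "exodesign: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{exodesign: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exodesign)
```

# The problem

Passive knee exoskeletons that place a rotational damper across the knee can
absorb part of the negative joint work of walking — most of it done in Early
Stance, and more of it when walking downhill — and thereby reduce the load
carried by the biological joint. Designing such a device means choosing (a)
the damping coefficient $c$ of the damper and (b) the *clutch pattern*: the
subset of gait phases in which a clutch mechanically engages the damper.
Because the wearer's gait adapts to the device, each candidate design must be
scored on an *adapted* gait, which makes design optimization a bilevel
problem:

* **inner loop** — given a device, optimize the controller of a predictive
  gait simulation (here with CMA-ES) so the simulated human walks as well as
  possible with that device;
* **outer loop** — optimize the device parameters themselves with
  Gaussian-process Bayesian optimization over the mixed
  continuous–categorical space (41-point damping grids cross 31 clutch
  patterns into 1271 designs when enumerated exhaustively).

`exodesign` implements the full two-loop platform at desk scale: the
commercial musculoskeletal engine is replaced by a reduced-order planar gait
model that produces every quantity the two cost functions need, so the whole
framework runs and is testable in seconds with no external data.

# The device model

The damper applies a resisting torque proportional to knee angular velocity,

$$\tau_{exo}(t) = \begin{cases} -c\,\omega_{knee}(t) & \text{clutch engaged} \\
0 & \text{otherwise,} \end{cases}$$

with $c \in [0, c_{max}]$ (default $c_{max} = 5$ N·m·s/rad, configurable;
`derive_c_max()` computes the bound as peak baseline knee moment over peak
knee angular velocity). The torque always opposes knee motion, so exo power
$\tau_{exo}\,\omega \le 0$: the device is strictly dissipative. The clutch
pattern is any nonempty subset of the five gait phases
(Early Stance, Late Stance, Lift Off, Swing, Landing), giving
$2^5 - 1 = 31$ patterns; the empty pattern is the no-device baseline and is
excluded from the design space.

# The five-phase gait machine

Phases follow a fixed cycle ES → LS → LO → SW → LN → ES. Transitions are
driven by two signals: the sagittal foot position (foot relative to the
whole-body center of mass, positive forward — a CoM-relative reference is
slope-invariant, which the source of the rules leaves unspecified) and the
normalized leg load (GRF magnitude / body weight):

| from | to | condition |
|------|----|-----------|
| Landing | Early Stance | leg load > stance load threshold |
| Early Stance | Late Stance | sagittal position < Late-Stance threshold |
| Late Stance | Lift Off | contralateral load > stance threshold **or** sagittal position < liftoff threshold |
| Lift Off | Swing | leg load < Swing load threshold |
| Swing | Landing | sagittal position > landing threshold |

All comparisons are strict (ties, a measure-zero event, do not fire), at most
one transition happens per time step (mirroring discrete controller
stepping), and the stance load threshold is part of the optimized controller
vector. Strides are touchdown-to-touchdown intervals of one leg, detected as
Landing → Early Stance transitions.

# The reduced gait model

The neuromuscular forward simulation is replaced by *prescribed-kinematics
inverse dynamics*: the controller vector `controller_theta()` holds a
truncated Fourier series (fundamental + second harmonic) per joint, a stride
period, a stride length, a fore-aft pelvis fluctuation and the stance load
threshold — 18 numbers. "Controller adaptation" is the inner optimizer
reshaping these trajectories. Three constructions make this robust for
derivative-free search:

* **Ground contact by construction.** The pelvis height is the smoothed soft
  maximum of each leg's downward reach (leg extension plus heel/toe drop
  below the ankle), so the most-reaching foot is pinned to the ground for
  *any* controller vector — no contact solver, no falling. A Gaussian
  low-pass (sigma 50 ms) keeps the implied pelvis accelerations, and hence
  ground reaction forces, physiological; without it the soft-max kinks
  produce stance-load spikes near 2 body weights.
* **GRF from momentum.** The total ground reaction force is
  $m(\mathbf{a}_{com} - \mathbf{g})$, shared between the feet by a logistic
  weight on foot clearance (width 5 mm). Averaged over whole strides of a
  periodic gait the vertical GRF therefore equals body weight by
  construction (impulse–momentum closure, verified to 1%).
* **Moment split, not motion change.** Newton–Euler recursion
  (foot → shank → thigh) yields net joint moments; the exo torque only
  re-splits the net knee moment into biological + device parts
  ($\tau_{bio} = \tau_{net} - \tau_{exo}$). Where net knee power is negative
  and $c|\omega| \le |\tau_{net}|$, the identity
  $|\tau_{bio}| = |\tau_{net}| - c|\omega|$ holds exactly — the damper
  offloads the joint precisely as hypothesized.

Slopes are handled in the ground frame: for the downhill scenario the ground
is tilted 5° and gravity acquires an along-slope component pushing the walker
forward.

Two metrics feed the design cost. The **knee load** proxy is
$(\,|F_{knee}| + |\tau_{bio}|/r_{eff}\,)/mg$ with effective extensor moment
arm $r_{eff} = 0.04$ m: a pure intersegmental force would be insensitive to
the damper's torque offloading, so the muscle-compression term is essential.
The **metabolic proxy** is $P_{met} = P_{basal} + \sum_j [\,4.0\,P_j^+ +
0.8\,P_j^-\,]$ over the six biological joint powers (reciprocal efficiencies
of concentric/eccentric muscle work; basal 1.2 W/kg); cost of transport is
total metabolic energy over distance.

# Inner loop

The movement cost mirrors a four-term predictive-simulation objective:
squared speed error (weight 100, target 1.2 m/s), mass-normalized metabolic
effort (weight 1), mean squared excess of ankle angle beyond ±0.7 rad and of
knee load beyond 2 body weights (weights 10), and mean excess of normalized
GRF above 1.4 BW (weight 10). All weights are configuration, chosen for
order-of-magnitude balance at the baseline gait; the knee-load limit is set
*below* the baseline's per-sample peak so the joint-protection term is
active — with a slack limit the term is dead code and knee load becomes an
uncontrolled outcome of the effort-dominated objective.

CMA-ES (rank-one + rank-µ covariance updates, cumulative step-size
adaptation, population $4 + \lfloor 3\ln d\rfloor$) minimizes this cost. The
warm-start mean is evaluated first, outside the budget, so the result can
never be worse than the starting point; invalid gaits (speed off target,
negative normal GRF, knee outside [0, 2.5] rad, loaded airborne foot, no
complete stride) score infinity.

## The matched two-stage protocol

The full-scale platform starts assisted optimizations from the converged
baseline optimum with the baseline's small CMA stds, so assisted solutions
stay near the baseline. At desk-scale budgets the inner optimizer is *not*
converged, and that protocol confounds device effects with leftover
optimization slack (a zero-damping device scored 0.58–0.91 instead of 1.0 in
development). `compute_baseline()` therefore uses two stages: stage 1
optimizes the baseline freely (budget 300); stage 2 refines the stage-1
optimum with small stds (fraction 0.2, budget 200). `evaluate_design()`
applies *exactly* stage 2 — same warm start, stds, budget and seed — to every
candidate device. Under these common random numbers a zero-damping device
reproduces the baseline bit-exactly (design cost 1.0), and cost differences
are paired comparisons attributable to the device.

# Outer loop

The design cost is
$J = w_1\, KL/KL_{base} + w_2\, COT/COT_{base}$ with $w_1 = w_2 = 0.5$,
where $KL$ is the knee-load statistic (mean of the top 10% of knee-load
samples per stride, averaged over strides and both legs) and both terms are
normalized by the baseline of the same scenario. Invalid designs receive a
penalty of 10, far above the ~1 scale of valid costs.

Bayesian optimization: 10 seeded random designs, then proposals maximizing
an acquisition function drawn uniformly each iteration from lower confidence
bound, expected improvement and probability of improvement, over a Gaussian
process with a Matern 5/2 kernel refitted by marginal-likelihood
maximization each iteration. The clutch dimension is encoded as the five
per-phase engagement bits — the natural structure of a subset-valued
categorical, letting the surrogate share information between patterns that
differ in one phase (a flat 31-level one-hot makes all patterns equidistant
and defeats the kernel) — and the acquisition optimum is taken over the
exact discrete pattern set crossed with a dense damping grid, never a
continuous relaxation. The run stops when the best cost improves by less
than 1e-3 over the trailing 15 iterations, or at 100 evaluations. Each
design problem is solved 5 times from different seeds and the best run
selected; brute-force evaluation of the 41 × 31 grid provides the validation
reference.

# What the synthetic fixtures establish — and what they do not

* The **scripted leg-state traces** fire every transition rule (including
  both branches of the Late Stance → Lift Off disjunction) with hand-derived
  expected labels; a green phase-machine suite establishes rule-for-rule
  equivalence with the stated transition logic, not robustness to noisy real
  sensor data.
* The **baseline gait presets** were fit once to standard sagittal-plane
  gait waypoints (knee double-bump, hip sinusoid, stride 1.32 m at 1.1 s)
  and frozen; the downhill preset has deeper loading-response knee flexion.
  They reproduce the qualitative features the platform needs — an M-ish
  stance GRF, a negative knee-power region in Early Stance that is larger
  downhill — not subject-specific kinematics.
* The **known-optimum surrogate** (quadratic in $c$, per-pattern offsets
  growing with symmetric difference from the optimal pattern, Gaussian noise
  sd 0.01, penalty region at near-maximal damping with Swing engagement)
  validates the *outer optimizer*: recovery of the optimum, brute-force
  parity, restart stability. It says nothing about the biomechanics; the
  real-model path is validated separately by the paired-comparison
  properties above.

# Numerical choices and degenerate inputs

* Time step 10 ms over 10 s (the knee-load statistic and COT change < 0.5%
  when the step is halved); derivatives of positions are second-order
  central differences, joint-angle derivatives are analytic.
* GP numerics: two ARD length scales (damping; pattern-bit block), amplitude
  and noise fitted by L-BFGS on the log marginal likelihood, warm-started
  from the previous iteration's optimum; penalties are capped before
  fitting so failures do not wreck the surrogate's conditioning; evaluated
  candidates are excluded from re-proposal.
* Ties in phase thresholds do not fire transitions; stride detection needs
  at least two touchdowns and errors otherwise; empty series, inverted
  bounds, non-finite coefficients and negative damping raise immediate
  errors.
* Cycle normalization resamples each stride to 101 points (0–100%) by
  linear interpolation; Toe Off is the ipsilateral Lift Off → Swing
  transition.

# Known limitations

* **No collision dynamics.** Because kinematics are prescribed and effort is
  the dominant term, a sufficiently converged inner optimizer stiffens the
  stance knee and shrinks the negative-power region the damper exploits —
  at large stage-2 budgets the measured device effect fades toward neutral.
  Real walkers cannot do this (heel-strike collisions force negative work),
  which is why the platform evaluates designs under the constrained
  stage-2 adaptation, and why the device effect here (~2–4% cost reduction)
  is deliberately modest compared to a musculoskeletal engine.
* CMA-ES outcome noise at desk-scale budgets is of the same order as that
  effect; design costs are therefore best interpreted as restart averages
  (the acceptance checks use means over restarts).
* The trunk is massless-rotation (vertical HAT segment); hip residual
  moments absorb the unmodeled trunk dynamics. Muscle-level quantities are
  out of scope by design.
* The exo cannot destabilize the gait (torque does not feed back into
  motion), so the penalty path for "unstable" designs is reachable only
  through inner-loop failure, not through large damping as such.
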