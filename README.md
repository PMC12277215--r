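# exodesign

Two-level design optimization for passive assistive exoskeletons, at desk
scale.

## Who this is for

Researchers and engineers prototyping **passive knee exoskeletons** — a
rotational damper across the knee, engaged by a clutch during chosen gait
phases — who want to explore the device design space *before* building
hardware or committing to a commercial musculoskeletal simulation engine.
The package implements the complete bilevel optimization architecture of
simulation-based device design with a fast reduced-order gait model standing
in for the forward-dynamics engine, so every stage runs in seconds and is
fully testable offline.

## The core method

A candidate device is a pair $(c, P)$: a damping coefficient
$c \in [0, c_{max}]$ and a clutch pattern $P$, a nonempty subset of the five
gait phases {Early Stance, Late Stance, Lift Off, Swing, Landing} —
$2^5 - 1 = 31$ patterns. The engaged damper applies
$\tau_{exo} = -c\,\omega_{knee}$ (zero when disengaged), a strictly
dissipative torque.

Two nested optimizations score and search designs:

1. **Inner loop** (`optimize_gait`): CMA-ES tunes an 18-parameter Fourier
   gait (joint trajectories, stride timing, stance load threshold) on a
   planar inverse-dynamics model, minimizing a four-term movement cost
   (speed error, metabolic effort, ankle/knee-load penalties, GRF penalty).
2. **Outer loop** (`bayes_optimize`): Gaussian-process Bayesian optimization
   with a Matern 5/2 kernel over the mixed continuous–categorical space,
   acquisition drawn per-iteration from {LCB, EI, PI}, 10 random initial
   designs, convergence when the best cost improves < 1e-3 over 15
   iterations (cap 100), 5 restarts with the best run selected. The design
   cost is

   $$J = \tfrac12\,\frac{KL}{KL_{base}} + \tfrac12\,\frac{COT}{COT_{base}},$$

   where $KL$ is the mean of the top-10% knee-load samples per stride
   (averaged over strides and legs) and $COT$ the metabolic cost of
   transport, both normalized by the no-device baseline of the same
   scenario (level ground or a 5° downhill slope). Invalid gaits score a
   penalty of 10.

Brute-force evaluation of the full 41 × 31 = 1271-design grid
(`brute_force`) validates the optimizer, and a known-optimum noisy surrogate
surface (`surrogate_spec`) makes the outer loop testable in isolation.

## Worked example

```r
library(exodesign)

# baseline gait, level ground (two-stage inner optimization)
bl <- compute_baseline("level", optimize = TRUE, budget = 300, seed = 1)

# score one candidate device: c = 2.5 N·m·s/rad, engaged in Early+Late Stance
d <- design_params(2.5, c("ES", "LS"))
r <- evaluate_design(d, bl)

# validate the outer loop on the known-optimum surrogate
spec <- surrogate_spec()
rs <- run_restarts(design_space(), function(d) surrogate_cost(d, spec),
                   seeds = 1:5)
```

printed (seed 1):

```
baseline: knee load 2.23 BW, COT 144.5 J/m, speed 1.18 m/s
design c=2.5, clutch {ES,LS}: cost 0.973 (KL ratio 0.934, COT ratio 1.012)
surrogate best-of-5: c = 1.90, clutch {ES,LS}, cost 0.841 (true optimum c = 2, {ES,LS})
```

Reading the numbers: the baseline walker carries a top-decile knee load of
2.23 body weights; with the stance-engaged damper the paired, matched-seed
comparison drops the knee load by ~6.6% at a ~1% cost-of-transport increase,
for a design cost of 0.973 (< 1 means the device helps overall; a
zero-damping device scores exactly 1.0 by construction). On the synthetic
design surface — whose true optimum is known — the best of five seeded
Bayesian runs recovers the optimal clutch pattern and lands within 2% of the
damping range of the true coefficient, in ~150 evaluations instead of the
grid's 1271.

A command-line interface wraps the same operations:

```sh
Rscript -e 'exodesign::exo_cli()' baseline --scenario level --out runs/
Rscript -e 'exodesign::exo_cli()' grid --n-c 41 --out grid.csv
Rscript -e 'exodesign::exo_cli()' optimize --surrogate --seeds 1,2,3,4,5 --out runs/
Rscript -e 'exodesign::exo_cli()' report --runs runs/
```

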