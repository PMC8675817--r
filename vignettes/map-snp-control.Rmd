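---
title: "Closed-loop control of mean arterial pressure by SNP infusion: models, controllers and design choices"
author: "mapmpc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop control of mean arterial pressure by SNP infusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapmpc)
```

## The control problem

Sodium nitroprusside (SNP) is a fast-acting vasodilator used to manage
arterial pressure during and after cardiac surgery. The infusion pump, the
drug's transport and recirculation, and the pressure measurement chain form
a single-input single-output plant whose controlled variable is the change
in mean arterial pressure (MAP) and whose manipulated variable is the
infusion rate in ml/h. The clinically dominant feature is a transport dead
time of about a minute between a change in infusion rate and its effect on
measured pressure: any useful controller must act on predictions, which is
why this package is built around receding-horizon model predictive control
(MPC).

## The patient model

The pharmacodynamic response is the delayed rational transfer function

$$G(s) = \frac{K (1 + T_3 s)\, e^{-\theta s}}
{\big((1 + T_3 s)(1 + T_2 s) - \alpha\big)(1 + T_1 s)},$$

with drug sensitivity $K$, effect time constants $T_1, T_2, T_3$,
recirculation fraction $\alpha \in [0, 1)$ and dead time $\theta$.
`build_continuous_model()` expands and normalizes this family;
`canonical_patient_model()` returns the reference patient

$$G_p(s) = \frac{5\,(1 + 30 s)\, e^{-60 s}}{1 + 130 s + 4600 s^2 + 30000 s^3},$$

which is stored directly in polynomial form because only the composite
polynomial form of this instance is given in the benchmark — we deliberately do not
reverse-engineer a $(K, T_1, T_2, T_3, \alpha)$ factorization that is not
stated.

`discretize_zoh()` computes the exact zero-order-hold equivalent at
sampling time $T_s$ via the augmented matrix exponential
$\exp\!\big(\begin{smallmatrix} A & B \\ 0 & 0 \end{smallmatrix}\big) T_s$
and converts the sampled state-space model back to transfer-function form
with the Faddeev–LeVerrier recursion. The dead time becomes an integer
sample delay $d = \theta / T_s$ ($d = 60$ at $T_s = 1$ s). The canonical
coefficients agree with the benchmark values to their printed precision,
and the discrete DC gain matches the continuous gain of 5 to better than
$10^{-9}$:

```{r}
dp <- discretize_zoh(canonical_patient_model(), Ts = 1)
dp
```

## Units, the display mapping, and the delay-aligned reference

The loop runs in normalized units: the commanded step has height 1 and the
steady-state infusion is $1/5 = 0.2$ ml/h, comfortably inside the actuator
bound of 2 ml/h. (In absolute units a 40 mmHg pressure change through a
gain of 5 mmHg per ml/h would require 8 ml/h, violating the bound — the
benchmark input constraint is only consistent with a normalized reference.)
For presentation, `run_scenario()` renders absolute pressure through the
display mapping $\mathrm{MAP}(t) = 40 + (80 - 40)\, y(t)$ mmHg: the patient
starts at 40 mmHg and stabilizes at the 80 mmHg target.

No controller can move the output during the transport delay. A unit step
commanded at $t = 0$ therefore has an *achievable* desired trajectory equal
to the commanded step passed through the same delay — a step at sample
$d$. The scenario runner tracks and scores this delay-aligned trajectory
(`make_reference(n, delay = d)`). Scoring the raw, unaligned step would add
a constant $\ge d$ to every IAE regardless of the controller and would make
all controllers look identical over the dead-time interval; the delay-aligned
error isolates what the controller can actually influence. The performance
indices are computed over the full 200-sample window at $T_s = 1$ s; this
window length is consistent with the internal ratio of the benchmark's ISE
and MSE values at $P = 20$.

## The MPC formulation

At each step the controller minimizes

$$J = \sum_{i=1}^{P} \mu_i\, (\hat y(t+i\,|\,t) - w(t+i))^2
    + \sum_{i=1}^{M} \lambda_i\, \Delta u(t+i)^2$$

over $M$ control increments, holding the input constant after the $M$-th
move, and applies only the first increment. The benchmark tuning is $P = 20$,
$M = 2$, $\mu_i = 1$, $\lambda_i = 0.1$, $0 \le u \le 2$ ml/h. Because the
moves are parameterized as increments, a persistent error keeps producing
nonzero increments — the loop has integral action and steps are tracked
without offset.

Three design choices deserve explanation.

**Horizon shift.** With $d = 60$ and $P = 20$, the literal cost window
$\hat y(t+1 .. t+20)$ cannot be influenced by the current moves at all —
read literally, the benchmark configuration is degenerate. The default
(`horizon_shift = TRUE`) therefore costs $\hat y(t+d+1 .. t+d+P)$: the
window starts where the plant becomes reachable, functionally a
Smith-predictor arrangement. The literal window remains available behind
the flag for study; `mpc_predict()` demonstrates the degeneracy.

**One sample of computation latency.** The move optimization (a full GA run
per control period) occupies a sizeable fraction of the 1-s sampling
interval, so `run_closed_loop()` computes $u(t)$ from measurements up to
$t - 1$, the standard arrangement for optimization-based controllers.
This timing also matters dynamically: with the idealized measure-then-act
timing, the unconstrained receding-horizon law for this plant and tuning
has a closed-loop spectral radius slightly above one (a slowly growing
oscillation that the input bounds trim into a small sustained limit cycle),
whereas with the one-sample latency the loop is asymptotically stable at
$P = 20$ and $P = 40$ and the tracking error decays below $10^{-3}$ well
inside the window. At $P = 5$ the loop limit-cycles in either timing, which
is exactly the "jumpier, worse" short-horizon behaviour the horizon sweep
reports. A reader can reproduce the analysis by closing the loop with the
analytic unconstrained law $\,m = (S^\top S + \lambda I)^{-1} S^\top (w -
\text{free})\,$ and examining the eigenvalues of the resulting linear map.

**Constraint handling.** Candidate genes are bounded by
$[u_{\min} - u(t-1),\; u_{\max} - u(t-1)]$, so every evaluated first move is
feasible by construction; cumulative inputs are additionally clipped
sequentially, and the cost is charged on the *effective* (clipped)
increments. The applied input is clipped once more as a hard guarantee.
The all-zero move chromosome is always injected into the optimizer's
initial candidates, so the optimized cost can never exceed the cost of
inaction.

## Optimizers

**Genetic algorithm** (`ga_optimize()`): real-coded chromosomes (the $M$
control increments), population 100, 10 generations, crossover probability
0.7, per-gene mutation probability 0.005, full generational replacement
with one elite — the benchmark GA budget. Where the benchmark description
is silent we use: tournament selection of size 2, whole-arithmetic blend
crossover with a uniform per-pair mixing coefficient, and additive Gaussian
mutation with standard deviation 10% of the gene's bound width, clipped to
bounds. "Insertion rate 1" is read as full generational replacement; the
mutation probability is read as per-gene. The GA search space is the
bounded move box above — the bounds are a design decision derived from the
input constraint, not part of the benchmark description.

**Grid search** (`grid_oracle()`): exhaustive evaluation on a regular
per-gene grid with lexicographic tie-breaking. At 101×101 resolution it is
the verification oracle for the GA; at the deliberately coarse 15×15
default it doubles as the "plain MPC" baseline — a deterministic optimizer
with a budget about a quarter of the GA's, whose move quantization produces
the visibly rougher tracking one expects from a plain implementation.

**Particle swarm** (`pso_optimize()`): global-best PSO, swarm 30 and 33
iterations (budget-matched to the GA's ~1000 evaluations per step),
inertia 0.7, cognitive and social coefficients 1.5, velocity clamping at
half the bound width, and bound reflection. The benchmark comparison names
PSO-MPC but gives no PSO settings; these are conventional defaults.

**PID** (`pid_step()`, `ziegler_nichols_tune()`): positional PID with
trapezoidal integral, derivative on error, output clamping and
conditional-integration anti-windup. Gains come from the classic
ultimate-cycle Ziegler–Nichols rules ($K_p = 0.6 K_u$,
$K_i = 1.2 K_u / T_u$, $K_d = 0.075 K_u T_u$) with the ultimate gain and
period found automatically on the continuous model's frequency response
(phase-crossover root search). A model whose phase never reaches −180° — a
pure first-order lag, say — has no finite ultimate gain and raises an
error. The PID acts on the raw commanded reference (it has no preview and
reacts when the set point changes) while being scored against the same
delay-aligned trajectory as the predictive controllers.

## Performance indices

Over a window of $N$ samples with error $e(k) = r(k) - y(k)$:
$\mathrm{IAE} = \sum |e| T_s$, $\mathrm{ISE} = \sum e^2 T_s$,
$\mathrm{MSE} = \frac{1}{N}\sum e^2$, so $\mathrm{MSE} \cdot N \cdot T_s =
\mathrm{ISE}$ identically. The benchmark table of error criteria is not
internally consistent across its rows under any single MSE definition; we
standardize on the definitions above, which reproduce the benchmark's
ISE/MSE ratio at $P = 20$.

### What the benchmark magnitudes can and cannot mean

The discretized canonical plant has a nonnegative impulse response, so with
$u \le 2$ the output after the dead time is bounded by twice the unit step
response: $y(d + m) \le 2\, s(m)$. Summing $\max(0,\, 1 - 2 s(m))$ gives a
controller-independent lower bound of about 11.5 on the IAE (and about 8.7
on the ISE) for unit-step tracking — even with delay-aligned scoring and a
perfect optimizer. The package's measured medians (IAE ≈ 14.4, ISE ≈ 10.2
at $P = 20$) sit close to this physical limit; the much smaller reported
absolute values are not reachable under the benchmark model, input bound
and reference scale, so the package treats the *orderings* (best horizon at
$P = 20$; degradation under disturbance; controller ranking) as the
reproducible content of the tables.

## Disturbance model

The disturbance experiment adds a zero-mean sinusoid at the measured
output: amplitude 10 in display units (mmHg), mapped through the 40-mmHg
display span to 0.25 in normalized units. The benchmark description gives
no frequency; the default period is 100 s (0.01 Hz, a slow drug-effect
fluctuation), configurable per scenario, entering at $t = 0$. Note the
structural limit: the dead time is 60% of this period, so feedback
correction arrives more than half a cycle late and sinusoidal rejection is
necessarily poor — the loop removes the disturbance's mean (integral
action) but not its oscillation. All three error criteria increase under
the disturbance, which is the direction the benchmark comparison reports.

## The muscle model

The heart muscle together with the transducer and injection set is
idealized as a rotational mass–spring–damper: inertia $J$, series spring
$k$ (muscle-tissue tension) and damper $B$ (viscous resistance), driven by
the torque difference $\Delta M = M_x - M_0$ between the applied
(pressure-increase) torque and the baseline muscle torque. Torque balance
and the damper relation combine into the third-order kinetic equation

$$\frac{BJ}{k}\dddot\theta + J\ddot\theta + B\dot\theta = M_x(t) - M_0(t),$$

whose Laplace form `muscle_transfer_function()` exposes through the same
transfer-function tooling as the patient model. `simulate_muscle()`
integrates the equation with `deSolve::lsoda` (interval-wise constant
torques, tolerances $10^{-11}$) and recovers the internal torque from the
balance $M = M_x - J\ddot\theta$. Two analytic anchors serve as oracles:
the angular velocity settles at $\Delta M / B$ (final-value theorem), and
the ODE solution matches the zero-order-hold discretization of the
transfer function at the sample instants to $10^{-6}$. No numeric $J$,
$B$, $k$ are given; the defaults are 1 (a dimensionless structural
study) and all three are configurable. The muscle model is a standalone
component — the benchmark describes it as the mechanical sensing metaphor but
states no coupling equation into the pressure loop, so none is invented.

## Problem sizes and reproducibility

The shipped experiments use the 200-sample window at $T_s = 1$ s, medians
over 10 seeds for the stochastic controllers, 101×101 grids for optimizer
verification and 15×15 for the plain-MPC baseline; the whole test suite and
the acceptance script each run in well under a minute of compute per
experiment group. Every stochastic component (GA, PSO, scenario driver)
is deterministic given its seed, and rerunning a scenario with the same
seed reproduces byte-identical CSV output.

## Known limitations

* Single-patient, single-drug SISO loop: no inter-patient variability
  beyond the sensitivity parameter, no drug interactions, no plant–model
  mismatch study (the controller uses the exact plant model).
* The synthetic scenarios exercise step references and a stationary
  sinusoidal disturbance only; real arterial-pressure records contain
  measurement artefacts, baroreflex dynamics and nonstationary noise that
  the generator does not emulate, so green tests here demonstrate
  correctness of the algorithms, not clinical readiness.
* The reported absolute error-criteria magnitudes are unreachable under
  the benchmark constraints (see above); comparisons should rely on the
  orderings.
* Ziegler–Nichols is an aggressive classical tuning; on a plant whose dead
  time dominates its dynamics it yields slow, oscillatory PID loops. It is
  retained as the documented baseline, not as a recommended design.
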