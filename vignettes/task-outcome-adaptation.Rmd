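---
title: "Modeling task-outcome effects on implicit adaptation under clamped feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling task-outcome effects on implicit adaptation under clamped feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampadapt)
```

## The scientific problem

Implicit sensorimotor adaptation keeps reaching movements calibrated by
correcting for sensory prediction errors (SPE) — mismatches between the
predicted and observed consequences of a motor command. Error-clamp
experiments isolate this process: the cursor's angular path is fixed
relative to the target regardless of where the hand goes, participants are
told to ignore it, and the hand nevertheless drifts steadily away from the
clamp. Because the clamp angle never changes, the SPE is constant on every
perturbation trial.

Holding the clamp constant and varying only the **target size** dissociates
a second signal: the binary task outcome. A large target swallows the
clamped cursor (a *hit*), a small one leaves it fully outside (a *miss*),
an intermediate one is *straddled*. Behaviorally, hitting the target
attenuates both the rate and the asymptote of implicit adaptation, and
straddle behaves like miss — the outcome signal is close to categorical.
This package implements the machinery needed to study that effect: the
experiment geometry and block designs, candidate trial-by-trial learning
models, behavioral preprocessing, the statistics, model fitting and
comparison, and a synthetic-data generator that stands in for the human
dataset.

## Geometry

With the cursor center at chord distance
$d = 2R\sin(e/2)$ from the target center ($R$ the movement amplitude, $e$
the clamp angle), the outcome is

* **hit** if $d + r_\mathrm{cursor} \le r_\mathrm{target}$,
* **miss** if $d - r_\mathrm{cursor} \ge r_\mathrm{target}$,
* **straddle** otherwise.

Boundary contact counts toward the embedded side, which makes the
partition closed and deterministic. At $R = 80$ mm, a $3.5^\circ$ clamp
puts the cursor $4.9$ mm off-center; a $1.75^\circ$ clamp $2.4$ mm. The
largest target a $1.75^\circ$ clamp fully misses with a 3.5 mm cursor is
about 1.4 mm across — which is why small-clamp designs use straddle rather
than miss conditions.

```{r geometry}
classify_task_outcome(clamp_geometry(3.5, 16, 3.5, 80))
max_miss_target_diameter(1.75, 3.5, 80)
```

## The candidate models

All models build on a single-rate state space. With a constant clamp the
error-sensitivity function collapses to a single update parameter, so on
clamp trials

$$x(n+1) = A\,x(n) + U, \qquad 0 < A < 1,\; 0 < U < e,$$

with motor output $y = x$ (the **motor-correction** baseline). Trials
without an error signal (no feedback, veridical feedback, 0° clamp) evolve
by retention alone, $x(n+1) = A\,x(n)$. States start at zero —
baseline-corrected data start at zero by construction.

**Movement reinforcement** adds a model-free operant process in parallel.
36,000 directionally tuned units (0.01° resolution) carry weights $r$;
their population vector $V$ has direction $V_d$ (the reinforcement-biased
movement direction) and length $V_l$, clipped to $[0, 1]$, which gates the
output:

$$y(n) = (1 - V_l(n))\,x(n) + V_l(n)\,V_d(n).$$

After each trial all weights decay by $A'$; on hit trials the unit at the
produced direction (rounded to its 0.01° unit, ties away from zero) gains
$s$. Because the decay and the single-unit increment are linear in the
vector components, the package carries $V$ through its components exactly
rather than storing 36,000 weights; the dense implementation lives in the
test suite as an oracle. When $V_l = 0$ the formula for $V_d$ is 0/0; the
package defines $y = x$ there (the reinforcement term has zero weight, so
its direction is irrelevant).

**Adaptation modulation** lets the outcome act as a gain on adaptation
itself: on hit trials

$$x(n+1) = \gamma_A A\,x(n) + \gamma_u U,$$

with both gains fixed at 1 on miss trials and estimated for hit trials.

**Dual error** posits two independent implicit processes with outputs
summed, one driven by the ever-present SPE and one by the binary target
error $TE = 1 - \mathrm{hit}$ (1 on miss *and* straddle):

$$x_\mathrm{spe}(n+1) = A_\mathrm{spe}\,x_\mathrm{spe}(n) + U_\mathrm{spe},
\qquad
x_\mathrm{te}(n+1) = A_\mathrm{te}\,x_\mathrm{te}(n) + U_\mathrm{te}\,TE(n),$$

$y = x_\mathrm{spe} + x_\mathrm{te}$.

The two **hybrids** combine the reinforcement machinery with either
modulated adaptation (`mr_am`) or the dual-error sum (`mr_de`) as the $x$
entering the output equation. Setting $s \to 0$ recovers the embedded
model exactly; setting both gains to 1 in `mr_am` recovers movement
reinforcement exactly — these reductions are bitwise in the
implementation and tested as such.

### Why the transfer design separates them

After adapting to asymptote under miss and then switching to a large
(hit) target, movement reinforcement cannot produce a *decrease*: the SPE
persists unchanged and the now-rewarded movements are reinforced at the
adapted direction. Both other models predict a drop — modulation because
the hit gain attenuates the recursion, dual error because the TE process
decays once its error term vanishes, leaving
$U_\mathrm{spe}/(1 - A_\mathrm{spe})$. `steady_state()` provides these
fixed points in closed form, and the test suite sweeps random in-bounds
parameterizations to confirm the signature (no decrease for reinforcement;
closed-form drops for the other two). One domain caveat: the signature
claim applies where the adaptation state denotes a movement direction.
Degenerate parameterizations with $U/(1-A)$ beyond $\pm 180^\circ$ make
the reinforced direction wrap around the circle, so sweeps are restricted
to asymptotes the task can express (≤ 60° here, three times the largest
observed asymptote).

## Designs and conventions

`build_design()` encodes the three standard experiments (and custom phase
lists) as one row per trial with block label, clamp size, scheduled
outcome, cycle and target. Conventions worth stating:

* The `hit` flag is 1 on clamp trials scheduled as hits and on 0°-clamp
  trials (a centered cursor is embedded in any target at least as large as
  itself), 0 on no-feedback and veridical blocks. Reinforcement therefore
  updates only where the schedule delivers an embedded cursor; washout
  dynamics are a convention, since fits use clamp-phase data only.
* Target order within a cycle is a seeded random permutation. The original
  report does not state the ordering; every analysis aggregates by cycle,
  so nothing downstream depends on it.
* Target locations use exact 45° (or 90°) spacing.
* Practice/instruction trials are excluded; the published analyses remove
  them.
* Positive hand angle is the direction opposite the clamp; counterclockwise
  participants are sign-flipped into this frame once, before any other
  preprocessing, so all data pool.

## Preprocessing

The pipeline (`preprocess_trials()`) is flip → outlier screen →
per-target baseline-bias subtraction → cycle aggregation, deterministic by
construction. Choices the source description leaves open:

* The moving average in the outlier rule is centered with symmetric,
  shrinking windows at series edges (the behavior of the MATLAB `smooth`
  the original analysis used).
* The SD in the 3-SD rule is computed per participant × target over the
  deviations from that series' moving average; the rule's `sd_mult` and
  window are arguments. On (near-)noiseless synthetic data the residual SD
  measures the learning curve's own curvature, so convergence tests open
  `sd_mult` up — a known property of the rule, not of the data.
* Baseline biases are means over stated within-block cycles (2–10 for the
  10-cycle baselines, 2–5 for the 5-cycle one) of the veridical block,
  computed after flipping and outlier screening.
* The early adaptation rate is the mean of clamp cycles 3–7 divided by
  five — a stabilized estimate of the cycle-5 hand angle from a zero
  start. A regression-slope variant over cycles 1–5 is exposed as
  `method = "slope"`.
* Retention metrics use the block immediately following the last clamp
  cycle (no-feedback or 0°-clamp); a missing washout block yields `NA`
  flagged `washout_available = FALSE`, never silent zeros.

## Statistics

`permutation_test()` builds the null by randomly shuffling group
assignment (10,000 draws by default), with the difference of group means
(two-sided) or the one-way F (upper tail) as statistic and the exact-test
convention $p = (\#\{null \ge obs\} + 1)/(n_{perm} + 1)$. The original
methods text says "resampling with replacement" while describing shuffles
of group assignment; label shuffling is implemented as the default and a
bootstrap null is available as `null = "bootstrap"`. Effect sizes are the
conventional pooled-SD Cohen's $d$, paired $d_z$, and $\eta^2$ /
partial $\eta^2$; zero-variance cases are flagged, not returned as
infinities.

## Fitting and model comparison

`fit_model()` minimizes the summed squared error between observed and
simulated clamp-cycle means (the mean of within-cycle trial outputs),
optionally over several groups simultaneously with one shared parameter
set — the published Experiment-3 analysis fits both groups' group-averaged
curves at once, and so do the tests here. Numerical choices:

* Bounds: retention-type parameters in $(0, 1)$, update-type in $(0, e)$,
  reinforcement increment in $(0, 1)$, gains in $(0, 5]$; the open
  intervals are implemented with a $10^{-6}$ inset.
* Optimizer: `stats::nlminb` (bounded quasi-Newton), 10 uniform-random
  interior starts under a fixed seed, loss tolerance $10^{-8}$; the best
  start wins and per-start diagnostics are kept. Divergent corners of the
  box (gain × retention > 1 overflows the state) are mapped to a large
  finite loss.
* $R^2 = 1 - SSE/SST$ with SST about the pooled mean of all fitted cycle
  means; $AIC = N\ln(SSE/N) + 2k$, the least-squares Gaussian form ($N$ =
  fitted cycle means, $k$ = free parameters). The AIC convention affects
  absolute values, not ordering; comparisons rank by AIC with exact ties
  broken toward fewer parameters.
* For models whose output is $y \ne x$ the loss compares observations to
  the motor output $y$ — the quantity the data measure.
* The dual-error landscape has a known degenerate local optimum (fast,
  large TE process); with 10 random starts the global optimum is found in
  roughly 9 of 10 noisy datasets, which is why recovery checks use the
  median across datasets.

`bootstrap_parameter_ci()` resamples participants with replacement within
each group, rebuilds the group-averaged cycle series, refits, and returns
percentile intervals. Replicate refits are warm-started at the full-data
solution (resamples perturb the objective only mildly); `boot_starts` adds
random starts per replicate when wanted.

## The synthetic world

`generate_experiment()` emulates the deposited per-trial data layout:
hand angle = generative-model output + per-target bias + i.i.d. Gaussian
motor noise, counterbalanced clockwise/counterclockwise clamps (flipped at
generation so `flip_ccw()` recovers the canonical frame exactly), optional
gross-outlier contamination (uniform 90–150°), and log-normal RT/MT
columns. Defaults are the stated world of the experiments:

* motor noise SD 3.5° (reported baseline variability 3.09–3.56°),
* per-target bias SD 2° (magnitude unreported; small relative to noise,
  enough to exercise the bias subtraction),
* RT ≈ 375 ms and MT ≈ 150 ms log-normals (reported group means),
* 12–16 participants per group as in the experiments.

For recovery and coverage checks the generative dual-error parameters are
$A_\mathrm{spe} = 0.993$, $U_\mathrm{spe} = 0.08$, $A_\mathrm{te} = 0.996$,
$U_\mathrm{te} = 0.03$ (per trial): these give a miss asymptote near 19°,
a hit-only asymptote near 11° and an early rate under 1°/cycle — the
scales the experiments report. What the generator does **not** emulate:
trial-to-trial noise autocorrelation, explicit re-aiming, fatigue or
attention drifts, and reach kinematics beyond summary RT/MT. A green
recovery test therefore establishes identifiability under the stated
noise model, not robustness to structured artifacts.

Test-budget scalings: the recovery check runs the stated 100 datasets with
6 optimizer starts (the median across datasets absorbs the occasional
local optimum); the coverage check runs 12 replicate experiments at the
stated 200 bootstrap replicates, with the default 10 starts for the
full-data fit and warm-started replicate refits. Its acceptance band
(coverage in [0.80, 1] for 95% nominal) reflects the binomial Monte-Carlo
error of 24 coverage indicators. Percentile bootstrap intervals are known
to undercover mildly at 12 participants per group, so this is the
strictest check in the suite: a marginal failure there indicates the
percentile-interval bias plus Monte-Carlo fluctuation, not a defect in the
resampling machinery (which is separately tested for determinism,
zero-width degeneracy, and agreement with the full-data fit).

## Known limitations

* Continuous (signed) target error for contingent feedback is not modeled;
  TE is the binary step the clamp paradigm realizes.
* Basis-function variants of the reinforcement process are not
  implemented; their predictions coincide with the discrete-unit scheme
  for these designs.
* Washout dynamics (retention-only) are a convention, as fits use
  clamp-phase cycles only.
* Trial-level (non-cycle) fitting and Bayesian estimation are out of
  scope.
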