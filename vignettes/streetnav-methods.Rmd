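---
title: "Simulating bimanual street-navigation studies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating bimanual street-navigation studies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streetnav)
```

## The paradigm

In the bimanual street-navigation task, a cursor is steered along a narrow
corridor ("street") with two keys, one per hand. One key accelerates the
cursor along the horizontal axis, the other along the vertical axis, by a
fixed amount per display frame; released keys decelerate at the same rate,
and the cursor can never move backwards along a controlled axis. A straight
street's angle therefore encodes the required division of labour between the
hands: 0° and 90° need one hand only, 45° needs both equally, and
intermediate angles require sustained asymmetric key ratios. Six streets
compose one trial (a "path"); hitting a wall resets the cursor to the street
start; entering the final 5 % of the street's arc length completes it.

Training tasks use straight streets on an inclusive angle grid from 0° to
90° whose spacing is the task's *minimum angular difference* (22.5°, 18°,
11.25°, 6.425° and 2° for Train-I … Train-V). Transfer tasks use six gently
curved streets; variant S keeps the trained cursor mapping (right/up),
variant M transposes the horizontal direction (the streets are mirrored
about the vertical window axis) and variant L transposes both. Crossing the
five training tasks with the three transfer variants gives the 15-cell
between-subject design (30 subjects per cell in the reference
configuration), with 100 training trials and 5 transfer trials before and
after training per subject.

All geometry lives in *height units* (1 = task-window height), origin at the
bottom-left, x rightwards, y upwards, so everything is
resolution-independent.

## Geometry choices

* **Angle grids.** The grid for a nominal minimum difference Δ is
  `seq(0, 90, length.out = round(90/Δ) + 1)`: it always contains 0 and 90
  and uses the uniform spacing closest to Δ that divides 90 evenly. A
  nominal Δ = 6.425°, which divides 90 into 14.004 intervals, therefore
  snaps to 15 angles at 90/14 = 6.4286° — the only uniform inclusive grid
  consistent with the task family's construction.
* **Street size.** Width 0.06 and length 0.5 height units by default (both
  configurable). These give visibly corridor-like streets inside a 16:9
  window with a realistic, nonzero error range; no canonical values exist
  for them, so they are free parameters of the geometry.
* **Scheduling.** 600 scheduled streets per session are spread maximally
  evenly over the task's angles (per-angle counts differ by at most 1 —
  exact equality is impossible for, e.g., 46 angles into 600 slots) and
  drawn by a seeded greedy sampler with restarts so that every pair of
  consecutive streets, *including across trial boundaries*, differs by at
  least 22.5°. Weighting the draw by the squared remaining count keeps the
  endgame feasible; infeasible specifications fail with an explicit error
  after a bounded number of restarts.
* **Transfer curves.** The six base curves are a fixed family: a 45° chord
  of length 0.5 centred in the window, deflected perpendicularly by two
  low-frequency sinusoids under a half-sine envelope (so the curves meet
  the chord at both ends). Amplitudes (≤ 0.04 height units) keep the bends
  gentle enough that a converged, low-noise agent can track them — with
  sharper bends the look-ahead controller corner-cuts into the walls and
  some curves become impossible, which no human participant population
  exhibits. M and L variants are exact reflections of these coordinates, so
  arc lengths are identical across variants by construction; reflections are
  exact to the last ulp but double reflection is not guaranteed bit-identical
  in IEEE arithmetic.
* **Distances.** Straight streets use the triangle-area (Heron)
  construction for the perpendicular distance to the ideal line; curved
  streets use the nearest neighbour over a centreline resampled at 0.002
  height units. The two agree within 10⁻⁴ on straight streets (a property
  the test suite checks against a dense-polyline oracle).

## Kinematics

Defaults follow the paradigm's standard settings: acceleration 0.001 height
units/frame, maximum speed 0.3 height units/frame, 60 Hz, end zone 5 % of
street length. Two decisions the task description leaves open:

* **Resets zero the velocity.** A cursor reset that preserved speed would
  re-collide immediately under the corridor geometry, so the cursor
  restarts from rest.
* **Collision test.** The corridor model (distance to centreline >
  width/2) replaces polygon-edge intersection; for constant-width corridors
  the two are equivalent, and the corridor test is cheaper and exact at
  street ends.
* **Termination.** A hard cap of 3600 frames (60 s) per street guarantees
  termination; capped streets are marked aborted, excluded from scoring,
  and counted in the pipeline log.

The frame loop exists twice: a plain-R reference implementation
(`simulate_street()`, usable with arbitrary policies) and a compiled
equivalent used at cohort scale. Both consume one standard-normal draw per
frame from R's RNG and perform the same windowed nearest-neighbour search,
so under equal seeds they produce identical trajectories — the test suite
asserts agreement at 10⁻¹² on positions, which guards every future change to
either path.

## The synthetic participant

The study the package emulates measured humans; simulation requires a
generative stand-in, and its construction is the main modelling freedom
here. Each agent is a closed-loop steering controller:

1. Aim at a look-ahead point 15 resampled points (~0.03 height units) ahead
   of the nearest centreline point. The raw heading may leave [0°, 90°]:
   values outside the quadrant encode the corrective "ease off this axis"
   signal when the cursor has drifted across the ideal line, and are only
   clamped after noise is added.
2. Corrupt the heading with zero-mean Gaussian noise of SD
   σ(t) = σ₀ · exp(−λ(t−1)) · d(θ) + floor, where t is the trial index,
   λ the agent's learning rate, and d(θ) = (1−g) + g·|sin 4θ| the
   street-angle difficulty term at weight g (default 1). With g = 1 the
   learnable noise vanishes on one-hand (0°, 90°) and symmetric (45°)
   streets and peaks at 22.5° and 67.5°, reproducing the observed
   "ends easiest, 10–40° and 50–80° hardest" difficulty profile.
3. Press each key whose axis speed is below the corrupted heading's demand
   (demands below 10⁻⁹ are zeroed: cos(π/2) is ~6·10⁻¹⁷ rather than 0, and
   a spurious positive demand at zero velocity would otherwise press a key
   every frame and make axis-aligned streets artificially hard).

Speed targets grow with the same learning curve,
`speed_base · min(1, skill + gain·(1 − exp(−λ(t−1))))`. On transfer variants
with transposed cursor directions, a configurable fraction
`min(1, remap_cost · √n_flips)` of the *learned* improvement (noise
reduction and speed gain alike) fails to transfer; untrained (pre) states
are identical across variants, matching the design argument that without
prior knowledge the three transfer variants are equally difficult. The
square-root form makes the cost saturate: transposing one hand's direction
already disrupts the learned coordination of both hands, so the second
transposition adds relatively little — which is why the M and L variants
end up empirically closer to each other than to S.

Population defaults (chosen once, before any cohort-level analysis, to
produce a behaviourally plausible cohort): baseline skill ~ N(0.55, 0.12)
clamped to [0.25, 0.95]; learning rate lognormal with median 0.02/trial and
σ_log = 0.35 (so most agents are clearly off asymptote after 100 trials and
individual differences in learning survive into the post-transfer scores);
initial noise σ₀ ~ N(25°, 5°) floored at 10°; residual floor 1°; speed gain
0.2; `speed_base` 0.015 height units/frame (≈ 0.9 window heights/s at full
skill). Under these values accuracy improves roughly twice as strongly as
speed over a session, so the printed performance index rises with practice.

Group-level structure is pure configuration (`effect_config()`), never
hard-coded: per-task learning-rate multipliers (default 1.5/1.0/1.0/0.7/0.7
— low-variability training concentrates practice on few streets and yields
the largest training change), the transposition cost (default 0.35), and the
competence model. Bimanual competence (1–3) is coupled to baseline skill by
a Gaussian copula with rank correlation 0.4 and shifts the learning rate by
±15 % per level. `null_effects()` zeroes all of these, giving a null world
in which the downstream group statistics are calibrated (the type-I-error
suite runs there).

## Scoring and denoising

Movement time runs from movement onset (first frame with nonzero velocity)
to completion. RMS error is taken over the same window — onset-aligned so
the two dependent variables describe the same epoch — and *includes* frames
of failed attempts before resets: excluding them would make wall hits
error-free. Trial-level values average the six streets; the performance
index is computed from these trial-level means (not from per-street
indices), with constants a (mean error) and b (mean movement time)
calibrated on an independent synthetic pilot of 75 agents (5 per cell) under
a fixed pilot seed.

The index is implemented exactly as conventionally printed, PI = (mt/b)·(a/err),
with a `pm_inverted` switch for the Pm = b/mt variant under which faster
movement raises the index. All package-level conclusions use relations that
hold under either convention.

Because street angles differ systematically in difficulty, a trial's score
partly reflects which streets it contained. Denoising removes this: per
training task and per dependent variable, the per-angle grand mean over all
street occurrences gives the difficulty profile; a trial's difficulty is the
mean over its six streets; the group-level per-trial series is regressed on
trial difficulty by OLS; and the mean-centred *fitted* component is
subtracted from every subject's series. This loses no trials and leaves the
between-subject variance at every trial untouched (only a common per-trial
offset is removed), and the denoised group mean is exactly orthogonal to
difficulty. Subtracting the raw *residuals* instead — a literal reading of
"residual subtraction" — would remove the learning-related variance along
with the difficulty variance, defeating the stated purpose; that mode is
nevertheless available (`mode = "residual"`) for comparison. Since the
regression needs one difficulty value per trial at the group level, all
subjects of a training task share one seeded schedule, mirroring group-wise
data acquisition.

## Statistics

The inferential layer rides on base R (`aov`, `lm`, `t.test`, `cor.test`)
plus `car::Anova` for Type-II sums of squares; the package adds the
quantities the design needs: partial η² = SS_effect/(SS_effect+SS_error),
Cohen's d (pooled for two-sample, difference-SD for paired, root-MSE for
ANOVA follow-ups), pooled-error pairwise follow-ups with Bonferroni
correction (family size an explicit parameter, defaulting to the number of
pairwise tests — a "family of 5" convention for 5 groups would understate
the correction for 10 comparisons), and ANCOVA with mean-centred covariates.

Power planning uses the noncentral-F formulation of the repeated-measures
between-factors test: λ = N·m·f²/(1+(m−1)ρ), df₁ = k−1, df₂ = N−k.
`required_sample_size()` searches total N over multiples of the group count.
With the pilot interaction effect η²p = 0.054 converted *unrounded* to
f = 0.23892, α = 0.05, power 0.95, k = 15, m = 2 and ρ = 0.663, the smallest
qualifying N is 420 (power 0.948 at 405, 0.957 at 420). Using the
two-decimal rounding f = 0.24 instead would admit 405 — the unrounded
conversion is the one consistent with standard planning tools, and the
package uses it.

## Numerical choices

* Resampling spacing 0.002 height units everywhere (distances, collision,
  arc-length projection); the windowed nearest-neighbour search (±40
  points) is exact for the speeds the control law can reach.
* The scheduling sampler retries up to 10 000 times before declaring a
  specification infeasible.
* Learning-curve recovery (`fit_learning_curve()`) fits
  `A·exp(−r(t−1)) + C` by Levenberg–Marquardt from a small grid of starting
  rates, using only streets whose angle carries difficulty weight
  |sin 4θ| ≥ 0.5: one-hand and symmetric streets express mostly floor noise
  and dilute the signal. Averaged over 50 agents at 100 trials this recovers
  the generating rate with a mean relative error below 25 %.
* Seeds: every stage derives its seed from the master seed by a stable
  string hash (`label:index`), so stages are independently re-runnable; the
  compiled simulator consumes R's own RNG stream, so R-level seeding governs
  all randomness.

## What the generator does and does not emulate

The synthetic cohort reproduces, qualitatively: improvement in both speed
and accuracy over 100 trials; the band-shaped street-difficulty profile;
overall performance ordered by training-task variability; larger training
change under low-variability training and higher competence; comparable
pre-transfer performance across variants; a post-transfer advantage of the
same-mapping variant with the two transposed variants closer to each other;
and a positive correlation between training change and transfer change.

It does not emulate: trial-to-trial autocorrelation beyond the learning
curve (noise is white across frames); fatigue, lapses, or strategy shifts;
device/browser timing jitter; drop-out or exclusion policies; or the
achievement-motivation questionnaire (only the scalar 1–3 competence is
modelled). Passing tests therefore validate the pipeline's *machinery* on a
cohort whose ground truth is known — they do not certify that real
participants behave like the agents, and inferential F/t/r values from real
data are not expected to match the simulated ones numerically.

Bayesian model-averaged tests (inclusion/exclusion Bayes factors) are out of
scope: their values depend on tool-specific default priors that are not part
of the design's specification. The frequentist interaction test is computed,
and the analysis list is an ordinary R structure to which a Bayesian layer
can be attached.

## Problem sizes used in the checks

The test suite simulates the full 450-agent default cohort once for the
denoising orthogonality property, 50 single agents for learning-rate
recovery, 2 000 small null cohorts (n = 10 per group, drawn directly at the
score level) for type-I calibration, and 100 schedules (5 specifications ×
20 seeds) for the scheduling properties. The complete suite runs in about
80 s on one CPU.
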