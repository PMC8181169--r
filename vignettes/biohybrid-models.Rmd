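---
title: "Mean-field models of robot-organism collectives: methods and design"
author: "biohybrid package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field models of robot-organism collectives: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biohybrid)
```

# Overview

`biohybrid` simulates three laboratory biohybrid systems in which robots take
part in the behavioural feedback loops of living organisms:

* **Bees**: young honeybees aggregating around two stationary
  sensor-actuator units (CASUs) that emit heat, vibration or airflow, and can
  close the loop by reacting to sensed bee density.
* **Fish**: a small zebrafish shoal choosing between clockwise (CW) and
  counter-clockwise (CCW) swimming in a ring corridor, together with
  bio-mimetic robotic fish that are partially accepted as conspecifics.
* **Plants**: a single growing bean shoot whose flexible tip bends under two
  controllable light sources.

All three are two-compartment mean-field models sharing one structure: the
state is a conserved pair of compartment masses, and the dynamics balance an
*individual* switching term (spontaneous, linear in the source compartment)
against a *social* switching term (mass-action, proportional to the product
of the two compartments). Robots enter either by modulating the rates
(bees: temperature changes the resting time; plants: light weights the
lateral flows) or as partially-counted extra agents (fish). The ratio of the
individual rate $\alpha$, the social rate $\beta$ and the noise scale
$\sigma$ spans the repertoire from even dispersal to strong symmetry
breaking; `run_sweep()` exposes exactly this ratio.

# The bee model

State: bees per side $B_R(t), B_L(t)$ with $B_R + B_L = B_{total}$, and side
temperatures $T_R(t), T_L(t)$. Bees leave side $X$ at rate $B_X/\tau_X$; a
fraction $\alpha_{bees}$ of leavers stops spontaneously on the other side,
and a mass-action fraction $\beta_{bees} B_R B_L / \tau_X$ stops socially.
The resting time is a linear ramp in local temperature, shortened by airflow
$\varphi$ and lengthened by vibration $\psi$:

$$\tau = \Big(1 + \frac{\tau_\Delta}{T_\Delta}(T - T_{min})(1-\varphi)\Big)(1+\psi),$$

with $\tau_\Delta = 24$ s over $T_\Delta = 8\,^\circ$C, so $\tau(28\,^\circ C)
= 1$ s and $\tau(36\,^\circ C) = 25$ s — the two anchors of the underlying
stopping-time calibration. Each CASU relaxes passively towards the
28 °C ambient and, outside a deadband $\varepsilon_{temp}$, actively heats or
cools at fixed rates towards its target. In closed loop the targets step by
$\pm\Delta_{temp}$ according to which side's 30-s gliding average of noisy,
one-sidedly underestimating bee counts is larger (positive feedback warms
the crowd, negative feedback cools it), clamped to $[28, 36]$ °C.

# The fish model

State: $F_{CW}(t) + F_{CCW}(t) = F_{total}$, plus the robot direction
$R_{CW} \in \{0,1\}$. A fish switches spontaneously only while effectively
alone; the aloneness probability follows from the sight-area to arena-area
ratio (defaulting to $1/5$, the average of the geometric bounds $1/3$ and
$1/7$), so that with six agents nobody is ever alone. Social switching is
mass-action in the opposing group, weighted by the ratio of *perceived*
counts: each direction class misperceives some of the fish it sees, with
four independent $U(0,1)$ draws per step scaling the misclassification
terms, and the $+1$ in the denominator standing for the focal fish itself.
Robots contribute $n_{robots}\gamma_{fish} R$ to the perceived and
switchable masses (linear superposition over robots, consistent with the
mean-field treatment); $\gamma_{fish}$ is how often a robot passes as a
conspecific.

Robot controllers: *constant* direction, *open-loop random switching*
(probability 0.014 per 1-s step), and *closed-loop majority following* — the
tracking software reports noisy direction proportions (antisymmetric error,
so proportions always sum to 1) and the robot swims with the majority,
choosing uniformly on an exact tie. The closed-loop gliding window defaults
to one model second, matching the one-proportion-per-second cadence of the
modelled controller; it is configurable (`decision_window`).

Perceived counts are floored at zero: the raw forms can only turn negative
when the observing class holds less than one mean-field fish, a state the
original per-individual reading cannot reach; the floor makes the
non-negativity guarantee unconditional.

# The plant model

State: stem mass $P^{stem}$, lateral flexible masses $P^{flex}_R, P^{flex}_L$
(dimensionless biomass), advanced by forward differences at 1-minute steps.
Mass enters at rate $\rho_{in}$, the stem empties half-half onto the two
sides each step, phototropism moves mass towards the lit side
($\alpha_{plant} X P_{source} \Lambda$, with $\Lambda \in [0,1]$ the light
ratio and $X \sim N(1, \sigma_{plant})$), circumnutation exchanges mass in
both directions ($\beta_{plant} X P_L P_R$), and each side loses
$\rho_{out}$ per minute to outgrowth. The tip-position proxy is

$$\Upsilon = \tfrac12\Big(\frac{P_R - P_L}{P_R + P_L + 1} + 1\Big) \in (0,1),$$

whose $+1$ keeps short shoots near the centre. Light controllers:
`posFB` ($\Lambda = \Upsilon + X^{detect}$), `negFB`
($\Lambda = 1 - \Upsilon + X^{detect}$), both clamped to $[0,1]$ after the
$N(0, \sigma_{plantCASU})$ detection noise, and the binary target-tracking
rule $\Lambda = 1$ iff $\Upsilon < \Gamma(t)$ (ties fall to the else-branch;
no detection noise, as tip detection by image processing is nearly exact).
The guidance schedule holds $\Gamma = 0.85$ to $t = 640$ min, $0.2$ to
$880$, and $0.5$ to $1200$.

Numerical safeguards: switch flows are floored at zero (a negative Gaussian
draw cannot reverse a flow's direction) and the total switch outflow of a
side is capped at $(1-\rho_{out})$ of its mass. Both adjustments apply the
same value with opposite signs in the two side equations, so the per-step
mass balance $\Delta(\text{total}) = \rho_{in} - \rho_{out}(P_R + P_L)$
holds to machine precision.

# Integration, noise and reproducibility

* **Solver.** Bees and fish use classical fixed-step RK4 at $\Delta t = 1$ s
  (the fish model exposes an `euler` switch); plants are difference
  equations at $\Delta t = 1$ min. Units live in the `sim_clock` and are
  never converted implicitly.
* **Noise semantics.** Every named noise variable is drawn once per step and
  frozen across the four RK4 stages — piecewise-constant random
  coefficients, matching the 1-s sense-and-act cadence of the physical
  robots. With all $\sigma$ at zero every run is fully deterministic and
  seed-independent.
* **Clamping.** Flows can transiently overshoot a compartment at
  $\Delta t = 1$; after each step negative compartments are clipped to zero
  and the pair rescaled to the conserved total. A run warns once if the
  correction ever exceeds $10^{-6}$ of the total.
* **Seeds.** A replicate is a pure function of (configuration, seed).
  Ensembles derive replicate seeds with a seed-sequence scheme
  (`replicate_seeds()`): the base seed seeds the generator once and distinct
  integers are sampled without replacement, giving collision-free,
  reproducible substreams. Lattice nodes own one substream each.

# Calibrated defaults

The resting-time spans, temperature bounds, arena protocol constants
(group sizes, run lengths, stimulus levels and onsets, replicate counts) and
the F2 switching probability are fixed protocol values. The behavioural
rates and noise scales ($\alpha, \beta, \sigma$ per organism, the CASU
thermal rates, $\gamma_{fish}$ and the observation noise scales) are
*calibration defaults*: they were chosen once, with
`scripts/calibrate_defaults.R`, so that the documented qualitative regimes
hold, and are ordinary configuration keys. Two findings from that
calibration shaped the defaults:

* **Bees.** The negative-feedback controller suppresses aggregation below
  the constant-28 °C control only when active heating is slow
  (0.005 °C/s) relative to the 30-s sensing lag while active cooling is
  fast (0.1 °C/s); with fast heating the counter-warmed side overshoots,
  the whole group follows it, and the "suppressing" controller paradoxically
  aggregates more than the control. Since at 28 °C both sides are already at
  the resting-time minimum, the control is the natural low-aggregation
  floor, and only small thermal excursions keep the negative regime below
  the noise-driven symmetry breaking of the control.
* **Plants.** Under $\Lambda = \Upsilon$ the net phototropic flow is
  $-\alpha\Delta/(2(M+1))$ for mass difference $\Delta$ and total $M$ —
  always weakly restoring, because the flow is proportional to the
  *opposite*-side mass. The committed one-sided state of the positive
  regime therefore arises from multiplicative circumnutation noise (which
  vanishes at the boundary, pinning the state there) acting against the
  weak leak $\rho_{out} + \alpha/(2(M+1))$; it requires a small outgrowth
  rate, a small phototropic gain and near-exact plant detection. The
  negative regime stays balanced because its restoring rate is
  $\approx \alpha$, independent of $\rho_{out}$.

# What the simulations do and do not emulate

The models reproduce population-level regularities: conservation of the
group, symmetry breaking and its modulation by stimuli, the ordering of
feedback regimes, robot-group coupling, and guided growth. They are
well-mixed mean-field descriptions — no spatial positions, no individual
identities, no age/state structure, no traffic-jam effects, and unlimited
sensing within a compartment. Ensemble variance is therefore substantially
smaller than in live-animal experiments; passing tests certify the model
dynamics and their implementation, not quantitative agreement with any
particular animal group.

# Protocol presets and analysis conventions

`experiment_preset()` materialises the in-silico protocols (`b1_homog`,
`b1_heterog`, `b2_vibration`, `b3_airflow`, `b4_posFB`, `b4_negFB`,
`b4_control`, `f1_pure`, `f1_mixed`, `f2_open_loop`, `f3_closed_loop`,
`p1_target`). Conventions adopted where the protocol left room:

* Bee counts are sampled every 30 s with inclusive window endpoints (a 5-min
  window yields 11 samples); the majority side is evaluated per sampling
  instant and then averaged, with the window-mean alternative exposed as an
  option. Both constant-temperature arenas use the minutes-8-to-13 window.
* The three-CASU vibration arena is represented by its two-side reduction
  (the middle population split 50:50); both sides are held at ambient so
  vibration is the only asymmetry, and the vibration effect applies from
  $t = 181$ s.
* Pre-heated arenas (`b1_heterog`, `b3_airflow`) start with the side
  temperatures at their targets. The airflow onset is drawn uniformly in
  minutes 13-15 per replicate (seeded); a fixed onset is available.
* The gliding average uses the mean of available samples during the first
  30 s (warm-up). On an exact observation tie both feedback targets step
  down.
* Robot-group correlation is Pearson on per-replicate time budgets; the
  closed-loop robot starts in a random direction.
* With an odd fish count the symmetric start is the mean-field 2.5/2.5
  split.
* The lattice neighbour flow (von Neumann neighbourhood, reflecting
  boundaries, outflow proportional to the mobile fraction $B/\tau$, split
  half-half onto the receiver's sides) is this package's extrapolation of
  the building-block idea; only its conservation and degeneracy properties
  are treated as load-bearing.

# Problem sizes in the test suite

The suite runs the full protocol durations (1200 s bees, 1800 s fish,
1200 min plants) with ensemble sizes chosen for stable medians at test time:
100 seeds per feedback arm (bees and plants), 100 seeds for the mixed-shoal
bias and 50 per arm for the open- vs closed-loop correlation comparison.
Fixed-point checks integrate 4000 steps; the lattice conservation check runs
$10^4$ steps on a 2x2 grid. Examples in the documentation use smaller
replicate counts.

# Known limitations

* The linear resting-time ramp approximates the sigmoid stopping-time curve
  of the underlying behavioural data; the sigmoid is a possible extension.
* Noise enters the ODEs as per-step frozen coefficients, not as a
  stochastic-calculus formulation; results at other step sizes will differ.
* The plant model tracks one tip; branching and 3-D stem geometry are out of
  scope, and the time-to-height mapping is a plotting convention only.
* The fish model has no spatial kinematics; the robot influences the shoal
  only through the perception-weighted terms.
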