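---
title: "Modeling host-microbiome behavioral feedback loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling host-microbiome behavioral feedback loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`microbehave` simulates a host whose behavior and gut microbiome regulate
each other. Three components are coupled in discrete time (steps of size
1):

**Host behavior.** The host is a point $\vec b$ in a D-dimensional
"microbiome-behavior space" (D = 2 by default), moving along the first
axis $b_1 \in [0, 1]$. In the two-strain scenario $b_1$ performs a random
walk with Laplace$(0, \sigma)$ steps starting at 0.5. In the addiction
scenario the baseline follows three phases: an initial equilibrium at the
origin that lasts until the microbiome composition stabilizes; an
addiction phase of $\tau$ steps with positive exponential$(\text{mean}=
\sigma)$ steps, bounded by the maximal addiction severity $R$; and a
withdrawal phase with the negated steps, bounded below by 0 and simulated
for a fixed horizon of $10^5$ steps so that withdrawal metrics are
comparable across runs.

**Microbiome composition.** Each of the $N$ strains has feature
coordinates $\vec m_i$ in the unit ball, and receives host-derived
resources through a monotonically decreasing function of its distance to
the host,

$$r_i(t) = 0.1 + \max\!\big(0,\; 1 - \beta\,\lVert \vec b(t) - \vec m_i
\rVert^{\alpha}\big), \qquad \alpha = 3,\ \beta = 0.1 .$$

Proportions evolve by a forward-Euler step of logistic competition,
$x_i \leftarrow x_i + x_i\,(r_i - s\,x_i - c_i)$, followed by
normalization, a small inflow $\mu / N$ to every strain and a second
normalization. The double normalization holds the community at carrying
capacity (pure resource competition: a strain prospers only relative to
the others), and the inflow ($\mu = 10^{-8}$) keeps every proportion
positive so that no strain is ever permanently lost. A generalized
Lotka-Volterra variant replaces this update by
$x_i \leftarrow x_i + x_i(r_i + A_i \cdot x) + \mu/N$ with
$A = -(1-\delta) I - \delta J$ and no normalization; it tracks raw
abundances and is provided for robustness analyses.

**Feedback to the host.** Each affecting strain carries an effect
magnitude $d_i \sim \text{Exponential}(E[d])$. At every step the strain
senses the trend of its own proportion — the OLS slope over the last
$\omega_m$ recorded values, mapped to an indicator $I_{m_i} \in \{-1, 0,
1\}$ with a neutrality band of $\pm 10^{-6}$ — and the host carries the
analogous indicator $I_b$ of its own recent behavior ($\omega_h$ window).
The aggregate behavioral nudge is

$$M(t) = |\sigma_A(t)|\; I_b(t) \sum_i x_i(t)\, d_i\, I_{m_i}(t),
\qquad b_1(t+1) = \mathrm{clamp}\big(b_1(t) + \sigma_A(t) + M(t)\big),$$

so a growing strain rewards (reinforces) the host's current trend and a
declining strain punishes (reverses) it. A second variant ("direct
pull") replaces the reward-circuit term by the abundance- and
$d_i$-weighted average of unit vectors from the host towards each strain,
projected on the behavior axis.

## Parameters, defaults, and why

| Parameter | Default | Meaning |
|---|---|---|
| `n_strains` (N) | 50 | community richness; 10-1000 is the interesting range |
| `dims` (D) | 2 | feature-space dimensionality |
| `sigma` | 1e-4 (addiction), 1e-3 (two-strain) | baseline step scale |
| `tau` | 20000 | addiction-phase length in steps |
| `R` | 0.7 | maximal addiction severity, clamp bound of `b1` |
| `mean_effect` (E[d]) | 10 | mean microbial effect magnitude |
| `s` | 1 (community), 0.1/0.01 (two-strain) | intra-strain competition |
| `mu` | 1e-8 | total inflow, floors proportions at `mu/(N(1+mu))` |
| `cost` | 0 (0.09-0.12 in two-strain sweeps) | per-step cost of affecting |
| `alpha`, `beta` | 3, 0.1 | growth-function decay; `beta` is also the maximal advantage between strains at coordinates 0 and 1 |
| `omega_m`, `omega_h` | 10 | trend windows (steps) |
| `slope_tol` | 1e-6 | neutrality band of the trend indicators |
| `withdrawal_horizon` | 1e5 | fixed withdrawal window |

These defaults are the standard study conditions; scenario functions take
a full `sim_config()` so any of them can be swept.

## Numerical and design choices

* **Windows.** `omega` is the window *length*: slopes use exactly the
  last `omega` recorded values (the current step included). All
  indicators are 0 until a buffer holds `omega` points (warm-up), and the
  buffers carry the initial state.
* **Clamping.** Behavior is clamped to $[0, R]$ in both the addiction and
  withdrawal phases, so relapses cannot exceed the maximal severity; a
  config switch (`allow_exceed_R`) lifts the withdrawal bound to 1 for
  sensitivity analyses. Negative intermediate abundances (possible only
  under aggressive cost sweeps) are clipped at 0 before normalization.
* **Stabilization.** The equilibrium phase ends when the largest
  per-strain change stays below `1e-10` for 100 consecutive steps, capped
  at `1e4` steps; hitting the cap is recorded as a warning in the run and
  its manifest rather than an error, since rich communities approach
  their equilibrium asymptotically.
* **Phase accounting.** $\phi$(Addiction) is the unit-step Riemann sum of
  $b_1$ over the $\tau$ addiction steps, $\phi$(Withdrawal) over the
  $10^5$ withdrawal steps; the maximal relapse is the largest rise
  $b_1(t_2) - b_1(t_1)$ over ordered withdrawal pairs, computed in linear
  time with a running prefix minimum (and cross-checked against the
  quadratic definition in the tests).
* **Interventions.** Strains introduced at withdrawal start enter at
  abundance 0 and join the inflow pool, which then distributes
  $\mu/(N+k)$ per strain — no arbitrary bolus size.
* **Seeding.** Each run derives independent sub-stream seeds for strain
  sampling and for behavior draws from its seed, so changing `n_strains`
  never perturbs the behavior-step sequence; ensembles and sweeps derive
  per-replicate and per-cell seeds the same way. Fixed seeds give
  byte-identical outputs.
* **Performance.** The per-step loop is implemented in C++ (Rcpp); the
  exported R functions (`step_normalized()`, `window_slope()`,
  `microbiome_effect()`, ...) define the semantics, and the test suite
  verifies the fused loop against a step-by-step composition of them to
  machine precision for every variant.
* **Baselines.** A run with all $d_i = 0$ reproduces the microbiome-free
  baseline schedule bit for bit (tested); `run_ensemble()` can therefore
  evaluate baseline arms directly from the schedule
  (`baseline = "schedule"`), which makes paired fold changes cheap for
  large communities.

Genuinely open points were resolved as follows: "uniform in the unit
sphere" is read as uniform over the *ball volume* (the features describe
positions within the space, and the radius transform $u^{1/D}$ makes this
exact); $\tau$ is counted from the addiction phase's initiation whether
or not $b_1$ has reached $R$; the step magnitude entering $M(t)$ during
the addiction plateau is the drawn value (draws happen every step); and
near-degenerate directions in the direct-pull variant (strain within
$10^{-12}$ of the host) contribute nothing.

## What the synthetic communities emulate — and what they do not

`sample_strains()` generates exchangeable strains: isotropic positions in
the feature ball and independent exponential effect magnitudes. This
captures the ecological ingredients the model needs — niche positions
relative to host states, heterogeneous feedback strength, tunable
richness — but deliberately omits phylogenetic correlation, realistic
abundance distributions, strain-strain metabolic interactions
(cross-feeding, toxins) and any mapping to real taxa. Passing tests
therefore demonstrate properties of the *model*, not predictions
calibrated to empirical microbiome data.

## Ensemble sizes

Single runs simulate the full standard horizons (equilibration, 2e4
addiction steps, 1e5 withdrawal steps). The packaged checks run ensembles
of 50-100 replicates per condition — enough for the directional claims
(fold changes, paired interventions, relapse ordering) at 95% confidence
— while published-style heatmaps at 1000 replicates per pixel are left to
`sweep_sim()` users with more patience.

## Known limitations

* At `s = 0.1` the two-strain coexistence point under a host pinned at
  the affecting strain is $x^* = 0.5 + (\beta - c)/(2s)$, i.e. 0.55 at
  cost 0.09 — the affecting strain wins, but never by much, and runs
  whose hosts drift early beyond $b_1 \approx 0.5$ (where the strain's
  equilibrium share, and with it the feedback force, vanishes) rarely
  return within $10^5$ steps. Ensemble means of the final affecting-strain
  proportion at cost just below `beta` therefore sit slightly below 0.5
  even for strong effects, although the typical (locked) run is won.
* Very large effect magnitudes destabilize the feedback lock itself: each
  nudge is proportional to $x_i d_i |\sigma|$, and when that exceeds the
  host's own step by an order of magnitude the trend regression starts
  chasing its own overshoot.
* The equilibrium-phase cap means very rich communities (N ~ 1000) enter
  the addiction phase close to, but not exactly at, their equilibrium.

```{r}
library(microbehave)
cfg <- sim_config(n_strains = 50, mean_effect = 10)
run <- run_addiction(cfg, seed = 1)
run$metrics
ens <- run_ensemble(cfg, n_reps = 20, base_seed = 1, baseline = "schedule")
ens$summary
```
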