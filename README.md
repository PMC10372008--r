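# microbehave

Simulations of host-microbiome behavioral feedback loops, for theoretical
ecologists and microbiome researchers studying how gut communities can
entrench host behaviors — in particular addiction, withdrawal and
relapse dynamics as a function of microbiome richness and effect
strength.

## The model in brief

A host moves on a behavior axis $b_1 \in [0, 1]$; $N$ microbial strains
with feature coordinates $\vec m_i$ in the unit ball compete for
host-derived resources through a distance-decaying growth rate

$$r_i(t) = 0.1 + \max\big(0,\ 1 - \beta\,\lVert\vec b(t) - \vec
m_i\rVert^{\alpha}\big),$$

with discrete-time logistic competition, double normalization (carrying
capacity) and a small inflow $\mu/N$ preventing permanent extinction
(a generalized Lotka-Volterra variant is also provided). Each affecting
strain senses the OLS trend of its own proportion over a sliding window
and secretes reward or aversion feedback; the host integrates these
against its own behavioral trend:

$$M(t) = |\sigma_A(t)|\,I_b(t) \sum_i x_i(t)\,d_i\,I_{m_i}(t), \qquad
b_1(t+1) = \mathrm{clamp}\big(b_1(t) + \sigma_A(t) + M(t)\big).$$

Scenarios: a two-strain competition testing when affecting the host pays
off despite a production cost, and a three-phase addiction scenario
(equilibrium → addiction bounded by severity $R$ → withdrawal) with
phase integrals $\phi(\mathrm{Addiction})$, $\phi(\mathrm{Withdrawal})$,
maximal-relapse magnitudes, seeded ensembles, parameter sweeps and
richness-boosting interventions at withdrawal start. See the vignette
(`vignettes/host-microbiome-feedback.Rmd`) for the full account.

## Worked example

```r
library(microbehave)
cfg <- sim_config(n_strains = 50, mean_effect = 10)   # standard conditions
run <- run_addiction(cfg, seed = 1)
run$metrics
#>  phi_addiction phi_withdrawal max_relapse reached_R returned final_b1
#>       12676.41       5698.188 0.008009907      TRUE     TRUE        0
```

The host reached the maximal severity ($R = 0.7$) during the addiction
phase, accumulated a behavior integral of 12676 over the 20,000
addiction steps and 5698 over the 100,000 withdrawal steps, relapsed by
at most 0.008 on the severity axis, and returned to the initial state.
Comparing against matched microbiome-free baselines:

```r
ens <- run_ensemble(cfg, n_reps = 20, base_seed = 1, baseline = "schedule")
ens$summary[, c("fold_phi_addiction", "fold_phi_withdrawal",
                "mean_max_relapse", "frac_not_returned")]
#>  fold_phi_addiction fold_phi_withdrawal mean_max_relapse frac_not_returned
#>            1.047213            3.527446       0.03321948              0.05
```

With 50 strains of mean effect 10, withdrawal is ~3.5-fold slower than
the microbiome-free baseline (the addiction phase is barely changed),
and 1 run in 20 fails to return to the initial state within the
withdrawal horizon — the feedback loop entrenches the addicted state.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/microbehave addiction --seed 1 --out run1/
Rscript inst/cli/microbehave two-strain --cost 0.09 --s 0.1 --sigma 0.001 --out fig1c/
Rscript inst/cli/microbehave sweep --grid 'n_strains=30|100|300,mean_effect=1|10' --reps 20 --out sweep/
```

Every output directory contains TSV trajectories / CSV metrics plus a
JSON manifest with the fully resolved configuration and seed; fixed
seeds give byte-identical outputs.

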