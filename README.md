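# nanocascade

Kinetic modelling of multienzyme cascades self-assembled on nanoparticle
scaffolds, built around the diagnostics used to demonstrate substrate
channeling in nanoparticle–enzyme clusters.

Multivalent His6-tagged enzymes cross-link quantum dots or nanoplatelets
into clusters in which sequential glycolytic enzymes sit close enough
that intermediates are consumed locally instead of diffusing into bulk.
The tell-tale observable is the **transient time** τ — the lag before a
sequential cascade reaches steady-state product flux, read off a progress
curve as the x-intercept of its late-time linear asymptote. For a
Michaelis–Menten cascade with steps *j* = 1…N,

    τ = Σ_j  K_M,j / (V_j − v0),     V_j = kcat_j · E_j,

with v₀ the first enzyme's velocity; in the strong-channeling limit
(V_j → ∞) τ → 0. Channeling is observable only in the diffusion-limited
regime, where the catalytic rate exceeds the encounter rate
∝ min([E],[I])^(2/3)·D.

The package provides, for whoever wants to model or reanalyse such
systems (enzymology and bionanotech groups, mostly):

- **Cascade presets and simulation** — the glucose → 3-phosphoglycerate
  7-enzyme cascade, its saccharification-extended 8E/9E/10E variants and
  the downstream 4E cascade to lactate, as coupled irreversible MM rate
  laws with cofactor mass balance, integrated with a stiff ODE solver
  (`build_cascade()`, `simulate_cascade()`); packaged apparent kinetic
  constants for all fourteen enzymes, free and quantum-dot-bound.
- **Transient-time analysis** — analytic τ (`tau_analytic()`), empirical
  τ by linear-region regression with error propagation
  (`detect_linear_region()`, `tau_empirical()`), and the
  diffusion-limited-regime report (`channeling_regime()`).
- **Progress-curve processing** — Beer–Lambert conversion, initial
  rates, Michaelis–Menten fitting, free-vs-bound fold-enhancement tables
  (`absorbance_to_concentration()`, `initial_rate()`, `fit_mm()`,
  `enhancement_table()`).
- **Stoichiometry optimization** — the two-round coordinate grid search
  over enzyme ratios under capacity and budget constraints
  (`opt_problem()`, `optimize_ratios()`).
- **Cluster assembly** — Poisson loading, geometric copies-per-particle
  estimates, and a stochastic coagulation simulator for cluster-size
  distributions (`poisson_loading()`, `capacity_estimate()`,
  `simulate_aggregation()`, `cluster_stats()`).
- **Synthetic data** — noisy plate-reader curves, MM titrations and
  known-τ lag curves with ground truth (`gen_progress_curve()`,
  `gen_mm_dataset()`, `gen_lag_curve()`).
- A thin command-line layer (`cascade_cli()`, wrapper in
  `inst/scripts/nanocascade`) over tidy CSV formats.

## Worked example

Simulate the 7-enzyme cascade with free (unassembled) enzymes at the
published working concentrations and estimate its transient time:

```r
library(nanocascade)

spec <- build_cascade("7E")
cond <- default_conditions("7E", t_end = 30000)
sim  <- simulate_cascade(spec, cond, preset_enzyme_concs("7E"))
sim
#> Cascade simulation: 7 steps, 13 species, t = 0..30000 s (501 samples)
#>   monitored NADH: 0 -> 122 uM

curve <- sim_progress_curve(sim)
keep  <- curve$time <= 25000          # the source assay's observation span
tau_empirical(progress_curve(curve$time[keep], curve$value[keep],
                             "concentration"))
#> tau = 13521 +/- 37 s (v_ss = 0.0068 uM/s, window 19920-24960 s, R^2 = 0.9986)
```

Only 122 uM NADH forms in 30,000 s from a 1.13 mM NAD+ pool and the
fitted lag is ~13,500 s: freely diffusing enzymes at low-nM
concentrations spend the entire assay far from steady state, which is
exactly why clustering the same enzymes on a scaffold (bound-context
kinetics, `context = "bound"`) pays off.

Fit a synthetic amylase titration and size up a quantum dot:

```r
fit_mm(gen_mm_dataset(default_enzymes()$Amy$params_free, 0.002), 0.002)
#> MM fit: Vmax = 0.05 uM/s, KM = 213 uM, kcat = 25 /s, kcat/KM = 117.4 /(mM s)

capacity_estimate(default_np_types()$QD520, monomer_kda = 34.6, subunits = 4)
#> [1] 7 9    # PFK tetramers per 4 nm quantum dot

linkers <- mapply(linker_spec,
                  c("Glk", "PGI", "PFK", "FBA", "TPI", "GPD", "PGK"),
                  c(5.5, 1, 9, 12, 1, 27, 7.5), SIMPLIFY = FALSE)
ens <- simulate_aggregation(6.25, default_np_types()$QD520, linkers, seed = 1)
ens
#> Cluster ensemble: 75 particles in 49 clusters (mean 1.53 NPs/cluster)
```

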