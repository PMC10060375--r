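---
title: "Modelling channeled multienzyme cascades on nanoparticle scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling channeled multienzyme cascades on nanoparticle scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocascade)
```

## The scientific problem

Multivalent His6-tagged enzymes can cross-link nanoparticles (quantum
dots, nanoplatelets, gold particles) into clusters in which sequential
cascade enzymes sit close enough together that intermediates are consumed
locally instead of diffusing into bulk — substrate channeling. The
experimental signatures are (i) a shortened *transient time* $\tau$, the
lag before a cascade reaches steady-state product flux, (ii) resistance
of the cascade to a competing enzyme that scavenges an intermediate from
bulk, and (iii) cluster-size statistics that track catalytic performance.

`nanocascade` provides the computational counterpart of such a study:
deterministic kinetics of the cascades, transient-time theory and
estimation, the diffusion-limited-regime criterion, enzyme-stoichiometry
optimization, nanoparticle loading and aggregation statistics, and
synthetic plate-reader data generators so that every stage can be tested
without instrument data.

## Cascade kinetic model

A cascade is an ordered chain of irreversible steps over a species
registry. Step $j$ with enzyme concentration $E_j$ proceeds at

$$ v_j = k_{\mathrm{cat},j} E_j \frac{S}{K_{\mathrm{M},j} + S}
   \prod_{c \in \mathrm{cofactors}(j)} \frac{C_c}{C_c + K_{\mathrm{cof}}} $$

where $S$ is the step's *limiting* substrate. The packaged presets cover
the glucose $\to$ 3-phosphoglycerate core (7E: Glk, PGI, PFK, FBA, TPI,
GPD, PGK, monitored by NADH formation at the GPD step), its
saccharification extensions (8E adds invertase/sucrose, 9E adds
amylase–maltase/maltoheptaose, 10E both), and the downstream
3-phosphoglycerate $\to$ lactate cascade (4E: PGM, Eno, PykA, LDH,
monitored by NADH consumption). Kinetic constants for every enzyme, free
in solution and quantum-dot-bound, ship in the package configuration
(`default_enzymes()`), which also records that the PGI and PGK constants
were measured in the reverse reaction direction; they are applied to the
forward step unchanged, as the only available estimates.

Modelling choices worth making explicit:

* **Irreversibility.** Reverse (gluconeogenic) fluxes are not modelled.
  The tabulated constants describe the forward assays; the endergonic GPD
  step is in practice pulled forward by PGK, and the assays terminate
  well before product pools build far enough for reverse rates to matter.
* **Cofactor factor.** Co-substrates (ATP, ADP, NAD+, NADH, phosphate)
  are near-saturating in all assay compositions, but the pools are
  finite. Each consumed co-substrate multiplies its step rate by
  $C/(C + K_\mathrm{cof})$ with $K_\mathrm{cof} = 10\ \mu M$: the factor
  is $> 0.99$ at assay concentrations and exists solely so depletion is
  smooth rather than a hard clamp that would make the ODE right-hand side
  discontinuous.
* **Triose bookkeeping.** Aldolase splits fructose 1,6-bisphosphate into
  DHAP + G3P and TPI converts DHAP to G3P irreversibly, so two NADH form
  per glucose in the excess-cofactor limit; the conservation tests assert
  exactly this. Maltoheptaose (7 glucose units) is hydrolysed to 3.5
  maltose equivalents and maltase releases 2 glucose per maltose, closing
  the glucose-unit balance for the 9E/10E presets.
* **Integration.** `deSolve::ode(method = "lsoda")` with absolute
  tolerance $10^{-6}\ \mu M$ and relative tolerance $10^{-8}$: enzymes
  are nM while substrate pools are mM, a six-order-of-magnitude span that
  demands a stiff-capable integrator. Cofactor couples (NAD+/NADH,
  ATP/ADP) are conserved by the stoichiometry itself; the test suite
  checks the drift stays below ten times the absolute tolerance. Rate
  evaluation floors concentrations at zero so roundoff can never produce
  negative rates.
* **Units.** Concentrations are internally $\mu M$, time s, rates
  $\mu M/s$; all interfaces state their units and convert explicitly
  (e.g. `preset_enzyme_concs()` converts the published nM values).

## Transient-time theory and estimation

For a sequential Michaelis–Menten cascade at steady state, each
intermediate-consuming step contributes a transit time
$\tau_j = K_{\mathrm{M},j} / (V_j - v_0)$, with $V_j = k_{\mathrm{cat},j} E_j$
and $v_0$ the first enzyme's velocity at the supplied (saturating)
substrate; the cascade transient is $\tau = \sum_j \tau_j$
(`tau_analytic()`). A step with $V_j \le v_0$ cannot keep pace and is
reported as non-steady-state ($\tau = \infty$) rather than as a number.
In the strong-channeling limit ($V_j \to \infty$) every term vanishes —
channeling manifests as $\tau \to 0$.

Empirically, $\tau$ is the x-intercept of the late-time linear portion of
a progress curve (`tau_empirical()`). The linear region is detected by
scanning all contiguous windows covering at least 20% of the curve (and
$\ge 20$ samples) and keeping the maximal-slope window whose fit reaches
$R^2 \ge 0.995$; slope ties prefer the longest, then the earliest,
window, so an exactly linear curve returns its full span. A curve that is
curved everywhere (the signature of a cascade still far from steady
state) raises a distinct `no linear region` condition instead of
returning a misleading number. The standard error of
$\hat\tau = -a/b$ is propagated from the fit covariance by the delta
method.

Both routes are cross-validated against each other: for two-step cascades
with the first enzyme saturated and $V_2 > v_0$, the simulated-curve
estimate agrees with the analytic sum to within 15%, the asymptotic
identity $\hat\tau = I^*/v_0 = K_M/(V_2 - v_0)$ holding exactly in the
long-time limit.

### The free-enzyme no-channeling estimate

The flagship desk computation simulates the 7E cascade with free-enzyme
constants at the published working concentrations (Glk 5.5, PGI 1, PFK 9,
FBA 12, TPI 1, GPD 27, PGK 7.5 nM) under the standard assay composition,
integrates to 30,000 s (the standard end-point readout time), and
estimates $\tau$ on the curve restricted to 25,000 s — the observation
span over which the source experiment for exactly these concentrations
was quantified. The analysis window matters and is therefore fixed and
logged: the free-enzyme curve is still convex throughout the assay span
(GPD, with $K_M \approx 3.5$ mM and $V$ barely above the input flux,
equilibrates on a $\sim 10^5$ s scale), so the fitted "asymptote" is an
extrapolation whose x-intercept grows with the analysis horizon
(≈ 11,200 s at 20,000 s, 13,521 s at 25,000 s, ≈ 15,700 s at 30,000 s).
Matching the window to the source assay's readout span is the choice this
package makes; `scripts/acceptance.R` logs the full configuration with
its result.

## Diffusion-limited-regime criterion

Channeling is only observable when catalysis outruns diffusion. The
encounter rate of an intermediate with the next enzyme scales as
$\min([E],[I])^{2/3} D$ with concentrations as number densities;
`channeling_regime()` converts $\mu M$ to molecules/nm$^3$ (so the scale
is already 1/s for $D$ in nm$^2$/s) and compares it with $k_\mathrm{cat}$
through a dimensionless ratio. The relation is a proportionality, not an
equality: the crossover factor is configurable (default 1) and reported
boundaries are order-of-magnitude indicators. Raising enzyme
concentration monotonically raises the encounter scale, so the
channeling-potential flag switches exactly once along a concentration
sweep — the behaviour asserted in the tests.

## Progress-curve processing

Absorbance converts to concentration by Beer–Lambert
($\varepsilon_{340} = 6220\ M^{-1} cm^{-1}$ for NADH). The optical path
length of a filled plate well depends on fill volume and well geometry,
so it is a required argument, never assumed to be 1 cm; the packaged
configuration carries 0.36 cm, the approximate depth of 50 uL in a
384-well plate. Initial rates take the earliest window of $\ge 10$
samples with $R^2 \ge 0.99$, extended while linearity holds and (when the
initial substrate concentration is supplied) at most 10% of substrate is
consumed. Michaelis–Menten fits use Levenberg–Marquardt least squares
seeded by a Hanes linearization; a titration whose levels do not straddle
the fitted $K_M$ triggers a poor-identifiability warning and carries an
inflated (possibly infinite) $K_M$ standard error rather than a
spuriously precise one. Fold-enhancement tables report bound/free ratios
of $k_\mathrm{cat}$, $K_M$, $k_\mathrm{cat}/K_M$ and specific activity,
flagging a ratio "NS" when its delta-method 95% interval includes 1 — a
concrete statistical reading of a qualitative published designation.

## Stoichiometry optimization

`optimize_ratios()` reproduces the two-round numerical-optimization
protocol as a coordinate-wise multiplicative grid search: round 1 sweeps
coarse factors (×1/2, ×1, ×2, ×4) per enzyme with passes repeated to
convergence, round 2 refines with ×0.75…×1.5. The published description
names two consecutive rounds but not the algorithm; a derivative-free
multiplicative scheme was chosen because the objective (simulated product
at the 30,000 s readout) is cheap but not smooth, and because enzyme
allocations are naturally reasoned about as ratios. Moves exceeding a
total-concentration budget rescale the remaining enzymes along the budget
simplex, which lets the search traverse the budget ridge that blocks
naive coordinate descent. Equal objectives break ties toward the lower
total enzyme concentration (parsimony). The incumbent is only replaced by
an improvement, so the best objective is non-decreasing across rounds.
The optimizer is validated against an exhaustive 50×50 lattice oracle on
a two-enzyme budget problem and against the closed-form rate-matching
solution of the symmetric problem; on the 7E cascade it must not fall
below the published empirical allocation's objective. The exact published
optimized ratios are not asserted — they came from an unpublished
simulation protocol — only the improvement direction.

## Nanoparticle loading and aggregation

Self-assembly of a single enzyme species onto particles follows a
Poisson distribution in the mixing ratio (`poisson_loading()`), truncated
and renormalized at the particle's binding-site budget.
`capacity_estimate()` derives that budget geometrically: the oligomer is
a sphere of volume $1.212 \times 10^{-3}$ nm$^3$/Da (globular-protein
specific volume), its circular footprint packs onto the contact shell
$4\pi(r_{NP} + r_{enz})^2$ for spheres or the stated face area for
platelets, and square versus hexagonal packing bound the count. For
phosphofructokinase on a 4 nm quantum dot this gives 8–9 copies against a
published estimate of 5–9.

`simulate_aggregation()` grows clusters by stochastic cluster–cluster
coagulation rather than on-lattice random-walk aggregation: the
event-driven form exposes exactly the dependencies the experiments vary
(particle concentration, linker valence, protein:particle ratio). Merge
propensities use the Brownian kernel
$K(i,j) = (r_i + r_j)(1/r_i + 1/r_j)$, $r \propto \mathrm{size}^{1/3}$,
times the acceptor's bindable-surface fraction, divided by the simulation
volume — so the merge rate rises with particle concentration as
coagulation kinetics require, which is the mechanism behind the observed
growth of cluster size with particle concentration at fixed enzyme. A
merge consumes one unused terminus of a bound multivalent linker on one
cluster and one binding site on the other; each multivalent molecule
supports one bridge. On a saturated surface the incoming terminus may
displace a resident singly-anchored molecule with efficiency
`w_exch = 0.1` — metal-affinity anchoring is dynamic, and a hard blockade
would unrealistically freeze enzyme-excess conditions at singletons.
Platelets carry a flat-shape collision enhancement (×2), the package's
minimal reading of the observation that planar scaffolds form larger
clusters. The kernel prefactor is uncalibrated: the observation span
`t_agg = 0.25` is in arbitrary coagulation units, chosen so the reference
mid-concentration condition shows partial aggregation, and absolute
cluster sizes are deliberately not matched to the published micrograph
means — only orderings and monotone trends are asserted, with
number-weighted and particle-weighted statistics both exposed
(`cluster_stats()`) because the weighting of published means is
ambiguous.

## Synthetic data

The generators produce the three data shapes the analysis consumes, each
with known ground truth: cascade progress curves as 340 nm absorbance
with additive Gaussian read noise (default $\sigma = 0.002$ AU at one
read per minute), Michaelis–Menten titrations (default eight levels
spanning 0.2–5 × $K_M$ in triplicate with multiplicative noise), and
closed-form lag curves $P(t) = v_{ss}(t - \tau(1 - e^{-t/\tau}))$ whose
asymptote x-intercept is exactly $\tau$. Noise always requires an
explicit seed. What the generators deliberately do not emulate: plate
effects (drift, evaporation, well-to-well bias), heteroscedastic
detector noise, temperature/pH dependence, and enzyme inactivation over
multi-day assays — so passing recovery tests demonstrate estimator
correctness under the stated noise model, not robustness to every
artefact of real plate data.

## Problem sizes

Default test and acceptance runs use 500-point trajectories (60 s
sampling over ≤ 30,000 s; the multi-day 4E preset samples at 300 s),
Monte-Carlo recoveries of 50–100 seeds, aggregation ensembles of ≤ 300
particles over ≤ 20 seeds per condition, and a 50×50 lattice oracle for
the optimizer — sizes chosen so the full suite completes in about a
minute while keeping every stochastic assertion comfortably powered.

## Known limitations

* No spatial reaction–diffusion model of the clusters and no explicit
  mechanistic channeling rate law: channeling enters through the regime
  criterion and the free-versus-bound kinetic contexts, mirroring how the
  experiments themselves infer it.
* Bound-context kinetics use a single parameter set per enzyme (the
  maximal-enhancement ratio); per-ratio kinetic tables are accepted as
  input but not packaged.
* The aggregation model conserves particles but simplifies linker
  bookkeeping (one bridge per multivalent molecule, displaced molecules
  leave the system); it is a trend model, not a structural one.
* Reverse reactions, product inhibition and temperature/pH effects are
  out of scope; the empirical surveys of those variables are not
  modelled.
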