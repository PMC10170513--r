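---
title: "Estimating ligand residence times from metadynamics simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ligand residence times from metadynamics simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadrt)
```

## The problem

The residence time (RT) of a drug on its target — the reciprocal of the
dissociation rate constant k\_off — often predicts duration of action
better than equilibrium affinity does. For slow binders (minutes to
hours) the unbinding event is far beyond the reach of plain molecular
dynamics, so enhanced-sampling protocols are used to force the ligand
out and then reconstruct, or at least rank, the unbiased kinetics.
`metadrt` implements two such protocols end to end at desk scale,
together with the replica statistics and the structure–kinetics
relationship (SKR) regression layer used to calibrate them against
experimental RTs of muscarinic M3 receptor antagonists:

1. **Conformational flooding**: a well-tempered metadynamics
   (wt-META-D) run is stopped at the first unbound configuration, and
   the unbiased residence time is estimated as
   RT\_calcd = α\_max × t\*, where α is the *acceleration factor* — the
   running average of exp(βV(s,t)) over the deposition records in the
   bound basin — and t\* the transition time.
2. **t\_META-D**: a constant-height metadynamics run, with the
   simulation time needed to reach the fully solvated unbound state
   used as an empirical kinetic descriptor.

The package deliberately separates the *estimators* (exact, unit-tested
bookkeeping) from the *dynamics* they are applied to. The bundled
dynamics are reduced Langevin systems with known kinetics, so every
estimator can be validated against brute-force oracles; the estimators
themselves also accept externally produced COLVAR/HILLS-style records.

## Metadynamics engine

Hills are multidimensional product Gaussians over the collective
variables (CVs),

V(s) = Σ\_j w\_j Π\_i exp(−(s\_i − c\_{j,i})² / 2σ\_i²),

with wrapped displacements on periodic CVs (dihedrals, period 360°).
The product-Gaussian form is the standard metadynamics kernel implied
by per-CV widths. Under well-tempering the deposited height decays with
the accumulated bias at the deposition point,

w = ω₀ · exp(−V(s,t) / k\_B ΔT).

Defaults follow common GPCR unbinding practice: ω₀ = 0.40 kcal/mol and
k\_B ΔT = 10 kcal/mol (a boost temperature ΔT ≈ 5000 K; the "kT"
bias-factor parameter is stored directly in energy units) for
well-tempered runs, ω₀ = 0.25 kcal/mol constant height for t\_META-D
runs, a 1 ps deposition stride, and hill widths of 0.2 Å on distance
CVs and 1.5° on angular CVs.

Three bookkeeping conventions matter for the flooding estimator and are
fixed as follows:

* hills are centered on the CV value at the deposition instant;
* the recorded V(s,t) is the bias *just before* the new hill is added —
  the bias the system has actually experienced;
* one-sided harmonic wall restraints (a floor keeping a pulling
  distance from collapsing, an upper wall capping an RMSD) steer the
  dynamics but are **excluded** from the recorded V(s,t): only
  deposited hills represent the flooding potential. The wall force
  constant is configuration (default 10 kcal mol⁻¹ unit⁻², stiff
  relative to the hill height); protocol descriptions in the
  literature typically leave it unstated.

Every deposition instant the engine records time, CV vector, V(s,t),
deposited height, and the unbound flag, and stops at the first unbound
record (recorded with zero deposited height) or at `max_time`. A run is
fully reproducible from its seed.

## Collective variables

`cv_geometry` provides mass-weighted COM distance, angle (vertex at the
middle COM, range [0°, 180°]), signed dihedral (atan2 formulation,
IUPAC sign convention — positive clockwise looking from the second to
the third COM; range (−180°, 180°]) and RMSD calculators, plus the
unbound detector (no receptor atom within 5 Å of any ligand atom).

RMSD is computed **without superposition by default**: in the protocols
this package models, the receptor backbone is held by harmonic
positional restraints (0.6 kcal mol⁻¹ Å⁻²), so the lab frame is
meaningful and the biased RMSD should reflect absolute displacement.
Kabsch superposition is available as an option. Degenerate geometries
(coincident or collinear COMs) raise errors instead of returning a
value, because a silently wrong CV would corrupt the bias. Coordinates
are Cartesian Å throughout with no minimum-image handling — the toy
systems are non-periodic; external trajectories from periodic boxes
must be pre-imaged (documented limitation).

One labeling quirk of the source protocols is worth noting: the width
assignments for the two RMSD CVs are stated in the opposite order to
the CV definitions (0.1 Å vs 0.2 Å). The engine treats widths as
per-CV configuration and makes no attempt to resolve the swap; the
package defaults follow the definition order.

## The flooding estimator

Given a trajectory, `acceleration_factor()` computes
α(t\_k) = (1/k) Σ\_{j≤k} exp(β V\_j), accumulated in log space
(shifted-exponential running mean), so the series stays finite for
βV per record up to ~700. β is the physical simulation temperature's
1/(k\_B T) at 300 K — not the boosted temperature, which only controls
hill decay.

`transition_time()` reads the transition off the α series as its
global maximum — for a unimodal series this is exactly where dα/dt
changes sign. Ties return the earliest time. If the maximum is the
final record the series is still rising, no transition was observed,
and the estimate is flagged unconverged rather than given a value.
Records after the transition (between the α peak and the stop frame)
remain in the running average; they cannot raise the recorded maximum,
and whether the original analysis scripts excluded them is not
documented — inclusion is the simpler and equally valid choice.

`rt_calcd()` multiplies α\_max by t\* and converts ps → minutes
(÷ 6×10¹³) and log₁₀ minutes, the units in which calibration data are
tabulated.

For constant-height runs, `t_metad()` returns the first unbound record
time in ns, with censoring flagged when the run never unbinds.

## Replica statistics

Unbinding is a rare event, so per-replica RT\_calcd values should be
roughly exponentially distributed and are summarized by the geometric
mean τ (`aggregate_replicas()`): the mean of log₁₀ values with the SEM
of the log₁₀ values (sample SD, n−1, over √n), n = 10 replicas being
the conventional campaign size. t\_META-D values are averaged
arithmetically (mean ± SEM, ns). Supporting checks:

* `ecd()` + `poisson_cdf()` compare the empirical cumulative
  distribution with P(x) = 1 − exp(−x/θ). Published comparisons of
  this kind divide by *log* τ; whether the abscissa is also on log
  scale is not stated in the sources, so both application modes are
  provided (`standard`: linear-scale exponential CDF; `as_printed`:
  the same formula applied to log₁₀ values) and the mode is recorded
  on every result — neither is asserted to be the original intent.
* `exponentiality_check()` is a one-sample Kolmogorov–Smirnov test
  against the exponential CDF with the rate fitted from the sample
  mean, using the asymptotic p-value. Because the rate is estimated
  from the same data the p-value is conservative (it under-rejects
  relative to a Lilliefors-corrected test); this approximation is
  deliberate and tested.
* `unpaired_t_test()` is the classic pooled-variance Student's t-test
  with star annotations (\*\*\* p < 0.001, \*\* p < 0.01, \* p < 0.05).

Campaigns (`run_campaign()`) derive replica seeds deterministically as
`base_seed + replica_index`. Replicas that fail numerically or never
unbind within `max_time` are logged and excluded, and the summary
carries `n_effective`; the calibration data sets this package ships
always report n = 10 and never describe censoring, so censored
replicas cannot honestly be imputed.

## Toy dynamics and what they do (and do not) show

The estimators are validated on overdamped (Brownian) Langevin dynamics
over analytic potentials. Overdamped dynamics is a deliberate
substitution for thermostatted all-atom MD: the flooding identity and
the t\_META-D descriptor are dynamics-agnostic, and Brownian dynamics
has cheap, well-characterized reference kinetics. Reduced systems keep
*physical units* (Å, kcal/mol, ps, K) so the standard metadynamics
parameter values apply verbatim.

The benchmark (`double_well_fixture()`) is a quartic double well
V(x) = h((x/x\_m)² − 1)² with the bound minimum at −1.5 Å, the barrier
top at 0 and the unbound threshold at +1.0 Å (past the top, committed
to the far basin; the same point is the absorbing boundary of the
unbiased oracle). Default choices, made once:

* **barrier h = 8 k\_BT** (≈ 4.77 kcal/mol at 300 K): high enough that
  no spontaneous escape occurs on the timescale of a biased run
  (unbiased MFPT ≈ 3.3 ns vs biased unbinding in tens of ps), low
  enough that the unbiased oracle is computable in seconds;
* **friction γ = 2 ps⁻¹, m = 1 amu**: the bound-basin relaxation time
  γm/V'' ≈ 0.1 ps is then well below the 1 ps deposition stride. This
  is the infrequent-deposition regime the flooding method assumes
  (bias must not be deposited while the system is crossing the
  barrier); with relaxation times comparable to the stride the
  recovered RT distribution becomes visibly over-dispersed;
* **timestep 0.001 ps**, comfortably inside the Euler–Maruyama
  stability limit (dt ≪ γm/V''\_max ≈ 0.12 ps);
* hill width 0.2 Å ≈ one third of the bound basin's thermal width
  (√(k\_BT/V'') ≈ 0.19 Å), matching the standard width-to-basin rule.

The unbiased reference is `reference_mfpt()`, a brute-force mean
first-passage time over independent replicas; its own correctness is
tested against the closed-form double-quadrature MFPT of 1-D Brownian
motion and the Kramers high-friction estimate, and an Arrhenius check
(one extra k\_BT multiplies the MFPT by ≈ e).

With these conditions, a 10-replica flooding campaign recovers the
unbiased MFPT within a factor of 3 (|log₁₀ τ − log₁₀ MFPT| ≤ 0.5), the
per-replica RT\_calcd sample passes the exponentiality check at
p > 0.01 in ≥ 8 of 10 repeated campaigns, and two benchmarks whose
barriers differ by 2 k\_BT are ranked correctly by both τ and mean
t\_META-D in ≥ 9 of 10 campaign repetitions. Standard problem sizes:
2000 ps of biased time per replica (rarely used — unbinding occurs in
tens of ps), 10 replicas per campaign, 40 oracle replicas; a full
validation sweep runs in well under a minute on one CPU.

The pseudo-molecular complex (`generate_pseudo_complex()`) exists to
exercise the *geometric* CV path end to end: a fixed particle cage with
distal anchor triads ~15 Å below (so the pulling COM distance is ~15 Å
when bound and the standard 15 Å floor applies as-is), a rigid
five-particle ligand, and a funnel potential on the ligand COM. Its
demonstration runs use hill widths matched to its own CV fluctuation
scales (0.5 Å / 3° rather than 0.2 Å / 1.5°) — the same
width-to-fluctuation rule, applied to a different system.

What passing these tests shows: the bias bookkeeping, the α algebra,
the transition detection, the unit chain, and the replica statistics
are correct, and the flooding identity does recover unbiased kinetics
when its applicability conditions hold. What it does **not** show: that
absolute RTs of real protein–ligand systems are recovered. The real
systems involve solvent, membrane, receptor conformational gating and
force-field error; the corresponding published τ values overestimate
experiment by many orders of magnitude and are shipped here as data
(`load_table("cv_comparison")` etc.), not reproduced by simulation.

## The SKR layer

`fit_skr()` is ordinary least squares of experimental log RT on a
computed descriptor (log τ in log₁₀ minutes, or t\_META-D in ns).
Conventions, each chosen to reproduce the published statistics exactly
and locked by tests:

* r² is the squared Pearson correlation (reported in prose as a
  percentage);
* RMSE uses the n−2 denominator (the regression standard error). The
  published tables never define their RMSE; n−2 reproduces both
  printed values (0.20 for the flooding calibration, 0.45 for the
  t\_META-D one) where a denominator of n does not;
* the training set for the first antagonist series is the packaged
  congeneric flag (the eight tiotropium analogues). A Tanimoto
  similarity filter is also provided (default threshold 0.45,
  motivated by the similarity range of the excluded compounds), but
  note the printed similarity of one excluded compound is 0.48, so
  the flag — not the threshold — defines the published training set;
* SRT/MRT/LRT class boundaries are not defined in the sources; the
  defaults (SRT < 1.0 ≤ MRT < 2.5 ≤ LRT, log₁₀ min) are configuration
  chosen to reproduce the published labels (~4 min SRT, ~50 min MRT,
  ~2724 min LRT).

The two flooding calibrations (the tiotropium-analogue set and the
second, chemically heterogeneous set) yield significantly different
slopes and intercepts; the package treats every SKR fit as a local
model, and `report()` only pushes a campaign descriptor through a fit
the caller supplies explicitly.

## Known limitations

* Hill lists are stored and summed directly (no grid interpolation);
  fine at 10²–10³ hills, quadratic beyond.
* No multiple-walker or bias-exchange variants; one CV set per run.
* The unbound detector and CV calculators assume non-periodic
  Cartesian coordinates.
* The exponentiality p-value is conservative (fitted-rate KS).
* The pseudo-complex ligand is rigid and translational only; it probes
  CV plumbing, not molecular realism.
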