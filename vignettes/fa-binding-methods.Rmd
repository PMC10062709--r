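---
title: "Models and methods: fluorescence anisotropy binding analysis under ligand depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: fluorescence anisotropy binding analysis under ligand depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fabind analyses plate-based fluorescence anisotropy (FA) ligand-binding
assays in the regime where a receptor preparation — here, G-protein-coupled
receptors displayed at high density on budded baculovirus (BBV) particles —
depletes a substantial fraction of the fluorescent probe. In that regime
the familiar closed-form binding equations (hyperbolic saturation,
Cheng-Prusoff) are biased, and the package instead works with an explicit
mass-action model solved exactly (at equilibrium) or integrated as an ODE
system (kinetics). This vignette documents the model, the estimation
machinery, the synthetic-data generator used for validation, and the
numerical and design choices a user or maintainer may want to audit.

## The binding model

Three reversible reactions connect seven species:

$$R + L \rightleftharpoons RL, \qquad R + C \rightleftharpoons RC, \qquad
  NBV + L \rightleftharpoons NBVL$$

with $R$ the free receptor, $L$ the fluorescent probe, $C$ an unlabeled
competitor, and $NBV$ non-specific binding sites contributed by the
particle preparation. Each reaction is parameterized by an association
rate constant and an equilibrium constant — $(k_{on,L}, K_{d,L})$,
$(k_{on,C}, K_{i,C})$, $(k_{on,NS}, k_{off,NS})$ — with dissociation rates
derived as $k_{off} = k_{on} K$. Units are fixed package-wide: nM for
concentrations, seconds for time, 1/(nM·s) and 1/s for rates; all I/O
converts at the boundary.

The receptor and non-specific-site totals of a well are expressed through
the *stock* concentrations of the undiluted particle preparation
(`R_stock`, `NBV_stock`) scaled by the well's dilution factor. This makes
one parameter set describe a whole dilution series and is what lets a
saturation experiment estimate the stock receptor concentration.

Non-specific binding is treated as a reversible reaction by default, with
`koff_NS` a fittable parameter. A reduced parameterization in which only
`kon_NS` is free — the dissociation rate held fixed — is obtained simply by
leaving `koff_NS` out of the free-parameter set, and is the default of the
recovery harness: with non-specific occupancy far from saturation only the
partition ratio is identifiable, so fitting both NS rates adds a pure
ridge direction to the loss surface.

The observable is the concentration-weighted mean of the intrinsic
anisotropies of the probe's states:

$$FA = \frac{[L]\,FA_{free} + [RL]\,FA_{bound} + [NBVL]\,FA_{ns}}
            {[L] + [RL] + [NBVL]}$$

a convex combination bounded by the intrinsic values. Raw plate data enter
as parallel/perpendicular intensity pairs; after channel-wise blank
subtraction, $FA = (I_\parallel - I_\perp)/(I_\parallel + 2 I_\perp)$. No
instrument G-factor appears: the package assumes pre-calibrated channels
(the generator emits G = 1 data), because the plate readers this targets
report calibrated polarized pairs. Values outside a configurable
plausibility window of (−0.2, 0.5) draw a warning but are never mutated.

## Simulation and the exact equilibrium

Kinetic predictions integrate the seven mass-action ODEs with compiled
derivatives under `deSolve::lsoda` (stiff-capable; relative tolerance
1e-8, absolute 1e-10 nM). Reagent additions — e.g. the excess-blocker
chase that initiates dissociation — are instantaneous concentration steps;
integration restarts at each event. An optional per-event volume-dilution
factor rescales the whole well before the increment; the default of 1
ignores addition volumes, which are typically negligible and unrecorded.
For fitting, wells sharing a time grid and event schedule are stacked into
one block ODE system and integrated in a single solver call, which is
roughly an order of magnitude faster than per-well calls.

Equilibrium analyses use an exact solver instead of long integrations:
eliminating $C$ and $NBV$ analytically reduces the coupled mass balances
to two unknowns (free $L$, free $R$), each solved by bracketed
root-finding on a monotone function, then polished by damped Newton
iteration. Residuals of every equilibrium relation are verified below
1e-10 relative; the tests require agreement with the single-site quadratic
closed form to ten significant digits and with $t = 10^7$ s integrations
to 1e-5 nM over random parameter draws.

## Equilibrium analyses

`fit_saturation()` fits endpoint anisotropy of a two-probe-concentration
dilution series (total and blocked/nonspecific conditions) with one global
parameter set, predicting each well through the exact equilibrium — the
full depletion treatment. Concentration-like parameters are fitted on the
log scale (positivity by construction) with Levenberg-Marquardt, and SEs
are mapped back by the delta method. `FA_ns` and the NS equilibrium
constant are held fixed here: at working dilutions non-specific binding is
linear in the site concentration, so only a combination is identifiable
and the scale is carried by `NBV_stock`.

`fit_sigmoid()` implements the log-inhibitor-vs-response model
$y = bottom + (top-bottom)/(1 + 10^{h(\log_{10}c - LogIC50)})$ with Hill
slope fixed at 1 (three-parameter, default) or free. Zero-concentration
wells are retained: $\log_{10} 0 = -\infty$ makes the model value exactly
`top` there, so they anchor the upper plateau without constraining it.

`ki_from_ic50_depletion()` defines the competitor affinity implicitly: Ki
is the value at which the competition equilibrium, evaluated at competitor
total equal to the IC50, halves the specific signal of the competitor-free
equilibrium. This is solved by monotone bracketing on $\log_{10} K_i$
rather than by any closed-form depletion correction — exact by
construction, and validated in the tests against a brute-force grid
search. It reduces to Cheng-Prusoff ($K_i = IC50/(1+L/K_d)$) as the
receptor total vanishes; an IC50 below the floor imposed by depletion
(where even an infinitely potent competitor cannot halve the signal) is
reported as an error rather than extrapolated. The competition endpoint
defaults to 180 minutes — late enough that the apparent IC50 of typical
competitors has stabilized — and display normalization (competitor-free =
100%, top concentration = 0%) is a presentation transform only; fitting
always operates on raw FA.

`z_prime()` scores the screening window as
$Z' = 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|$ with sample (n−1)
standard deviations.

## Global kinetic estimation

`kinetic_loss()` is the weighted mean-squared error of predicted versus
observed anisotropy over all (well, time) points, the prediction running
the full ODE simulation. Early time points carry most of the information
about association rates, so the default weighting is the mild hyperbolic
down-weighting $w(t) = 1/(1 + t/\tau)$ with $\tau$ = 600 s, applied with
$t$ measured from the most recent addition event of the well (so points
right after a chase are re-weighted like points right after association
start) and normalized to mean 1. The scheme is a declared surrogate for
the "less timescaling" weighting of the systems-biology tooling it
emulates, whose exact form is not documented; the uniform scheme is one
flag away. A failed simulation maps to an infinite loss with a warning, so
stochastic optimization continues past pathological proposals.

`fit_global()` minimizes this loss with a seeded hybrid of Nelder-Mead
simplex refinement inside a simulated-annealing temperature ladder
(start temperature 1000, 10³ loss evaluations per temperature, reduction
factor 0.2, cooling until the temperature falls below 0.1 — giving the
ladder 1000, 200, 40, 8, 1.6, 0.32). The named algorithm family fixes the
schedule but not the restart mechanics, so the package defines them
explicitly and fully seeded:

1. **Initialization.** Concentration- and rate-like parameters start at
   neutral mid-range magnitudes (`kon` 1e-3, `K` 1 nM, `R_stock` 10 nM)
   and anisotropy levels at data quantiles; a deterministic iterated
   simplex descent (restarting Nelder-Mead until the loss stops improving)
   converges this start before any stochastic step. Iteration matters:
   a single Nelder-Mead run reliably stalls on the long shallow ridges
   that couple stock concentration, affinity and bound-state anisotropy.
2. **Ladder.** At each temperature, restart points are drawn around the
   best point so far with magnitude proportional to temperature on the
   log-parameter scale (3 decades at the start temperature), refined by a
   short Nelder-Mead run, and accepted into the current state by the
   Metropolis criterion with the Boltzmann scale calibrated so the
   initial loss is borderline-acceptable at the start temperature.
3. **Polish and uncertainty.** A final iterated Nelder-Mead polish runs
   from the best point. Uncertainty is the spread of 25 short refits
   started from small perturbations of the optimum (count configurable);
   reported SEs are the standard deviations of those re-estimates.

Parameters are optimized on the log scale within bounds of [1e-8, 1e2]
for rates and [1e-3, 1e4] nM for concentrations (anisotropies in
(−0.2, 0.5) on the natural scale, the physical plausibility window of dye
anisotropies); bound violations are clamped with a
smooth penalty. Identical seed, config and dataset give bit-identical
results, and the tests assert the optimizer-competence property that the
returned loss never exceeds the loss at the generating truth.

For competition kinetics, `select_competition_points()` reproduces the
practice of dropping uninformative plateau wells: points with fitted
response between 10% and 90% of the window are kept, plus the two plateau
points nearest the slope on each side; a curve with fewer than four slope
points is used whole, with a warning.

## IC50 time courses

Before equilibrium, the apparent IC50 of a competition series drifts: it
decreases in time when the competitor equilibrates more slowly than the
probe and increases when it equilibrates faster, so the drift direction
and rate carry kinetic information. `theoretical_ic50_timecourse()`
simulates the full concentration series and fits the three-parameter
sigmoid at every time point; `observed_ic50_timecourse()` does the same
per-time fits on measured data (times with incomplete series are skipped,
failed fits flagged, nothing interpolated). `fit_ic50_decay()` then fits

$$Log(IC50)_t = \left(Log(IC50)_{t=0} - Log(IC50)_{eq}\right) e^{-kt}
  + Log(IC50)_{eq}$$

with $t$ in minutes from reaction initiation (the receptor-addition event,
which is pipetted last) and reports the stabilization half-life
$\ln 2 / k$. Points are weighted by their inverse squared per-time SE by
default; whether to weight is switchable because per-time SEs can be
unreliable when a plateau is poorly sampled.

## The synthetic generator, and what it does not emulate

`generate_experiment()` produces complete raw 384-well datasets: it lays
out measurement wells and matched blanks (blanks adjacent to their
dilution group, recorded explicitly in the well map — no positional
inference), simulates every well with the ODE model, converts anisotropy
to channel intensities using a probe brightness of 1000 a.u./nM, adds a
blank baseline proportional to the BBV dilution (autofluorescence and
scattering surrogate; 150/120 a.u. per channel at dilution 1), and applies
multiplicative Gaussian channel noise with 1% CV — plate readers show
roughly constant CV at these intensities. A Poisson shot-noise mode was
considered and rejected as indistinguishable at these intensities.
Generation is byte-identical given the seed.

The emulated designs follow the assay they model: saturation kinetics uses
probe at 0.5 and 3 nM against a six-point two-fold BBV dilution series
starting at 0.2 (receptor totals 4 nM down to 0.125 nM, spanning
receptor-excess through receptor-limiting), a 90-minute association
phase, then dissociation initiated by 333 µM blocker in a chased total
well while a paired association-control well runs on; 50 µM blocker from
time zero defines nonspecific wells; sampling every 5 minutes to a 3 h
horizon. The layout, horizon and dilution range are package choices with
identifiability rationale, each verified by a noise-free profile of the
loss: the chased well carries the dissociation phase (90 minutes spans
over two probe off-rate half-lives, pinning `koff`); the association
controls reach their equilibrium plateaus; and the series must reach
receptor excess over the 3 nM probe so that the top wells approach the
bound-state anisotropy directly. A series confined to the
receptor-limiting regime (e.g. dilutions below 1/30) leaves
`R_stock`–`FA_bound`–`Kd` on a ridge where a 7 nM-stock model reproduces
a 20 nM-stock truth to 0.0002 FA units — far under the noise floor — and
single-experiment estimates then wander over a several-fold range, which
is also why anisotropy parameters are bounded to the physical window
(−0.2, 0.5) during fitting. Competition kinetics uses constant probe
(0.5–1 nM) and BBV (dilution 1/30, receptor ≈ 0.67 nM), a half-log
competitor series plus a competitor-free well, sampled every 5 minutes
for 5 h.

The reference ground truth (`celt419_parameters()`) combines the fitted
constants of the Cy3B-probe/D3-receptor BBV system — kon 4.2e-4 1/(nM·s),
koff 2.8e-4 1/s (Kd 0.667 nM), stock receptor 20 nM, free-probe
anisotropy 0.081 — with package-chosen values where no fitted constant
exists: bound-state anisotropy 0.20 (a specific window of ~0.12 FA units
at high occupancy), non-specifically bound anisotropy 0.15, and NS
parameters (kon 1e-5 1/(nM·s), koff 4e-4 1/s, stock 100 nM) sized so that
on the order of 8% of probe is non-specifically bound at a 1/30 working
dilution. The blocker is modelled as a fast high-affinity competitor
(kon 1e-3, Ki 0.1 nM) and treated as a known assay constant during
fitting.

What the generator deliberately does not model: evaporation and
photobleaching over the ≤5 h horizon, liquid-handling errors, air
bubbles, well-position effects, and G-factor miscalibration. Passing
recovery tests therefore demonstrate the correctness and identifiability
of the estimation machinery under the stated noise model — not robustness
to those instrumental artifacts.

## Validation by parameter recovery

`saturation_recovery_study()` is the end-to-end harness: per seed it
generates a saturation-kinetics experiment from the reference truth,
blank-corrects, computes anisotropy, and runs the global fit with eight
free parameters (probe kinetics, NS on-rate, both stocks, three
anisotropies). The headline check — run both in the test suite and by
`scripts/acceptance.R` — is that median recovered stock concentration,
probe on-rate and free-probe anisotropy over five seeds fall within one
reported SEM of the generating values (20 ± 5 nM, 4.2 ± 0.7e-4 1/(nM·s),
0.081 ± 0.009). Each experiment is 30 measurement wells × 37 time points;
a full study runs in roughly 15 minutes on one core. These problem sizes
are deliberate: large enough that all eight parameters are identifiable,
small enough to keep the study interactive.

## Known limitations

* One-site model only: no cooperativity, multi-site binding, ternary
  G-protein complexes or receptor internalization.
* The NS ridge: with non-specific occupancy in the linear regime, only
  the NS partition product is identifiable; individual NS parameters
  (`kon_NS`, `NBV_stock`, `FA_ns`) carry large SEs by construction, which
  the recovery harness reports honestly rather than hiding.
* The Metropolis/restart mechanics inside the annealing ladder are this
  package's explicit construction; other implementations of the same
  named algorithm family will differ in trajectory (though not, on these
  problems, in the optimum found).
* Closed-form competition-kinetics approximations (association-rate
  equations of the two-ligand problem) are intentionally absent — the ODE
  model supersedes them here.
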