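---
title: "Modelling Xenopus oocyte meiotic maturation with meiodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Xenopus oocyte meiotic maturation with meiodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

A resting *Xenopus laevis* oocyte is arrested in a G2-like prophase-I state.
A progesterone signal triggers meiotic maturation: MPF (the cyclin B--Cdk1
complex) activates sharply at meiotic resumption (G2/MI), drops partially as
the anaphase-promoting complex (APC) degrades cyclin B at the end of meiosis
I, reactivates at the MI/MII transition, and finally holds a high plateau at
the metaphase-II arrest where the egg awaits fertilization. `meiodyn`
implements a dynamical model of the regulatory network that produces this
non-monotonous MPF time course, together with the analysis machinery used to
dissect it: time-course simulation, equilibrium continuation with
saddle-node detection, dual parameter-sensitivity measures, in-silico
knockout phenotyping and robustness Monte Carlo.

## The model

Twelve proteins are represented. Six *class-I* proteins have dynamic total
concentrations (synthesis and degradation) and exist in active and inactive
forms: Mos, MPF, APC, CPEB1, CPEB4, and Emi2, the last with three
phosphoforms -- unphosphorylated (partially active toward APC),
Rsk-phosphorylated (fully active) and MPF-phosphorylated (inactive and
destabilized, i.e. degraded faster). This gives the 13-variable ODE state
(`state_names()`). Six *class-II* proteins have constant totals (normalized
to 1) and are treated by the quasi-steady-state approximation: Plx1, Cdc25
and Myt1 activate through one-step phosphorylation (active fraction
$v_+/(v_+ + v_-)$), while MEK, ERK and Rsk activate through two-step
distributive phosphorylation, giving the squared fraction
$(v_+/(v_+ + v_-))^2$ that sharpens the cascade response. The absolute scale
of class-II interconversion rates cancels in these expressions and is kept
as the free parameter `lambda_class2`.

Class-I activation and inactivation follow Michaelis--Menten kinetics with a
single shared Michaelis constant (0.1 concentration units, well below the
order-one totals, so interconversion operates in the zero-order
ultrasensitive regime). The regulatory links are:

* **MPF autoamplification**: Cdc25 activates MPF, Myt1 inactivates it; MPF
  activates Cdc25 and inactivates Myt1; Plx1 activates Cdc25 and
  inactivates Myt1 and is itself activated by MPF and by progesterone.
* **MPF-APC negative feedback**: MPF activates APC; active APC degrades
  cyclin B (both MPF forms). Emi2 inhibits APC (the unphosphorylated form
  partially, the Rsk-phosphorylated form strongly).
* **MAPK cascade**: Mos activates MEK, MEK activates ERK, ERK activates Rsk
  and feeds back on Mos; MPF also phosphorylates/stabilizes Mos; Mos and
  Rsk--ERK downstream effects on Cdc25/Myt1 other than the Mos--Myt1 link
  are not modelled.
* **Translational control**: CPEB1 (activated by progesterone and MPF)
  drives translation of Mos, cyclin B1/B5 and CPEB4; CPEB4 (activated by
  MPF) drives cyclin B2 and Emi2; CPEB1 is degraded by the joint action of
  MPF and APC at the meiotic transition.

Two routing choices matter and are deliberate: newly synthesized
cyclin--Cdk1 enters the *active* pool (Myt1 then pushes it into the
inactive pre-MPF store), and newly translated Mos is active. With synthesis
routed into the inactive forms, the saturating Michaelis--Menten activation
flux makes it impossible for an accumulating store or an accumulating Mos
pool to trigger anything -- the model could neither fire from its pre-MPF
store nor engage the MAPK cascade at resumption.

Parameters carry systematic identifiers (`ks_<target>_<driver>`,
`ka_`/`ki_` maximal rates, `kd_` degradation, `km_` Michaelis constants).
The set has 73 entries; fixing the six class-II totals at 1, the twelve
class-I Michaelis constants at the shared value and the class-II scale
leaves 54 free parameters, split 7 (MAPK module) + 15 (MPF-APC module) + 32
(remaining couplings). `audit_parameters()` checks these counts.

## Calibration of the reference parameter set

Rate constants of this network are mostly unmeasured, so the reference set
(`default_parameters()`) was calibrated hierarchically against qualitative
dynamical constraints, each submodule first, then the couplings:

1. **MAPK module (7 parameters)** -- the isolated cascade must be a
   bistable switch with hysteresis in the Mos-activating drive
   (`mapk_switch_diagram()`): two saddle-nodes with both switching
   thresholds positive (reference: up 0.131, down 0.054).
2. **MPF-APC module (15 parameters)** -- the isolated oscillator must have
   a stable low-MPF state at basal cyclin synthesis, lose it at a
   saddle-node as the drive increases (reference onset near drive 0.92),
   oscillate beyond it, and be excitable below it (`mpf_apc_scan()`,
   `mpf_apc_sn()`).
3. **Remaining 32 couplings** -- the full network must show a stable G2
   state at zero progesterone, the wild-type peak/trough/plateau MPF
   course under a unit progesterone step, a stable metaphase-II state at
   zero input (bistability and irreversibility), four saddle-nodes with
   the G2-destabilizing threshold positive and the MII-bounding threshold
   negative, and the catalogued knockout phenotype classes.

Time is in hours (first MPF peak near 2 h, plateau approached within
roughly a day); concentrations are in arbitrary units with class-II totals
and the resting pre-MPF store of order one. Only relative concentrations
are meaningful.

```{r}
library(meiodyn)
audit_parameters()
traj <- simulate_maturation(default_parameters(), input_step(1),
                            horizon = 60)
mpf_features(traj)
autoplot(traj)
```

## Trajectory indicators and phenotype classification

The MPF course is summarized by the time and height of the first prominent
peak, the trough between peak and plateau, and the late plateau
(`mpf_features()`). A peak must exceed 20% of the wild-type plateau; the
plateau is the mean over the final 10% of the horizon and is flagged
converged only if the residual slope is below $10^{-3} \cdot
M_\mathrm{peak}$ per hour; peak and trough locations are refined by local
parabolic interpolation (exact for smooth extrema; an option disables this
for piecewise-linear test fixtures). Phenotypes are assigned by explicit
threshold rules (`classifier_rules()`): entry delay above 1.5x the
wild-type peak time, entry failure beyond 3x, MII-entry failure below 0.2x
the wild-type plateau, intermediate-plateau MI/MII failure between 0.2x and
0.7x, metaphase-I arrest when the trough stays above 0.8x the peak with a
high plateau reached on time, oscillations for three or more similar
maxima. The thresholds are package choices -- the phenotype classes
themselves are only described verbally in the experimental literature --
and are configurable.

## Continuation and thresholds

Equilibrium branches versus progesterone are computed by pseudo-arclength
continuation (secant predictor, Newton corrector on the bordered system,
adaptive steps, every accepted point re-converged below a 1e-10 residual;
Jacobians by central finite differences with relative step 1e-6; stability
from dense eigenvalues of the 13x13 Jacobian). Progesterone is treated as a
formal real parameter that may be negative during continuation; simulations
never use negative input. Folds are detected from parameter-direction
reversals along the branch and refined by Newton iteration on the extended
fold system (state, null vector, parameter), with a trust check that
rejects refinements that jump away from their seed. The maturation
thresholds are identified structurally: `P_I` is the fold terminating the
stable branch through the G2 state, `P_IV` the fold terminating the stable
branch through the metaphase-II state. In the reference model the diagram
has four saddle-nodes, `P_I` is about 0.248 and `P_IV` about -0.160, and
the dynamic maturation threshold found by amplitude bisection on
simulations matches `P_I` to a few parts in 1e-5 -- the switch is governed
by the fold structure.

```{r}
bd <- bifurcation_diagram(default_parameters())
progesterone_thresholds(bd)
autoplot(bd)
```

## Sensitivity measures and module partition

Two local measures are computed per interaction parameter (a parameter
attached to a network link), both as two-sided central differences on the
log scale with a default 10% perturbation:

* the *dynamic* measure combines the absolute logarithmic derivatives of
  the indicators, weighted equally by default ($w_j = 1$): the peak time
  (early, G2/MI) against trough and plateau (late, MI/MII);
* the *bifurcation* measure combines the absolute displacements of `P_I`
  and `P_IV` per unit log-parameter, with each perturbed threshold
  re-located by local Newton fold tracking from the reference fold (a test
  verifies agreement with full-diagram recomputation to 1e-4).

Each measure is normalized to the late-component share, a number in [0, 1]:
near 0 means the parameter controls meiotic resumption, near 1 the MI/MII
transition. Parameters with zero reference value have zero sensitivity by
convention; indicators that disappear under perturbation are capped at a
saturation value and flagged. In the reference screen the two normalized
measures correlate strongly (about 0.84) and are bimodal near 0 and 1, and
thresholding them (below 0.3 versus above 0.7, after discarding
sensitivities below 5% of the median total) recovers the two-module
architecture: Plx1/Cdc25/Myt1 links fall in the resumption module,
APC/Emi2/CPEB4 links in the transition module, and Mos and MPF contribute
links to both.

## Knockouts and robustness

`knockout_suite()` simulates the catalogued interventions -- antisense-like
synthesis ablations (parameters set to zero), MEK inhibition (the MEK-ERK
activation rate set to zero), Emi2 overexpression (constitutive Emi2
synthesis set to 0.2, giving roughly MII-level Emi2 from the start, since
the reference basal Emi2 synthesis is zero) -- from the unperturbed G2
state and classifies each against the wild type. All seven protocols
reproduce their catalogued phenotype classes. Two calibration notes: the
Mos-ablation outcome is accepted as either MII-entry failure or sustained
oscillations, since that choice is parameter-sensitive in this network; and
the cyclin-ablation initiation delay, while strictly positive, is mild
(about 1.2x the wild-type peak time) because in this parameterization the
G2-escape time is dominated by the shared CPEB1/Plx1 activation ramp --
the match criterion for that protocol therefore checks the phenotype class
plus a strictly delayed peak rather than the 1.5x delay label.

`robustness_kinetic()` multiplies every free parameter by independent
lognormal factors of mean 1 at a given coefficient of variation (the
distribution is a package choice; lognormal guarantees positivity),
re-relaxes the perturbed system, applies the standard step and classifies
the outcome; success means normal maturation or a pure entry delay. With
100 seeded trials per level, success is 1 at CV 0 and decreases with CV
(about half the trials fail by CV 0.3). `robustness_input()` quantifies the
insensitivity of the (MPF, APC) state-space path to the input profile:
arc-length-reparameterized paths for step versus long-pulse inputs deviate
by under 3% of the path diameter while timing shifts freely.

## Numerical contract

Stiff integration uses `deSolve::lsoda` with relative tolerance 1e-8 and
absolute tolerance 1e-10; the output grid resolves the horizon to at least
1/200 (default 1/400), and integration restarts at input discontinuities so
pulse edges are never stepped over. The default horizon of 60 h is chosen
so the plateau-convergence criterion is met in the reference run (about
30x the wild-type peak time). Equilibrium residual tolerances are 1e-10,
fold refinement converges the extended system to similar residuals, and the
oscillation onset of the MPF-APC module is bracketed by Newton tracking of
the low node to 1e-7 in the drive. Monte Carlo sizes (100 trials per CV
level) and the sensitivity perturbation (10%) balance resolution against
runtime; all stochastic results are reproducible from their seeds.

## Known limitations

* **The saddle-node at the oscillator onset is marginally off the invariant
  circle.** The isolated MPF-APC module is excitable below onset and its
  oscillation appears exactly where the low-MPF node folds, but the period
  above onset grows only to about 50 h rather than diverging as
  $\varepsilon^{-1/2}$: the limit cycle exists by virtue of the APC
  relaxation lag, and that same lag keeps the cycle a small but finite
  distance from the saddle-node ghost. Parameter exploration indicates a
  structural trade-off in this module: making APC fast enough to put the
  saddle-node on the cycle stabilizes a pinned intermediate state and
  kills the oscillation. The package reports the measured log-log period
  slope honestly (about -0.2 over the last resolvable decade).
* The wild-type plateau exceeds the first peak by a factor of about two;
  experimentally the MII plateau is closer to the first-peak height. All
  classifier comparisons are relative to the wild-type reference, so this
  scale choice does not affect phenotype calls.
* Only qualitative state-space invariance is checked for the slow-manifold
  canalization; no quantitative slow-manifold geometry is computed.
* Excluded biology (deliberately, following the model's scope): PKA and
  Ringo signalling, PP2A dynamics, direct ERK/Rsk regulation of Cdc25 and
  Myt1, a third CPEB-driven translation wave, spatial and morphological
  events, stochastic kinetics, and any fitting to quantitative time-course
  data.
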