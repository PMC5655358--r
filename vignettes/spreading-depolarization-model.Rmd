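---
title: "A neuron-glia-ECS model of spreading depolarization with glutamate homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neuron-glia-ECS model of spreading depolarization with glutamate homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sdglu)
```

# The model

Spreading depolarization (SD) is a near-complete breakdown of
transmembrane ion gradients: the neuron depolarizes to around -10 mV and
stays there for a minute or more, extracellular K+ rises from 4 mM to
tens of mM, Na+ and Cl- invade the cell, both neuron and astrocyte swell
and the extracellular space (ECS) shrinks dramatically.  `sdglu`
implements a single-unit (one neuron, one glial compartment, shared ECS,
external bath) biophysical model of this event with a full glutamate
subsystem, so that the role of transmitter clearance in the duration and
termination of SD can be studied.

## Ion dynamics backbone

The membrane carries Hodgkin-Huxley Na+ (m^3 h, with m instantaneous)
and K+ (n^4) channels, ohmic leaks for Na+, K+ and Cl-, and an
electrogenic 3Na+/2K+ pump whose current is a product of sigmoids in
intracellular Na+ (half-activation 25.5 mM, slope 3 mM) and
extracellular K+ (half 5.5 mM, slope 1 mM), scaled by the maximal
density `rho_p` (default 5.25 uA/cm^2).  Every transmembrane current
moves the corresponding ion amount between neuron and ECS
(1 uA/cm^2 over the 6e-4 cm^2 membrane moves about 6.2e-3 fmol/ms), so
ion concentrations are dynamical variables and the Nernst potentials
move with them.

Two slow processes remove K+ from the neuron-ECS system and are the
backbone of SD recovery:

* **glial buffering** — the buffer content relaxes (rate `lambda_glia`,
  default 1e-5/ms) toward a sigmoidal equilibrium curve in extracellular
  K+ (half 18 mM, slope 2.5 mM, capacity 350 fmol).  Uptake is
  electroneutral KCl co-movement, which is what makes glia swell
  osmotically during SD;
* **bath exchange** — K+ and Cl- each couple diffusively (rate
  `lambda_bath`, default 3.5e-5/ms) toward the bath composition.  The
  bath stands for the perfusion solution of a slice experiment: an
  infinite reservoir whose K+ concentration is the main experimental
  control.

Osmotic water movement makes each cell volume relax (time constant
250 ms) toward osmotic balance with the ECS; impermeant intracellular
anions are fixed at initialization.  The ECS volume is the complement of
the two cell volumes in a closed tissue box, so total volume is
conserved identically.

**Resting-state calibration.**  Rather than listing leak conductances as
free constants, `sd_model()` derives them: intracellular Cl- sits at its
Nernst equilibrium, the Na+ and K+ leaks are solved from the requirement
that gated + leak + pump fluxes cancel per ion at the resting potential
(-68 mV), and impermeant anion amounts enforce per-compartment
electroneutrality.  Because the resting cation sums of all three
compartments are chosen equal, electroneutral rest is automatically
isotonic.  The resting state is therefore an exact fixed point (residual
at machine precision), which the test suite asserts.

## Glutamate subsystem

Four pools track the transmitter: the releasable pool in the presynaptic
terminals (`N_i`, per synapse), the synaptic cleft/glial envelope pool
(`N_c`, per synapse), the ECS pool (`N_e`, total) and the buffered,
not-yet-recycled pool (`N_up`, total).  The model unit owns 10,000
synapses; since each synapse is shared between two neurons, only half of
the cleft efflux, uptake and recycling is attributed to this unit, and
with the recycling return divided among the synapses the weighted total
`(N_syn/2)(N_i + N_c) + N_e + N_up` is conserved exactly (an option
reproduces the non-conservative textbook bookkeeping in which every
synapse receives the whole recycled amount).

* **Release** is continuous rather than quantal: beyond a critical
  potential the rate grows quadratically with depolarization and
  linearly with the pool filling.  `R_max` is not free: it is fixed so
  that the release integrated over one simulated action potential equals
  the experimental quantum of ~3,000 molecules per synapse
  (`calibrate_release()`).
* **Receptors** (NMDA/AMPA) follow first-order kinetics driven by the
  cleft concentration, with the printed magnesium-block factor
  `1/(1 + 0.33 Mg exp(-0.07 V - 0.7))` on NMDA.  The maximal conductance
  densities, 0.139 and 0.486 mS/cm^2, come from per-event conductances
  of 1e-7 and 3.5e-7 mS scaled to all 5,000 postsynaptic synapses active
  simultaneously.
* **Diffusion** out of the cleft runs through 5% of the outer synapse
  surface over a cutoff distance `dx` (default 3 um) with
  `D_G = 0.3 um^2/ms`.
* **Uptake** is Michaelis-Menten (half-saturation 0.02 mM) through four
  pathways.  Only the base cleft-to-neuron velocity (0.03 mM/ms) is a
  parameter; glial cleft uptake is four times larger (eight-fold
  transporter density on half the contact area) and the ECS pathways
  carry fixed coefficients 0.12 and 0.24 rescaled by the instantaneous
  ECS shrinkage.  Neuronal uptake carries 3 Na+ into the cell per
  glutamate (cotransport current).

## Morphology and calibrated constants

The synapse radius is chosen so that one release quantum raises the
envelope concentration by 1.3 mM (envelope volume 3.83e-3 um^3,
r = 0.1008 um at cleft height h = 0.02 um).  The resting volumes are
neuron and glia 22,500 um^3 each and ECS 7,500 um^3 (an ECS fraction of
~14%, realistic for cortex); the membrane area of 6e-4 cm^2 is the value
consistent with the 0.12/0.24 ECS-uptake coefficients at this geometry.
The releasable pool of 0.015 fmol/synapse (~9e6 molecules) is sized so
that, with clearance fully blocked, cleft and ECS equilibrate in the
multi-mM range as observed during oxygen-glucose deprivation.  Vesicle
recycling has a 50 s time constant.  The slow-side rates
(`lambda_bath`, `lambda_glia`, capacity) were calibrated once against
the published simulation timing of the high-K+ perfusion experiment —
depolarization near 70 s, a ~70 s depolarized phase, repolarization near
140 s — and then frozen.

# Protocols

* `perfusion_protocol(K_high = 15)` — bath K+ steps from 4 to 15 mM and
  stays elevated; all regulatory functions stay active.
* `ogd_protocol()` — pump, glial buffering, bath exchange and glutamate
  uptake all ramp to zero over 15 s, stay off for 40 s and ramp back
  over 15 s (linear by default, cosine optionally); bath K+ stays at
  4 mM.
* `impaired_uptake(protocol, fraction)` — multiplies the base maximal
  uptake velocity; all four pathway velocities follow through the fixed
  ratios.

# What the simulations show

```{r}
mod <- sd_model()
traj <- simulate(mod, protocol = perfusion_protocol(15), t_end = 250000)
summary(traj)
plot(traj, "V")
```

Under perfusion the cell drifts slowly as K+ loads, fires a short burst
of action potentials at ~62 s, and enters depolarization block near
-10 mV.  The depolarized phase lasts ~71 s and ends in an abrupt
repolarization with a transient hyperpolarization overshoot; the ECS
shrinks by ~80% at the peak of the event.  Cleft glutamate spikes to the
mM range during the burst, is cleared within seconds to a 10-20 uM
plateau maintained while the neuron is depolarized, and ECS glutamate
stays near zero — clearance outruns diffusion.  Under OGD the neuron
depolarizes without a single preceding action potential, the cleft and
ECS concentrations equalize at several mM during the zero-clearance
window (diffusion is the only transport left), and glial swelling is
blocked until the regulatory functions reactivate.

The uptake scan (`scan_uptake()`) shows SD duration independent of the
transporter rate from 100% down to ~10% of normal, and recovery failure
below ~8%: with that little clearance the cleft concentration never
falls below the critical level and the neuron stays depolarized for the
rest of the run.

# Slow-fast analysis

The two slow variables are the glial and bath K+ exports; their sum
`dNK` is the slow variable of a quasi-steady-state reduction.  Freezing
them (and treating cleft glutamate as a parameter) defines the fast
"transmembrane" subsystem.  Because the membrane potential and the
neuron's net ionic charge are exactly redundant (1 fmol of net charge
moves V by ~160 mV), root finding and continuation work on a 9-variable
reduction with V derived from the amounts; on the full 10-variable set
the Jacobian is structurally singular.

`continue_branch()` follows fixed points in `dNK` by pseudo-arclength
continuation with secant predictors, bordered Newton correctors and
central-difference Jacobians on scaled variables; markers are placed
where the leading eigenvalue crosses the imaginary axis (bisection
refined) and classified Hopf/fold by its imaginary part.  The
depolarized branch ends in a Hopf bifurcation near `dNK = 610` fmol; the
full trajectory depolarizes at the minimum of `dNK` and repolarizes at
its maximum (both within 1%), and the repolarization `dNK` (~706 fmol)
overshoots the static Hopf by ~14%.  That overshoot is a dynamic (slow
passage) effect: the slow variables here are only ~30x slower than the
slowest fast mode, so the trajectory travels past the static bifurcation
before the instability has time to grow.  This is the one place where
the package's behavior deviates quantitatively from the published
slow-fast picture, where the separation is treated as asymptotic.

Scanning the cleft glutamate clamp shows the mechanism by which
transmitter blocks recovery: the polarized branch begins at larger `dNK`
as `G_c` grows (the receptor conductance denies a strongly polarized
state), while the depolarized branch end barely moves.  The two stable
branches stop overlapping at a critical `G_c` of ~0.011 mM.  A second,
independent determination — tracking the pump-driven hyperpolarized
fixed point of the membrane-only model (ion concentrations as
parameters) until it disappears — gives ~0.0125 mM, consistent within
~12%.  At the hyperpolarized state the gated conductances have
collapsed, and the leak-and-pump-only current balance holds to a
fraction of a percent; the pump current forces the potential below the
K+ Nernst potential, and that reserve of polarization is what the
glutamate-gated conductance destroys.

# Numerical choices

* Stiff integration by `lsoda` on a compiled right-hand side; the pure-R
  reference implementation is retained and the suite asserts exact
  agreement between the two on random states.  Default tolerances
  rtol = atol = 1e-10.
* The maximal internal step is fixed (100 ms) so that results do not
  depend on the output sampling grid; `lsoda` otherwise caps its step at
  the output interval, which near the critical uptake fraction was
  enough to flip a run between recovery and failure.
* Event detection: depolarization onset is the first crossing of -30 mV
  sustained for 5 s; repolarization is the first later downward crossing
  to within 2 mV of the pre-onset baseline (a crossing, not a
  band-dwell, because the repolarization drop traverses the band in
  milliseconds).  All three thresholds are arguments.
* Volume collapse (ECS below 5% of its resting value) aborts with a
  diagnostic.  Concentrations are floored at 1e-9 mM inside the compiled
  right-hand side before logarithms; the floor is unreachable from valid
  states and only guards solver trial steps and root-finder excursions.
* Continuation uses scaled variables (amount scale 10 fmol — through the
  charge relation a 1 fmol net change is ~160 mV), Newton residual
  tolerance 1e-11, adaptive arclength steps with halving on failure.

# Design decisions and limitations

* **Conservative recycling.**  The per-synapse bookkeeping of the
  four-pool model conserves total glutamate only if the recycled amount
  is divided among the synapses; the package does so by default and
  offers `literal_recycling = TRUE` for the non-conservative variant.
* **Release above `V_hi`.**  The quadratic release factor is evaluated
  literally (unbounded) by default; `clamp_release = TRUE` caps it at 1.
* **Release threshold.**  `V_cr = -50 mV` keeps release active over the
  whole depolarized branch (including its late, declining phase), which
  is required for transmitter to participate in the repolarization
  decision; the threshold still sits well above rest so there is no
  spontaneous release.
* **Bath chloride.**  Strict Cl- co-export with K+ would drain the ECS
  of chloride during a long SD; the bath therefore exchanges K+ and Cl-
  independently, each toward the perfusion-solution composition.
* **All-or-none uptake effect.**  In this parameterization the
  transporter scan shows a sharp transition: durations stay at the
  normal ~71 s down to ~10% uptake and recovery fails below ~8%, rather
  than lengthening gradually below 35% as reported for the published
  parameter set (whose supplementary constants are not available and
  were re-derived here by calibration).  Prolonged-but-recovering events
  (4-5x the normal duration) exist only in a razor-thin band of uptake
  fractions near the threshold.  The qualitative chain — impaired
  clearance, elevated cleft glutamate, loss of the polarized state,
  recovery failure — is reproduced, and the critical glutamate level
  falls in the published band; the graded delay is not.
* The OGD transition carries a sub-second flurry of a few spikes in some
  parameter settings; with the packaged defaults there are no action
  potentials before the depolarization onset, matching the experimental
  definition of SD onset.
* Out of scope, as in the published model family: Ca2+ entry through
  NMDA receptors, AMPA desensitization, transporter reversal under high
  K+, extrasynaptic receptors, ATP-dependent glutamate-glutamine
  cycling, and any spatial propagation.  Limit cycles are observed only
  by direct simulation; periodic-orbit continuation is not implemented.

# What the tests do and do not show

The synthetic fixtures (trapezoid voltage traces, the two-dimensional
Hopf normal form, randomized valid states) exercise event detection,
bifurcation-marker location and the conservation laws against
constructed ground truth.  The acceptance suite re-runs the perfusion,
OGD and uptake-scan experiments at the problem sizes stated above
(250 s, 150 s, and 15 runs of 900 s) and the slow-fast analysis at
trajectory-matched clamps.  All of this validates the implementation
against its own stated model and against analytic values — it does not
validate the model against tissue: the unit is a local average (no
propagation), the bath is ideal, and release, recycling and buffering
are deliberately minimal phenomenological descriptions.
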