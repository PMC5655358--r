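# sdglu

Biophysical single-unit model of **spreading depolarization (SD)** — the
near-complete, minutes-long breakdown of neuronal transmembrane ion
gradients that underlies migraine aura and spreads through injured
cortex in stroke and trauma — with a full **glutamate homeostasis**
subsystem.  The package is for computational neuroscientists who want to
study how transmitter clearance shapes the duration and termination of
SD, and for anyone who needs a compact, conservation-exact
neuron–glia–ECS ion model with osmotic volume dynamics.

## The model

One neuron, one glial compartment, a shared extracellular space (ECS)
and an external bath.  The state couples:

* Hodgkin–Huxley membrane dynamics
  `C dV/dt = -(I_Na + I_K + I_Cl)` with gated `g_Na m^3 h`,
  `g_K n^4`, ohmic leaks, and a 3Na/2K pump
  `I_p = rho_p / ((1 + exp((25.5 - [Na]_i)/3)) (1 + exp(5.5 - [K]_e)))`;
* dynamic ion amounts in neuron, ECS and glia — every current moves the
  matching ion, so Nernst potentials are state-dependent;
* two slow K⁺ sinks (glial buffering toward a sigmoidal equilibrium in
  `[K]_e`; diffusive exchange with the bath), whose combined export
  `ΔN^K` is the slow variable of the model's slow–fast structure;
* osmotic volume dynamics for both cells, with the ECS as the complement
  of a closed tissue box;
* a four-pool glutamate cycle over 10,000 synapses: voltage-dependent
  continuous release `J_rel = R_max ((V - V_cr)/(V_hi - V_cr))^2 N_i/N_max`
  (calibrated so one action potential releases ~3,000 molecules),
  NMDA/AMPA receptor gating driven by the cleft concentration (with the
  magnesium block on NMDA), cleft↔ECS diffusion, Michaelis–Menten uptake
  `v = v_max G/(G + k_m)` through four pathways (cleft/ECS ×
  neuron/glia, with fixed ratios `v_cg = 4 v_cn`, `v_en = 0.12 v_cn`,
  `v_eg = 0.24 v_cg`), and vesicle recycling that conserves total
  glutamate exactly.

A slow–fast toolkit finds fixed points of the clamped "transmembrane"
subsystem by damped Newton iteration, follows them in `ΔN^K` by
pseudo-arclength continuation with Hopf/fold detection, and locates the
critical cleft-glutamate level beyond which the polarized state — and
with it any recovery from SD — disappears.

## Worked example

```r
library(sdglu)

mod <- sd_model()
mod
#> Spreading-depolarization model (neuron + glia + ECS + bath)
#>   resting V = -68 mV; leak conductances (derived): g_Na_l = 0.01129, g_K_l = 0.03531 mS/cm^2
#>   26 state variables; glutamate pools over 10000 synapses

## high-K+ perfusion: bath K+ steps 4 -> 15 mM at t = 0
traj <- simulate(mod, protocol = perfusion_protocol(K_high = 15),
                 t_end = 250000, dt = 100)
summary(traj)
#> SD simulation summary (perfusion protocol)
#>   depolarization at 62.2 s, repolarization at 133.4 s (duration 71.2 s)
#>   conservation drift (relative): ions 2.07e-13, glutamate 3.16e-14, volume 0.00e+00
plot(traj, "V")          # burst of spikes -> depolarization block ->
                         # abrupt repolarization with overshoot

## transporter impairment: SD duration vs maximal uptake velocity
scan_uptake(c(1, 0.5, 0.2, 0.1, 0.08), mod, t_end = 900000)[,
            c("fraction", "duration", "recovered")]
#>   fraction duration recovered
#> 1     1.00    71200      TRUE
#> 2     0.50    70500      TRUE
#> 3     0.20    71000      TRUE
#> 4     0.10    72700      TRUE
#> 5     0.08       NA     FALSE
```

The perfusion run shows the canonical SD sequence: slow K⁺ loading, a
short spike burst at 62 s, a ~71 s depolarized plateau near −10 mV with
~80% ECS shrinkage, then an abrupt repolarization with a transient
hyperpolarization overshoot.  Cleft glutamate spikes into the mM range
during the burst and is cleared to a 10–20 µM plateau; with transporters
below ~8% of normal capacity the cleft level never falls below the
critical value (~0.011 mM, see the vignette) and the neuron never
recovers — the model's expression of glutamate-mediated recovery
failure.

A thin command-line front end is installed at `inst/cli/sdglu`
(`simulate`, `scan-uptake`, `bifurcation`, `fixtures`,
`validate-config`); configuration files use a flat key–value format with
units in the key names (`load_config()`, packaged defaults in
`inst/extdata/defaults.cfg`).

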