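# Reference configuration of the spreading-depolarization model.
# Units are embedded in the key names.  Receptor kinetics follow the
# first-order fits of Destexhe, Mainen & Sejnowski; the maximal release
# rate is the calibrate_release() result (one action potential releases
# ~3,000 glutamate molecules per synapse).

[morphology]
r_um = 0.100825
h_um = 0.02
A_m_n_cm2 = 6e-4
A_m_g_cm2 = 6e-4
N_syn = 10000
N_syn_AP = 20
omega_n0_um3 = 22500
omega_g0_um3 = 22500
omega_e0_um3 = 7500

[release]
R_max_fmol_per_ms = 9.643e-6
V_cr_mV = -50
V_hi_mV = 40
N_max_fmol = 0.015
k_rec_per_ms = 2e-5

[receptors]
g_NMDA_mS_per_cm2 = 0.1388889
g_AMPA_mS_per_cm2 = 0.4861111
alpha_NMDA_per_mM_ms = 0.072
beta_NMDA_per_ms = 0.0066
alpha_AMPA_per_mM_ms = 1.1
beta_AMPA_per_ms = 0.19
Mg_mM = 1.0

[uptake]
D_G_um2_per_ms = 0.3
dx_um = 3.0
v_cn_max_mM_per_ms = 0.03
k_m_mM = 0.02

[ion_dynamics]
rho_p_uA_per_cm2 = 5.25
lambda_glia_per_ms = 1e-5
B_glia_fmol = 350
glia_K_half_mM = 18
glia_K_slope_mM = 2.5
lambda_bath_per_ms = 3.5e-5
tau_osm_ms = 250

[protocol]
type = perfusion
K_high_mM = 15
t_on_ms = 0
ramp_ms = 15000
hold_ms = 40000
uptake_fraction = 1

[solver]
rtol = 1e-10
atol = 1e-10
dt_ms = 10
t_end_ms = 300000

[events]
depol_threshold_mV = -30
persistence_ms = 5000
repol_tol_mV = 2
baseline_window_ms = 5000
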