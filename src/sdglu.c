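/* Compiled right-hand side of the spreading-depolarization model.
 *
 * Mirrors the R reference implementation (full_rhs) exactly; the test
 * suite asserts agreement between the two on random states.  State layout
 * and parameter order are documented in R/simulate.R (sd_c_parms).
 *
 * Units: mV, ms, mM, um^3, fmol, uA/cm^2.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 56
static double parms[NPAR];

/* parameter accessors by index (kept in one place) */
#define C_m        parms[0]
#define g_Na       parms[1]
#define g_K        parms[2]
#define g_Cl_l     parms[3]
#define g_Na_l     parms[4]
#define g_K_l      parms[5]
#define phi_gate   parms[6]
#define rho_p      parms[7]
#define pNa_half   parms[8]
#define pNa_slope  parms[9]
#define pK_half    parms[10]
#define pK_slope   parms[11]
#define lam_glia   parms[12]
#define B_glia     parms[13]
#define gK_half    parms[14]
#define gK_slope   parms[15]
#define K_e_rest   parms[16]
#define lam_bath   parms[17]
#define L_n        parms[18]
#define L_g        parms[19]
#define A_n_amt    parms[20]
#define A_g_amt    parms[21]
#define A_e_amt    parms[22]
#define omega_tot  parms[23]
#define omega_e0   parms[24]
#define omega_en   parms[25]
#define diff_coef  parms[26]   /* A_sigma * D_G / dx  (um^3/ms) */
#define N_half     parms[27]   /* N_syn / 2 */
#define gamma_n    parms[28]   /* fmol/ms per uA/cm^2 */
#define R_max      parms[29]
#define V_cr       parms[30]
#define V_hi       parms[31]
#define N_max      parms[32]
#define k_rec      parms[33]
#define literal_rec parms[34]
#define clamp_rel  parms[35]
#define g_NMDA     parms[36]
#define g_AMPA     parms[37]
#define aN         parms[38]
#define bN         parms[39]
#define aA         parms[40]
#define bA         parms[41]
#define Mg_conc    parms[42]
#define v_cn_max   parms[43]
#define k_m        parms[44]
#define K_g_rest   parms[45]
#define phi_rtf    parms[46]
#define pr_code    parms[47]
#define pr_Kbase   parms[48]
#define pr_Khigh   parms[49]
#define pr_ton     parms[50]
#define pr_ramp    parms[51]
#define pr_hold    parms[52]
#define pr_shape   parms[53]
#define pr_upfrac  parms[54]
#define Cl_bath0   parms[55]

void sd_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

static double ogd_scale_c(double t)
{
    double t1 = pr_ton, t2 = pr_ton + pr_ramp;
    double t3 = t2 + pr_hold, t4 = t3 + pr_ramp;
    double s;
    if (t < t1) s = 1.0;
    else if (t < t2) s = (t2 - t) / pr_ramp;
    else if (t < t3) s = 0.0;
    else if (t < t4) s = (t - t3) / pr_ramp;
    else s = 1.0;
    if (pr_shape > 0.5) s = (1.0 - cos(M_PI * s)) / 2.0;
    return s;
}

void sd_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double V = y[0], n = y[1], h = y[2], rA = y[3], rN = y[4];
    double Na_n_a = y[5], K_n_a = y[6], Cl_n_a = y[7];
    double Na_e_a = y[8], K_e_a = y[9], Cl_e_a = y[10];
    double Na_g_a = y[11], K_g_a = y[12], Cl_g_a = y[13];
    double dNK_bath = y[14], w_n = y[15], w_g = y[16];
    double Ni = y[17], Nc = y[18], Ne = y[19], Nup = y[20];
    /* y[21..24]: cumulative uptake; y[25]: cumulative bath Cl- export */

    double w_e = omega_tot - w_n - w_g;
    if (w_e < 1e-6) w_e = 1e-6;   /* guarded; collapse flagged in R */

    /* concentrations (mM) */
    /* guarded against transiently non-positive amounts during solver
     * trial steps / root-finding excursions (floor far below any
     * physiological value) */
    #define CONC_FLOOR 1e-9
    double Na_n = 1000.0 * Na_n_a / w_n, K_n = 1000.0 * K_n_a / w_n;
    double Cl_n = 1000.0 * Cl_n_a / w_n;
    double Na_e = 1000.0 * Na_e_a / w_e, K_e = 1000.0 * K_e_a / w_e;
    double Cl_e = 1000.0 * Cl_e_a / w_e;
    double Na_g = 1000.0 * Na_g_a / w_g, K_g = 1000.0 * K_g_a / w_g;
    double Cl_g = 1000.0 * Cl_g_a / w_g;
    if (Na_n < CONC_FLOOR) Na_n = CONC_FLOOR;
    if (K_n < CONC_FLOOR) K_n = CONC_FLOOR;
    if (Cl_n < CONC_FLOOR) Cl_n = CONC_FLOOR;
    if (Na_e < CONC_FLOOR) Na_e = CONC_FLOOR;
    if (K_e < CONC_FLOOR) K_e = CONC_FLOOR;
    if (Cl_e < CONC_FLOOR) Cl_e = CONC_FLOOR;
    if (Na_g < CONC_FLOOR) Na_g = CONC_FLOOR;
    if (K_g < CONC_FLOOR) K_g = CONC_FLOOR;
    if (Cl_g < CONC_FLOOR) Cl_g = CONC_FLOOR;

    double E_Na = phi_rtf * log(Na_e / Na_n);
    double E_K = phi_rtf * log(K_e / K_n);
    double E_Cl = -phi_rtf * log(Cl_e / Cl_n);

    /* protocol */
    double K_bath, pump_sc, glia_sc, upt_sc;
    if (pr_code < 1.5) {                    /* perfusion */
        K_bath = (*t < pr_ton) ? pr_Kbase : pr_Khigh;
        pump_sc = glia_sc = upt_sc = 1.0;
    } else {                                /* OGD */
        K_bath = pr_Kbase;
        pump_sc = glia_sc = upt_sc = ogd_scale_c(*t);
    }

    /* glutamate */
    double G_c = 1000.0 * Nc / omega_en; if (G_c < 0) G_c = 0;
    double G_e = 1000.0 * Ne / w_e; if (G_e < 0) G_e = 0;
    double v_base = upt_sc * pr_upfrac * v_cn_max;
    double v_cn = v_base * G_c / (G_c + k_m);
    double v_cg = 4.0 * v_base * G_c / (G_c + k_m);
    double v_en = 0.12 * v_base * (omega_e0 / w_e) * G_e / (G_e + k_m);
    double v_eg = 0.24 * 4.0 * v_base * (omega_e0 / w_e) * G_e / (G_e + k_m);

    double q = (V - V_cr) / (V_hi - V_cr);
    if (q < 0) q = 0;
    q = q * q;
    if (clamp_rel > 0.5 && q > 1.0) q = 1.0;
    double Ni_pos = (Ni > 0) ? Ni : 0;
    double J_rel = R_max * q * (Ni_pos / N_max);
    double J_diff = -diff_coef * (G_c - G_e) / 1000.0;

    double up_cn = N_half * omega_en * v_cn / 1000.0;
    double up_cg = N_half * omega_en * v_cg / 1000.0;
    double up_en = w_e * v_en / 1000.0;
    double up_eg = w_e * v_eg / 1000.0;

    double rec_per_syn = (literal_rec > 0.5)
        ? k_rec * Nup : (1.0 / N_half) * k_rec * Nup;

    /* membrane currents */
    double am, bm, an_r, bn_r, ah, bh, x;
    x = V + 30.0;
    am = (fabs(x) < 1e-7) ? 1.0 : 0.1 * x / (1.0 - exp(-0.1 * x));
    bm = 4.0 * exp(-(V + 55.0) / 18.0);
    x = V + 34.0;
    an_r = (fabs(x) < 1e-7) ? 0.1 : 0.01 * x / (1.0 - exp(-0.1 * x));
    bn_r = 0.125 * exp(-(V + 44.0) / 80.0);
    ah = 0.07 * exp(-(V + 44.0) / 20.0);
    bh = 1.0 / (1.0 + exp(-0.1 * (V + 14.0)));
    double m_inf = am / (am + bm);

    double I_p = pump_sc * rho_p /
        ((1.0 + exp((pNa_half - Na_n) / pNa_slope)) *
         (1.0 + exp((pK_half - K_e) / pK_slope)));

    double blk = 1.0 / (1.0 + 0.33 * Mg_conc * exp(-0.07 * V - 0.7));
    double I_Na_AMPA = g_AMPA * rA * (V - E_Na);
    double I_K_AMPA = g_AMPA * rA * (V - E_K);
    double I_Na_NMDA = g_NMDA * rN * blk * (V - E_Na);
    double I_K_NMDA = g_NMDA * rN * blk * (V - E_K);

    double U_n = up_cn + up_en;            /* neuronal glutamate uptake */
    double I_co = -3.0 * U_n / gamma_n;    /* 3 Na+ per glutamate, inward */

    double I_Na = g_Na * m_inf * m_inf * m_inf * h * (V - E_Na)
        + g_Na_l * (V - E_Na) + 3.0 * I_p + I_Na_AMPA + I_Na_NMDA + I_co;
    double I_K = g_K * n * n * n * n * (V - E_K)
        + g_K_l * (V - E_K) - 2.0 * I_p + I_K_AMPA + I_K_NMDA;
    double I_Cl = g_Cl_l * (V - E_Cl);

    /* glia / bath K+ handling (KCl co-movement) */
    double dNK_glia = K_g_a - K_g_rest;
    double Sg = 1.0 / (1.0 + exp((gK_half - K_e) / gK_slope));
    double Sg0 = 1.0 / (1.0 + exp((gK_half - K_e_rest) / gK_slope));
    double eq = B_glia * (Sg - Sg0);
    double J_glia = glia_sc * lam_glia * (eq - dNK_glia);
    double J_bath = glia_sc * lam_bath * omega_e0 * (K_bath - K_e) / 1000.0;
    double J_bath_Cl = glia_sc * lam_bath * omega_e0 * (Cl_bath0 - Cl_e) / 1000.0;

    /* osmolarities (impermeant anion amounts fixed) */
    double osm_n = Na_n + K_n + Cl_n + 1000.0 * A_n_amt / w_n;
    double osm_g = Na_g + K_g + Cl_g + 1000.0 * A_g_amt / w_g;
    double osm_e = Na_e + K_e + Cl_e + 1000.0 * A_e_amt / w_e;

    double dNa_n = -gamma_n * I_Na;
    double dK_n = -gamma_n * I_K;
    double dCl_n = gamma_n * I_Cl;

    ydot[0] = -(I_Na + I_K + I_Cl) / C_m;
    ydot[1] = phi_gate * (an_r * (1.0 - n) - bn_r * n);
    ydot[2] = phi_gate * (ah * (1.0 - h) - bh * h);
    ydot[3] = G_c * aA * (1.0 - rA) - bA * rA;
    ydot[4] = G_c * aN * (1.0 - rN) - bN * rN;
    ydot[5] = dNa_n;
    ydot[6] = dK_n;
    ydot[7] = dCl_n;
    ydot[8] = -dNa_n;
    ydot[9] = -dK_n - J_glia + J_bath;
    ydot[10] = -dCl_n - J_glia + J_bath_Cl;
    ydot[11] = 0.0;
    ydot[12] = J_glia;
    ydot[13] = J_glia;
    ydot[14] = -J_bath;
    ydot[15] = L_n * (osm_n - osm_e);
    ydot[16] = L_g * (osm_g - osm_e);
    ydot[17] = -J_rel + rec_per_syn;
    ydot[18] = J_rel + J_diff - omega_en * (v_cn + v_cg) / 1000.0;
    ydot[19] = -N_half * J_diff - (up_en + up_eg);
    ydot[20] = up_cn + up_cg + up_en + up_eg - k_rec * Nup;
    ydot[21] = up_cn;
    ydot[22] = up_cg;
    ydot[23] = up_en;
    ydot[24] = up_eg;
    ydot[25] = -J_bath_Cl;

    if (ip[0] >= 8) {
        yout[0] = G_c;
        yout[1] = G_e;
        yout[2] = E_Na;
        yout[3] = E_K;
        yout[4] = E_Cl;
        yout[5] = I_p;
        yout[6] = w_e;
        yout[7] = dNK_glia + dNK_bath;
    }
}

/* one-shot RHS evaluation for root finding / continuation: returns
 * c(ydot[25], yout[8]) given (t, y, parms) without solver overhead */
SEXP sd_rhs_eval(SEXP t_s, SEXP y_s, SEXP p_s)
{
    if (LENGTH(p_s) != NPAR) error("parameter vector must have %d entries", NPAR);
    if (LENGTH(y_s) != 26) error("state vector must have 26 entries");
    double t = REAL(t_s)[0];
    for (int i = 0; i < NPAR; i++) parms[i] = REAL(p_s)[i];
    SEXP out = PROTECT(allocVector(REALSXP, 34));
    double yout[8];
    int neq = 26, ip[1] = {8};
    sd_derivs(&neq, &t, REAL(y_s), REAL(out), yout, ip);
    for (int i = 0; i < 8; i++) REAL(out)[26 + i] = yout[i];
    UNPROTECT(1);
    return out;
}

static const R_CMethodDef CEntries[] = {
    {"sd_initmod", (DL_FUNC) &sd_initmod, 1},
    {"sd_derivs",  (DL_FUNC) &sd_derivs,  6},
    {NULL, NULL, 0}
};

static const R_CallMethodDef CallEntries[] = {
    {"sd_rhs_eval", (DL_FUNC) &sd_rhs_eval, 3},
    {NULL, NULL, 0}
};

void R_init_sdglu(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
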