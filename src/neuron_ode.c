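/* Membrane ODE right-hand sides for the Wang-Buzsaki (WB) interneuron and the
 * single-compartment excitatory accommodating neuron (SEAN, reduced from the
 * Pinsky-Rinzel soma), in the compiled-function form expected by deSolve.
 *
 * State y = (V_m, n, h).  Gating variable m is instantaneous (m = m_inf(V)).
 * Units: mV, ms, uA/cm2, mS/cm2, uF/cm2, mM.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 18
static double parms[N_PARMS];
/* parameter slots */
#define P_KIND   parms[0]   /* 1 = WB, 2 = SEAN */
#define P_CM     parms[1]
#define P_GNA    parms[2]
#define P_GK     parms[3]
#define P_GL     parms[4]
#define P_NUNA   parms[5]
#define P_NUL    parms[6]
#define P_NUK    parms[7]   /* actual Nernst potential (nominal + shift) */
#define P_PSI    parms[8]   /* gating rate scale (WB); 1 for SEAN */
#define P_RHO    parms[9]
#define P_KHATO  parms[10]  /* nominal extracellular K */
#define P_KO     parms[11]  /* actual extracellular K */
#define P_GAHP   parms[12]
#define P_QHAT   parms[13]
#define P_IINJ   parms[14]
#define P_IEXTRA parms[15]  /* additive current hook (e.g. slow K-AHP) */
#define P_EXPM   parms[16]  /* exponent on m_inf in I_Na */
#define P_EXPN   parms[17]  /* exponent on n in I_K */

void mnm_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* a*x/(1 - exp(-x/b)) with the removable singularity at x = 0 */
static double xexp_ratio(double a, double x, double b)
{
    if (fabs(x) < 1e-7) return a * b;
    return a * x / (1.0 - exp(-x / b));
}

/* a*x/(exp(x/b) - 1) with the removable singularity at x = 0 */
static double xexp_ratio_rev(double a, double x, double b)
{
    if (fabs(x) < 1e-7) return a * b;
    return a * x / (exp(x / b) - 1.0);
}

static void rates_wb(double V, double *r)
{
    r[0] = xexp_ratio(0.1, V + 35.0, 10.0);        /* alpha_m */
    r[1] = 4.0 * exp(-(V + 60.0) / 18.0);          /* beta_m  */
    r[2] = xexp_ratio(0.01, V + 34.0, 10.0);       /* alpha_n */
    r[3] = 0.125 * exp(-(V + 44.0) / 80.0);        /* beta_n  */
    r[4] = 0.07 * exp(-(V + 58.0) / 20.0);         /* alpha_h */
    r[5] = 1.0 / (1.0 + exp(-(V + 28.0) / 10.0));  /* beta_h  */
}

static void rates_sean(double V, double *r)
{
    r[0] = xexp_ratio(0.32, V + 46.9, 4.0);        /* alpha_m */
    r[1] = xexp_ratio_rev(0.28, V + 19.9, 5.0);    /* beta_m  */
    r[2] = xexp_ratio(0.016, V + 24.9, 5.0);       /* alpha_n */
    r[3] = 0.25 * exp(-(V + 40.0) / 40.0);         /* beta_n  */
    r[4] = 0.128 * exp(-(V + 43.0) / 18.0);        /* alpha_h */
    r[5] = 4.0 / (1.0 + exp(-(V + 20.0) / 5.0));   /* beta_h  */
}

static double pump_current(void)
{
    /* intracellular Na held at nominal: that logistic factor is exactly 2 */
    return P_RHO / (2.0 * (1.0 + exp(P_KHATO - P_KO)));
}

void mnm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double r[6], V = y[0], n = y[1], h = y[2];
    double minf, GK, INa, IK, IL, Ip, Iahp, kflux;

    if (P_KIND < 1.5) rates_wb(V, r); else rates_sean(V, r);
    minf = r[0] / (r[0] + r[1]);

    GK   = P_GK * pow(n, P_EXPN);
    IK   = GK * (V - P_NUK);
    INa  = P_GNA * pow(minf, P_EXPM) * h * (V - P_NUNA);
    IL   = P_GL * (V - P_NUL);
    Ip   = pump_current();
    Iahp = P_GAHP * P_QHAT * (V - P_NUK);

    ydot[0] = (P_IINJ + P_IEXTRA - IK - INa - IL - Ip - Iahp) / P_CM;
    ydot[1] = P_PSI * (r[2] * (1.0 - n) - r[3] * n);
    ydot[2] = P_PSI * (r[4] * (1.0 - h) - r[5] * h);

    if (ip[0] >= 1) {
        /* net transmembrane K current: channel + accommodation - 2*pump
         * (the pump imports 2 K+ per cycle) */
        kflux = IK + Iahp - 2.0 * Ip;
        yout[0] = kflux;
    }
}
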