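/* Fixed-step RK4 integrator for the two-mass excitatory-inhibitory rate
 * network.  The mass transfer functions are algebraic (thresholds and maximal
 * firing rate are constants for a fixed potassium shift), so the whole
 * right-hand side reduces to a handful of scalar operations per step.
 *
 * State y = (FR_E, FR_I, h_E, hdot_E, h_I, hdot_I).
 * The external drive I_E,inj(t) is piecewise linear over (tbreak, ibreak).
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

typedef struct {
    double th1E, th2E, M1E, IpE;
    double th1I, th2I, M1I, IpI;
    double gEI, gIE, lamE, lamI, tauE, tauI, IIinj;
} net_par;

static double interp_drive(const double *tb, const double *ib, int nb, double t)
{
    int lo, hi, mid;
    double w;
    if (t <= tb[0]) return ib[0];
    if (t >= tb[nb - 1]) return ib[nb - 1];
    lo = 0; hi = nb - 1;
    while (hi - lo > 1) {
        mid = (lo + hi) / 2;
        if (tb[mid] <= t) lo = mid; else hi = mid;
    }
    w = (t - tb[lo]) / (tb[hi] - tb[lo]);
    return ib[lo] + w * (ib[hi] - ib[lo]);
}

static double phi(double X, double th1, double th2, double M1)
{
    double Q = (X - th1) / (th2 - th1);
    if (Q < 0.0 || Q > 1.0) return 0.0;
    return M1 * sqrt(Q);
}

static void rhs(const net_par *p, double Idrive, const double *y, double *dy)
{
    double XE = Idrive + p->IpE - p->gIE * y[4];
    double XI = p->IIinj + p->IpI + p->gEI * y[2];
    double phiE = phi(XE, p->th1E, p->th2E, p->M1E);
    double phiI = phi(XI, p->th1I, p->th2I, p->M1I);
    dy[0] = (phiE - y[0]) / p->lamE;
    dy[1] = (phiI - y[1]) / p->lamI;
    dy[2] = y[3];
    dy[3] = (y[0] - y[2]) / (p->tauE * p->tauE) - 2.0 * y[3] / p->tauE;
    dy[4] = y[5];
    dy[5] = (y[1] - y[4]) / (p->tauI * p->tauI) - 2.0 * y[5] / p->tauI;
}

SEXP mnm_net_rk4(SEXP s_par, SEXP s_tbreak, SEXP s_ibreak,
                 SEXP s_dt, SEXP s_nstep, SEXP s_thin, SEXP s_y0)
{
    const double *pv = REAL(s_par);
    const double *tb = REAL(s_tbreak), *ib = REAL(s_ibreak);
    int nb = LENGTH(s_tbreak);
    double dt = REAL(s_dt)[0];
    R_xlen_t nstep = (R_xlen_t) REAL(s_nstep)[0];
    int thin = INTEGER(s_thin)[0];
    net_par p;
    double y[6], k1[6], k2[6], k3[6], k4[6], ytmp[6];
    double t = 0.0, Id, XE, XI;
    R_xlen_t i, row, nout;
    int j;
    SEXP ans;
    double *a;

    p.th1E = pv[0]; p.th2E = pv[1]; p.M1E = pv[2]; p.IpE = pv[3];
    p.th1I = pv[4]; p.th2I = pv[5]; p.M1I = pv[6]; p.IpI = pv[7];
    p.gEI = pv[8]; p.gIE = pv[9]; p.lamE = pv[10]; p.lamI = pv[11];
    p.tauE = pv[12]; p.tauI = pv[13]; p.IIinj = pv[14];

    for (j = 0; j < 6; j++) y[j] = REAL(s_y0)[j];

    nout = nstep / thin + 1;
    ans = PROTECT(allocMatrix(REALSXP, nout, 8));
    a = REAL(ans);

    row = 0;
    for (i = 0; i <= nstep; i++) {
        t = i * dt;
        Id = interp_drive(tb, ib, nb, t);
        if (i % thin == 0 && row < nout) {
            XE = Id + p.IpE - p.gIE * y[4];
            XI = p.IIinj + p.IpI + p.gEI * y[2];
            a[row] = t;
            a[nout + row] = Id;
            a[2 * nout + row] = y[0];
            a[3 * nout + row] = y[1];
            a[4 * nout + row] = y[2];
            a[5 * nout + row] = y[4];
            a[6 * nout + row] = (XE - p.th1E) / (p.th2E - p.th1E);
            a[7 * nout + row] = (XI - p.th1I) / (p.th2I - p.th1I);
            row++;
        }
        if (i == nstep) break;

        rhs(&p, Id, y, k1);
        for (j = 0; j < 6; j++) ytmp[j] = y[j] + 0.5 * dt * k1[j];
        Id = interp_drive(tb, ib, nb, t + 0.5 * dt);
        rhs(&p, Id, ytmp, k2);
        for (j = 0; j < 6; j++) ytmp[j] = y[j] + 0.5 * dt * k2[j];
        rhs(&p, Id, ytmp, k3);
        for (j = 0; j < 6; j++) ytmp[j] = y[j] + dt * k3[j];
        Id = interp_drive(tb, ib, nb, t + dt);
        rhs(&p, Id, ytmp, k4);
        for (j = 0; j < 6; j++)
            y[j] += dt * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]) / 6.0;
        if (!R_FINITE(y[0]) || !R_FINITE(y[1]))
            error("network state became non-finite at t = %.3f ms", t);
    }

    UNPROTECT(1);
    return ans;
}
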