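/* Compiled right-hand sides for the four-compartment host-symbiont
 * model and its one-host/one-symbiont reduction, in the deSolve
 * compiled-function convention, plus a fixed-step classical RK4
 * integrator used as an independent reference in tests.
 *
 * Full-model parameter vector (27 entries, canonical order):
 *   0 r_pn  1 r_pi
 *   2 alpha_nn 3 alpha_ni 4 alpha_in 5 alpha_ii
 *   6 beta_nn  7 beta_ni  8 beta_in  9 beta_ii
 *  10 q_hpn 11 q_cpn 12 q_hpi 13 q_cpi
 *  14 q_cmn 15 q_hmn 16 q_cmi 17 q_hmi
 *  18 c_p_in 19 c_p_ni 20 c_m_in 21 c_m_ni
 *  22 mu_pn 23 mu_mn 24 mu_pi 25 mu_mi
 *  26 d
 * plus entry 27 = convergence threshold for the root function.
 *
 * Reduced parameter vector: 0 r_p, 1 Q_p, 2 Q_m, 3 mu_p, 4 mu_m, 5 d,
 * plus entry 6 = convergence threshold.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define N_FULL_PARMS 28
#define N_RED_PARMS 7

static double parms_full[N_FULL_PARMS];
static double parms_red[N_RED_PARMS];

static void rhs_full(const double *pp, const double *y, double *ydot)
{
    const double pn = y[0], mn = y[1], pi = y[2], mi = y[3];
    const double d = pp[26];
    const double Da = (pn + pi) / d + mn + mi;
    const double Db = pn + pi + d * (mn + mi);

    double Fpn = 0.0, Fmn = 0.0, Fpi = 0.0, Fmi = 0.0;
    if (Da > 0.0) {
        Fpn += pp[10] * pn * (pp[2] * mn + pp[4] * mi) / Da;
        Fmn -= pp[15] * mn * (pp[2] * pn + pp[3] * pi) / Da;
        Fpi += pp[12] * pi * (pp[5] * mi + pp[3] * mn) / Da;
        Fmi -= pp[17] * mi * (pp[5] * pi + pp[4] * pn) / Da;
    }
    if (Db > 0.0) {
        Fpn -= pp[11] * pn * (pp[6] * mn + pp[7] * mi) / Db;
        Fmn += pp[14] * mn * (pp[6] * pn + pp[8] * pi) / Db;
        Fpi -= pp[13] * pi * (pp[9] * mi + pp[8] * mn) / Db;
        Fmi += pp[16] * mi * (pp[9] * pi + pp[7] * pn) / Db;
    }

    ydot[0] = pp[0] * pn + Fpn - pp[18] * pn * pi - pp[22] * pn * pn;
    ydot[1] = Fmn - pp[20] * mn * mi - pp[23] * mn * mn;
    ydot[2] = pp[1] * pi + Fpi - pp[19] * pn * pi - pp[24] * pi * pi;
    ydot[3] = Fmi - pp[21] * mn * mi - pp[25] * mi * mi;
}

static void rhs_reduced(const double *pp, const double *y, double *ydot)
{
    const double p = y[0], m = y[1];
    const double D = p / pp[5] + m;
    const double flux = (D > 0.0) ? p * m / D : 0.0;
    ydot[0] = pp[0] * p + pp[1] * flux - pp[3] * p * p;
    ydot[1] = pp[2] * flux - pp[4] * m * m;
}

/* deSolve entry points */

void sv_init_full(void (*odeparms)(int *, double *))
{
    int n = N_FULL_PARMS;
    odeparms(&n, parms_full);
}

void sv_derivs_full(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    rhs_full(parms_full, y, ydot);
}

void sv_root_full(int *neq, double *t, double *y, int *ng, double *gout,
                  double *out, int *ip)
{
    double ydot[4], m = 0.0;
    rhs_full(parms_full, y, ydot);
    for (int k = 0; k < 4; k++) {
        double a = fabs(ydot[k]);
        if (a > m) m = a;
    }
    gout[0] = m - parms_full[27];
}

void sv_init_reduced(void (*odeparms)(int *, double *))
{
    int n = N_RED_PARMS;
    odeparms(&n, parms_red);
}

void sv_derivs_reduced(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    rhs_reduced(parms_red, y, ydot);
}

void sv_root_reduced(int *neq, double *t, double *y, int *ng, double *gout,
                     double *out, int *ip)
{
    double ydot[2], m = 0.0;
    rhs_reduced(parms_red, y, ydot);
    for (int k = 0; k < 2; k++) {
        double a = fabs(ydot[k]);
        if (a > m) m = a;
    }
    gout[0] = m - parms_red[6];
}

/* fixed-step classical Runge-Kutta, independent of deSolve */

static SEXP rk4_run(SEXP y0, SEXP parms, SEXP t1, SEXP h, int neq,
                    void (*rhs)(const double *, const double *, double *))
{
    const double *pp = REAL(parms);
    const double T = asReal(t1), hh = asReal(h);
    double y[4], k1[4], k2[4], k3[4], k4[4], tmp[4];

    if (neq > 4 || LENGTH(y0) != neq)
        error("bad state dimension");
    if (!(hh > 0.0) || !(T >= 0.0))
        error("horizon and step must be positive");

    for (int k = 0; k < neq; k++) y[k] = REAL(y0)[k];

    double t = 0.0;
    R_xlen_t nstep = (R_xlen_t)ceil(T / hh - 1e-12);
    for (R_xlen_t s = 0; s < nstep; s++) {
        double step = hh;
        if (t + step > T) step = T - t;
        rhs(pp, y, k1);
        for (int k = 0; k < neq; k++) tmp[k] = y[k] + 0.5 * step * k1[k];
        rhs(pp, tmp, k2);
        for (int k = 0; k < neq; k++) tmp[k] = y[k] + 0.5 * step * k2[k];
        rhs(pp, tmp, k3);
        for (int k = 0; k < neq; k++) tmp[k] = y[k] + step * k3[k];
        rhs(pp, tmp, k4);
        for (int k = 0; k < neq; k++)
            y[k] += step * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]) / 6.0;
        t += step;
    }

    SEXP out = PROTECT(allocVector(REALSXP, neq));
    for (int k = 0; k < neq; k++) REAL(out)[k] = y[k];
    UNPROTECT(1);
    return out;
}

SEXP C_rk4_full(SEXP y0, SEXP parms, SEXP t1, SEXP h)
{
    if (LENGTH(parms) < 27) error("need 27 parameters");
    return rk4_run(y0, parms, t1, h, 4, rhs_full);
}

SEXP C_rk4_reduced(SEXP y0, SEXP parms, SEXP t1, SEXP h)
{
    if (LENGTH(parms) < 6) error("need 6 parameters");
    return rk4_run(y0, parms, t1, h, 2, rhs_reduced);
}
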