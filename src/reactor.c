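/* Compiled right-hand side of the coupled batch-reactor model, called by
 * deSolve's lsoda through the compiled-model interface. Mirrors the R
 * reference implementation reactor_rhs() exactly; the test suite checks
 * the two against each other.
 *
 * State y[9]: Ng_H2 Ng_CO2 Ng_CH4 Ng_N2 Nl_H2 Nl_CO2 Nl_CH4 Nl_N2 X
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[18];
#define V_gas       parms[0]
#define V_liq       parms[1]
#define Temp        parms[2]
#define k_gw        parms[3]
#define C_ref       parms[4]
#define mu_max      parms[5]
#define K_H2        parms[6]
#define K_CO2       parms[7]
#define decay_b     parms[8]
#define Y_H2        parms[9]
#define t_L         parms[10]
#define t_E         parms[11]
#define n2_transfer parms[16]
#define lag_origin  parms[17]
/* parms[12..15]: Henry solubilities H2 CO2 CH4 N2 */

static const double RGAS = 8.314;
static const double ZETA[4] = {-1.0, -0.25, 0.25, 0.0};

void reactor_init(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, parms);
}

void reactor_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double tau = *t - lag_origin;
    double lambda;
    if (t_E > t_L) {
        lambda = (tau - t_L) / (t_E - t_L);
        if (lambda < 0.0) lambda = 0.0;
        if (lambda > 1.0) lambda = 1.0;
    } else {
        lambda = (tau >= t_L) ? 1.0 : 0.0;
    }

    double RTV = RGAS * Temp / V_gas;
    double C_H2 = y[4] / V_liq, C_CO2 = y[5] / V_liq;
    if (C_H2 < 0.0) C_H2 = 0.0;       /* clamp only inside Monod factors */
    if (C_CO2 < 0.0) C_CO2 = 0.0;
    double mu = mu_max * (C_H2 / (K_H2 + C_H2)) * (C_CO2 / (K_CO2 + C_CO2));
    double growth_mol = lambda * mu * y[8] / Y_H2;

    for (int n = 0; n < 4; n++) {
        double J = 0.0;
        if (n < 3 || n2_transfer > 0.5) {
            double Ceq = parms[12 + n] * y[n] * RTV;
            double Cl = y[4 + n] / V_liq;
            J = k_gw * (Ceq - Cl) / C_ref;   /* gas -> liquid positive */
        }
        ydot[n] = -J;
        ydot[4 + n] = J + ZETA[n] * growth_mol;
    }
    ydot[8] = lambda * y[8] * (mu - decay_b);
}

static const R_CMethodDef CEntries[] = {
    {"reactor_init",   (DL_FUNC) &reactor_init,   1},
    {"reactor_derivs", (DL_FUNC) &reactor_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_methanobatch(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
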