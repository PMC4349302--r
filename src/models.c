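/* Right-hand sides and reaction fluxes for the two kinetic model variants
 * of the PKD / PI4KIIIbeta / CERT network.
 *
 * Species order (both variants):
 *   0 PKD   1 PKDpDAG   2 PI4K   3 PI4Kp
 *   variant A: 4 CERTpER  5 CERTaER  6 CERTaTGN
 *   variant B: 4 CERTp    5 CERTa    6 CERTaERTGN
 *
 * Parameter order (variant A, 26; variant B appends k_phos_free = 27):
 *   0 vmax1  1 K1E  2 K1S  3 kdp_PI4K
 *   4 vmax3  5 K3E  6 K3S  7 k9
 *   8 vmax5  9 K5E 10 K5S 11 k10
 *  12 k_act 13 vmax_cer 14 K_cer 15 k_pdbu 16 k_deact
 *  17 s_PKD 18 s_PI4K 19 s_CERT 20 s_ect_PI4K 21 s_ect_CERT
 *  22 d_PKD 23 d_PI4K 24 d_CERT 25 k_inh [26 k_phos_free]
 *
 * For deSolve the parms vector is the parameter vector with the four
 * constant input levels u1..u4 appended (inputs are piecewise constant;
 * integration is restarted at every switch time from R).
 *
 * Flux order (see R/model-build.R, must stay in sync):
 *   0 R1  1 dephos_PI4K  2 R3  3 R9  4 R5  5 R10
 *   6 act_basal  7 act_pdbu  8 R6  9 deact_PKD
 *  10 syn_PKD 11 syn_PI4K 12 syn_ect_PI4K 13 syn_CERT 14 syn_ect_CERT
 *  15..21 deg_<species i>
 *  22 phos_free (variant B only)
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define NSP 7
#define NPAR_A 26
#define NPAR_B 27
#define NFLUX_A 22
#define NFLUX_B 23

static double parmsA[NPAR_A + 4];
static double parmsB[NPAR_B + 4];

void ck_init_A(void (*odeparms)(int *, double *))
{
    int n = NPAR_A + 4;
    odeparms(&n, parmsA);
}

void ck_init_B(void (*odeparms)(int *, double *))
{
    int n = NPAR_B + 4;
    odeparms(&n, parmsB);
}

/* Core evaluation shared by the deSolve entry points and the .Call
 * wrapper.  States are clipped at zero for flux evaluation so that small
 * negative integrator excursions cannot produce negative fluxes. */
static void ck_core(int variant, const double *p, const double *u,
                    const double *y, double *dy, double *flux)
{
    double yc[NSP];
    int i;
    for (i = 0; i < NSP; i++)
        yc[i] = (y[i] > 0.0) ? y[i] : 0.0;

    const double inh = 1.0 / (1.0 + p[25] * u[1]);
    const double E = yc[1];              /* PKDpDAG */

    const double vR1 = inh * p[0] * E / (p[1] + E) * yc[2] / (p[2] + yc[2]);
    const double vdp = p[3] * yc[3];
    const double vR3 = inh * p[4] * E / (p[5] + E) * yc[6] / (p[6] + yc[6]);
    const double vR9 = p[7] * yc[4];
    const double vR5 = p[8] * yc[3] / (p[9] + yc[3]) * yc[5] / (p[10] + yc[5]);
    const double J   = p[11] * yc[6];
    const double vab = inh * p[12] * yc[0];
    const double vap = inh * u[0] * p[15] * yc[0];
    /* CERT-transfer-dependent PKD activation: saturating in the transfer
     * flux J, substrate-independent; guarded so it cannot consume PKD
     * that is not there. */
    const double vR6 = (yc[0] > 0.0) ? p[13] * J / (p[14] + J) : 0.0;
    const double vde = p[16] * yc[1];

    const double sPKD  = p[17];
    const double sPI4K = p[18];
    const double sCERT = p[19];
    const double sEctI = u[2] * p[20];
    const double sEctC = u[3] * p[21];

    const double dP = p[22], dI = p[23], dC = p[24];
    const double vpf = (variant == 1) ? inh * p[26] * E * yc[5] : 0.0;

    flux[0] = vR1;   flux[1] = vdp;  flux[2] = vR3;  flux[3] = vR9;
    flux[4] = vR5;   flux[5] = J;    flux[6] = vab;  flux[7] = vap;
    flux[8] = vR6;   flux[9] = vde;
    flux[10] = sPKD; flux[11] = sPI4K; flux[12] = sEctI;
    flux[13] = sCERT; flux[14] = sEctC;
    flux[15] = dP * yc[0];
    flux[16] = dP * yc[1];
    flux[17] = dI * yc[2];
    flux[18] = dI * yc[3];
    flux[19] = dC * yc[4];
    flux[20] = dC * yc[5];
    flux[21] = dC * yc[6];
    if (variant == 1)
        flux[22] = vpf;

    dy[0] = sPKD + vde - vab - vap - vR6 - dP * yc[0];
    dy[1] = vab + vap + vR6 - vde - dP * yc[1];
    dy[2] = sPI4K + sEctI + vdp - vR1 - dI * yc[2];
    dy[3] = vR1 - vdp - dI * yc[3];
    if (variant == 0) {
        dy[4] = vR3 - vR9 - dC * yc[4];                  /* CERTpER  */
        dy[5] = sCERT + sEctC + vR9 - vR5 - dC * yc[5];  /* CERTaER  */
        dy[6] = vR5 - vR3 - dC * yc[6];                  /* CERTaTGN */
    } else {
        dy[4] = vR3 + vpf - vR9 - dC * yc[4];                  /* CERTp      */
        dy[5] = sCERT + sEctC + vR9 - vR5 - vpf - dC * yc[5];  /* CERTa      */
        dy[6] = vR5 - vR3 - dC * yc[6];                        /* CERTaERTGN */
    }
}

void ck_derivs_A(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double flux[NFLUX_A];
    ck_core(0, parmsA, parmsA + NPAR_A, y, ydot, flux);
}

void ck_derivs_B(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double flux[NFLUX_B];
    ck_core(1, parmsB, parmsB + NPAR_B, y, ydot, flux);
}

/* .Call wrapper: derivative vector and per-reaction fluxes at one state.
 * variant: 0 = A, 1 = B; params: kinetic parameters (26 or 27);
 * u: the four input levels at the evaluation time. */
SEXP C_ck_rates(SEXP variant, SEXP y, SEXP params, SEXP u)
{
    const int v = INTEGER(variant)[0];
    const int npar = (v == 1) ? NPAR_B : NPAR_A;
    const int nflux = (v == 1) ? NFLUX_B : NFLUX_A;

    if (LENGTH(y) != NSP) error("state vector must have length %d", NSP);
    if (LENGTH(params) != npar) error("parameter vector must have length %d", npar);
    if (LENGTH(u) != 4) error("input vector must have length 4");

    SEXP dy = PROTECT(allocVector(REALSXP, NSP));
    SEXP fl = PROTECT(allocVector(REALSXP, nflux));
    ck_core(v, REAL(params), REAL(u), REAL(y), REAL(dy), REAL(fl));

    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, dy);
    SET_VECTOR_ELT(out, 1, fl);
    SEXP nms = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nms, 0, mkChar("dy"));
    SET_STRING_ELT(nms, 1, mkChar("flux"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(4);
    return out;
}

static const R_CallMethodDef call_methods[] = {
    {"C_ck_rates", (DL_FUNC) &C_ck_rates, 4},
    {NULL, NULL, 0}
};

void R_init_certkinetics(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_methods, NULL, NULL);
    /* deSolve looks the derivative/initialiser functions up by name */
    R_useDynamicSymbols(dll, TRUE);
}
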