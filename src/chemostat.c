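/* Augmented chemostat ODE system: state (C0, C1, N), forward log-scaled
 * sensitivities of the full state w.r.t. the focal parameters
 * (mu_max, K0, K1), and the accumulating scaled Fisher information matrix
 * for the single measured output N.
 *
 * State vector layout (18 components):
 *   y[0]  C0                 auxotrophic nutrient (g/L)
 *   y[1]  C1                 carbon source (g/L)
 *   y[2]  N                  population (cells/L)
 *   y[3..11]  S[i + 3*j]     S[i,j] = theta_j * dX_i/dtheta_j (column-major)
 *   y[12..17] upper triangle of I, column-major: I11 I12 I22 I13 I23 I33
 *
 * Parameter vector (11 components):
 *   p[0] mu_max, p[1] K0, p[2] K1, p[3] gamma0, p[4] gamma1, p[5] q,
 *   p[6] C0_in, p[7] C1_in, p[8] cv (noise variance fraction),
 *   p[9] nfloor (N clamp for the information increment),
 *   p[10] sigma_mode (1: Sigma = cv*N^2, 2: Sigma = cv*N, 3: Sigma = cv)
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 11
#define N_STATE 18

static double parms[N_PARMS];

/* Core RHS shared by the deSolve entry point and the .Call wrapper. */
static void chem_rhs_core(const double *y, const double *p, double *ydot)
{
    const double mu_max = p[0], K0 = p[1], K1 = p[2];
    const double g0 = p[3], g1 = p[4], q = p[5];
    const double C0in = p[6], C1in = p[7];
    const double cv = p[8], nfloor = p[9];
    const int sigma_mode = (int) p[10];

    const double C0 = y[0], C1 = y[1], N = y[2];

    const double d0 = K0 + C0, d1 = K1 + C1;
    const double m0 = C0 / d0, m1 = C1 / d1;
    const double mu = mu_max * m0 * m1;

    /* state derivatives */
    ydot[0] = q * (C0in - C0) - mu * N / g0;
    ydot[1] = q * (C1in - C1) - mu * N / g1;
    ydot[2] = (mu - q) * N;

    /* partials of mu */
    const double dmu_dC0 = mu_max * m1 * K0 / (d0 * d0);
    const double dmu_dC1 = mu_max * m0 * K1 / (d1 * d1);

    /* Jacobian dF/dX (3x3, row i = equation, col k = state) */
    double J[3][3];
    J[0][0] = -q - (N / g0) * dmu_dC0;
    J[0][1] = -(N / g0) * dmu_dC1;
    J[0][2] = -mu / g0;
    J[1][0] = -(N / g1) * dmu_dC0;
    J[1][1] = -q - (N / g1) * dmu_dC1;
    J[1][2] = -mu / g1;
    J[2][0] = N * dmu_dC0;
    J[2][1] = N * dmu_dC1;
    J[2][2] = mu - q;

    /* theta_j * dmu/dtheta_j for theta = (mu_max, K0, K1) */
    double smu[3];
    smu[0] = mu;                                    /* mu_max * dmu/dmu_max */
    smu[1] = -mu_max * m1 * C0 * K0 / (d0 * d0);    /* K0 * dmu/dK0 */
    smu[2] = -mu_max * m0 * C1 * K1 / (d1 * d1);    /* K1 * dmu/dK1 */

    /* sensitivity block: dS[,j]/dt = theta_j dF/dtheta_j + J %*% S[,j] */
    for (int j = 0; j < 3; j++) {
        const double s0 = y[3 + 3 * j], s1 = y[4 + 3 * j], s2 = y[5 + 3 * j];
        const double f0 = -smu[j] * N / g0;
        const double f1 = -smu[j] * N / g1;
        const double f2 = smu[j] * N;
        ydot[3 + 3 * j] = f0 + J[0][0] * s0 + J[0][1] * s1 + J[0][2] * s2;
        ydot[4 + 3 * j] = f1 + J[1][0] * s0 + J[1][1] * s1 + J[1][2] * s2;
        ydot[5 + 3 * j] = f2 + J[2][0] * s0 + J[2][1] * s1 + J[2][2] * s2;
    }

    /* information increment from the measured channel N (state row 2) */
    const double Nm = (N < nfloor) ? nfloor : N;
    const double sigma = (sigma_mode == 3) ? cv
        : (sigma_mode == 2) ? cv * Nm : cv * Nm * Nm;
    const double w = 1.0 / sigma;
    const double sN0 = y[5], sN1 = y[8], sN2 = y[11];
    ydot[12] = w * sN0 * sN0;
    ydot[13] = w * sN0 * sN1;
    ydot[14] = w * sN1 * sN1;
    ydot[15] = w * sN0 * sN2;
    ydot[16] = w * sN1 * sN2;
    ydot[17] = w * sN2 * sN2;
}

/* deSolve compiled-model interface */
void chemostat_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void chemostat_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    chem_rhs_core(y, parms, ydot);
}

/* Sample-and-hold episode variant: the full input sequence is part of the
 * parameter vector and the active input pair is selected from the current
 * time, so a whole multi-interval experiment integrates in one solver
 * call. Layout: p[0..10] as above (u slots 6/7 ignored), p[11] = interval
 * duration (h), p[12] = number of intervals T, p[13 + 2k], p[14 + 2k] =
 * input pair of interval k (k = 0..T-1). */

#define SEQ_MAX_T 64
static double seq_parms[13 + 2 * SEQ_MAX_T];

void chemoseq_init(void (*odeparms)(int *, double *))
{
    int n = 13 + 2 * SEQ_MAX_T;
    odeparms(&n, seq_parms);
}

void chemoseq_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double p[N_PARMS];
    for (int i = 0; i < N_PARMS; i++) p[i] = seq_parms[i];
    const double dt = seq_parms[11];
    const int T = (int) seq_parms[12];
    int k = (int) (*t / dt);
    if (k < 0) k = 0;
    if (k >= T) k = T - 1;
    p[6] = seq_parms[13 + 2 * k];
    p[7] = seq_parms[14 + 2 * k];
    chem_rhs_core(y, p, ydot);
}

/* Direct RHS evaluation, used by augmented_derivatives() and the tests */
SEXP C_chem_rhs(SEXP ySEXP, SEXP pSEXP)
{
    if (LENGTH(ySEXP) != N_STATE)
        error("state vector must have length %d", N_STATE);
    if (LENGTH(pSEXP) != N_PARMS)
        error("parameter vector must have length %d", N_PARMS);
    SEXP out = PROTECT(allocVector(REALSXP, N_STATE));
    chem_rhs_core(REAL(ySEXP), REAL(pSEXP), REAL(out));
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef callMethods[] = {
    {"C_chem_rhs", (DL_FUNC) &C_chem_rhs, 2},
    {NULL, NULL, 0}
};

void R_init_rloed(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
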