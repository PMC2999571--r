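/* Compiled right-hand sides for the vaccination model, in the deSolve
 * compiled-model interface. Parameter vector layout (see .parms_vec in R):
 *  0 k_i, 1 n_V, 2 V_p, 3 k_m, 4 alpha_l, 5 k_CR, 6 mu_D, 7 a_R, 8 mu_R,
 *  9 a_C, 10 mu_C, 11 k_R, 12 h_P, 13 r, 14 a_p, 15 damp_mode (0 = damping
 *  in tumor burden, 1 = damping in effector number).
 * State order: V, Dm, DC, DR, R, C, P (cells); time in hours.
 */
#include <R.h>

static double parms[16];
#define K_I      parms[0]
#define N_V      parms[1]
#define V_P      parms[2]
#define K_M      parms[3]
#define ALPHA_L  parms[4]
#define K_CR     parms[5]
#define MU_D     parms[6]
#define A_R      parms[7]
#define MU_R     parms[8]
#define A_C      parms[9]
#define MU_C     parms[10]
#define K_R      parms[11]
#define H_P      parms[12]
#define R_T      parms[13]
#define A_P      parms[14]
#define DAMP_EFF parms[15]

static double forc[1];   /* effector forcing C(t) for the scalar tumor solve */
#define C_FORC forc[0]

void psavax_initparms(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, parms);
}

void psavax_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

/* full seven-compartment system */
void psavax_derivs_full(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    double V = y[0], Dm = y[1], DC = y[2], DR = y[3], R = y[4],
           C = y[5], P = y[6];
    double damp = (DAMP_EFF > 0.5) ? H_P / (H_P + C) : H_P / (H_P + P);
    ydot[0] = -K_I * V;
    ydot[1] = (K_I / N_V) * V - K_M * Dm;
    ydot[2] = ALPHA_L * K_M * Dm + V_P - K_CR * DC;
    ydot[3] = K_CR * DC - MU_D * DR;
    ydot[4] = A_R * DR - MU_R * R;
    ydot[5] = A_C * DC - MU_C * C - K_R * R * C;
    ydot[6] = R_T * P - A_P * C * P * damp;
}

/* immune cascade only (V, Dm, DC, DR, R, C); independent of the patient-
 * specific parameters, solved once per protocol */
void psavax_derivs_immune(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    double V = y[0], Dm = y[1], DC = y[2], DR = y[3], R = y[4], C = y[5];
    ydot[0] = -K_I * V;
    ydot[1] = (K_I / N_V) * V - K_M * Dm;
    ydot[2] = ALPHA_L * K_M * Dm + V_P - K_CR * DC;
    ydot[3] = K_CR * DC - MU_D * DR;
    ydot[4] = A_R * DR - MU_R * R;
    ydot[5] = A_C * DC - MU_C * C - K_R * R * C;
}

/* scalar tumor equation driven by a precomputed effector forcing C(t) */
void psavax_derivs_tumor(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    double P = y[0];
    double damp = (DAMP_EFF > 0.5) ? H_P / (H_P + C_FORC) : H_P / (H_P + P);
    ydot[0] = R_T * P - A_P * C_FORC * P * damp;
}
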