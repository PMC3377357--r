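/* Flow-limited closed-chamber PBPK model for a volatile chemical.
 *
 * States (one rat, scaled by n_rats in the chamber exchange):
 *   y[0]  A_ch   amount in chamber gas, mg
 *   y[1..5]      tissue concentrations, mg/L: adipose, rapidly perfused,
 *                slowly perfused, liver, kidney
 *   y[6]  A_met_liver   cumulative amount metabolized in liver, mg
 *   y[7]  A_met_kidney  cumulative amount metabolized in kidney, mg
 *   y[8]  A_met_linear  cumulative amount through the linear term, mg
 *   y[9]  A_lost        cumulative first-order chamber loss, mg
 *
 * Lung and blood are algebraic (steady-state); arterial concentration is
 * C_art = (QC*C_ven + QP*C_ch) / (QC + QP/Pb).
 */
#include <R.h>

static double parms[27];

#define P_QC      parms[0]
#define P_QP      parms[1]
#define P_PB      parms[2]
#define P_FLOW(i) parms[3 + (i)]   /* adi, rap, slo, liv, kid */
#define P_VOL(i)  parms[8 + (i)]
#define P_PART(i) parms[13 + (i)]
#define P_VCH     parms[18]
#define P_NRATS   parms[19]
#define P_KLOSS   parms[20]
#define P_HYP     parms[21]        /* 1 = two-pathway, 2 = two-binding-site */
#define P_M1      parms[22]        /* Vmax   | Vmax1 */
#define P_M2      parms[23]        /* Km     | Km1   */
#define P_M3      parms[24]        /* kGST   | CL2   */
#define P_SHL     parms[25]
#define P_SHK     parms[26]

#define I_LIV 3
#define I_KID 4

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = 27;
    odeparms(&n, parms);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double c_ch = y[0] / P_VCH;
    double c_ven = 0.0, c_art, denom;
    double met_l, met_k, lin_l, lin_k;
    double cl, ck;
    int i;

    for (i = 0; i < 5; i++)
        c_ven += P_FLOW(i) * (y[1 + i] / P_PART(i));
    c_ven /= P_QC;

    denom = P_QC + P_QP / P_PB;
    c_art = (P_QC * c_ven + P_QP * c_ch) / denom;

    /* stiff solvers may probe slightly negative concentrations */
    cl = y[1 + I_LIV] > 0.0 ? y[1 + I_LIV] : 0.0;
    ck = y[1 + I_KID] > 0.0 ? y[1 + I_KID] : 0.0;

    if (P_HYP < 1.5) {                      /* MM + first-order GST term */
        met_l = P_SHL * (P_M1 * cl / (P_M2 + cl) + P_M3 * cl * P_VOL(I_LIV));
        met_k = P_SHK * (P_M1 * ck / (P_M2 + ck) + P_M3 * ck * P_VOL(I_KID));
        lin_l = P_SHL * P_M3 * cl * P_VOL(I_LIV);
        lin_k = P_SHK * P_M3 * ck * P_VOL(I_KID);
    } else {                                /* two-binding-site */
        met_l = P_SHL * (P_M1 * cl + P_M3 * cl * cl) / (P_M2 + cl);
        met_k = P_SHK * (P_M1 * ck + P_M3 * ck * ck) / (P_M2 + ck);
        lin_l = P_SHL * P_M3 * cl * cl / (P_M2 + cl);
        lin_k = P_SHK * P_M3 * ck * ck / (P_M2 + ck);
    }

    ydot[0] = P_NRATS * P_QP * (c_art / P_PB - c_ch) - P_KLOSS * y[0];

    for (i = 0; i < 5; i++)
        ydot[1 + i] = P_FLOW(i) * (c_art - y[1 + i] / P_PART(i)) / P_VOL(i);
    ydot[1 + I_LIV] -= met_l / P_VOL(I_LIV);
    ydot[1 + I_KID] -= met_k / P_VOL(I_KID);

    ydot[6] = met_l;
    ydot[7] = met_k;
    ydot[8] = lin_l + lin_k;
    ydot[9] = P_KLOSS * y[0];

    if (ip[0] >= 2) {
        yout[0] = c_art;
        yout[1] = c_ven;
    }
}
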