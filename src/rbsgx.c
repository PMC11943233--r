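/* Two-compartment disposition of free rocuronium (Rb), free sugammadex
 * (SGX) and the 1:1 Rb-SGX complex, with an effect-compartment link and
 * cumulative elimination accounting.
 *
 * State vector y (time unit: seconds):
 *   0 a1r  free Rb, central            [ug]
 *   1 a2r  free Rb, peripheral         [ug]
 *   2 a1s  free SGX, central           [ug]
 *   3 a2s  free SGX, peripheral        [ug]
 *   4 ac1  complex, central            [umol]
 *   5 ac2  complex, peripheral         [umol]
 *   6 ce   Rb effect-site conc         [ug/mL]
 *   7 elr  eliminated Rb (incl. Rb carried out in complex)  [ug]
 *   8 els  eliminated SGX (incl. SGX carried out in complex) [ug]
 *
 * Parameters p (rate constants per minute, volumes in L):
 *   0 v1r 1 v2r 2 clr 3 qr      Rb two-compartment terms
 *   4 v1s 5 v2s 6 cls 7 qs      SGX two-compartment terms
 *   8 v1c 9 v2c 10 clc 11 qc    complex two-compartment terms
 *   12 kon   association rate   [1/uM/min]
 *   13 koff  dissociation rate  [1/min]
 *   14 ke0   effect link        [1/min]
 *   15 mwr   Rb molecular weight  [g/mol]
 *   16 mws   SGX molecular weight [g/mol]
 *   17 vbind binding volume (central plasma) [L]
 *   18 rater Rb infusion rate   [ug/min]
 *   19 rates SGX infusion rate  [ug/min]
 *
 * Binding is 1:1 molar in the central compartment:
 *   J = kon * [Rb]_uM * [SGX]_uM * vbind   [umol/min].
 * ug amounts convert to umol as a/MW (ug / (g/mol) = umol), so central
 * molar concentrations are a1/(MW*V1) in umol/L.
 */
#include <R.h>

#define N_PARMS 20

static double p[N_PARMS];

void rbsgx_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void rbsgx_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double v1r = p[0], v2r = p[1], clr = p[2], qr = p[3];
    const double v1s = p[4], v2s = p[5], cls = p[6], qs = p[7];
    const double v1c = p[8], v2c = p[9], clc = p[10], qc = p[11];
    const double kon = p[12], koff = p[13], ke0 = p[14];
    const double mwr = p[15], mws = p[16], vbind = p[17];
    const double rater = p[18], rates = p[19];

    /* Fluxes are evaluated on non-negative amounts: the solver may probe
     * values a rounding error below zero. */
    const double a1r = y[0] > 0 ? y[0] : 0;
    const double a2r = y[1] > 0 ? y[1] : 0;
    const double a1s = y[2] > 0 ? y[2] : 0;
    const double a2s = y[3] > 0 ? y[3] : 0;
    const double ac1 = y[4] > 0 ? y[4] : 0;
    const double ac2 = y[5] > 0 ? y[5] : 0;

    const double crb_uM = a1r / (mwr * v1r);
    const double csx_uM = a1s / (mws * v1s);
    const double jbind = kon * crb_uM * csx_uM * vbind; /* umol/min */
    const double jdiss = koff * ac1;                    /* umol/min */

    const double dist_r = qr * (a1r / v1r - a2r / v2r);
    const double dist_s = qs * (a1s / v1s - a2s / v2s);
    const double dist_c = qc * (ac1 / v1c - ac2 / v2c);
    const double el_r = clr * a1r / v1r;
    const double el_s = cls * a1s / v1s;
    const double el_c = clc * ac1 / v1c; /* umol/min */

    /* per-minute derivatives, converted to per-second at the end */
    double d[9];
    d[0] = rater - el_r - dist_r - mwr * jbind + mwr * jdiss;
    d[1] = dist_r;
    d[2] = rates - el_s - dist_s - mws * jbind + mws * jdiss;
    d[3] = dist_s;
    d[4] = jbind - jdiss - el_c - dist_c;
    d[5] = dist_c;
    d[6] = ke0 * (a1r / (v1r * 1000.0) - y[6]);
    d[7] = el_r + mwr * el_c;
    d[8] = el_s + mws * el_c;

    for (int i = 0; i < 9; i++)
        ydot[i] = d[i] / 60.0;
}
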