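/* Right-hand side of the HSF1/HSP70 heat shock response network,
 * in the form deSolve expects from a compiled model.
 *
 * State y = (theta, MFP, HSP, mHSP); time in hours, temperature in degC,
 * concentrations in uM.  The temperature setpoint is passed as a parameter,
 * so the integrator is driven segment-by-segment over a piecewise-constant
 * protocol from R.
 */
#include <R.h>
#include <math.h>

static double parms[13];
#define k_d       parms[0]
#define k_r       parms[1]
#define mu        parms[2]
#define lam       parms[3]
#define S0        parms[4]
#define beta      parms[5]
#define H0        parms[6]
#define tau_temp  parms[7]
#define tau_mfp   parms[8]
#define tau_mhsp  parms[9]
#define tau_hsp   parms[10]
#define hsf1_tot  parms[11]
#define thetac    parms[12]

void hsr_initmod(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, parms);
}

/* denaturation rate kappa(theta), clamped at 0 below ~34.7 degC */
static double kappa(double theta)
{
    double k = k_d * (1.0 - 0.4 * exp(37.0 - theta)) * pow(1.4, theta - 37.0);
    return k > 0.0 ? k : 0.0;
}

void hsr_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double theta = y[0], mfp = y[1], hsp = y[2], mhsp = y[3];

    /* negative undershoot from the solver is treated as zero concentration */
    if (mfp < 0.0) mfp = 0.0;
    if (hsp < 0.0) hsp = 0.0;
    if (mhsp < 0.0) mhsp = 0.0;

    double pool = hsp + mfp;
    /* titration ratios: continuous extension 0/0 -> 0 */
    double hsp_free = (pool > 0.0) ? hsp / pool : 0.0;
    double mfp_over_pool = (pool > 0.0) ? mfp / pool : 0.0;
    double hsf1_free = hsf1_tot / (hsf1_tot + hsp * hsp_free);
    double f3 = hsf1_free * hsf1_free * hsf1_free;
    double s3 = S0 * S0 * S0;

    ydot[0] = (thetac - theta) / tau_temp;
    ydot[1] = (kappa(theta) - mfp * mfp_over_pool - k_r * mfp * hsp_free) / tau_mfp;
    ydot[2] = (beta * hsp_free / (H0 + hsp_free) * mhsp - hsp) / tau_hsp;
    ydot[3] = (mu + lam * f3 / (s3 + f3) - mhsp) / tau_mhsp;
}
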