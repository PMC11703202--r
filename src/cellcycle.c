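/* Compiled right-hand side of the two-ODE cyclin B / Cdk1 relaxation
 * oscillator, in the parameter layout produced by pack_parms():
 *   0 ks, 1 kd, 2 ka, 3 ki, 4 eps,
 *   5-8   deg   (basal, amplitude, ec50, n)  increasing
 *   9-12  cdc25 (basal, amplitude, ec50, n)  increasing
 *   13-16 wee1  (basal, amplitude, ec50, n)  decreasing
 */
#include <R.h>
#include <math.h>

static double parms[17];

void cellcycle_init(void (*odeparms)(int *, double *))
{
    int n = 17;
    odeparms(&n, parms);
}

static double hill_up(double x, const double *q)
{
    double xn, en;
    if (x < 0.0) x = 0.0;
    xn = pow(x, q[3]);
    en = pow(q[2], q[3]);
    return q[0] + q[1] * xn / (en + xn);
}

static double hill_down(double x, const double *q)
{
    double xn, en;
    if (x < 0.0) x = 0.0;
    xn = pow(x, q[3]);
    en = pow(q[2], q[3]);
    return q[0] + q[1] * en / (en + xn);
}

void cellcycle_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double cyc = y[0], a = y[1];
    double deg = hill_up(a, parms + 5);
    double cdc = hill_up(a, parms + 9);
    double wee = hill_down(a, parms + 13);
    ydot[0] = parms[0] - parms[1] * deg * cyc;
    ydot[1] = (parms[2] * cdc * (cyc - a) - parms[3] * wee * a) / parms[4];
}
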