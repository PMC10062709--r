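/* Mass-action one-site receptor binding model for deSolve.
 *
 * Species per well (7): R, L, C, NBV, RL, RC, NBVL  [nM]
 * Reactions: R + L <-> RL, R + C <-> RC, NBV + L <-> NBVL
 * Parameters (6): kon_L, koff_L, kon_C, koff_C, kon_NS, koff_NS
 *   rates in 1/(nM*s) and 1/s.
 *
 * The state vector may hold any number of wells stacked in blocks of 7;
 * all wells share one rate-parameter set, so a whole plate group is
 * integrated in a single call.
 */
#include <R.h>

static double parms[6];

void fabind_init(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void fabind_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    int nwell = *neq / 7;
    for (int w = 0; w < nwell; w++) {
        double *s = y + 7 * w;
        double *d = ydot + 7 * w;
        double vRL = parms[0] * s[0] * s[1] - parms[1] * s[4];
        double vRC = parms[2] * s[0] * s[2] - parms[3] * s[5];
        double vNS = parms[4] * s[3] * s[1] - parms[5] * s[6];
        d[0] = -vRL - vRC;
        d[1] = -vRL - vNS;
        d[2] = -vRC;
        d[3] = -vNS;
        d[4] = vRL;
        d[5] = vRC;
        d[6] = vNS;
    }
}
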