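/* deSolve-compatible right-hand sides for the cone phototransduction model.
 *
 * Units: surface densities um^-2, concentrations uM, time s, currents pA.
 * The activation front-end tracks activated-subunit densities on disc
 * membrane; the full model appends well-stirred cGMP and Ca dynamics.
 */
#include <R.h>
#include <math.h>

/* ---- activation cascade: y = (Rstar, Gstar, Estar) ---- */

static double cas_p[6];
#define CAS_KR    cas_p[0]
#define CAS_NURG  cas_p[1]
#define CAS_KGE   cas_p[2]
#define CAS_KE    cas_p[3]
#define CAS_GSIG  cas_p[4]
#define CAS_ETOT  cas_p[5]

void cascade_init(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, cas_p);
}

static void cascade_rhs(const double *y, double *ydot)
{
    double R = y[0], G = y[1], E = y[2];
    double avail = (CAS_GSIG - G - E) / CAS_GSIG;
    double act, form;
    if (avail < 0.0) avail = 0.0;        /* guard: invariant G + E <= G_sigma */
    act = CAS_NURG * R * avail;
    form = CAS_KGE * (CAS_ETOT - E) * G;
    ydot[0] = -CAS_KR * R;
    ydot[1] = act - form;
    ydot[2] = form - CAS_KE * E;
}

void cascade_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    cascade_rhs(y, ydot);
}

/* ---- full photoresponse: y = (Rstar, Gstar, Estar, cG, Ca) ---- */

static double ph_p[20];
#define PH_KR      ph_p[0]
#define PH_NURG    ph_p[1]
#define PH_KGE     ph_p[2]
#define PH_KE      ph_p[3]
#define PH_GSIG    ph_p[4]
#define PH_ETOT    ph_p[5]
#define PH_BDARK   ph_p[6]
#define PH_BLIGHT  ph_p[7]   /* k*_{sigma;hyd} / (2 eta_um): s^-1 per unit Estar density */
#define PH_AMIN    ph_p[8]
#define PH_AMAX    ph_p[9]
#define PH_KCYC    ph_p[10]  /* uM */
#define PH_MCYC    ph_p[11]
#define PH_JCGMAX  ph_p[12]
#define PH_KCG     ph_p[13]
#define PH_MCG     ph_p[14]
#define PH_FCA     ph_p[15]
#define PH_JEXSAT  ph_p[16]
#define PH_KEX     ph_p[17]
#define PH_BCA     ph_p[18]
#define PH_CONV    ph_p[19]  /* 1e9 / (F * V_cyto): pA -> uM/s at charge 1 */

void photo_init(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, ph_p);
}

void photo_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double cG = y[3], Ca = y[4];
    double xc, JcG, Jex, cyc, hyd;

    {
        double R = y[0], G = y[1], E = y[2];
        double avail = (PH_GSIG - G - E) / PH_GSIG;
        double act, form;
        if (avail < 0.0) avail = 0.0;
        act = PH_NURG * R * avail;
        form = PH_KGE * (PH_ETOT - E) * G;
        ydot[0] = -PH_KR * R;
        ydot[1] = act - form;
        ydot[2] = form - PH_KE * E;
    }

    if (cG < 0.0) cG = 0.0;
    if (Ca < 0.0) Ca = 0.0;

    xc = pow(cG / PH_KCG, PH_MCG);
    JcG = PH_JCGMAX * xc / (1.0 + xc);
    Jex = PH_JEXSAT * Ca / (PH_KEX + Ca);
    cyc = PH_AMIN + (PH_AMAX - PH_AMIN) /
          (1.0 + pow(Ca / PH_KCYC, PH_MCYC));
    hyd = (PH_BDARK + PH_BLIGHT * y[2]) * cG;

    ydot[3] = cyc - hyd;
    ydot[4] = (PH_FCA * JcG * PH_CONV / 2.0 - Jex * PH_CONV) / PH_BCA;
}
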