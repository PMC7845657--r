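/* Whole-body PBPK-PD right-hand side for the three clopidogrel species
 * (parent, 2-oxo intermediate, active metabolite) plus the gut-lumen
 * transit chain and the platelet turnover state.  Used through the
 * deSolve compiled-model interface; the parameter vector layout is
 * produced by pack_parms() on the R side and must stay in sync with it.
 *
 * Units: time h, volumes L, flows L/h, amounts nmol, concentrations
 * nmol/L (the platelet binding term converts venous concentration to
 * nmol/ml because kirre is in ml/nmol/h).
 */
#include <R.h>
#include <R_ext/Rdynload.h>

#define NPAR 142
static double parms[NPAR];

void clopbpk_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

/* compartment order; must match .clop_compartments in R */
#define SPL 0
#define LIV 1
#define ADI 2
#define MUS 3
#define LUN 4
#define KID 5
#define BRA 6
#define HEA 7
#define SKI 8
#define ROB 9
#define VEN 10
#define ART 11
#define STO 12
#define GW0 13              /* duodenal wall; GW0+4 is colonic wall */
#define NC  18

#define P_QTOT     parms[0]
#define P_QLIVO    parms[1] /* pooled liver outflow: hepatic artery + portal */
#define P_PBSF     parms[2]
#define P_FUGUT    parms[3]
#define P_KT0      parms[4]
#define P_KT(i)    parms[5 + (i)]
#define P_KA(i)    parms[10 + (i)]
#define P_KB(i)    parms[15 + (i)]
#define P_KIN      parms[20]
#define P_KOUT     parms[21]
#define P_KIRRE    parms[22]
#define P_FUBAM    parms[23]
#define P_V(c)     parms[24 + (c)]
#define P_Q(c)     parms[42 + (c)]
#define P_KTB(s,c) parms[60 + (s) * NC + (c)]
#define P_FUB(s)   parms[114 + (s)]
#define P_CES1(s)  parms[117 + (s)]
#define P_NCYP(s)  parms[120 + (s)]
#define P_VC(s,k)  parms[122 + (s) * 5 + (k)]  /* Vmax*content, nmol/h/mg */
#define P_KMF(s,k) parms[132 + (s) * 5 + (k)]  /* Km*fumic, nmol/L */

/* extra states after the 3 x 18 concentration block */
#define YLUM(i)  y[3 * NC + (i)]      /* 0 stomach lumen, 1..5 duodenum..colon */
#define DLUM(i)  ydot[3 * NC + (i)]
#define IM_      (3 * NC + 6)         /* platelet aggregation state M */
#define ICES(s)  (3 * NC + 7 + (s))   /* cumulative CES1-hydrolysed, nmol */
#define IFEC     (3 * NC + 10)        /* cumulative faecal loss, nmol */
#define ICYP(s)  (3 * NC + 11 + (s))  /* cumulative CYP flux parent->product */

void clopbpk_rhs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    static const int sys[7] = { ADI, MUS, KID, BRA, HEA, SKI, ROB };
    int s, c, i, k;

    for (s = 0; s < 3; s++) {
        const double *C = y + s * NC;
        double *D = ydot + s * NC;
        double cart = C[ART], ven_in = 0.0, inflow;

        /* perfusion-limited tissues */
        for (i = 0; i < 7; i++) {
            c = sys[i];
            D[c] = P_Q(c) * (cart - C[c] / P_KTB(s, c)) / P_V(c);
            ven_in += P_Q(c) * C[c] / P_KTB(s, c);
        }
        D[SPL] = P_Q(SPL) * (cart - C[SPL] / P_KTB(s, SPL)) / P_V(SPL);
        D[STO] = P_Q(STO) * (cart - C[STO] / P_KTB(s, STO)) / P_V(STO);
        for (c = GW0; c < GW0 + 5; c++)
            D[c] = P_Q(c) * (cart - C[c] / P_KTB(s, c)) / P_V(c);

        /* lung in series between the venous and arterial pools */
        D[LUN] = P_QTOT * (C[VEN] - C[LUN] / P_KTB(s, LUN)) / P_V(LUN);
        D[ART] = P_QTOT * (C[LUN] / P_KTB(s, LUN) - cart) / P_V(ART);

        /* liver: hepatic artery plus portal drainage of stomach, spleen
         * and the five gut-wall segments; drains at the pooled flow */
        inflow = P_Q(LIV) * cart
               + P_Q(STO) * C[STO] / P_KTB(s, STO)
               + P_Q(SPL) * C[SPL] / P_KTB(s, SPL);
        for (c = GW0; c < GW0 + 5; c++)
            inflow += P_Q(c) * C[c] / P_KTB(s, c);
        D[LIV] = (inflow - P_QLIVO * C[LIV] / P_KTB(s, LIV)) / P_V(LIV);

        ven_in += P_QLIVO * C[LIV] / P_KTB(s, LIV);
        D[VEN] = (ven_in - P_QTOT * C[VEN]) / P_V(VEN);
    }

    /* gastric emptying and gut-lumen transit/absorption/efflux (parent only) */
    DLUM(0) = -P_KT0 * YLUM(0);
    for (i = 0; i < 5; i++) {
        double trans_in = (i == 0) ? P_KT0 * YLUM(0) : P_KT(i - 1) * YLUM(i);
        double absn = P_KA(i) * YLUM(i + 1);
        double effl = P_KB(i) * y[GW0 + i] * P_V(GW0 + i) * P_FUGUT;
        DLUM(i + 1) = trans_in - P_KT(i) * YLUM(i + 1) - absn + effl;
        ydot[GW0 + i] += (absn - effl) / P_V(GW0 + i);
    }
    ydot[IFEC] = P_KT(4) * YLUM(5);   /* colonic transit = irreversible loss */

    /* hepatic elimination: saturable CYP oxidation (scaled by total
     * microsomal protein) in 1:1 molar cascade, linear CES1 hydrolysis */
    for (s = 0; s < 3; s++) {
        double cfree = y[s * NC + LIV] * P_FUB(s) / P_KTB(s, LIV);
        double clcyp = 0.0, rcyp, rces;
        int n = (s < 2) ? (int) P_NCYP(s) : 0;
        for (k = 0; k < n; k++)
            clcyp += P_VC(s, k) / (P_KMF(s, k) + cfree);
        rcyp = P_PBSF * clcyp * cfree;
        rces = P_CES1(s) * cfree;
        ydot[s * NC + LIV] -= (rcyp + rces) / P_V(LIV);
        ydot[ICES(s)] = rces;
        if (s < 2) {
            ydot[(s + 1) * NC + LIV] += rcyp / P_V(LIV);
            ydot[ICYP(s)] = rcyp;
        }
    }

    /* indirect-response platelet model on free venous active metabolite */
    {
        double cam = y[2 * NC + VEN] / 1000.0;   /* nmol/L -> nmol/ml */
        ydot[IM_] = P_KIN - P_KOUT * y[IM_]
                  - P_KIRRE * cam * P_FUBAM * y[IM_];
    }
}

void R_init_clopbpk(DllInfo *dll)
{
    /* deSolve looks the routines up by name */
    R_useDynamicSymbols(dll, TRUE);
}
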