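/* Whole-body perfusion-limited PBPK right-hand side with well-stirred liver,
 * gut first-pass (Q_Gut model) and dynamic enzyme pools (turnover with
 * mechanism-based inactivation, induction, competitive inhibition).
 *
 * State vector (amounts in mg unless noted):
 *   0  gut lumen
 *   1  arterial blood
 *   2  venous blood
 *   3..14 tissues: lung adipose bone brain heart kidney muscle skin gut
 *         spleen liver rest
 *   15 liver CYP3A4 pool (fraction of baseline)
 *   16 liver CYP2C8 pool
 *   17 gut CYP3A4 pool
 *   18 cumulative renal elimination
 *   19 cumulative hepatic metabolism (incl. compensatory pathway)
 *   20 cumulative biliary elimination
 *   21 cumulative gut-wall metabolism
 *   22 cumulative unabsorbed (fraction 1-fa leaving the lumen)
 *
 * Forcings: forc[0] perpetrator total plasma concentration (umol/L),
 *           forc[1] co-species (metabolite) total concentration (umol/L).
 */
#include <R.h>

#define N_TISS 12
#define I_LUNG 0
#define I_KIDNEY 5
#define I_GUT 8
#define I_SPLEEN 9
#define I_LIVER 10

/* parameter layout */
#define P_KA      0
#define P_FA      1
#define P_QGUT    2
#define P_FUGUT   3
#define P_BP      4
#define P_FUP     5
#define P_MW      6
#define P_VART    7
#define P_VVEN    8
#define P_CO      9
#define P_V       10            /* 12 tissue volumes (L) */
#define P_Q       22            /* 12 tissue flows (L/h); liver = hep. artery */
#define P_KPB     34            /* 12 Kp/B:P */
#define P_CL1_0   46            /* NDMI CYP3A4, L/h at C->0 */
#define P_KM1     47            /* unbound Km, umol/L */
#define P_CL2_0   48            /* NDMI CYP2C8 */
#define P_KM2     49
#define P_CL3     50            /* others CYP3A4, linear */
#define P_CL4     51            /* others CYP2C8 (budget residual), linear */
#define P_CLCOMP  52            /* compensatory, pool-independent */
#define P_CLB1    53            /* ABCB1 linear */
#define P_CLG2_0  54            /* ABCG2, L/h at C->0 */
#define P_KMG2    55
#define P_CLR     56
#define P_CLGUT   57            /* gut CYP3A4 intrinsic clearance, L/h */
#define P_KDEG1   58            /* liver CYP3A4 */
#define P_KDEG2   59            /* liver CYP2C8 */
#define P_KDEG3   60            /* gut CYP3A4 */
#define P_KINACT  61
#define P_KIU     62            /* umol/L */
#define P_FUPERP  63
#define P_FUCO    64
#define P_IM3P    65            /* Ind_max CYP3A4, parent */
#define P_IC3P    66
#define P_IM2P    67            /* Ind_max CYP2C8, parent */
#define P_IC2P    68
#define P_IM3C    69            /* co-species */
#define P_IC3C    70
#define P_IM2C    71
#define P_IC2C    72
#define P_KIU3A4  73            /* competitive Ki_u, 0 = absent */
#define P_KIU2C8  74
#define P_INFRATE 75            /* iv infusion rate, mg/h (per segment) */
#define P_INDBASE 76            /* 0: induction on total conc, 1: unbound */
#define P_MBIFAC  77            /* intracellular:plasma unbound ratio (pH
                                   partitioning) driving hepatic MBI */
#define P_COMPMODE 78           /* 0: compensatory clearance always active;
                                   1: scaled by the inactivated CYP3A4
                                   fraction (1 - pool) */
#define NP        79

static double p[NP];
static double forc[2];

void pbpk_initmod(void (* odeparms)(int *, double *))
{
    int n = NP;
    odeparms(&n, p);
}

void pbpk_initforc(void (* odeforcs)(int *, double *))
{
    int n = 2;
    odeforcs(&n, forc);
}

static double ind_scale(double imax_p, double ic50_p, double imax_c,
                        double ic50_c, double ip, double ic)
{
    double s = 1.0;
    if (imax_p > 1.0) s += (imax_p - 1.0) * ip / (ic50_p + ip);
    if (imax_c > 1.0) s += (imax_c - 1.0) * ic / (ic50_c + ic);
    return s;
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double *V = p + P_V, *Q = p + P_Q, *Kpb = p + P_KPB;
    double c_art = y[1] / p[P_VART];
    double c_ven = y[2] / p[P_VVEN];

    /* perpetrator terms */
    double ip_tot = forc[0] > 0 ? forc[0] : 0.0;
    double ic_tot = forc[1] > 0 ? forc[1] : 0.0;
    double ip_u = ip_tot * p[P_FUPERP], ic_u = ic_tot * p[P_FUCO];
    double ind_p = p[P_INDBASE] > 0.5 ? ip_u : ip_tot;
    double ind_c = p[P_INDBASE] > 0.5 ? ic_u : ic_tot;
    double s3 = ind_scale(p[P_IM3P], p[P_IC3P], p[P_IM3C], p[P_IC3C],
                          ind_p, ind_c);
    double s2 = ind_scale(p[P_IM2P], p[P_IC2P], p[P_IM2C], p[P_IC2C],
                          ind_p, ind_c);
    double ks3 = 1.0, ks2 = 1.0;        /* competitive Km scales */
    if (p[P_KIU3A4] > 0) ks3 += ip_u / p[P_KIU3A4];
    if (p[P_KIU2C8] > 0) ks2 += ip_u / p[P_KIU2C8];

    /* absorption and gut first pass */
    double abs_flux = p[P_KA] * p[P_FA] * y[0];        /* mg/h */
    double unabs_flux = p[P_KA] * (1.0 - p[P_FA]) * y[0];
    double clgut_eff = p[P_CLGUT] * y[17] / ks3;
    double fg = p[P_QGUT] / (p[P_QGUT] + p[P_FUGUT] * clgut_eff);
    double to_portal = abs_flux * fg;
    double gut_met = abs_flux * (1.0 - fg);

    /* liver unbound concentration (plasma-water basis) */
    double c_liv_out = y[3 + I_LIVER] / (V[I_LIVER] * Kpb[I_LIVER]); /* blood */
    double cu_liv = p[P_FUP] * c_liv_out / p[P_BP];                  /* mg/L */
    double cu_uM = cu_liv * 1000.0 / p[P_MW];

    /* hepatic clearances (L/h, applied to cu_liv) */
    double cl3a4 = y[15] * (p[P_CL1_0] * p[P_KM1] /
                            (p[P_KM1] * ks3 + cu_uM) + p[P_CL3] / ks3);
    double cl2c8 = y[16] * (p[P_CL2_0] * p[P_KM2] /
                            (p[P_KM2] * ks2 + cu_uM) + p[P_CL4] / ks2);
    double comp = p[P_CLCOMP];
    if (p[P_COMPMODE] > 0.5) {
        double lost = 1.0 - y[15];
        comp *= (lost > 0.0) ? lost : 0.0;
    }
    double cl_met = cl3a4 + cl2c8 + comp;
    double cl_bile = p[P_CLB1] + p[P_CLG2_0] * p[P_KMG2] /
        (p[P_KMG2] + cu_uM);
    double e_met = cl_met * cu_liv;
    double e_bile = cl_bile * cu_liv;

    /* tissues */
    double ven_in = 0.0;
    for (int i = 0; i < N_TISS; i++) {
        if (i == I_LUNG || i == I_GUT || i == I_SPLEEN || i == I_LIVER)
            continue;
        double c_out = y[3 + i] / (V[i] * Kpb[i]);
        ydot[3 + i] = Q[i] * (c_art - c_out);
        ven_in += Q[i] * c_out;
    }
    /* renal elimination from arterial plasma */
    double e_renal = p[P_CLR] * c_art / p[P_BP];
    ydot[3 + I_KIDNEY] -= e_renal;

    double c_gut_out = y[3 + I_GUT] / (V[I_GUT] * Kpb[I_GUT]);
    double c_spl_out = y[3 + I_SPLEEN] / (V[I_SPLEEN] * Kpb[I_SPLEEN]);
    ydot[3 + I_GUT] = Q[I_GUT] * (c_art - c_gut_out);
    ydot[3 + I_SPLEEN] = Q[I_SPLEEN] * (c_art - c_spl_out);

    double q_liv = Q[I_LIVER] + Q[I_GUT] + Q[I_SPLEEN];
    ydot[3 + I_LIVER] = Q[I_LIVER] * c_art + Q[I_GUT] * c_gut_out +
        Q[I_SPLEEN] * c_spl_out + to_portal - q_liv * c_liv_out -
        e_met - e_bile;
    ven_in += q_liv * c_liv_out;

    /* lung, arterial, venous, lumen */
    double c_lung_out = y[3 + I_LUNG] / (V[I_LUNG] * Kpb[I_LUNG]);
    ydot[3 + I_LUNG] = p[P_CO] * (c_ven - c_lung_out);
    ydot[1] = p[P_CO] * c_lung_out - p[P_CO] * c_art;
    ydot[2] = ven_in - p[P_CO] * c_ven + p[P_INFRATE];
    ydot[0] = -p[P_KA] * y[0];

    /* enzyme pools */
    double inact_l = 0.0, inact_g = 0.0;
    if (p[P_KINACT] > 0) {
        double kiu = p[P_KIU] * ks3;
        double cg_uM = p[P_FUGUT] * (abs_flux / p[P_QGUT]) * 1000.0 /
            p[P_MW];
        double cu_cell = cu_uM * p[P_MBIFAC];
        inact_l = p[P_KINACT] * cu_cell / (kiu + cu_cell);
        inact_g = p[P_KINACT] * cg_uM / (kiu + cg_uM);
    }
    ydot[15] = p[P_KDEG1] * s3 - y[15] * (p[P_KDEG1] + inact_l);
    ydot[16] = p[P_KDEG2] * s2 - y[16] * p[P_KDEG2];
    ydot[17] = p[P_KDEG3] * s3 - y[17] * (p[P_KDEG3] + inact_g);

    /* cumulative eliminations */
    ydot[18] = e_renal;
    ydot[19] = e_met;
    ydot[20] = e_bile;
    ydot[21] = gut_met;
    ydot[22] = unabs_flux;

    if (*ip > 0) yout[0] = cu_uM;
}
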