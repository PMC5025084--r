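// Compiled integration core: full-model derivative and fixed-step RK4.
//
// The rate laws here mirror the pure-R reference implementation in
// R/rates_r.R one-to-one; the two are cross-checked in the test suite.
// State layout (flat vector):
//   [ hep comp 1 (17) | ... | hep comp N | blood comp 1 (7) | ... |
//     blood comp N | body (7) ]
// Hepatocyte species order:
//   Gc, G6P, Gly, G3P, Lac, ACoA, FFA, TG, Glyc, ATP, ADP, AMP, Pi,
//   UTP, UDP, GTP, GDP
// Blood species order: Gb, Lacb, FFAb, TGb, Glycb, Ins, Glg

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const int NH = 17, NB = 7, NPROC = 27;

enum HepSp { iGc, iG6P, iGly, iG3P, iLac, iACoA, iFFA, iTG, iGlyc,
             iATP, iADP, iAMP, iPi, iUTP, iUDP, iGTP, iGDP };
enum BloodSp { jGb, jLacb, jFFAb, jTGb, jGlycb, jIns, jGlg };
enum Proc { pGlut, pGK, pG6Pase, pGS, pGP, pPFK, pPK, pPEPCK, pFBP,
            pPDH, pBoxi, pATPS, pNDKG, pNDKU, pAK, pATPu, pPReg,
            pLgen, pTSyn, pLply, pGConv, pLact,
            pFFAup, pFFArel, pTGup, pVLDL, pGlyt };

static inline double powi(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}
static inline double Hact(double c, double K, int n) {
  if (c <= 0.0) return 0.0;
  double cn = powi(c, n), Kn = powi(K, n);
  return cn / (Kn + cn);
}
static inline double Hinh(double c, double K, int n) {
  if (c <= 0.0) return 1.0;
  double cn = powi(c, n), Kn = powi(K, n);
  return Kn / (Kn + cn);
}
static inline double fact(double h, double a, double K, int n) {
  return (1.0 - a) + a * Hact(h, K, n);
}
static inline double finh(double h, double b, double K, int n) {
  return (1.0 - b) + b * Hinh(h, K, n);
}

struct Model {
  int N;
  double Vb_i, Vh_i, Vbody, flow, rho, tau_rate, tau_body;
  double kdeg_ins_sin, kdeg_glg_sin;
  std::vector<double> o2, x;
  // hormones
  double K_I, K_G; int n_I, n_G;
  double ins_basal, ins_vmax, ins_K, glg_basal, glg_vmax, glg_K;
  int ins_n, glg_n;
  double kdI, kdG;
  // zonation constants
  double kn[NPROC], kn_ins, kn_glg;
  // hepatic rate-law constants
  double glut_vb, glut_Kglc;
  double gk_vb, gk_Kglc, gk_Katp, gk_Kig6p, gk_a; int gk_nglc;
  double g6pase_vb, g6pase_Kg6p, g6pase_b, g6pase_ag;
  double gs_vb, gs_Kg6p, gs_Kutp, gs_Kcap, gs_a, gs_bg; int gs_ng6p, gs_ncap;
  double gp_vb, gp_Kgly, gp_Kpi, gp_b, gp_ag;
  double pfk_vb, pfk_Kg6p, pfk_Katp, pfk_a; int pfk_ng6p;
  double pk_vb, pk_Kg3p, pk_Kadp, pk_Kpi, pk_a;
  double pepck_vb, pepck_Klac, pepck_Katp, pepck_Kgtp, pepck_b, pepck_ag;
  double fbp_vb, fbp_Kg3p, fbp_b, fbp_ag; int fbp_ng3p;
  double pdh_vb, pdh_Klac, pdh_Kiacoa, pdh_a;
  double boxi_vb, boxi_Kffa, boxi_Kiacoa, boxi_Katp, boxi_b; int boxi_niacoa;
  double atps_vb, atps_Kacoa, atps_Kadp, atps_Kpi, atps_Ko2;
  double ndkg_vb, ndkg_Kgdp, ndkg_Katp;
  double ndku_vb, ndku_Kudp, ndku_Katp;
  double ak_vb;
  double atpu_vb, atpu_Katp;
  double preg_k, preg_set;
  double lgen_vb, lgen_Kacoa, lgen_Kg6p, lgen_Katp, lgen_Kiffa, lgen_a;
  int lgen_nacoa, lgen_niffa;
  double tsyn_vb, tsyn_Kg3p, tsyn_Kffa, tsyn_Katp, tsyn_a;
  double lply_vb, lply_Ktg, lply_b, lply_ag; int lply_ntg;
  double gconv_vb, gconv_Kglyc, gconv_Katp;
  double lact_vb, lact_Klac;
  double ffaup_vb, ffaup_Kffab, ffaup_pass, ffaup_Kscav;
  int ffaup_nscav, ffaup_inh;
  double ffarel_vb, ffarel_Kffa; int ffarel_nffa;
  double tgup_vb, tgup_Ktgb;
  double vldl_vb, vldl_Ktg;
  double glyt_vb, glyt_Kglyc;
  // body
  double algen_vb, algen_Kglc, algen_Kins; int algen_nglc, algen_nins;
  double alply_vb, alply_Ktg, alply_frac, alply_Kins; int alply_nins;
  double gut_vb, gut_Kffa, gut_Kglyc;
  double musg_vb, musg_Kglc, musg_frac, musg_Kins; int musg_nins;
  double musf_vb, musf_Kffa, musf_frac, musf_Kins; int musf_nins;
  double lacp_vb, lacp_Kglc;
  double lacu_vb, lacu_Klac;
  double glycu_vb, glycu_Kglyc;
  double renal_k, renal_thresh;
  // scenario
  double K_IR, clamp; bool srebp; int wave;
  double in_glc, in_ffa, period_s;
};

static double getv(const NumericVector& v, const char* name) {
  CharacterVector nm = v.names();
  for (int i = 0; i < v.size(); ++i)
    if (std::string(nm[i]) == name) return v[i];
  stop("core: missing parameter '%s'", std::string(name));
  return NA_REAL;
}

static Model build_model(NumericVector phys, NumericVector horm,
                         NumericVector hep, NumericVector knv,
                         NumericVector body, NumericVector scen,
                         NumericVector o2) {
  Model M;
  M.N = (int)getv(phys, "n_comp");
  double Vh = getv(phys, "V_hep"), Vb = getv(phys, "V_blood");
  M.Vbody = getv(phys, "V_body");
  M.flow = getv(phys, "flow");
  M.Vb_i = Vb / M.N;
  M.Vh_i = Vh / M.N;
  M.rho = M.Vh_i / M.Vb_i;
  M.tau_rate = M.flow / M.Vb_i;
  M.tau_body = M.flow / M.Vbody;
  M.kdeg_ins_sin = getv(horm, "kdeg_ins_sin");
  M.kdeg_glg_sin = getv(horm, "kdeg_glg_sin");
  M.o2.assign(o2.begin(), o2.end());
  if ((int)M.o2.size() != M.N) stop("core: oxygen profile length mismatch");
  M.x.resize(M.N);
  for (int i = 0; i < M.N; ++i) M.x[i] = 1.0 - 2.0 * i / (M.N - 1.0);

  M.K_I = getv(horm, "K_I"); M.n_I = (int)getv(horm, "n_I");
  M.K_G = getv(horm, "K_G"); M.n_G = (int)getv(horm, "n_G");
  M.ins_basal = getv(horm, "ins_basal"); M.ins_vmax = getv(horm, "ins_vmax");
  M.ins_K = getv(horm, "ins_K"); M.ins_n = (int)getv(horm, "ins_n");
  M.glg_basal = getv(horm, "glg_basal"); M.glg_vmax = getv(horm, "glg_vmax");
  M.glg_K = getv(horm, "glg_K"); M.glg_n = (int)getv(horm, "glg_n");
  M.kdI = getv(horm, "kdeg_ins_body"); M.kdG = getv(horm, "kdeg_glg_body");

  const char* pn[NPROC] = {"glut", "gk", "g6pase", "gs", "gp", "pfk", "pk",
    "pepck", "fbp", "pdh", "boxi", "atps", "ndkg", "ndku", "ak", "atpu",
    "preg", "lgen", "tsyn", "lply", "gconv", "lact", "ffa_up", "ffa_rel",
    "tg_up", "vldl", "glyt"};
  for (int p = 0; p < NPROC; ++p) M.kn[p] = getv(knv, pn[p]);
  M.kn_ins = getv(knv, "ins_recept");
  M.kn_glg = getv(knv, "glg_recept");

  M.glut_vb = getv(hep, "glut.vb"); M.glut_Kglc = getv(hep, "glut.K_glc");
  M.gk_vb = getv(hep, "gk.vb"); M.gk_Kglc = getv(hep, "gk.K_glc");
  M.gk_nglc = (int)getv(hep, "gk.n_glc");
  M.gk_Katp = getv(hep, "gk.K_atp"); M.gk_a = getv(hep, "gk.a_ins");
  M.gk_Kig6p = getv(hep, "gk.Ki_g6p");
  M.g6pase_vb = getv(hep, "g6pase.vb"); M.g6pase_Kg6p = getv(hep, "g6pase.K_g6p");
  M.g6pase_b = getv(hep, "g6pase.b_ins"); M.g6pase_ag = getv(hep, "g6pase.a_glg");
  M.gs_vb = getv(hep, "gs.vb"); M.gs_Kg6p = getv(hep, "gs.K_g6p");
  M.gs_ng6p = (int)getv(hep, "gs.n_g6p"); M.gs_Kutp = getv(hep, "gs.K_utp");
  M.gs_Kcap = getv(hep, "gs.K_cap"); M.gs_ncap = (int)getv(hep, "gs.n_cap");
  M.gs_a = getv(hep, "gs.a_ins"); M.gs_bg = getv(hep, "gs.b_glg");
  M.gp_vb = getv(hep, "gp.vb"); M.gp_Kgly = getv(hep, "gp.K_gly");
  M.gp_Kpi = getv(hep, "gp.K_pi"); M.gp_b = getv(hep, "gp.b_ins");
  M.gp_ag = getv(hep, "gp.a_glg");
  M.pfk_vb = getv(hep, "pfk.vb"); M.pfk_Kg6p = getv(hep, "pfk.K_g6p");
  M.pfk_ng6p = (int)getv(hep, "pfk.n_g6p"); M.pfk_Katp = getv(hep, "pfk.K_atp");
  M.pfk_a = getv(hep, "pfk.a_ins");
  M.pk_vb = getv(hep, "pk.vb"); M.pk_Kg3p = getv(hep, "pk.K_g3p");
  M.pk_Kadp = getv(hep, "pk.K_adp"); M.pk_Kpi = getv(hep, "pk.K_pi");
  M.pk_a = getv(hep, "pk.a_ins");
  M.pepck_vb = getv(hep, "pepck.vb"); M.pepck_Klac = getv(hep, "pepck.K_lac");
  M.pepck_Katp = getv(hep, "pepck.K_atp"); M.pepck_Kgtp = getv(hep, "pepck.K_gtp");
  M.pepck_b = getv(hep, "pepck.b_ins"); M.pepck_ag = getv(hep, "pepck.a_glg");
  M.fbp_vb = getv(hep, "fbp.vb"); M.fbp_Kg3p = getv(hep, "fbp.K_g3p");
  M.fbp_ng3p = (int)getv(hep, "fbp.n_g3p"); M.fbp_b = getv(hep, "fbp.b_ins");
  M.fbp_ag = getv(hep, "fbp.a_glg");
  M.pdh_vb = getv(hep, "pdh.vb"); M.pdh_Klac = getv(hep, "pdh.K_lac");
  M.pdh_Kiacoa = getv(hep, "pdh.Ki_acoa"); M.pdh_a = getv(hep, "pdh.a_ins");
  M.boxi_vb = getv(hep, "boxi.vb"); M.boxi_Kffa = getv(hep, "boxi.K_ffa");
  M.boxi_Kiacoa = getv(hep, "boxi.Ki_acoa");
  M.boxi_niacoa = (int)getv(hep, "boxi.ni_acoa");
  M.boxi_Katp = getv(hep, "boxi.K_atp"); M.boxi_b = getv(hep, "boxi.b_ins");
  M.atps_vb = getv(hep, "atps.vb"); M.atps_Kacoa = getv(hep, "atps.K_acoa");
  M.atps_Kadp = getv(hep, "atps.K_adp"); M.atps_Kpi = getv(hep, "atps.K_pi");
  M.atps_Ko2 = getv(hep, "atps.K_o2");
  M.ndkg_vb = getv(hep, "ndkg.vb"); M.ndkg_Kgdp = getv(hep, "ndkg.K_gdp");
  M.ndkg_Katp = getv(hep, "ndkg.K_atp");
  M.ndku_vb = getv(hep, "ndku.vb"); M.ndku_Kudp = getv(hep, "ndku.K_udp");
  M.ndku_Katp = getv(hep, "ndku.K_atp");
  M.ak_vb = getv(hep, "ak.vb");
  M.atpu_vb = getv(hep, "atpu.vb"); M.atpu_Katp = getv(hep, "atpu.K_atp");
  M.preg_k = getv(hep, "preg.k_relax"); M.preg_set = getv(hep, "preg.pi_set");
  M.lgen_vb = getv(hep, "lgen.vb"); M.lgen_Kacoa = getv(hep, "lgen.K_acoa");
  M.lgen_nacoa = (int)getv(hep, "lgen.n_acoa"); M.lgen_Katp = getv(hep, "lgen.K_atp");
  M.lgen_Kg6p = getv(hep, "lgen.K_g6p");
  M.lgen_Kiffa = getv(hep, "lgen.Ki_ffa");
  M.lgen_niffa = (int)getv(hep, "lgen.ni_ffa"); M.lgen_a = getv(hep, "lgen.a_ins");
  M.tsyn_vb = getv(hep, "tsyn.vb"); M.tsyn_Kg3p = getv(hep, "tsyn.K_g3p");
  M.tsyn_Kffa = getv(hep, "tsyn.K_ffa"); M.tsyn_Katp = getv(hep, "tsyn.K_atp");
  M.tsyn_a = getv(hep, "tsyn.a_ins");
  M.lply_vb = getv(hep, "lply.vb"); M.lply_Ktg = getv(hep, "lply.K_tg");
  M.lply_ntg = (int)getv(hep, "lply.n_tg");
  M.lply_b = getv(hep, "lply.b_ins"); M.lply_ag = getv(hep, "lply.a_glg");
  M.gconv_vb = getv(hep, "gconv.vb"); M.gconv_Kglyc = getv(hep, "gconv.K_glyc");
  M.gconv_Katp = getv(hep, "gconv.K_atp");
  M.lact_vb = getv(hep, "lact.vb"); M.lact_Klac = getv(hep, "lact.K_lac");
  M.ffaup_vb = getv(hep, "ffa_up.vb"); M.ffaup_Kffab = getv(hep, "ffa_up.K_ffab");
  M.ffaup_pass = getv(hep, "ffa_up.passive_frac");
  M.ffaup_Kscav = getv(hep, "ffa_up.K_scav");
  M.ffaup_nscav = (int)getv(hep, "ffa_up.n_scav");
  M.ffaup_inh = (int)getv(hep, "ffa_up.scav_inh");
  M.ffarel_vb = getv(hep, "ffa_rel.vb"); M.ffarel_Kffa = getv(hep, "ffa_rel.K_ffa");
  M.ffarel_nffa = (int)getv(hep, "ffa_rel.n_ffa");
  M.tgup_vb = getv(hep, "tg_up.vb"); M.tgup_Ktgb = getv(hep, "tg_up.K_tgb");
  M.vldl_vb = getv(hep, "vldl.vb"); M.vldl_Ktg = getv(hep, "vldl.K_tg");
  M.glyt_vb = getv(hep, "glyt.vb"); M.glyt_Kglyc = getv(hep, "glyt.K_glyc");

  M.algen_vb = getv(body, "a_lgen.vb"); M.algen_Kglc = getv(body, "a_lgen.K_glc");
  M.algen_nglc = (int)getv(body, "a_lgen.n_glc");
  M.algen_Kins = getv(body, "a_lgen.K_ins");
  M.algen_nins = (int)getv(body, "a_lgen.n_ins");
  M.alply_vb = getv(body, "a_lply.vb"); M.alply_Ktg = getv(body, "a_lply.K_tg");
  M.alply_frac = getv(body, "a_lply.ins_frac");
  M.alply_Kins = getv(body, "a_lply.K_ins");
  M.alply_nins = (int)getv(body, "a_lply.n_ins");
  M.gut_vb = getv(body, "gut_tsyn.vb"); M.gut_Kffa = getv(body, "gut_tsyn.K_ffa");
  M.gut_Kglyc = getv(body, "gut_tsyn.K_glyc");
  M.musg_vb = getv(body, "mus_glc.vb"); M.musg_Kglc = getv(body, "mus_glc.K_glc");
  M.musg_frac = getv(body, "mus_glc.ins_frac");
  M.musg_Kins = getv(body, "mus_glc.K_ins");
  M.musg_nins = (int)getv(body, "mus_glc.n_ins");
  M.musf_vb = getv(body, "mus_ffa.vb"); M.musf_Kffa = getv(body, "mus_ffa.K_ffa");
  M.musf_frac = getv(body, "mus_ffa.ins_frac");
  M.musf_Kins = getv(body, "mus_ffa.K_ins");
  M.musf_nins = (int)getv(body, "mus_ffa.n_ins");
  M.lacp_vb = getv(body, "lac_prod.vb"); M.lacp_Kglc = getv(body, "lac_prod.K_glc");
  M.lacu_vb = getv(body, "lac_use.vb"); M.lacu_Klac = getv(body, "lac_use.K_lac");
  M.glycu_vb = getv(body, "glyc_use.vb");
  M.glycu_Kglyc = getv(body, "glyc_use.K_glyc");
  M.renal_k = getv(body, "renal.k"); M.renal_thresh = getv(body, "renal.thresh");

  M.K_IR = getv(scen, "K_IR");
  M.srebp = getv(scen, "srebp") != 0.0;
  M.clamp = getv(scen, "clamp");
  M.wave = (int)getv(scen, "wave");
  M.in_glc = getv(scen, "in_glc");
  M.in_ffa = getv(scen, "in_ffa");
  M.period_s = getv(scen, "period_s");
  return M;
}

// Full model derivative. rates (if non-null) receives N*NPROC entries,
// compartment-major.
static void derivs(const Model& M, double t, const double* y, double* dy,
                   double* rates) {
  const int N = M.N;
  const double* bodyv = y + N * (NH + NB);
  double* dbody = dy + N * (NH + NB);
  for (int k = 0; k < N * (NH + NB) + NB; ++k) dy[k] = 0.0;

  for (int c = 0; c < N; ++c) {
    const double* h = y + c * NH;
    const double* b = y + N * NH + c * NB;
    double* dh = dy + c * NH;
    double* db = dy + N * NH + c * NB;
    const double xz = M.x[c];
    const double o2 = M.o2[c];

    double ins_sensed = b[jIns] * (1.0 + M.kn_ins * xz);
    double glg_sensed = b[jGlg] * (1.0 + M.kn_glg * xz);
    double ins = M.K_IR * ins_sensed;
    double ins_lip = M.srebp ? M.clamp : ins;  // lipogenesis/TG-synthesis site
    double glg = glg_sensed;

    double r[NPROC];
    double m;
#define ZON(P) (1.0 + M.kn[P] * xz)
    m = ZON(pGlut);
    r[pGlut] = M.glut_vb * m *
      (Hact(b[jGb], M.glut_Kglc, 1) - Hact(h[iGc], M.glut_Kglc, 1));
    m = ZON(pGK);
    r[pGK] = M.gk_vb * m * Hact(h[iGc], M.gk_Kglc, M.gk_nglc) *
      Hact(h[iATP], M.gk_Katp, 1) * Hinh(h[iG6P], M.gk_Kig6p, 1) *
      fact(ins, M.gk_a, M.K_I, M.n_I);
    m = ZON(pG6Pase);
    r[pG6Pase] = M.g6pase_vb * m * Hact(h[iG6P], M.g6pase_Kg6p, 1) *
      finh(ins, M.g6pase_b, M.K_I, M.n_I) * fact(glg, M.g6pase_ag, M.K_G, M.n_G);
    m = ZON(pGS);
    r[pGS] = M.gs_vb * m * Hact(h[iG6P], M.gs_Kg6p, M.gs_ng6p) *
      Hact(h[iUTP], M.gs_Kutp, 1) * Hinh(h[iGly], M.gs_Kcap, M.gs_ncap) *
      fact(ins, M.gs_a, M.K_I, M.n_I) * finh(glg, M.gs_bg, M.K_G, M.n_G);
    m = ZON(pGP);
    r[pGP] = M.gp_vb * m * Hact(h[iGly], M.gp_Kgly, 1) *
      Hact(h[iPi], M.gp_Kpi, 1) * finh(ins, M.gp_b, M.K_I, M.n_I) *
      fact(glg, M.gp_ag, M.K_G, M.n_G);
    m = ZON(pPFK);
    r[pPFK] = M.pfk_vb * m * Hact(h[iG6P], M.pfk_Kg6p, M.pfk_ng6p) *
      Hact(h[iATP], M.pfk_Katp, 1) * fact(ins, M.pfk_a, M.K_I, M.n_I);
    m = ZON(pPK);
    r[pPK] = M.pk_vb * m * Hact(h[iG3P], M.pk_Kg3p, 1) *
      Hact(h[iADP], M.pk_Kadp, 1) * Hact(h[iPi], M.pk_Kpi, 1) *
      fact(ins, M.pk_a, M.K_I, M.n_I);
    m = ZON(pPEPCK);
    r[pPEPCK] = M.pepck_vb * m * Hact(h[iLac], M.pepck_Klac, 1) *
      Hact(h[iATP], M.pepck_Katp, 1) * Hact(h[iGTP], M.pepck_Kgtp, 1) *
      finh(ins, M.pepck_b, M.K_I, M.n_I) * fact(glg, M.pepck_ag, M.K_G, M.n_G);
    m = ZON(pFBP);
    r[pFBP] = M.fbp_vb * m * Hact(h[iG3P], M.fbp_Kg3p, M.fbp_ng3p) *
      finh(ins, M.fbp_b, M.K_I, M.n_I) * fact(glg, M.fbp_ag, M.K_G, M.n_G);
    m = ZON(pPDH);
    r[pPDH] = M.pdh_vb * m * Hact(h[iLac], M.pdh_Klac, 1) *
      Hinh(h[iACoA], M.pdh_Kiacoa, 1) * fact(ins, M.pdh_a, M.K_I, M.n_I);
    m = ZON(pBoxi);
    r[pBoxi] = M.boxi_vb * m * Hact(h[iFFA], M.boxi_Kffa, 1) *
      Hinh(h[iACoA], M.boxi_Kiacoa, M.boxi_niacoa) *
      Hact(h[iATP], M.boxi_Katp, 1) * finh(ins, M.boxi_b, M.K_I, M.n_I);
    m = ZON(pATPS);
    r[pATPS] = M.atps_vb * m * Hact(h[iACoA], M.atps_Kacoa, 1) *
      Hact(h[iADP], M.atps_Kadp, 1) * Hact(h[iPi], M.atps_Kpi, 1) *
      Hact(o2, M.atps_Ko2, 1);
    m = ZON(pNDKG);
    r[pNDKG] = M.ndkg_vb * m * Hact(h[iGDP], M.ndkg_Kgdp, 1) *
      Hact(h[iATP], M.ndkg_Katp, 1);
    m = ZON(pNDKU);
    r[pNDKU] = M.ndku_vb * m * Hact(h[iUDP], M.ndku_Kudp, 1) *
      Hact(h[iATP], M.ndku_Katp, 1);
    r[pAK] = M.ak_vb * (h[iATP] * h[iAMP] - h[iADP] * h[iADP]);
    m = ZON(pATPu);
    r[pATPu] = M.atpu_vb * m * Hact(h[iATP], M.atpu_Katp, 1);
    r[pPReg] = M.preg_k * (h[iPi] - M.preg_set);
    m = ZON(pLgen);
    r[pLgen] = M.lgen_vb * m * Hact(h[iACoA], M.lgen_Kacoa, M.lgen_nacoa) *
      Hact(h[iG6P], M.lgen_Kg6p, 1) * Hact(h[iATP], M.lgen_Katp, 1) *
      Hinh(h[iFFA], M.lgen_Kiffa, M.lgen_niffa) *
      fact(ins_lip, M.lgen_a, M.K_I, M.n_I);
    m = ZON(pTSyn);
    r[pTSyn] = M.tsyn_vb * m * Hact(h[iG3P], M.tsyn_Kg3p, 1) *
      Hact(h[iFFA], M.tsyn_Kffa, 1) * Hact(h[iATP], M.tsyn_Katp, 1) *
      fact(ins_lip, M.tsyn_a, M.K_I, M.n_I);
    m = ZON(pLply);
    r[pLply] = M.lply_vb * m * Hact(h[iTG], M.lply_Ktg, M.lply_ntg) *
      finh(ins, M.lply_b, M.K_I, M.n_I) * fact(glg, M.lply_ag, M.K_G, M.n_G);
    m = ZON(pGConv);
    r[pGConv] = M.gconv_vb * m * Hact(h[iGlyc], M.gconv_Kglyc, 1) *
      Hact(h[iATP], M.gconv_Katp, 1);
    m = ZON(pLact);
    r[pLact] = M.lact_vb * m *
      (Hact(b[jLacb], M.lact_Klac, 1) - Hact(h[iLac], M.lact_Klac, 1));
    m = ZON(pFFAup);
    r[pFFAup] = M.ffaup_vb * m * Hact(b[jFFAb], M.ffaup_Kffab, 1) *
      (M.ffaup_pass + (1.0 - M.ffaup_pass) *
         (M.ffaup_inh ? Hinh(ins, M.ffaup_Kscav, M.ffaup_nscav)
                      : Hact(ins, M.ffaup_Kscav, M.ffaup_nscav)));
    m = ZON(pFFArel);
    r[pFFArel] = M.ffarel_vb * m * Hact(h[iFFA], M.ffarel_Kffa, M.ffarel_nffa);
    m = ZON(pTGup);
    r[pTGup] = M.tgup_vb * m * Hact(b[jTGb], M.tgup_Ktgb, 1);
    m = ZON(pVLDL);
    r[pVLDL] = M.vldl_vb * m * Hact(h[iTG], M.vldl_Ktg, 1);
    m = ZON(pGlyt);
    r[pGlyt] = M.glyt_vb * m *
      (Hact(b[jGlycb], M.glyt_Kglyc, 1) - Hact(h[iGlyc], M.glyt_Kglyc, 1));
#undef ZON
    if (rates) for (int p = 0; p < NPROC; ++p) rates[c * NPROC + p] = r[p];

    // Hepatic rate equations (stoichiometry table transcribed line by line)
    dh[iGc]   = -r[pGK] + r[pG6Pase] + r[pGlut];
    dh[iG6P]  = r[pGK] - r[pG6Pase] + r[pGP] - r[pGS] + r[pFBP] - r[pPFK];
    dh[iGly]  = r[pGS] - r[pGP];
    dh[iG3P]  = r[pPEPCK] - 2.0 * r[pFBP] + 2.0 * r[pPFK] - r[pPK] +
                r[pGConv] - r[pTSyn];
    dh[iLac]  = r[pLact] - r[pPEPCK] + r[pPK] - r[pPDH];
    dh[iACoA] = r[pPDH] - 8.0 * r[pLgen] + 8.0 * r[pBoxi] - r[pATPS];
    dh[iFFA]  = (r[pFFAup] - r[pFFArel]) + 3.0 * r[pLply] - 3.0 * r[pTSyn] +
                r[pLgen] - r[pBoxi];
    dh[iTG]   = (r[pTGup] - r[pVLDL]) + r[pTSyn] - r[pLply];
    dh[iGlyc] = r[pGlyt] - r[pGConv] + r[pLply];
    dh[iATP]  = 12.0 * r[pATPS] - r[pAK] - 2.0 * r[pPEPCK] - r[pPFK] +
                3.25 * r[pPK] - r[pGK] - r[pNDKG] - r[pNDKU] - r[pATPu] -
                2.0 * r[pBoxi] - 7.0 * r[pLgen] - r[pGConv] +
                2.5 * r[pPDH] - 3.0 * r[pTSyn];
    dh[iADP]  = -12.0 * r[pATPS] + 2.0 * r[pAK] + 2.0 * r[pPEPCK] + r[pPFK] -
                3.25 * r[pPK] + r[pGK] + r[pNDKG] + r[pNDKU] + r[pATPu] +
                7.0 * r[pLgen] + r[pGConv] + r[pBoxi] - 2.5 * r[pPDH];
    dh[iAMP]  = -r[pAK] + r[pBoxi] + 3.0 * r[pTSyn];
    dh[iPi]   = -12.0 * r[pATPS] - r[pGP] + r[pG6Pase] + 2.0 * r[pGS] -
                2.25 * r[pPK] + 2.0 * r[pPEPCK] + r[pFBP] - r[pPReg] +
                r[pATPu] + 7.0 * r[pLgen] + r[pBoxi] - 2.5 * r[pPDH] +
                7.0 * r[pTSyn];
    dh[iUTP]  = r[pNDKU] - r[pGS];
    dh[iUDP]  = -r[pNDKU] + r[pGS];
    dh[iGTP]  = r[pNDKG] - r[pPEPCK];
    dh[iGDP]  = -r[pNDKG] + r[pPEPCK];

    // Blood-side exchange, scaled by the hepatocyte:blood volume ratio
    db[jGb]    -= M.rho * r[pGlut];
    db[jLacb]  -= M.rho * r[pLact];
    db[jFFAb]  -= M.rho * (r[pFFAup] - r[pFFArel]);
    db[jTGb]   -= M.rho * (r[pTGup] - r[pVLDL]);
    db[jGlycb] -= M.rho * r[pGlyt];
  }

  // Plug-flow advection + sinusoidal hormone degradation
  for (int c = 0; c < N; ++c) {
    const double* up = (c == 0) ? bodyv : y + N * NH + (c - 1) * NB;
    const double* b = y + N * NH + c * NB;
    double* db = dy + N * NH + c * NB;
    for (int s = 0; s < NB; ++s) db[s] += M.tau_rate * (up[s] - b[s]);
    db[jIns] -= M.kdeg_ins_sin * b[jIns];
    db[jGlg] -= M.kdeg_glg_sin * b[jGlg];
  }

  // Body compartment: return flow, peripheral processes, hormones, feeding
  {
    const double* bN = y + N * NH + (N - 1) * NB;
    for (int s = 0; s < NB; ++s) dbody[s] += M.tau_body * (bN[s] - bodyv[s]);
    double ins_eff = M.K_IR * bodyv[jIns];
    double a_lgen = M.algen_vb * Hact(bodyv[jGb], M.algen_Kglc, M.algen_nglc) *
      Hact(ins_eff, M.algen_Kins, M.algen_nins);
    double a_lply = M.alply_vb * Hact(bodyv[jTGb], M.alply_Ktg, 1) *
      ((1.0 - M.alply_frac) +
       M.alply_frac * Hinh(ins_eff, M.alply_Kins, M.alply_nins));
    double gut = M.gut_vb * Hact(bodyv[jFFAb], M.gut_Kffa, 1) *
      Hact(bodyv[jGlycb], M.gut_Kglyc, 1);
    double musg = M.musg_vb * Hact(bodyv[jGb], M.musg_Kglc, 1) *
      ((1.0 - M.musg_frac) +
       M.musg_frac * Hact(ins_eff, M.musg_Kins, M.musg_nins));
    double musf = M.musf_vb * Hact(bodyv[jFFAb], M.musf_Kffa, 1) *
      ((1.0 - M.musf_frac) +
       M.musf_frac * Hinh(ins_eff, M.musf_Kins, M.musf_nins));
    double lacp = M.lacp_vb * Hact(bodyv[jGb], M.lacp_Kglc, 1);
    double lacu = M.lacu_vb * Hact(bodyv[jLacb], M.lacu_Klac, 1);
    double glycu = M.glycu_vb * Hact(bodyv[jGlycb], M.glycu_Kglyc, 1);
    double renal = bodyv[jGb] > M.renal_thresh
      ? M.renal_k * (bodyv[jGb] - M.renal_thresh) : 0.0;
    double w = 1.0;
    if (M.wave == 1) {
      double s = std::sin(M_PI * t / M.period_s);
      w = powi(s, 6);
    }
    dbody[jGb]    += -4.0 * a_lgen - musg - lacp - renal + M.in_glc * w;
    dbody[jLacb]  += 2.0 * lacp - lacu;
    dbody[jFFAb]  += a_lgen + 3.0 * a_lply - 3.0 * gut - musf + M.in_ffa * w;
    dbody[jTGb]   += -a_lply + gut;
    // dietary lipid hydrolysis supplies one glycerol per three fatty acids
    dbody[jGlycb] += a_lply - gut - glycu + M.in_ffa * w / 3.0;
    dbody[jIns]   += M.ins_basal +
      M.ins_vmax * Hact(bodyv[jGb], M.ins_K, M.ins_n) - M.kdI * bodyv[jIns];
    dbody[jGlg]   += M.glg_basal +
      M.glg_vmax * Hinh(bodyv[jGb], M.glg_K, M.glg_n) - M.kdG * bodyv[jGlg];
  }
}

// [[Rcpp::export]]
List hz_core_derivs(NumericVector y, double t, NumericVector phys,
                    NumericVector horm, NumericVector hep, NumericVector kn,
                    NumericVector body, NumericVector scen,
                    NumericVector o2) {
  Model M = build_model(phys, horm, hep, kn, body, scen, o2);
  int len = M.N * (NH + NB) + NB;
  if (y.size() != len) stop("core: state length %d, expected %d",
                            (int)y.size(), len);
  NumericVector dy(len);
  NumericVector rates(M.N * NPROC);
  derivs(M, t, y.begin(), dy.begin(), rates.begin());
  return List::create(_["dy"] = dy, _["rates"] = rates);
}

// One RK4 step with rejection on negative states: on failure the step is
// retried as two half steps (recursively, bounded depth) rather than
// clipping, which would silently violate the conservation audits.
static bool rk4_span(const Model& M, double t, double dt, std::vector<double>& y,
                     std::vector<double>& k1, std::vector<double>& k2,
                     std::vector<double>& k3, std::vector<double>& k4,
                     std::vector<double>& tmp, std::vector<double>& ynew,
                     int depth, int& bad_index) {
  const int len = (int)y.size();
  derivs(M, t, y.data(), k1.data(), nullptr);
  for (int i = 0; i < len; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
  derivs(M, t + 0.5 * dt, tmp.data(), k2.data(), nullptr);
  for (int i = 0; i < len; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
  derivs(M, t + 0.5 * dt, tmp.data(), k3.data(), nullptr);
  for (int i = 0; i < len; ++i) tmp[i] = y[i] + dt * k3[i];
  derivs(M, t + dt, tmp.data(), k4.data(), nullptr);
  bool ok = true;
  for (int i = 0; i < len; ++i) {
    ynew[i] = y[i] + dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (ynew[i] < 0.0 || !std::isfinite(ynew[i])) { ok = false; bad_index = i; }
  }
  if (ok) { y.swap(ynew); return true; }
  if (depth >= 14) {
    // tolerate round-off-level undershoot only
    bool tiny = true;
    for (int i = 0; i < len; ++i) {
      if (!std::isfinite(ynew[i]) || ynew[i] < -1e-9) { tiny = false; bad_index = i; }
    }
    if (tiny) {
      for (int i = 0; i < len; ++i) y[i] = ynew[i] < 0.0 ? 0.0 : ynew[i];
      return true;
    }
    return false;
  }
  if (!rk4_span(M, t, dt / 2.0, y, k1, k2, k3, k4, tmp, ynew, depth + 1, bad_index))
    return false;
  return rk4_span(M, t + dt / 2.0, dt / 2.0, y, k1, k2, k3, k4, tmp, ynew,
                  depth + 1, bad_index);
}

static std::string state_name(const Model& M, int idx) {
  const char* hs[NH] = {"glucose_c", "g6p", "glycogen", "g3p_gadp", "pyr_lac",
    "acetyl_coa", "ffa_c", "tg_c", "glycerol_c", "atp", "adp", "amp", "pi",
    "utp", "udp", "gtp", "gdp"};
  const char* bsn[NB] = {"glucose_b", "lactate_b", "ffa_b", "tg_b",
    "glycerol_b", "insulin", "glucagon"};
  char buf[64];
  if (idx < M.N * NH) {
    snprintf(buf, sizeof(buf), "%s (hepatocyte compartment %d)",
             hs[idx % NH], idx / NH + 1);
  } else if (idx < M.N * (NH + NB)) {
    int k = idx - M.N * NH;
    snprintf(buf, sizeof(buf), "%s (blood compartment %d)",
             bsn[k % NB], k / NB + 1);
  } else {
    snprintf(buf, sizeof(buf), "%s (body pool)", bsn[idx - M.N * (NH + NB)]);
  }
  return std::string(buf);
}

// [[Rcpp::export]]
List hz_core_simulate(NumericVector y0, double t0, int n_steps, double dt,
                      int sample_every, NumericVector phys, NumericVector horm,
                      NumericVector hep, NumericVector kn, NumericVector body,
                      NumericVector scen, NumericVector o2,
                      bool record_rates = true) {
  Model M = build_model(phys, horm, hep, kn, body, scen, o2);
  const int len = M.N * (NH + NB) + NB;
  if (y0.size() != len) stop("core: state length %d, expected %d",
                             (int)y0.size(), len);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(len), k2(len), k3(len), k4(len), tmp(len), ynew(len);
  int n_samp = n_steps / sample_every + 1;
  NumericVector times(n_samp);
  NumericMatrix states(n_samp, len);
  NumericMatrix rmat(record_rates ? n_samp : 1,
                     record_rates ? M.N * NPROC : 1);
  std::vector<double> rbuf(M.N * NPROC);
  int row = 0;
  auto record = [&](double t) {
    times[row] = t;
    for (int i = 0; i < len; ++i) states(row, i) = y[i];
    if (record_rates) {
      derivs(M, t, y.data(), tmp.data(), rbuf.data());
      for (int i = 0; i < M.N * NPROC; ++i) rmat(row, i) = rbuf[i];
    }
    ++row;
  };
  record(t0);
  double t = t0;
  for (int s = 1; s <= n_steps; ++s) {
    int bad = -1;
    if (!rk4_span(M, t, dt, y, k1, k2, k3, k4, tmp, ynew, 0, bad)) {
      stop("integration failed at t = %.3f s: state '%s' went negative or "
           "non-finite despite local step halving", t,
           state_name(M, bad));
    }
    t = t0 + s * dt;
    if (s % sample_every == 0 && row < n_samp) record(t);
  }
  NumericVector y_end(y.begin(), y.end());
  return List::create(_["times"] = times, _["states"] = states,
                      _["rates"] = rmat, _["y_end"] = y_end, _["t_end"] = t);
}
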