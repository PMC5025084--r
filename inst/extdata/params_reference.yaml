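physiology:
  n_comp: 8.0
  V_hep: 1.2
  V_blood: 0.3
  V_body: 15.0
  flow: 0.025
  o2_inlet: 65.0
  o2_outlet: 35.0
  tg_molar_mass: 885.399999999999977
  tissue_density: 1.0
hormones:
  K_I: 0.15
  n_I: 2.0
  K_G: 0.04
  n_G: 2.0
  ins_sec:
    basal: 0.0001
    vmax: 0.0023
    K: 9000.0
    'n': 6.0
  glg_sec:
    basal: 5.0e-06
    vmax: 8.000000000000001e-05
    K: 5000.0
    'n': 4.0
  k_deg_ins_body: 0.0008
  k_deg_glg_body: 0.0008
  hep_extract_ins: 0.551765414968964
  hep_extract_glg: 0.2
hepatic:
  glut:
    vb: 473.835570934257021
    K_glc: 17000.0
  gk:
    vb: 26.185442861347777
    K_glc: 12000.0
    n_glc: 2.0
    K_atp: 400.0
    a_ins: 0.7
    Ki_g6p: 1200.0
  g6pase:
    vb: 16.349726480917329
    K_g6p: 200.0
    b_ins: 0.5
    a_glg: 0.8
  gs:
    vb: 347.810926777329144
    K_g6p: 300.0
    n_g6p: 2.0
    K_utp: 150.0
    K_cap: 350000.0
    n_cap: 4.0
    a_ins: 0.8
    b_glg: 0.5
  gp:
    vb: 8.465246405361288
    K_gly: 150000.0
    K_pi: 1500.0
    b_ins: 0.7
    a_glg: 0.8
  pfk:
    vb: 11.825568062662233
    K_g6p: 250.0
    n_g6p: 2.0
    K_atp: 400.0
    a_ins: 0.5
  pk:
    vb: 24.694292335861451
    K_g3p: 1500.0
    K_adp: 400.0
    K_pi: 800.0
    a_ins: 0.3
  pepck:
    vb: 9.639427703351009
    K_lac: 800.0
    K_atp: 400.0
    K_gtp: 80.0
    b_ins: 0.6
    a_glg: 0.6
  fbp:
    vb: 51.345517057106143
    K_g3p: 400.0
    n_g3p: 2.0
    b_ins: 0.4
    a_glg: 0.3
  pdh:
    vb: 11.048746245097581
    K_lac: 800.0
    Ki_acoa: 120.0
    a_ins: 0.4
  boxi:
    vb: 1.2
    K_ffa: 12.0
    Ki_acoa: 128.752219570514484
    ni_acoa: 2.0
    K_atp: 400.0
    b_ins: 0.1
  atps:
    vb: 26.124529092737767
    K_acoa: 15.0
    K_adp: 100.0
    K_pi: 800.0
    K_o2: 30.0
  ndkg:
    vb: 40.0
    K_gdp: 60.0
    K_atp: 400.0
  ndku:
    vb: 30.0
    K_udp: 60.0
    K_atp: 400.0
  ak:
    vb: 2.0e-05
  atpu:
    vb: 252.12353276630904
    K_atp: 2500.0
  preg:
    k_relax: 0.005
    pi_set: 4000.0
  lgen:
    vb: 7.791843137215719
    K_acoa: 20.0
    n_acoa: 1.0
    K_atp: 150.0
    Ki_ffa: 100.0
    ni_ffa: 2.0
    a_ins: 0.92
    K_g6p: 300.0
  tsyn:
    vb: 19.922409831531564
    K_g3p: 460.0
    K_ffa: 882.696809084177744
    K_atp: 150.0
    a_ins: 0.7
  lply:
    vb: 1.2
    K_tg: 200000.0
    b_ins: 0.3
    a_glg: 0.3
    n_tg: 2.0
  gconv:
    vb: 0.6
    K_glyc: 150.0
    K_atp: 400.0
  lact:
    vb: 363.999999999999659
    K_lac: 1500.0
  ffa_up:
    vb: 8.666569626394953
    K_ffab: 800.0
    passive_frac: 0.2
    K_scav: 0.15
    n_scav: 2.0
    scav_inh: 1.0
  ffa_rel:
    vb: 2.0
    K_ffa: 150.0
    n_ffa: 2.0
  tg_up:
    vb: 0.199012554657213
    K_tgb: 1500.0
  vldl:
    vb: 0.324841305020318
    K_tg: 60000.0
  glyt:
    vb: 1.932
    K_glyc: 150.0
zonation:
  glut: 0.0
  gk: -0.428571428571429
  g6pase: 0.310344827586207
  gs: 0.5
  gp: 0.0
  pfk: 0.0
  pk: -0.354838709677419
  pepck: 0.411764705882353
  fbp: 0.272727272727273
  pdh: 0.0
  boxi: 0.230769230769231
  atps: 0.2
  ndkg: 0.0
  ndku: 0.0
  ak: 0.0
  atpu: 0.0
  preg: 0.0
  lgen: -0.230769230769231
  tsyn: 0.0
  lply: 0.0
  gconv: 0.0
  lact: 0.0
  ffa_up: 0.2
  ffa_rel: 0.0
  tg_up: 0.0
  vldl: 0.0
  glyt: 0.0
  ins_recept: -0.148936170212766
  glg_recept: 0.148936170212766
body:
  a_lgen:
    vb: 0.003
    K_glc: 8000.0
    n_glc: 2.0
    K_ins: 0.15
    n_ins: 2.0
  a_lply:
    vb: 0.74
    K_tg: 6000.0
    ins_frac: 0.65
    K_ins: 0.15
    n_ins: 2.0
  gut_tsyn:
    vb: 0.156281371476164
    K_ffa: 400.0
    K_glyc: 100.0
  mus_glc:
    vb: 21.839152119700746
    K_glc: 30000.0
    ins_frac: 0.85
    K_ins: 0.2
    n_ins: 2.0
  mus_ffa:
    vb: 1.3
    K_ffa: 300.0
    ins_frac: 0.0
    K_ins: 0.15
    n_ins: 2.0
  lac_prod:
    vb: 0.870560636182903
    K_glc: 7000.0
  renal:
    k: 0.0004
    thresh: 10000.0
  lac_use:
    vb: 0.983875383718111
    K_lac: 1500.0
  glyc_use:
    vb: 0.2
    K_glyc: 200.0
inputs:
  cycle_hours: 4.0
  carb_grams: 78.099999999999994
  lipid_grams: 22.199999999999999
  glucose_mw: 180.159999999999997
  ffa_mw: 256.399999999999977
  const_glucose: 1.282547349946227
  const_ffa: 0.831204070016452
numerics:
  dt: 0.05
  sample_dt: 60.0
  cycle_tol: 0.0001
  max_cycles: 400.0
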