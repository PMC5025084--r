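# Reference (pure R) evaluation of the zonated rate laws.
#
# This is the package's readable specification of every rate law. The
# compiled integration core reimplements the same formulas for speed; the
# two implementations are cross-checked on random states in the test suite.
#
# Every hepatic rate has the form
#   rate = vb * m_i * prod(substrate Hill terms) * prod(allosteric terms)
#          * hormone factor * (oxygen factor, oxidative phosphorylation only)
# with m_i = 1 + k_n * x_i the linear zonation multiplier. Reversible
# membrane transport is the difference of two saturable unidirectional
# terms; adenylate kinase is reversible mass action; inorganic phosphate
# regulation is a first-order relaxation toward a set-point.

# Hormone response factors: a process with activation strength a responds as
# (1-a) + a*H(hormone); strength 0 means hormone-independent.
f_act <- function(h, strength, K, n) (1 - strength) + strength * hill_term(h, K, n)
f_inh <- function(h, strength, K, n) {
  (1 - strength) + strength * hill_term(h, K, n, "inhibition")
}

#' Rate of one hepatic process in one compartment
#'
#' Reference implementation of the zonated Hill-form rate law for a single
#' process. Used for documentation, audits and as the oracle against which
#' the compiled core is tested.
#'
#' @param process a `hz_process` from [process_table()], or a process name
#'   (resolved against `params`).
#' @param hep named numeric vector over [hep_species()] (uM).
#' @param blood named numeric vector over [blood_species()] (uM; hormones nM).
#' @param scenario scenario object or list with `K_IR`, `srebp1c` (default
#'   metabolically healthy).
#' @param compartment compartment index (1 = periportal).
#' @param params parameter list; used to resolve the process, the hormone
#'   constants and the compartment grid.
#' @param o2 local oxygen tension (mmHg); defaults to the fixed gradient
#'   value for the compartment.
#' @return rate in uM/s (signed for reversible processes).
#' @export
process_rate <- function(process, hep, blood, scenario = NULL,
                         compartment = 1, params = default_params(),
                         o2 = NULL) {
  if (is.character(process)) {
    tab <- process_table(params)
    if (!process %in% names(tab)) {
      stop("process_rate: unknown process '", process, "'")
    }
    process <- tab[[process]]
  }
  if (is.null(scenario)) scenario <- list(K_IR = 1, srebp1c = FALSE)
  n_comp <- params$physiology$n_comp
  if (compartment < 1 || compartment > n_comp) {
    stop("process_rate: compartment index out of range")
  }
  if (is.null(o2)) o2 <- oxygen_profile(params)[compartment]
  x <- zonation_positions(n_comp)[compartment]
  m <- 1 + process$k_n * x
  kn <- params$zonation
  hz <- params$hormones
  ins_sensed <- blood[["insulin"]] * (1 + kn$ins_recept * x)
  glg_sensed <- blood[["glucagon"]] * (1 + kn$glg_recept * x)
  eh <- effective_hormones(ins_sensed, glg_sensed, scenario, process$name)
  ins <- eh$insulin_eff
  glg <- eh$glucagon_eff
  p <- process$pars
  H <- hill_term
  Hi <- function(c, K, n = 1) hill_term(c, K, n, "inhibition")
  fI <- function(a) f_act(ins, a, hz$K_I, hz$n_I)
  fIi <- function(b) f_inh(ins, b, hz$K_I, hz$n_I)
  fG <- function(a) f_act(glg, a, hz$K_G, hz$n_G)
  fGi <- function(b) f_inh(glg, b, hz$K_G, hz$n_G)

  switch(process$name,
    glut = p$vb * m * (H(blood[["glucose_b"]], p$K_glc) - H(hep[["glucose_c"]], p$K_glc)),
    gk = p$vb * m * H(hep[["glucose_c"]], p$K_glc, p$n_glc) *
      H(hep[["atp"]], p$K_atp) * Hi(hep[["g6p"]], p$Ki_g6p) * fI(p$a_ins),
    g6pase = p$vb * m * H(hep[["g6p"]], p$K_g6p) * fIi(p$b_ins) * fG(p$a_glg),
    gs = p$vb * m * H(hep[["g6p"]], p$K_g6p, p$n_g6p) * H(hep[["utp"]], p$K_utp) *
      Hi(hep[["glycogen"]], p$K_cap, p$n_cap) * fI(p$a_ins) * fGi(p$b_glg),
    gp = p$vb * m * H(hep[["glycogen"]], p$K_gly) * H(hep[["pi"]], p$K_pi) *
      fIi(p$b_ins) * fG(p$a_glg),
    pfk = p$vb * m * H(hep[["g6p"]], p$K_g6p, p$n_g6p) *
      H(hep[["atp"]], p$K_atp) * fI(p$a_ins),
    pk = p$vb * m * H(hep[["g3p_gadp"]], p$K_g3p) * H(hep[["adp"]], p$K_adp) *
      H(hep[["pi"]], p$K_pi) * fI(p$a_ins),
    pepck = p$vb * m * H(hep[["pyr_lac"]], p$K_lac) * H(hep[["atp"]], p$K_atp) *
      H(hep[["gtp"]], p$K_gtp) * fIi(p$b_ins) * fG(p$a_glg),
    fbp = p$vb * m * H(hep[["g3p_gadp"]], p$K_g3p, p$n_g3p) *
      fIi(p$b_ins) * fG(p$a_glg),
    pdh = p$vb * m * H(hep[["pyr_lac"]], p$K_lac) *
      Hi(hep[["acetyl_coa"]], p$Ki_acoa) * fI(p$a_ins),
    boxi = p$vb * m * H(hep[["ffa_c"]], p$K_ffa) *
      Hi(hep[["acetyl_coa"]], p$Ki_acoa, p$ni_acoa) *
      H(hep[["atp"]], p$K_atp) * fIi(p$b_ins),
    atps = p$vb * m * H(hep[["acetyl_coa"]], p$K_acoa) * H(hep[["adp"]], p$K_adp) *
      H(hep[["pi"]], p$K_pi) * H(o2, p$K_o2),
    ndkg = p$vb * m * H(hep[["gdp"]], p$K_gdp) * H(hep[["atp"]], p$K_atp),
    ndku = p$vb * m * H(hep[["udp"]], p$K_udp) * H(hep[["atp"]], p$K_atp),
    ak = p$vb * (hep[["atp"]] * hep[["amp"]] - hep[["adp"]]^2),
    atpu = p$vb * m * H(hep[["atp"]], p$K_atp),
    preg = p$k_relax * (hep[["pi"]] - p$pi_set),
    # G6P activation: glucose induction of the lipogenic programme, which
    # follows the pericentral accumulation of phosphorylated intermediates
    lgen = p$vb * m * H(hep[["acetyl_coa"]], p$K_acoa, p$n_acoa) *
      H(hep[["g6p"]], p$K_g6p) * H(hep[["atp"]], p$K_atp) *
      Hi(hep[["ffa_c"]], p$Ki_ffa, p$ni_ffa) * fI(p$a_ins),
    tsyn = p$vb * m * H(hep[["g3p_gadp"]], p$K_g3p) * H(hep[["ffa_c"]], p$K_ffa) *
      H(hep[["atp"]], p$K_atp) * fI(p$a_ins),
    # n_tg = 2 makes droplet lipolysis negligible in healthy liver but
    # substantial in steatosis (droplet surface area scaling)
    lply = p$vb * m * H(hep[["tg_c"]], p$K_tg, p$n_tg) *
      fIi(p$b_ins) * fG(p$a_glg),
    gconv = p$vb * m * H(hep[["glycerol_c"]], p$K_glyc) * H(hep[["atp"]], p$K_atp),
    lact = p$vb * m * (H(blood[["lactate_b"]], p$K_lac) - H(hep[["pyr_lac"]], p$K_lac)),
    ffa_up = p$vb * m * H(blood[["ffa_b"]], p$K_ffab) *
      (p$passive_frac + (1 - p$passive_frac) *
         (if (isTRUE(p$scav_inh == 1)) Hi(ins, p$K_scav, p$n_scav)
          else H(ins, p$K_scav, p$n_scav))),
    ffa_rel = p$vb * m * H(hep[["ffa_c"]], p$K_ffa, p$n_ffa),
    tg_up = p$vb * m * H(blood[["tg_b"]], p$K_tgb),
    vldl = p$vb * m * H(hep[["tg_c"]], p$K_tg),
    glyt = p$vb * m * (H(blood[["glycerol_b"]], p$K_glyc) - H(hep[["glycerol_c"]], p$K_glyc)),
    stop("process_rate: no rate law for '", process$name, "'")
  )
}

#' All hepatic process rates in one compartment
#'
#' @inheritParams process_rate
#' @return named numeric vector over [process_names()] (uM/s).
#' @export
compartment_rates <- function(hep, blood, scenario = NULL, compartment = 1,
                              params = default_params(), o2 = NULL) {
  tab <- process_table(params)
  vapply(tab, function(pr) {
    process_rate(pr, hep, blood, scenario, compartment, params, o2)
  }, numeric(1))
}

# Body-compartment process rates (uM/s on the body-volume scale).
body_rates <- function(body, scenario, params, t = 0) {
  bp <- params$body
  H <- hill_term
  Hi <- function(c, K, n = 1) hill_term(c, K, n, "inhibition")
  ins_eff <- scenario$K_IR * body[["insulin"]]
  list(
    a_lgen = bp$a_lgen$vb * H(body[["glucose_b"]], bp$a_lgen$K_glc, bp$a_lgen$n_glc) *
      H(ins_eff, bp$a_lgen$K_ins, bp$a_lgen$n_ins),
    a_lply = bp$a_lply$vb * H(body[["tg_b"]], bp$a_lply$K_tg) *
      ((1 - bp$a_lply$ins_frac) +
         bp$a_lply$ins_frac * Hi(ins_eff, bp$a_lply$K_ins, bp$a_lply$n_ins)),
    gut_tsyn = bp$gut_tsyn$vb * H(body[["ffa_b"]], bp$gut_tsyn$K_ffa) *
      H(body[["glycerol_b"]], bp$gut_tsyn$K_glyc),
    mus_glc = bp$mus_glc$vb * H(body[["glucose_b"]], bp$mus_glc$K_glc) *
      ((1 - bp$mus_glc$ins_frac) +
         bp$mus_glc$ins_frac * H(ins_eff, bp$mus_glc$K_ins, bp$mus_glc$n_ins)),
    mus_ffa = bp$mus_ffa$vb * H(body[["ffa_b"]], bp$mus_ffa$K_ffa) *
      ((1 - bp$mus_ffa$ins_frac) +
         bp$mus_ffa$ins_frac * Hi(ins_eff, bp$mus_ffa$K_ins, bp$mus_ffa$n_ins)),
    lac_prod = bp$lac_prod$vb * H(body[["glucose_b"]], bp$lac_prod$K_glc),
    lac_use = bp$lac_use$vb * H(body[["lactate_b"]], bp$lac_use$K_lac),
    glyc_use = bp$glyc_use$vb * H(body[["glycerol_b"]], bp$glyc_use$K_glyc),
    renal = bp$renal$k * max(0, body[["glucose_b"]] - bp$renal$thresh)
  )
}

#' Body-compartment derivative contributions from non-hepatic physiology
#'
#' Adipose lipogenesis (4 glucose -> 1 FFA), adipose lipolysis (TG -> 3 FFA
#' + glycerol), gut triglyceride synthesis (3 FFA + glycerol -> TG), muscle
#' glucose/FFA consumption, peripheral lactate production, pancreatic
#' hormone secretion, hormone degradation, and the feeding inputs. Advective
#' exchange with the sinusoid is excluded here (see the full model
#' derivative).
#'
#' @param body named vector over [blood_species()] for the systemic pool.
#' @param scenario scenario object.
#' @param params parameter list.
#' @param t time in seconds (for the feeding waveform).
#' @return named numeric vector of d/dt (uM/s; hormones nM/s).
#' @export
body_derivatives <- function(body, scenario, params = default_params(), t = 0) {
  r <- body_rates(body, scenario, params, t)
  hz <- params$hormones
  sec_i <- hz$ins_sec$basal +
    hz$ins_sec$vmax * hill_term(body[["glucose_b"]], hz$ins_sec$K, hz$ins_sec$n)
  sec_g <- hz$glg_sec$basal +
    hz$glg_sec$vmax * hill_term(body[["glucose_b"]], hz$glg_sec$K, hz$glg_sec$n, "inhibition")
  inp <- feeding_input(t / 3600, scenario, params)
  d <- c(
    glucose_b = -4 * r$a_lgen - r$mus_glc - r$lac_prod - r$renal + inp$glucose,
    lactate_b = 2 * r$lac_prod - r$lac_use,
    ffa_b = r$a_lgen + 3 * r$a_lply - 3 * r$gut_tsyn - r$mus_ffa + inp$ffa,
    tg_b = -r$a_lply + r$gut_tsyn,
    # dietary lipid hydrolysis supplies one glycerol per three fatty acids
    glycerol_b = r$a_lply - r$gut_tsyn - r$glyc_use + inp$ffa / 3,
    insulin = sec_i - hz$k_deg_ins_body * body[["insulin"]],
    glucagon = sec_g - hz$k_deg_glg_body * body[["glucagon"]]
  )
  d
}
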