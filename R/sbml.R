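# Export of the single-compartment kinetic core to SBML Level 3 Version 2,
# for cross-tool checking of the hepatic reaction network. The export
# covers one hepatocyte compartment plus its local blood species (boundary
# conditions), with full kinetic laws in MathML.

mml_cn <- function(x) sprintf("<cn>%.10g</cn>", x)
mml_ci <- function(x) sprintf("<ci>%s</ci>", x)
mml_apply <- function(op, ...) {
  paste0("<apply><", op, "/>", paste0(..., collapse = ""), "</apply>")
}
mml_pow <- function(a, n) {
  if (n == 1) a else mml_apply("power", a, mml_cn(n))
}
# c^n / (K^n + c^n)  or  K^n / (K^n + c^n)
mml_hill <- function(species, K, n = 1, mode = "act") {
  cn <- mml_pow(mml_ci(species), n)
  Kn <- mml_pow(mml_cn(K), n)
  num <- if (mode == "act") cn else Kn
  mml_apply("divide", num, mml_apply("plus", Kn, cn))
}
# (1-a) + a*hill
mml_hfactor <- function(species, a, K, n, mode) {
  if (a == 0) return(NULL)
  mml_apply("plus", mml_cn(1 - a),
            mml_apply("times", mml_cn(a), mml_hill(species, K, n, mode)))
}
mml_times <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  if (length(parts) == 1) return(parts[[1]])
  mml_apply("times", paste0(unlist(parts), collapse = ""))
}

# MathML kinetic law for one process in a single mid-sinusoid compartment
# (zonation multiplier 1, oxygen at the sinusoid mean).
process_mathml <- function(pr, params, o2_mid) {
  p <- pr$pars
  hz <- params$hormones
  vb <- mml_cn(p$vb)
  fI <- function(a) mml_hfactor("insulin", a, hz$K_I, hz$n_I, "act")
  fIi <- function(b) mml_hfactor("insulin", b, hz$K_I, hz$n_I, "inh")
  fG <- function(a) mml_hfactor("glucagon", a, hz$K_G, hz$n_G, "act")
  fGi <- function(b) mml_hfactor("glucagon", b, hz$K_G, hz$n_G, "inh")
  H <- mml_hill
  body <- switch(pr$name,
    glut = mml_times(vb, mml_apply("minus", H("glucose_b", p$K_glc),
                                   H("glucose_c", p$K_glc))),
    gk = mml_times(vb, H("glucose_c", p$K_glc, p$n_glc), H("atp", p$K_atp),
                   H("g6p", p$Ki_g6p, 1, "inh"), fI(p$a_ins)),
    g6pase = mml_times(vb, H("g6p", p$K_g6p), fIi(p$b_ins), fG(p$a_glg)),
    gs = mml_times(vb, H("g6p", p$K_g6p, p$n_g6p), H("utp", p$K_utp),
                   H("glycogen", p$K_cap, p$n_cap, "inh"), fI(p$a_ins),
                   fGi(p$b_glg)),
    gp = mml_times(vb, H("glycogen", p$K_gly), H("pi", p$K_pi),
                   fIi(p$b_ins), fG(p$a_glg)),
    pfk = mml_times(vb, H("g6p", p$K_g6p, p$n_g6p), H("atp", p$K_atp),
                    fI(p$a_ins)),
    pk = mml_times(vb, H("g3p_gadp", p$K_g3p), H("adp", p$K_adp),
                   H("pi", p$K_pi), fI(p$a_ins)),
    pepck = mml_times(vb, H("pyr_lac", p$K_lac), H("atp", p$K_atp),
                      H("gtp", p$K_gtp), fIi(p$b_ins), fG(p$a_glg)),
    fbp = mml_times(vb, H("g3p_gadp", p$K_g3p, p$n_g3p), fIi(p$b_ins),
                    fG(p$a_glg)),
    pdh = mml_times(vb, H("pyr_lac", p$K_lac),
                    H("acetyl_coa", p$Ki_acoa, 1, "inh"), fI(p$a_ins)),
    boxi = mml_times(vb, H("ffa_c", p$K_ffa),
                     H("acetyl_coa", p$Ki_acoa, p$ni_acoa, "inh"),
                     H("atp", p$K_atp), fIi(p$b_ins)),
    atps = mml_times(vb, H("acetyl_coa", p$K_acoa), H("adp", p$K_adp),
                     H("pi", p$K_pi), mml_cn(o2_mid / (p$K_o2 + o2_mid))),
    ndkg = mml_times(vb, H("gdp", p$K_gdp), H("atp", p$K_atp)),
    ndku = mml_times(vb, H("udp", p$K_udp), H("atp", p$K_atp)),
    ak = mml_times(vb, mml_apply("minus",
           mml_apply("times", mml_ci("atp"), mml_ci("amp")),
           mml_pow(mml_ci("adp"), 2))),
    atpu = mml_times(vb, H("atp", p$K_atp)),
    preg = mml_times(mml_cn(p$k_relax),
                     mml_apply("minus", mml_ci("pi"), mml_cn(p$pi_set))),
    lgen = mml_times(vb, H("acetyl_coa", p$K_acoa, p$n_acoa),
                     H("g6p", p$K_g6p), H("atp", p$K_atp),
                     H("ffa_c", p$Ki_ffa, p$ni_ffa, "inh"), fI(p$a_ins)),
    tsyn = mml_times(vb, H("g3p_gadp", p$K_g3p), H("ffa_c", p$K_ffa),
                     H("atp", p$K_atp), fI(p$a_ins)),
    lply = mml_times(vb, H("tg_c", p$K_tg), fIi(p$b_ins), fG(p$a_glg)),
    gconv = mml_times(vb, H("glycerol_c", p$K_glyc), H("atp", p$K_atp)),
    lact = mml_times(vb, mml_apply("minus", H("lactate_b", p$K_lac),
                                   H("pyr_lac", p$K_lac))),
    ffa_up = mml_times(vb, H("ffa_b", p$K_ffab),
                       mml_apply("plus", mml_cn(p$passive_frac),
                                 mml_apply("times", mml_cn(1 - p$passive_frac),
                                           mml_hill("insulin", p$K_scav,
                                                    p$n_scav)))),
    ffa_rel = mml_times(vb, H("ffa_c", p$K_ffa)),
    tg_up = mml_times(vb, H("tg_b", p$K_tgb)),
    vldl = mml_times(vb, H("tg_c", p$K_tg)),
    glyt = mml_times(vb, mml_apply("minus", H("glycerol_b", p$K_glyc),
                                   H("glycerol_c", p$K_glyc)))
  )
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', body, "</math>")
}

#' Export the single-compartment kinetic core as SBML Level 3
#'
#' Writes the 17 hepatocyte species, the local blood species (as boundary
#' species), and all 27 directional processes of one mid-sinusoid
#' compartment (zonation multiplier 1, oxygen at the sinusoid mean) with
#' full MathML kinetic laws, for cross-checking in SBML-aware tools.
#'
#' @param params parameter list.
#' @param file output path for the `.sbml`/`.xml` file.
#' @param initial_hep,initial_blood optional named initial concentrations.
#' @return the file path, invisibly.
#' @export
export_sbml <- function(params = reference_params(), file,
                        initial_hep = NULL, initial_blood = NULL) {
  tab <- process_table(params)
  o2_mid <- mean(oxygen_profile(params))
  if (is.null(initial_hep)) {
    initial_hep <- stats::setNames(rep(100, 17), hep_species())
  }
  if (is.null(initial_blood)) {
    initial_blood <- stats::setNames(rep(100, 7), blood_species())
  }
  sp_xml <- c(
    vapply(hep_species(), function(s) sprintf(
      '<species id="%s" compartment="hepatocyte" initialConcentration="%g" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      s, initial_hep[[s]]), character(1)),
    vapply(blood_species(), function(s) sprintf(
      '<species id="%s" compartment="blood" initialConcentration="%g" hasOnlySubstanceUnits="false" boundaryCondition="true" constant="false"/>',
      s, initial_blood[[s]]), character(1))
  )
  rx_xml <- vapply(tab, function(pr) {
    st <- c(pr$stoich, pr$blood_stoich)
    reac <- st[st < 0]
    prod <- st[st > 0]
    fmt <- function(v) paste(vapply(names(v), function(s) sprintf(
      '<speciesReference species="%s" stoichiometry="%g" constant="true"/>',
      s, abs(v[[s]])), character(1)), collapse = "")
    paste0(
      sprintf('<reaction id="R_%s" name="%s" reversible="%s">', pr$name,
              pr$label, tolower(as.character(pr$reversible))),
      if (length(reac)) paste0("<listOfReactants>", fmt(reac),
                               "</listOfReactants>") else "",
      if (length(prod)) paste0("<listOfProducts>", fmt(prod),
                               "</listOfProducts>") else "",
      "<kineticLaw>", process_mathml(pr, params, o2_mid), "</kineticLaw>",
      "</reaction>")
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="hepatocyte_core" name="Zonated hepatocyte kinetic core (single compartment)">',
    '<listOfCompartments>',
    '<compartment id="hepatocyte" spatialDimensions="3" size="1" constant="true"/>',
    '<compartment id="blood" spatialDimensions="3" size="0.25" constant="true"/>',
    '</listOfCompartments>',
    '<listOfSpecies>', paste0(sp_xml, collapse = ""), '</listOfSpecies>',
    '<listOfReactions>', paste0(rx_xml, collapse = ""), '</listOfReactions>',
    '</model></sbml>'
  )
  # validate well-formedness before writing
  parsed <- xml2::read_xml(doc)
  xml2::write_xml(parsed, file)
  invisible(file)
}
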