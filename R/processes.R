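# Model structure: species, hepatic processes, stoichiometry.
#
# Stoichiometry follows the hepatic rate-equation table of the model exactly,
# including the fractional ATP coefficients (3.25 on glycolysis stage 2, 2.5
# on pyruvate oxidation, 2.25/2.5 on inorganic phosphate) that encode the
# indirect NADH-derived ATP of the lumped stages, and the coefficient 12 on
# ATP synthesis from acetyl-CoA.

#' Names of the intracellular (hepatocyte) species
#' @return character vector of length 17.
#' @export
hep_species <- function() {
  c("glucose_c", "g6p", "glycogen", "g3p_gadp", "pyr_lac", "acetyl_coa",
    "ffa_c", "tg_c", "glycerol_c", "atp", "adp", "amp", "pi",
    "utp", "udp", "gtp", "gdp")
}

#' Names of the dynamic blood species (per sinusoid compartment and body pool)
#'
#' Oxygen is carried alongside these as a fixed porto-central gradient and is
#' not a dynamic state of the full model (see [oxygen_profile()]).
#' @return character vector of length 7.
#' @export
blood_species <- function() {
  c("glucose_b", "lactate_b", "ffa_b", "tg_b", "glycerol_b",
    "insulin", "glucagon")
}

#' Internal (directional) hepatic process identifiers
#' @return character vector of length 27.
#' @export
process_names <- function() {
  c("glut", "gk", "g6pase", "gs", "gp", "pfk", "pk", "pepck", "fbp",
    "pdh", "boxi", "atps", "ndkg", "ndku", "ak", "atpu", "preg",
    "lgen", "tsyn", "lply", "gconv", "lact",
    "ffa_up", "ffa_rel", "tg_up", "vldl", "glyt")
}

# Stoichiometry of each directional process on the 17 hepatocyte species.
# Reversible membrane transport carries a signed rate; uptake/release and
# VLDL/TG-uptake are split into separate directional processes because their
# forward and backward constants differ and are perturbed independently in
# the sensitivity protocols (net R_FFAt = ffa_up - ffa_rel, net R_TGt =
# tg_up - vldl).
hep_stoich_list <- function() {
  list(
    glut   = c(glucose_c = 1),
    gk     = c(glucose_c = -1, g6p = 1, atp = -1, adp = 1),
    g6pase = c(g6p = -1, glucose_c = 1, pi = 1),
    gs     = c(g6p = -1, glycogen = 1, utp = -1, udp = 1, pi = 2),
    gp     = c(glycogen = -1, g6p = 1, pi = -1),
    pfk    = c(g6p = -1, g3p_gadp = 2, atp = -1, adp = 1),
    pk     = c(g3p_gadp = -1, pyr_lac = 1, atp = 3.25, adp = -3.25, pi = -2.25),
    pepck  = c(pyr_lac = -1, g3p_gadp = 1, atp = -2, adp = 2,
               gtp = -1, gdp = 1, pi = 2),
    fbp    = c(g3p_gadp = -2, g6p = 1, pi = 1),
    pdh    = c(pyr_lac = -1, acetyl_coa = 1, atp = 2.5, adp = -2.5, pi = -2.5),
    # Pi coefficient 1 per the rate-equation table (the process conversion
    # string would read 3; the rate-equation table is authoritative).
    boxi   = c(ffa_c = -1, acetyl_coa = 8, atp = -2, adp = 1, amp = 1, pi = 1),
    atps   = c(acetyl_coa = -1, atp = 12, adp = -12, pi = -12),
    ndkg   = c(gdp = -1, gtp = 1, atp = -1, adp = 1),
    ndku   = c(udp = -1, utp = 1, atp = -1, adp = 1),
    ak     = c(atp = -1, amp = -1, adp = 2),
    atpu   = c(atp = -1, adp = 1, pi = 1),
    preg   = c(pi = -1),
    lgen   = c(acetyl_coa = -8, ffa_c = 1, atp = -7, adp = 7, pi = 7),
    tsyn   = c(ffa_c = -3, g3p_gadp = -1, tg_c = 1, atp = -3, amp = 3, pi = 7),
    lply   = c(tg_c = -1, ffa_c = 3, glycerol_c = 1),
    gconv  = c(glycerol_c = -1, g3p_gadp = 1, atp = -1, adp = 1),
    lact   = c(pyr_lac = 1),
    ffa_up  = c(ffa_c = 1),
    ffa_rel = c(ffa_c = -1),
    tg_up   = c(tg_c = 1),
    vldl    = c(tg_c = -1),
    glyt    = c(glycerol_c = 1)
  )
}

# Blood-side stoichiometry (per unit of cellular rate; the derivative of a
# blood compartment is scaled by the hepatocyte:blood volume ratio).
blood_stoich_list <- function() {
  list(
    glut    = c(glucose_b = -1),
    lact    = c(lactate_b = -1),
    ffa_up  = c(ffa_b = -1),
    ffa_rel = c(ffa_b = 1),
    tg_up   = c(tg_b = -1),
    vldl    = c(tg_b = 1),
    glyt    = c(glycerol_b = -1)
  )
}

#' Stoichiometric matrix of the hepatic reaction network
#'
#' @return numeric matrix, 17 hepatocyte species x 27 directional processes.
#' @export
stoichiometry_matrix <- function() {
  sp <- hep_species()
  pr <- process_names()
  S <- matrix(0, length(sp), length(pr), dimnames = list(sp, pr))
  st <- hep_stoich_list()
  for (p in pr) S[names(st[[p]]), p] <- st[[p]]
  S
}

#' Hepatocyte state derivative from a set of process rates
#'
#' Applies the hepatic stoichiometric matrix to a vector of process rates:
#' the exact linear combinations of the model's rate-equation table (e.g.
#' dACoA/dt = R_PDH - 8 R_Lgen + 8 R_boxi - R_ATPS). By construction the
#' adenine, uridine and guanine nucleotide pools have zero net derivative.
#'
#' @param rates named numeric vector containing every name in
#'   [process_names()] (uM/s).
#' @return named numeric vector of d(species)/dt over [hep_species()].
#' @export
hepatic_derivatives <- function(rates) {
  pr <- process_names()
  missing <- setdiff(pr, names(rates))
  if (length(missing)) {
    stop("hepatic_derivatives: missing process rates: ",
         paste(missing, collapse = ", "))
  }
  drop(stoichiometry_matrix() %*% rates[pr])
}

#' Full process definitions
#'
#' Materialises every hepatic process as a `hz_process` record: display
#' label, stoichiometry on the hepatocyte and blood species, zonation
#' constant, kind of rate law, and the rate-law constants drawn from the
#' parameter set.
#'
#' @param params parameter list (see [reference_params()]).
#' @return named list of `hz_process` objects.
#' @export
process_table <- function(params = default_params()) {
  hp <- params$hepatic
  kn <- params$zonation
  labels <- c(
    glut = "Glucose uptake (GLUT2)", gk = "Glucokinase",
    g6pase = "Glucose-6-phosphatase", gs = "Glycogen synthesis",
    gp = "Glycogen phosphorylase", pfk = "Glycolysis 1 (G6P->GADP, PFK)",
    pk = "Glycolysis 2 (GADP->Pyr, PK)",
    pepck = "Gluconeogenesis 1 (Pyr->GADP, PEPCK)",
    fbp = "Gluconeogenesis 2 (GADP->G6P, FBP)",
    pdh = "Pyruvate oxidation (PDH)", boxi = "Beta-oxidation",
    atps = "ATP synthesis (citrate cycle/oxphos)",
    ndkg = "Nucleoside diphosphate kinase (GDP)",
    ndku = "Nucleoside diphosphate kinase (UDP)",
    ak = "Adenylate kinase", atpu = "Cellular ATP consumption",
    preg = "Inorganic phosphate regulation", lgen = "De novo lipogenesis",
    tsyn = "Triglyceride synthesis", lply = "Lipolysis",
    gconv = "Glycerol kinase", lact = "Lactate uptake/output",
    ffa_up = "FFA uptake", ffa_rel = "FFA release",
    tg_up = "Triglyceride uptake", vldl = "Triglyceride release as VLDL",
    glyt = "Glycerol uptake/output"
  )
  kinds <- c(
    glut = "transport_sym", lact = "transport_sym", glyt = "transport_sym",
    ak = "mass_action_ak", preg = "relaxation", atpu = "hill",
    ffa_up = "hill_scav"
  )
  hs <- hep_stoich_list()
  bs <- blood_stoich_list()
  reversible <- c("glut", "lact", "glyt", "ak", "preg")
  out <- lapply(process_names(), function(p) {
    structure(list(
      name = p,
      label = labels[[p]],
      stoich = hs[[p]],
      blood_stoich = if (p %in% names(bs)) bs[[p]] else NULL,
      k_n = kn[[p]],
      pp_pc_ratio = (1 + kn[[p]]) / (1 - kn[[p]]),
      kind = if (p %in% names(kinds)) kinds[[p]] else "hill",
      reversible = p %in% reversible,
      pars = hp[[p]]
    ), class = "hz_process")
  })
  names(out) <- process_names()
  out
}

#' @export
print.hz_process <- function(x, ...) {
  cat(sprintf("<hz_process> %s (%s)\n", x$name, x$label))
  cat("  stoichiometry:",
      paste(sprintf("%+g %s", x$stoich, names(x$stoich)), collapse = ", "), "\n")
  cat(sprintf("  k_n = %.4f (pp:pc endpoint ratio %.3g:1), kind = %s\n",
              x$k_n, x$pp_pc_ratio, x$kind))
  invisible(x)
}
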