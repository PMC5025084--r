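# Shared fixtures: small deterministic states and models built in code.

structural_params <- function() default_params()

test_model <- function(params = structural_params()) sinusoid_model(params)

# a plausible fixed hepatocyte/blood state for rate-law evaluation
fixture_hep <- function() {
  c(glucose_c = 5200, g6p = 150, glycogen = 2e5, g3p_gadp = 130,
    pyr_lac = 900, acetyl_coa = 60, ffa_c = 20, tg_c = 26000,
    glycerol_c = 60, atp = 2600, adp = 700, amp = 188, pi = 4000,
    utp = 300, udp = 100, gtp = 250, gdp = 80)
}
fixture_blood <- function() {
  c(glucose_b = 5030, lactate_b = 1000, ffa_b = 432, tg_b = 1050,
    glycerol_b = 80, insulin = 0.06, glucagon = 0.035)
}

random_state <- function(model, seed = 1) {
  set.seed(seed)
  n <- model$n_comp
  hep <- matrix(runif(n * 17, 1, 5000), n, 17,
                dimnames = list(NULL, hep_species()))
  blood <- matrix(runif(n * 7, 0.01, 5000), n, 7,
                  dimnames = list(NULL, blood_species()))
  body <- setNames(runif(7, 0.01, 5000), blood_species())
  pack_state(hep, blood, body)
}

# a model with every process, input and hormone source switched off:
# the state is then an exact fixed point of the dynamics only if it is
# uniform along the chain (advection of a uniform field is zero)
inert_params <- function() {
  p <- default_params()
  for (nm in names(p$hepatic)) {
    if (!is.null(p$hepatic[[nm]]$vb)) p$hepatic[[nm]]$vb <- 0
  }
  p$hepatic$preg$k_relax <- 0
  for (nm in c("a_lgen", "a_lply", "gut_tsyn", "mus_glc", "mus_ffa",
               "lac_prod", "lac_use", "glyc_use")) {
    p$body[[nm]]$vb <- 0
  }
  p$body$renal$k <- 0
  p$hormones$ins_sec$basal <- 0; p$hormones$ins_sec$vmax <- 0
  p$hormones$glg_sec$basal <- 0; p$hormones$glg_sec$vmax <- 0
  p$hormones$k_deg_ins_body <- 0; p$hormones$k_deg_glg_body <- 0
  p$hormones$hep_extract_ins <- 0; p$hormones$hep_extract_glg <- 0
  p$inputs$const_glucose <- 0; p$inputs$const_ffa <- 0
  p
}

uniform_state <- function(model, value_hep = 100, value_blood = 50) {
  n <- model$n_comp
  hep <- matrix(value_hep, n, 17, dimnames = list(NULL, hep_species()))
  blood <- matrix(value_blood, n, 7, dimnames = list(NULL, blood_species()))
  body <- setNames(rep(value_blood, 7), blood_species())
  pack_state(hep, blood, body)
}
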