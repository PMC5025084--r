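# Sinusoid assembly: N hepatic compartments in series, plug-flow blood
# advection, body compartment, hormone degradation, fixed oxygen gradient.

#' Construct a sinusoid model
#'
#' Bundles a parameter set with the derived per-compartment quantities:
#' compartment volumes, porto-central positions, the fixed oxygen profile
#' and the per-compartment hormone degradation constants implied by the
#' whole-liver extraction fractions.
#'
#' @param params nested parameter list (default: the calibrated reference
#'   set shipped with the package).
#' @return object of class `hz_model`.
#' @export
sinusoid_model <- function(params = reference_params()) {
  ph <- params$physiology
  n <- ph$n_comp
  if (n < 2) stop("sinusoid_model: need at least 2 compartments")
  if (ph$flow <= 0) stop("sinusoid_model: flow must be > 0")
  if (ph$V_hep <= 0 || ph$V_blood <= 0 || ph$V_body <= 0) {
    stop("sinusoid_model: volumes must be > 0")
  }
  vb_i <- ph$V_blood / n
  vh_i <- ph$V_hep / n
  tau_rate <- ph$flow / vb_i          # 1/s, advective turnover per compartment
  f_ins <- (1 - params$hormones$hep_extract_ins)^(1 / n)
  f_glg <- (1 - params$hormones$hep_extract_glg)^(1 / n)
  structure(list(
    params = params,
    n_comp = n,
    x = zonation_positions(n),
    vb_i = vb_i,
    vh_i = vh_i,
    rho = vh_i / vb_i,                # hepatocyte:blood volume ratio
    tau_rate = tau_rate,
    o2 = oxygen_profile(params),
    f_ins = f_ins,
    f_glg = f_glg,
    kdeg_ins_sin = tau_rate * (1 / f_ins - 1),
    kdeg_glg_sin = tau_rate * (1 / f_glg - 1)
  ), class = "hz_model")
}

#' @export
print.hz_model <- function(x, ...) {
  ph <- x$params$physiology
  cat(sprintf(
    "<hz_model> %d compartments | flow %.3g L/s | V_hep %.3g L, V_blood %.3g L, V_body %.3g L\n",
    x$n_comp, ph$flow, ph$V_hep, ph$V_blood, ph$V_body
  ))
  cat(sprintf("  oxygen %.1f -> %.1f mmHg; insulin survival/compartment %.4f, glucagon %.4f\n",
              ph$o2_inlet, x$o2[x$n_comp], x$f_ins, x$f_glg))
  invisible(x)
}

#' Fixed porto-central oxygen profile
#'
#' Blood oxygen tension in each well-mixed compartment under constant inflow
#' and zero-order consumption, falling linearly from the inlet value to the
#' outlet value (compartment N equals the outlet, since a well-mixed
#' compartment's concentration is its outflow concentration).
#'
#' @param params parameter list.
#' @return numeric vector of length `n_comp` (mmHg).
#' @export
oxygen_profile <- function(params = default_params()) {
  ph <- params$physiology
  n <- ph$n_comp
  ph$o2_inlet - seq_len(n) * (ph$o2_inlet - ph$o2_outlet) / n
}

#' Advective derivatives along the compartment chain
#'
#' Plug flow between well-mixed compartments: compartment 1 is fed by the
#' body pool and compartment N drains into it. For each transported species
#' the contribution is `flow * (c_upstream - c_i) / V_i`; what leaves
#' compartment i enters compartment i+1, so an inert species is conserved to
#' machine precision.
#'
#' @param blood matrix (`n_comp` x species) of compartment concentrations.
#' @param body named vector of body-pool concentrations (same columns).
#' @param flow blood flow (L/s), > 0.
#' @param vb_i per-compartment blood volume (L).
#' @return matrix of d/dt contributions, same shape as `blood`.
#' @export
advection_derivatives <- function(blood, body, flow, vb_i) {
  if (flow <= 0) stop("advection_derivatives: flow must be > 0")
  if (nrow(blood) < 2) stop("advection_derivatives: need >= 2 compartments")
  upstream <- rbind(body[colnames(blood)], blood[-nrow(blood), , drop = FALSE])
  (flow / vb_i) * (upstream - blood)
}

# --- flat state layout -------------------------------------------------
# [ hep compartment 1 (17) | ... | hep compartment N | blood compartment 1
#   (7) | ... | blood compartment N | body (7) ]

#' Pack compartment states into the flat state vector
#' @param hep matrix `n_comp` x 17 (columns [hep_species()]).
#' @param blood matrix `n_comp` x 7 (columns [blood_species()]).
#' @param body named vector over [blood_species()].
#' @return numeric state vector.
#' @export
pack_state <- function(hep, blood, body) {
  unname(c(as.vector(t(hep)), as.vector(t(blood)), body[blood_species()]))
}

#' Unpack the flat state vector
#' @param y numeric state vector.
#' @param n_comp number of compartments.
#' @return list with matrices `hep`, `blood` and vector `body`.
#' @export
unpack_state <- function(y, n_comp) {
  nh <- length(hep_species())
  nb <- length(blood_species())
  stopifnot(length(y) == n_comp * (nh + nb) + nb)
  hep <- matrix(y[seq_len(n_comp * nh)], n_comp, nh, byrow = TRUE,
                dimnames = list(NULL, hep_species()))
  blood <- matrix(y[n_comp * nh + seq_len(n_comp * nb)], n_comp, nb,
                  byrow = TRUE, dimnames = list(NULL, blood_species()))
  body <- y[n_comp * (nh + nb) + seq_len(nb)]
  names(body) <- blood_species()
  list(hep = hep, blood = blood, body = body)
}

#' Full model derivative (reference implementation)
#'
#' Pure-R evaluation of the complete state derivative: hepatic reaction
#' network in every compartment (via the stoichiometric matrix), blood-side
#' exchange scaled by the hepatocyte:blood volume ratio, plug-flow
#' advection, sinusoidal hormone degradation and the body compartment. The
#' compiled core is cross-checked against this function.
#'
#' @param y flat state vector.
#' @param t time (s).
#' @param model `hz_model`.
#' @param scenario scenario object.
#' @return list with `dy` (flat derivative) and `rates` (matrix `n_comp` x
#'   27 of hepatic process rates).
#' @export
model_derivatives <- function(y, t, model, scenario) {
  params <- model$params
  n <- model$n_comp
  st <- unpack_state(y, n)
  S <- stoichiometry_matrix()
  bs <- blood_stoich_list()
  pr <- process_names()
  dhep <- matrix(0, n, length(hep_species()),
                 dimnames = list(NULL, hep_species()))
  dblood <- matrix(0, n, length(blood_species()),
                   dimnames = list(NULL, blood_species()))
  rates <- matrix(0, n, length(pr), dimnames = list(NULL, pr))
  for (i in seq_len(n)) {
    r <- compartment_rates(st$hep[i, ], st$blood[i, ], scenario, i,
                           params, model$o2[i])
    rates[i, ] <- r
    dhep[i, ] <- drop(S %*% r)
    for (p in names(bs)) {
      dblood[i, names(bs[[p]])] <- dblood[i, names(bs[[p]])] +
        model$rho * bs[[p]] * r[[p]]
    }
  }
  dblood <- dblood + advection_derivatives(st$blood, st$body,
                                           params$physiology$flow, model$vb_i)
  dblood[, "insulin"] <- dblood[, "insulin"] - model$kdeg_ins_sin * st$blood[, "insulin"]
  dblood[, "glucagon"] <- dblood[, "glucagon"] - model$kdeg_glg_sin * st$blood[, "glucagon"]
  dbody <- body_derivatives(st$body, scenario, params, t)
  tau_body <- params$physiology$flow / params$physiology$V_body
  dbody <- dbody + tau_body * (st$blood[n, ] - st$body)
  list(dy = pack_state(dhep, dblood, dbody), rates = rates)
}
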