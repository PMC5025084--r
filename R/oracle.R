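# Theoretical decay profiles used to verify the transport chain, and the
# pancreatic secretion laws.

#' Theoretical porto-central concentration profile
#'
#' Closed-form steady-state profile of a species consumed along the
#' compartment chain, used as the verification oracle for oxygen
#' (zero-order consumption: linear decline) and the hormones (first-order
#' degradation: geometric decline). For well-mixed compartments in series
#' the steady solutions are exactly `c_in - i * rate` (zero-order, with
#' `rate` the drop per compartment) and `c_in * f^i` (first-order, with
#' `f` the per-compartment survival fraction `1/(1 + k tau)`).
#'
#' @param c_in inflow concentration (>= 0).
#' @param mode `"zero-order"` or `"first-order"`.
#' @param rate drop per compartment (zero-order) or survival fraction per
#'   compartment (first-order, in (0, 1]).
#' @param n_comp number of compartments.
#' @return numeric vector of per-compartment concentrations.
#' @export
gradient_oracle <- function(c_in, mode = c("zero-order", "first-order"),
                            rate, n_comp = 8) {
  mode <- match.arg(mode)
  if (c_in < 0) stop("gradient_oracle: c_in must be >= 0")
  i <- seq_len(n_comp)
  if (mode == "zero-order") {
    out <- c_in - i * rate
    if (any(out < 0)) {
      stop("gradient_oracle: zero-order profile goes negative; ",
           "consumption inconsistent with the inflow concentration")
    }
    out
  } else {
    if (rate <= 0 || rate > 1) {
      stop("gradient_oracle: first-order survival fraction must be in (0, 1]")
    }
    c_in * rate^i
  }
}

#' Pancreatic hormone secretion rates
#'
#' Sigmoidal (Hill-form) glucose dependence: insulin secretion is a bounded
#' increasing function of body glucose, glucagon secretion a bounded
#' decreasing one, each with a basal floor.
#'
#' @param glucose_body body-pool glucose (uM), >= 0.
#' @param params parameter list.
#' @return list with `insulin` and `glucagon` secretion rates (nM/s on the
#'   body-volume scale).
#' @export
pancreas_rates <- function(glucose_body, params = default_params()) {
  if (any(glucose_body < 0)) stop("pancreas_rates: glucose must be >= 0")
  hz <- params$hormones
  list(
    insulin = hz$ins_sec$basal +
      hz$ins_sec$vmax * hill_term(glucose_body, hz$ins_sec$K, hz$ins_sec$n),
    glucagon = hz$glg_sec$basal +
      hz$glg_sec$vmax * hill_term(glucose_body, hz$glg_sec$K, hz$glg_sec$n,
                                  "inhibition")
  )
}

#' Verify simulated hormone and oxygen profiles against the oracles
#'
#' Runs the model at the constant-input baseline to steady state, then
#' compares the simulated sinusoidal profiles of insulin and glucagon with
#' the first-order oracle and the fixed oxygen profile with the zero-order
#' oracle. Reported errors are mean absolute deviations normalised by the
#' profile mean, in percent.
#'
#' @param model `hz_model`.
#' @param scenario scenario used for the steady run (default constant
#'   baseline).
#' @param horizon settle time in seconds.
#' @param dt integrator step (s).
#' @return list of per-species percent errors and the profiles.
#' @export
profile_verification <- function(model, scenario = make_scenario("constant_baseline"),
                                 horizon = 4 * 3600,
                                 dt = model$params$numerics$dt) {
  y0 <- initial_state(model, scenario$name)
  sim <- integrate_model(model, scenario, horizon, y0 = y0, dt = dt,
                         record_rates = FALSE)
  st <- unpack_state(sim$y_end, model$n_comp)
  n <- model$n_comp
  pct_err <- function(sim_prof, oracle_prof) {
    100 * mean(abs(sim_prof - oracle_prof)) / mean(oracle_prof)
  }
  ins_oracle <- gradient_oracle(st$body[["insulin"]], "first-order",
                                model$f_ins, n)
  glg_oracle <- gradient_oracle(st$body[["glucagon"]], "first-order",
                                model$f_glg, n)
  ph <- model$params$physiology
  o2_oracle <- gradient_oracle(ph$o2_inlet, "zero-order",
                               (ph$o2_inlet - ph$o2_outlet) / n, n)
  list(
    insulin_pct = pct_err(st$blood[, "insulin"], ins_oracle),
    glucagon_pct = pct_err(st$blood[, "glucagon"], glg_oracle),
    oxygen_pct = pct_err(model$o2, o2_oracle),
    profiles = list(
      insulin = st$blood[, "insulin"], insulin_oracle = ins_oracle,
      glucagon = st$blood[, "glucagon"], glucagon_oracle = glg_oracle,
      oxygen = model$o2, oxygen_oracle = o2_oracle
    )
  )
}

#' Dynamic steady-state oxygen profile
#'
#' The production model holds oxygen at the fixed measured gradient; this
#' helper integrates the advection/zero-order-consumption balance for
#' oxygen dynamically (inflow at the inlet tension, constant consumption
#' per compartment) and returns the steady profile, as an independent check
#' that the fixed gradient is the steady state of the transport chain.
#'
#' @param model `hz_model`.
#' @param horizon integration horizon (s).
#' @param dt time step (s).
#' @return vector of per-compartment oxygen tensions (mmHg).
#' @export
oxygen_steady_state <- function(model, horizon = 600, dt = 0.05) {
  ph <- model$params$physiology
  n <- model$n_comp
  tau <- model$tau_rate
  cons <- tau * (ph$o2_inlet - ph$o2_outlet) / n  # mmHg/s per compartment
  o2 <- rep(ph$o2_inlet, n)
  f <- function(o2) {
    up <- c(ph$o2_inlet, o2[-n])
    tau * (up - o2) - cons
  }
  for (s in seq_len(round(horizon / dt))) {
    k1 <- f(o2); k2 <- f(o2 + dt / 2 * k1)
    k3 <- f(o2 + dt / 2 * k2); k4 <- f(o2 + dt * k3)
    o2 <- o2 + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  o2
}
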