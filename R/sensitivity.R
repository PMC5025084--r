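# Local sensitivity protocols: one-at-a-time rate-constant perturbations
# under constant inputs, and zonation-constant perturbations under the
# NAFLD feeding scenario.

#' Hepatic processes included in the rate-constant sweep
#' @return character vector of process names.
#' @export
rate_sweep_processes <- function() {
  c("boxi", "atps", "pfk", "fbp", "pk", "pepck", "pdh", "vldl", "tsyn",
    "ffa_up", "lgen", "gk", "tg_up", "g6pase", "lply", "gs", "glut", "gp")
}

#' Lipid-relevant processes included in the zonation sweep
#' @return character vector of process names.
#' @export
zonation_sweep_processes <- function() {
  c("ffa_up", "vldl", "pdh", "boxi", "pfk", "lgen", "fbp", "pepck", "pk",
    "tsyn", "tg_up", "gk", "g6pase", "lply")
}

with_vb <- function(params, process, factor) {
  params$hepatic[[process]]$vb <- params$hepatic[[process]]$vb * factor
  params
}

sweep_outputs <- function(sim) {
  st <- unpack_state(sim$y_end, sim$model$n_comp)
  c(ffa_c = mean(st$hep[, "ffa_c"]),
    tg_c = mean(st$hep[, "tg_c"]),
    ffa_b = st$body[["ffa_b"]],
    tg_b = st$body[["tg_b"]])
}

#' Rate-constant sensitivity sweep
#'
#' From the constant-input baseline steady state, each hepatic rate
#' constant is increased and reduced by `delta` (default 10%) and the model
#' integrated for `horizon_h` hours with inputs held constant. Reported are
#' the changes at the horizon, relative to the unperturbed control run, in
#' mean hepatic FFA and triglyceride and in plasma (body-pool) FFA and
#' triglyceride.
#'
#' @param model `hz_model` (parameters at the calibrated reference values).
#' @param processes processes to perturb (default [rate_sweep_processes()]).
#' @param delta fractional perturbation of the base rate constant.
#' @param horizon_h horizon in hours (state measured at the horizon, not
#'   time-averaged, since inputs are constant).
#' @param dt integrator step (s).
#' @param y0 baseline steady state (default: shipped constant-baseline state).
#' @param check_steady abort if the baseline drifts by more than
#'   `steady_tol` (relative) over a 1-hour control run.
#' @param steady_tol relative drift tolerance for the steady-state check.
#' @return object of class `hz_rate_sweep`: data frame with one row per
#'   (process, direction), columns `d_ffa_c`, `d_tg_c`, `d_ffa_b`, `d_tg_b`
#'   (uM changes vs control).
#' @export
rate_sweep <- function(model, processes = rate_sweep_processes(),
                       delta = 0.10, horizon_h = 36,
                       dt = model$params$numerics$dt, y0 = NULL,
                       check_steady = TRUE, steady_tol = 0.02) {
  scen <- make_scenario("constant_baseline")
  if (is.null(y0)) y0 <- initial_state(model, scen$name)
  if (check_steady) {
    probe <- integrate_model(model, scen, 3600, y0 = y0, dt = dt,
                             record_rates = FALSE)
    drift <- max(abs(probe$y_end - y0) / (abs(y0) + 1e-9))
    if (drift > steady_tol) {
      stop(sprintf(
        "rate_sweep: baseline is not at steady state (relative drift %.3g over 1 h)",
        drift))
    }
  }
  horizon <- horizon_h * 3600
  run_once <- function(params) {
    m <- sinusoid_model(params)
    sim <- integrate_model(m, scen, horizon, y0 = y0, dt = dt,
                           record_rates = FALSE)
    sweep_outputs(sim)
  }
  control <- run_once(model$params)
  rows <- list()
  for (p in processes) {
    for (dir in c(1, -1)) {
      out <- run_once(with_vb(model$params, p, 1 + dir * delta))
      rows[[length(rows) + 1]] <- data.frame(
        process = p, direction = ifelse(dir > 0, "increased", "reduced"),
        delta = dir * delta,
        d_ffa_c = out[["ffa_c"]] - control[["ffa_c"]],
        d_tg_c = out[["tg_c"]] - control[["tg_c"]],
        d_ffa_b = out[["ffa_b"]] - control[["ffa_b"]],
        d_tg_b = out[["tg_b"]] - control[["tg_b"]]
      )
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "control") <- control
  attr(res, "horizon_h") <- horizon_h
  class(res) <- c("hz_rate_sweep", "data.frame")
  res
}

#' Zonation-constant sensitivity sweep
#'
#' Under the NAFLD scenario (severe insulin resistance with the SREBP-1c
#' clamp, moderate diet) each zonation constant is shifted by `+delta` (20%
#' more periportal) and `-delta` (20% more pericentral) and the model re-run
#' to full cycle equilibrium. Reported is the steatosis distribution as the
#' compartment-1 : compartment-N cycle-averaged triglyceride ratio
#' (stored as the scalar r of "1:r"), together with the normalised
#' pericentral-minus-periportal difference statistic
#' (dTG_pc - dTG_pp)/TG_av comparing the -delta and +delta runs.
#'
#' @param model `hz_model`.
#' @param scenario feeding scenario (default NAFLD).
#' @param processes processes to perturb (default
#'   [zonation_sweep_processes()]).
#' @param delta zonation-constant shift.
#' @param dt integrator step (s).
#' @param y0 starting state (default: shipped state for the scenario).
#' @param tol cycle-equilibrium tolerance.
#' @param max_cycles cycle cap per perturbation.
#' @return object of class `hz_zonation_sweep`: data frame with baseline
#'   ratio attribute; per process the equilibrium ratios at +delta and
#'   -delta and the difference statistic.
#' @export
zonation_sweep <- function(model, scenario = make_scenario("NAFLD"),
                           processes = zonation_sweep_processes(),
                           delta = 0.2, dt = model$params$numerics$dt,
                           y0 = NULL,
                           tol = model$params$numerics$cycle_tol,
                           max_cycles = model$params$numerics$max_cycles) {
  if (is.null(y0)) y0 <- initial_state(model, scenario$name)
  run_ratio <- function(params, start) {
    m <- sinusoid_model(params)
    eq <- run_to_cycle_equilibrium(m, scenario, y0 = start, tol = tol,
                                   max_cycles = max_cycles, dt = dt)
    ob <- observables(eq)
    tg <- ob$hep_avg[, "tg_c"]
    list(ratio = unname(tg[length(tg)] / tg[1]), tg = tg,
         tg_av = mean(tg), y_end = eq$y_end)
  }
  base <- run_ratio(model$params, y0)
  rows <- list()
  for (p in processes) {
    kn0 <- model$params$zonation[[p]]
    entry <- list(process = p, ratio_plus = NA_real_, ratio_minus = NA_real_,
                  stat = NA_real_)
    res <- list()
    for (dir in c(1, -1)) {
      kn <- kn0 + dir * delta
      if (abs(kn) >= 1) {
        warning(sprintf(
          "zonation_sweep: skipping %s (k_n %+0.2f would leave (-1, 1))",
          p, kn))
        next
      }
      params <- model$params
      params$zonation[[p]] <- kn
      res[[as.character(dir)]] <- run_ratio(params, base$y_end)
    }
    if (!is.null(res[["1"]])) entry$ratio_plus <- res[["1"]]$ratio
    if (!is.null(res[["-1"]])) entry$ratio_minus <- res[["-1"]]$ratio
    if (!is.null(res[["1"]]) && !is.null(res[["-1"]])) {
      n <- model$n_comp
      d_pc <- res[["-1"]]$tg[n] - res[["1"]]$tg[n]
      d_pp <- res[["-1"]]$tg[1] - res[["1"]]$tg[1]
      entry$stat <- (d_pc - d_pp) / base$tg_av
    }
    rows[[p]] <- as.data.frame(entry)
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline_ratio") <- base$ratio
  attr(out, "delta") <- delta
  class(out) <- c("hz_zonation_sweep", "data.frame")
  out
}
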