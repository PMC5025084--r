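# Integration engine: fixed-step RK4 trajectories, cycle-equilibrium
# detection, and the summary observables (cycle averages, zonal profiles,
# pc:pp ratios, glycogen swings).

flatten_block <- function(block) {
  out <- numeric(0)
  for (p in names(block)) {
    v <- unlist(block[[p]])
    names(v) <- paste(p, names(v), sep = ".")
    out <- c(out, v)
  }
  out
}

# Assemble the numeric argument vectors consumed by the compiled core.
core_args <- function(model, scenario) {
  params <- model$params
  ph <- params$physiology
  hz <- params$hormones
  phys <- c(n_comp = ph$n_comp, V_hep = ph$V_hep, V_blood = ph$V_blood,
            V_body = ph$V_body, flow = ph$flow)
  horm <- c(K_I = hz$K_I, n_I = hz$n_I, K_G = hz$K_G, n_G = hz$n_G,
            ins_basal = hz$ins_sec$basal, ins_vmax = hz$ins_sec$vmax,
            ins_K = hz$ins_sec$K, ins_n = hz$ins_sec$n,
            glg_basal = hz$glg_sec$basal, glg_vmax = hz$glg_sec$vmax,
            glg_K = hz$glg_sec$K, glg_n = hz$glg_sec$n,
            kdeg_ins_body = hz$k_deg_ins_body, kdeg_glg_body = hz$k_deg_glg_body,
            kdeg_ins_sin = model$kdeg_ins_sin, kdeg_glg_sin = model$kdeg_glg_sin)
  period_s <- params$inputs$cycle_hours * 3600
  if (identical(scenario$waveform, "constant")) {
    in_glc <- params$inputs$const_glucose * scenario$glucose_mult
    in_ffa <- params$inputs$const_ffa * scenario$ffa_mult
    wave <- 0
  } else {
    pk <- input_peaks(params)
    in_glc <- pk$glucose * scenario$glucose_mult
    in_ffa <- pk$ffa * scenario$ffa_mult
    wave <- 1
  }
  scen <- c(K_IR = scenario$K_IR, srebp = as.numeric(isTRUE(scenario$srebp1c)),
            clamp = scenario$srebp_clamp_nM, wave = wave,
            in_glc = in_glc, in_ffa = in_ffa, period_s = period_s)
  list(phys = phys, horm = horm, hep = flatten_block(params$hepatic),
       kn = unlist(params$zonation), body = flatten_block(params$body),
       scen = scen, o2 = model$o2)
}

#' Full model derivative via the compiled core
#'
#' @param y flat state vector.
#' @param t time (s).
#' @param model `hz_model`.
#' @param scenario `hz_scenario`.
#' @return list with `dy` and the `n_comp` x 27 rate matrix.
#' @export
core_derivatives <- function(y, t, model, scenario) {
  a <- core_args(model, scenario)
  out <- hz_core_derivs(y, t, a$phys, a$horm, a$hep, a$kn, a$body, a$scen, a$o2)
  rates <- matrix(out$rates, model$n_comp, 27, byrow = TRUE,
                  dimnames = list(NULL, process_names()))
  list(dy = out$dy, rates = rates)
}

#' Default (uncalibrated) initial state
#'
#' A physiologically plausible cold-start state used by the calibration
#' module; production runs start from the shipped near-equilibrium states.
#'
#' @param model `hz_model`.
#' @return flat state vector.
#' @export
cold_start_state <- function(model) {
  n <- model$n_comp
  hep0 <- c(glucose_c = 5200, g6p = 150, glycogen = 2e5, g3p_gadp = 130,
            pyr_lac = 900, acetyl_coa = 60, ffa_c = 20, tg_c = 26000,
            glycerol_c = 80, atp = 2600, adp = 700, amp = 150, pi = 4000,
            utp = 300, udp = 100, gtp = 250, gdp = 80)
  blood0 <- c(glucose_b = 5030, lactate_b = 1000, ffa_b = 432, tg_b = 1050,
              glycerol_b = 80, insulin = 0.06, glucagon = 0.035)
  hep <- matrix(hep0, n, length(hep0), byrow = TRUE,
                dimnames = list(NULL, names(hep0)))
  blood <- matrix(blood0, n, length(blood0), byrow = TRUE,
                  dimnames = list(NULL, names(blood0)))
  blood[, "insulin"] <- blood0[["insulin"]] * model$f_ins^seq_len(n)
  blood[, "glucagon"] <- blood0[["glucagon"]] * model$f_glg^seq_len(n)
  pack_state(hep, blood, blood0)
}

#' Load a shipped near-equilibrium initial state
#'
#' The calibration module serialises the end-of-cycle state of each
#' reference scenario as plain text; starting from these, re-running to
#' cycle equilibrium converges in a handful of cycles. Falls back to the
#' cold-start state when no file matches.
#'
#' @param model `hz_model`.
#' @param name state name (scenario name, e.g. `"MH"`, `"NAFLD"`,
#'   `"constant_baseline"`).
#' @return flat state vector.
#' @export
initial_state <- function(model, name = "MH") {
  candidates <- unique(c(name, sub("\\+.*$", "", name), "MH"))
  n_expected <- model$n_comp * 24 + 7
  for (cand in candidates) {
    file <- system.file("extdata", "states", paste0(cand, ".csv"),
                        package = "hepzone")
    if (nzchar(file) && file.exists(file)) {
      y <- utils::read.csv(file)$value
      if (length(y) == n_expected) return(y)
    }
  }
  cold_start_state(model)
}

#' Integrate the full model
#'
#' Classic fixed-step 4th-order Runge-Kutta (the reference configuration is
#' dt = 0.05 s with 8 compartments). A step producing a negative
#' concentration is rejected and retried with locally halved steps rather
#' than clipped. An adaptive backend (`method = "lsoda"`, via deSolve) is
#' available as an independent cross-check.
#'
#' @param model `hz_model`.
#' @param scenario `hz_scenario`.
#' @param horizon simulation horizon in seconds.
#' @param y0 initial flat state (default: shipped state for the scenario).
#' @param dt RK4 time step in seconds (> 0).
#' @param t0 start time (s); the feeding waveform is phase-locked to t = 0.
#' @param sample_dt sampling interval for the returned trajectory (s).
#' @param record_rates record per-process rate trajectories.
#' @param method `"rk4"` (reference) or `"lsoda"` (adaptive cross-check).
#' @return object of class `hz_sim`: list with `times`, `states` (samples x
#'   states), `rates` (samples x (27 n_comp)), `y_end`, `model`, `scenario`.
#' @export
integrate_model <- function(model, scenario, horizon, y0 = NULL,
                            dt = model$params$numerics$dt, t0 = 0,
                            sample_dt = model$params$numerics$sample_dt,
                            record_rates = TRUE, method = c("rk4", "lsoda")) {
  method <- match.arg(method)
  if (dt <= 0) stop("integrate_model: dt must be > 0")
  if (is.null(y0)) y0 <- initial_state(model, scenario$name)
  sample_every <- max(1L, round(sample_dt / dt))
  n_steps <- max(1L, round(horizon / dt))
  a <- core_args(model, scenario)
  if (method == "rk4") {
    out <- hz_core_simulate(y0, t0, n_steps, dt, sample_every, a$phys, a$horm,
                            a$hep, a$kn, a$body, a$scen, a$o2, record_rates)
    times <- out$times
    states <- out$states
    y_end <- out$y_end
    rates <- if (record_rates) out$rates else NULL
  } else {
    if (!requireNamespace("deSolve", quietly = TRUE)) {
      stop("integrate_model: the lsoda backend needs the deSolve package")
    }
    f <- function(t, y, parms) {
      list(hz_core_derivs(y, t, a$phys, a$horm, a$hep, a$kn, a$body,
                          a$scen, a$o2)$dy)
    }
    times <- seq(t0, t0 + n_steps * dt, by = sample_every * dt)
    sol <- deSolve::lsoda(y0, times, f, NULL, rtol = 1e-8, atol = 1e-8)
    states <- unname(sol[, -1, drop = FALSE])
    y_end <- states[nrow(states), ]
    rates <- NULL
    if (record_rates) {
      rates <- t(apply(states, 1, function(y) {
        hz_core_derivs(y, 0, a$phys, a$horm, a$hep, a$kn, a$body,
                       a$scen, a$o2)$rates
      }))
    }
  }
  structure(list(times = times, states = states, rates = rates,
                 y_end = y_end, t_end = t0 + n_steps * dt, dt = dt,
                 model = model, scenario = scenario),
            class = "hz_sim")
}

#' @export
print.hz_sim <- function(x, ...) {
  cat(sprintf("<hz_sim> %s: %d samples over %.2f h (dt = %g s, %d compartments)\n",
              x$scenario$name, length(x$times),
              (x$times[length(x$times)] - x$times[1]) / 3600, x$dt,
              x$model$n_comp))
  invisible(x)
}

#' Extract a species trajectory from a simulation
#'
#' @param sim `hz_sim` object.
#' @param species a hepatocyte or blood species name, or `"body.<species>"`.
#' @return matrix samples x compartments (or a vector for body species).
#' @export
species_trajectory <- function(sim, species) {
  n <- sim$model$n_comp
  nh <- length(hep_species())
  nb <- length(blood_species())
  if (startsWith(species, "body.")) {
    s <- sub("^body\\.", "", species)
    k <- match(s, blood_species())
    if (is.na(k)) stop("unknown body species: ", s)
    return(sim$states[, n * (nh + nb) + k])
  }
  if (species %in% hep_species()) {
    k <- match(species, hep_species())
    idx <- (seq_len(n) - 1) * nh + k
  } else if (species %in% blood_species()) {
    k <- match(species, blood_species())
    idx <- n * nh + (seq_len(n) - 1) * nb + k
  } else {
    stop("unknown species: ", species)
  }
  sim$states[, idx, drop = FALSE]
}

#' Extract a process-rate trajectory
#' @param sim `hz_sim` with recorded rates.
#' @param process process name from [process_names()], or `"ffat"` /
#'   `"tgt"` for the net transport rates.
#' @return matrix samples x compartments.
#' @export
rate_trajectory <- function(sim, process) {
  if (is.null(sim$rates)) stop("simulation was run without rate recording")
  n <- sim$model$n_comp
  np <- length(process_names())
  get <- function(p) {
    k <- match(p, process_names())
    sim$rates[, (seq_len(n) - 1) * np + k, drop = FALSE]
  }
  switch(process,
    ffat = get("ffa_up") - get("ffa_rel"),
    tgt = get("tg_up") - get("vldl"),
    get(process)
  )
}

#' Run to feeding-cycle equilibrium
#'
#' Integrates successive feeding cycles until the maximum relative change of
#' every state between consecutive cycle ends falls below `tol`
#' (|x - x_prev| / (|x_prev| + 1e-9)), then returns the final full cycle.
#'
#' @param model `hz_model`.
#' @param scenario cyclic-waveform scenario.
#' @param y0 initial state (default: shipped state for the scenario).
#' @param tol relative cycle-equilibrium tolerance.
#' @param max_cycles cycle cap; exceeding it is an error with a trend report.
#' @param dt integrator step (s).
#' @param sample_dt sampling interval for the returned cycle (s).
#' @return `hz_sim` for the final cycle, with `n_cycles` and the
#'   convergence `history` attached.
#' @export
run_to_cycle_equilibrium <- function(model, scenario, y0 = NULL,
                                     tol = model$params$numerics$cycle_tol,
                                     max_cycles = model$params$numerics$max_cycles,
                                     dt = model$params$numerics$dt,
                                     sample_dt = model$params$numerics$sample_dt) {
  if (identical(scenario$waveform, "constant")) {
    stop("run_to_cycle_equilibrium: scenario has a constant waveform")
  }
  if (is.null(y0)) y0 <- initial_state(model, scenario$name)
  period_s <- model$params$inputs$cycle_hours * 3600
  y_prev <- y0
  history <- numeric(0)
  for (cyc in seq_len(max_cycles)) {
    sim <- integrate_model(model, scenario, period_s, y0 = y_prev, dt = dt,
                           t0 = 0, sample_dt = sample_dt,
                           record_rates = FALSE)
    delta <- max(abs(sim$y_end - y_prev) / (abs(y_prev) + 1e-9))
    history[cyc] <- delta
    y_prev <- sim$y_end
    if (delta < tol) {
      final <- integrate_model(model, scenario, period_s, y0 = y_prev,
                               dt = dt, t0 = 0, sample_dt = sample_dt,
                               record_rates = TRUE)
      final$n_cycles <- cyc
      final$history <- history
      final$converged <- TRUE
      return(final)
    }
  }
  stop(sprintf(
    paste0("run_to_cycle_equilibrium: no equilibrium within %d cycles ",
           "(last relative changes: %s)"),
    max_cycles,
    paste(signif(utils::tail(history, 5), 3), collapse = ", ")
  ))
}

half_means <- function(v) {
  n <- length(v)
  pp <- mean(v[seq_len(n %/% 2)])
  pc <- mean(v[(n %/% 2 + 1):n])
  c(pp = pp, pc = pc)
}

#' Summary observables of an equilibrium cycle
#'
#' Per-compartment cycle averages of every species and process rate;
#' pericentral:periportal ratios (both the half-sinusoid means and the
#' endpoint compartments, since zonal ratios are quoted in both forms);
#' glycogen swing (postprandial peak minus pre-prandial trough, in
#' glucose-equivalent concentration); and sinusoid-average triglyceride as
#' percent of cell mass. The sinusoid average weights compartments equally
#' (compartment volumes are equal by construction).
#'
#' @param sim an `hz_sim` covering one feeding cycle (or a steady-state
#'   window) with recorded rates.
#' @return object of class `hz_observables`.
#' @export
observables <- function(sim) {
  model <- sim$model
  n <- model$n_comp
  ns <- length(sim$times)
  keep <- seq_len(ns - 1)  # half-open cycle: drop duplicate endpoint
  hep_avg <- sapply(hep_species(), function(s) {
    colMeans(species_trajectory(sim, s)[keep, , drop = FALSE])
  })
  blood_avg <- sapply(blood_species(), function(s) {
    colMeans(species_trajectory(sim, s)[keep, , drop = FALSE])
  })
  np <- c(process_names(), "ffat", "tgt")
  rate_avg <- sapply(np, function(p) {
    colMeans(rate_trajectory(sim, p)[keep, , drop = FALSE])
  })
  gly <- species_trajectory(sim, "glycogen")
  swing <- apply(gly, 2, max) - apply(gly, 2, min)
  pct <- tg_percent(hep_avg[, "tg_c"],
                    model$params$physiology$tg_molar_mass,
                    model$params$physiology$tissue_density)
  zonal_ratio <- function(v) {
    hm <- half_means(v)
    c(half = unname(hm["pc"] / hm["pp"]), endpoint = v[n] / v[1])
  }
  structure(list(
    scenario = sim$scenario$name,
    n_comp = n,
    hep_avg = hep_avg,
    blood_avg = blood_avg,
    rate_avg = rate_avg,
    body_avg = vapply(blood_species(), function(s) {
      mean(species_trajectory(sim, paste0("body.", s))[keep])
    }, numeric(1)),
    tg_pct = pct,
    tg_pct_avg = mean(pct),
    glycogen_swing = swing,
    tsyn_ratio = zonal_ratio(rate_avg[, "tsyn"]),
    tg_ratio = zonal_ratio(hep_avg[, "tg_c"]),
    ffa_ratio = zonal_ratio(hep_avg[, "ffa_c"]),
    atp_avg = mean(hep_avg[, "atp"]),
    boxi_avg = mean(rate_avg[, "boxi"]),
    lgen_avg = mean(rate_avg[, "lgen"]),
    tsyn_avg = mean(rate_avg[, "tsyn"])
  ), class = "hz_observables")
}

#' @export
print.hz_observables <- function(x, ...) {
  cat(sprintf("<hz_observables> scenario %s (%d compartments)\n",
              x$scenario, x$n_comp))
  cat(sprintf("  TG %% cell mass: sinusoid mean %.2f%% (pp %.2f%% -> pc %.2f%%)\n",
              x$tg_pct_avg, x$tg_pct[1], x$tg_pct[x$n_comp]))
  cat(sprintf("  TG-synthesis pc:pp ratio: %.3f (half-sinusoid), %.3f (endpoints)\n",
              x$tsyn_ratio[["half"]], x$tsyn_ratio[["endpoint"]]))
  cat(sprintf("  mean ATP %.0f uM; mean beta-oxidation %.4f uM/s\n",
              x$atp_avg, x$boxi_avg))
  cat(sprintf("  glycogen swing: comp 1 %.1f mM, comp %d %.1f mM (glucose units)\n",
              x$glycogen_swing[1] / 1000, x$n_comp,
              x$glycogen_swing[x$n_comp] / 1000))
  invisible(x)
}
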