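#' Hill saturation/inhibition factor
#'
#' Evaluates the Hill function used throughout the model for substrate
#' saturation, allosteric activation and allosteric inhibition. Activation
#' returns \eqn{c^n/(K^n + c^n)}, inhibition returns \eqn{K^n/(K^n + c^n)};
#' both lie in \[0, 1\].
#'
#' @param c concentration (same units as `K`), must be >= 0. Vectorised.
#' @param K half-saturation constant, > 0.
#' @param n Hill exponent, > 0.
#' @param mode `"activation"` or `"inhibition"`.
#' @return dimensionless factor in \[0, 1\].
#' @examples
#' hill_term(460, 460, 1)          # 0.5 at the half-saturation point
#' hill_term(0, 10, 2, "inhibition")  # 1 at zero concentration
#' @export
hill_term <- function(c, K, n = 1, mode = c("activation", "inhibition")) {
  mode <- match.arg(mode)
  if (!is.numeric(K) || any(K <= 0)) stop("hill_term: K must be > 0")
  if (!is.numeric(n) || any(n <= 0)) stop("hill_term: n must be > 0")
  if (any(c < 0)) stop("hill_term: concentration must be >= 0")
  cn <- c^n
  Kn <- K^n
  if (mode == "activation") cn / (Kn + cn) else Kn / (Kn + cn)
}

#' Zonation constant from a periportal:pericentral ratio
#'
#' The activity of a zonated process varies linearly along the sinusoid as
#' \eqn{m_i = 1 + k_n x_i} with \eqn{x_i} falling from +1 (periportal) to -1
#' (pericentral), so the endpoint ratio is \eqn{m_1/m_N = (1+k_n)/(1-k_n)}.
#' This inverts that relation: given the measured periportal:pericentral
#' activity ratio `r` (e.g. 1/2.5 for glucokinase), returns
#' \eqn{k_n = (r-1)/(r+1)}.
#'
#' @param ratio periportal:pericentral activity ratio expressed as a single
#'   number (periportal value divided by pericentral value), > 0.
#' @return zonation constant in (-1, 1).
#' @export
kn_from_ratio <- function(ratio) {
  if (any(ratio <= 0)) stop("kn_from_ratio: ratio must be > 0")
  (ratio - 1) / (ratio + 1)
}

#' Linear porto-central position grid
#'
#' @param n_comp number of compartments (>= 2).
#' @return vector of length `n_comp` falling linearly from +1 to -1.
#' @export
zonation_positions <- function(n_comp) {
  if (n_comp < 2) stop("zonation_positions: need at least 2 compartments")
  1 - 2 * (seq_len(n_comp) - 1) / (n_comp - 1)
}

#' Build a zonation profile
#'
#' Per-compartment multipliers on a process's base rate constant. The base
#' constant is the sinusoid mean: `mean(m) == 1` by construction, and the
#' endpoint ratio `m[1]/m[N]` equals `(1 + k_n)/(1 - k_n)`.
#'
#' @param k_n zonation constant, |k_n| < 1 (positive = periportal).
#' @param n_comp number of compartments (>= 2).
#' @return object of class `hz_zonation`: list with `k_n`, `n_comp`,
#'   multipliers `m` and positions `x`.
#' @export
build_zonation_profile <- function(k_n, n_comp = 8) {
  if (abs(k_n) >= 1) {
    stop("build_zonation_profile: |k_n| must be < 1 (multiplier would be negative)")
  }
  x <- zonation_positions(n_comp)
  structure(
    list(k_n = k_n, n_comp = n_comp, x = x, m = 1 + k_n * x),
    class = "hz_zonation"
  )
}

#' @export
print.hz_zonation <- function(x, ...) {
  cat(sprintf(
    "Zonation profile: k_n = %.4f over %d compartments (pp:pc = %.3g:1)\n",
    x$k_n, x$n_comp, (1 + x$k_n) / (1 - x$k_n)
  ))
  print(round(x$m, 4))
  invisible(x)
}

#' Hormone concentrations as sensed by a hepatic process
#'
#' Insulin resistance scales the detected insulin concentration by a constant
#' `K_IR` (0 < K_IR <= 1; 1 = metabolically healthy). When the SREBP-1c flag
#' of the scenario is set, lipogenesis and triglyceride synthesis instead
#' sense a clamped high insulin concentration (1 nM by default), representing
#' the persistently elevated SREBP-1c expression of insulin-resistant NAFLD.
#' Glucagon detection is unaffected.
#'
#' @param insulin,glucagon local hormone concentrations (nM), >= 0.
#' @param scenario a scenario object (see [make_scenario()]) or a list with
#'   elements `K_IR` and `srebp1c`.
#' @param process process name (one of `process_names()`); the SREBP-1c clamp
#'   applies to `"lgen"` and `"tsyn"` only.
#' @return named list with `insulin_eff` and `glucagon_eff` (nM).
#' @export
effective_hormones <- function(insulin, glucagon, scenario, process = "") {
  k_ir <- scenario$K_IR
  if (is.null(k_ir) || k_ir <= 0 || k_ir > 1) {
    stop("effective_hormones: K_IR must be in (0, 1]")
  }
  if (any(insulin < 0) || any(glucagon < 0)) {
    stop("effective_hormones: hormone concentrations must be >= 0")
  }
  ins <- k_ir * insulin
  clamp <- scenario$srebp_clamp_nM
  if (is.null(clamp)) clamp <- 1.0
  if (isTRUE(scenario$srebp1c) && process %in% c("lgen", "tsyn")) {
    ins <- rep_len(clamp, length(insulin))
  }
  list(insulin_eff = ins, glucagon_eff = glucagon)
}

#' Convert a hepatic triglyceride concentration to percent of cell mass
#'
#' Linear conversion anchored so that the concentration equivalent to
#' 50 mg triglyceride per g wet tissue maps to 5.0% of total cell mass,
#' the usual diagnostic threshold for early-stage steatosis. With the
#' default triolein-like molar mass (885.4 g/mol) and unit tissue density
#' (1 g/mL), percent = TG \[uM\] * molar_mass * 1e-7.
#'
#' @param tg_c triglyceride concentration in uM (umol per litre of cell
#'   volume), >= 0.
#' @param molar_mass triglyceride molar mass in g/mol.
#' @param density tissue density in g/mL.
#' @return percent of total cell mass.
#' @export
tg_percent <- function(tg_c, molar_mass = 885.4, density = 1.0) {
  if (any(tg_c < 0)) stop("tg_percent: concentration must be >= 0")
  100 * tg_c * 1e-6 * molar_mass / (density * 1000)
}

#' Inverse of [tg_percent()]
#' @param pct percent of total cell mass.
#' @inheritParams tg_percent
#' @return triglyceride concentration in uM.
#' @export
tg_from_percent <- function(pct, molar_mass = 885.4, density = 1.0) {
  pct * (density * 1000) / (100 * 1e-6 * molar_mass)
}
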