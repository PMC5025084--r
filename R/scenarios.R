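# Scenario construction: feeding waveforms, diets, insulin resistance,
# SREBP-1c over-expression.

#' Feeding waveform
#'
#' Spiked meal input `v_input * sin^6(pi t / period)` with a 4-hour period
#' by default, giving alternating post-prandial storage and inter-prandial
#' mobilisation. The cycle mean of sin^6 is 5/16, so one cycle delivers
#' `v_input * 5/16 * period`.
#'
#' @param t_hours time in hours (>= 0), vectorised.
#' @param v_input peak input rate (>= 0).
#' @param period_hours cycle period in hours.
#' @return input rate, same units as `v_input`.
#' @export
feeding_waveform <- function(t_hours, v_input, period_hours = 4) {
  if (any(v_input < 0)) stop("feeding_waveform: v_input must be >= 0")
  if (any(t_hours < 0)) stop("feeding_waveform: t must be >= 0")
  v_input * sin(pi * t_hours / period_hours)^6
}

#' Feeding input rates for a scenario
#'
#' @param t_hours time in hours.
#' @param scenario scenario object (see [make_scenario()]).
#' @param params parameter list.
#' @return list with `glucose` and `ffa` input rates (uM/s, body scale).
#' @export
feeding_input <- function(t_hours, scenario, params = default_params()) {
  if (identical(scenario$waveform, "constant")) {
    list(glucose = params$inputs$const_glucose * scenario$glucose_mult,
         ffa = params$inputs$const_ffa * scenario$ffa_mult)
  } else {
    pk <- input_peaks(params)
    period <- params$inputs$cycle_hours
    list(glucose = feeding_waveform(t_hours, pk$glucose * scenario$glucose_mult, period),
         ffa = feeding_waveform(t_hours, pk$ffa * scenario$ffa_mult, period))
  }
}

# Diet multipliers relative to the moderate intake diet.
diet_multipliers <- function(diet = c("moderate", "raised_fat", "high_fat",
                                      "very_high_fat", "low_fat",
                                      "raised_carb", "high_carb",
                                      "very_high_carb", "low_carb")) {
  diet <- match.arg(diet)
  g <- 1
  f <- 1
  switch(diet,
    raised_fat = f <- 1.05,
    high_fat = f <- 1.125,
    very_high_fat = f <- 1.25,
    low_fat = f <- 0.875,
    raised_carb = g <- 1.05,
    high_carb = g <- 1.125,
    very_high_carb = g <- 1.25,
    low_carb = g <- 0.875,
    moderate = NULL
  )
  list(glucose = g, ffa = f)
}

#' Construct a scenario
#'
#' Insulin-sensitivity presets: `"MH"` (metabolically healthy, K_IR = 1),
#' `"developing_IR"` (K_IR = 0.05), `"severe_IR"` (K_IR = 0.015) and
#' `"NAFLD"` (severe IR plus the SREBP-1c clamp holding lipogenesis and
#' triglyceride synthesis at an effective 1 nM insulin).
#' `"constant_baseline"` is the constant-input scenario used by the
#' rate-constant sensitivity protocol. Diet variants combine freely with
#' any insulin-sensitivity preset: raised +5%, high +12.5%, very high +25%
#' (and low -12.5%) on the relevant input.
#'
#' @param preset one of `"MH"`, `"developing_IR"`, `"severe_IR"`, `"NAFLD"`,
#'   `"constant_baseline"`, or a diet name (applied to an otherwise healthy
#'   individual).
#' @param diet diet preset name (see Details); default moderate.
#' @param K_IR override the preset insulin-resistance constant (0 < K_IR <= 1).
#' @param srebp1c override the SREBP-1c flag.
#' @param glucose_mult,ffa_mult explicit input multipliers (override `diet`).
#' @return object of class `hz_scenario`.
#' @export
make_scenario <- function(preset = "MH", diet = "moderate", K_IR = NULL,
                          srebp1c = NULL, glucose_mult = NULL,
                          ffa_mult = NULL) {
  diets <- c("raised_fat", "high_fat", "very_high_fat", "low_fat",
             "raised_carb", "high_carb", "very_high_carb", "low_carb")
  if (preset %in% diets) {
    diet <- preset
    preset <- "MH"
  }
  base <- switch(preset,
    MH = list(K_IR = 1, srebp1c = FALSE, waveform = "cyclic"),
    developing_IR = list(K_IR = 0.05, srebp1c = FALSE, waveform = "cyclic"),
    severe_IR = list(K_IR = 0.015, srebp1c = FALSE, waveform = "cyclic"),
    NAFLD = list(K_IR = 0.015, srebp1c = TRUE, waveform = "cyclic"),
    constant_baseline = list(K_IR = 1, srebp1c = FALSE, waveform = "constant"),
    stop("make_scenario: unknown preset '", preset, "'")
  )
  mult <- diet_multipliers(diet)
  if (!is.null(K_IR)) base$K_IR <- K_IR
  if (!is.null(srebp1c)) base$srebp1c <- srebp1c
  if (base$K_IR <= 0 || base$K_IR > 1) {
    stop("make_scenario: K_IR must be in (0, 1]")
  }
  sc <- structure(list(
    name = if (diet == "moderate") preset else paste(preset, diet, sep = "+"),
    preset = preset,
    diet = diet,
    K_IR = base$K_IR,
    srebp1c = base$srebp1c,
    srebp_clamp_nM = 1.0,
    waveform = base$waveform,
    glucose_mult = if (is.null(glucose_mult)) mult$glucose else glucose_mult,
    ffa_mult = if (is.null(ffa_mult)) mult$ffa else ffa_mult
  ), class = "hz_scenario")
  if (sc$glucose_mult <= 0 || sc$ffa_mult <= 0) {
    stop("make_scenario: diet multipliers must be > 0")
  }
  sc
}

#' @export
print.hz_scenario <- function(x, ...) {
  cat(sprintf(
    "<hz_scenario> %s: K_IR = %g, SREBP-1c %s, %s input (glucose x%.3g, FFA x%.3g)\n",
    x$name, x$K_IR, if (x$srebp1c) "clamped at 1 nM" else "off",
    x$waveform, x$glucose_mult, x$ffa_mult
  ))
  invisible(x)
}
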