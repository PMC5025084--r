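# Feeding waveform and scenario presets.

test_that("the feeding waveform has the sin^6 shape and 5/16 cycle mean", {
  expect_equal(feeding_waveform(0, 10), 0)
  expect_equal(feeding_waveform(2, 10), 10)  # peak mid-cycle
  expect_equal(feeding_waveform(4, 10), 0, tolerance = 1e-12)
  # numeric integration oracle for the cycle mean of sin^6
  mean_frac <- stats::integrate(function(t) sin(pi * t / 4)^6, 0, 4)$value / 4
  expect_equal(mean_frac, 5 / 16, tolerance = 1e-9)
  expect_error(feeding_waveform(1, -1), "v_input")
})

test_that("peak input rates deliver the dietary masses over one cycle", {
  params <- structural_params()
  pk <- input_peaks(params)
  # integrate the waveform over one cycle and convert back to grams
  tt <- seq(0, 4, length.out = 20001)
  wsum <- mean(sin(pi * tt / 4)^6)
  vol <- params$physiology$V_body
  g_carb <- pk$glucose * wsum * 4 * 3600 * vol * params$inputs$glucose_mw / 1e6
  g_fat <- pk$ffa * wsum * 4 * 3600 * vol * params$inputs$ffa_mw / 1e6
  expect_equal(g_carb, 78.1, tolerance = 1e-3)
  expect_equal(g_fat, 22.2, tolerance = 1e-3)
})

test_that("insulin-sensitivity presets carry the declared constants", {
  expect_equal(make_scenario("MH")$K_IR, 1)
  expect_false(make_scenario("MH")$srebp1c)
  expect_equal(make_scenario("developing_IR")$K_IR, 0.05)
  sev <- make_scenario("severe_IR")
  expect_equal(sev$K_IR, 0.015)
  expect_false(sev$srebp1c)
  naf <- make_scenario("NAFLD")
  expect_equal(naf$K_IR, 0.015)
  expect_true(naf$srebp1c)
  expect_equal(naf$srebp_clamp_nM, 1)
  expect_equal(make_scenario("constant_baseline")$waveform, "constant")
  expect_error(make_scenario("unknown"), "preset")
  expect_error(make_scenario("MH", K_IR = 0), "K_IR")
})

test_that("diet variants compose orthogonally with insulin sensitivity", {
  expect_equal(make_scenario("high_fat")$ffa_mult, 1.125)
  expect_equal(make_scenario("very_high_fat")$ffa_mult, 1.25)
  expect_equal(make_scenario("raised_carb")$glucose_mult, 1.05)
  expect_equal(make_scenario("low_fat")$ffa_mult, 0.875)
  for (preset in c("MH", "developing_IR", "severe_IR", "NAFLD")) {
    for (diet in c("moderate", "raised_fat", "high_fat", "very_high_fat",
                   "high_carb")) {
      sc <- make_scenario(preset, diet = diet)
      base <- make_scenario(preset)
      expect_equal(sc$K_IR, base$K_IR, info = paste(preset, diet))
      expect_equal(sc$srebp1c, base$srebp1c, info = paste(preset, diet))
      mult <- if (grepl("fat", diet)) sc$ffa_mult else sc$glucose_mult
      expect_true(mult >= 1 || diet == "moderate")
    }
  }
  # explicit multipliers override the diet name
  sc <- make_scenario("MH", glucose_mult = 1.3)
  expect_equal(sc$glucose_mult, 1.3)
})

test_that("feeding_input respects waveform type and multipliers", {
  params <- structural_params()
  const <- feeding_input(1.7, make_scenario("constant_baseline"), params)
  expect_equal(const$glucose, params$inputs$const_glucose)
  hf <- feeding_input(2, make_scenario("severe_IR", diet = "high_fat"), params)
  mod <- feeding_input(2, make_scenario("severe_IR"), params)
  expect_equal(hf$ffa / mod$ffa, 1.125)
  expect_equal(hf$glucose, mod$glucose)
})
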