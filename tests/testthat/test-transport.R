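# Advection chain, body compartment, gradient oracles, pancreas.

test_that("advection of a uniform field vanishes and mass is conserved", {
  model <- test_model()
  n <- model$n_comp
  blood <- matrix(123.4, n, 7, dimnames = list(NULL, blood_species()))
  body <- setNames(rep(123.4, 7), blood_species())
  adv <- advection_derivatives(blood, body, model$params$physiology$flow,
                               model$vb_i)
  expect_equal(max(abs(adv)), 0)
  # random fields: the flux chain telescopes, so total mass change equals
  # inflow minus outflow exactly
  set.seed(3)
  for (i in 1:20) {
    blood[] <- runif(n * 7, 0, 100)
    body[] <- runif(7, 0, 100)
    adv <- advection_derivatives(blood, body, model$params$physiology$flow,
                                 model$vb_i)
    total <- model$vb_i * colSums(adv)
    inout <- model$params$physiology$flow * (body[blood_species()] - blood[n, ])
    expect_equal(unname(total), unname(inout), tolerance = 1e-12)
  }
  expect_error(advection_derivatives(blood, body, 0, model$vb_i), "flow")
})

test_that("an inert tracer is conserved end to end through the chain", {
  params <- inert_params()
  model <- sinusoid_model(params)
  y0 <- uniform_state(model, 100, 0)
  # inject tracer into the body glucose pool
  st <- unpack_state(y0, model$n_comp)
  st$body[["glucose_b"]] <- 500
  y0 <- pack_state(st$hep, st$blood, st$body)
  scen <- make_scenario("constant_baseline")
  sim <- integrate_model(model, scen, 600, y0 = y0, dt = 0.05,
                         sample_dt = 60, record_rates = FALSE)
  st1 <- unpack_state(sim$y_end, model$n_comp)
  mass0 <- 500 * model$params$physiology$V_body
  mass1 <- st1$body[["glucose_b"]] * model$params$physiology$V_body +
    sum(st1$blood[, "glucose_b"]) * model$vb_i
  expect_equal(mass1, mass0, tolerance = 1e-9)
})

test_that("gradient oracles give the closed-form profiles", {
  expect_equal(gradient_oracle(65, "zero-order", 0, 8), rep(65, 8))
  o2 <- gradient_oracle(65, "zero-order", 30 / 8, 8)
  expect_equal(o2[8], 35)
  expect_equal(diff(o2), rep(-30 / 8, 7))
  f <- gradient_oracle(1, "first-order", 0.9, 8)
  expect_equal(f[8], 0.9^8)
  expect_equal(f[8], 0.430, tolerance = 2e-3)
  expect_error(gradient_oracle(65, "zero-order", 10, 8), "negative")
  expect_error(gradient_oracle(1, "first-order", 1.2, 8), "survival")
})

test_that("the fixed oxygen profile is the steady state of the chain", {
  model <- test_model()
  o2 <- oxygen_steady_state(model, horizon = 400, dt = 0.05)
  expect_equal(o2, oxygen_profile(model$params), tolerance = 1e-6)
  expect_equal(o2[model$n_comp], 35, tolerance = 1e-6)
  expect_true(all(diff(oxygen_profile(model$params)) < 0))
})

test_that("pancreatic secretion is sigmoidal, bounded and monotone", {
  params <- structural_params()
  g <- seq(0, 30000, length.out = 60)
  ins <- pancreas_rates(g, params)$insulin
  glg <- pancreas_rates(g, params)$glucagon
  expect_true(all(diff(ins) >= 0))
  expect_true(all(diff(glg) <= 0))
  hz <- params$hormones
  expect_equal(pancreas_rates(0, params)$insulin, hz$ins_sec$basal)
  expect_equal(pancreas_rates(0, params)$glucagon,
               hz$glg_sec$basal + hz$glg_sec$vmax)
  expect_lte(max(ins), hz$ins_sec$basal + hz$ins_sec$vmax)
  expect_error(pancreas_rates(-5), ">= 0")
})

test_that("body-compartment stoichiometry follows the declared conversions", {
  params <- structural_params()
  scen <- make_scenario("MH")
  body <- fixture_blood()
  d <- body_derivatives(body, scen, params, t = 0)
  # isolate adipose lipolysis: TG -> 3 FFA + glycerol
  p <- params
  for (nm in c("a_lgen", "gut_tsyn", "mus_glc", "mus_ffa", "lac_prod",
               "lac_use", "glyc_use")) {
    p$body[[nm]]$vb <- 0
  }
  p$body$renal$k <- 0
  p$hormones$ins_sec$basal <- 0; p$hormones$ins_sec$vmax <- 0
  p$hormones$glg_sec$basal <- 0; p$hormones$glg_sec$vmax <- 0
  p$hormones$k_deg_ins_body <- 0; p$hormones$k_deg_glg_body <- 0
  p$inputs$const_glucose <- 0; p$inputs$const_ffa <- 0
  scen_c <- make_scenario("constant_baseline")
  dl <- body_derivatives(body, scen_c, p, t = 0)
  r <- -dl[["tg_b"]]
  expect_gt(r, 0)
  expect_equal(dl[["ffa_b"]], 3 * r, tolerance = 1e-12)
  expect_equal(dl[["glycerol_b"]], r, tolerance = 1e-12)
  # isolate adipose lipogenesis: 4 glucose -> 1 FFA
  p2 <- p; p2$body$a_lply$vb <- 0
  p2$body$a_lgen$vb <- params$body$a_lgen$vb
  d2 <- body_derivatives(body, scen_c, p2, t = 0)
  r2 <- d2[["ffa_b"]]
  expect_gt(r2, 0)
  expect_equal(d2[["glucose_b"]], -4 * r2, tolerance = 1e-12)
  # all-zero state produces no negative-going derivatives
  zero <- setNames(rep(0, 7), blood_species())
  dz <- body_derivatives(zero, scen_c, p, t = 0)
  expect_true(all(dz >= 0))
})

test_that("hormone degradation constants reproduce the extraction fractions", {
  model <- test_model()
  n <- model$n_comp
  f <- model$f_ins
  expect_equal(f^n, 1 - model$params$hormones$hep_extract_ins)
  # steady state of one compartment: outflow/inflow = 1/(1 + k tau)
  expect_equal(1 / (1 + model$kdeg_ins_sin / model$tau_rate), f)
})
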