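# Integrator behaviour, cross-implementation agreement, observables.

test_that("compiled and reference derivatives agree to round-off", {
  model <- test_model()
  scen <- make_scenario("NAFLD")
  for (seed in 1:3) {
    y <- random_state(model, seed)
    dC <- core_derivatives(y, 1234, model, scen)
    dR <- model_derivatives(y, 1234, model, scen)
    expect_equal(dC$dy, dR$dy, tolerance = 1e-12)
    expect_equal(unname(dC$rates), unname(dR$rates), tolerance = 1e-12)
  }
})

test_that("a uniform state of the inert model is a fixed point", {
  params <- inert_params()
  model <- sinusoid_model(params)
  y0 <- uniform_state(model)
  sim <- integrate_model(model, make_scenario("constant_baseline"), 300,
                         y0 = y0, dt = 0.1, record_rates = FALSE)
  expect_equal(sim$y_end, y0, tolerance = 1e-12)
})

test_that("the RK4 global error scales as dt^4 (Richardson check)", {
  model <- test_model()
  scen <- make_scenario("MH")
  y0 <- cold_start_state(model)
  run <- function(dt) integrate_model(model, scen, 60, y0 = y0, dt = dt,
                                      record_rates = FALSE)$y_end
  ref <- run(0.0125)
  e1 <- max(abs(run(0.4) - ref))
  e2 <- max(abs(run(0.2) - ref))
  expect_gt(e1 / e2, 8)   # ~16 for a clean 4th-order method
  expect_lt(e1 / e2, 40)
})

test_that("integration aborts with a diagnostic on forced blow-up", {
  params <- structural_params()
  params$hepatic$atpu$vb <- 1e9   # pathological ATP drain
  model <- sinusoid_model(params)
  y0 <- cold_start_state(model)
  expect_error(
    integrate_model(model, make_scenario("MH"), 60, y0 = y0, dt = 0.1,
                    record_rates = FALSE),
    "negative|non-finite")
})

test_that("trajectory extraction is consistent with the state layout", {
  model <- test_model()
  y0 <- cold_start_state(model)
  sim <- integrate_model(model, make_scenario("MH"), 120, y0 = y0, dt = 0.1,
                         sample_dt = 60)
  expect_equal(dim(species_trajectory(sim, "atp")), c(3, 8))
  expect_equal(dim(rate_trajectory(sim, "boxi")), c(3, 8))
  expect_equal(length(species_trajectory(sim, "body.glucose_b")), 3)
  net <- rate_trajectory(sim, "ffat")
  expect_equal(net, rate_trajectory(sim, "ffa_up") -
                 rate_trajectory(sim, "ffa_rel"))
  expect_error(species_trajectory(sim, "nope"), "unknown")
})

test_that("observables report exact unit ratios for a uniform cycle", {
  model <- test_model()
  n <- model$n_comp
  # synthetic spatially-uniform "cycle"
  ns <- 5
  states <- matrix(rep(uniform_state(model, 100, 50), each = ns), ns)
  rates <- matrix(0.25, ns, n * 27)
  sim <- structure(list(times = seq(0, 14400, length.out = ns),
                        states = states, rates = rates, model = model,
                        scenario = make_scenario("MH")), class = "hz_sim")
  ob <- observables(sim)
  expect_equal(unname(ob$tsyn_ratio), c(1, 1))
  expect_equal(unname(ob$tg_ratio), c(1, 1))
  expect_equal(unname(ob$ffa_ratio), c(1, 1))
  expect_equal(unname(ob$glycogen_swing), rep(0, n))
  expect_equal(ob$tg_pct_avg, tg_percent(100))
})

test_that("adaptive and RK4 backends agree on a short trajectory", {
  skip_if_not_installed("deSolve")
  model <- test_model()
  scen <- make_scenario("MH")
  y0 <- cold_start_state(model)
  a <- integrate_model(model, scen, 600, y0 = y0, dt = 0.1,
                       record_rates = FALSE)
  b <- integrate_model(model, scen, 600, y0 = y0, dt = 0.1,
                       record_rates = FALSE, method = "lsoda")
  expect_equal(a$y_end, unname(b$y_end), tolerance = 1e-4)
})

test_that("cycle equilibrium refuses constant-waveform scenarios", {
  model <- test_model()
  expect_error(run_to_cycle_equilibrium(model, make_scenario("constant_baseline")),
               "constant")
})
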