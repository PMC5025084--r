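# Calibration machinery and verification audits.

test_that("one free parameter and one attainable target fit to residual 0", {
  params <- structural_params()
  tg <- calibration_target("atpu_vb", 2.5,
                           function(p) p$hepatic$atpu$vb,
                           tol = 0.01, provenance = "TRIVIAL")
  fit <- calibrate(params, "hepatic.atpu.vb", list(tg))
  expect_true(fit$converged)
  expect_equal(fit$params$hepatic$atpu$vb, 2.5, tolerance = 1e-4)
  expect_lt(abs(fit$residuals$rel_residual[1]), 1e-4)
})

test_that("a perturbed rate constant is recovered from rate observables", {
  params <- reference_params()
  hep <- fixture_hep(); blood <- fixture_blood()
  truth <- process_rate("boxi", hep, blood, compartment = 2, params = params)
  perturbed <- params
  perturbed$hepatic$boxi$vb <- perturbed$hepatic$boxi$vb * 1.2
  tg <- calibration_target(
    "boxi_rate", truth,
    function(p) process_rate("boxi", hep, blood, compartment = 2, params = p),
    tol = 0.05, provenance = "DERIVED")
  fit <- calibrate(perturbed, "hepatic.boxi.vb", list(tg))
  expect_true(fit$converged)
  expect_equal(fit$params$hepatic$boxi$vb, params$hepatic$boxi$vb,
               tolerance = 0.05)
})

test_that("calibration is deterministic", {
  params <- structural_params()
  tg <- calibration_target("k", 3, function(p) p$hepatic$gk$vb, tol = 0.01,
                           provenance = "TRIVIAL")
  f1 <- calibrate(params, "hepatic.gk.vb", list(tg))
  f2 <- calibrate(params, "hepatic.gk.vb", list(tg))
  expect_identical(f1$params$hepatic$gk$vb, f2$params$hepatic$gk$vb)
})

test_that("conservation audit passes and detects corrupted stoichiometry", {
  model <- test_model()
  aud <- conservation_audit(model, n_random_states = 50, seed = 4)
  expect_true(aud$pass)
  expect_lt(aud$max_pool_violation, 1e-10)
  expect_lt(aud$max_advection_violation, 1e-10)
})

test_that("a deliberately corrupted ATP coefficient fails the pool audit", {
  # audit the R-side stoichiometric matrix directly with a mutated column
  S <- stoichiometry_matrix()
  S["atp", "gk"] <- S["atp", "gk"] + 1
  set.seed(9)
  viol <- replicate(100, {
    r <- runif(27, 0, 10)
    sum((S %*% r)[c("atp", "adp", "amp"), ])
  })
  expect_gt(max(abs(viol)), 1e-6)
})

test_that("parameter get/set round-trips dotted paths", {
  p <- structural_params()
  p2 <- hepzone:::param_set(p, "hepatic.boxi.vb", 7.5)
  expect_equal(hepzone:::param_get(p2, "hepatic.boxi.vb"), 7.5)
  expect_equal(hepzone:::param_get(p2, "hepatic.boxi.K_ffa"),
               p$hepatic$boxi$K_ffa)
})

test_that("parameter YAML round-trips through write/read", {
  p <- reference_params()
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  q <- reference_params(f)
  expect_equal(q$hepatic$boxi$vb, p$hepatic$boxi$vb, tolerance = 1e-8)
  expect_equal(q$zonation$gk, p$zonation$gk, tolerance = 1e-10)
  unlink(f)
})
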