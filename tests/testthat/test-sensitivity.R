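# Sensitivity sweep mechanics (cheap configurations; the quantitative
# values of the full protocol are covered by the acceptance suite).

test_that("a zero-size perturbation reproduces the control exactly", {
  model <- sinusoid_model(reference_params())
  res <- rate_sweep(model, processes = c("boxi", "vldl"), delta = 0,
                    horizon_h = 0.25, dt = 0.2, check_steady = FALSE)
  expect_equal(nrow(res), 4)
  expect_equal(max(abs(res$d_tg_c)), 0)
  expect_equal(max(abs(res$d_ffa_c)), 0)
  expect_equal(max(abs(res$d_tg_b)), 0)
})

test_that("opposite perturbations move hepatic TG in opposite directions", {
  model <- sinusoid_model(reference_params())
  res <- rate_sweep(model, processes = c("boxi", "vldl"), delta = 0.10,
                    horizon_h = 2, dt = 0.2, check_steady = FALSE)
  for (p in c("boxi", "vldl")) {
    up <- res$d_tg_c[res$process == p & res$direction == "increased"]
    dn <- res$d_tg_c[res$process == p & res$direction == "reduced"]
    expect_lt(up * dn, 0)
    # raising oxidation or export lowers hepatic TG
    expect_lt(up, 0)
  }
})

test_that("the steady-state guard trips on a drifting baseline", {
  params <- reference_params()
  params$inputs$const_glucose <- params$inputs$const_glucose * 3
  model <- sinusoid_model(params)
  expect_error(rate_sweep(model, processes = "boxi", horizon_h = 1,
                          dt = 0.2, steady_tol = 1e-4),
               "steady state")
})

test_that("zonation shifts that would leave (-1,1) are skipped with warning", {
  model <- sinusoid_model(reference_params())
  # gs has k_n = 0.5; +0.6 would reach 1.1
  expect_warning(
    res <- zonation_sweep(model, processes = "gs", delta = 0.6,
                          dt = 0.4, max_cycles = 2, tol = 1),
    "skip")
  expect_true(is.na(res$ratio_plus[1]) || is.finite(res$ratio_plus[1]))
})
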