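# Rate-law primitives, stoichiometry and unit conversions.

test_that("Hill factors have the closed-form values and stay in [0,1]", {
  expect_equal(hill_term(460, 460, 1), 0.5)
  expect_equal(hill_term(0, 10, 2), 0)
  expect_equal(hill_term(0, 10, 2, "inhibition"), 1)
  # c = 2K, n = 2: (2K)^2 / (K^2 + (2K)^2) = 4/5
  expect_equal(hill_term(20, 10, 2), 0.8)
  set.seed(7)
  for (i in 1:50) {
    c <- runif(1, 0, 1e4); K <- runif(1, 1e-3, 1e4); n <- sample(1:4, 1)
    a <- hill_term(c, K, n); b <- hill_term(c, K, n, "inhibition")
    expect_gte(a, 0); expect_lte(a, 1)
    expect_equal(a + b, 1)
  }
  expect_error(hill_term(1, -1, 1), "K must be")
  expect_error(hill_term(1, 1, 0), "n must be")
  expect_error(hill_term(-1, 1, 1), ">= 0")
})

test_that("rate laws are monotone in each substrate", {
  hep <- fixture_hep(); blood <- fixture_blood()
  grid <- seq(1, 2000, length.out = 25)
  for (spec in c("g3p_gadp", "ffa_c", "atp")) {
    rates <- vapply(grid, function(v) {
      h <- hep; h[[spec]] <- v
      process_rate("tsyn", h, blood, compartment = 4)
    }, numeric(1))
    expect_true(all(diff(rates) >= 0),
                info = paste("tsyn monotone in", spec))
  }
})

test_that("triglyceride synthesis substrate factor is 0.5 at the 460 uM K_M", {
  hep <- fixture_hep(); blood <- fixture_blood()
  h460 <- hep; h460[["g3p_gadp"]] <- 460
  hsat <- hep; hsat[["g3p_gadp"]] <- 460e6
  r <- process_rate("tsyn", h460, blood, compartment = 1) /
    process_rate("tsyn", hsat, blood, compartment = 1)
  expect_equal(r, 0.5, tolerance = 1e-5)
})

test_that("irreversible processes stall at zero substrate", {
  hep <- fixture_hep(); blood <- fixture_blood()
  stalls <- list(gk = "glucose_c", gs = "utp", boxi = "ffa_c",
                 tsyn = "ffa_c", lgen = "acetyl_coa", pdh = "pyr_lac",
                 atpu = "atp")
  for (p in names(stalls)) {
    h <- hep; h[[stalls[[p]]]] <- 0
    expect_equal(process_rate(p, h, blood, compartment = 3), 0,
                 info = p)
  }
})

test_that("stoichiometry reproduces the rate-equation table", {
  S <- stoichiometry_matrix()
  # fractional coefficients encoding indirect NADH-derived ATP
  expect_equal(S["atp", "pk"], 3.25)
  expect_equal(S["adp", "pk"], -3.25)
  expect_equal(S["pi", "pk"], -2.25)
  expect_equal(S["atp", "pdh"], 2.5)
  expect_equal(S["atp", "atps"], 12)
  expect_equal(S["acetyl_coa", "lgen"], -8)
  expect_equal(S["acetyl_coa", "boxi"], 8)
  expect_equal(S["ffa_c", "tsyn"], -3)
  expect_equal(S["amp", "tsyn"], 3)
  expect_equal(S["pi", "tsyn"], 7)
  # lipogenesis-only rate vector
  rates <- setNames(rep(0, 27), process_names())
  rates[["lgen"]] <- 1
  d <- hepatic_derivatives(rates)
  expect_equal(d[["acetyl_coa"]], -8)
  expect_equal(d[["ffa_c"]], 1)
  expect_equal(d[["atp"]], -7)
  expect_equal(d[["adp"]], 7)
  expect_equal(d[["pi"]], 7)
  expect_error(hepatic_derivatives(rates[-1]), "missing process")
})

test_that("nucleotide pools are conserved for any rate vector", {
  S <- stoichiometry_matrix()
  set.seed(11)
  for (i in 1:200) {
    r <- setNames(runif(27, 0, 10), process_names())
    d <- hepatic_derivatives(r)
    expect_equal(sum(d[c("atp", "adp", "amp")]), 0, tolerance = 1e-12)
    expect_equal(sum(d[c("utp", "udp")]), 0, tolerance = 1e-12)
    expect_equal(sum(d[c("gtp", "gdp")]), 0, tolerance = 1e-12)
  }
})

test_that("carbon bookkeeping balances for the lipid conversions", {
  carbons <- c(glucose_c = 6, g6p = 6, glycogen = 6, g3p_gadp = 3,
               pyr_lac = 3, acetyl_coa = 2, ffa_c = 16, tg_c = 51,
               glycerol_c = 3, atp = 0, adp = 0, amp = 0, pi = 0,
               utp = 0, udp = 0, gtp = 0, gdp = 0)
  S <- stoichiometry_matrix()
  balanced <- c("gs", "gp", "pfk", "pk", "pepck", "fbp", "lgen", "boxi",
                "tsyn", "lply", "gconv", "gk", "g6pase")
  for (p in balanced) {
    expect_equal(sum(carbons * S[, p]), 0, info = p)
  }
})

test_that("triglyceride percent conversion is anchored at 50 mg/g = 5%", {
  expect_equal(tg_percent(0), 0)
  tg5 <- tg_from_percent(5)
  # 50 mg TG per g wet weight at unit density and 885.4 g/mol
  expect_equal(tg5 * 1e-6 * 885.4, 50, tolerance = 1e-9)
  expect_equal(tg_percent(tg5), 5)
  expect_equal(tg_percent(tg5 / 2), 2.5)
  expect_error(tg_percent(-1), ">= 0")
})

test_that("effective hormones implement insulin resistance and the clamp", {
  mh <- list(K_IR = 1, srebp1c = FALSE)
  expect_equal(effective_hormones(0.5, 0.1, mh)$insulin_eff, 0.5)
  sev <- list(K_IR = 0.015, srebp1c = FALSE)
  expect_equal(effective_hormones(0.5, 0.1, sev)$insulin_eff, 0.0075)
  naf <- list(K_IR = 0.015, srebp1c = TRUE, srebp_clamp_nM = 1)
  expect_equal(effective_hormones(0.1, 0.1, naf, "lgen")$insulin_eff, 1)
  expect_equal(effective_hormones(0.1, 0.1, naf, "tsyn")$insulin_eff, 1)
  # non-lipogenic processes still see the resistant signal
  expect_equal(effective_hormones(0.1, 0.1, naf, "gs")$insulin_eff, 0.0015)
  expect_equal(effective_hormones(0.1, 0.2, naf, "lgen")$glucagon_eff, 0.2)
  expect_error(effective_hormones(0.1, 0.1, list(K_IR = 0)), "K_IR")
})
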