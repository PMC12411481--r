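patient <- list(bsa_m2 = 1.72, weight_kg = 65)

test_that("drug cost per cycle follows dose rules, caps and mixtures", {
  costs <- list(drug_price_per_100mg = list(pembrolizumab = 2451.60,
                                            gemcitabine = 18.64))
  pem <- list(list(drug = "pembrolizumab", dose_mg = 200, rule = "flat",
                   admin_per_cycle = 1, max_cycles = 35, weight = 1))
  expect_equal(drug_cost_per_cycle(pem, costs, patient, 1, "pfs"), 4903.20)
  expect_equal(drug_cost_per_cycle(pem, costs, patient, 35, "pfs"), 4903.20)
  # beyond the treated-cycle cap, and outside PFS: zero
  expect_equal(drug_cost_per_cycle(pem, costs, patient, 36, "pfs"), 0)
  expect_equal(drug_cost_per_cycle(pem, costs, patient, 1, "pd"), 0)
  # BSA dosing: gemcitabine 1000 mg/m2 on days 1+8
  gem <- list(list(drug = "gemcitabine", dose_mg = 1000, rule = "per_m2",
                   admin_per_cycle = 2, max_cycles = Inf, weight = 1))
  expect_equal(drug_cost_per_cycle(gem, costs, patient, 1, "pfs"),
               2 * (1000 * 1.72 / 100) * 18.64)
  expect_equal(round(drug_cost_per_cycle(gem, costs, patient, 1, "pfs"), 2),
               641.22)
  # unknown drug is a config error
  bad <- list(list(drug = "mystery", dose_mg = 1, rule = "flat",
                   admin_per_cycle = 1))
  expect_error(drug_cost_per_cycle(bad, costs, patient, 1, "pfs"),
               "no unit price")
})

test_that("discounting is annual-rate compounding in cycle time", {
  expect_identical(discount_factor(0, 0.05), 1)
  expect_identical(discount_factor(0:10, 0), rep(1, 11))
  # 365.25/21 cycles = exactly one year
  expect_equal(discount_factor(365.25 / 21, 0.05), 1 / 1.05)
  expect_error(discount_factor(1, -0.01), ">= 0")
})

test_that("QALY and terminal-cost accrual match direct arithmetic", {
  cfg <- base_config()
  settings <- cfg$settings
  settings$horizon_cycles <- 1
  settings$discount_rate <- 0
  # one cycle fully progression-free
  tr <- run_cohort(function(t) 1, function(t) 1, mortality = 0, horizon = 1)
  no_ae <- list(incidence = list(), disutility = list())
  costs <- cfg$costs
  res <- accumulate_outcomes(tr, regimen = list(), costs = costs,
                             utilities = list(pfs = 0.76, pd = 0.55),
                             ae = no_ae, settings = settings,
                             patient = patient,
                             apply_ae_disutility = FALSE)
  expect_equal(res$qalys, 0.76 * 21 / 365.25)
  expect_equal(res$life_years, 21 / 365.25)
  # newly-dead fraction 0.1 at cycle k adds 0.1 x terminal x df(k)
  k <- 4
  cyc_mo <- 21 / 30.4375
  s_os <- function(t) ifelse(t < (k - 0.5) * cyc_mo, 1, 0.9)
  settings2 <- cfg$settings
  settings2$horizon_cycles <- 6
  tr2 <- run_cohort(s_os, s_os, mortality = 0, horizon = 6)
  expect_equal(tr2$newDead[k + 1], 0.1)
  res2 <- accumulate_outcomes(tr2, regimen = list(), costs = costs,
                              utilities = list(pfs = 0.76, pd = 0.55),
                              ae = no_ae, settings = settings2,
                              patient = patient,
                              apply_ae_disutility = FALSE)
  expect_equal(res2$components[["terminal"]],
               0.1 * 2325.75 * discount_factor(k, 0.05))
  # horizon mismatch errors
  expect_error(accumulate_outcomes(tr2, list(), costs,
                                   list(pfs = 0.76, pd = 0.55), no_ae,
                                   settings, patient), "cycles")
})

test_that("discounting shrinks totals and QALYs never exceed life-years", {
  cfg <- base_config()
  res <- run_cea(cfg)
  cfg0 <- set_config_value(cfg, "settings.discount_rate", 0)
  res0 <- run_cea(cfg0)
  for (nm in names(res$results)) {
    expect_lt(res$results[[nm]]$cost, res0$results[[nm]]$cost)
    expect_lt(res$results[[nm]]$qalys, res0$results[[nm]]$qalys)
    expect_lte(res$results[[nm]]$qalys,
               res$results[[nm]]$life_years * 0.76)
    expect_gte(res$results[[nm]]$cost, 0)
  }
})

test_that("the ICER reports ratios and dominance flags", {
  mk <- function(cost, qalys) {
    structure(list(cost = cost, qalys = qalys, life_years = qalys),
              class = "econ_result")
  }
  expect_equal(icer(mk(100, 2), mk(0, 0))$icer, 50)
  expect_identical(icer(mk(100, 1), mk(50, 1))$dominance, "zero_dqaly")
  expect_true(is.na(icer(mk(100, 1), mk(50, 1))$icer))
  expect_identical(icer(mk(10, 2), mk(50, 1))$dominance, "dominant")
  expect_identical(icer(mk(100, 1), mk(50, 2))$dominance, "dominated")
  # printed scenario-table cells back-derive the unrounded dQALY
  expect_equal(16494.37 / 35362.45, 0.46644, tolerance = 1e-4)
})

test_that("price discounts rescale exactly one unit price", {
  cfg <- base_config()
  same <- apply_price_discount(cfg, "pembrolizumab", 0)
  expect_equal(same$costs, cfg$costs)
  zero <- apply_price_discount(cfg, "pembrolizumab", 1)
  expect_equal(zero$costs$drug_price_per_100mg$pembrolizumab, 0)
  d8 <- apply_price_discount(cfg, "pembrolizumab", 0.8)
  expect_equal(d8$costs$drug_price_per_100mg$pembrolizumab, 490.32)
  expect_equal(d8$costs$drug_price_per_100mg$gemcitabine, 18.64)
  expect_error(apply_price_discount(cfg, "nope", 0.5), "unknown drug")
  expect_error(apply_price_discount(cfg, "pembrolizumab", 1.2), "\\[0, 1\\]")
})

test_that("ICER falls strictly as the pembrolizumab discount deepens", {
  cfg <- base_config()
  icers <- vapply(c(0, 0.4, 0.8, 0.95), function(d) {
    run_cea(apply_price_discount(cfg, "pembrolizumab", d))$incremental$icer
  }, numeric(1))
  expect_true(all(diff(icers) < 0))
})
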