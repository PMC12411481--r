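test_that("tornado entries are sorted and degenerate bounds give zero width", {
  cfg <- base_config()
  specs <- tibble::tibble(
    id = c("utility_pfs", "flat", "inert"),
    path = c("utilities.pfs", "utilities.pd", "patient.weight_kg"),
    base = c(0.76, 0.55, 65), lower = c(0.57, 0.55, 50),
    upper = c(0.95, 0.55, 80),
    dist = c("beta", "beta", "fixed"), valid = TRUE)
  tor <- owsa(cfg, specs)
  expect_true(all(diff(tor$width) <= 0))
  expect_equal(tor$width[tor$id == "flat"], 0)
  # weight_kg feeds no dose rule in the base regimen: exactly zero width
  expect_equal(tor$width[tor$id == "inert"], 0)
  expect_gt(tor$width[tor$id == "utility_pfs"], 0)
})

test_that("parameter sampling is moment-matched and reproducible", {
  specs <- tibble::tibble(
    id = c("price", "util", "fix"),
    path = c("costs.drug_price_per_100mg.pembrolizumab", "utilities.pfs",
             "settings.wtp"),
    base = c(2451.60, 0.76, 38224),
    lower = c(1838.70, 0.57, 38224),
    upper = c(3064.50, 0.95, 38224),
    dist = c("gamma", "beta", "fixed"), valid = TRUE)
  d1 <- sample_parameters(specs, 10000, seed = 9)
  d2 <- sample_parameters(specs, 10000, seed = 9)
  expect_identical(d1, d2)
  # gamma mean within 2 Monte-Carlo standard errors of the base price
  sdv <- (3064.50 - 1838.70) / 3.92
  expect_lt(abs(mean(d1[, "price"]) - 2451.60), 2 * sdv / sqrt(10000))
  # beta draws stay inside the printed interval
  expect_true(all(d1[, "util"] >= 0.57 & d1[, "util"] <= 0.95))
  expect_true(all(d1[, "fix"] == 38224))
})

test_that("all-fixed specs reproduce the base case in every iteration", {
  cfg <- base_config()
  cfg$psa$include_survival_uncertainty <- FALSE
  specs <- param_specs(cfg)
  specs$dist[] <- "fixed"
  psa <- run_psa(cfg, specs, n_iter = 5, seed = 1)
  base <- run_cea(cfg)$incremental
  expect_equal(psa$n_failed, 0L)
  expect_true(all(psa$iterations$delta_cost == base$delta_cost))
  expect_true(all(psa$iterations$delta_qaly == base$delta_qaly))
})

test_that("PSA output is bit-identical under a fixed seed", {
  cfg <- base_config()
  specs <- param_specs(cfg)
  p1 <- run_psa(cfg, specs, n_iter = 25, seed = 77)
  p2 <- run_psa(cfg, specs, n_iter = 25, seed = 77)
  expect_identical(p1$iterations, p2$iterations)
  # and a different seed genuinely changes the draws
  p3 <- run_psa(cfg, specs, n_iter = 25, seed = 78)
  expect_false(identical(p1$iterations$delta_cost, p3$iterations$delta_cost))
})

test_that("PSA means converge to the base case as intervals shrink", {
  cfg <- base_config()
  cfg$psa$include_survival_uncertainty <- FALSE
  specs <- param_specs(cfg)
  eps <- 1e-6
  specs$lower <- specs$base * (1 - eps) - eps
  specs$upper <- specs$base * (1 + eps) + eps
  psa <- run_psa(cfg, specs, n_iter = 30, seed = 4)
  base <- run_cea(cfg)$incremental
  expect_equal(mean(psa$iterations$delta_cost), base$delta_cost,
               tolerance = 1e-3)
  expect_equal(mean(psa$iterations$delta_qaly), base$delta_qaly,
               tolerance = 1e-3)
})

test_that("the acceptability curve is a proper probability curve", {
  cfg <- base_config()
  cfg$psa$include_survival_uncertainty <- FALSE
  psa <- run_psa(cfg, param_specs(cfg), n_iter = 200, seed = 12)
  grid <- seq(0, 8e5, by = 2e4)
  cc <- ceac(psa, grid)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # at lambda = 0 the definition reduces to P(dCost < 0)
  it <- psa$iterations
  expect_equal(cc$probability[cc$wtp == 0], mean(it$delta_cost < 0))
  # dQALY > 0 throughout here, so the curve is non-decreasing in lambda
  if (all(it$delta_qaly > 0)) {
    expect_true(all(diff(cc$probability) >= 0))
  }
  # the limit as lambda grows equals P(dQALY > 0)
  expect_equal(ceac(psa, 1e15)$probability, mean(it$delta_qaly > 0))
  expect_error(ceac(psa, numeric()), "empty")
})
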