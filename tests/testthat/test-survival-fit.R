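test_that("exponential MLE matches the closed form events/total-time", {
  d <- simulate_ipd(sim_spec("exponential", c(rate = 0.12), n = 400,
                             seed = 7))
  fit <- fit_surv_mle(d, "exponential")
  expect_true(fit$converged)
  expect_equal(unname(fit$model$params[["rate"]]),
               sum(d$event) / sum(d$time), tolerance = 1e-5)
  # and the log-likelihood identity for the exponential family
  r <- fit$model$params[["rate"]]
  ll <- sum(d$event) * log(r) - r * sum(d$time)
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("lognormal MLE recovers meanlog against the log-mean oracle", {
  d <- simulate_ipd(sim_spec("lognormal",
                             c(meanlog = 2.3487, sdlog = 1.2258),
                             n = 5000, seed = 11))
  fit <- fit_surv_mle(d, "lognormal")
  # uncensored data: the MLE of meanlog is the sample mean of log-times
  expect_equal(unname(fit$model$params[["meanlog"]]), mean(log(d$time)),
               tolerance = 1e-4)
  expect_lt(abs(fit$model$params[["meanlog"]] - 2.3487), 0.05)
})

test_that("AIC and BIC identities hold exactly given loglik, k, n", {
  d <- simulate_ipd(sim_spec("weibull", c(shape = 1.5, scale = 10),
                             n = 300, censor_rate = 0.02, seed = 3))
  for (fam in surv_families()) {
    fit <- fit_surv_mle(d, fam)
    expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$k, info = fam)
    expect_equal(fit$bic, -2 * fit$loglik + fit$k * log(fit$n), info = fam)
  }
})

test_that("each family is recovered within 3 SE at n = 5000", {
  set.seed(101)
  cases <- list(
    exponential = c(rate = 0.08),
    weibull = c(shape = 1.5, scale = 10),
    gamma = c(shape = 2, rate = 0.2),
    lognormal = c(meanlog = 2.3487, sdlog = 1.2258),
    loglogistic = c(shape = 1.763, scale = 6.618),
    gompertz = c(shape = 0.06, rate = 0.02))
  for (fam in names(cases)) {
    d <- simulate_ipd(sim_spec(fam, cases[[fam]], n = 5000,
                               censor_rate = 0.01, seed = 101))
    fit <- fit_surv_mle(d, fam)
    expect_true(fit$converged, info = fam)
    est_t <- surv_params_transform(fam, fit$model$params)
    true_t <- surv_params_transform(fam, cases[[fam]])
    se <- sqrt(diag(fit$vcov))
    expect_true(all(abs(est_t - true_t) <= 3 * se),
                info = sprintf("%s: |z| = %s", fam,
                               paste(round(abs(est_t - true_t) / se, 2),
                                     collapse = ", ")))
  }
})

test_that("model selection minimizes AIC with BIC then family-order ties", {
  mk <- function(fam, aic, bic) {
    structure(list(family = fam, aic = aic, bic = bic,
                   model = surv_model("exponential", rate = 1),
                   loglik = 0, k = 1, n = 10, converged = TRUE),
              class = "surv_fit")
  }
  expect_identical(select_surv_model(list(mk("weibull", 100, 90),
                                          mk("gamma", 90, 95)))$family,
                   "gamma")
  expect_identical(select_surv_model(list(mk("weibull", 90, 85),
                                          mk("gamma", 90, 80)))$family,
                   "gamma")
  # full tie resolved by the fixed family order
  expect_identical(select_surv_model(list(mk("gompertz", 90, 80),
                                          mk("weibull", 90, 80)))$family,
                   "weibull")
  expect_error(select_surv_model(list()), "empty")
})

test_that("weibull data prefers weibull over exponential in >= 80% of seeds", {
  wins <- 0L
  for (s in 1:50) {
    d <- simulate_ipd(sim_spec("weibull", c(shape = 1.5, scale = 10),
                               n = 2000, seed = 500 + s))
    fits <- list(fit_surv_mle(d, "exponential"), fit_surv_mle(d, "weibull"))
    if (select_surv_model(fits)$family == "weibull") wins <- wins + 1L
  }
  expect_gte(wins / 50, 0.8)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_surv_mle(tibble::tibble(time = numeric(),
                                           event = integer()),
                            "exponential"), "at least 2")
  all_cens <- tibble::tibble(time = c(1, 2, 3), event = c(0L, 0L, 0L))
  expect_error(fit_surv_mle(all_cens, "weibull"), "no events")
})
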