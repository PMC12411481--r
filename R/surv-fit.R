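#' Fit a parametric survival family to right-censored data
#'
#' Maximizes the right-censored log-likelihood
#' `sum(events) log f(t) + sum(censored) log S(t)` for one family, via
#' [flexsurv::flexsurvreg()] with parameters optimized on the log scale for
#' positivity-constrained components. Three documented starting points are
#' tried in sequence until convergence: the flexsurv default initial values,
#' then the defaults halved, then doubled (on the natural scale).
#'
#' @param data A data frame with columns `time` (months, >= 0) and `event`
#'   (1 = event, 0 = right-censored). At least two records and one event.
#' @param family A family name from [surv_families()].
#' @return A `surv_fit` object: list with `model` ([surv_model()]),
#'   `family`, `loglik`, `k` (number of free parameters), `n`, `aic`
#'   (`-2 loglik + 2k`), `bic` (`-2 loglik + k log n`), `converged`, and
#'   `vcov` (covariance of the transformed parameters, or NULL).
#' @examples
#' d <- simulate_ipd(sim_spec("exponential", c(rate = 0.1), n = 100, seed = 1))
#' fit_surv_mle(d, "exponential")
#' @export
fit_surv_mle <- function(data, family) {
  family <- match.arg(family, surv_families())
  check_ipd(data, min_records = 2L)
  if (sum(data$event) < 1) {
    stop("cannot fit a survival model to data with no events", call. = FALSE)
  }
  dist <- flexsurv_dist(family)
  # flexsurv chokes on exact zeros for log-time families
  d <- data
  d$time <- pmax(d$time, 1e-8)

  attempt <- function(inits) {
    fit <- tryCatch(suppressWarnings({
      if (is.null(inits)) {
        flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = d,
                              dist = dist)
      } else {
        flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = d,
                              dist = dist, inits = inits)
      }
    }), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    conv <- is.finite(fit$loglik) &&
      (is.null(fit$opt$convergence) || fit$opt$convergence == 0)
    list(fit = fit, converged = conv)
  }

  res <- attempt(NULL)
  if (is.null(res) || !res$converged) {
    base_inits <- tryCatch(
      flexsurv::flexsurv.dists[[dist]]$inits(d$time[d$event == 1]),
      error = function(e) NULL)
    for (mult in c(0.5, 2)) {
      if (!is.null(res) && res$converged) break
      if (is.null(base_inits)) break
      res2 <- attempt(base_inits * mult)
      if (!is.null(res2) && (is.null(res) || res2$converged ||
                             res2$fit$loglik > res$fit$loglik)) {
        res <- res2
      }
    }
  }
  if (is.null(res)) {
    stop(sprintf("MLE for family '%s' failed from all starting points", family),
         call. = FALSE)
  }

  fit <- res$fit
  est <- fit$res[, "est"]
  names(est) <- rownames(fit$res)
  params <- stats::setNames(est[flexsurv_param_order(family)],
                            surv_param_names(family))
  k <- nrow(fit$res)
  n <- nrow(d)
  ll <- fit$loglik
  structure(list(
    model     = surv_model_from_params(family, params),
    family    = family,
    loglik    = ll,
    k         = k,
    n         = n,
    aic       = -2 * ll + 2 * k,
    bic       = -2 * ll + k * log(n),
    converged = res$converged,
    vcov      = tryCatch(stats::vcov(fit), error = function(e) NULL)
  ), class = "surv_fit")
}

# flexsurv's internal parameter row order, mapped onto our names
flexsurv_param_order <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gamma       = c("shape", "rate"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"),
    gompertz    = c("shape", "rate"))
}

surv_model_from_params <- function(family, params) {
  do.call(surv_model, c(list(family = family), as.list(params)))
}

#' @export
print.surv_fit <- function(x, ...) {
  cat(sprintf("<surv_fit> %s  loglik = %.3f  AIC = %.2f  BIC = %.2f  %s\n",
              x$family, x$loglik, x$aic, x$bic,
              if (x$converged) "converged" else "NOT CONVERGED"))
  print(x$model)
  invisible(x)
}

#' Select the best-fitting survival model
#'
#' Smaller AIC wins; exact AIC ties are broken by smaller BIC, then by the
#' fixed family order of [surv_families()].
#'
#' @param fits A non-empty list of `surv_fit` objects on the same data.
#' @return The selected `surv_fit`.
#' @export
select_surv_model <- function(fits) {
  if (length(fits) == 0) stop("empty fit list", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "surv_fit")))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  fam <- match(vapply(fits, `[[`, character(1), "family"), surv_families())
  fits[[order(aic, bic, fam)[1]]]
}

#' Tabulate a list of survival fits
#'
#' One row per candidate family, mirroring the layout of a model-selection
#' supplement: family, parameter estimates, log-likelihood, AIC, BIC,
#' convergence.
#'
#' @param fits List of `surv_fit` objects.
#' @return A tibble.
#' @export
fit_table <- function(fits) {
  tibble::tibble(
    family    = vapply(fits, `[[`, character(1), "family"),
    params    = vapply(fits, function(f) {
      paste(sprintf("%s = %.4g", names(f$model$params), f$model$params),
            collapse = ", ")
    }, character(1)),
    loglik    = vapply(fits, `[[`, numeric(1), "loglik"),
    aic       = vapply(fits, `[[`, numeric(1), "aic"),
    bic       = vapply(fits, `[[`, numeric(1), "bic"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
}

check_ipd <- function(data, min_records = 1L) {
  if (!is.data.frame(data) || !all(c("time", "event") %in% names(data))) {
    stop("pseudo-IPD must be a data frame with columns 'time' and 'event'",
         call. = FALSE)
  }
  if (nrow(data) < min_records) {
    stop(sprintf("at least %d record(s) required", min_records), call. = FALSE)
  }
  if (any(data$time < 0)) stop("times must be non-negative", call. = FALSE)
  if (!all(data$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  invisible(TRUE)
}
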