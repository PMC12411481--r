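#' Sensitivity-parameter specifications of a configuration
#'
#' One row per uncertain parameter: a dotted config path, the base value,
#' the deterministic range, and the probabilistic sampling family (gamma
#' for costs, beta for probabilities/utilities on their interval, fixed to
#' exclude). Rows whose base value falls outside its own interval are
#' flagged in the `valid` column (and warned about at config load), never
#' silently corrected.
#'
#' @param config A `cea_config`.
#' @return A tibble: `id`, `path`, `base`, `lower`, `upper`, `dist`,
#'   `valid`.
#' @export
param_specs <- function(config) {
  ps <- config$parameters
  if (length(ps) == 0) {
    return(tibble::tibble(id = character(), path = character(),
                          base = numeric(), lower = numeric(),
                          upper = numeric(), dist = character(),
                          valid = logical()))
  }
  tibble::tibble(
    id = vapply(ps, `[[`, character(1), "id"),
    path = vapply(ps, `[[`, character(1), "path"),
    base = vapply(ps, `[[`, numeric(1), "base"),
    lower = vapply(ps, `[[`, numeric(1), "lower"),
    upper = vapply(ps, `[[`, numeric(1), "upper"),
    dist = vapply(ps, `[[`, character(1), "dist"),
    valid = vapply(ps, function(p) p$base >= p$lower && p$base <= p$upper,
                   logical(1))
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the full two-arm model once at the lower and once at the upper
#' bound of each parameter, all other inputs at base, and records the two
#' ICERs. Entries are sorted by descending bar width `|ICER_hi - ICER_lo|`.
#' A bound that produces an invalid model run is flagged (`ok = FALSE`)
#' and the analysis continues.
#'
#' @param config A `cea_config`.
#' @param specs Parameter specifications, default [param_specs()].
#' @return A tibble: `id`, `icer_low`, `icer_high`, `width`, `ok`, sorted
#'   by descending width.
#' @export
owsa <- function(config, specs = param_specs(config)) {
  base_res <- run_cea(config)
  one <- function(path, value) {
    tryCatch({
      res <- run_cea(set_config_value(config, path, value))
      res$incremental$icer
    }, error = function(e) NA_real_)
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    lo <- one(specs$path[i], specs$lower[i])
    hi <- one(specs$path[i], specs$upper[i])
    tibble::tibble(id = specs$id[i], icer_low = lo, icer_high = hi,
                   width = abs(hi - lo), ok = !is.na(lo) && !is.na(hi))
  })
  out <- do.call(rbind, rows)
  out$width[!out$ok] <- NA_real_
  out <- out[order(-out$width, method = "radix", na.last = TRUE), ]
  attr(out, "base_icer") <- base_res$incremental$icer
  out
}

#' Moment-matched distribution draws for probabilistic sensitivity analysis
#'
#' The printed range of each parameter is read as a 95 per cent interval,
#' `sd = (upper - lower)/3.92`. Costs are sampled from a gamma
#' distribution moment-matched to (base, sd); probabilities, utilities and
#' other bounded quantities from a beta distribution on the interval
#' `[lower, upper]` rescaled so its mean is the base value. `fixed`
#' parameters, zero-width intervals, and flagged rows (base outside the
#' interval) are returned at their base value. Identical seed, identical
#' draws.
#'
#' @param specs Parameter specification tibble ([param_specs()]).
#' @param n Number of joint draws.
#' @param seed Optional integer seed (`set.seed` when non-NULL).
#' @return An `n` x `nrow(specs)` matrix, columns named by `id`.
#' @export
sample_parameters <- function(specs, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(rep(specs$base, each = n), nrow = n,
                  dimnames = list(NULL, specs$id))
  for (i in seq_len(nrow(specs))) {
    sdv <- (specs$upper[i] - specs$lower[i]) / 3.92
    if (specs$dist[i] == "fixed" || sdv <= 0 || !specs$valid[i]) next
    base <- specs$base[i]
    if (specs$dist[i] == "gamma") {
      shape <- (base / sdv)^2
      rate <- base / sdv^2
      draws[, i] <- stats::rgamma(n, shape = shape, rate = rate)
    } else if (specs$dist[i] == "beta") {
      lo <- specs$lower[i]; hi <- specs$upper[i]
      m <- (base - lo) / (hi - lo)
      s <- sdv / (hi - lo)
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0) next # interval too wide for a proper beta; keep base
      draws[, i] <- lo + (hi - lo) * stats::rbeta(n, m * nu, (1 - m) * nu)
    }
  }
  draws
}

#' Survival-parameter uncertainty for the PSA
#'
#' The published curve parameters come without standard errors, so the
#' parameter-uncertainty covariance of each fitted curve is estimated by
#' refitting its stated family to one synthetic trial arm of the published
#' size (`n_trial` per strategy), drawn from the base-case curve with the
#' configured administrative cutoff and random-censoring rate. PSA
#' iterations then draw curve parameters from a multivariate normal
#' centred at the base-case estimates on the unconstrained (log) scale.
#'
#' @param config A `cea_config`.
#' @return Nested list `[[strategy]][[endpoint]]` with `family`, `center`
#'   (transformed scale) and `vcov`.
#' @export
survival_uncertainty <- function(config) {
  s <- config$psa
  out <- list()
  for (nm in names(config$strategies)) {
    st <- config$strategies[[nm]]
    out[[nm]] <- list()
    for (ep in c("pfs", "os")) {
      model <- strategy_curve(st, ep)
      spec <- sim_spec(model$family, model$params,
                       n = st$n_trial %||% 200,
                       censor_rate = s$censor_rate_per_month,
                       cutoff = s$trial_cutoff_months,
                       seed = sample.int(.Machine$integer.max, 1))
      fit <- fit_surv_mle(simulate_ipd(spec), model$family)
      V <- fit$vcov
      if (is.null(V)) {
        stop(sprintf(
          "could not estimate curve-parameter covariance for %s/%s", nm, ep),
          call. = FALSE)
      }
      out[[nm]][[ep]] <- list(
        family = model$family,
        center = surv_params_transform(model$family, model$params),
        vcov = V)
    }
  }
  out
}

draw_curve_params <- function(unc_entry) {
  mu <- unc_entry$center
  L <- chol(unc_entry$vcov)
  tp <- as.numeric(mu) + as.numeric(t(L) %*% stats::rnorm(length(mu)))
  names(tp) <- names(mu)
  surv_params_untransform(unc_entry$family, tp)
}

apply_draw <- function(config, specs, draw) {
  for (i in seq_len(nrow(specs))) {
    config <- set_config_value(config, specs$path[i], unname(draw[[i]]))
  }
  config
}

#' Probabilistic sensitivity analysis
#'
#' `n_iter` Monte-Carlo replications; each jointly redraws every sampled
#' parameter (and, when `psa.include_survival_uncertainty` is set, the
#' four curve-parameter vectors) and reruns the full two-arm model. Failed
#' iterations are recorded as NA and counted, never silently dropped.
#' Results are bit-reproducible for a fixed seed.
#'
#' @param config A `cea_config`.
#' @param specs Parameter specifications, default [param_specs()].
#' @param n_iter Number of replications (>= 1).
#' @param seed Integer seed for the whole analysis.
#' @return A `psa_result`: list with `iterations` (tibble: `iter`,
#'   `delta_cost`, `delta_qaly`), `n_iter`, `n_failed`, `seed`, `wtp`.
#' @export
run_psa <- function(config, specs = param_specs(config), n_iter = 1000,
                    seed = config$psa$seed) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  set.seed(seed)
  unc <- if (isTRUE(config$psa$include_survival_uncertainty)) {
    survival_uncertainty(config)
  } else NULL
  draws <- sample_parameters(specs, n_iter)
  dc <- rep(NA_real_, n_iter); dq <- rep(NA_real_, n_iter)
  n_failed <- 0L
  for (it in seq_len(n_iter)) {
    cfg <- apply_draw(config, specs, draws[it, , drop = TRUE])
    if (!is.null(unc)) {
      for (nm in names(unc)) {
        for (ep in names(unc[[nm]])) {
          pars <- draw_curve_params(unc[[nm]][[ep]])
          cv <- c(list(family = unc[[nm]][[ep]]$family), as.list(pars))
          cfg$strategies[[nm]]$curves[[ep]] <- cv
        }
      }
    }
    res <- tryCatch(suppressWarnings(run_cea(cfg)), error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      dc[it] <- res$incremental$delta_cost
      dq[it] <- res$incremental$delta_qaly
    }
  }
  structure(list(
    iterations = tibble::tibble(iter = seq_len(n_iter),
                                delta_cost = dc, delta_qaly = dq),
    n_iter = n_iter, n_failed = n_failed, seed = seed,
    wtp = config$settings$wtp
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  ok <- stats::complete.cases(x$iterations)
  cat(sprintf(
    "<psa_result> %d iterations (%d failed), seed %s\n",
    x$n_iter, x$n_failed, format(x$seed)))
  cat(sprintf("  mean dCost $%.0f, mean dQALY %.4f, P(CE at WTP $%s) = %.3f\n",
              mean(x$iterations$delta_cost[ok]),
              mean(x$iterations$delta_qaly[ok]),
              format(x$wtp, big.mark = ","),
              prob_cost_effective(x, x$wtp)))
  invisible(x)
}

prob_cost_effective <- function(psa, wtp) {
  it <- psa$iterations[stats::complete.cases(psa$iterations), ]
  mean(wtp * it$delta_qaly - it$delta_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective is the fraction of PSA iterations with
#' positive net monetary benefit, `wtp * dQALY - dCost > 0`.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Non-empty vector of WTP thresholds ($/QALY). Default
#'   $0 to $800,000 in $5,000 steps.
#' @return A tibble: `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 800000, by = 5000)) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0) stop("empty WTP grid", call. = FALSE)
  it <- psa$iterations[stats::complete.cases(psa$iterations), ]
  if (nrow(it) == 0) stop("no successful PSA iterations", call. = FALSE)
  tibble::tibble(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(l) {
      mean(l * it$delta_qaly - it$delta_cost > 0)
    }, numeric(1)))
}
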