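#' Specification for a synthetic trial-like time-to-event dataset
#'
#' The generator emulates the survival data of a randomized oncology trial
#' arm: event times drawn from a known parametric family, thinned by random
#' (exponential) loss to follow-up and an administrative data cutoff. It
#' provides ground truth for testing the fitting, reconstruction and
#' model-selection pipeline without any external data.
#'
#' @param family Survival family name (see [surv_families()]).
#' @param params Named parameter vector for the family.
#' @param n Number of subjects (>= 1).
#' @param censor_rate Rate (per month) of the exponential random-censoring
#'   distribution; 0 disables random censoring.
#' @param cutoff Administrative cutoff in months (`Inf` disables).
#' @param seed Integer seed; draws are reproducible given the spec.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(family, params, n, censor_rate = 0, cutoff = Inf,
                     seed = 1L) {
  family <- match.arg(family, surv_families())
  model <- surv_model_from_params(family, unlist(params)[surv_param_names(family)])
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (censor_rate < 0) stop("censor_rate must be >= 0", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  structure(list(model = model, n = as.integer(n),
                 censor_rate = censor_rate, cutoff = cutoff,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate trial-like pseudo-IPD with known ground truth
#'
#' Observed time is `min(event time, random censoring time, cutoff)`; the
#' event indicator is 1 when the event time comes first.
#'
#' @param spec A [sim_spec()].
#' @return A tibble with columns `time` (months), `event` (0/1).
#' @examples
#' d <- simulate_ipd(sim_spec("lognormal", c(meanlog = 2.3487, sdlog = 1.2258),
#'                            n = 200, censor_rate = 0.01, cutoff = 44,
#'                            seed = 42))
#' mean(d$event)
#' @export
simulate_ipd <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  ev <- surv_rand(spec$model, spec$n)
  cens <- if (spec$censor_rate > 0) {
    stats::rexp(spec$n, spec$censor_rate)
  } else {
    rep(Inf, spec$n)
  }
  cens <- pmin(cens, spec$cutoff)
  tibble::tibble(time = pmin(ev, cens),
                 event = as.integer(ev <= cens))
}

#' Sample a Kaplan-Meier curve on a time grid
#'
#' Evaluates the product-limit estimate of `ipd` on `grid`, emulating the
#' coordinates a graph digitizer would produce from a published curve.
#'
#' @param ipd Pseudo-IPD data frame (`time`, `event`), non-empty.
#' @param grid Non-empty vector of non-negative times (months), increasing.
#' @return A tibble with columns `time`, `survival` (non-increasing).
#' @export
export_km_curve <- function(ipd, grid) {
  check_ipd(ipd, min_records = 1L)
  if (length(grid) == 0) stop("empty time grid", call. = FALSE)
  if (any(grid < 0)) stop("grid times must be non-negative", call. = FALSE)
  grid <- sort(unique(grid))
  km <- km_estimator(ipd)
  sf <- stats::stepfun(km$time[-1], km$survival, right = FALSE)
  surv <- if (nrow(km) == 1) rep(1, length(grid)) else sf(grid)
  tibble::tibble(time = grid, survival = surv)
}
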