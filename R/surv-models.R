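#' Parametric survival curve families
#'
#' The model extrapolates progression-free survival (PFS) and overall
#' survival (OS) beyond the trial follow-up with standard two-parameter
#' survival families. Time is measured in months throughout.
#'
#' Parameterizations (all times `t` in months):
#' \describe{
#'   \item{exponential}{`rate` lambda; S(t) = exp(-lambda t)}
#'   \item{weibull}{`shape`, `scale`; S(t) = exp(-(t/scale)^shape)}
#'   \item{gamma}{`shape`, `rate`; standard two-parameter gamma}
#'   \item{lognormal}{`meanlog`, `sdlog`; S(t) = 1 - Phi((log t - meanlog)/sdlog)}
#'   \item{loglogistic}{`shape`, `scale`; S(t) = 1/(1 + (t/scale)^shape),
#'     so the median survival time equals `scale`}
#'   \item{gompertz}{`shape`, `rate`; S(t) = exp(-rate/shape (exp(shape t)-1)).
#'     A negative `shape` gives a survival plateau exp(rate/shape) > 0, so
#'     S does not vanish as t grows; all other families tend to 0.}
#' }
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gamma"`,
#'   `"lognormal"`, `"loglogistic"`, `"gompertz"`.
#' @param ... Named parameters for the family (see Details).
#' @return An object of class `surv_model`.
#' @examples
#' m <- surv_model("lognormal", meanlog = 2.3487, sdlog = 1.2258)
#' surv_prob(m, c(0, 6, 12))
#' @export
surv_model <- function(family, ...) {
  family <- match.arg(family, surv_families())
  params <- unlist(list(...))
  need <- surv_param_names(family)
  if (!setequal(names(params), need)) {
    stop(sprintf("family '%s' needs parameters {%s}, got {%s}",
                 family, paste(need, collapse = ", "),
                 paste(names(params), collapse = ", ")), call. = FALSE)
  }
  params <- params[need]
  validate_surv_params(family, params)
  structure(list(family = family, params = params), class = "surv_model")
}

#' Supported survival families, in the fixed tie-break order used by
#' [select_surv_model()].
#' @return Character vector of family names.
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gamma", "lognormal", "loglogistic", "gompertz")
}

surv_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gamma       = c("shape", "rate"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"),
    gompertz    = c("shape", "rate"))
}

validate_surv_params <- function(family, params) {
  if (any(!is.finite(params))) {
    stop("survival parameters must be finite", call. = FALSE)
  }
  positive <- switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gamma       = c("shape", "rate"),
    lognormal   = "sdlog",
    loglogistic = c("shape", "scale"),
    gompertz    = "rate")
  bad <- positive[params[positive] <= 0]
  if (length(bad)) {
    stop(sprintf("parameter(s) %s of the %s family must be > 0",
                 paste(bad, collapse = ", "), family), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.surv_model <- function(x, ...) {
  cat(sprintf("<surv_model> %s(%s)\n", x$family,
              paste(sprintf("%s = %g", names(x$params), x$params),
                    collapse = ", ")))
  invisible(x)
}

#' Survival probability S(t)
#'
#' @param model A [surv_model()].
#' @param t Time(s) in months, non-negative; vectorized.
#' @return S(t) in \[0, 1\], same length as `t`.
#' @examples
#' surv_prob(surv_model("loglogistic", shape = 1.763, scale = 6.618), 6.618)
#' @export
surv_prob <- function(model, t) {
  stopifnot(inherits(model, "surv_model"))
  if (any(!is.finite(t) & !is.infinite(t)) || any(t < 0)) {
    stop("t must be non-negative", call. = FALSE)
  }
  p <- model$params
  s <- switch(model$family,
    exponential = exp(-p[["rate"]] * t),
    weibull     = stats::pweibull(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    gamma       = stats::pgamma(t, p[["shape"]], p[["rate"]], lower.tail = FALSE),
    lognormal   = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p[["shape"]], scale = p[["scale"]],
                                    lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = p[["shape"]], rate = p[["rate"]],
                                      lower.tail = FALSE))
  s[t == 0] <- 1
  unname(s)
}

#' Random event times from a fitted family
#'
#' @inheritParams surv_prob
#' @param n Number of draws.
#' @return Numeric vector of event times (months).
#' @keywords internal
surv_rand <- function(model, n) {
  p <- model$params
  switch(model$family,
    exponential = stats::rexp(n, p[["rate"]]),
    weibull     = stats::rweibull(n, p[["shape"]], p[["scale"]]),
    gamma       = stats::rgamma(n, p[["shape"]], p[["rate"]]),
    lognormal   = stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
    loglogistic = flexsurv::rllogis(n, shape = p[["shape"]], scale = p[["scale"]]),
    gompertz    = flexsurv::rgompertz(n, shape = p[["shape"]], rate = p[["rate"]]))
}

# flexsurv distribution name for each family
flexsurv_dist <- function(family) {
  switch(family,
    exponential = "exp",
    weibull     = "weibull",
    gamma       = "gamma",
    lognormal   = "lnorm",
    loglogistic = "llogis",
    gompertz    = "gompertz")
}

# Transform parameters to the unconstrained scale used for MLE and for
# multivariate-normal parameter uncertainty (log for positive parameters;
# meanlog and the gompertz shape may take any sign).
surv_params_transform <- function(family, params) {
  switch(family,
    exponential = c(rate = log(params[["rate"]])),
    weibull     = log(params),
    gamma       = log(params),
    lognormal   = c(meanlog = params[["meanlog"]], sdlog = log(params[["sdlog"]])),
    loglogistic = log(params),
    gompertz    = c(shape = params[["shape"]], rate = log(params[["rate"]])))
}

surv_params_untransform <- function(family, tpars) {
  out <- switch(family,
    exponential = c(rate = exp(tpars[["rate"]])),
    weibull     = exp(tpars),
    gamma       = exp(tpars),
    lognormal   = c(meanlog = tpars[["meanlog"]], sdlog = exp(tpars[["sdlog"]])),
    loglogistic = exp(tpars),
    gompertz    = c(shape = tpars[["shape"]], rate = exp(tpars[["rate"]])))
  out[surv_param_names(family)]
}
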