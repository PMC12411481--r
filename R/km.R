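#' Kaplan-Meier estimate of a pseudo-IPD set
#'
#' Product-limit estimate at each distinct event time, computed with
#' [survival::survfit()]. The returned curve always starts at (0, 1).
#'
#' @param data Data frame with columns `time`, `event` (1 = event).
#' @return A tibble with columns `time`, `survival`, ordered by time,
#'   survival non-increasing.
#' @export
km_estimator <- function(data) {
  check_ipd(data, min_records = 1L)
  if (sum(data$event) == 0) {
    # no events: the product-limit estimate is identically 1
    return(tibble::tibble(time = 0, survival = 1))
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  keep <- sf$n.event > 0
  tibble::tibble(time = c(0, sf$time[keep]),
                 survival = c(1, sf$surv[keep]))
}

#' Validate digitized Kaplan-Meier coordinates
#'
#' @param curve Data frame with columns `time`, `survival`.
#' @keywords internal
check_km_curve <- function(curve) {
  if (!is.data.frame(curve) || !all(c("time", "survival") %in% names(curve))) {
    stop("a KM curve needs columns 'time' and 'survival'", call. = FALSE)
  }
  if (nrow(curve) < 1) stop("empty KM curve", call. = FALSE)
  if (any(diff(curve$time) <= 0)) {
    stop("KM curve times must be strictly increasing", call. = FALSE)
  }
  if (any(curve$survival < 0 | curve$survival > 1)) {
    stop("KM survival values must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(curve$survival) > 1e-12)) {
    stop("KM survival values must be non-increasing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Reconstruct pseudo individual patient data from digitized KM coordinates
#'
#' Published survival curves are digitized as (time, survival) step points;
#' this routine emits `n_total` individual (time, event) records whose own
#' Kaplan-Meier estimate interpolates the input curve at its step points to
#' within 1/(2 `n_total`). Events are assigned to reproduce each step drop
#' (rounded survivor counts); patients still at risk after the last
#' digitized point are administratively censored there. Published curves
#' here come without number-at-risk tables, so no interior censoring is
#' imputed; the reconstruction is exact at the step points under that
#' convention.
#'
#' @param curve Data frame with columns `time`, `survival` (a digitized KM
#'   curve; a leading (0, 1) point is implied if absent).
#' @param n_total Cohort size to emit, >= 1.
#' @return A tibble with columns `time`, `event`.
#' @export
reconstruct_pseudo_ipd <- function(curve, n_total) {
  check_km_curve(curve)
  if (!is.numeric(n_total) || length(n_total) != 1 || n_total < 1) {
    stop("n_total must be a count >= 1", call. = FALSE)
  }
  n_total <- as.integer(round(n_total))
  cv <- curve[curve$time > 0, , drop = FALSE]
  times <- numeric(0)
  events <- integer(0)
  at_risk <- n_total
  for (i in seq_len(nrow(cv))) {
    target <- round(n_total * cv$survival[i])
    d <- at_risk - target
    if (d > 0) {
      times <- c(times, rep(cv$time[i], d))
      events <- c(events, rep(1L, d))
      at_risk <- target
    }
  }
  if (at_risk > 0) {
    t_end <- max(curve$time)
    times <- c(times, rep(t_end, at_risk))
    events <- c(events, rep(0L, at_risk))
  }
  tibble::tibble(time = times, event = events)
}

#' Read / write the delimited-text dialects used for survival inputs
#'
#' Digitized curves are CSV files with columns `time_months,survival`;
#' pseudo-IPD files have columns `time_months,event`.
#'
#' @param path File path.
#' @return A tibble with package-internal column names.
#' @export
read_km_curve <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("time_months", "survival") %in% names(x))) {
    stop("expected columns 'time_months' and 'survival' in ", path,
         call. = FALSE)
  }
  out <- tibble::tibble(time = x$time_months, survival = x$survival)
  check_km_curve(out)
  out
}

#' @rdname read_km_curve
#' @param curve,ipd Object to write.
#' @export
write_km_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(time_months = curve$time, survival = curve$survival),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_km_curve
#' @export
read_ipd <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("time_months", "event") %in% names(x))) {
    stop("expected columns 'time_months' and 'event' in ", path, call. = FALSE)
  }
  out <- tibble::tibble(time = x$time_months, event = as.integer(x$event))
  check_ipd(out)
  out
}

#' @rdname read_km_curve
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(data.frame(time_months = ipd$time, event = ipd$event),
                   path, row.names = FALSE)
  invisible(path)
}
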