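#' Convert an annual probability to a per-cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - annual_p)^(cycle_days/365.25)`.
#'
#' @param annual_p Annual probability in \[0, 1\].
#' @param cycle_days Cycle length in days (> 0).
#' @return Per-cycle probability.
#' @export
per_cycle_prob <- function(annual_p, cycle_days = 21) {
  if (any(annual_p < 0 | annual_p > 1)) {
    stop("annual_p must lie in [0, 1]", call. = FALSE)
  }
  if (cycle_days <= 0) stop("cycle_days must be > 0", call. = FALSE)
  1 - (1 - annual_p)^(cycle_days / 365.25)
}

DAYS_PER_MONTH <- 30.4375 # 365.25 / 12

#' One row of time-dependent transition probabilities
#'
#' Implements the transition construction that ties the cohort to the two
#' fitted curves. With `S` the relevant survival function evaluated at the
#' cycle boundaries (months):
#' \itemize{
#'   \item `pFTF = S_pfs(t)/S_pfs(t-1)` - stay progression-free;
#'   \item `pFTD` - background (general-population) mortality per cycle;
#'   \item `pFTP = 1 - pFTD - pFTF` - progress;
#'   \item `pSTS = S_os(t)/S_os(t-1)` - overall survive the cycle;
#'   \item `pPTP = ((nPFS + nPD) pSTS - nPFS pFTF - nPFS pFTP)/nPD`, the
#'     remain-progressed probability that makes total survival follow the
#'     OS curve, with `nPFS`, `nPD` the previous-cycle occupancies;
#'   \item `pPTD = 1 - pPTP`.
#' }
#' All probabilities are clamped to \[0, 1\]; the number of clamped values
#' is reported. An exhausted PFS curve (`S(t-1) = 0`) is treated as
#' absorbing (`pFTF = 0`), not as a division error; an empty progressed
#' compartment (`nPD < 1e-12`) yields `pPTP = 0`.
#'
#' @param t Cycle index (>= 1).
#' @param S_pfs,S_os [surv_model()] objects (or functions of time in
#'   months) for progression-free and overall survival.
#' @param prev Previous-cycle occupancy: numeric `c(nPFS, nPD, nDead)`.
#' @param pFTD Per-cycle background mortality probability.
#' @param cycle_days Cycle length in days.
#' @return A tibble row: `cycle`, `pFTF`, `pFTP`, `pFTD`, `pSTS`, `pPTP`,
#'   `pPTD`, `clamped` (count of out-of-range raw values).
#' @export
transition_row <- function(t, S_pfs, S_os, prev, pFTD,
                           cycle_days = 21) {
  if (t < 1) stop("t must be >= 1", call. = FALSE)
  if (length(prev) < 2 || any(prev < -1e-12)) {
    stop("prev must be a valid occupancy vector", call. = FALSE)
  }
  sp <- as_surv_fun(S_pfs)
  so <- as_surv_fun(S_os)
  cyc_mo <- cycle_days / DAYS_PER_MONTH
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0 || x > 1) clamped <<- clamped + 1L
    min(1, max(0, x))
  }
  sp0 <- sp((t - 1) * cyc_mo); sp1 <- sp(t * cyc_mo)
  so0 <- so((t - 1) * cyc_mo); so1 <- so(t * cyc_mo)
  pFTF <- if (sp0 <= 0) 0 else clamp(sp1 / sp0)
  pFTP <- clamp(1 - pFTD - pFTF)
  pSTS <- if (so0 <= 0) 0 else clamp(so1 / so0)
  f <- prev[1]; p <- prev[2]
  pPTP <- if (p < 1e-12) 0 else clamp(((f + p) * pSTS - f * pFTF - f * pFTP) / p)
  tibble::tibble(cycle = t, pFTF = pFTF, pFTP = pFTP, pFTD = pFTD,
                 pSTS = pSTS, pPTP = pPTP, pPTD = 1 - pPTP,
                 clamped = clamped)
}

as_surv_fun <- function(x) {
  if (inherits(x, "surv_model")) {
    function(t) surv_prob(x, t)
  } else if (is.function(x)) {
    x
  } else {
    stop("survival curve must be a surv_model or a function", call. = FALSE)
  }
}

#' Run the three-state Markov cohort trace
#'
#' The cohort starts fully progression-free and moves between
#' progression-free (PFS), progressed disease (PD) and death over
#' `horizon` cycles using [transition_row()]. While the PD compartment is
#' still empty (no previous-cycle progressors) the construction above
#' cannot place any OS-curve deaths, so the PFS-to-PD outflow of such a
#' cycle is split between PD and death to keep total survival on the OS
#' curve (the cycle-1 seeding rule; see the methods vignette). As a result
#' the trace reproduces both curves exactly: `nPFS(t) = S_pfs(t)` and
#' `nPFS(t) + nPD(t) = S_os(t)` whenever background mortality is zero and
#' no clamping triggers.
#'
#' @param S_pfs,S_os Survival curves ([surv_model()] or functions of
#'   months).
#' @param mortality Background mortality: an annual probability scalar, or
#'   a numeric vector of annual probabilities indexed by model year.
#' @param horizon Number of cycles (>= 1).
#' @param cycle_days Cycle length in days.
#' @return A tibble with `horizon + 1` rows (cycle 0 .. horizon):
#'   `cycle`, `time_months`, `nPFS`, `nPD`, `nDead`, `newDead`, with
#'   attribute `clamp_events` (count of clamped transition probabilities).
#'   A warning reports clamp events.
#' @export
run_cohort <- function(S_pfs, S_os, mortality = 0.002, horizon = 174,
                       cycle_days = 21) {
  if (!is.numeric(horizon) || horizon < 1) {
    stop("horizon must be >= 1 cycles", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  sp <- as_surv_fun(S_pfs)
  so <- as_surv_fun(S_os)
  cyc_mo <- cycle_days / DAYS_PER_MONTH
  cyc_yr <- cycle_days / 365.25
  if (any(mortality < 0 | mortality > 1)) {
    stop("mortality probabilities must lie in [0, 1]", call. = FALSE)
  }
  mort_at <- function(t) {
    if (length(mortality) == 1) return(mortality)
    yr <- min(length(mortality), floor((t - 1) * cyc_yr) + 1)
    mortality[yr]
  }
  nPFS <- numeric(horizon + 1); nPD <- numeric(horizon + 1)
  nDead <- numeric(horizon + 1); newDead <- numeric(horizon + 1)
  nPFS[1] <- 1
  clamp_events <- 0L
  tgrid <- (0:horizon) * cyc_mo
  spv <- vapply(tgrid, sp, numeric(1))
  sov <- vapply(tgrid, so, numeric(1))
  for (t in seq_len(horizon)) {
    pFTD <- per_cycle_prob(mort_at(t), cycle_days)
    f <- nPFS[t]; p <- nPD[t]
    pFTF <- if (spv[t] <= 0) 0 else min(1, max(0, spv[t + 1] / spv[t]))
    pFTP <- max(0, 1 - pFTD - pFTF)
    pSTS <- if (sov[t] <= 0) 0 else min(1, max(0, sov[t + 1] / sov[t]))
    flow_fp <- f * pFTP
    dead_f  <- f * pFTD
    if (p < 1e-12) {
      # PD empty: split the PFS outflow so deaths match the OS curve
      target_dead <- (f + p) * (1 - pSTS)
      extra <- min(flow_fp, max(0, target_dead - dead_f))
      dead_cycle <- dead_f + extra
      pd_next <- flow_fp - extra
    } else {
      raw <- ((f + p) * pSTS - f * pFTF - f * pFTP) / p
      if (raw < -1e-12 || raw > 1 + 1e-12) clamp_events <- clamp_events + 1L
      pPTP <- min(1, max(0, raw))
      pd_next <- flow_fp + p * pPTP
      dead_cycle <- dead_f + p * (1 - pPTP)
    }
    nPFS[t + 1] <- f * pFTF
    nPD[t + 1] <- pd_next
    newDead[t + 1] <- dead_cycle
    nDead[t + 1] <- nDead[t] + dead_cycle
  }
  if (clamp_events > 0) {
    warning(sprintf("%d transition probabilit%s clamped to [0, 1]",
                    clamp_events, if (clamp_events == 1) "y" else "ies"),
            call. = FALSE)
  }
  out <- tibble::tibble(cycle = 0:horizon, time_months = tgrid,
                        nPFS = nPFS, nPD = nPD, nDead = nDead,
                        newDead = newDead)
  attr(out, "clamp_events") <- clamp_events
  attr(out, "cycle_days") <- cycle_days
  out
}
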