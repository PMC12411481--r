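#' Discount factor for a model cycle
#'
#' Annual discounting compounded continuously in cycles:
#' `(1 + rate)^(-cycle * cycle_days / 365.25)`.
#'
#' @param cycle Cycle index (vectorized).
#' @param annual_rate Annual discount rate (>= 0).
#' @param cycle_days Cycle length in days.
#' @return Discount factor(s) in (0, 1].
#' @export
discount_factor <- function(cycle, annual_rate, cycle_days = 21) {
  if (annual_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle * cycle_days / 365.25)
}

#' Per-cycle drug acquisition cost of a regimen
#'
#' Each regimen component carries a dosing rule (`flat` mg,
#' `per_m2` mg/m2 scaled by body surface area, or `per_kg` mg/kg scaled by
#' weight), the number of administrations per cycle, a treated-cycle cap,
#' and a mixture weight (share of the cohort receiving that backbone).
#' Pricing is linear in milligrams at the per-100 mg unit price (no vial
#' wastage). Treatment is gated to the progression-free state.
#'
#' @param regimen List of components, each a list with `drug`, `dose_mg`,
#'   `rule`, `admin_per_cycle`, `max_cycles` (or `Inf`), `weight`.
#' @param costs Cost list holding `drug_price_per_100mg` (named).
#' @param patient List with `bsa_m2` and `weight_kg`.
#' @param cycle Cycle index (>= 1; rewards accrue end-of-cycle).
#' @param state Health state of the treated cohort: `"pfs"`, `"pd"` or
#'   `"death"`.
#' @return Cost in US$ for one fully treated patient-cycle.
#' @examples
#' reg <- list(list(drug = "pembrolizumab", dose_mg = 200, rule = "flat",
#'                  admin_per_cycle = 1, max_cycles = 35, weight = 1))
#' costs <- list(drug_price_per_100mg = list(pembrolizumab = 2451.60))
#' drug_cost_per_cycle(reg, costs, list(bsa_m2 = 1.72, weight_kg = 65),
#'                     cycle = 1, state = "pfs")
#' @export
drug_cost_per_cycle <- function(regimen, costs, patient, cycle,
                                state = "pfs") {
  state <- match.arg(state, c("pfs", "pd", "death"))
  if (state != "pfs") return(0)
  total <- 0
  for (comp in regimen) {
    price <- costs$drug_price_per_100mg[[comp$drug]]
    if (is.null(price)) {
      stop(sprintf("no unit price configured for drug '%s'", comp$drug),
           call. = FALSE)
    }
    max_cycles <- comp$max_cycles %||% Inf
    if (is.character(max_cycles)) max_cycles <- Inf # yaml ".inf" safety
    if (cycle > max_cycles) next
    mg <- comp$dose_mg * switch(comp$rule %||% "flat",
      flat   = 1,
      per_m2 = patient$bsa_m2,
      per_kg = patient$weight_kg,
      stop(sprintf("unknown dose rule '%s'", comp$rule), call. = FALSE))
    mg <- mg * (comp$admin_per_cycle %||% 1)
    total <- total + (comp$weight %||% 1) * mg / 100 * price
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accumulate discounted costs, life-years and QALYs over a cohort trace
#'
#' Rewards accrue on the post-transition state occupancy of cycles
#' `1..horizon` (end-of-cycle convention), each multiplied by the cycle's
#' discount factor:
#' \itemize{
#'   \item drug acquisition cost for the PFS-resident, still-treated
#'     fraction (per-component treated-cycle caps);
#'   \item supportive care per cycle, gated by `costs$supportive_gate`:
#'     `"on_treatment"` (PFS cycles within the chemotherapy cap) or
#'     `"pfs"` (all PFS cycles);
#'   \item routine follow-up per cycle, gated by `costs$follow_up_gate`:
#'     `"pd"` or `"pfs_pd"`;
#'   \item terminal care once per death, on the newly-dead fraction;
#'   \item serious adverse-event management costs once, at cycle 1, as
#'     incidence-weighted one-off amounts.
#' }
#' QALYs weight PFS/PD occupancy by the state utilities; an optional
#' one-off adverse-event QALY decrement (incidence x |disutility|) is
#' subtracted when `apply_ae_disutility` is `TRUE`. Setting
#' `half_cycle_correction` replaces each cycle's occupancy by the mean of
#' its start and end values (life-table correction).
#'
#' @param trace A [run_cohort()] trace.
#' @param regimen Regimen component list (see [drug_cost_per_cycle()]).
#' @param costs Cost list: `drug_price_per_100mg`, `supportive_per_cycle`,
#'   `follow_up_per_cycle`, `terminal_care`, `ae_per_event` (named),
#'   `supportive_gate`, `follow_up_gate`.
#' @param utilities List with `pfs`, `pd` (death is 0).
#' @param ae List with named vectors `incidence` and `disutility`.
#' @param settings List with `discount_rate`, `cycle_days`,
#'   `horizon_cycles`, optional `half_cycle_correction`.
#' @param patient List with `bsa_m2`, `weight_kg`.
#' @param apply_ae_disutility Apply the one-off AE QALY decrement to this
#'   arm?
#' @return An `econ_result`: list with `cost`, `life_years`, `qalys` and a
#'   `components` breakdown (named cost components, all discounted).
#' @export
accumulate_outcomes <- function(trace, regimen, costs, utilities, ae,
                                settings, patient,
                                apply_ae_disutility = TRUE) {
  horizon <- settings$horizon_cycles
  if (nrow(trace) != horizon + 1) {
    stop(sprintf("trace has %d cycles but settings expect %d",
                 nrow(trace) - 1, horizon), call. = FALSE)
  }
  cyc <- trace$cycle
  cyc_yr <- settings$cycle_days / 365.25
  df <- discount_factor(cyc, settings$discount_rate, settings$cycle_days)
  hcc <- isTRUE(settings$half_cycle_correction)
  occ <- function(x) {
    if (hcc) (x + c(x[1], x[-length(x)])) / 2 else x
  }
  pfs <- occ(trace$nPFS); pd <- occ(trace$nPD)
  live <- cyc >= 1 # accrual cycles

  # utilities must be proper
  for (u in c("pfs", "pd")) {
    if (utilities[[u]] < 0 || utilities[[u]] > 1) {
      stop(sprintf("utility '%s' must lie in [0, 1]", u), call. = FALSE)
    }
  }

  ly   <- sum(((pfs + pd) * cyc_yr * df)[live])
  qaly <- sum(((pfs * utilities$pfs + pd * utilities$pd) * cyc_yr * df)[live])

  drug <- vapply(cyc, function(t) {
    if (t < 1) return(0)
    drug_cost_per_cycle(regimen, costs, patient, t, "pfs")
  }, numeric(1))
  drug_cost <- sum(drug * pfs * df)
  # discounted pembrolizumab acquisition alone (price-discount identity)
  pembro_cost <- 0
  if (any(vapply(regimen, function(cp) cp$drug == "pembrolizumab", logical(1)))) {
    reg_p <- Filter(function(cp) cp$drug == "pembrolizumab", regimen)
    dp <- vapply(cyc, function(t) {
      if (t < 1) return(0)
      drug_cost_per_cycle(reg_p, costs, patient, t, "pfs")
    }, numeric(1))
    pembro_cost <- sum(dp * pfs * df)
  }

  chemo_cap <- max(c(0, vapply(regimen, function(cp) {
    if (cp$drug == "pembrolizumab") return(0)
    mc <- cp$max_cycles %||% Inf
    if (is.character(mc)) Inf else as.numeric(mc)
  }, numeric(1))))
  supp_gate <- costs$supportive_gate %||% "pfs"
  supp_on <- switch(supp_gate,
    on_treatment = live & cyc <= chemo_cap,
    pfs          = live,
    stop(sprintf("unknown supportive_gate '%s'", supp_gate), call. = FALSE))
  supportive <- costs$supportive_per_cycle * sum((pfs * df)[supp_on])

  fu_gate <- costs$follow_up_gate %||% "pfs_pd"
  follow_up <- switch(fu_gate,
    pd     = costs$follow_up_per_cycle * sum((pd * df)[live]),
    pfs_pd = costs$follow_up_per_cycle * sum(((pfs + pd) * df)[live]),
    stop(sprintf("unknown follow_up_gate '%s'", fu_gate), call. = FALSE))

  terminal <- costs$terminal_care * sum(trace$newDead * df)

  ae_names <- names(ae$incidence)
  ae_cost <- sum(vapply(ae_names, function(a) {
    ae$incidence[[a]] * costs$ae_per_event[[a]]
  }, numeric(1))) * df[2] # one-off at cycle 1
  ae_decrement <- if (apply_ae_disutility) {
    sum(vapply(ae_names, function(a) {
      ae$incidence[[a]] * abs(ae$disutility[[a]])
    }, numeric(1)))
  } else 0

  total <- drug_cost + supportive + follow_up + terminal + ae_cost
  structure(list(
    cost = total,
    life_years = ly,
    qalys = qaly - ae_decrement,
    components = c(drug = drug_cost, pembrolizumab = pembro_cost,
                   supportive = supportive, follow_up = follow_up,
                   terminal = terminal, ae = ae_cost,
                   ae_qaly_decrement = ae_decrement)
  ), class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("<econ_result> cost $%.2f  LY %.4f  QALY %.4f\n",
              x$cost, x$life_years, x$qalys))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' `(cost_i - cost_c) / (qaly_i - qaly_c)`. When the incremental QALY is
#' zero or the signs disagree, a dominance flag is reported instead of a
#' ratio: `"dominant"` (cheaper and more effective), `"dominated"` (more
#' expensive and less effective), or `"zero_dqaly"`.
#'
#' @param intervention,comparator `econ_result` objects.
#' @return List: `delta_cost`, `delta_qaly`, `icer` (NA when flagged),
#'   `dominance`.
#' @export
icer <- function(intervention, comparator) {
  dc <- intervention$cost - comparator$cost
  dq <- intervention$qalys - comparator$qalys
  if (dq == 0) {
    flag <- "zero_dqaly"; ratio <- NA_real_
  } else if (dq > 0 && dc < 0) {
    flag <- "dominant"; ratio <- NA_real_
  } else if (dq < 0 && dc > 0) {
    flag <- "dominated"; ratio <- NA_real_
  } else {
    flag <- "none"; ratio <- dc / dq
  }
  list(delta_cost = dc, delta_qaly = dq, icer = ratio, dominance = flag)
}

#' Apply a price-discount scenario to one drug
#'
#' Returns a copy of the configuration with the drug's per-100 mg price
#' multiplied by `1 - fraction`; nothing else changes.
#'
#' @param config A model configuration (see [load_config()]).
#' @param drug Drug name present in `costs$drug_price_per_100mg`.
#' @param fraction Price reduction in \[0, 1\].
#' @return The modified configuration.
#' @export
apply_price_discount <- function(config, drug, fraction) {
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(config$costs$drug_price_per_100mg[[drug]])) {
    stop(sprintf("unknown drug '%s'", drug), call. = FALSE)
  }
  config$costs$drug_price_per_100mg[[drug]] <-
    config$costs$drug_price_per_100mg[[drug]] * (1 - fraction)
  config
}
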