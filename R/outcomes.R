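## Outcomes: discounted life-years, QALYs, category-split costs, and
## comparative cost-effectiveness statistics.

#' Monthly discount factor
#'
#' @param cycle Month index (0-based).
#' @param annual_rate Annual discount rate (e.g. 0.035).
#' @return `(1 + annual_rate)^(-cycle/12)`.
#' @examples
#' discount_factor(12, 0.035)  # 1/1.035
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (any(cycle < 0) || annual_rate < 0) {
    abort("cycle and annual_rate must be non-negative")
  }
  (1 + annual_rate)^(-cycle / 12)
}

#' General-population utility norm by age
#'
#' Piecewise-constant EQ-5D population utility schedule (UK national survey
#' age bands). Used as the utility of the off-treatment state and as a
#' ceiling on the VTE state utilities.
#'
#' @param age Age in years (vectorised).
#' @return Utility value(s).
#' @export
population_utility_norm <- function(age) {
  breaks <- c(-Inf, 25, 35, 45, 55, 65, 75, Inf)
  vals <- c(0.94, 0.93, 0.91, 0.85, 0.80, 0.78, 0.73)
  vals[findInterval(age, breaks, rightmost.closed = TRUE)]
}

## Weighted utility of the index-VTE health state (PE/DVT mix).
u_ivte_weighted <- function(params) {
  cl <- params$clinical
  cl$prop_index_pe * params$utilities$u_pe +
    (1 - cl$prop_index_pe) * params$utilities$u_dvt
}

#' Mean utility of a cohort state mix
#'
#' Applies the baseline state utilities (index-mix-weighted VTE utility on
#' treatment, the age-specific population norm off treatment), relative
#' decrements for acute event states and -- in the warfarin arm -- the
#' treatment decrement on the initial episode, then the concomitant-state
#' decrements multiplicatively on the alive cohort. Death contributes 0.
#'
#' @param occupancy Named vector/list of exclusive-state occupancy
#'   fractions: `on_treatment_ivte`, `on_treatment_rvte`, `off_treatment`,
#'   `rvte`, `crnmb`, `non_ich_mb`, `ich`, `death`.
#' @param prev Named vector of concomitant prevalences
#'   (`pts`, `cteph`, `dis`), each <= the alive fraction.
#' @param arm `"edoxaban"` or `"warfarin"`.
#' @param params A `vte_params` object.
#' @param age Age in years for the population norm.
#' @return Mean utility of the mix (a scalar in \[-1, 1\]).
#' @examples
#' p <- vte_parameters()
#' cycle_utility(c(on_treatment_ivte = 1, on_treatment_rvte = 0,
#'                 off_treatment = 0, rvte = 0, crnmb = 0, non_ich_mb = 0,
#'                 ich = 0, death = 0),
#'               c(pts = 0, cteph = 0, dis = 0), "edoxaban", p, age = 56)
#' @export
cycle_utility <- function(occupancy, prev, arm, params,
                          age = params$settings$start_age) {
  arm <- match.arg(arm, c("edoxaban", "warfarin"))
  u <- params$utilities
  occ <- as.list(occupancy)
  norm <- population_utility_norm(age)
  base <- u_ivte_weighted(params)
  if (params$settings$use_age_utility) {
    base <- min(base, norm)
    u_off <- norm
  } else {
    u_off <- base
  }
  wf <- if (arm == "warfarin") 1 - u$du_warfarin else 1

  total <- base * wf * occ$on_treatment_ivte +
    base * occ$on_treatment_rvte +
    u_off * occ$off_treatment +
    base * (1 - u$du_rvte_first_month) * occ$rvte +
    base * (1 - u$du_crnmb) * occ$crnmb +
    base * (1 - u$du_non_ich_mb) * occ$non_ich_mb +
    base * (1 - u$du_ich) * occ$ich

  alive <- 1 - occ$death
  if (alive > 0) {
    pv <- as.list(prev)
    total <- total * (1 - u$du_pts * pv$pts / alive) *
      (1 - u$du_cteph * pv$cteph / alive) *
      (1 - u$du_ich_disability * pv$dis / alive)
  }
  if (total < -1 || total > 1) {
    abort("Cycle utility outside [-1, 1]")
  }
  total
}

# ---------------------------------------------------------------------------
# Effective cost schedule
#
# The four per-cycle treatment costs are primitives (the printed first and
# subsequent cycle costs per arm). Resource-use components (heparin days and
# daily cost, INR visit costs and counts) are kept alongside so sensitivity
# analyses can perturb a component: the effective cycle cost is then the
# primitive plus the component delta from its base value, which reproduces
# the primitives exactly at base.

effective_costs <- function(params) {
  co <- params$costs
  hep_w <- co$heparin_days_warfarin * co$c_heparin_daily
  hep_e <- co$heparin_days_edoxaban * co$c_heparin_daily
  inr_first_block <- co$c_inr_first + co$n_inr_titration * co$c_inr_subsequent
  inr_monthly <- co$n_inr_monthly * co$c_inr_subsequent

  w_first <- co$c_warfarin_cycle_first + (hep_w - 83.33) +
    (inr_first_block - 191)
  w_later <- co$c_warfarin_cycle_later + (inr_monthly - 26)
  e_first <- co$c_edoxaban_cycle_first + (hep_e - 64.10)
  e_later <- co$c_edoxaban_cycle_later

  acute_rvte <- params$clinical$prop_recurrence_pe * co$c_pe_event +
    (1 - params$clinical$prop_recurrence_pe) * co$c_dvt_event

  list(
    w_first = w_first, w_later = w_later,
    e_first = e_first, e_later = e_later,
    inr_first_block = inr_first_block, inr_monthly = inr_monthly,
    hep_w = hep_w, hep_e = hep_e,
    # tertiary prevention: anticoagulation re-initiated after a recurrence
    # is costed as the NOAC-era strategy in both arms -- 5-day heparin
    # lead-in plus NOAC maintenance (see the methods vignette)
    retreat_first = co$c_edoxaban_cycle_first + (hep_e - 64.10),
    retreat_later = co$c_edoxaban_cycle_later,
    acute_rvte = acute_rvte,
    cteph_onset = params$clinical$prop_cteph_endarterectomy *
      co$c_endarterectomy + co$c_cteph_drugs_monthly
  )
}

# ---------------------------------------------------------------------------
# Accumulation

#' Discount and accumulate a cohort trace
#'
#' Converts a [run_cohort()] trace into per-cycle and total discounted
#' life-years, QALYs (split into on-treatment, off-treatment, recurrence,
#' adverse-event and complication components) and costs split by category
#' (treatment excluding INR, INR monitoring, recurrent VTE acute +
#' tertiary-prevention treatment, CRNMB, non-ICH MB, ICH acute + long-term
#' disability, and PTS/CTEPH complications), plus the cumulative event
#' incidences at the horizon.
#'
#' @param trace A `vte_trace` object.
#' @param params Parameter set (defaults to the one stored in the trace).
#' @return A `vte_ledger` object with elements `cycles` (tibble),
#'   `totals` (named list), and `incidence` (named vector).
#' @export
accumulate <- function(trace, params = trace$params) {
  stopifnot(inherits(trace, "vte_trace"))
  arm <- trace$arm
  s <- params$settings
  u <- params$utilities
  H <- nrow(trace$trace) - 1L

  occ <- trace$occupancy
  prevm <- trace$prevalence
  flows <- trace$flows
  ec <- effective_costs(params)

  if (H == 0L) {
    ## degenerate horizon: the cohort is enrolled (first treatment cycle is
    ## dispensed) but no time is lived
    first_cost <- if (arm == "warfarin") ec$w_first - ec$inr_first_block
                  else ec$e_first
    inr0 <- if (arm == "warfarin") ec$inr_first_block else 0
    totals <- list(ly = 0, qaly = 0,
                   cost_treatment = first_cost, cost_inr = inr0,
                   cost_rvte = 0, cost_crnmb = 0, cost_non_ich_mb = 0,
                   cost_ich = 0, cost_complications = 0,
                   cost_total = first_cost + inr0)
    return(structure(list(
      cycles = tibble::tibble(cycle = integer(0)),
      totals = totals,
      incidence = c(rvte = 0, crnmb = 0, non_ich_mb = 0, ich = 0,
                    pts = trace$init$onsets[["pts"]],
                    cteph = trace$init$onsets[["cteph"]],
                    specific_death = trace$init$onsets[["d_endart"]]),
      arm = arm), class = "vte_ledger"))
  }

  tt <- seq_len(H)            # accrual cycles t = 0..H-1 (matrix rows tt)
  t0 <- tt - 1L
  disc <- discount_factor(t0, s$discount_rate_annual)
  age <- s$start_age + t0 / 12
  alive <- 1 - occ[tt, SLOT_DEAD]

  ## ------------------------------------------------------------------ QALYs
  norm <- population_utility_norm(age)
  base0 <- u_ivte_weighted(params)
  if (s$use_age_utility) {
    base <- pmin(base0, norm)
    u_off <- norm
  } else {
    base <- rep(base0, H)
    u_off <- rep(base0, H)
  }
  wf <- if (arm == "warfarin") 1 - u$du_warfarin else 1

  occ_on_i <- rowSums(occ[tt, 1:6, drop = FALSE])
  occ_on_r6 <- rowSums(occ[tt, 7:11, drop = FALSE])
  occ_on_rl <- occ[tt, 12L]
  occ_on_r <- occ_on_r6 + occ_on_rl
  occ_cr_on <- rowSums(occ[tt, 16:23, drop = FALSE])  # CRNMB, treatment ctx
  occ_cr_off <- occ[tt, 24L]
  occ_off <- occ[tt, 13L]
  occ_rv <- rowSums(occ[tt, 14:15, drop = FALSE])
  occ_mb <- occ[tt, 25L]
  occ_ich <- rowSums(occ[tt, 26:27, drop = FALSE])

  ## warfarin-arm occupancy subject to the treatment utility decrement
  occ_wf <- occ_on_i
  if (identical(s$du_warfarin_scope, "all")) {
    occ_wf <- occ_wf + occ_on_r6 +
      if (isTRUE(s$lifelong_common)) 0 else occ_on_rl
  }
  u_on <- base * (wf * occ_wf + (occ_on_i + occ_on_r - occ_wf))
  u_offs <- u_off * occ_off
  u_rvte <- base * (1 - u$du_rvte_first_month) * occ_rv
  u_cr <- base * (1 - u$du_crnmb) * (occ_cr_on + occ_cr_off)
  u_mb <- base * (1 - u$du_non_ich_mb) * occ_mb
  u_ich <- base * (1 - u$du_ich) * occ_ich
  u_event <- u_cr + u_mb + u_ich

  u_raw <- u_on + u_offs + u_rvte + u_event
  pi_safe <- function(x) ifelse(alive > 0, x / alive, 0)
  conc <- (1 - u$du_pts * pi_safe(prevm[tt, "pts"])) *
    (1 - u$du_cteph * pi_safe(prevm[tt, "cteph"])) *
    (1 - u$du_ich_disability * pi_safe(prevm[tt, "dis"]))
  u_total <- u_raw * conc

  qaly <- u_total / 12 * disc
  ly <- alive / 12 * disc

  ## split: complications = multiplicative loss; adverse events = the
  ## decrement part of the event tunnels (incl. warfarin decrement)
  q_compl <- -(u_raw - u_total) / 12 * disc
  ## on-treatment time includes the event-tunnel months; the adverse-event
  ## component below then carries pure decrements
  q_on <- base * (occ_on_i + occ_on_r + occ_cr_on + occ_cr_off + occ_mb +
                    occ_ich) / 12 * disc
  q_off <- u_offs / 12 * disc
  q_rvte <- base * occ_rv / 12 * disc
  q_events <- (u_event - base * (occ_cr_on + occ_cr_off + occ_mb + occ_ich) +
                 u_rvte - base * occ_rv +
                 u_on - base * (occ_on_i + occ_on_r)) / 12 * disc

  ## ------------------------------------------------------------------ costs
  f_rv <- flows[tt, "f_rvte"]
  f_cr <- flows[tt, "f_crnmb"]
  f_mb <- flows[tt, "f_mb"]
  f_ich <- flows[tt, "f_ich"]
  on_pts <- flows[tt, "onset_pts"]
  on_ct <- flows[tt, "onset_cteph"]

  ## existing prevalence = carriers beyond their onset month; the cycle-0
  ## prevalences are the index-event onsets themselves
  p_pts_ex <- prevm[tt, "pts"]
  p_ct_ex <- prevm[tt, "cteph"]
  p_dis_ex <- prevm[tt, "dis"]
  p_pts_ex[1L] <- 0
  p_ct_ex[1L] <- 0
  p_dis_ex[1L] <- 0

  if (arm == "warfarin") {
    c_first <- ec$w_first
    c_later <- ec$w_later
    inr_first <- ec$inr_first_block
    inr_later <- ec$inr_monthly
  } else {
    c_first <- ec$e_first
    c_later <- ec$e_later
    inr_first <- 0
    inr_later <- 0
  }
  retreat_first <- ec$retreat_first

  occ_i1 <- occ[tt, 1L]
  occ_i_later <- rowSums(occ[tt, 2:6, drop = FALSE]) +
    rowSums(occ[tt, 16:19, drop = FALSE])
  cost_treat <- occ_i1 * (c_first - inr_first) +
    occ_i_later * (c_later - inr_later)
  cost_inr <- occ_i1 * inr_first + occ_i_later * inr_later

  occ_retreat_later <- rowSums(occ[tt, 7:12, drop = FALSE]) +
    rowSums(occ[tt, 20:23, drop = FALSE])
  cost_rvte <- f_rv * ec$acute_rvte + occ_rv * retreat_first +
    occ_retreat_later * ec$retreat_later

  cost_crnmb <- f_cr * params$costs$c_crnmb
  cost_mb <- f_mb * params$costs$c_non_ich_mb
  cost_ich <- f_ich * params$costs$c_ich_acute +
    p_dis_ex * params$costs$c_ich_disability_monthly
  cost_compl <- on_pts * params$costs$c_pts_first_month +
    p_pts_ex * params$costs$c_pts_monthly +
    on_ct * ec$cteph_onset +
    p_ct_ex * params$costs$c_cteph_drugs_monthly

  cycles <- tibble::tibble(
    cycle = t0, discount = disc, alive = alive,
    ly = ly, qaly = qaly,
    qaly_on_treatment = q_on, qaly_off_treatment = q_off,
    qaly_rvte = q_rvte, qaly_adverse_events = q_events,
    qaly_complications = q_compl,
    cost_treatment = cost_treat * disc,
    cost_inr = cost_inr * disc,
    cost_rvte = cost_rvte * disc,
    cost_crnmb = cost_crnmb * disc,
    cost_non_ich_mb = cost_mb * disc,
    cost_ich = cost_ich * disc,
    cost_complications = cost_compl * disc
  )
  cycles$cost_total <- cycles$cost_treatment + cycles$cost_inr +
    cycles$cost_rvte + cycles$cost_crnmb + cycles$cost_non_ich_mb +
    cycles$cost_ich + cycles$cost_complications

  totals <- as.list(colSums(cycles[, setdiff(names(cycles),
                                             c("cycle", "discount",
                                               "alive"))]))
  fin <- trace$trace[H + 1L, ]
  incidence <- c(rvte = fin$cum_rvte, crnmb = fin$cum_crnmb,
                 non_ich_mb = fin$cum_non_ich_mb, ich = fin$cum_ich,
                 pts = fin$cum_pts, cteph = fin$cum_cteph,
                 specific_death = fin$cum_specific_death)

  structure(list(cycles = cycles, totals = totals, incidence = incidence,
                 arm = arm),
            class = "vte_ledger")
}

#' @export
print.vte_ledger <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<vte_ledger> %s arm\n", x$arm))
  cat(sprintf("  discounted LY %.3f, QALY %.3f, total cost £%.0f\n",
              t$ly, t$qaly, t$cost_total))
  invisible(x)
}

#' @rdname accumulate
#' @param x A `vte_ledger` object.
#' @param ... Unused.
#' @export
tidy.vte_ledger <- function(x, ...) {
  x$cycles
}

#' @rdname accumulate
#' @export
glance.vte_ledger <- function(x, ...) {
  tibble::as_tibble(c(list(arm = x$arm), x$totals,
                      as.list(setNames(x$incidence,
                                       paste0("cum_", names(x$incidence))))))
}

# ---------------------------------------------------------------------------
# Comparison

#' Compare two arms' accumulated outcomes
#'
#' Computes incremental QALYs and costs (edoxaban minus warfarin), the
#' dominance classification, the ICER where the signs admit one, and the
#' net monetary benefit \eqn{\mathrm{NMB} = \Delta E \lambda - \Delta C}.
#'
#' @param ledger_edoxaban,ledger_warfarin `vte_ledger` objects from
#'   [accumulate()].
#' @param wtp Willingness-to-pay per QALY (lambda).
#' @return A `vte_ce_result` object.
#' @export
compare_arms <- function(ledger_edoxaban, ledger_warfarin, wtp = 20000) {
  stopifnot(inherits(ledger_edoxaban, "vte_ledger"),
            inherits(ledger_warfarin, "vte_ledger"))
  te <- ledger_edoxaban$totals
  tw <- ledger_warfarin$totals
  d_qaly <- te$qaly - tw$qaly
  d_cost <- te$cost_total - tw$cost_total
  d_ly <- te$ly - tw$ly
  status <- if (d_qaly > 0 && d_cost < 0) "dominant"
            else if (d_qaly < 0 && d_cost > 0) "dominated"
            else "trade-off"
  icer <- if (status == "trade-off" && d_qaly != 0) d_cost / d_qaly else NA_real_
  nmb <- d_qaly * wtp - d_cost
  structure(list(
    edoxaban = ledger_edoxaban, warfarin = ledger_warfarin,
    d_qaly = d_qaly, d_cost = d_cost, d_ly = d_ly,
    status = status, icer = icer, wtp = wtp, nmb = nmb),
    class = "vte_ce_result")
}

#' Run the full cost-effectiveness analysis
#'
#' Runs the cohort model for both arms, accumulates discounted outcomes,
#' and compares them at the configured willingness-to-pay.
#'
#' @param params A `vte_params` object.
#' @param wtp Willingness-to-pay per QALY (defaults to
#'   `params$settings$wtp`).
#' @return A `vte_ce_result` object.
#' @examples
#' \donttest{
#' res <- run_ce_analysis(vte_parameters(horizon_months = 120))
#' glance(res)
#' }
#' @export
run_ce_analysis <- function(params, wtp = params$settings$wtp) {
  le <- accumulate(run_cohort(params, "edoxaban"), params)
  lw <- accumulate(run_cohort(params, "warfarin"), params)
  compare_arms(le, lw, wtp)
}

#' @export
print.vte_ce_result <- function(x, ...) {
  cat("<vte_ce_result> edoxaban vs. warfarin\n")
  cat(sprintf("  incremental QALYs %.4f, incremental costs £%.1f\n",
              x$d_qaly, x$d_cost))
  cat(sprintf("  %s; NMB at £%s/QALY: £%.0f\n",
              if (x$status == "trade-off")
                sprintf("ICER £%.0f/QALY", x$icer) else x$status,
              format(x$wtp, big.mark = ","), x$nmb))
  invisible(x)
}

#' @rdname compare_arms
#' @param x A `vte_ce_result` object.
#' @param ... Unused.
#' @export
tidy.vte_ce_result <- function(x, ...) {
  dplyr::bind_rows(glance(x$edoxaban), glance(x$warfarin))
}

#' @rdname compare_arms
#' @export
glance.vte_ce_result <- function(x, ...) {
  tibble::tibble(
    d_qaly = x$d_qaly, d_cost = x$d_cost, d_ly = x$d_ly,
    status = x$status, icer = x$icer, wtp = x$wtp, nmb = x$nmb)
}
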