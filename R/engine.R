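## Markov cohort engine.
##
## Eight mutually exclusive health states -- on treatment after the index
## VTE, off treatment, recurrent VTE, on treatment after a recurrence,
## CRNMB, non-ICH major bleed, ICH, death -- with three concomitant states
## (severe PTS, CTEPH, post-ICH disability) tracked as prevalences alongside
## the exclusive occupancy. Monthly cycles. The acute event states are
## one-cycle tunnels: the acute utility decrement and acute cost apply for
## one cycle, after which mass is routed to its destination. Tunnel slots
## are stratified by destination so that CRNMB survivors resume exactly the
## treatment month they would otherwise have reached.
##
## Internal state vector layout (28 slots):
##   1-6   on_i[m]    initial treatment episode, months 1..6 (first-6 risks)
##   7-11  on_r[m]    6-month re-treatment, months 2..6 (later risks)
##   12    on_rl      lifelong re-treatment (later risks)
##   13    off        off treatment
##   14    t_rv_l     rVTE tunnel -> lifelong re-treatment
##   15    t_rv_6     rVTE tunnel -> 6-month re-treatment
##   16-19 t_cr_i     CRNMB tunnel -> on_i months 3..6
##   20-22 t_cr_r     CRNMB tunnel -> on_r months 4..6
##   23    t_cr_rl    CRNMB tunnel -> lifelong re-treatment
##   24    t_cr_off   CRNMB tunnel -> off treatment
##   25    t_mb       non-ICH MB tunnel -> off treatment
##   26    t_ich_d    ICH tunnel -> off treatment, disabled
##   27    t_ich_n    ICH tunnel -> off treatment, not disabled
##   28    dead

N_SLOTS <- 28
SLOT_DEAD <- 28
SLOT_NAMES <- c(paste0("on_i", 1:6), paste0("on_r", 2:6), "on_rl", "off",
                "t_rv_l", "t_rv_6", paste0("t_cr_i", 3:6),
                paste0("t_cr_r", 4:6), "t_cr_rl", "t_cr_off",
                "t_mb", "t_ich_d", "t_ich_n", "dead")

## tunnel exit destinations for slots 14..27
TUNNEL_SRC <- 14:27
TUNNEL_DEST <- c(12L, 7L, 3L, 4L, 5L, 6L, 9L, 10L, 11L, 12L, 13L, 13L, 13L, 13L)
## CRNMB tunnel destination by source: on_i months 1..6, on_r months 2..6
CR_DEST_ON_I <- c(16L, 17L, 18L, 19L, 24L, 24L)
CR_DEST_ON_R <- c(20L, 21L, 22L, 24L, 24L)

FLOW_NAMES <- c("f_rvte", "f_crnmb", "f_mb", "f_ich",
                "d_bg", "d_rvte", "d_mb", "d_ich", "d_endart",
                "d_cteph", "d_dis", "onset_pts", "onset_cteph", "dis_onset")

# ---------------------------------------------------------------------------
# Probability helpers

#' Apply an odds ratio to a baseline probability
#'
#' Converts the baseline monthly probability to odds, scales by the odds
#' ratio, and converts back:
#' \eqn{p' = \mathrm{OR}\,p / (1 - p + \mathrm{OR}\,p)}. Equals `p` when
#' `or_value = 1`, and reduces to rate-ratio behaviour for small `p`.
#'
#' @param p Baseline probability in \[0, 1).
#' @param or_value Odds ratio (> 0).
#' @return Adjusted probability.
#' @examples
#' apply_odds_ratio(0.018, 0.83)  # 0.01499
#' @export
apply_odds_ratio <- function(p, or_value) {
  if (any(or_value <= 0)) abort("Odds ratio must be > 0")
  if (any(p < 0 | p > 1)) abort("Baseline probability must be in [0, 1]")
  if (any(p == 1 & or_value != 1)) {
    abort("p = 1 cannot be rescaled by an odds ratio != 1")
  }
  or_value * p / (1 - p + or_value * p)
}

#' Monthly event probabilities for a health state
#'
#' On-treatment states return the four adverse-event probabilities (VTE
#' recurrence, CRNMB, non-ICH MB, ICH) on the time stratum implied by
#' `months_on_treatment` (<= 6 months of the initial episode vs. later)
#' plus background mortality; the edoxaban arm applies the trial odds
#' ratios via [apply_odds_ratio()]. The off-treatment state carries only
#' the off-treatment recurrence risk and background mortality. Acute event
#' (tunnel) states return their resolution transition; death returns an
#' empty set.
#'
#' @param state One of `"on_treatment_ivte"`, `"on_treatment_rvte"`,
#'   `"off_treatment"`, `"rvte"`, `"crnmb"`, `"non_ich_mb"`, `"ich"`,
#'   `"death"`.
#' @param months_on_treatment Months since the current treatment episode
#'   started (>= 1).
#' @param arm `"edoxaban"` or `"warfarin"`.
#' @param params A `vte_params` object.
#' @param age Age used for background mortality (default: cohort start age).
#' @return Named numeric vector of monthly probabilities.
#' @examples
#' p <- vte_parameters()
#' event_probabilities("on_treatment_ivte", 3, "warfarin", p)
#' @export
event_probabilities <- function(state, months_on_treatment = 1, arm, params,
                                age = params$settings$start_age) {
  arm <- match.arg(arm, c("edoxaban", "warfarin"))
  if (months_on_treatment < 1) abort("months_on_treatment must be >= 1")
  bg <- monthly_background_mortality(params$life_table, age,
                                     params$settings$prop_male)
  on_probs <- function(stratum) {
    p <- vapply(params$risks, function(r) r[[paste0("p_", stratum)]],
                numeric(1))
    if (arm == "edoxaban") {
      ors <- vapply(params$risks, function(r) r[[paste0("or_", stratum)]],
                    numeric(1))
      if (!isTRUE(params$settings$rvte_or_in_base)) ors["rvte"] <- 1
      p <- apply_odds_ratio(p, ors)
    }
    c(rvte = unname(p["rvte"]), crnmb = unname(p["crnmb"]),
      non_ich_mb = unname(p["mb"]), ich = unname(p["ich"]),
      background_death = bg)
  }
  switch(
    state,
    on_treatment_ivte = on_probs(
      if (months_on_treatment <= params$settings$initial_treatment_months)
        "first6" else "later"),
    on_treatment_rvte = on_probs("later"),
    off_treatment = c(rvte = params$clinical$p_recur_off_treatment,
                      background_death = bg),
    rvte = c(resolve = 1),
    crnmb = c(resolve = 1),
    non_ich_mb = c(resolve = 1),
    ich = c(resolve = 1),
    death = setNames(numeric(0), character(0)),
    abort(paste0("Unknown state: ", state))
  )
}

#' Resolution branches of an acute event
#'
#' Describes how the cohort mass experiencing an acute event is split:
#' immediate case fatality, then routing of survivors. Recurrent VTE
#' survivors start a new treatment episode, lifelong for the fraction with
#' both an index and a recurrent PE; CRNMB survivors continue their current
#' treatment; non-ICH MB and ICH survivors discontinue treatment, the
#' latter splitting into disabled and non-disabled.
#'
#' @param event One of `"rvte"`, `"crnmb"`, `"non_ich_mb"`, `"ich"`.
#' @param params A `vte_params` object.
#' @return A tibble with columns `destination` and `prob` (summing to 1).
#' @examples
#' resolve_event_consequences("ich", vte_parameters())
#' @export
resolve_event_consequences <- function(event, params) {
  cl <- params$clinical
  switch(
    event,
    rvte = {
      cfr <- cl$cfr_pe_recurrence * cl$prop_recurrence_pe
      pl <- prop_lifelong(params)
      tibble::tibble(
        destination = c("death", "on_treatment_rvte_lifelong",
                        "on_treatment_rvte_6m"),
        prob = c(cfr, (1 - cfr) * pl, (1 - cfr) * (1 - pl)))
    },
    crnmb = tibble::tibble(destination = "continue_treatment", prob = 1),
    non_ich_mb = tibble::tibble(
      destination = c("death", "off_treatment"),
      prob = c(cl$cfr_non_ich_mb, 1 - cl$cfr_non_ich_mb)),
    ich = {
      cfr <- cl$cfr_ich
      tibble::tibble(
        destination = c("death", "off_treatment_disabled", "off_treatment"),
        prob = c(cfr, (1 - cfr) * cl$p_disabled_after_ich,
                 (1 - cfr) * (1 - cl$p_disabled_after_ich)))
    },
    abort(paste0("Unknown event: ", event))
  )
}

#' Long-term sequela incidence for an event mix
#'
#' CTEPH can follow a PE and severe PTS a DVT, so the per-event sequela
#' probabilities scale with the PE/DVT composition of the triggering event.
#'
#' @param event_context `"index"` (uses the index-event mix), `"recurrence"`
#'   (uses the recurrence mix), or a list with elements `frac_pe` and
#'   `frac_dvt`.
#' @param params A `vte_params` object.
#' @return Named vector `c(p_pts, p_cteph)`.
#' @examples
#' sequela_incidence("recurrence", vte_parameters())  # p_cteph ~ 0.0271
#' @export
sequela_incidence <- function(event_context, params) {
  cl <- params$clinical
  mix <- if (identical(event_context, "index")) {
    list(frac_pe = cl$prop_index_pe,
         frac_dvt = (1 - cl$prop_index_pe) +
           cl$prop_index_pe * cl$prop_index_pe_with_dvt)
  } else if (identical(event_context, "recurrence")) {
    list(frac_pe = cl$prop_recurrence_pe,
         frac_dvt = 1 - cl$prop_recurrence_pe)
  } else {
    event_context
  }
  if (mix$frac_pe < 0 || mix$frac_pe > 1 || mix$frac_dvt < 0 ||
      mix$frac_dvt > 1) {
    abort("Event-mix fractions must be in [0, 1]")
  }
  c(p_pts = cl$p_pts_after_dvt * mix$frac_dvt,
    p_cteph = cl$p_cteph_after_pe * mix$frac_pe)
}

## Fraction of recurrence survivors treated lifelong: patients with both an
## index and a recurrent PE, derived from the event mix unless overridden.
prop_lifelong <- function(params) {
  params$clinical$prop_lifelong_after_recurrence %||%
    (params$clinical$prop_index_pe * params$clinical$prop_recurrence_pe)
}

# ---------------------------------------------------------------------------
# Engine precomputation

engine_inputs <- function(params, arm) {
  arm <- match.arg(arm, c("edoxaban", "warfarin"))
  cl <- params$clinical
  s <- params$settings
  pvec <- function(stratum, use_or) {
    p <- vapply(params$risks, function(r) r[[paste0("p_", stratum)]],
                numeric(1))
    if (use_or) {
      ors <- vapply(params$risks, function(r) r[[paste0("or_", stratum)]],
                    numeric(1))
      if (!isTRUE(s$rvte_or_in_base)) ors["rvte"] <- 1
      p <- apply_odds_ratio(p, ors)
    }
    unname(p)  # order: rvte, crnmb, mb, ich
  }
  seq_rec <- sequela_incidence("recurrence", params)
  list(
    arm = arm,
    p_first6 = pvec("first6", arm == "edoxaban"),
    ## 6-month re-treatment stays on the randomised agent (later stratum)
    p_later = pvec("later", arm == "edoxaban"),
    ## lifelong tertiary prevention: common strategy unless disabled
    p_lifelong = pvec("later", arm == "edoxaban" && !isTRUE(s$lifelong_common)),
    p_off = cl$p_recur_off_treatment,
    bg = background_mortality_by_cycle(params),
    cfr_rv = cl$cfr_pe_recurrence * cl$prop_recurrence_pe,
    cfr_mb = cl$cfr_non_ich_mb,
    cfr_ich = cl$cfr_ich,
    pdis = cl$p_disabled_after_ich,
    pl = prop_lifelong(params),
    p_pts_rec = unname(seq_rec["p_pts"]),
    p_ct_rec = unname(seq_rec["p_cteph"]),
    pend = cl$prop_cteph_endarterectomy,
    cfr_en = cl$cfr_endarterectomy,
    m_cteph = cl$p_monthly_death_cteph,
    m_dis = cl$p_monthly_death_post_ich_disability
  )
}

# ---------------------------------------------------------------------------
# Single transition

#' Advance the cohort by one monthly cycle
#'
#' Applies, in order: adverse-event and recurrence draws from the
#' on/off-treatment states (mutually exclusive competing draws; an error is
#' raised if the per-state probabilities sum beyond 1), background
#' mortality on every alive slot, tunnel resolution, sequela onset with the
#' endarterectomy branch, and the extra monthly mortality of CTEPH and
#' post-ICH disability carriers (removed proportionally from the alive
#' occupancy). Mass is conserved to 1e-9.
#'
#' This is the single-step primitive behind [run_cohort()]; it operates on
#' the internal 28-slot state vector (`vte_state_init()` builds the starting
#' state).
#'
#' @param state Numeric vector of length 28 (see `vtecea:::SLOT_NAMES`).
#' @param prev Numeric vector `c(pts, cteph, dis)` of concomitant
#'   prevalences.
#' @param cycle Zero-based cycle index (selects the background-mortality
#'   row).
#' @param arm `"edoxaban"` or `"warfarin"`.
#' @param params A `vte_params` object.
#' @return A list with elements `state`, `prev`, `flows`.
#' @export
markov_step <- function(state, prev, cycle, arm, params) {
  ei <- engine_inputs(params, arm)
  step_core(state, prev, cycle, ei)
}

step_core <- function(state, prev, cycle, ei) {
  pbg <- ei$bg[cycle + 1L]
  p1 <- ei$p_first6
  p2 <- ei$p_later
  pL <- ei$p_lifelong
  s1 <- sum(p1)
  s2 <- sum(p2)
  sL <- sum(pL)
  if (s1 + pbg > 1 || s2 + pbg > 1 || sL + pbg > 1 || ei$p_off + pbg > 1) {
    state_lab <- if (s1 + pbg > 1) "initial-episode"
                 else if (s2 + pbg > 1) "re-treatment"
                 else if (sL + pbg > 1) "lifelong-treatment"
                 else "off-treatment"
    abort(sprintf("Event probabilities sum beyond 1 in the %s state at cycle %d",
                  state_lab, cycle))
  }

  new <- numeric(N_SLOTS)
  occ_i <- state[1:6]
  occ_r <- state[7:11]
  occ_rl <- state[12L]
  off <- state[13L]
  sum_i <- sum(occ_i)
  sum_r <- sum(occ_r)

  ## event flows
  f_rv <- sum_i * p1[1L] + sum_r * p2[1L] + occ_rl * pL[1L] + off * ei$p_off
  f_mb <- sum_i * p1[3L] + sum_r * p2[3L] + occ_rl * pL[3L]
  f_ich <- sum_i * p1[4L] + sum_r * p2[4L] + occ_rl * pL[4L]
  f_cr_i <- occ_i * p1[2L]
  f_cr_r <- occ_r * p2[2L]
  f_cr_rl <- occ_rl * pL[2L]
  f_cr <- sum(f_cr_i) + sum(f_cr_r) + f_cr_rl

  d_bg <- sum(state[1:27]) * pbg

  ## survivors advance through the treatment calendar
  stay_i <- occ_i * (1 - s1 - pbg)
  stay_r <- occ_r * (1 - s2 - pbg)
  new[2:6] <- stay_i[1:5]
  new[8:11] <- new[8:11] + stay_r[1:4]
  new[12L] <- occ_rl * (1 - sL - pbg)
  new[13L] <- stay_i[6L] + stay_r[5L] + off * (1 - ei$p_off - pbg)

  ## tunnels resolve to their destinations (background mortality applies)
  ex <- state[14:27] * (1 - pbg)
  new[12L] <- new[12L] + ex[1L] + ex[10L]          # t_rv_l, t_cr_rl
  new[7L] <- ex[2L]                                # t_rv_6 -> on_r month 2
  new[3:6] <- new[3:6] + ex[3:6]                   # t_cr_i -> on_i months 3-6
  new[9:11] <- new[9:11] + ex[7:9]                 # t_cr_r -> on_r months 4-6
  new[13L] <- new[13L] + ex[11L] + ex[12L] + ex[13L] + ex[14L]
  dis_onset <- ex[13L]                             # t_ich_d exits, disabled

  ## CRNMB entries keep their return context
  new[16:19] <- f_cr_i[1:4]
  new[20:22] <- f_cr_r[1:3]
  new[23L] <- f_cr_rl
  new[24L] <- f_cr_i[5L] + f_cr_i[6L] + f_cr_r[4L] + f_cr_r[5L]

  ## recurrent VTE: case fatality, sequela onset, re-treatment assignment
  d_rv <- f_rv * ei$cfr_rv
  surv <- f_rv - d_rv
  onset_pts <- surv * ei$p_pts_rec
  onset_ct <- surv * ei$p_ct_rec
  d_en <- onset_ct * ei$pend * ei$cfr_en
  onset_ct <- onset_ct - d_en
  surv <- surv - d_en
  new[14L] <- new[14L] + surv * ei$pl
  new[15L] <- new[15L] + surv * (1 - ei$pl)

  ## major bleeds
  d_mb <- f_mb * ei$cfr_mb
  new[25L] <- new[25L] + f_mb - d_mb
  d_ich <- f_ich * ei$cfr_ich
  s_ich <- f_ich - d_ich
  new[26L] <- new[26L] + s_ich * ei$pdis
  new[27L] <- new[27L] + s_ich * (1 - ei$pdis)

  ## concomitant states: background then state-specific mortality
  prev2 <- prev * (1 - pbg)
  d_ct <- prev2[2L] * ei$m_cteph
  d_dis <- prev2[3L] * ei$m_dis
  alive <- sum(new[1:27])
  extra <- d_ct + d_dis
  if (extra > 0 && alive > 0) {
    new[1:27] <- new[1:27] * (1 - extra / alive)
  }
  prev_new <- c(prev2[1L] + onset_pts,
                prev2[2L] - d_ct + onset_ct,
                prev2[3L] - d_dis + dis_onset)
  alive_new <- alive - extra
  prev_new <- pmin(prev_new, alive_new)

  new[SLOT_DEAD] <- state[SLOT_DEAD] + d_bg + d_rv + d_en + d_mb + d_ich +
    extra

  flows <- c(f_rv, f_cr, f_mb, f_ich, d_bg, d_rv, d_mb, d_ich, d_en,
             d_ct, d_dis, onset_pts, onset_ct, dis_onset)
  list(state = new, prev = prev_new, flows = flows)
}

#' Starting state of the cohort
#'
#' The full cohort starts in month 1 of the initial treatment episode.
#' Index-event sequelae (PTS after an index DVT, CTEPH after an index PE,
#' with the endarterectomy branch and its perioperative mortality) are
#' applied at entry.
#'
#' @param params A `vte_params` object.
#' @return A list with elements `state` (length 28), `prev`
#'   (`c(pts, cteph, dis)`) and `onsets` (index sequela onsets, used for
#'   first-month sequela costs).
#' @export
vte_state_init <- function(params) {
  seq_idx <- sequela_incidence("index", params)
  pts0 <- unname(seq_idx["p_pts"])
  ct_raw <- unname(seq_idx["p_cteph"])
  d_en0 <- ct_raw * params$clinical$prop_cteph_endarterectomy *
    params$clinical$cfr_endarterectomy
  ct0 <- ct_raw - d_en0
  state <- numeric(N_SLOTS)
  state[1L] <- 1 - d_en0
  state[SLOT_DEAD] <- d_en0
  list(state = state, prev = c(pts = pts0, cteph = ct0, dis = 0),
       onsets = c(pts = pts0, cteph = ct0, d_endart = d_en0))
}

# ---------------------------------------------------------------------------
# Cohort roll-forward

#' Run the cohort model for one treatment arm
#'
#' Rolls the cohort forward over the full horizon, recording per-cycle
#' occupancy of the exclusive states, concomitant prevalences, and
#' cumulative event counters. The cohort model is deterministic.
#'
#' @param params A `vte_params` object.
#' @param arm `"edoxaban"` or `"warfarin"`.
#' @return A `vte_trace` object; its `$trace` element is a tibble with one
#'   row per cycle 0..horizon giving the aggregated state occupancy,
#'   prevalences and cumulative counters. Internal matrices used by
#'   [accumulate()] are attached.
#' @examples
#' tr <- run_cohort(vte_parameters(horizon_months = 24), "warfarin")
#' tail(tr$trace, 2)
#' @export
run_cohort <- function(params, arm) {
  ei <- engine_inputs(params, arm)
  H <- params$settings$horizon_months
  init <- vte_state_init(params)

  occ <- matrix(0, nrow = H + 1L, ncol = N_SLOTS,
                dimnames = list(NULL, SLOT_NAMES))
  prevm <- matrix(0, nrow = H + 1L, ncol = 3L,
                  dimnames = list(NULL, c("pts", "cteph", "dis")))
  flows <- matrix(0, nrow = max(H, 1L), ncol = length(FLOW_NAMES),
                  dimnames = list(NULL, FLOW_NAMES))

  state <- init$state
  prev <- init$prev
  occ[1L, ] <- state
  prevm[1L, ] <- prev

  t <- 0L
  while (t < H) {
    res <- step_core(state, prev, t, ei)
    state <- res$state
    prev <- res$prev
    flows[t + 1L, ] <- res$flows
    occ[t + 2L, ] <- state
    prevm[t + 2L, ] <- prev
    t <- t + 1L
  }

  ## index-event sequela onsets count into cycle-0 flows for costing and
  ## cumulative counters
  if (H >= 1L) {
    flows[1L, "onset_pts"] <- flows[1L, "onset_pts"] + init$onsets[["pts"]]
    flows[1L, "onset_cteph"] <- flows[1L, "onset_cteph"] +
      init$onsets[["cteph"]]
    flows[1L, "d_endart"] <- flows[1L, "d_endart"] +
      init$onsets[["d_endart"]]
  }

  trace <- tibble::tibble(
    cycle = 0:H,
    age = params$settings$start_age + (0:H) / 12,
    on_treatment_ivte = rowSums(occ[, 1:6, drop = FALSE]),
    on_treatment_rvte = rowSums(occ[, 7:12, drop = FALSE]),
    off_treatment = occ[, 13L],
    rvte = rowSums(occ[, 14:15, drop = FALSE]),
    crnmb = rowSums(occ[, 16:24, drop = FALSE]),
    non_ich_mb = occ[, 25L],
    ich = rowSums(occ[, 26:27, drop = FALSE]),
    death = occ[, 28L],
    prev_pts = prevm[, "pts"],
    prev_cteph = prevm[, "cteph"],
    prev_dis = prevm[, "dis"],
    cum_rvte = cumsum(c(0, flows[seq_len(H), "f_rvte"])),
    cum_crnmb = cumsum(c(0, flows[seq_len(H), "f_crnmb"])),
    cum_non_ich_mb = cumsum(c(0, flows[seq_len(H), "f_mb"])),
    cum_ich = cumsum(c(0, flows[seq_len(H), "f_ich"])),
    cum_pts = cumsum(c(0, flows[seq_len(H), "onset_pts"])),
    cum_cteph = cumsum(c(0, flows[seq_len(H), "onset_cteph"])),
    cum_specific_death = cumsum(c(0, flows[seq_len(H), "d_rvte"] +
                                    flows[seq_len(H), "d_mb"] +
                                    flows[seq_len(H), "d_ich"] +
                                    flows[seq_len(H), "d_endart"] +
                                    flows[seq_len(H), "d_cteph"] +
                                    flows[seq_len(H), "d_dis"]))
  )

  structure(
    list(trace = trace, arm = ei$arm, params = params,
         occupancy = occ, prevalence = prevm, flows = flows,
         init = init),
    class = "vte_trace"
  )
}

#' @export
print.vte_trace <- function(x, ...) {
  H <- nrow(x$trace) - 1L
  cat(sprintf("<vte_trace> %s arm, %d monthly cycles\n", x$arm, H))
  cat(sprintf("  final death fraction: %.4f\n", x$trace$death[H + 1L]))
  cat(sprintf("  cumulative rVTE: %.2f per patient\n",
              x$trace$cum_rvte[H + 1L]))
  invisible(x)
}
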