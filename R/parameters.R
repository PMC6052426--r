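## Model parameters: construction, access, validation, scenarios, subgroups.
##
## The parameter object is a nested, validated list (class "vte_params") with
## five blocks -- risks, clinical, utilities, costs, settings -- plus a life
## table. A flat registry of DSA-able parameters (dotted ids -> bounds and
## sampling family) drives the tornado and probabilistic analyses.

# ---------------------------------------------------------------------------
# Constructor

#' Base-case model parameters
#'
#' Builds the complete base-case parameter set of the edoxaban vs. warfarin
#' VTE treatment model: time-stratified monthly event probabilities and odds
#' ratios, clinical proportions and case-fatality probabilities, state
#' utilities and relative utility decrements, unit costs and resource use,
#' and run settings (horizon, discounting, cohort demographics).
#'
#' Event risks are stratified into the first six months of the initial
#' anticoagulation episode and all later on-treatment time. Odds ratios whose
#' confidence intervals include 1 carry `sig_* = FALSE` and are the ones
#' replaced by 1 in the `or_nonsig_to_one` scenario (see
#' [apply_scenario()]).
#'
#' @param ... Named settings overriding the defaults in `settings` (for
#'   example `horizon_months = 60`, `start_age = 60`, `wtp = 30000`).
#' @param life_table A life table as returned by [make_life_table()]. The
#'   default synthetic Gompertz-Makeham table approximates contemporary UK
#'   all-cause mortality.
#'
#' @return An object of class `vte_params`.
#' @examples
#' p <- vte_parameters()
#' p$risks$rvte$p_first6      # 0.018 / month on warfarin, months 1-6
#' p$utilities$u_dvt          # 0.71
#' @export
vte_parameters <- function(..., life_table = make_life_table()) {
  risk <- function(p1, p1l, p1h, p2, p2l, p2h,
                   or1, or1l, or1h, or2, or2l, or2h, sig1, sig2) {
    list(p_first6 = p1, p_first6_low = p1l, p_first6_high = p1h,
         p_later = p2, p_later_low = p2l, p_later_high = p2h,
         or_first6 = or1, or_first6_low = or1l, or_first6_high = or1h,
         or_later = or2, or_later_low = or2l, or_later_high = or2h,
         sig_first6 = sig1, sig_later = sig2)
  }

  risks <- list(
    # VTE recurrence: neither OR stratum significant
    rvte  = risk(0.018, 0.014, 0.022, 0.002, 0.000, 0.004,
                 0.83, 0.59, 1.17, 0.82, 0.25, 2.68, FALSE, FALSE),
    # clinically relevant non-major bleed: first-6 OR significant
    crnmb = risk(0.017, 0.014, 0.020, 0.004, 0.002, 0.006,
                 0.78, 0.66, 0.93, 0.89, 0.59, 1.32, TRUE, FALSE),
    # non-ICH major bleed: later OR significant
    mb    = risk(0.0016, 0.0007, 0.0026, 0.0004, 0.0000, 0.0010,
                 1.15, 0.75, 1.75, 0.44, 0.13, 1.42, FALSE, TRUE),
    # intracranial haemorrhage: first-6 OR significant
    ich   = risk(0.0003, 0.0000, 0.0008, 0.0003, 0.0000, 0.0008,
                 0.23, 0.07, 0.81, 0.39, 0.08, 2.02, TRUE, FALSE)
  )

  clinical <- list(
    prop_index_pe           = 0.401,  # index events that are PE (+/- DVT)
    prop_index_pe_with_dvt  = 0.441,  # index PE that also have DVT
    prop_recurrence_pe      = 0.565,  # recurrences that are PE
    p_recur_off_treatment   = 0.0042, # monthly rVTE risk off treatment
    p_cteph_after_pe        = 0.048,
    p_pts_after_dvt         = 0.027,
    p_disabled_after_ich    = 0.65,
    cfr_pe_recurrence       = 0.061,
    cfr_non_ich_mb          = 0.061,
    cfr_ich                 = 0.261,
    cfr_endarterectomy      = 0.044,
    p_monthly_death_post_ich_disability = 0.033,
    p_monthly_death_cteph   = 0.007,
    # NULL = derived as prop_index_pe * prop_recurrence_pe (both index and
    # recurrent event are PE); an explicit value overrides the derivation.
    prop_lifelong_after_recurrence = NULL,
    prop_cteph_endarterectomy = 0.503
  )

  utilities <- list(
    u_pe  = 0.67,
    u_dvt = 0.71,
    du_warfarin        = 0.0137, # relative decrement vs. edoxaban, initial episode
    du_crnmb           = 0.05,
    du_non_ich_mb      = 0.3158,
    du_ich             = 0.6526,
    du_ich_disability  = 0.6526,
    du_cteph           = 0.30,
    du_pts             = 0.1368,
    du_rvte_first_month = 0.14
  )

  costs <- list(
    # per-cycle treatment cost primitives (include heparin lead-in and, for
    # warfarin, INR monitoring); components below feed the DSA rebuild
    c_warfarin_cycle_first  = 273.81,
    c_warfarin_cycle_later  = 26.73,
    c_edoxaban_cycle_first  = 108.62,
    c_edoxaban_cycle_later  = 53.27,
    c_warfarin_monthly_drug = 1.22,
    c_edoxaban_monthly_first = 44.50,
    c_edoxaban_monthly_later = 53.30,
    c_heparin_daily         = 12.82,  # effective: 6.5 x 12.82 = 83.33
    heparin_days_warfarin   = 6.5,
    heparin_days_edoxaban   = 5.0,
    c_inr_first             = 87,
    c_inr_subsequent        = 26,
    n_inr_titration         = 4,
    n_inr_monthly           = 1,
    c_pe_event              = 1647,
    c_dvt_event             = 551,
    c_ich_acute             = 3012,
    c_non_ich_mb            = 2940,
    c_crnmb                 = 384,
    c_ich_disability_monthly = 524,
    c_pts_first_month       = 168,
    c_pts_monthly           = 23,
    c_endarterectomy        = 7824,
    c_cteph_drugs_monthly   = 1348
  )

  settings <- list(
    horizon_months       = 600,
    discount_rate_annual = 0.035,
    wtp                  = 20000,
    start_age            = 56,
    prop_male            = 0.57,
    initial_treatment_months   = 6,
    recurrence_treatment_months = 6,
    subgroup             = "all",
    or_nonsig_to_one     = FALSE,
    half_cycle_correction = FALSE,
    use_age_utility      = TRUE,
    # scope of the warfarin utility decrement: "initial" applies it to the
    # initial 6-month episode; "all" also to re-treatment on the randomised
    # agent (lifelong months only when lifelong_common = FALSE)
    du_warfarin_scope    = "all",
    # base-case recurrence efficacy is assumed equal across arms (the trial
    # was a non-inferiority study and both recurrence odds ratios are
    # non-significant); TRUE applies the recurrence ORs in the base case
    rvte_or_in_base      = FALSE,
    # lifelong tertiary prevention is a new anticoagulant strategy common
    # to both arms (baseline risks, NOAC-era costs); FALSE keeps patients
    # on their randomised agent for life
    lifelong_common      = TRUE,
    rng_seed             = 20180717
  )

  dots <- list(...)
  unknown <- setdiff(names(dots), names(settings))
  if (length(unknown) > 0) {
    abort(paste0("Unknown setting(s): ", paste(unknown, collapse = ", ")))
  }
  settings[names(dots)] <- dots

  params <- structure(
    list(risks = risks, clinical = clinical, utilities = utilities,
         costs = costs, settings = settings, life_table = life_table),
    class = "vte_params"
  )
  v <- validate_parameters(params)
  if (nrow(v) > 0) {
    abort(paste0("Invalid parameters:\n",
                 paste(format_violations(v), collapse = "\n")))
  }
  params
}

#' @export
print.vte_params <- function(x, ...) {
  s <- x$settings
  cat("<vte_params> Markov VTE treatment model parameters\n")
  cat(sprintf("  horizon: %d months, discount %.1f%%/yr, WTP £%s/QALY\n",
              s$horizon_months, 100 * s$discount_rate_annual,
              format(s$wtp, big.mark = ",")))
  cat(sprintf("  cohort: start age %.0f, %.0f%% male, subgroup '%s'\n",
              s$start_age, 100 * s$prop_male, s$subgroup))
  cat(sprintf("  index mix: %.1f%% PE (of which %.1f%% with DVT)\n",
              100 * x$clinical$prop_index_pe,
              100 * x$clinical$prop_index_pe_with_dvt))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Dotted-path access (used by the DSA/PSA registry)

param_get <- function(params, id) {
  path <- strsplit(id, ".", fixed = TRUE)[[1]]
  purrr::reduce(path, function(x, nm) x[[nm]], .init = params)
}

param_set <- function(params, id, value) {
  path <- strsplit(id, ".", fixed = TRUE)[[1]]
  params[[path]] <- value
  params
}

#' Registry of parameters with deterministic sensitivity bounds
#'
#' One row per model input that carries a low/high uncertainty interval:
#' its dotted id inside the parameter object, base value, bounds, and the
#' sampling family used by the probabilistic analysis (`beta` for
#' probabilities, proportions and utility values/decrements, `lognormal`
#' for odds ratios, `gamma` for costs and resource counts).
#'
#' @param params A `vte_params` object.
#' @return A tibble with columns `id`, `label`, `base`, `low`, `high`,
#'   `family`.
#' @export
parameter_registry <- function(params) {
  rows <- list()
  add <- function(id, label, family, low, high) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      id = id, label = label, base = as.numeric(param_get(params, id)),
      low = low, high = high, family = family)
  }

  lab_ev <- c(rvte = "VTE recurrence", crnmb = "CRNMB",
              mb = "Non-ICH MB", ich = "ICH")
  for (ev in names(params$risks)) {
    r <- params$risks[[ev]]
    add(paste0("risks.", ev, ".p_first6"),
        paste0(lab_ev[[ev]], " baseline probability, months 1-6"),
        "beta", r$p_first6_low, r$p_first6_high)
    add(paste0("risks.", ev, ".p_later"),
        paste0(lab_ev[[ev]], " baseline probability, months 7+"),
        "beta", r$p_later_low, r$p_later_high)
    add(paste0("risks.", ev, ".or_first6"),
        paste0(lab_ev[[ev]], " odds ratio, months 1-6"),
        "lognormal", r$or_first6_low, r$or_first6_high)
    add(paste0("risks.", ev, ".or_later"),
        paste0(lab_ev[[ev]], " odds ratio, months 7+"),
        "lognormal", r$or_later_low, r$or_later_high)
  }

  cl <- function(id, label, low, high) {
    add(paste0("clinical.", id), label, "beta", low, high)
  }
  cl("prop_index_pe", "Proportion of PE in index events", 0.391, 0.412)
  cl("prop_index_pe_with_dvt", "Proportion of index PE with DVT", 0.424, 0.458)
  cl("prop_recurrence_pe", "Proportion of PE among recurrences", 0.507, 0.624)
  cl("p_recur_off_treatment", "Monthly VTE recurrence risk off treatment",
     0.0036, 0.0049)
  cl("p_cteph_after_pe", "Probability of CTEPH after a PE", 0.023, 0.096)
  cl("p_pts_after_dvt", "Probability of severe PTS after a DVT", 0.027, 0.081)
  cl("p_disabled_after_ich", "Probability of disability after ICH", 0.56, 0.75)
  cl("cfr_pe_recurrence", "Death after PE recurrence", 0.030, 0.308)
  cl("cfr_non_ich_mb", "Death after non-ICH MB", 0.014, 0.108)
  cl("cfr_ich", "Death after ICH", 0.081, 0.440)
  cl("cfr_endarterectomy", "Death after pulmonary endarterectomy", 0.026, 0.062)
  cl("p_monthly_death_post_ich_disability",
     "Monthly mortality, post-ICH disability", 0.014, 0.033)
  cl("p_monthly_death_cteph", "Monthly mortality, CTEPH", 0.006, 0.007)
  cl("prop_cteph_endarterectomy", "CTEPH patients undergoing endarterectomy",
     0.40, 0.60)

  ut <- function(id, label, low, high) {
    add(paste0("utilities.", id), label, "beta", low, high)
  }
  ut("u_pe", "Utility, PE", 0.30, 0.72)
  ut("u_dvt", "Utility, DVT", 0.54, 0.80)
  ut("du_warfarin", "Utility decrement with warfarin", 0.000, 0.019)
  ut("du_crnmb", "Utility decrement, CRNMB", 0.00, 0.10)
  ut("du_non_ich_mb", "Utility decrement, non-ICH MB", 0.09, 0.48)
  ut("du_ich", "Utility decrement, ICH", 0.44, 0.85)
  ut("du_ich_disability", "Utility decrement, post-ICH disability", 0.44, 0.85)
  ut("du_cteph", "Utility decrement, CTEPH", 0.26, 0.34)
  ut("du_pts", "Utility decrement, severe PTS", 0.00, 0.31)

  co <- function(id, label, low, high) {
    add(paste0("costs.", id), label, "gamma", low, high)
  }
  co("c_heparin_daily", "Daily heparin cost", 7.9, 15.5)
  co("heparin_days_warfarin", "Heparin lead-in days, warfarin", 5.0, 8.5)
  co("heparin_days_edoxaban", "Heparin lead-in days, edoxaban", 5.0, 7.5)
  co("c_inr_first", "Cost of first INR visit", 42, 92)
  co("c_inr_subsequent", "Cost of subsequent INR visit", 16, 37)
  co("n_inr_titration", "INR visits for titration", 3.0, 6.0)
  co("n_inr_monthly", "Monthly INR visits after month 1", 0.8, 1.7)
  co("c_pe_event", "Cost per PE event", 1238, 3668)
  # printed interval (654-1086) does not bracket the printed base 551;
  # the low bound is clamped to the base value
  co("c_dvt_event", "Cost per DVT event", 551, 1086)
  co("c_ich_acute", "Inpatient cost, ICH", 1964, 6493)
  co("c_non_ich_mb", "Inpatient cost, non-ICH MB", 2330, 5610)
  co("c_crnmb", "Cost, CRNMB", 308, 461)
  co("c_ich_disability_monthly", "Monthly cost, post-ICH disability", 164, 1053)
  co("c_pts_first_month", "PTS cost, first month", 167, 173)
  co("c_pts_monthly", "PTS cost, subsequent months", 23, 24)
  co("c_endarterectomy", "Cost of pulmonary endarterectomy", 6540, 10227)
  co("c_cteph_drugs_monthly", "Monthly CTEPH drug cost", 1078, 1617)

  dplyr::bind_rows(rows)
}

# ---------------------------------------------------------------------------
# Validation

#' Validate a parameter set
#'
#' Checks every type invariant: probabilities, proportions, utilities and
#' decrements in \[0, 1\]; odds ratios > 0; costs and counts >= 0; DSA bounds
#' bracketing their base value; settings within their enumerations.
#' Violations are returned as data, not raised.
#'
#' @param params A structurally complete `vte_params` object.
#' @param check_bounds Also check that every DSA interval brackets its base
#'   value (disabled when validating sampled parameter sets, whose values
#'   legitimately leave the printed intervals).
#' @return A tibble with columns `field`, `value`, `rule`; zero rows if the
#'   parameter set is valid.
#' @examples
#' nrow(validate_parameters(vte_parameters()))  # 0
#' @export
validate_parameters <- function(params, check_bounds = TRUE) {
  out <- list()
  bad <- function(field, value, rule) {
    out[[length(out) + 1]] <<- tibble::tibble(
      field = field, value = as.numeric(value)[1], rule = rule)
  }
  chk_prob <- function(field, value) {
    if (!is.numeric(value) || is.na(value) || value < 0 || value > 1) {
      bad(field, value, "probability in [0, 1]")
    }
  }
  chk_pos <- function(field, value) {
    if (!is.numeric(value) || is.na(value) || value <= 0) {
      bad(field, value, "odds ratio > 0")
    }
  }
  chk_nonneg <- function(field, value) {
    if (!is.numeric(value) || is.na(value) || value < 0) {
      bad(field, value, "cost/count >= 0")
    }
  }

  for (ev in names(params$risks)) {
    r <- params$risks[[ev]]
    for (st in c("first6", "later")) {
      chk_prob(paste0("risks.", ev, ".p_", st), r[[paste0("p_", st)]])
      chk_pos(paste0("risks.", ev, ".or_", st), r[[paste0("or_", st)]])
      if (check_bounds) {
        for (kind in c("p", "or")) {
          base <- r[[paste0(kind, "_", st)]]
          lo <- r[[paste0(kind, "_", st, "_low")]]
          hi <- r[[paste0(kind, "_", st, "_high")]]
          if (lo > base) bad(paste0("risks.", ev, ".", kind, "_", st, "_low"),
                             lo, "low <= base")
          if (hi < base) bad(paste0("risks.", ev, ".", kind, "_", st, "_high"),
                             hi, "base <= high")
        }
      }
    }
  }

  for (nm in names(params$clinical)) {
    v <- params$clinical[[nm]]
    if (is.null(v)) next  # derived field
    chk_prob(paste0("clinical.", nm), v)
  }
  for (nm in names(params$utilities)) {
    chk_prob(paste0("utilities.", nm), params$utilities[[nm]])
  }
  for (nm in names(params$costs)) {
    chk_nonneg(paste0("costs.", nm), params$costs[[nm]])
  }

  reg <- if (check_bounds) {
    tryCatch(parameter_registry(params), error = function(e) NULL)
  }
  if (!is.null(reg)) {
    bad_lo <- reg[reg$low > reg$base + 1e-12, ]
    bad_hi <- reg[reg$high < reg$base - 1e-12, ]
    for (i in seq_len(nrow(bad_lo))) {
      bad(bad_lo$id[i], bad_lo$low[i], "low <= base")
    }
    for (i in seq_len(nrow(bad_hi))) {
      bad(bad_hi$id[i], bad_hi$high[i], "base <= high")
    }
  }

  s <- params$settings
  if (!is.numeric(s$horizon_months) || s$horizon_months < 0) {
    bad("settings.horizon_months", s$horizon_months, "horizon >= 0")
  }
  if (s$discount_rate_annual < 0) {
    bad("settings.discount_rate_annual", s$discount_rate_annual,
        "discount rate >= 0")
  }
  if (!s$subgroup %in% c("all", "dvt_only", "pe_any", "pe_only",
                         "pe_plus_dvt")) {
    bad("settings.subgroup", NA, "subgroup from enumeration")
  }
  if (s$prop_male < 0 || s$prop_male > 1) {
    bad("settings.prop_male", s$prop_male, "proportion in [0, 1]")
  }

  lt <- params$life_table
  if (!all(c("age", "sex", "qx") %in% names(lt))) {
    bad("life_table", NA, "columns age, sex, qx present")
  } else if (any(lt$qx < 0 | lt$qx > 1)) {
    bad("life_table.qx", min(lt$qx), "qx in [0, 1]")
  }

  if (length(out) == 0) {
    return(tibble::tibble(field = character(), value = numeric(),
                          rule = character()))
  }
  dplyr::bind_rows(out)
}

format_violations <- function(v) {
  sprintf("  %s = %s violates '%s'", v$field, signif(v$value, 6), v$rule)
}

# ---------------------------------------------------------------------------
# Scenarios and subgroups

#' Apply a named scenario to a parameter set
#'
#' `or_nonsig_to_one` replaces exactly those odds ratios whose confidence
#' intervals include 1 (flagged `sig_* = FALSE`) by 1.0, leaving the
#' significant ones (CRNMB months 1-6, non-ICH MB months 7+, ICH months 1-6)
#' untouched. `horizon_1y` / `horizon_5y` truncate the time horizon to 12 /
#' 60 monthly cycles. The input object is never modified.
#'
#' @param params A `vte_params` object.
#' @param scenario One of `"or_nonsig_to_one"`, `"horizon_1y"`,
#'   `"horizon_5y"`.
#' @return A new `vte_params` object.
#' @examples
#' p <- apply_scenario(vte_parameters(), "or_nonsig_to_one")
#' p$risks$rvte$or_first6  # 1
#' p$risks$ich$or_first6   # still 0.23
#' @export
apply_scenario <- function(params, scenario) {
  scenario <- match.arg(scenario,
                        c("or_nonsig_to_one", "horizon_1y", "horizon_5y"))
  if (scenario == "or_nonsig_to_one") {
    for (ev in names(params$risks)) {
      if (!params$risks[[ev]]$sig_first6) params$risks[[ev]]$or_first6 <- 1
      if (!params$risks[[ev]]$sig_later) params$risks[[ev]]$or_later <- 1
    }
    params$settings$or_nonsig_to_one <- TRUE
  } else if (scenario == "horizon_1y") {
    params$settings$horizon_months <- 12
  } else {
    params$settings$horizon_months <- 60
  }
  params
}

#' Restrict the cohort to an index-event subgroup
#'
#' Adjusts the index-event composition only; all trial odds ratios, baseline
#' probabilities and other inputs stay at their pooled values.
#'
#' * `dvt_only`: index DVT without PE (`prop_index_pe = 0`)
#' * `pe_any`: index PE with or without DVT (`prop_index_pe = 1`)
#' * `pe_only`: index PE without DVT (`prop_index_pe = 1`,
#'   `prop_index_pe_with_dvt = 0`)
#' * `pe_plus_dvt`: both index PE and index DVT (both set to 1)
#' * `all`: unchanged
#'
#' @param params A `vte_params` object.
#' @param subgroup Subgroup id.
#' @return A new `vte_params` object.
#' @export
subgroup_parameters <- function(params, subgroup) {
  subgroup <- match.arg(subgroup, c("all", "dvt_only", "pe_any", "pe_only",
                                    "pe_plus_dvt"))
  cl <- params$clinical
  if (subgroup == "dvt_only") {
    cl$prop_index_pe <- 0
  } else if (subgroup == "pe_any") {
    cl$prop_index_pe <- 1
  } else if (subgroup == "pe_only") {
    cl$prop_index_pe <- 1
    cl$prop_index_pe_with_dvt <- 0
  } else if (subgroup == "pe_plus_dvt") {
    cl$prop_index_pe <- 1
    cl$prop_index_pe_with_dvt <- 1
  }
  params$clinical <- cl
  params$settings$subgroup <- subgroup
  params
}

# ---------------------------------------------------------------------------
# File round-trip

#' Write a parameter set to a YAML file
#'
#' The file mirrors the parameter blocks (`risks`, `clinical`, `utilities`,
#' `costs`, `settings`) so the transcription of the model inputs is
#' reviewable as plain text. The life table is not embedded; see
#' [make_life_table()] and the `life_table_csv` argument of
#' [load_parameters()].
#'
#' @param params A `vte_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  x <- list(risks = params$risks, clinical = params$clinical,
            utilities = params$utilities, costs = params$costs,
            settings = params$settings)
  # drop NULL-valued derived fields so the round trip is exact
  x$clinical <- x$clinical[!vapply(x$clinical, is.null, logical(1))]
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' Load and validate a parameter file
#'
#' Reads a YAML parameter file (as written by [write_parameters()] or
#' [write_base_case_fixture()]), fills any omitted `settings` fields with
#' the documented defaults, validates the result, and records every applied
#' default in the run log attached as attribute `"run_log"`.
#'
#' @param path Path to the parameter file.
#' @param life_table_csv Optional path to a life-table CSV
#'   (columns `age,sex,qx`, sex coded `M`/`F`); the synthetic default table
#'   is used when omitted.
#' @return A validated `vte_params` object.
#' @export
load_parameters <- function(path, life_table_csv = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Parameter file not found: ", path))
  }
  x <- yaml::read_yaml(path)
  required <- c("risks", "clinical", "utilities", "costs")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("Parameter file is missing block(s): ",
                 paste(missing, collapse = ", ")))
  }

  defaults <- vte_parameters()
  log <- character()

  for (block in c("risks", "clinical", "utilities", "costs")) {
    miss <- setdiff(names(defaults[[block]]), names(x[[block]]))
    miss <- miss[!vapply(defaults[[block]][miss], is.null, logical(1))]
    if (length(miss) > 0) {
      abort(paste0("Missing required field(s) in '", block, "': ",
                   paste(miss, collapse = ", ")))
    }
  }

  settings <- defaults$settings
  given <- intersect(names(settings), names(x$settings %||% list()))
  settings[given] <- x$settings[given]
  for (nm in setdiff(names(settings), given)) {
    log <- c(log, sprintf("default applied: settings.%s = %s", nm,
                          format(settings[[nm]])))
  }

  lt <- if (is.null(life_table_csv)) {
    log <- c(log, "default applied: synthetic Gompertz-Makeham life table")
    make_life_table()
  } else {
    read_life_table(life_table_csv)
  }

  clin <- defaults$clinical
  clin[names(x$clinical)] <- x$clinical

  params <- structure(
    list(risks = x$risks, clinical = clin, utilities = x$utilities,
         costs = x$costs, settings = settings, life_table = lt),
    class = "vte_params"
  )
  v <- validate_parameters(params)
  if (nrow(v) > 0) {
    abort(paste0("Invalid parameter file '", path, "':\n",
                 paste(format_violations(v), collapse = "\n")))
  }
  attr(params, "run_log") <- log
  params
}
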