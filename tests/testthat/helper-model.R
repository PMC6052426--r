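# Shared helpers: short-horizon parameter sets and an independent
# path-enumeration oracle for the transition engine.

params_short <- function(horizon = 60, ...) {
  vte_parameters(horizon_months = horizon, ...)
}

# A constant-mortality literal life table (both sexes identical), handy for
# closed-form checks.
flat_life_table <- function(q = 0.012, ages = 18:110) {
  make_life_table(data.frame(
    age = rep(ages, 2),
    sex = rep(c("male", "female"), each = length(ages)),
    qx = q))
}

# Simplified parameters for exact path enumeration: no sequelae, no
# concomitant mortality, flat background mortality.
params_oracle <- function(horizon = 3) {
  p <- vte_parameters(horizon_months = horizon,
                      life_table = flat_life_table(0.024))
  p$clinical$p_cteph_after_pe <- 0
  p$clinical$p_pts_after_dvt <- 0
  p$clinical$p_monthly_death_cteph <- 0
  p$clinical$p_monthly_death_post_ich_disability <- 0
  p
}

# ---------------------------------------------------------------------------
# Independent oracle: exhaustive enumeration of all event paths over a few
# cycles. Written directly from the model's stated transition rules as a
# per-slot branch distribution plus a recursive tree walk; it shares no code
# with the engine's vectorised step.

oracle_branches <- function(slot, arm, p, pbg) {
  probs_for <- function(stratum, arm_specific) {
    pr <- vapply(p$risks, function(r) r[[paste0("p_", stratum)]], numeric(1))
    if (arm == "edoxaban" && arm_specific) {
      ors <- vapply(p$risks, function(r) r[[paste0("or_", stratum)]],
                    numeric(1))
      ors["rvte"] <- 1  # base case: equal recurrence efficacy
      pr <- ors * pr / (1 - pr + ors * pr)
    }
    pr
  }
  cl <- p$clinical
  cfr_rv <- cl$cfr_pe_recurrence * cl$prop_recurrence_pe
  pl <- cl$prop_index_pe * cl$prop_recurrence_pe

  event_branches <- function(pr, advance_to) {
    cr_dest <- if (slot <= 6) c(16, 17, 18, 19, 24, 24)[slot]
               else if (slot <= 11) c(20, 21, 22, 24, 24)[slot - 6]
               else 23
    b <- list(
      list(28, pr[["rvte"]] * cfr_rv),
      list(14, pr[["rvte"]] * (1 - cfr_rv) * pl),
      list(15, pr[["rvte"]] * (1 - cfr_rv) * (1 - pl)),
      list(cr_dest, pr[["crnmb"]]),
      list(28, pr[["mb"]] * cl$cfr_non_ich_mb),
      list(25, pr[["mb"]] * (1 - cl$cfr_non_ich_mb)),
      list(28, pr[["ich"]] * cl$cfr_ich),
      list(26, pr[["ich"]] * (1 - cl$cfr_ich) * cl$p_disabled_after_ich),
      list(27, pr[["ich"]] * (1 - cl$cfr_ich) *
             (1 - cl$p_disabled_after_ich)),
      list(28, pbg),
      list(advance_to, 1 - sum(pr) - pbg)
    )
    b
  }

  if (slot <= 6) {
    event_branches(probs_for("first6", TRUE), if (slot == 6) 13 else slot + 1)
  } else if (slot <= 11) {
    event_branches(probs_for("later", TRUE), if (slot == 11) 13 else slot + 1)
  } else if (slot == 12) {
    event_branches(probs_for("later", FALSE), 12)
  } else if (slot == 13) {
    list(list(28, cl$p_recur_off_treatment * cfr_rv),
         list(14, cl$p_recur_off_treatment * (1 - cfr_rv) * pl),
         list(15, cl$p_recur_off_treatment * (1 - cfr_rv) * (1 - pl)),
         list(28, pbg),
         list(13, 1 - cl$p_recur_off_treatment - pbg))
  } else if (slot == 28) {
    list(list(28, 1))
  } else {
    dest <- c(12, 7, 3, 4, 5, 6, 9, 10, 11, 12, 13, 13, 13, 13)[slot - 13]
    list(list(28, pbg), list(dest, 1 - pbg))
  }
}

oracle_enumerate <- function(p, arm, cycles) {
  pbg <- monthly_background_mortality(p$life_table, p$settings$start_age,
                                      p$settings$prop_male)
  final <- numeric(28)
  walk <- function(slot, mass, depth) {
    if (depth == cycles) {
      final[slot] <<- final[slot] + mass
      return(invisible())
    }
    for (b in oracle_branches(slot, arm, p, pbg)) {
      if (b[[2]] > 0) walk(b[[1]], mass * b[[2]], depth + 1)
    }
  }
  walk(1, 1, 0)
  final
}
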