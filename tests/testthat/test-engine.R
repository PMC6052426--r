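test_that("odds-ratio transform matches its closed form and edge cases", {
  expect_equal(apply_odds_ratio(0.018, 0.83),
               0.83 * 0.018 / (1 - 0.018 + 0.83 * 0.018), tolerance = 1e-15)
  expect_equal(round(apply_odds_ratio(0.018, 0.83), 5), 0.01499)
  expect_equal(apply_odds_ratio(0.018, 1), 0.018)
  expect_equal(apply_odds_ratio(0, 7.5), 0)
  expect_equal(apply_odds_ratio(1, 1), 1)
  expect_error(apply_odds_ratio(1, 0.5), "rescaled")
  expect_error(apply_odds_ratio(0.5, 0), "> 0")
})

test_that("event probabilities follow the published time strata", {
  p <- vte_parameters()
  w3 <- event_probabilities("on_treatment_ivte", 3, "warfarin", p)
  expect_equal(unname(w3[c("rvte", "crnmb", "non_ich_mb", "ich")]),
               c(0.018, 0.017, 0.0016, 0.0003))
  w9 <- event_probabilities("on_treatment_ivte", 9, "warfarin", p)
  expect_equal(unname(w9["rvte"]), 0.002)
  off <- event_probabilities("off_treatment", 1, "warfarin", p)
  expect_equal(unname(off["rvte"]), 0.0042)

  # edoxaban arm: bleed ORs applied; recurrence risk equal in the base case
  e3 <- event_probabilities("on_treatment_ivte", 3, "edoxaban", p)
  expect_equal(unname(e3["crnmb"]), apply_odds_ratio(0.017, 0.78))
  expect_equal(unname(e3["ich"]), apply_odds_ratio(0.0003, 0.23))
  expect_equal(unname(e3["rvte"]), 0.018)

  # with the recurrence OR switched on it modifies the edoxaban risk
  p2 <- vte_parameters(rvte_or_in_base = TRUE)
  e3b <- event_probabilities("on_treatment_ivte", 3, "edoxaban", p2)
  expect_equal(unname(e3b["rvte"]), apply_odds_ratio(0.018, 0.83))

  expect_equal(unname(event_probabilities("death", 1, "warfarin", p)),
               numeric(0))
  expect_error(event_probabilities("limbo", 1, "warfarin", p), "Unknown")
})

test_that("event resolution branches carry the published case fatalities", {
  p <- vte_parameters()
  rv <- resolve_event_consequences("rvte", p)
  expect_equal(sum(rv$prob), 1)
  expect_equal(rv$prob[rv$destination == "death"], 0.061 * 0.565,
               tolerance = 1e-12)
  ich <- resolve_event_consequences("ich", p)
  expect_equal(ich$prob[ich$destination == "death"], 0.261)
  expect_equal(ich$prob[ich$destination == "off_treatment_disabled"],
               (1 - 0.261) * 0.65)
  cr <- resolve_event_consequences("crnmb", p)
  expect_equal(cr$destination, "continue_treatment")
  mb <- resolve_event_consequences("non_ich_mb", p)
  expect_equal(mb$prob[mb$destination == "off_treatment"], 1 - 0.061)
  expect_error(resolve_event_consequences("sneeze", p), "Unknown")
})

test_that("sequela incidence scales with the PE/DVT composition", {
  p <- vte_parameters()
  idx <- sequela_incidence("index", p)
  expect_equal(unname(idx["p_cteph"]), 0.048 * 0.401, tolerance = 1e-12)
  expect_equal(unname(idx["p_pts"]),
               0.027 * (0.599 + 0.401 * 0.441), tolerance = 1e-12)
  rec <- sequela_incidence("recurrence", p)
  expect_equal(unname(rec["p_cteph"]), 0.048 * 0.565, tolerance = 1e-12)
  d <- subgroup_parameters(p, "dvt_only")
  expect_equal(unname(sequela_incidence("index", d)["p_cteph"]), 0)
  expect_error(sequela_incidence(list(frac_pe = 1.4, frac_dvt = 0), p),
               "\\[0, 1\\]")
})

test_that("mass is conserved and death is absorbing and monotone", {
  for (arm in c("edoxaban", "warfarin")) {
    tr <- run_cohort(params_short(240), arm)
    occ <- tr$occupancy
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(occ >= -1e-12))
    expect_true(all(diff(tr$trace$death) >= -1e-12))
    # cumulative counters monotone
    for (ctr in grep("^cum_", names(tr$trace), value = TRUE)) {
      expect_true(all(diff(tr$trace[[ctr]]) >= -1e-12), info = ctr)
    }
    # concomitant prevalence never exceeds the alive fraction
    alive <- 1 - tr$trace$death
    expect_true(all(tr$trace$prev_pts <= alive + 1e-12))
    expect_true(all(tr$trace$prev_cteph <= alive + 1e-12))
  }
})

test_that("all mass in death stays there", {
  p <- params_oracle(1)
  st <- numeric(28)
  st[28] <- 1
  res <- markov_step(st, c(0, 0, 0), 0, "warfarin", p)
  expect_equal(res$state[28], 1)
  expect_equal(sum(res$state), 1)
})

test_that("with all risks and mortality zeroed only the episode clock moves", {
  p <- vte_parameters(horizon_months = 3, life_table = flat_life_table(0))
  for (ev in names(p$risks)) {
    p$risks[[ev]]$p_first6 <- 0
    p$risks[[ev]]$p_later <- 0
  }
  p$clinical$p_recur_off_treatment <- 0
  p$clinical$p_cteph_after_pe <- 0
  p$clinical$p_pts_after_dvt <- 0
  init <- vte_state_init(p)
  res <- markov_step(init$state, init$prev, 0, "warfarin", p)
  expected <- numeric(28)
  expected[2] <- 1  # month 1 -> month 2, nothing else
  expect_equal(res$state, expected)
})

test_that("a single step from full initial occupancy matches hand arithmetic", {
  p <- params_oracle(1)
  init <- vte_state_init(p)
  res <- markov_step(init$state, init$prev, 0, "warfarin", p)
  pbg <- monthly_background_mortality(p$life_table, 56, 0.57)
  cl <- p$clinical
  d_expected <- pbg +
    0.018 * cl$cfr_pe_recurrence * cl$prop_recurrence_pe +
    0.0016 * cl$cfr_non_ich_mb +
    0.0003 * cl$cfr_ich
  expect_equal(res$state[28], d_expected, tolerance = 1e-14)
  expect_equal(res$state[16], 0.017)  # CRNMB tunnel -> on_i month 3
})

test_that("three-cycle trace matches exhaustive path enumeration to 1e-12", {
  p <- params_oracle(3)
  for (arm in c("warfarin", "edoxaban")) {
    tr <- run_cohort(p, arm)
    expect_equal(unname(tr$occupancy[4, ]), oracle_enumerate(p, arm, 3),
                 tolerance = 1e-12, info = arm)
  }
})

test_that("setting every OR to 1 makes the arms clinically identical", {
  p <- params_short(240)
  for (ev in names(p$risks)) {
    p$risks[[ev]]$or_first6 <- 1
    p$risks[[ev]]$or_later <- 1
  }
  te <- run_cohort(p, "edoxaban")
  tw <- run_cohort(p, "warfarin")
  expect_equal(te$occupancy, tw$occupancy, tolerance = 1e-12)
  expect_equal(te$flows, tw$flows, tolerance = 1e-12)
  # costs still differ through treatment bookkeeping
  expect_false(isTRUE(all.equal(
    accumulate(te)$totals$cost_total, accumulate(tw)$totals$cost_total)))
})

test_that("raising the ICH case fatality weakly increases lifetime deaths", {
  p <- params_short(240)
  base_death <- run_cohort(p, "warfarin")$trace$death[241]
  p2 <- p
  p2$clinical$cfr_ich <- 0.44
  expect_gte(run_cohort(p2, "warfarin")$trace$death[241], base_death)
})

test_that("arms differ only through OR-modified probabilities", {
  p <- params_short(120)
  te <- run_cohort(p, "edoxaban")
  tw <- run_cohort(p, "warfarin")
  # same starting state, different bleed flows
  expect_equal(te$occupancy[1, ], tw$occupancy[1, ])
  expect_lt(sum(te$flows[, "f_crnmb"]), sum(tw$flows[, "f_crnmb"]))
  expect_lt(sum(te$flows[, "f_ich"]), sum(tw$flows[, "f_ich"]))
})

test_that("lifetime recurrence counts are events per patient, above 1", {
  tr <- run_cohort(vte_parameters(), "warfarin")
  expect_gt(tr$trace$cum_rvte[601], 1)
})

test_that("horizon zero gives a single-row trace", {
  p <- vte_parameters(horizon_months = 0)
  tr <- run_cohort(p, "warfarin")
  expect_identical(nrow(tr$trace), 1L)
  expect_gt(tr$trace$on_treatment_ivte[1], 0.99)
})
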