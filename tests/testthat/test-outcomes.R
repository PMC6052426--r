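test_that("discount factor matches its closed form", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(12, 0.035), 1 / 1.035, tolerance = 1e-15)
  expect_equal(discount_factor(c(0, 24, 600), 0), rep(1, 3))
  expect_error(discount_factor(-1, 0.035))
})

test_that("state utilities compose the published weighting and decrements", {
  p <- vte_parameters()
  # index-mix-weighted VTE utility: 0.599 x 0.71 + 0.401 x 0.67
  occ1 <- c(on_treatment_ivte = 1, on_treatment_rvte = 0, off_treatment = 0,
            rvte = 0, crnmb = 0, non_ich_mb = 0, ich = 0, death = 0)
  prev0 <- c(pts = 0, cteph = 0, dis = 0)
  u_ivte <- 0.599 * 0.71 + 0.401 * 0.67
  expect_equal(cycle_utility(occ1, prev0, "edoxaban", p, age = 56), u_ivte,
               tolerance = 1e-12)
  expect_equal(round(u_ivte, 2), 0.69)

  # warfarin decrement, relative
  expect_equal(cycle_utility(occ1, prev0, "warfarin", p, age = 56),
               u_ivte * (1 - 0.0137), tolerance = 1e-12)

  # concomitant decrements compose multiplicatively
  prev_both <- c(pts = 1, cteph = 1, dis = 0)
  expect_equal(cycle_utility(occ1, prev_both, "edoxaban", p, age = 56),
               u_ivte * (1 - 0.1368) * (1 - 0.30), tolerance = 1e-12)

  # all mass in death contributes nothing
  occ_dead <- occ1
  occ_dead["on_treatment_ivte"] <- 0
  occ_dead["death"] <- 1
  expect_equal(cycle_utility(occ_dead, prev0, "edoxaban", p), 0)

  # off treatment takes the age-specific population norm
  occ_off <- occ1
  occ_off["on_treatment_ivte"] <- 0
  occ_off["off_treatment"] <- 1
  expect_equal(cycle_utility(occ_off, prev0, "edoxaban", p, age = 60), 0.80)
  expect_equal(cycle_utility(occ_off, prev0, "edoxaban", p, age = 80), 0.73)
})

test_that("heparin lead-in costs reproduce the worked example to the penny", {
  ec <- vtecea:::effective_costs(vte_parameters())
  expect_equal(round(ec$hep_w, 2), 83.33)
  expect_equal(round(ec$hep_e, 2), 64.10)
  expect_equal(ec$w_first, 273.81)
  expect_equal(ec$e_first, 108.62)
})

test_that("ledger invariants: life-years, zero-discount, category sums", {
  p <- params_short(120)
  tr <- run_cohort(p, "warfarin")
  led <- accumulate(tr)
  cy <- led$cycles

  # per-cycle life-years equal alive fraction / 12 (discounted)
  expect_equal(cy$ly, cy$alive / 12 * cy$discount, tolerance = 1e-12)
  expect_true(all(cy$ly <= cy$alive / 12 + 1e-12))

  # all cost categories non-negative; total equals the sum of categories
  cats <- c("cost_treatment", "cost_inr", "cost_rvte", "cost_crnmb",
            "cost_non_ich_mb", "cost_ich", "cost_complications")
  for (cc in cats) expect_true(all(cy[[cc]] >= 0), info = cc)
  expect_equal(cy$cost_total, Reduce(`+`, lapply(cats, function(cc) cy[[cc]])),
               tolerance = 1e-12)
  expect_equal(led$totals$cost_total,
               sum(unlist(led$totals[cats])), tolerance = 1e-9)

  # QALY split components add up to the total
  expect_equal(cy$qaly,
               cy$qaly_on_treatment + cy$qaly_off_treatment + cy$qaly_rvte +
                 cy$qaly_adverse_events + cy$qaly_complications,
               tolerance = 1e-12)

  # discounting at rate zero equals the undiscounted sums
  p0 <- p
  p0$settings$discount_rate_annual <- 0
  led0 <- accumulate(run_cohort(p0, "warfarin"))
  tr0 <- run_cohort(p0, "warfarin")
  alive0 <- 1 - tr0$occupancy[1:120, 28]
  expect_equal(led0$totals$ly, sum(alive0) / 12, tolerance = 1e-9)
})

test_that("INR monitoring is charged in the warfarin arm only", {
  p <- params_short(120)
  le <- accumulate(run_cohort(p, "edoxaban"))
  lw <- accumulate(run_cohort(p, "warfarin"))
  expect_identical(le$totals$cost_inr, 0)
  expect_gt(lw$totals$cost_inr, 250)
})

test_that("comparison yields exact NMB and dominance classification", {
  p <- params_short(120)
  le <- accumulate(run_cohort(p, "edoxaban"))
  lw <- accumulate(run_cohort(p, "warfarin"))
  res <- compare_arms(le, lw, wtp = 20000)
  expect_equal(res$nmb, res$d_qaly * 20000 - res$d_cost, tolerance = 1e-12)
  expect_equal(res$d_qaly, le$totals$qaly - lw$totals$qaly)

  # NMB is linear in lambda; at lambda = 0 it equals -dC
  r0 <- compare_arms(le, lw, wtp = 0)
  expect_equal(r0$nmb, -res$d_cost, tolerance = 1e-12)
  r40 <- compare_arms(le, lw, wtp = 40000)
  expect_equal(r40$nmb - res$nmb, res$d_qaly * 20000, tolerance = 1e-9)

  # dominance requires both more QALYs and lower costs
  if (res$d_qaly > 0 && res$d_cost < 0) {
    expect_identical(res$status, "dominant")
    expect_true(is.na(res$icer))
  }

  g <- glance(res)
  expect_identical(names(g),
                   c("d_qaly", "d_cost", "d_ly", "status", "icer", "wtp",
                     "nmb"))
  expect_identical(nrow(tidy(res)), 2L)
})

test_that("a zero-horizon run accrues only the first treatment dispense", {
  p <- vte_parameters(horizon_months = 0)
  le <- accumulate(run_cohort(p, "edoxaban"))
  expect_equal(le$totals$ly, 0)
  expect_equal(le$totals$qaly, 0)
  expect_equal(le$totals$cost_treatment, 108.62)
  expect_equal(le$totals$cost_rvte, 0)
})
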