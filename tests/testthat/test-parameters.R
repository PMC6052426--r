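test_that("packaged base-case fixture reproduces the printed inputs", {
  p <- load_parameters(base_case_path())

  # time-stratified risks (monthly probabilities and odds ratios)
  expect_equal(p$risks$rvte$p_first6, 0.018)
  expect_equal(p$risks$rvte$p_later, 0.002)
  expect_equal(p$risks$crnmb$p_first6, 0.017)
  expect_equal(p$risks$crnmb$p_later, 0.004)
  expect_equal(p$risks$mb$p_first6, 0.0016)
  expect_equal(p$risks$ich$p_first6, 0.0003)
  expect_equal(p$risks$rvte$or_first6, 0.83)
  expect_equal(p$risks$crnmb$or_first6, 0.78)
  expect_equal(p$risks$mb$or_later, 0.44)
  expect_equal(p$risks$ich$or_first6, 0.23)
  expect_equal(p$risks$ich$or_later, 0.39)

  # significance flags follow the published scenario marking
  expect_false(p$risks$rvte$sig_first6)
  expect_false(p$risks$rvte$sig_later)
  expect_true(p$risks$crnmb$sig_first6)
  expect_false(p$risks$crnmb$sig_later)
  expect_false(p$risks$mb$sig_first6)
  expect_true(p$risks$mb$sig_later)
  expect_true(p$risks$ich$sig_first6)
  expect_false(p$risks$ich$sig_later)

  # clinical parameters
  expect_equal(p$clinical$prop_index_pe, 0.401)
  expect_equal(p$clinical$prop_index_pe_with_dvt, 0.441)
  expect_equal(p$clinical$prop_recurrence_pe, 0.565)
  expect_equal(p$clinical$p_recur_off_treatment, 0.0042)
  expect_equal(p$clinical$p_cteph_after_pe, 0.048)
  expect_equal(p$clinical$p_pts_after_dvt, 0.027)
  expect_equal(p$clinical$p_disabled_after_ich, 0.65)
  expect_equal(p$clinical$cfr_pe_recurrence, 0.061)
  expect_equal(p$clinical$cfr_ich, 0.261)
  expect_equal(p$clinical$cfr_endarterectomy, 0.044)
  expect_equal(p$clinical$p_monthly_death_post_ich_disability, 0.033)
  expect_equal(p$clinical$p_monthly_death_cteph, 0.007)

  # utilities
  expect_equal(p$utilities$u_pe, 0.67)
  expect_equal(p$utilities$u_dvt, 0.71)
  expect_equal(p$utilities$du_warfarin, 0.0137)
  expect_equal(p$utilities$du_non_ich_mb, 0.3158)
  expect_equal(p$utilities$du_ich, 0.6526)
  expect_equal(p$utilities$du_cteph, 0.30)
  expect_equal(p$utilities$du_pts, 0.1368)

  # costs
  expect_equal(p$costs$c_warfarin_cycle_first, 273.81)
  expect_equal(p$costs$c_warfarin_cycle_later, 26.73)
  expect_equal(p$costs$c_edoxaban_cycle_first, 108.62)
  expect_equal(p$costs$c_edoxaban_cycle_later, 53.27)
  expect_equal(p$costs$c_heparin_daily, 12.82)
  expect_equal(p$costs$c_pe_event, 1647)
  expect_equal(p$costs$c_dvt_event, 551)
  expect_equal(p$costs$c_cteph_drugs_monthly, 1348)
})

test_that("write/load round-trip preserves every field", {
  p <- vte_parameters()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  q <- load_parameters(f)
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  for (block in c("risks", "clinical", "utilities", "costs")) {
    expect_equal(drop_null(q[[block]]), drop_null(p[[block]]), info = block)
  }
  expect_equal(q$settings, p$settings)
})

test_that("fixture emission is deterministic and loading logs defaults", {
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_base_case_fixture(f1)
  write_base_case_fixture(f2)
  expect_identical(readLines(f1), readLines(f2))

  # a file without settings gets the documented defaults, all logged
  x <- yaml::read_yaml(f1)
  x$settings <- NULL
  f3 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(x, f3)
  q <- load_parameters(f3)
  log <- attr(q, "run_log")
  expect_true(any(grepl("settings.rng_seed", log)))
  expect_equal(q$settings$horizon_months, 600)
})

test_that("validation reports out-of-range values as data, with field paths", {
  p <- vte_parameters()
  expect_identical(nrow(validate_parameters(p)), 0L)

  # 1.2 violates both the probability bound and its DSA bracket
  p$clinical$p_cteph_after_pe <- 1.2
  v <- validate_parameters(p)
  expect_true(all(v$field == "clinical.p_cteph_after_pe"))
  expect_true(any(grepl("probability", v$rule)))

  p2 <- vte_parameters()
  p2$risks$ich$or_first6 <- -0.2
  v2 <- validate_parameters(p2)
  expect_true("risks.ich.or_first6" %in% v2$field)
  expect_true(any(grepl("odds ratio", v2$rule)))

  p3 <- vte_parameters()
  p3$costs$c_heparin_daily <- 20  # above its DSA high: bracket violation
  v3 <- validate_parameters(p3)
  expect_true(any(grepl("base <= high", v3$rule)))
  expect_identical(nrow(validate_parameters(p3, check_bounds = FALSE)), 0L)

  # a malformed file fails loudly with the field named
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)  # p has p_cteph_after_pe = 1.2
  expect_error(load_parameters(f), "p_cteph_after_pe")
})

test_that("the OR=1 scenario rewrites exactly the non-significant ORs", {
  p <- vte_parameters()
  q <- apply_scenario(p, "or_nonsig_to_one")
  expect_equal(q$risks$rvte$or_first6, 1)
  expect_equal(q$risks$rvte$or_later, 1)
  expect_equal(q$risks$crnmb$or_later, 1)
  expect_equal(q$risks$mb$or_first6, 1)
  expect_equal(q$risks$ich$or_later, 1)
  # significant ORs untouched
  expect_equal(q$risks$crnmb$or_first6, 0.78)
  expect_equal(q$risks$mb$or_later, 0.44)
  expect_equal(q$risks$ich$or_first6, 0.23)
  # idempotent; input never mutated
  expect_equal(apply_scenario(q, "or_nonsig_to_one"), q)
  expect_equal(p$risks$rvte$or_first6, 0.83)

  expect_equal(apply_scenario(p, "horizon_1y")$settings$horizon_months, 12)
  expect_equal(apply_scenario(p, "horizon_5y")$settings$horizon_months, 60)
  expect_error(apply_scenario(p, "nonsense"))
})

test_that("subgroup transformations set only the index-event mix", {
  p <- vte_parameters()
  expect_equal(subgroup_parameters(p, "all"), p,
               ignore_attr = TRUE)
  d <- subgroup_parameters(p, "dvt_only")
  expect_equal(d$clinical$prop_index_pe, 0)
  expect_equal(unname(sequela_incidence("index", d)["p_cteph"]), 0)
  pe <- subgroup_parameters(p, "pe_only")
  expect_equal(pe$clinical$prop_index_pe, 1)
  expect_equal(pe$clinical$prop_index_pe_with_dvt, 0)
  both <- subgroup_parameters(p, "pe_plus_dvt")
  expect_equal(both$clinical$prop_index_pe_with_dvt, 1)
  # everything else unchanged
  expect_equal(d$risks, p$risks)
  expect_equal(d$costs, p$costs)
  expect_error(subgroup_parameters(p, "everyone"))
})

test_that("the DSA registry brackets every base value", {
  reg <- parameter_registry(vte_parameters())
  expect_gt(nrow(reg), 40)
  expect_true(all(reg$low <= reg$base + 1e-12))
  expect_true(all(reg$high >= reg$base - 1e-12))
  expect_setequal(unique(reg$family), c("beta", "lognormal", "gamma"))
})
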