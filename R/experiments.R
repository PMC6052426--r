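## Named, reproducible experiment bundles: base case, scenario analyses
## and index-event subgroup analyses.

EXPERIMENTS <- c("base", "dvt_only", "pe_any", "pe_only", "pe_plus_dvt",
                 "or_nonsig_to_one", "horizon_1y", "horizon_5y")

#' Parameter transformation for a named experiment
#'
#' @param params A `vte_params` object.
#' @param experiment One of `r paste0('\x60', EXPERIMENTS, '\x60', collapse = ", ")`.
#' @return A transformed `vte_params` object.
#' @export
experiment_parameters <- function(params, experiment) {
  if (!experiment %in% EXPERIMENTS) {
    abort(paste0("Unknown experiment '", experiment, "'. Valid ids: ",
                 paste(EXPERIMENTS, collapse = ", ")))
  }
  switch(experiment,
         base = params,
         dvt_only = subgroup_parameters(params, "dvt_only"),
         pe_any = subgroup_parameters(params, "pe_any"),
         pe_only = subgroup_parameters(params, "pe_only"),
         pe_plus_dvt = subgroup_parameters(params, "pe_plus_dvt"),
         or_nonsig_to_one = apply_scenario(params, "or_nonsig_to_one"),
         horizon_1y = apply_scenario(params, "horizon_1y"),
         horizon_5y = apply_scenario(params, "horizon_5y"))
}

#' Run a named experiment
#'
#' Applies the experiment's parameter transformation and runs the full
#' two-arm analysis. Experiments are pure: the same parameters and id give
#' identical output.
#'
#' @inheritParams experiment_parameters
#' @param wtp Willingness-to-pay per QALY.
#' @return A `vte_ce_result` with attribute `"experiment"`.
#' @export
run_experiment <- function(params = vte_parameters(), experiment = "base",
                           wtp = params$settings$wtp) {
  res <- run_ce_analysis(experiment_parameters(params, experiment), wtp)
  attr(res, "experiment") <- experiment
  res
}

#' Run every registered experiment
#'
#' @param params A `vte_params` object.
#' @param experiments Character vector of experiment ids.
#' @param wtp Willingness-to-pay per QALY.
#' @return A tibble with one row per experiment: incremental QALYs, costs,
#'   life-years, status and NMB.
#' @examples
#' \donttest{
#' run_experiments(vte_parameters(horizon_months = 120),
#'                 c("base", "dvt_only"))
#' }
#' @export
run_experiments <- function(params = vte_parameters(),
                            experiments = EXPERIMENTS,
                            wtp = params$settings$wtp) {
  purrr::map_dfr(experiments, function(ex) {
    g <- glance(run_experiment(params, ex, wtp))
    dplyr::bind_cols(tibble::tibble(experiment = ex), g)
  })
}

#' Table of per-arm results for one experiment
#'
#' Mirrors the published result-table layout: cumulative incidences,
#' health outcomes and category-split costs per arm, followed by the
#' cost-effectiveness statistics.
#'
#' @param result A `vte_ce_result` object.
#' @return A tibble with columns `quantity`, `edoxaban`, `warfarin`.
#' @export
result_table <- function(result) {
  stopifnot(inherits(result, "vte_ce_result"))
  ge <- glance(result$edoxaban)
  gw <- glance(result$warfarin)
  pick <- function(nm) c(ge[[nm]], gw[[nm]])
  rows <- list(
    c("Cumulative VTE recurrence (%)", 100 * pick("cum_rvte")),
    c("Cumulative CRNMB (%)", 100 * pick("cum_crnmb")),
    c("Cumulative non-ICH MB (%)", 100 * pick("cum_non_ich_mb")),
    c("Cumulative ICH (%)", 100 * pick("cum_ich")),
    c("Cumulative severe PTS (%)", 100 * pick("cum_pts")),
    c("Cumulative CTEPH (%)", 100 * pick("cum_cteph")),
    c("Cumulative disease-specific death (%)",
      100 * pick("cum_specific_death")),
    c("Life years (discounted)", pick("ly")),
    c("QALYs (discounted)", pick("qaly")),
    c("Treatment costs excl. INR (£)", pick("cost_treatment")),
    c("INR monitoring (£)", pick("cost_inr")),
    c("Recurrent VTE, acute & treatment (£)", pick("cost_rvte")),
    c("CRNMB (£)", pick("cost_crnmb")),
    c("Non-ICH MB (£)", pick("cost_non_ich_mb")),
    c("ICH, acute & long-term (£)", pick("cost_ich")),
    c("Complications PTS & CTEPH (£)", pick("cost_complications")),
    c("Total costs (£)", pick("cost_total"))
  )
  tibble::tibble(
    quantity = vapply(rows, `[[`, character(1), 1),
    edoxaban = as.numeric(vapply(rows, `[[`, character(1), 2)),
    warfarin = as.numeric(vapply(rows, `[[`, character(1), 3))
  )
}
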