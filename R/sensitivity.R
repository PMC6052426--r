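## One-way deterministic sensitivity analysis (tornado) and probabilistic
## sensitivity analysis with CE-plane and CEAC outputs.

#' Distribution assignment for a sensitivity parameter
#'
#' Maps a parameter's base value and uncertainty interval onto a sampling
#' distribution: `beta` for probabilities, proportions and utilities
#' (moment-matched so the mean equals the base value and the standard
#' deviation is a quarter of the interval width, i.e. the interval is read
#' as a central ~95% range), `lognormal` for odds ratios (median at the
#' base value, the interval read as a 95% CI on the log scale), and
#' `gamma` for costs and resource counts (mean at base, same
#' interval-width rule). Degenerate intervals give a point mass.
#'
#' @param id Parameter id (used in error messages).
#' @param base Base value.
#' @param low,high Uncertainty interval.
#' @param family `"beta"`, `"lognormal"` or `"gamma"`.
#' @return A list describing the distribution with a `sample(n)` function.
#' @examples
#' d <- assign_distribution("p", 0.018, 0.014, 0.022, "beta")
#' d$pars
#' @export
assign_distribution <- function(id, base, low, high, family) {
  family <- match.arg(family, c("beta", "lognormal", "gamma"))
  if (low > base || high < base) {
    abort(paste0("Bounds [", low, ", ", high, "] do not bracket base ",
                 base, " for ", id))
  }
  sd <- (high - low) / (2 * 1.96)
  if (sd == 0 || (family != "lognormal" && base == 0 && sd == 0)) {
    return(list(id = id, family = "point", pars = c(value = base),
                sample = function(n) rep(base, n)))
  }
  if (family == "beta") {
    if (base <= 0 || base >= 1) {
      ## boundary base value with nonzero spread: fall back to a point mass
      ## (a beta cannot have its mean on the boundary)
      return(list(id = id, family = "point", pars = c(value = base),
                  sample = function(n) rep(base, n)))
    }
    v <- min(sd^2, base * (1 - base) * 0.999)
    k <- base * (1 - base) / v - 1
    a <- base * k
    b <- (1 - base) * k
    list(id = id, family = "beta", pars = c(shape1 = a, shape2 = b),
         sample = function(n) rbeta(n, a, b))
  } else if (family == "lognormal") {
    if (low <= 0) abort(paste0("Log-normal bounds must be > 0 for ", id))
    mu <- log(base)
    sigma <- (log(high) - log(low)) / (2 * 1.96)
    list(id = id, family = "lognormal", pars = c(meanlog = mu, sdlog = sigma),
         sample = function(n) rlnorm(n, mu, sigma))
  } else {
    shape <- base^2 / sd^2
    rate <- base / sd^2
    list(id = id, family = "gamma", pars = c(shape = shape, rate = rate),
         sample = function(n) rgamma(n, shape, rate))
  }
}

# ---------------------------------------------------------------------------
# One-way DSA

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full two-arm model twice per parameter -- once at the low
#' and once at the high bound, all other inputs at base -- and records the
#' net monetary benefit at each bound. Rows are sorted by span (absolute
#' NMB difference) descending, ties broken by parameter id.
#'
#' @param params A `vte_params` object.
#' @param ids Parameter ids to vary (default: every registry row). Ids
#'   without a proper interval (low = high) produce a zero span.
#' @param wtp Willingness-to-pay per QALY.
#' @return A `vte_tornado` tibble: `id`, `label`, `low`, `high`,
#'   `nmb_low`, `nmb_high`, `span`, plus the base NMB as attribute
#'   `"nmb_base"`.
#' @export
one_way_dsa <- function(params, ids = NULL, wtp = params$settings$wtp) {
  reg <- parameter_registry(params)
  if (!is.null(ids)) {
    missing <- setdiff(ids, reg$id)
    if (length(missing) > 0) {
      warn(paste0("Skipping parameter(s) without DSA bounds: ",
                  paste(missing, collapse = ", ")))
    }
    reg <- reg[reg$id %in% ids, ]
  }
  base_res <- run_ce_analysis(params, wtp)

  rows <- purrr::pmap_dfr(reg[, c("id", "label", "low", "high")],
    function(id, label, low, high) {
      nmb_at <- function(v) {
        run_ce_analysis(param_set(params, id, v), wtp)$nmb
      }
      nmb_low <- if (low == param_get(params, id)) base_res$nmb
                 else nmb_at(low)
      nmb_high <- if (high == param_get(params, id)) base_res$nmb
                  else nmb_at(high)
      tibble::tibble(id = id, label = label, low = low, high = high,
                     nmb_low = nmb_low, nmb_high = nmb_high,
                     span = abs(nmb_high - nmb_low))
    })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$span), .data$id)
  attr(rows, "nmb_base") <- base_res$nmb
  class(rows) <- c("vte_tornado", class(rows))
  rows
}

# ---------------------------------------------------------------------------
# PSA

psa_distributions <- function(params) {
  reg <- parameter_registry(params)
  purrr::pmap(reg[, c("id", "base", "low", "high", "family")],
              function(id, base, low, high, family) {
                assign_distribution(id, base, low, high, family)
              })
}

sample_draw <- function(params, dists, max_retries = 100) {
  for (i in seq_len(max_retries)) {
    p <- params
    for (d in dists) {
      p <- param_set(p, d$id, d$sample(1))
    }
    v <- validate_parameters(p, check_bounds = FALSE)
    if (nrow(v) == 0) return(list(params = p, retries = i - 1L))
  }
  abort("Could not sample a valid parameter set within the retry cap")
}

#' Probabilistic sensitivity analysis
#'
#' Samples every parameter with an uncertainty interval from its assigned
#' distribution (independently, jointly per draw), re-runs both arms, and
#' records incremental outcomes per draw. Reproducible given `seed`.
#'
#' @param params A `vte_params` object.
#' @param n Number of draws.
#' @param seed RNG seed (defaults to `params$settings$rng_seed`).
#' @param wtp Willingness-to-pay per QALY.
#' @return A `vte_psa` object: `draws` tibble (`draw`, `d_qaly`, `d_cost`,
#'   `nmb`, `quadrant`) and `summary` list (fraction dominant, fraction
#'   cost-effective at `wtp`, means, NMB percentile interval).
#' @examples
#' \donttest{
#' psa <- run_psa(vte_parameters(horizon_months = 60), n = 20, seed = 1)
#' psa$summary$frac_dominant
#' }
#' @export
run_psa <- function(params, n = 2000, seed = params$settings$rng_seed,
                    wtp = params$settings$wtp) {
  stopifnot(n >= 1)
  set.seed(seed)
  dists <- psa_distributions(params)
  total_retries <- 0L

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sample_draw(params, dists)
    total_retries <- total_retries + s$retries
    res <- run_ce_analysis(s$params, wtp)
    rows[[i]] <- c(d_qaly = res$d_qaly, d_cost = res$d_cost, nmb = res$nmb)
  }
  m <- do.call(rbind, rows)
  draws <- tibble::tibble(
    draw = seq_len(n),
    d_qaly = m[, "d_qaly"], d_cost = m[, "d_cost"], nmb = m[, "nmb"],
    quadrant = dplyr::case_when(
      m[, "d_qaly"] > 0 & m[, "d_cost"] < 0 ~ "dominant",
      m[, "d_qaly"] > 0 & m[, "d_cost"] >= 0 ~ "trade-off NE",
      m[, "d_qaly"] <= 0 & m[, "d_cost"] < 0 ~ "trade-off SW",
      TRUE ~ "dominated")
  )
  if (total_retries > 0) {
    warn(sprintf("PSA resampled %d invalid draw(s)", total_retries))
  }
  summary <- list(
    n = n, seed = seed, wtp = wtp,
    frac_dominant = mean(draws$quadrant == "dominant"),
    frac_cost_effective = mean(draws$nmb > 0),
    mean_d_qaly = mean(draws$d_qaly),
    mean_d_cost = mean(draws$d_cost),
    nmb_ci = unname(quantile(draws$nmb, c(0.025, 0.975))),
    resamples = total_retries
  )
  structure(list(draws = draws, summary = summary), class = "vte_psa")
}

#' @export
print.vte_psa <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<vte_psa> %d draws (seed %s)\n", s$n, format(s$seed)))
  cat(sprintf("  dominant: %.1f%%; cost-effective at £%s/QALY: %.1f%%\n",
              100 * s$frac_dominant, format(s$wtp, big.mark = ","),
              100 * s$frac_cost_effective))
  cat(sprintf("  NMB 95%% interval: £%.0f to £%.0f\n",
              s$nmb_ci[1], s$nmb_ci[2]))
  invisible(x)
}

#' @rdname run_psa
#' @param x A `vte_psa` object.
#' @param ... Unused.
#' @export
tidy.vte_psa <- function(x, ...) x$draws

#' @rdname run_psa
#' @export
glance.vte_psa <- function(x, ...) {
  s <- x$summary
  tibble::tibble(n = s$n, frac_dominant = s$frac_dominant,
                 frac_cost_effective = s$frac_cost_effective,
                 mean_d_qaly = s$mean_d_qaly, mean_d_cost = s$mean_d_cost,
                 nmb_lo = s$nmb_ci[1], nmb_hi = s$nmb_ci[2])
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit.
#'
#' @param psa A `vte_psa` object (or its `draws` tibble).
#' @param lambdas Willingness-to-pay grid.
#' @return A tibble with columns `lambda` and `probability`.
#' @export
ceac <- function(psa, lambdas = seq(0, 50000, by = 1000)) {
  draws <- if (inherits(psa, "vte_psa")) psa$draws else psa
  stopifnot(nrow(draws) > 0, length(lambdas) > 0)
  out <- tibble::tibble(
    lambda = lambdas,
    probability = vapply(lambdas, function(l) {
      mean(draws$d_qaly * l - draws$d_cost > 0)
    }, numeric(1))
  )
  class(out) <- c("vte_ceac", class(out))
  out
}
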