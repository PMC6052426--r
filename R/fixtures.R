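## Synthetic inputs: general-population life table and the packaged
## base-case parameter fixture. Everything here is deterministic so the
## whole pipeline runs with zero downloads.

#' Default Gompertz-Makeham mortality law
#'
#' Sex-specific coefficients of the hazard \eqn{\mu(x) = \lambda + a e^{b x}}
#' chosen to approximate contemporary UK all-cause mortality (annual death
#' probabilities of roughly 0.6%/0.4% at age 56 and 9.6%/6.9% at age 85 for
#' men/women). Absolute survival from this synthetic law is approximate;
#' incremental model results are insensitive to modest background-mortality
#' error.
#'
#' @return A list with components `male` and `female`, each containing
#'   `lambda`, `a`, `b`.
#' @export
gompertz_makeham_defaults <- function() {
  list(male   = list(lambda = 5e-4, a = 2.0e-5, b = 0.100),
       female = list(lambda = 3e-4, a = 1.1e-5, b = 0.103))
}

#' Synthetic general-population life table
#'
#' Builds a deterministic life table over ages 18-110 from a
#' Gompertz-Makeham law, with annual death probability
#' \eqn{q = 1 - \exp(-(\lambda + a e^{b\,\mathrm{age}}))} clipped to
#' \[0, 1\]. Passing a literal table (a data frame with columns
#' `age`, `sex`, `qx`) returns it unchanged after checking bounds.
#'
#' @param model A mortality-law spec as returned by
#'   [gompertz_makeham_defaults()], or a literal life-table data frame.
#' @param ages Integer ages covered by the parametric table.
#' @return A tibble with columns `age`, `sex` (`"male"`/`"female"`), `qx`.
#' @examples
#' lt <- make_life_table()
#' range(lt$qx)
#' @export
make_life_table <- function(model = gompertz_makeham_defaults(),
                            ages = 18:110) {
  if (is.data.frame(model)) {
    stopifnot(all(c("age", "sex", "qx") %in% names(model)))
    if (any(model$qx < 0 | model$qx > 1)) {
      abort("Literal life table has qx outside [0, 1]")
    }
    return(tibble::as_tibble(model))
  }
  for (sx in c("male", "female")) {
    m <- model[[sx]]
    if (any(c(m$lambda, m$a, m$b) < 0)) {
      abort(paste0("Negative Gompertz-Makeham coefficient for ", sx))
    }
  }
  qx <- function(m) pmin(pmax(1 - exp(-(m$lambda + m$a * exp(m$b * ages))), 0), 1)
  dplyr::bind_rows(
    tibble::tibble(age = ages, sex = "male", qx = qx(model$male)),
    tibble::tibble(age = ages, sex = "female", qx = qx(model$female))
  )
}

#' Read a life table from CSV
#'
#' Accepts the dialect `age,sex,qx` with sex coded `M`/`F` (or
#' `male`/`female`).
#'
#' @param path CSV file path.
#' @return A life-table tibble.
#' @export
read_life_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age", "sex", "qx") %in% names(x)))
  x$sex <- c(M = "male", F = "female", male = "male", female = "female")[x$sex]
  if (any(is.na(x$sex))) abort("Life-table sex must be coded M/F")
  make_life_table(x)
}

#' Sex-mixed monthly background mortality
#'
#' Mixes the male and female annual death probabilities at the given age by
#' the cohort's sex ratio and converts to a monthly probability via
#' \eqn{p = 1 - (1 - q)^{1/12}}.
#'
#' @param table A life table (see [make_life_table()]).
#' @param age Age in years (fractional ages are truncated to the
#'   integer-age row).
#' @param prop_male Proportion of the cohort that is male.
#' @return Monthly probability of death.
#' @examples
#' lt <- make_life_table()
#' monthly_background_mortality(lt, 60, 0.57)
#' @export
monthly_background_mortality <- function(table, age, prop_male) {
  a <- floor(age)
  qm <- table$qx[table$age == a & table$sex == "male"]
  qf <- table$qx[table$age == a & table$sex == "female"]
  if (length(qm) != 1 || length(qf) != 1) {
    abort(paste0("Age ", a, " outside the life-table range"))
  }
  q <- prop_male * qm + (1 - prop_male) * qf
  1 - (1 - q)^(1 / 12)
}

## Vectorised per-cycle background mortality for the engine: age advances
## deterministically with cycle number, truncated into integer-age rows.
background_mortality_by_cycle <- function(params) {
  s <- params$settings
  ages <- floor(s$start_age + (seq_len(s$horizon_months) - 1) / 12)
  lt <- params$life_table
  qm <- setNames(lt$qx[lt$sex == "male"], lt$age[lt$sex == "male"])
  qf <- setNames(lt$qx[lt$sex == "female"], lt$age[lt$sex == "female"])
  key <- as.character(ages)
  if (any(!key %in% names(qm)) || any(!key %in% names(qf))) {
    abort("Cohort ages exceed the life-table range; extend the table")
  }
  q <- s$prop_male * qm[key] + (1 - s$prop_male) * qf[key]
  unname(1 - (1 - q)^(1 / 12))
}

#' Write the packaged base-case parameter fixture
#'
#' Emits the complete base-case parameter file; re-loading it with
#' [load_parameters()] reproduces every base value. Writing twice produces
#' byte-identical files.
#'
#' @param path Output path for the YAML parameter file.
#' @return `path`, invisibly.
#' @export
write_base_case_fixture <- function(path = "base_case.yaml") {
  write_parameters(vte_parameters(), path)
}

#' Path to the installed base-case parameter file
#'
#' @return File path of the YAML fixture shipped with the package.
#' @export
base_case_path <- function() {
  system.file("extdata", "base_case.yaml", package = "vtecea", mustWork = TRUE)
}
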