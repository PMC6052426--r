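## Command-line entry point and human-readable report generation.

fmt_gbp <- function(x) paste0("£", formatC(round(x), format = "d",
                                           big.mark = ","))

run_manifest <- function(params_path, seed, experiments) {
  c(sprintf("vtecea version: %s",
            as.character(utils::packageVersion("vtecea"))),
    sprintf("parameter file: %s", params_path %||% "<packaged base case>"),
    sprintf("parameter file sha: %s",
            if (is.null(params_path)) "-" else
              substr(paste(tools::md5sum(params_path)), 1, 12)),
    sprintf("seed: %s", format(seed)),
    sprintf("experiments: %s", paste(experiments, collapse = ", ")),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
}

#' Render a markdown summary of a results directory
#'
#' Collects the experiment, tornado and PSA exports written by the
#' command-line interface (or by [write_experiment_outputs()]) into one
#' human-readable markdown document. Missing outputs produce warnings in
#' the report rather than errors.
#'
#' @param results_dir Directory containing `experiments.csv`,
#'   `tornado.csv`, `psa_summary.csv` (any subset).
#' @param path Output markdown file (default
#'   `file.path(results_dir, "report.md")`).
#' @return The output path, invisibly.
#' @export
render_report <- function(results_dir,
                          path = file.path(results_dir, "report.md")) {
  lines <- c("# Edoxaban vs. warfarin for VTE: model report", "")
  md_table <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 6))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                      " |")))
  }

  f <- file.path(results_dir, "experiments.csv")
  if (file.exists(f)) {
    ex <- utils::read.csv(f)
    lines <- c(lines, "## Experiments (incremental, edoxaban vs. warfarin)",
               "", md_table(ex), "")
  } else {
    lines <- c(lines, "> WARNING: no experiment results found", "")
  }

  f <- file.path(results_dir, "tornado.csv")
  if (file.exists(f)) {
    to <- utils::read.csv(f)
    lines <- c(lines, "## One-way sensitivity (top 10 by NMB span)", "",
               md_table(utils::head(to, 10)), "")
  } else {
    lines <- c(lines, "> WARNING: no tornado results found", "")
  }

  f <- file.path(results_dir, "psa_summary.csv")
  if (file.exists(f)) {
    ps <- utils::read.csv(f)
    lines <- c(lines, "## Probabilistic sensitivity analysis", "",
               md_table(ps), "")
  } else {
    lines <- c(lines, "> WARNING: no PSA results found", "")
  }

  writeLines(lines, path)
  invisible(path)
}

#' Write the standard exports for one experiment
#'
#' @param result A `vte_ce_result`.
#' @param dir Output directory (created if needed).
#' @param name Experiment name used in filenames.
#' @return `dir`, invisibly.
#' @export
write_experiment_outputs <- function(result, dir, name = "base") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- result_table(result)
  write.csv(tab, file.path(dir, paste0(name, "_table.csv")),
            row.names = FALSE)
  g <- glance(result)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(as.list(g),
                         file.path(dir, paste0(name, "_ce.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Command-line interface
#'
#' Subcommands: `run` (named experiments), `dsa` (tornado), `psa`,
#' `fixture` (emit the base-case parameter file and life-table CSV),
#' `report` (markdown summary of a results directory). Used by the
#' `inst/scripts/vtecea` launcher; see that script for the flag set.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status (0 on success, 2 on usage errors).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: vtecea <command> [options]",
    "commands:",
    "  fixture --out DIR                 write base-case parameters + life table",
    "  run     [--params F] [--experiment ID|all] [--horizon N] [--wtp W]",
    "          --out DIR                 run experiments, write tables",
    "  dsa     [--params F] --out DIR    one-way sensitivity (tornado)",
    "  psa     [--params F] [--n N] [--seed S] --out DIR",
    "  report  --results DIR             render markdown report",
    sep = "\n")
  if (length(argv) < 1) {
    message(usage)
    return(2L)
  }
  cmd <- argv[1]
  opts <- list()
  rest <- argv[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--") || i + 1 > length(rest)) {
      message("bad flag: ", rest[i], "\n", usage)
      return(2L)
    }
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  out <- opts$out %||% "vtecea_results"

  load_p <- function() {
    p <- if (is.null(opts$params)) {
      load_parameters(base_case_path())
    } else {
      load_parameters(opts$params)
    }
    if (!is.null(opts$horizon)) {
      p$settings$horizon_months <- as.integer(opts$horizon)
    }
    if (!is.null(opts$wtp)) p$settings$wtp <- as.numeric(opts$wtp)
    p
  }

  status <- tryCatch({
    if (cmd == "fixture") {
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_base_case_fixture(file.path(out, "base_case.yaml"))
      lt <- make_life_table()
      lt$sex <- c(male = "M", female = "F")[lt$sex]
      write.csv(lt, file.path(out, "life_table.csv"), row.names = FALSE)
      message("wrote ", file.path(out, "base_case.yaml"))
      0L
    } else if (cmd == "run") {
      p <- load_p()
      ids <- if (is.null(opts$experiment) || opts$experiment == "all")
        EXPERIMENTS else opts$experiment
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      res <- run_experiments(p, ids)
      write.csv(res, file.path(out, "experiments.csv"), row.names = FALSE)
      for (id in ids) {
        write_experiment_outputs(run_experiment(p, id), out, id)
      }
      writeLines(run_manifest(opts$params, p$settings$rng_seed, ids),
                 file.path(out, "manifest.txt"))
      message("wrote ", file.path(out, "experiments.csv"))
      0L
    } else if (cmd == "dsa") {
      p <- load_p()
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      to <- one_way_dsa(p)
      write.csv(to, file.path(out, "tornado.csv"), row.names = FALSE)
      writeLines(run_manifest(opts$params, p$settings$rng_seed, "dsa"),
                 file.path(out, "manifest.txt"))
      0L
    } else if (cmd == "psa") {
      p <- load_p()
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      n <- as.integer(opts$n %||% 2000)
      seed <- as.integer(opts$seed %||% p$settings$rng_seed)
      psa <- run_psa(p, n = n, seed = seed)
      write.csv(psa$draws, file.path(out, "psa_draws.csv"),
                row.names = FALSE)
      write.csv(glance(psa), file.path(out, "psa_summary.csv"),
                row.names = FALSE)
      write.csv(ceac(psa), file.path(out, "ceac.csv"), row.names = FALSE)
      writeLines(run_manifest(opts$params, seed, "psa"),
                 file.path(out, "manifest.txt"))
      0L
    } else if (cmd == "report") {
      render_report(opts$results %||% out)
      0L
    } else {
      message("unknown command: ", cmd, "\n", usage)
      2L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
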