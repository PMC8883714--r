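#' Validate pipeline inputs, aggregating all violations
#'
#' Reads the configuration and schedule files and collects every
#' invariant violation found in either — schema problems, out-of-range
#' probabilities with the offending cycle and column named,
#' coverage/efficiency products of 1, and a config/schedule horizon
#' mismatch — rather than stopping at the first.
#'
#' @param config_path Path to a YAML/JSON scenario configuration.
#' @param schedule_path Path to a transition-schedule CSV.
#' @return Character vector of violations; empty when everything is valid.
#' @export
validate_inputs <- function(config_path, schedule_path) {
  problems <- character()
  config <- NULL
  sched <- NULL

  for (p in c(config_path, schedule_path)) {
    if (!file.exists(p)) {
      problems <- c(problems, paste("file not found:", p))
    }
  }
  if (length(problems) > 0L) return(problems)

  config <- tryCatch(read_cea_config(config_path), error = function(e) {
    problems <<- c(problems, conditionMessage(e))
    NULL
  })
  sched <- tryCatch(read_schedule(schedule_path), error = function(e) {
    problems <<- c(problems, conditionMessage(e))
    NULL
  })
  if (!is.null(config) && !is.null(sched) &&
      nrow(sched) != config$horizon_cycles) {
    problems <- c(problems, sprintf(
      "schedule has %d cycles but config horizon_cycles is %d",
      nrow(sched), config$horizon_cycles))
  }
  problems
}

#' Run the full cost-effectiveness pipeline
#'
#' Reads and validates the inputs, evaluates every arm, builds the
#' vs-null incremental table and the dominance frontier, and writes the
#' result bundle to `out_dir`: `cea_table.csv`, `frontier.csv`,
#' `arm_outcomes.csv`, one `trace_<arm>.csv` per arm, and a
#' `manifest.json` recording input paths, their MD5 hashes, the package
#' version and timestamp, so a run is reproducible from its manifest
#' alone. Inputs are never mutated.
#'
#' @param config_path Path to a YAML/JSON scenario configuration.
#' @param schedule_path Path to a transition-schedule CSV.
#' @param out_dir Output directory (created if missing).
#' @param mode Incremental reporting mode for [cea_table()].
#' @return Invisibly, a list with `outcomes`, `cea_table`, `frontier`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config_path, schedule_path, out_dir,
                         mode = c("vs_null", "sequential")) {
  mode <- match.arg(mode)
  problems <- validate_inputs(config_path, schedule_path)
  if (length(problems) > 0L) {
    stop("invalid inputs:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  config <- read_cea_config(config_path)
  sched <- read_schedule(schedule_path)

  outcomes <- evaluate_all_arms(config, sched)
  policy <- threshold_policy(config$per_capita_gdp, config$wtp_multipliers)
  null_arm <- tryCatch(find_null_arm(config), error = function(e) NULL)
  tab <- cea_table(outcomes, null_arm = null_arm, mode = mode,
                   policy = policy)
  frontier <- cea_frontier(outcomes)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, file.path(out_dir, "cea_table.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(frontier, file.path(out_dir, "frontier.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(outcome_summary(outcomes),
                   file.path(out_dir, "arm_outcomes.csv"),
                   row.names = FALSE, quote = FALSE)
  for (nm in names(outcomes)) {
    write_trace(outcomes[[nm]]$trace,
                file.path(out_dir, paste0("trace_", nm, ".csv")))
  }

  manifest <- list(
    config_path = normalizePath(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    schedule_path = normalizePath(schedule_path),
    schedule_md5 = unname(tools::md5sum(schedule_path)),
    mode = mode,
    package_version = as.character(utils::packageVersion("cwpcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(outcomes = outcomes, cea_table = tab, frontier = frontier,
                 manifest = manifest))
}
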