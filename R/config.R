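#' Default scenario configuration
#'
#' Scenario used throughout the package: a cohort of healthy miners
#' entering underground work at age 20 and followed for 43 annual cycles.
#' Four arms are compared under the GCEA counterfactual:
#' \describe{
#'   \item{null}{no dust interventions; annual cost is occupational
#'     health management only (2,477.76 RMB).}
#'   \item{engineering}{engineering dust controls, coverage = efficiency
#'     = 0.95; cost engineering (1,582.80) + management.}
#'   \item{individual}{individual protective equipment, coverage =
#'     efficiency = 0.70; cost equipment (2,486.25) + management.}
#'   \item{comprehensive}{both interventions; total cost 6,546.81 RMB.}
#' }
#' CWP utility is 0.666 (EQ-5D survey of Chinese pneumoconiosis cases),
#' healthy utility 1, discount rate 5\%/year, and the willingness-to-pay
#' thresholds are 1x and 3x China's 2020 per-capita GDP (72,447 RMB).
#' The base arm — whose interventions generated the schedule's observed
#' incidence — is the comprehensive arm.
#'
#' @return A list of class `cea_config`.
#' @export
default_config <- function() {
  structure(list(
    entry_age = 20,
    horizon_cycles = 43,
    discount_rate = 0.05,
    utility_health = 1,
    per_capita_gdp = 72447,
    wtp_multipliers = c(1, 3),
    base_arm = "comprehensive",
    arms = list(
      list(name = "null", annual_cost = 2477.76, utility_cwp = 0.666,
           interventions = list()),
      list(name = "engineering", annual_cost = 1582.80 + 2477.76,
           utility_cwp = 0.666,
           interventions = list(list(coverage = 0.95, efficiency = 0.95))),
      list(name = "individual", annual_cost = 2486.25 + 2477.76,
           utility_cwp = 0.666,
           interventions = list(list(coverage = 0.70, efficiency = 0.70))),
      list(name = "comprehensive", annual_cost = 6546.81,
           utility_cwp = 0.666,
           interventions = list(list(coverage = 0.95, efficiency = 0.95),
                                list(coverage = 0.70, efficiency = 0.70))))
  ), class = "cea_config")
}

config_global_fields <- c("entry_age", "horizon_cycles", "discount_rate",
                          "utility_health", "per_capita_gdp",
                          "wtp_multipliers", "base_arm", "arms")
config_arm_fields <- c("name", "annual_cost", "utility_cwp", "interventions")

#' Validate a scenario configuration
#'
#' Aggregates every violation rather than stopping at the first: required
#' fields, unknown fields (typo protection), domain constraints on rates
#' and utilities, coverage/efficiency bounds and the `c e < 1`
#' back-adjustment requirement, duplicate arm names, and that `base_arm`
#' names an existing arm.
#'
#' @param config A configuration list.
#' @return Character vector of violations; empty when valid.
#' @export
validate_config <- function(config) {
  problems <- character()
  if (!is.list(config)) return("config must be a list")
  unknown <- setdiff(names(config), config_global_fields)
  if (length(unknown) > 0L) {
    problems <- c(problems, paste("unknown config field(s):",
                                  paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(config_global_fields, names(config))
  if (length(missing) > 0L) {
    return(c(problems, paste("missing config field(s):",
                             paste(missing, collapse = ", "))))
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  if (!num1(config$discount_rate) || config$discount_rate < 0) {
    problems <- c(problems, "discount_rate must be a number >= 0")
  }
  if (!num1(config$utility_health) || config$utility_health < 0 ||
      config$utility_health > 1) {
    problems <- c(problems, "utility_health must lie in [0, 1]")
  }
  if (!num1(config$per_capita_gdp) || config$per_capita_gdp <= 0) {
    problems <- c(problems, "per_capita_gdp must be > 0")
  }
  if (!num1(config$horizon_cycles) || config$horizon_cycles < 1) {
    problems <- c(problems, "horizon_cycles must be >= 1")
  }
  if (!is.list(config$arms) || length(config$arms) == 0L) {
    return(c(problems, "arms must be a non-empty list"))
  }
  arm_names <- character()
  for (k in seq_along(config$arms)) {
    arm <- config$arms[[k]]
    lab <- if (!is.null(arm$name)) arm$name else paste("arm", k)
    unknown <- setdiff(names(arm), config_arm_fields)
    if (length(unknown) > 0L) {
      problems <- c(problems, sprintf("%s: unknown field(s): %s", lab,
                                      paste(unknown, collapse = ", ")))
    }
    miss <- setdiff(setdiff(config_arm_fields, "interventions"), names(arm))
    if (length(miss) > 0L) {
      problems <- c(problems, sprintf("%s: missing field(s): %s", lab,
                                      paste(miss, collapse = ", ")))
      next
    }
    arm_names <- c(arm_names, arm$name)
    if (!num1(arm$annual_cost) || arm$annual_cost < 0) {
      problems <- c(problems, sprintf("%s: annual_cost must be >= 0", lab))
    }
    if (!num1(arm$utility_cwp) || arm$utility_cwp < 0 || arm$utility_cwp > 1) {
      problems <- c(problems, sprintf("%s: utility_cwp must lie in [0, 1]", lab))
    }
    for (iv in arm$interventions) {
      c_ <- iv$coverage; e_ <- iv$efficiency
      if (is.null(c_) || is.null(e_) || !num1(c_) || !num1(e_) ||
          c_ < 0 || c_ > 1 || e_ < 0 || e_ > 1) {
        problems <- c(problems, sprintf(
          "%s: intervention coverage/efficiency must lie in [0, 1]", lab))
      } else if (c_ * e_ >= 1) {
        problems <- c(problems, sprintf(
          "%s: coverage * efficiency = 1 makes back-adjustment divide by zero",
          lab))
      }
    }
  }
  if (anyDuplicated(arm_names)) {
    problems <- c(problems, "duplicate arm names")
  }
  if (!config$base_arm %in% arm_names) {
    problems <- c(problems, sprintf("base_arm '%s' is not among the arms",
                                    config$base_arm))
  }
  problems
}

#' Read a scenario configuration from YAML or JSON
#'
#' The format is chosen from the file extension (`.yaml`/`.yml` or
#' `.json`). Unknown keys are rejected to catch typos in parameter names.
#'
#' @param path Path to the configuration file.
#' @return A validated list of class `cea_config`.
#' @export
read_cea_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  config <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE),
    stop("unsupported config extension: .", ext, " (use .yaml or .json)",
         call. = FALSE))
  if (!is.null(config$wtp_multipliers)) {
    config$wtp_multipliers <- as.numeric(unlist(config$wtp_multipliers))
  }
  problems <- validate_config(config)
  if (length(problems) > 0L) {
    stop("invalid config '", path, "':\n",
         paste("-", problems, collapse = "\n"), call. = FALSE)
  }
  structure(config, class = "cea_config")
}

#' Write a scenario configuration to YAML
#'
#' @param config A configuration list.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_cea_config <- function(config, path) {
  problems <- validate_config(config)
  if (length(problems) > 0L) {
    stop("refusing to write invalid config:\n",
         paste("-", problems, collapse = "\n"), call. = FALSE)
  }
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
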