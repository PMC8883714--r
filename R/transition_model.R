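#' Create a coverage/efficiency pair for one intervention
#'
#' An intervention is summarised by its coverage \eqn{c} (fraction of the
#' exposed setting the intervention reaches) and efficiency \eqn{e}
#' (fractional reduction of dust exposure where applied). Together they
#' scale the health-to-CWP transition probability by \eqn{1 - c e}.
#'
#' @param coverage Proportion in `[0, 1]`.
#' @param efficiency Proportion in `[0, 1]`.
#' @return A list of class `coverage_efficiency`.
#' @examples
#' coverage_efficiency(0.95, 0.95) # engineering dust controls
#' @export
coverage_efficiency <- function(coverage, efficiency) {
  if (!is.numeric(coverage) || length(coverage) != 1L || is.na(coverage) ||
      coverage < 0 || coverage > 1) {
    stop("`coverage` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(efficiency) || length(efficiency) != 1L || is.na(efficiency) ||
      efficiency < 0 || efficiency > 1) {
    stop("`efficiency` must be a single number in [0, 1]", call. = FALSE)
  }
  if (coverage * efficiency >= 1) {
    stop("coverage * efficiency must be < 1 (back-adjustment would divide by zero)",
         call. = FALSE)
  }
  structure(list(coverage = coverage, efficiency = efficiency),
            class = "coverage_efficiency")
}

# Coerce a list of interventions (coverage_efficiency objects or plain
# lists with $coverage/$efficiency) into a validated list.
as_interventions <- function(interventions) {
  if (is.null(interventions)) return(list())
  if (inherits(interventions, "coverage_efficiency")) {
    interventions <- list(interventions)
  }
  if (!is.list(interventions)) {
    stop("`interventions` must be a list of coverage/efficiency pairs",
         call. = FALSE)
  }
  lapply(interventions, function(iv) {
    if (inherits(iv, "coverage_efficiency")) return(iv)
    if (is.list(iv) && !is.null(iv$coverage) && !is.null(iv$efficiency)) {
      return(coverage_efficiency(iv$coverage, iv$efficiency))
    }
    stop("each intervention needs `coverage` and `efficiency`", call. = FALSE)
  })
}

# Product of (1 - c_i e_i) over interventions; 1 for the empty list.
retention_factor <- function(interventions) {
  ivs <- as_interventions(interventions)
  if (length(ivs) == 0L) return(1)
  prod(vapply(ivs, function(iv) 1 - iv$coverage * iv$efficiency, numeric(1)))
}

#' Actuarial life-table incidence estimator
#'
#' Estimates the transition probability over an interval as
#' \deqn{\hat P = I / (N_0' - W / 2)}
#' where \eqn{I} is the number of new cases, \eqn{W} the number of
#' withdrawals (assumed at risk for half the interval on average) and
#' \eqn{N_0'} the number of disease-free individuals at the start.
#'
#' @param new_cases Number of incident cases during the interval (\eqn{I}).
#' @param withdrawals Number of withdrawals during the interval (\eqn{W}).
#' @param at_risk_start Disease-free individuals at interval start
#'   (\eqn{N_0'}).
#' @return The estimated probability, guaranteed in `[0, 1]`. Vectorised
#'   over its arguments.
#' @examples
#' estimate_incidence(2873, 0, 87904)
#' estimate_incidence(10, 20, 110) # 10 / (110 - 10) = 0.1
#' @export
estimate_incidence <- function(new_cases, withdrawals, at_risk_start) {
  if (any(new_cases < 0) || any(withdrawals < 0)) {
    stop("`new_cases` and `withdrawals` must be non-negative", call. = FALSE)
  }
  if (any(at_risk_start <= 0)) {
    stop("`at_risk_start` must be positive", call. = FALSE)
  }
  denom <- at_risk_start - withdrawals / 2
  if (any(denom <= 0)) {
    stop("invalid record: N0' - W/2 must be positive", call. = FALSE)
  }
  p <- new_cases / denom
  if (any(p > 1)) {
    stop("invalid record: estimated probability exceeds 1 (I + W/2 > N0')",
         call. = FALSE)
  }
  p
}

#' Convert an interval probability to a shorter sub-interval
#'
#' Converts a probability over \eqn{j} equal sub-intervals into a
#' per-sub-interval probability assuming a constant hazard:
#' \deqn{\hat P_j = 1 - (1 - \hat P)^{1/j}}
#' Used to turn 5-year mortality bands into annual cycle probabilities.
#'
#' @param p_interval Probability over the whole interval, in `[0, 1]`.
#' @param n_subintervals Number of equal sub-intervals \eqn{j \ge 1}.
#' @return Per-sub-interval probability. Vectorised over `p_interval`.
#' @examples
#' convert_interval(0.4, 5)
#' @export
convert_interval <- function(p_interval, n_subintervals) {
  if (any(p_interval < 0) || any(p_interval > 1)) {
    stop("`p_interval` must lie in [0, 1]", call. = FALSE)
  }
  if (length(n_subintervals) != 1L || n_subintervals < 1 ||
      n_subintervals != round(n_subintervals)) {
    stop("`n_subintervals` must be a single integer >= 1", call. = FALSE)
  }
  1 - (1 - p_interval)^(1 / n_subintervals)
}

#' Back-adjust incidence to the null (no-intervention) scenario
#'
#' The GCEA counterfactual removes the currently deployed preventive
#' interventions: the observed incidence under the current mix,
#' \eqn{\lambda_C}, is divided by the joint retention factor
#' \eqn{\prod_i (1 - c_i e_i)} to reconstruct the incidence
#' \eqn{\lambda_N} that would prevail with no interventions in place.
#'
#' @param lambda_current Observed per-cycle health-to-CWP probability under
#'   the current intervention mix, in `[0, 1]`. Vectorised.
#' @param interventions List of [coverage_efficiency()] pairs currently in
#'   force (may be empty, in which case the input is returned unchanged).
#' @param overflow Policy when the adjusted probability exceeds 1:
#'   `"error"` (default; large inputs signal bad data) or `"clamp"` to cap
#'   at 1 for exploratory use.
#' @return The null-scenario probability \eqn{\lambda_N}.
#' @seealso [apply_interventions()] for the forward direction.
#' @examples
#' iv <- list(coverage_efficiency(0.95, 0.95), coverage_efficiency(0.7, 0.7))
#' back_adjust_to_null(0.001, iv) # 0.001 / 0.049725
#' @export
back_adjust_to_null <- function(lambda_current, interventions,
                                overflow = c("error", "clamp")) {
  overflow <- match.arg(overflow)
  if (any(lambda_current < 0) || any(lambda_current > 1)) {
    stop("`lambda_current` must lie in [0, 1]", call. = FALSE)
  }
  out <- lambda_current / retention_factor(interventions)
  if (any(out > 1)) {
    if (overflow == "error") {
      stop("back-adjusted probability exceeds 1; use overflow = \"clamp\" ",
           "only if this is intentional", call. = FALSE)
    }
    out <- pmin(out, 1)
  }
  out
}

#' Apply interventions to a null-scenario incidence
#'
#' Forward direction of the back-adjustment: the incidence under a given
#' intervention mix is \eqn{\lambda = \lambda_N \prod_i (1 - c_i e_i)}.
#' Round-tripping through [back_adjust_to_null()] is the identity.
#'
#' @param lambda_null Null-scenario per-cycle probability in `[0, 1]`.
#'   Vectorised.
#' @param interventions List of [coverage_efficiency()] pairs deployed in
#'   the target arm (may be empty).
#' @return The arm's per-cycle health-to-CWP probability.
#' @export
apply_interventions <- function(lambda_null, interventions) {
  if (any(lambda_null < 0) || any(lambda_null > 1)) {
    stop("`lambda_null` must lie in [0, 1]", call. = FALSE)
  }
  lambda_null * retention_factor(interventions)
}

#' Construct a transition-probability schedule
#'
#' A schedule holds, for each model cycle, the age at cycle start and the
#' three per-cycle transition probabilities: health to CWP
#' (\eqn{\lambda}), health to death, and CWP to death. The probability of
#' staying healthy is the complement \eqn{1 - \lambda - q_h} and must be
#' non-negative; CWP is irreversible so there is no CWP-to-health entry,
#' and death is absorbing.
#'
#' @param cycle Integer cycle indices, contiguous from 0.
#' @param age Age in years at cycle start.
#' @param p_health_to_cwp Per-cycle probability of developing CWP.
#' @param p_health_to_death Per-cycle background mortality of healthy
#'   miners.
#' @param p_cwp_to_death Per-cycle mortality of CWP cases.
#' @return A `data.frame` of class `transition_schedule`.
#' @export
transition_schedule <- function(cycle, age, p_health_to_cwp,
                                p_health_to_death, p_cwp_to_death) {
  sched <- data.frame(cycle = as.integer(cycle), age = age,
                      p_health_to_cwp = p_health_to_cwp,
                      p_health_to_death = p_health_to_death,
                      p_cwp_to_death = p_cwp_to_death)
  class(sched) <- c("transition_schedule", "data.frame")
  problems <- validate_schedule(sched)
  if (length(problems) > 0L) {
    stop("invalid transition schedule:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  sched
}

#' Validate a transition schedule
#'
#' Collects (rather than stops at) every invariant violation: probabilities
#' in `[0, 1]`, non-negative stay-healthy complement, and contiguous cycle
#' indices starting at 0.
#'
#' @param sched A data frame with the [transition_schedule()] columns.
#' @return Character vector of violations; empty when the schedule is valid.
#' @export
validate_schedule <- function(sched) {
  problems <- character()
  needed <- c("cycle", "age", "p_health_to_cwp", "p_health_to_death",
              "p_cwp_to_death")
  missing_cols <- setdiff(needed, names(sched))
  if (length(missing_cols) > 0L) {
    return(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(sched) == 0L) return("schedule has no rows")
  if (!identical(as.integer(sched$cycle), seq_len(nrow(sched)) - 1L)) {
    problems <- c(problems, "cycle indices must be contiguous from 0")
  }
  for (col in c("p_health_to_cwp", "p_health_to_death", "p_cwp_to_death")) {
    bad <- which(is.na(sched[[col]]) | sched[[col]] < 0 | sched[[col]] > 1)
    if (length(bad) > 0L) {
      problems <- c(problems, sprintf(
        "%s outside [0, 1] at cycle(s) %s", col,
        paste(sched$cycle[bad], collapse = ", ")))
    }
  }
  stay <- 1 - sched$p_health_to_cwp - sched$p_health_to_death
  bad <- which(!is.na(stay) & stay < 0)
  if (length(bad) > 0L) {
    problems <- c(problems, sprintf(
      "p_health_to_cwp + p_health_to_death exceeds 1 at cycle(s) %s",
      paste(sched$cycle[bad], collapse = ", ")))
  }
  problems
}

#' Derive one arm's schedule from another's via the null scenario
#'
#' The incidence column of `base` reflects the base arm's interventions.
#' It is first back-adjusted to the null scenario and then forward-adjusted
#' to the target arm's intervention mix. Removing or adding purely
#' preventive interventions only changes the health-to-CWP probability, so
#' both mortality columns are carried over unchanged.
#'
#' @param base A [transition_schedule()] whose `p_health_to_cwp` column was
#'   observed under `base_arm_interventions`.
#' @param base_arm_interventions Interventions in force when the base
#'   schedule's incidence was observed (comprehensive measures, typically).
#' @param target_arm_interventions Interventions of the arm to construct
#'   (empty list for the null scenario).
#' @param overflow Passed to [back_adjust_to_null()].
#' @return A `transition_schedule` for the target arm.
#' @export
build_arm_schedule <- function(base, base_arm_interventions,
                               target_arm_interventions,
                               overflow = c("error", "clamp")) {
  overflow <- match.arg(overflow)
  problems <- validate_schedule(base)
  if (length(problems) > 0L) {
    stop("invalid base schedule:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  lambda_null <- back_adjust_to_null(base$p_health_to_cwp,
                                     base_arm_interventions, overflow)
  lambda_target <- apply_interventions(lambda_null, target_arm_interventions)
  out <- base
  out$p_health_to_cwp <- lambda_target
  problems <- validate_schedule(out)
  if (length(problems) > 0L) {
    stop("arm schedule violates invariants:\n",
         paste("-", problems, collapse = "\n"), call. = FALSE)
  }
  out
}

#' One-cycle transition matrix for a schedule entry
#'
#' Builds the 3x3 row-stochastic matrix over states
#' `(health, cwp, death)`. Health transitions to CWP with probability
#' \eqn{\lambda} and to death with \eqn{q_h}; staying healthy takes the
#' complement. CWP is irreversible (no return to health) and transitions
#' to death with \eqn{q_c}. Death is absorbing.
#'
#' @param entry A single schedule row (list or one-row data frame with
#'   `p_health_to_cwp`, `p_health_to_death`, `p_cwp_to_death`).
#' @return A 3x3 numeric matrix with dimnames
#'   `c("health", "cwp", "death")`; rows sum to 1.
#' @export
to_matrix <- function(entry) {
  lambda <- entry$p_health_to_cwp
  q_h <- entry$p_health_to_death
  q_c <- entry$p_cwp_to_death
  probs <- c(lambda, q_h, q_c)
  if (length(lambda) != 1L || length(q_h) != 1L || length(q_c) != 1L) {
    stop("`entry` must be a single schedule row", call. = FALSE)
  }
  if (any(probs < 0) || any(probs > 1)) {
    stop("schedule entry probabilities must lie in [0, 1]", call. = FALSE)
  }
  stay_healthy <- 1 - lambda - q_h
  if (stay_healthy < 0) {
    stop("p_health_to_cwp + p_health_to_death exceeds 1", call. = FALSE)
  }
  states <- c("health", "cwp", "death")
  matrix(c(stay_healthy, lambda, q_h,
           0, 1 - q_c, q_c,
           0, 0, 1),
         nrow = 3, byrow = TRUE, dimnames = list(states, states))
}

#' Read a transition schedule from CSV
#'
#' Expects the exact header
#' `cycle,age,p_health_to_cwp,p_health_to_death,p_cwp_to_death`, one row
#' per cycle, UTF-8, `.` decimal separator.
#'
#' @param path Path to the CSV file.
#' @return A validated `transition_schedule`.
#' @export
read_schedule <- function(path) {
  header <- readLines(path, n = 1L)
  expected <- "cycle,age,p_health_to_cwp,p_health_to_death,p_cwp_to_death"
  if (!identical(trimws(header), expected)) {
    stop("schedule CSV header must be exactly `", expected, "`; found `",
         header, "`", call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "numeric")
  transition_schedule(raw$cycle, raw$age, raw$p_health_to_cwp,
                      raw$p_health_to_death, raw$p_cwp_to_death)
}

#' Write a transition schedule to CSV
#'
#' @param sched A `transition_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(sched, path) {
  problems <- validate_schedule(sched)
  if (length(problems) > 0L) {
    stop("refusing to write invalid schedule:\n",
         paste("-", problems, collapse = "\n"), call. = FALSE)
  }
  utils::write.csv(as.data.frame(sched), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
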