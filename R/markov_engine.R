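#' Propagate a cohort through the time-dependent Markov model
#'
#' Starting from everyone healthy at entry, the cohort distribution over
#' `(health, cwp, death)` is advanced one cycle at a time with the
#' cycle-specific transition matrix, so the trace has one more row than
#' the schedule has cycles. Mass is conserved exactly and death occupancy
#' is non-decreasing because death is absorbing.
#'
#' @param schedule A [transition_schedule()] covering the full horizon.
#' @param initial Initial occupancy over `(health, cwp, death)`; defaults
#'   to `c(1, 0, 0)`.
#' @return A `(horizon + 1) x 3` matrix of class `cohort_trace` with
#'   columns `health`, `cwp`, `death`; row `t + 1` is the distribution at
#'   the start of cycle `t`. The schedule's ages (extended by one final
#'   year) are kept in the `age` attribute.
#' @export
run_cohort <- function(schedule, initial = c(1, 0, 0)) {
  problems <- validate_schedule(schedule)
  if (length(problems) > 0L) {
    stop("invalid schedule:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  if (length(initial) != 3L || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-12) {
    stop("`initial` must be a non-negative 3-vector summing to 1",
         call. = FALSE)
  }
  horizon <- nrow(schedule)
  trace <- matrix(0, nrow = horizon + 1L, ncol = 3L,
                  dimnames = list(NULL, c("health", "cwp", "death")))
  trace[1L, ] <- initial
  for (t in seq_len(horizon)) {
    trace[t + 1L, ] <- trace[t, ] %*% to_matrix(schedule[t, ])
  }
  structure(trace, class = "cohort_trace",
            age = c(schedule$age, schedule$age[horizon] + 1))
}

# Per-cycle discount weights (1 + r)^-t for t = 0 .. n - 1.
discount_weights <- function(n, discount_rate) {
  if (discount_rate < 0) stop("`discount_rate` must be >= 0", call. = FALSE)
  (1 + discount_rate)^-(seq_len(n) - 1L)
}

#' Accrue discounted quality-adjusted life years from a trace
#'
#' Each cycle contributes
#' \eqn{v_t = (u_h \cdot \mathrm{health}_t + u_c \cdot \mathrm{cwp}_t) / (1 + r)^t}.
#' With the default half-cycle correction the contributions are summed
#' trapezoidally, \eqn{v_0 / 2 + v_1 + \dots + v_{T-1} + v_T / 2},
#' reflecting that transitions occur on average mid-cycle; without it the
#' first `T` cycle-start values are summed.
#'
#' @param trace A [run_cohort()] trace.
#' @param utility_health Utility of the healthy state (1 = perfect health).
#' @param utility_cwp Utility of the CWP state.
#' @param discount_rate Annual discount rate (e.g. `0.05`).
#' @param half_cycle Apply the trapezoidal half-cycle correction
#'   (default `TRUE`).
#' @return Discounted QALYs per cohort member.
#' @export
accrue_qalys <- function(trace, utility_health = 1, utility_cwp,
                         discount_rate, half_cycle = TRUE) {
  if (utility_health < 0 || utility_health > 1 ||
      utility_cwp < 0 || utility_cwp > 1) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(trace)
  v <- (utility_health * trace[, "health"] + utility_cwp * trace[, "cwp"]) *
    discount_weights(n, discount_rate)
  if (half_cycle) {
    sum(v) - v[1L] / 2 - v[n] / 2
  } else {
    sum(v[-n])
  }
}

#' Accrue discounted prevention costs from a trace
#'
#' The annual per-capita prevention cost accrues, by default, to every
#' cohort member alive at the start of a cycle (health + CWP occupancy)
#' and is discounted by \eqn{(1 + r)^{-t}} with the first year
#' undiscounted. Costs are summed at cycle starts over cycles
#' `0 .. T - 1`; a half-cycle-corrected variant is available for parity
#' with decision-tree software conventions.
#'
#' @param trace A [run_cohort()] trace.
#' @param annual_cost Annual per-capita cost (RMB/person/year), `>= 0`.
#' @param discount_rate Annual discount rate.
#' @param states Which occupancy bears the cost: `"alive"` (default,
#'   health + CWP) or `"health"` (working miners only).
#' @param half_cycle Apply a trapezoidal half-cycle correction to costs
#'   (default `FALSE`).
#' @return Discounted cost per cohort member (RMB).
#' @export
accrue_costs <- function(trace, annual_cost, discount_rate,
                         states = c("alive", "health"), half_cycle = FALSE) {
  states <- match.arg(states)
  if (annual_cost < 0) stop("`annual_cost` must be >= 0", call. = FALSE)
  occ <- if (states == "alive") {
    trace[, "health"] + trace[, "cwp"]
  } else {
    trace[, "health"]
  }
  n <- nrow(trace)
  v <- annual_cost * occ * discount_weights(n, discount_rate)
  if (half_cycle) {
    sum(v) - v[1L] / 2 - v[n] / 2
  } else {
    sum(v[-n])
  }
}

#' Evaluate one intervention arm end to end
#'
#' Derives the arm's schedule from the base schedule via the null
#' scenario, propagates the cohort, and accrues discounted costs and
#' half-cycle-corrected discounted QALYs.
#'
#' @param arm A list with `name`, `annual_cost`, `utility_cwp`, and
#'   `interventions` (a list of coverage/efficiency pairs).
#' @param base_schedule The schedule whose incidence reflects
#'   `base_arm_interventions`.
#' @param base_arm_interventions Interventions behind the base schedule.
#' @param utility_health Utility of the healthy state.
#' @param discount_rate Annual discount rate.
#' @param cost_states,cost_half_cycle,qaly_half_cycle Accrual conventions;
#'   see [accrue_costs()] and [accrue_qalys()].
#' @param overflow Passed to [build_arm_schedule()].
#' @return A list of class `arm_outcome` with `arm_name`,
#'   `discounted_cost`, `discounted_qaly`, `trace`, and `schedule`.
#' @export
evaluate_arm <- function(arm, base_schedule, base_arm_interventions,
                         utility_health = 1, discount_rate = 0.05,
                         cost_states = "alive", cost_half_cycle = FALSE,
                         qaly_half_cycle = TRUE,
                         overflow = c("error", "clamp")) {
  if (is.null(arm$name) || is.null(arm$annual_cost) ||
      is.null(arm$utility_cwp)) {
    stop("`arm` needs `name`, `annual_cost` and `utility_cwp`",
         call. = FALSE)
  }
  sched <- build_arm_schedule(base_schedule, base_arm_interventions,
                              arm$interventions, overflow = overflow)
  trace <- run_cohort(sched)
  structure(
    list(arm_name = arm$name,
         discounted_cost = accrue_costs(trace, arm$annual_cost,
                                        discount_rate, states = cost_states,
                                        half_cycle = cost_half_cycle),
         discounted_qaly = accrue_qalys(trace, utility_health,
                                        arm$utility_cwp, discount_rate,
                                        half_cycle = qaly_half_cycle),
         trace = trace,
         schedule = sched),
    class = "arm_outcome")
}

#' Evaluate every arm of a scenario configuration
#'
#' @param config A scenario configuration (see [default_config()]); its
#'   `base_arm` entry names the arm whose interventions produced the
#'   schedule's incidence column.
#' @param schedule The base [transition_schedule()].
#' @param ... Passed on to [evaluate_arm()].
#' @return Named list of `arm_outcome` objects, in config order.
#' @export
evaluate_all_arms <- function(config, schedule, ...) {
  problems <- validate_config(config)
  if (length(problems) > 0L) {
    stop("invalid config:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  arm_names <- vapply(config$arms, `[[`, character(1), "name")
  base_ivs <- config$arms[[match(config$base_arm, arm_names)]]$interventions
  outcomes <- lapply(config$arms, evaluate_arm, base_schedule = schedule,
                     base_arm_interventions = base_ivs,
                     utility_health = config$utility_health,
                     discount_rate = config$discount_rate, ...)
  names(outcomes) <- arm_names
  outcomes
}

#' Summarise arm outcomes as a data frame
#'
#' @param outcomes A list of `arm_outcome` objects.
#' @return A data frame with columns `arm`, `cost_rmb`, `qaly`.
#' @export
outcome_summary <- function(outcomes) {
  data.frame(
    arm = vapply(outcomes, `[[`, character(1), "arm_name"),
    cost_rmb = vapply(outcomes, `[[`, numeric(1), "discounted_cost"),
    qaly = vapply(outcomes, `[[`, numeric(1), "discounted_qaly"),
    row.names = NULL)
}

#' Write a cohort trace to CSV
#'
#' Columns: `cycle,age,occ_health,occ_cwp,occ_death`.
#'
#' @param trace A `cohort_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(cycle = seq_len(nrow(trace)) - 1L,
                   age = attr(trace, "age"),
                   occ_health = trace[, "health"],
                   occ_cwp = trace[, "cwp"],
                   occ_death = trace[, "death"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
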