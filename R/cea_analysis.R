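#' Incremental cost-effectiveness ratio
#'
#' \eqn{(C_a - C_b) / (Q_a - Q_b)}, the incremental cost per QALY gained
#' when moving from strategy `b` to strategy `a`. The sign is preserved:
#' a negative ICER arises when one strategy both costs more and yields
#' fewer QALYs (dominance), and must not be ranked numerically.
#'
#' @param cost_a,qaly_a Discounted cost and QALYs of the strategy of
#'   interest.
#' @param cost_b,qaly_b Discounted cost and QALYs of the comparator.
#' @return The ICER in cost units per QALY. When the QALY difference is
#'   zero the ICER is undefined: `NaN` if the cost difference is also
#'   zero, otherwise signed `Inf`.
#' @examples
#' icer(71448.94, 17.50, 36262.67, 16.36) # engineering controls vs null
#' @export
icer <- function(cost_a, qaly_a, cost_b, qaly_b) {
  dc <- cost_a - cost_b
  dq <- qaly_a - qaly_b
  ifelse(dq == 0, ifelse(dc == 0, NaN, sign(dc) * Inf), dc / dq)
}

#' GDP-multiple threshold policy
#'
#' @param per_capita_gdp Per-capita GDP in cost units (default China 2020,
#'   72,447 RMB).
#' @param multipliers Lower and upper WTP multiples of GDP (default 1 and 3).
#' @return A list of class `threshold_policy`.
#' @export
threshold_policy <- function(per_capita_gdp = 72447, multipliers = c(1, 3)) {
  if (per_capita_gdp <= 0) stop("`per_capita_gdp` must be > 0", call. = FALSE)
  if (length(multipliers) != 2L || multipliers[1] >= multipliers[2]) {
    stop("`multipliers` must be two increasing values", call. = FALSE)
  }
  structure(list(per_capita_gdp = per_capita_gdp, multipliers = multipliers),
            class = "threshold_policy")
}

#' Classify an ICER against GDP-multiple thresholds
#'
#' An intervention is `highly_cost_effective` when its ICER is below one
#' times per-capita GDP, `cost_effective` between one and three times
#' (boundaries inclusive: the decision rule is "less than" below and
#' "exceeds" above), and `not_cost_effective` above three times. A
#' negative ICER paired with a QALY gain means the intervention saves
#' money and health and is classified `dominant`; a negative ICER with a
#' QALY loss is `dominated`.
#'
#' @param icer_value The ICER to classify. Vectorised.
#' @param policy A [threshold_policy()].
#' @param delta_qaly Optional QALY difference underlying the ICER, used to
#'   resolve negative ICERs into `dominant` vs `dominated`.
#' @return Character vector of categories.
#' @export
classify_icer <- function(icer_value, policy = threshold_policy(),
                          delta_qaly = NULL) {
  stopifnot(inherits(policy, "threshold_policy"))
  lo <- policy$per_capita_gdp * policy$multipliers[1]
  hi <- policy$per_capita_gdp * policy$multipliers[2]
  out <- ifelse(is.nan(icer_value), NA_character_,
         ifelse(icer_value < lo, "highly_cost_effective",
         ifelse(icer_value <= hi, "cost_effective", "not_cost_effective")))
  neg <- !is.nan(icer_value) & icer_value < 0
  if (any(neg)) {
    if (is.null(delta_qaly)) {
      out[neg] <- "dominant_or_dominated"
    } else {
      out[neg] <- ifelse(delta_qaly[neg] > 0, "dominant", "dominated")
    }
  }
  out
}

#' Net monetary benefit
#'
#' \eqn{\mathrm{NMB} = Q \cdot \mathrm{WTP} - C}: linearises the ICER
#' decision rule so strategies can be compared at a given
#' willingness-to-pay per QALY.
#'
#' @param cost Discounted cost.
#' @param qaly Discounted QALYs.
#' @param wtp Willingness-to-pay threshold per QALY, `>= 0`.
#' @return Net monetary benefit in cost units. Vectorised.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be >= 0", call. = FALSE)
  qaly * wtp - cost
}

#' Dominance analysis and cost-effectiveness frontier
#'
#' Sorts strategies by ascending cost (ties: higher QALY first, then
#' stable input order), flags strict dominance (another strategy with at
#' most the cost and at least the QALYs, one comparison strict) and
#' extended dominance (removed iteratively wherever sequential ICERs
#' along the cost-sorted survivors fail to increase). The survivors form
#' the frontier, along which incremental ICERs strictly increase.
#'
#' @param outcomes A data frame with columns `arm`, `cost_rmb` (or
#'   `cost`), `qaly`, or a list of `arm_outcome` objects.
#' @return A data frame sorted by cost with columns `arm`, `cost_rmb`,
#'   `qaly`, `dominance` (`none`, `dominated`, `extendedly_dominated`),
#'   `on_frontier`, and `frontier_icer` (sequential ICER along the
#'   frontier, `NA` off it and for the cheapest frontier strategy).
#' @export
cea_frontier <- function(outcomes) {
  df <- as_outcome_df(outcomes)
  if (nrow(df) < 2L) stop("need at least 2 arms", call. = FALSE)
  if (anyDuplicated(df$arm)) stop("duplicate arm names", call. = FALSE)

  ord <- order(df$cost_rmb, -df$qaly)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  dominance <- rep("none", n)

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost_rmb[j] <= df$cost_rmb[i] && df$qaly[j] >= df$qaly[i] &&
          (df$cost_rmb[j] < df$cost_rmb[i] || df$qaly[j] > df$qaly[i])) {
        dominance[i] <- "dominated"
        break
      }
    }
  }

  # extended dominance: along the cost-sorted non-dominated set, a strategy
  # whose incremental ICER exceeds that of the next step is bypassed by a
  # blend of its neighbours
  repeat {
    keep <- which(dominance == "none")
    if (length(keep) < 3L) break
    seq_icer <- icer(df$cost_rmb[keep[-1]], df$qaly[keep[-1]],
                     df$cost_rmb[keep[-length(keep)]],
                     df$qaly[keep[-length(keep)]])
    drop_idx <- which(diff(seq_icer) < 0)
    if (length(drop_idx) == 0L) break
    dominance[keep[drop_idx[1L] + 1L]] <- "extendedly_dominated"
  }

  df$dominance <- dominance
  df$on_frontier <- dominance == "none"
  df$frontier_icer <- NA_real_
  fr <- which(df$on_frontier)
  if (length(fr) > 1L) {
    df$frontier_icer[fr[-1L]] <- icer(
      df$cost_rmb[fr[-1L]], df$qaly[fr[-1L]],
      df$cost_rmb[fr[-length(fr)]], df$qaly[fr[-length(fr)]])
  }
  rownames(df) <- NULL
  df
}

as_outcome_df <- function(outcomes) {
  if (is.data.frame(outcomes)) {
    df <- outcomes
    if ("cost" %in% names(df) && !"cost_rmb" %in% names(df)) {
      df$cost_rmb <- df$cost
    }
    needed <- c("arm", "cost_rmb", "qaly")
    if (!all(needed %in% names(df))) {
      stop("outcomes need columns arm, cost_rmb (or cost), qaly",
           call. = FALSE)
    }
    df[, needed]
  } else {
    outcome_summary(outcomes)
  }
}

#' Incremental cost-effectiveness table
#'
#' Builds the base-case analysis table: per-arm discounted cost and QALYs,
#' incremental cost/QALYs, ICER, threshold classification, and dominance
#' flag. Increments are taken against the null (no-intervention) arm by
#' default, matching the common reporting layout; `mode = "sequential"`
#' compares each strategy with the next-cheaper non-dominated one instead.
#'
#' @param outcomes Data frame or list of `arm_outcome`s (see
#'   [cea_frontier()]).
#' @param null_arm Name of the comparator arm for `mode = "vs_null"`;
#'   defaults to the cheapest arm.
#' @param mode `"vs_null"` (default) or `"sequential"`.
#' @param policy A [threshold_policy()] for classification.
#' @return A data frame with columns `arm`, `cost_rmb`, `qaly`,
#'   `delta_cost`, `delta_qaly`, `icer`, `classification`, `dominance`,
#'   sorted by ascending cost. The comparator row carries `NA` increments.
#' @export
cea_table <- function(outcomes, null_arm = NULL,
                      mode = c("vs_null", "sequential"),
                      policy = threshold_policy()) {
  mode <- match.arg(mode)
  fr <- cea_frontier(outcomes)
  if (is.null(null_arm)) null_arm <- fr$arm[1L]
  if (!null_arm %in% fr$arm) {
    stop("`null_arm` '", null_arm, "' is not among the arms", call. = FALSE)
  }

  n <- nrow(fr)
  delta_cost <- delta_qaly <- icer_v <- rep(NA_real_, n)
  if (mode == "vs_null") {
    ref <- match(null_arm, fr$arm)
    for (i in seq_len(n)) {
      if (i == ref) next
      delta_cost[i] <- fr$cost_rmb[i] - fr$cost_rmb[ref]
      delta_qaly[i] <- fr$qaly[i] - fr$qaly[ref]
      icer_v[i] <- icer(fr$cost_rmb[i], fr$qaly[i],
                        fr$cost_rmb[ref], fr$qaly[ref])
    }
  } else {
    prev <- NULL
    for (i in seq_len(n)) {
      if (!fr$on_frontier[i]) next
      if (!is.null(prev)) {
        delta_cost[i] <- fr$cost_rmb[i] - fr$cost_rmb[prev]
        delta_qaly[i] <- fr$qaly[i] - fr$qaly[prev]
        icer_v[i] <- icer(fr$cost_rmb[i], fr$qaly[i],
                          fr$cost_rmb[prev], fr$qaly[prev])
      }
      prev <- i
    }
  }

  classification <- rep(NA_character_, n)
  has <- !is.na(icer_v)
  classification[has] <- classify_icer(icer_v[has], policy,
                                       delta_qaly = delta_qaly[has])
  out <- data.frame(arm = fr$arm, cost_rmb = fr$cost_rmb, qaly = fr$qaly,
                    delta_cost = delta_cost, delta_qaly = delta_qaly,
                    icer = icer_v, classification = classification,
                    dominance = fr$dominance)
  rownames(out) <- NULL
  out
}

#' Round half away from zero
#'
#' Monetary reporting convention for tables: internal computation stays at
#' full precision, reports round half-up (base `round()` rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
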