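#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full cohort model with a single parameter scaled to
#' `(1 - fraction)` and `(1 + fraction)` of its base value, and reports
#' each non-comparator arm's ICER against the null scenario. Recognised
#' parameters are `utility_cwp` (perturbed in every arm at once, as a
#' single shared quantity) and `cost_<arm>` for each configured arm.
#' A perturbed utility exceeding 1 is clamped to 1 with a warning so the
#' utility stays in its legal domain.
#'
#' @param config Scenario configuration (see [default_config()]).
#' @param schedule Base [transition_schedule()].
#' @param parameters Character vector of parameter names; defaults to
#'   `utility_cwp` plus every arm cost.
#' @param fraction Relative perturbation (default 0.4 for +/-40\%).
#' @param null_arm Comparator arm name; defaults to the arm with no
#'   interventions.
#' @return A data frame with columns `parameter`, `direction`
#'   (`low`/`high`), `arm`, `icer_vs_null`, covering every
#'   non-comparator arm for each perturbation.
#' @export
one_way_sensitivity <- function(config, schedule, parameters = NULL,
                                fraction = 0.4, null_arm = NULL) {
  if (fraction < 0) stop("`fraction` must be >= 0", call. = FALSE)
  arm_names <- vapply(config$arms, `[[`, character(1), "name")
  if (is.null(null_arm)) null_arm <- find_null_arm(config)
  if (is.null(parameters)) {
    parameters <- c("utility_cwp", paste0("cost_", arm_names))
  }
  known <- c("utility_cwp", paste0("cost_", arm_names))
  bad <- setdiff(parameters, known)
  if (length(bad) > 0L) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(known, collapse = ", "), call. = FALSE)
  }

  rows <- list()
  for (param in parameters) {
    for (direction in c("low", "high")) {
      scale <- if (direction == "low") 1 - fraction else 1 + fraction
      pconfig <- perturb_config(config, param, scale)
      tab <- vs_null_icers(pconfig, schedule, null_arm)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = param, direction = direction,
        arm = tab$arm, icer_vs_null = tab$icer_vs_null)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

find_null_arm <- function(config) {
  arm_names <- vapply(config$arms, `[[`, character(1), "name")
  n_iv <- vapply(config$arms, function(a) length(a$interventions), integer(1))
  if (sum(n_iv == 0L) != 1L) {
    stop("cannot identify the null arm automatically; pass `null_arm`",
         call. = FALSE)
  }
  arm_names[n_iv == 0L]
}

perturb_config <- function(config, parameter, scale) {
  arm_names <- vapply(config$arms, `[[`, character(1), "name")
  if (parameter == "utility_cwp") {
    clamped <- FALSE
    for (k in seq_along(config$arms)) {
      u <- config$arms[[k]]$utility_cwp * scale
      if (u > 1) {
        clamped <- TRUE
        u <- 1
      }
      config$arms[[k]]$utility_cwp <- u
    }
    if (clamped) {
      warning("perturbed utility_cwp exceeds 1; clamped to 1",
              call. = FALSE)
    }
  } else {
    arm <- sub("^cost_", "", parameter)
    k <- match(arm, arm_names)
    config$arms[[k]]$annual_cost <- config$arms[[k]]$annual_cost * scale
  }
  config
}

vs_null_icers <- function(config, schedule, null_arm) {
  outcomes <- outcome_summary(evaluate_all_arms(config, schedule))
  ref <- match(null_arm, outcomes$arm)
  others <- setdiff(seq_len(nrow(outcomes)), ref)
  data.frame(arm = outcomes$arm[others],
             icer_vs_null = icer(outcomes$cost_rmb[others],
                                 outcomes$qaly[others],
                                 outcomes$cost_rmb[ref],
                                 outcomes$qaly[ref]))
}

#' Specification of a probabilistic sensitivity analysis
#'
#' Costs receive gamma distributions and the CWP utility a beta
#' distribution, each parameterised by method of moments around the base
#' value with a common coefficient of variation. The default CV of 0.204
#' treats the +/-40\% one-way range as an approximate 95\% interval
#' (0.4 / 1.96); the distributions' variances are otherwise
#' unconstrained by the base-case inputs, so the CV is fully
#' configurable.
#'
#' @param n_iterations Number of Monte Carlo iterations (default 10,000).
#' @param seed Integer seed; required so every run is reproducible.
#' @param cv Coefficient of variation shared by all sampled parameters
#'   (`>= 0`; 0 collapses every distribution to its base value).
#' @return A list of class `psa_spec`.
#' @export
psa_spec <- function(n_iterations = 10000, seed, cv = 0.204) {
  if (n_iterations < 1) stop("`n_iterations` must be >= 1", call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` is required (a single integer)", call. = FALSE)
  }
  if (cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), cv = cv),
            class = "psa_spec")
}

# Method-of-moments gamma draws with the requested mean and CV.
rgamma_mean_cv <- function(n, mean, cv) {
  if (mean == 0 || cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

# Method-of-moments beta draws; errors early when the implied variance is
# incompatible with the beta support.
rbeta_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  if (mean <= 0 || mean >= 1) {
    stop("beta mean must lie in (0, 1)", call. = FALSE)
  }
  v <- (cv * mean)^2
  if (v >= mean * (1 - mean)) {
    stop("cv ", cv, " is incompatible with a beta distribution of mean ",
         mean, " (variance must be < mean * (1 - mean))", call. = FALSE)
  }
  a <- mean * (mean * (1 - mean) / v - 1)
  stats::rbeta(n, a, (1 - mean) / mean * a)
}

# Run `expr` under a local RNG stream: seeds deterministically, restores
# the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Draw sampled parameter sets for the PSA
#'
#' Samples every arm's annual cost from a gamma distribution and the CWP
#' utility from a beta distribution (shared across arms, mirroring the
#' single utility source), each centred on the base configuration value
#' with the spec's coefficient of variation. Transition probabilities are
#' held fixed: no distributional information exists for them.
#'
#' @param spec A [psa_spec()].
#' @param config Base scenario configuration.
#' @return A list with `costs` (an `n_iterations x n_arms` matrix, columns
#'   named by arm) and `utility_cwp` (length `n_iterations`).
#' @export
draw_psa_inputs <- function(spec, config) {
  stopifnot(inherits(spec, "psa_spec"))
  arm_names <- vapply(config$arms, `[[`, character(1), "name")
  base_costs <- vapply(config$arms, `[[`, numeric(1), "annual_cost")
  base_u <- config$arms[[1L]]$utility_cwp
  with_local_seed(spec$seed, {
    costs <- vapply(base_costs, function(m) {
      rgamma_mean_cv(spec$n_iterations, m, spec$cv)
    }, numeric(spec$n_iterations))
    costs <- matrix(costs, nrow = spec$n_iterations,
                    dimnames = list(NULL, arm_names))
    list(costs = costs,
         utility_cwp = rbeta_mean_cv(spec$n_iterations, base_u, spec$cv))
  })
}

#' Run a probabilistic sensitivity analysis
#'
#' Draws parameter sets with [draw_psa_inputs()] and evaluates the cohort
#' model under each: transition dynamics are fixed across iterations (only
#' costs and utilities are sampled), so each arm's trace is propagated
#' once and costs/QALYs are re-accrued per iteration with the sampled
#' values. Identical spec and seed give bit-identical results.
#'
#' @param spec A [psa_spec()].
#' @param config Base scenario configuration.
#' @param schedule Base [transition_schedule()].
#' @return A list of class `psa_result` with `samples` (data frame
#'   `iteration`, `arm`, `cost`, `qaly`, arms in config order within each
#'   iteration), `spec`, `arm_names`, and `config`.
#' @export
run_psa <- function(spec, config, schedule) {
  stopifnot(inherits(spec, "psa_spec"))
  problems <- validate_config(config)
  if (length(problems) > 0L) {
    stop("invalid config:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  outcomes <- evaluate_all_arms(config, schedule)
  arm_names <- names(outcomes)
  draws <- draw_psa_inputs(spec, config)

  n <- spec$n_iterations
  cost_mat <- matrix(0, n, length(arm_names),
                     dimnames = list(NULL, arm_names))
  qaly_mat <- cost_mat
  for (k in seq_along(arm_names)) {
    trace <- outcomes[[k]]$trace
    for (i in seq_len(n)) {
      cost_mat[i, k] <- accrue_costs(trace, draws$costs[i, k],
                                     config$discount_rate)
      qaly_mat[i, k] <- accrue_qalys(trace, config$utility_health,
                                     draws$utility_cwp[i],
                                     config$discount_rate)
    }
  }
  samples <- data.frame(
    iteration = rep(seq_len(n), each = length(arm_names)),
    arm = rep(arm_names, times = n),
    cost = as.vector(t(cost_mat)),
    qaly = as.vector(t(qaly_mat)))
  structure(list(samples = samples, spec = spec, arm_names = arm_names,
                 config = config,
                 cost = cost_mat, qaly = qaly_mat),
            class = "psa_result")
}

#' Pairwise cost-effectiveness probability
#'
#' Fraction of PSA iterations in which `arm` has strictly greater net
#' monetary benefit than `comparator` at the given willingness-to-pay.
#' Ties are credited to the comparator; for continuous cost/utility draws
#' ties occur with probability zero.
#'
#' @param psa A [run_psa()] result.
#' @param arm,comparator Arm names.
#' @param wtp Willingness-to-pay per QALY.
#' @return Probability in `[0, 1]`. Vectorised over `wtp`.
#' @export
pairwise_ce_prob <- function(psa, arm, comparator, wtp) {
  stopifnot(inherits(psa, "psa_result"))
  for (a in c(arm, comparator)) {
    if (!a %in% psa$arm_names) stop("unknown arm: ", a, call. = FALSE)
  }
  dq <- psa$qaly[, arm] - psa$qaly[, comparator]
  dc <- psa$cost[, arm] - psa$cost[, comparator]
  vapply(wtp, function(w) mean(dq * w - dc > 0), numeric(1))
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that an arm is the
#' optimal strategy — the one with the maximum net monetary benefit — over
#' the PSA iterations. Probabilities across arms sum to 1 at every
#' threshold (ties, which have probability zero for continuous draws, are
#' credited to the earliest arm in configuration order).
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Strictly increasing vector of at least two thresholds;
#'   defaults to 0 to 300,000 RMB in steps of 5,000, covering both GDP
#'   multiples.
#' @return A data frame with columns `wtp`, `arm`, `probability`.
#' @export
ceac_table <- function(psa, wtp_grid = seq(0, 300000, by = 5000)) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) < 2L || any(diff(wtp_grid) <= 0)) {
    stop("`wtp_grid` must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  arms <- psa$arm_names
  rows <- lapply(wtp_grid, function(w) {
    nmb <- psa$qaly * w - psa$cost
    best <- arms[max.col(nmb, ties.method = "first")]
    data.frame(wtp = w, arm = arms,
               probability = as.vector(vapply(arms, function(a) mean(best == a),
                                              numeric(1))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
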