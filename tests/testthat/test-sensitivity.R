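test_that("a zero-fraction perturbation returns the base-case ICERs", {
  base <- cwpcea:::vs_null_icers(base_config, synthetic_schedule, "null")
  ow <- one_way_sensitivity(base_config, synthetic_schedule, fraction = 0)
  for (d in c("low", "high")) {
    sub <- ow[ow$direction == d & ow$parameter == "utility_cwp", ]
    expect_equal(sub$icer_vs_null[match(base$arm, sub$arm)],
                 base$icer_vs_null, tolerance = 1e-12)
  }
})

test_that("cost perturbations move ICERs by the closed-form affine relation", {
  outcomes <- outcome_summary(evaluate_all_arms(base_config,
                                                synthetic_schedule))
  eng <- outcomes[outcomes$arm == "engineering", ]
  nul <- outcomes[outcomes$arm == "null", ]
  ow <- one_way_sensitivity(base_config, synthetic_schedule,
                            parameters = "cost_engineering", fraction = 0.4)
  # discounted arm cost is linear in the annual cost, so the perturbed
  # ICER has closed form (s * C_eng - C_null) / dQ
  for (d in c("low", "high")) {
    s <- if (d == "low") 0.6 else 1.4
    expected <- (s * eng$cost_rmb - nul$cost_rmb) / (eng$qaly - nul$qaly)
    got <- ow$icer_vs_null[ow$direction == d & ow$arm == "engineering"]
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("utility perturbations shift QALYs in the expected direction", {
  low_cfg <- cwpcea:::perturb_config(base_config, "utility_cwp", 0.6)
  base_out <- outcome_summary(evaluate_all_arms(base_config,
                                                synthetic_schedule))
  low_out <- outcome_summary(evaluate_all_arms(low_cfg, synthetic_schedule))
  expect_true(all(low_out$qaly < base_out$qaly))
  expect_identical(low_cfg$arms[[1]]$utility_cwp, 0.666 * 0.6)
})

test_that("utilities pushed past 1 are clamped with a warning", {
  cfg <- base_config
  for (k in seq_along(cfg$arms)) cfg$arms[[k]]$utility_cwp <- 0.8
  expect_warning(pc <- cwpcea:::perturb_config(cfg, "utility_cwp", 1.4),
                 "clamped")
  expect_identical(pc$arms[[1]]$utility_cwp, 1)
})

test_that("unknown one-way parameters are rejected by name", {
  expect_error(one_way_sensitivity(base_config, synthetic_schedule,
                                   parameters = "cost_of_tea"),
               "cost_of_tea")
})

test_that("PSA draws have the requested moments and supports", {
  spec <- psa_spec(n_iterations = 10000, seed = 42, cv = 0.204)
  draws <- draw_psa_inputs(spec, base_config)
  base_costs <- vapply(base_config$arms, `[[`, numeric(1), "annual_cost")
  for (k in seq_along(base_costs)) {
    m <- base_costs[k]
    se <- m * spec$cv / sqrt(spec$n_iterations)
    expect_lt(abs(mean(draws$costs[, k]) - m), 3 * se)
    expect_true(all(draws$costs[, k] > 0)) # gamma support
  }
  u <- draws$utility_cwp
  expect_true(all(u > 0 & u < 1)) # beta support
  expect_lt(abs(mean(u) - 0.666), 3 * 0.666 * spec$cv / sqrt(spec$n_iterations))
  expect_lt(abs(sd(u) - 0.666 * spec$cv), 3 * 0.666 * spec$cv / sqrt(spec$n_iterations))

  # degenerate-variance limit: every draw equals the base value
  d0 <- draw_psa_inputs(psa_spec(n_iterations = 5, seed = 1, cv = 0),
                        base_config)
  expect_equal(unname(d0$costs), matrix(base_costs, 5, 4, byrow = TRUE))
  expect_identical(d0$utility_cwp, rep(0.666, 5))
})

test_that("incompatible beta parameterisations error early", {
  cfg <- base_config
  for (k in seq_along(cfg$arms)) cfg$arms[[k]]$utility_cwp <- 0.95
  expect_error(
    draw_psa_inputs(psa_spec(n_iterations = 10, seed = 1, cv = 0.5), cfg),
    "incompatible")
})

test_that("PSA results are bit-identical under a fixed seed", {
  spec <- psa_spec(n_iterations = 200, seed = 7)
  a <- run_psa(spec, base_config, synthetic_schedule)
  b <- run_psa(spec, base_config, synthetic_schedule)
  expect_identical(a$samples, b$samples)
  c <- run_psa(psa_spec(n_iterations = 200, seed = 8), base_config,
               synthetic_schedule)
  expect_false(identical(a$samples$cost, c$samples$cost))
})

test_that("zero-variance PSA reproduces the base-case ICERs", {
  spec <- psa_spec(n_iterations = 3, seed = 1, cv = 0)
  psa <- run_psa(spec, base_config, synthetic_schedule)
  base <- outcome_summary(evaluate_all_arms(base_config, synthetic_schedule))
  mean_cost <- colMeans(psa$cost)
  mean_qaly <- colMeans(psa$qaly)
  for (a in c("engineering", "individual", "comprehensive")) {
    got <- icer(mean_cost[a], mean_qaly[a], mean_cost["null"],
                mean_qaly["null"])
    want <- icer(base$cost_rmb[base$arm == a], base$qaly[base$arm == a],
                 base$cost_rmb[base$arm == "null"],
                 base$qaly[base$arm == "null"])
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("pairwise CE probabilities are complementary for continuous draws", {
  psa <- run_psa(psa_spec(n_iterations = 500, seed = 3), base_config,
                 synthetic_schedule)
  for (wtp in c(0, 72447, 217341)) {
    p_ab <- pairwise_ce_prob(psa, "engineering", "comprehensive", wtp)
    p_ba <- pairwise_ce_prob(psa, "comprehensive", "engineering", wtp)
    expect_equal(p_ab + p_ba, 1)
    expect_true(p_ab >= 0 && p_ab <= 1)
  }
})

test_that("acceptability curves partition probability across arms", {
  psa <- run_psa(psa_spec(n_iterations = 500, seed = 3), base_config,
                 synthetic_schedule)
  ceac <- ceac_table(psa, wtp_grid = seq(0, 300000, by = 50000))
  sums <- as.vector(tapply(ceac$probability, ceac$wtp, sum))
  expect_equal(sums, rep(1, length(sums)))

  # at zero willingness-to-pay the cheapest arm is most acceptable
  at0 <- ceac[ceac$wtp == 0, ]
  expect_identical(at0$arm[which.max(at0$probability)], "null")

  # at an extreme threshold the QALY-richest arm dominates the curve
  high <- ceac_table(psa, wtp_grid = c(5e6, 1e7))
  at_inf <- high[high$wtp == 1e7, ]
  expect_identical(at_inf$arm[which.max(at_inf$probability)],
                   "comprehensive")

  expect_error(ceac_table(psa, wtp_grid = c(5, 4)), "increasing")
  expect_error(ceac_table(psa, wtp_grid = 10), ">= 2")
})

test_that("single-iteration zero-variance PSA matches the deterministic comparison", {
  psa <- run_psa(psa_spec(n_iterations = 1, seed = 1, cv = 0), base_config,
                 synthetic_schedule)
  base <- outcome_summary(evaluate_all_arms(base_config, synthetic_schedule))
  wtp <- 217341
  nmb <- net_monetary_benefit(base$cost_rmb, base$qaly, wtp)
  deterministic <- nmb[base$arm == "engineering"] > nmb[base$arm == "null"]
  p <- pairwise_ce_prob(psa, "engineering", "null", wtp)
  expect_identical(p, as.numeric(deterministic))
})
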