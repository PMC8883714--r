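test_that("life-table estimator matches the actuarial formula and guards its domain", {
  expect_identical(estimate_incidence(0, 0, 1000), 0)
  expect_equal(estimate_incidence(2873, 0, 87904), 2873 / 87904)
  expect_equal(estimate_incidence(10, 20, 110), 0.1)
  # vectorised
  expect_equal(estimate_incidence(c(0, 10), c(0, 20), c(1000, 110)),
               c(0, 0.1))
  expect_error(estimate_incidence(-1, 0, 100), "non-negative")
  expect_error(estimate_incidence(0, 0, 0), "positive")
  expect_error(estimate_incidence(5, 200, 100), "positive")
  expect_error(estimate_incidence(99, 10, 100), "exceeds 1")
})

test_that("interval conversion follows the constant-hazard transform", {
  expect_identical(convert_interval(0, 5), 0)
  expect_identical(convert_interval(1, 5), 1)
  expect_equal(convert_interval(0.4, 5), 1 - 0.6^(1 / 5))
  # idempotent for j = 1
  p <- c(0, 0.013, 0.4, 0.97, 1)
  expect_equal(convert_interval(p, 1), p)
  expect_error(convert_interval(1.2, 5), "\\[0, 1\\]")
  expect_error(convert_interval(0.5, 0), ">= 1")
})

test_that("annual probabilities compound back to the interval probability", {
  set.seed(7)
  for (p in runif(25)) {
    annual <- convert_interval(p, 5)
    expect_equal(1 - (1 - annual)^5, p, tolerance = 1e-12)
  }
})

test_that("back-adjustment reconstructs the null scenario and round-trips", {
  both <- list(coverage_efficiency(0.95, 0.95), coverage_efficiency(0.7, 0.7))
  expect_equal(back_adjust_to_null(0.001, both), 0.001 / 0.049725)
  expect_identical(back_adjust_to_null(0, both), 0)
  expect_identical(back_adjust_to_null(0.05, list()), 0.05)
  expect_equal(apply_interventions(0.02, list(coverage_efficiency(0.95, 0.95))),
               0.02 * 0.0975)
  expect_equal(apply_interventions(0.02, list(coverage_efficiency(0.7, 0.7))),
               0.02 * 0.51)
  expect_identical(apply_interventions(0.37, list()), 0.37)

  set.seed(11)
  for (i in 1:1000) {
    ivs <- replicate(sample(1:3, 1), {
      coverage_efficiency(runif(1), runif(1, 0, 0.99))
    }, simplify = FALSE)
    # keep the null-adjusted value inside [0, 1] so the round trip is defined
    lambda <- runif(1, 0, min(0.04, cwpcea:::retention_factor(ivs)))
    expect_equal(apply_interventions(back_adjust_to_null(lambda, ivs), ivs),
                 lambda, tolerance = 1e-12)
  }
})

test_that("removing interventions never decreases incidence", {
  set.seed(3)
  for (i in 1:50) {
    lambda <- runif(1, 0, 0.01)
    ivs <- list(coverage_efficiency(runif(1), runif(1, 0, 0.99)))
    expect_gte(back_adjust_to_null(lambda, ivs), lambda)
  }
})

test_that("probability overflow errors by default and clamps on request", {
  both <- list(coverage_efficiency(0.95, 0.95), coverage_efficiency(0.7, 0.7))
  expect_error(back_adjust_to_null(0.5, both), "exceeds 1")
  expect_identical(back_adjust_to_null(0.5, both, overflow = "clamp"), 1)
  expect_error(coverage_efficiency(1, 1), "divide by zero")
  expect_error(coverage_efficiency(1.2, 0.5), "\\[0, 1\\]")
})

test_that("arm schedules are derived through the null with mortality untouched", {
  base <- toy_schedule(n = 3, lambda = 0.001)
  comp <- paper_interventions$comprehensive

  # round trip to the base arm's own interventions is the identity
  same <- build_arm_schedule(base, comp, comp)
  expect_equal(same$p_health_to_cwp, base$p_health_to_cwp, tolerance = 1e-12)

  null_sched <- build_arm_schedule(base, comp, list())
  expect_equal(null_sched$p_health_to_cwp, base$p_health_to_cwp / 0.049725)
  expect_identical(null_sched$p_health_to_death, base$p_health_to_death)
  expect_identical(null_sched$p_cwp_to_death, base$p_cwp_to_death)

  eng <- build_arm_schedule(base, comp, paper_interventions$engineering)
  expect_equal(eng$p_health_to_cwp, rep(0.001 / 0.51, 3))

  # an offending cycle is named when back-adjustment breaks the invariants
  bad <- toy_schedule(n = 3, lambda = 0.06)
  expect_error(build_arm_schedule(bad, comp, list()), "exceeds 1")
})

test_that("incidence ordering across arms holds at every cycle", {
  base <- synthetic_schedule
  comp <- paper_interventions$comprehensive
  l_comp <- base$p_health_to_cwp
  l_eng <- build_arm_schedule(base, comp, paper_interventions$engineering)$p_health_to_cwp
  l_ind <- build_arm_schedule(base, comp, paper_interventions$individual)$p_health_to_cwp
  l_null <- build_arm_schedule(base, comp, list())$p_health_to_cwp
  expect_true(all(l_comp <= l_eng))
  expect_true(all(l_eng <= l_ind))
  expect_true(all(l_ind <= l_null))
})

test_that("transition matrices are row-stochastic with absorbing death", {
  id <- to_matrix(list(p_health_to_cwp = 0, p_health_to_death = 0,
                       p_cwp_to_death = 0))
  expect_equal(unname(id), diag(3))

  m <- to_matrix(list(p_health_to_cwp = 0.01, p_health_to_death = 0.002,
                      p_cwp_to_death = 0.05))
  expect_equal(unname(m), matrix(c(0.988, 0.01, 0.002,
                                   0, 0.95, 0.05,
                                   0, 0, 1), nrow = 3, byrow = TRUE))
  expect_equal(m["cwp", "health"], 0) # irreversible disease
  expect_equal(unname(m["death", ]), c(0, 0, 1)) # absorbing

  set.seed(5)
  for (i in 1:20) {
    p <- runif(3, 0, 0.3)
    m <- to_matrix(list(p_health_to_cwp = p[1], p_health_to_death = p[2],
                        p_cwp_to_death = p[3]))
    expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)
  }
  expect_error(to_matrix(list(p_health_to_cwp = 0.7, p_health_to_death = 0.4,
                              p_cwp_to_death = 0)), "exceeds 1")
})

test_that("schedule CSV round-trips and the header is enforced", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(synthetic_schedule, path)
  back <- read_schedule(path)
  expect_equal(as.data.frame(back), as.data.frame(synthetic_schedule),
               tolerance = 1e-12, ignore_attr = TRUE)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cycle,age,p_cwp,p_hd,p_cd", "0,20,0,0,0"), bad)
  expect_error(read_schedule(bad), "header must be exactly")
})

test_that("schedule validation names the offending cycle and column", {
  sched <- as.data.frame(toy_schedule(n = 5))
  sched$p_health_to_cwp[3] <- 1.2
  problems <- validate_schedule(sched)
  expect_match(problems, "p_health_to_cwp.*cycle\\(s\\) 2", all = FALSE)
})
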