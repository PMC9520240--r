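test_that("risk classification uses the 0.10 and 0.20 edges half-open", {
  r <- classify_risk(c(0.05, 0.15, 0.199999, 0.20, 0.25))
  expect_identical(as.character(r),
                   c("moderate", "high", "high", "very_high", "very_high"))
  expect_lt(as.integer(classify_risk(0.05)), as.integer(classify_risk(0.15)))
  expect_error(classify_risk(1.2), "\\[0, 1\\]")
})

test_that("intervention assignment follows strategy, threshold and uptake", {
  coh <- stub_cohort(risk_no_prs = c(0.15, 0.15, 0.15, 0.15),
                     risk_with_prs = c(0.25, 0.25, 0.18, 0.21))
  pol <- intervention_policy()
  # usual arm screens without PRS: the whole 10-20% band gets nothing
  expect_true(all(assign_intervention(coh, "usual", pol) == "none"))
  # PRS arm: >= 0.20 with PRS triggers lifestyle; uptake draw < 0.30 adds
  # medical therapy
  st <- assign_intervention(coh, "prs", pol,
                            u = c(0.1, 0.9, 0.1, 0.29),
                            u_adherence = rep(0, 4))
  expect_identical(as.character(st),
                   c("lifestyle_medical", "lifestyle", "none",
                     "lifestyle_medical"))
  expect_error(assign_intervention(data.frame(x = 1), "prs", pol),
               "risk10_with_prs")
})

test_that("intervention effect modifies onset probability for 15 years", {
  pol <- intervention_policy()
  p <- 1 - exp(-0.1)
  expect_equal(effective_t2d_prob(p, "none", 0, pol), p)
  expect_equal(effective_t2d_prob(p, "lifestyle", 0, pol), 1 - exp(-0.074))
  expect_equal(effective_t2d_prob(p, "lifestyle_medical", 0, pol),
               1 - exp(-0.1 * 0.51))
  # effect lapses after 15 years: year 16 (14 completed years -> active,
  # 15 completed years -> back to baseline exactly)
  expect_lt(effective_t2d_prob(p, "lifestyle", 14, pol), p)
  expect_identical(effective_t2d_prob(p, "lifestyle", 15, pol), p)
})

test_that("one-cycle transitions match exact enumeration of the two draws", {
  # degenerate cases
  expect_identical(step_state("healthy", 0, 0, 0.5, 0.5), 1L)
  expect_identical(step_state("healthy", 1, 0, 0.5, 0.5), 4L)
  expect_identical(step_state("dead", 1, 1, 0.01, 0.01), 4L)
  # death drawn first, then progression for survivors:
  # P(dead) = 0.1, P(t2d) = 0.9 * 0.2 = 0.18, P(stay) = 0.72
  n <- 10000
  set.seed(8)
  out <- step_state(rep("healthy", n), 0.1, 0.2, runif(n), runif(n))
  p_exact <- c(healthy = 0.72, t2d = 0.18, dead = 0.10)
  for (s in names(p_exact)) {
    obs <- mean(out == match(s, health_states()))
    expect_lt(abs(obs - p_exact[[s]]),
              3 * sqrt(p_exact[[s]] * (1 - p_exact[[s]]) / n))
  }
  # T2D progresses to complications, never back
  out2 <- step_state(rep("t2d", n), 0, 1, runif(n), runif(n))
  expect_true(all(out2 == 3L))
})

test_that("zero hazards keep an individual healthy until age 100", {
  none <- weibull_aft(Inf, scale = 1)
  ms <- model_set(none, none, none, life_table = flat_life_table(q = 0))
  ind <- stub_cohort(0.15, age = 30)
  tr <- simulate_individual(ind, "usual", ms, seed = 1)
  expect_identical(nrow(tr), 70L)
  expect_true(all(tr$state == "healthy"))
  expect_equal(max(tr$age), 99)
  res <- attr(tr, "result")
  expect_equal(res$death_fraction, 0)
  expect_equal(res$mean_life_years, 70)
})

test_that("trajectories respect the state-machine topology and accounting", {
  b <- default_bundle()
  allowed <- list(healthy = c("healthy", "t2d", "dead"),
                  t2d = c("t2d", "t2d_complications", "dead"),
                  t2d_complications = c("t2d_complications", "dead"))
  coh <- default_target_cohort(15, seed = 91)
  for (i in seq_len(nrow(coh))) {
    tr <- simulate_individual(coh[i, ], "prs", b$models, b$econ, b$policy,
                              seed = 300 + i)
    # no rows after death (dead state never recorded), age caps at 99
    expect_true(all(tr$state != "dead"))
    expect_true(all(tr$age <= 99))
    for (j in seq_len(nrow(tr) - 1)) {
      expect_true(tr$state[j + 1] %in% allowed[[tr$state[j]]])
    }
    # onset clock: NA before/at onset year, then 0, 1, 2, ...
    ys <- tr$years_since_onset[!is.na(tr$years_since_onset)]
    if (length(ys)) expect_identical(ys, seq_along(ys) - 1L)
    if (any(tr$state == "t2d_complications")) {
      expect_gt(sum(tr$state == "t2d"), 0)
      expect_lt(min(which(tr$state == "t2d")),
                min(which(tr$state == "t2d_complications")))
    }
    # conservation: one record per life-year, QALYs bounded by life-years
    res <- attr(tr, "result")
    expect_equal(nrow(tr), res$mean_life_years)
    expect_lte(res$mean_qaly, res$mean_life_years)
    expect_gte(res$mean_t2d_free_years, 0)
    # trajectory aggregation reproduces the engine's discounted totals
    agg <- aggregate_trajectory(tr, rate = 0.03)
    expect_equal(agg[["cost"]], res$mean_cost, tolerance = 1e-12)
    expect_equal(agg[["qaly"]], res$mean_qaly, tolerance = 1e-12)
  }
})

test_that("a null PRS with free testing makes the arms exactly equal", {
  b <- default_bundle()
  ms <- null_prs_models(b$raw)
  econ0 <- b$econ
  econ0$costs$prs_test <- 0
  coh <- generate_cohort(cohort_spec(n = 800), seed = 101)
  coh <- compute_risks(coh, ms$incidence_no_prs, ms$incidence_with_prs)
  sel <- select_target_population(coh)
  cmp <- compare_strategies(sel, ms, econ0, b$policy, seed = 102)
  expect_identical(cmp$usual$per_person$cost, cmp$prs$per_person$cost)
  expect_identical(cmp$usual$per_person$qaly, cmp$prs$per_person$qaly)
  expect_identical(cmp$usual$mean_cost, cmp$prs$mean_cost)
  expect_identical(cmp$incremental$delta_cost, 0)
  expect_identical(cmp$incremental$delta_qaly, 0)
})

test_that("the PRS test price moves the incremental cost one-for-one", {
  b <- default_bundle()
  coh <- default_target_cohort(400, seed = 111)
  delta <- 37.5
  econ_hi <- b$econ
  econ_hi$costs$prs_test <- b$econ$costs$prs_test + delta
  c1 <- compare_strategies(coh, b$models, b$econ, b$policy, seed = 112)
  c2 <- compare_strategies(coh, b$models, econ_hi, b$policy, seed = 112)
  expect_equal(c2$prs$mean_cost - c1$prs$mean_cost, delta, tolerance = 1e-9)
  expect_identical(c2$usual$mean_cost, c1$usual$mean_cost)
  expect_equal(c2$incremental$delta_cost - c1$incremental$delta_cost, delta,
               tolerance = 1e-9)
})

test_that("cost accounting is linear: doubling all prices doubles costs", {
  b <- default_bundle()
  coh <- default_target_cohort(300, seed = 121)
  econ2 <- b$econ
  econ2$costs <- do.call(cost_parameters,
                         lapply(unclass(b$econ$costs), `*`, 2))
  r1 <- run_arm(coh, "prs", b$models, b$econ, b$policy, seed = 122)
  r2 <- run_arm(coh, "prs", b$models, econ2, b$policy, seed = 122)
  expect_equal(r2$mean_cost, 2 * r1$mean_cost, tolerance = 1e-12)
  expect_identical(r2$mean_qaly, r1$mean_qaly)
})

test_that("a cohort of one reproduces the single-individual run", {
  b <- default_bundle()
  coh <- default_target_cohort(5, seed = 131)
  one <- coh[3, ]
  r <- run_arm(one, "prs", b$models, b$econ, b$policy, seed = 132)
  tr <- simulate_individual(one, "prs", b$models, b$econ, b$policy,
                            seed = 132)
  res <- attr(tr, "result")
  expect_identical(r$mean_cost, res$mean_cost)
  expect_identical(r$mean_qaly, res$mean_qaly)
  expect_identical(r$per_person$final_state, res$per_person$final_state)
  expect_error(run_arm(coh[0, ], "prs", b$models, b$econ, b$policy,
                       seed = 1), "empty")
})

test_that("reclassification counts the band members crossing 0.20", {
  coh <- stub_cohort(risk_no_prs = rep(0.15, 4),
                     risk_with_prs = c(0.21, 0.15, 0.25, 0.19))
  expect_equal(reclassification_rate(coh), 0.5)
  expect_equal(reclassification_rate(stub_cohort(rep(0.15, 3),
                                                 rep(0.25, 3))), 1)
  # a null PRS reclassifies nobody out of the sub-threshold band
  expect_equal(reclassification_rate(stub_cohort(rep(0.15, 3))), 0)
})
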