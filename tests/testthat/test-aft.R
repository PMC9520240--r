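test_that("survival function obeys S(0) = 1 and known closed forms", {
  m <- weibull_aft(2, c(age = -0.02), scale = 0.5)
  expect_equal(survival_at(m, list(age = 50), 0), 1)
  # exponential special case: k = 1, lambda = 10, t = 10 -> exp(-1)
  expo <- weibull_aft(log(10), scale = 1)
  expect_equal(survival_at(expo, NULL, 10), exp(-1))
  expect_equal(risk_over(expo, NULL, 10), 1 - exp(-1))
  # Weibull k = 1.5, lambda = 20, t = 10 -> exp(-0.5^1.5)
  wb <- weibull_aft(log(20), scale = 1 / 1.5)
  expect_equal(survival_at(wb, NULL, 10), exp(-0.5^1.5))
  expect_error(survival_at(m, list(bmi = 20), 1), "age")
})

test_that("survival agrees with numerical hazard integration to 1e-8", {
  k <- 1.5; lambda <- 20
  wb <- weibull_aft(log(lambda), scale = 1 / k)
  hazard <- function(t) (k / lambda) * (t / lambda)^(k - 1)
  for (t in c(1, 5, 10, 25, 60)) {
    H <- integrate(hazard, 0, t, rel.tol = 1e-12)$value
    expect_lt(abs(survival_at(wb, NULL, t) - exp(-H)), 1e-8)
  }
})

test_that("10-year risk is monotone in horizon and in the PRS", {
  m <- weibull_aft(6, c(age = -0.02, prs = -0.25), scale = 0.75)
  cov0 <- list(age = 60, prs = 0)
  risks <- risk_over(m, cov0, c(0, 5, 10, 20))
  expect_equal(risks[1], 0)
  expect_true(all(diff(risks) > 0))
  expect_gt(risk_over(m, list(age = 60, prs = 1), 10),
            risk_over(m, cov0, 10))
})

test_that("annual event probabilities telescope back to the survival curve", {
  # constant hazard: memoryless, identical p every year
  h <- 0.1
  expo <- weibull_aft(log(1 / h), scale = 1)
  p <- annual_event_prob(expo, NULL, 0:9)
  expect_equal(p, rep(1 - exp(-h), 10))
  # Weibull: p_t matches direct S-ratio oracle and telescopes exactly
  wb <- weibull_aft(log(20), scale = 1 / 1.5)
  pt <- annual_event_prob(wb, NULL, 0:9)
  s <- survival_at(wb, NULL, 0:10)
  expect_equal(pt, 1 - s[-1] / s[-11], tolerance = 1e-12)
  expect_equal(prod(1 - pt), survival_at(wb, NULL, 10), tolerance = 1e-12)
  # increasing hazard (k > 1) gives non-decreasing annual probabilities
  expect_true(all(diff(pt) > 0))
})

test_that("hazard-ratio adjustment matches rate-space conversion and composes", {
  p <- 1 - exp(-0.1)
  expect_equal(apply_hazard_ratio(p, 1), p)
  expect_equal(apply_hazard_ratio(p, 2), 1 - exp(-0.2))
  set.seed(1)
  ps <- runif(50); hrs <- runif(50, 0.2, 3)
  # rate-space oracle: p -> rate -> scaled rate -> probability
  oracle <- 1 - exp(-(-log(1 - ps)) * hrs)
  expect_equal(apply_hazard_ratio(ps, hrs), oracle, tolerance = 1e-12)
  # composition: hr1 then hr2 equals hr1 * hr2
  expect_equal(apply_hazard_ratio(apply_hazard_ratio(ps, 1.3), 1.7),
               apply_hazard_ratio(ps, 1.3 * 1.7), tolerance = 1e-12)
  expect_equal(apply_hazard_ratio(1, 2.5), 1)
  expect_error(apply_hazard_ratio(0.5, 0), "positive")
})

test_that("state-specific mortality applies the published hazard ratios", {
  lt <- flat_life_table(q = 0.01)
  expect_equal(mortality_prob(lt, 60, "male", "healthy"), 0.01)
  expect_equal(mortality_prob(lt, 60, "female", "t2d"), 1 - 0.99^2.47)
  expect_equal(mortality_prob(lt, 60, "male", "t2d"), 1 - 0.99^1.93)
  expect_equal(mortality_prob(lt, 60, "male", "t2d_complications"),
               1 - 0.99^2.36)
  # ordering: diseased risk never below healthy risk for HR >= 1
  q <- mortality_prob(lt, 60, "male", c("healthy", "t2d"))
  expect_lte(q[1], q[2])
  # interpretation switch: complications HR on top of the T2D HR
  adj <- mortality_adjustment(complications_on_top = TRUE)
  expect_equal(mortality_prob(lt, 60, "male", "t2d_complications", adj),
               1 - 0.99^(2.36 * 1.93))
  expect_error(mortality_prob(lt, 101, "male"), "life-table range")
})

test_that("fitting requires events and recovers known Weibull coefficients", {
  coh <- generate_cohort(cohort_spec(n = 50000), seed = 41)
  truth <- load_aft_models()$incidence_with_prs
  covs <- data.frame(age = coh$age, male = as.numeric(coh$sex == "male"),
                     findrisc = coh$findrisc, prs = coh$prs)
  expect_error(fit_aft(rep(10, 100), rep(0, 100)), "no events")
  fu <- simulate_followup(coh, truth, years = 10, seed = 42)
  fit <- fit_aft(fu$time, fu$event, covs, "weibull")
  expect_true(fit$converged)
  true_vec <- c("(Intercept)" = truth$intercept, truth$coefficients)
  est <- c("(Intercept)" = fit$intercept, fit$coefficients)
  for (nm in names(true_vec)) {
    expect_lt(abs(est[[nm]] - true_vec[[nm]]) / fit$se[[nm]], 3)
  }
  expect_lt(abs(fit$scale - truth$scale), 3 * fit$se[["Log(scale)"]] * fit$scale)
  # consistency at a second, smaller n: recovery still within 3 SE
  coh2 <- generate_cohort(cohort_spec(n = 5000), seed = 43)
  covs2 <- data.frame(age = coh2$age, male = as.numeric(coh2$sex == "male"),
                      findrisc = coh2$findrisc, prs = coh2$prs)
  fu2 <- simulate_followup(coh2, truth, years = 10, seed = 44)
  fit2 <- fit_aft(fu2$time, fu2$event, covs2, "weibull")
  est2 <- c("(Intercept)" = fit2$intercept, fit2$coefficients)
  for (nm in names(true_vec)) {
    expect_lt(abs(est2[[nm]] - true_vec[[nm]]) / fit2$se[[nm]], 3)
  }
  # standard errors (hence bias bounds) shrink as n grows
  expect_lt(fit$se[["(Intercept)"]], fit2$se[["(Intercept)"]])
})

test_that("family comparison selects by AIC with a correct table", {
  coh <- generate_cohort(cohort_spec(n = 5000), seed = 51)
  expo <- weibull_aft(log(15), c(age = -0.002), scale = 1)
  covs <- data.frame(age = coh$age)
  fu <- simulate_followup(coh, expo, years = 10, seed = 52)
  expect_error(compare_families(fu$time, fu$event, covs, "weibull"),
               "two families")
  cmp <- compare_families(fu$time, fu$event, covs,
                          c("exponential", "weibull"))
  # nested-model property: on exponential data the two AICs are within 2
  expect_lt(abs(diff(cmp$table$aic)), 2)
  # AIC/BIC recomputable from the reported logLik and df
  with(cmp$table, {
    expect_equal(aic, 2 * df - 2 * loglik)
    expect_equal(bic, df * log(nrow(fu)) - 2 * loglik)
  })
})

test_that("Weibull data with shape 1.6 selects the weibull family", {
  coh <- generate_cohort(cohort_spec(n = 50000), seed = 61)
  truth <- weibull_aft(4.4, c(age = -0.01, findrisc = -0.05),
                       scale = 1 / 1.6)
  covs <- data.frame(age = coh$age, findrisc = coh$findrisc)
  fu <- simulate_followup(coh, truth, years = 10, seed = 62)
  cmp <- compare_families(fu$time, fu$event, covs,
                          c("exponential", "weibull", "lognormal",
                            "loglogistic"))
  expect_identical(cmp$selected, "weibull")
  expect_lt(cmp$table$aic[cmp$table$family == "weibull"],
            cmp$table$aic[cmp$table$family == "exponential"])
  # the fitted model reproduces the truth's survival curve closely
  refit <- as_weibull_aft(cmp$fits$weibull)
  cov0 <- list(age = 60, findrisc = 12)
  expect_equal(survival_at(refit, cov0, 10), survival_at(truth, cov0, 10),
               tolerance = 0.02)
})
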