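test_that("SE-from-CI rule reproduces published standard errors", {
  expect_equal(round(se_from_ci(3301, 5501)), 561)
  expect_equal(se_from_ci(-1.96, 1.96), 1)
  expect_equal(round(se_from_ci(1.79, 2.07), 2), 0.07)
  expect_error(se_from_ci(5, 5), "exceed")
})

test_that("plus/minus 25% bounds bracket the mean symmetrically", {
  b <- pm25_bounds(650)
  expect_equal(round_half_up(b$lower), 488)
  expect_equal(round_half_up(b$upper), 813)
  expect_equal(b$upper - 650, 650 - b$lower)
  expect_equal(round(pm25_bounds(584)$lower), 438)
  expect_equal(round(pm25_bounds(584)$upper), 730)
  expect_equal(pm25_bounds(100)$lower, 75)
  expect_equal(pm25_bounds(100)$se, se_from_ci(75, 125))
})

test_that("Beta moment fit reproduces printed shape terms and moments", {
  ab <- beta_mom(0.041, 0.012)
  expect_equal(round(ab[["alpha"]], 2), 11.15)
  expect_equal(round(ab[["beta"]], 1), 260.9)
  # mean recovered exactly; SD recovered exactly
  expect_equal(ab[["alpha"]] / sum(ab), 0.041)
  v <- ab[["alpha"]] * ab[["beta"]] / (sum(ab)^2 * (sum(ab) + 1))
  expect_equal(sqrt(v), 0.012, tolerance = 1e-9)
  # uniform distribution corner: mean 1/2, var 1/12 -> Beta(1, 1)
  expect_equal(unname(beta_mom(0.5, sqrt(1 / 12))), c(1, 1),
               tolerance = 1e-12)
  expect_equal(round(beta_mom(0.770, 0.008)[["alpha"]]), 2130)
  expect_equal(round(beta_mom(0.770, 0.008)[["beta"]]), 636)
  expect_error(beta_mom(0.5, 0.6), "variance too large")
})

test_that("Gamma and lognormal moment fits round-trip to 1e-9", {
  g <- gamma_mom(4401, 561)
  expect_equal(g[["shape"]] / g[["rate"]], 4401, tolerance = 1e-9)
  expect_equal(sqrt(g[["shape"]]) / g[["rate"]], 561, tolerance = 1e-9)
  expect_equal(unname(gamma_mom(1, 1)), c(1, 1))
  g2 <- gamma_mom(3315, 423)
  expect_equal(sqrt(g2[["shape"]]) / g2[["rate"]], 423, tolerance = 1e-9)
  ln <- lognormal_mom(0.74, 0.17)
  m <- exp(ln[["mu"]] + ln[["sigma"]]^2 / 2)
  s <- m * sqrt(exp(ln[["sigma"]]^2) - 1)
  expect_equal(m, 0.74, tolerance = 1e-9)
  expect_equal(s, 0.17, tolerance = 1e-9)
  # degenerate limit: mean 1 with vanishing SE collapses to mu = sigma = 0
  ln0 <- lognormal_mom(1, 1e-9)
  expect_lt(abs(ln0[["mu"]]), 1e-12)
  expect_lt(ln0[["sigma"]], 1e-8)
})

test_that("sampled parameters respect support and published means", {
  dists <- psa_distributions()
  # all fixed -> deterministic
  fx <- list(a = param_distribution("a", "fixed", mean = 5),
             b = param_distribution("b", "fixed", mean = 7))
  expect_identical(sample_parameters(fx), c(a = 5, b = 7))
  set.seed(17)
  draws <- t(replicate(20000, sample_parameters(dists)))
  # beta draws in [0,1], gamma/lognormal positive
  expect_true(all(draws[, "disutility_t2d"] >= 0 &
                    draws[, "disutility_t2d"] <= 1))
  expect_true(all(draws[, "u_female_65+"] >= 0 & draws[, "u_female_65+"] <= 1))
  expect_true(all(draws[, "hr_lifestyle"] > 0))
  expect_true(all(draws[, "cost_complications_extra"] > 0))
  # Monte-Carlo means within 3 SE of the declared means
  for (nm in c("hr_lifestyle", "cost_complications_extra",
               "disutility_t2d", "u_female_65+")) {
    m <- mean(draws[, nm]); s <- sd(draws[, nm]) / sqrt(nrow(draws))
    target <- c(hr_lifestyle = 0.74, cost_complications_extra = 4401,
                disutility_t2d = 0.041, `u_female_65+` = 0.770)[[nm]]
    expect_lt(abs(m - target), 3 * s)
  }
  expect_identical(unique(draws[, "cost_prs_test"]), 50)
})

test_that("incremental analysis labels dominance and computes ICERs", {
  # lower cost, higher QALYs: dominant, no ICER division
  inc <- incremental_analysis(13619, 12.13, 13373, 12.15)
  expect_identical(inc$label, "dominant")
  expect_true(is.na(inc$icer))
  expect_lt(inc$delta_cost, 0)
  expect_gt(inc$delta_qaly, 0)
  expect_equal(incremental_analysis(0, 0, 100, 0.01)$icer, 10000)
  expect_equal(incremental_analysis(0, 0, 31, 0.003)$icer, 10333,
               tolerance = 1e-4)
  expect_identical(incremental_analysis(0, 1, 10, 0.9)$label, "dominated")
  expect_identical(incremental_analysis(0, 1, 10, 1)$label, "undefined")
  expect_identical(incremental_analysis(5, 1, 5, 1)$label, "equivalent")
})

test_that("net monetary benefit is the linear WTP trade-off", {
  expect_equal(nmb(120, 2, 0), -120)
  expect_equal(nmb(100, 1, 100), 0)
  expect_equal(nmb(c(10, 20), c(1, 2), 50), c(40, 80))
  expect_error(nmb(1, 1, -5), "non-negative")
})

test_that("CEAC counts favourable draws with ties at one half", {
  # dNMB draws {+1, +1, -1, +1} at wtp 0 <=> cost differences
  psa <- psa_result(cost_usual = c(1, 1, 1, 1), qaly_usual = rep(1, 4),
                    cost_prs = c(0, 0, 2, 0), qaly_prs = rep(1, 4))
  ce <- ceac(psa, wtp_grid = 0)
  expect_equal(ce$probability, 0.75)
  # all draws favour PRS -> 1
  all_win <- psa_result(rep(2, 3), rep(1, 3), rep(1, 3), rep(1.1, 3))
  expect_equal(ceac(all_win, c(0, 10000))$probability, c(1, 1))
  # exact ties count 0.5
  tie <- psa_result(rep(1, 2), rep(1, 2), rep(1, 2), rep(1, 2))
  expect_equal(ceac(tie, c(0, 50000))$probability, c(0.5, 0.5))
  # identity: CEAC at wtp 0 equals the fraction of cost-saving draws,
  # and the NMB route agrees with direct per-draw comparison of pairs
  set.seed(23)
  rnd <- psa_result(rnorm(200, 100, 30), rnorm(200, 10, 1),
                    rnorm(200, 100, 30), rnorm(200, 10, 1))
  expect_equal(ceac(rnd, 0)$probability,
               mean(rnd$cost_prs < rnd$cost_usual))
  for (w in c(0, 20000)) {
    direct <- mean(w * rnd$qaly_prs - rnd$cost_prs >
                     w * rnd$qaly_usual - rnd$cost_usual)
    expect_equal(ceac(rnd, w)$probability, direct)
  }
})

test_that("EVPI is the expected opportunity loss, non-negative, shift-proof", {
  # hand enumeration: per-draw best NMB averages to 10, best mean is 5
  psa <- psa_result(cost_usual = c(-10, 0), qaly_usual = c(0, 0),
                    cost_prs = c(0, -10), qaly_prs = c(0, 0))
  expect_equal(evpi(psa, 0)$evpi, 5)
  # one strategy dominant in every draw -> 0
  dom <- psa_result(rep(10, 4), rep(1, 4), rep(5, 4), rep(2, 4))
  expect_equal(evpi(dom, c(0, 10000))$evpi, c(0, 0))
  # shift invariance: adding a constant cost to both strategies per draw
  set.seed(29)
  a <- psa_result(rnorm(100), rnorm(100), rnorm(100), rnorm(100, 0.2))
  shift <- rnorm(100)
  b <- psa_result(a$cost_usual + shift, a$qaly_usual,
                  a$cost_prs + shift, a$qaly_prs)
  expect_equal(evpi(a, c(0, 1, 5))$evpi, evpi(b, c(0, 1, 5))$evpi,
               tolerance = 1e-12)
  expect_true(all(evpi(a, seq(0, 10, 2))$evpi >= 0))
})

test_that("degenerate PSA (null effect, free test) is perfectly undecided", {
  b <- default_bundle()
  ms <- null_prs_models(b$raw)
  econ0 <- b$econ
  econ0$costs$prs_test <- 0
  cu <- qu <- cp <- qp <- numeric(5)
  for (d in 1:5) {
    coh <- generate_cohort(cohort_spec(n = 400), seed = 500 + d)
    coh <- compute_risks(coh, ms$incidence_no_prs, ms$incidence_with_prs)
    sel <- select_target_population(coh)
    cmp <- compare_strategies(sel, ms, econ0, b$policy, seed = 600 + d)
    cu[d] <- cmp$usual$mean_cost; qu[d] <- cmp$usual$mean_qaly
    cp[d] <- cmp$prs$mean_cost; qp[d] <- cmp$prs$mean_qaly
  }
  psa <- psa_result(cu, qu, cp, qp)
  expect_identical(psa$cost_usual, psa$cost_prs)
  expect_equal(ceac(psa, c(0, 25000))$probability, c(0.5, 0.5))
  expect_equal(evpi(psa, c(0, 25000))$evpi, c(0, 0))
})

test_that("cost-neutral price offsets the incremental cost exactly", {
  expect_equal(cost_neutral_price(-253, 50), 303)
  expect_equal(cost_neutral_price(31, 50), 19)
  expect_equal(cost_neutral_price(0, 50), 50)
  expect_warning(p <- cost_neutral_price(80, 50), "negative")
  expect_equal(p, 0)
})
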