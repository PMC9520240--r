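STATE_HEALTHY <- 1L
STATE_T2D <- 2L
STATE_T2D_COMPL <- 3L
STATE_DEAD <- 4L

#' Health-state labels of the four-state model
#'
#' The model's mutually exclusive states: healthy, T2D, T2D with
#' complications, dead. Transitions run healthy -> T2D ->
#' T2D-with-complications, any state -> dead, plus self-loops; death is
#' absorbing and simulation stops at death or age 100.
#'
#' @return Character vector of state names in engine code order.
#' @export
health_states <- function() c("healthy", "t2d", "t2d_complications", "dead")

# Map state names (or already-integer codes) to engine codes.
normalize_state <- function(state) {
  if (is.numeric(state)) {
    state <- as.integer(state)
    if (any(state < 1L | state > 4L)) stop("unknown state code", call. = FALSE)
    return(state)
  }
  i <- match(as.character(state), health_states())
  if (anyNA(i)) {
    stop("unknown health state '", state[which(is.na(i))[1]], "'",
         call. = FALSE)
  }
  i
}

#' Classify a 10-year risk into screening categories
#'
#' Five ordered categories with half-open edges; the consequential edges
#' are 0.10 (entry to `high`, the band screened for PRS testing) and 0.20
#' (entry to `very_high`, the intervention trigger). A risk of exactly 0.20
#' is `very_high`. The lower edges are conventions and configurable.
#'
#' @param risk10 10-year risk(s) in `[0, 1]`.
#' @param edges increasing interior edges, default
#'   `c(0.025, 0.05, 0.10, 0.20)`.
#' @return Ordered factor with levels `very_low`, `low`, `moderate`,
#'   `high`, `very_high`.
#' @export
#' @examples
#' classify_risk(c(0.05, 0.15, 0.20))
classify_risk <- function(risk10, edges = c(0.025, 0.05, 0.10, 0.20)) {
  if (any(risk10 < 0 | risk10 > 1)) {
    stop("'risk10' must be in [0, 1]", call. = FALSE)
  }
  lv <- c("very_low", "low", "moderate", "high", "very_high")
  factor(lv[findInterval(risk10, edges) + 1L], levels = lv, ordered = TRUE)
}

#' Intervention policy parameters
#'
#' The risk threshold triggering preventive intervention, the hazard
#' ratios of the lifestyle and combined (lifestyle + medical) interventions
#' on T2D incidence, the duration of their effect, the fraction of
#' intervened individuals eligible for the added medical therapy, and
#' adherence (1 = full adherence). `medical_cost_years` sets for how many
#' years the annual medical-therapy cost is charged (the effect duration is
#' unaffected).
#'
#' @param risk_threshold 10-year risk at or above which intervention is
#'   assigned (default 0.20).
#' @param hr_lifestyle,hr_combined hazard ratios in `(0, 1]` applied to the
#'   annual T2D onset probability.
#' @param effect_duration years the intervention effect lasts (default 15).
#' @param medical_uptake probability that an intervened individual also
#'   receives medical therapy (default 0.30).
#' @param adherence probability of taking up an assigned intervention
#'   (default 1, full adherence).
#' @param medical_cost_years years the medical-therapy cost is charged
#'   (default 1).
#' @return Object of class `intervention_policy`.
#' @export
intervention_policy <- function(risk_threshold = 0.20,
                                hr_lifestyle = 0.74,
                                hr_combined = 0.51,
                                effect_duration = 15,
                                medical_uptake = 0.30,
                                adherence = 1,
                                medical_cost_years = 1) {
  stopifnot(risk_threshold >= 0, risk_threshold <= 1,
            hr_lifestyle > 0, hr_combined > 0,
            effect_duration >= 0,
            medical_uptake >= 0, medical_uptake <= 1,
            adherence >= 0, adherence <= 1,
            medical_cost_years >= 0)
  structure(
    list(risk_threshold = risk_threshold, hr_lifestyle = hr_lifestyle,
         hr_combined = hr_combined, effect_duration = effect_duration,
         medical_uptake = medical_uptake, adherence = adherence,
         medical_cost_years = medical_cost_years),
    class = "intervention_policy"
  )
}

#' Assign intervention status under a screening strategy
#'
#' The usual strategy screens on `risk10_no_prs`, the PRS strategy on
#' `risk10_with_prs`. Individuals at or above the policy threshold are
#' assigned the lifestyle intervention (subject to adherence) and
#' additionally the medical therapy with probability
#' `policy$medical_uptake`. In the pre-screened 10-20% target population
#' no one reaches the threshold without PRS, so the usual arm assigns none.
#'
#' @param cohort cohort with the risk columns from [compute_risks()].
#' @param strategy `"usual"` or `"prs"`.
#' @param policy an [intervention_policy()].
#' @param u,u_adherence uniform(0,1) draws per individual for the medical
#'   uptake and adherence decisions; fresh draws if `NULL` (supply them for
#'   common-random-number pairing).
#' @return Factor with levels `none`, `lifestyle`, `lifestyle_medical`.
#' @export
assign_intervention <- function(cohort, strategy = c("usual", "prs"),
                                policy = intervention_policy(),
                                u = NULL, u_adherence = NULL) {
  strategy <- match.arg(strategy)
  col <- if (strategy == "usual") "risk10_no_prs" else "risk10_with_prs"
  if (!col %in% names(cohort)) {
    stop("cohort lacks '", col, "'; run compute_risks() first", call. = FALSE)
  }
  risk <- cohort[[col]]
  n <- length(risk)
  if (is.null(u)) u <- stats::runif(n)
  if (is.null(u_adherence)) u_adherence <- stats::runif(n)
  status <- rep("none", n)
  take <- risk >= policy$risk_threshold & u_adherence < policy$adherence
  status[take] <- "lifestyle"
  status[take & u < policy$medical_uptake] <- "lifestyle_medical"
  factor(status, levels = c("none", "lifestyle", "lifestyle_medical"))
}

#' Intervention-adjusted annual T2D onset probability
#'
#' Applies the policy hazard ratio to the baseline annual onset
#' probability while the intervention effect lasts
#' (`years_since_start < effect_duration`); afterwards the baseline
#' probability is returned unchanged.
#'
#' @param base_p baseline annual onset probability(ies) in `[0, 1)`.
#' @param status intervention status (see [assign_intervention()]).
#' @param years_since_start completed years since intervention start
#'   (0 in the first effect year).
#' @param policy an [intervention_policy()].
#' @return Adjusted probability(ies).
#' @export
effective_t2d_prob <- function(base_p, status, years_since_start,
                               policy = intervention_policy()) {
  n <- max(length(base_p), length(status), length(years_since_start))
  base_p <- rep_len(base_p, n)
  status <- rep_len(as.character(status), n)
  years_since_start <- rep_len(years_since_start, n)
  hr <- rep(1, n)
  hr[status == "lifestyle"] <- policy$hr_lifestyle
  hr[status == "lifestyle_medical"] <- policy$hr_combined
  active <- years_since_start < policy$effect_duration & hr != 1
  out <- base_p
  out[active] <- apply_hazard_ratio(base_p[active], hr[active])
  out
}

#' One annual transition of the state machine
#'
#' Within-cycle ordering: death is drawn first; survivors then draw the
#' disease-progression event (healthy -> T2D, T2D -> complications).
#' Pure given the supplied uniforms, so paired arms can share random
#' number streams. Dead individuals pass through unchanged.
#'
#' @param state current state code(s)/name(s).
#' @param p_death,p_event annual death and progression probabilities.
#' @param u_death,u_event uniform(0,1) draws.
#' @return Integer state codes after the cycle.
#' @export
step_state <- function(state, p_death, p_event, u_death, u_event) {
  state <- normalize_state(state)
  new <- state
  alive <- state != STATE_DEAD
  dies <- alive & u_death < p_death
  new[dies] <- STATE_DEAD
  prog <- alive & !dies & u_event < p_event
  new[prog & state == STATE_HEALTHY] <- STATE_T2D
  new[prog & state == STATE_T2D] <- STATE_T2D_COMPL
  new
}

#' Pre-generate common-random-number draws for one cohort
#'
#' One uniform stream per person-year for death and progression plus one
#' per person for medical uptake and adherence. Running both strategy arms
#' on the same draws pairs them (common random numbers), reducing the
#' Monte-Carlo variance of the increments.
#'
#' @param n cohort size.
#' @param n_cycles maximum number of annual cycles.
#' @param seed integer RNG seed.
#' @return List with matrices `u_death`, `u_event` (`n` x `n_cycles`) and
#'   vectors `u_uptake`, `u_adherence`.
#' @export
make_crn_draws <- function(n, n_cycles, seed) {
  set.seed(seed)
  list(u_death = matrix(stats::runif(n * n_cycles), nrow = n),
       u_event = matrix(stats::runif(n * n_cycles), nrow = n),
       u_uptake = stats::runif(n),
       u_adherence = stats::runif(n))
}

#' Bundle of survival models used by the engine
#'
#' @param incidence_no_prs,incidence_with_prs [weibull_aft()] T2D incidence
#'   models (screening estimates without/with PRS).
#' @param complications [weibull_aft()] model of time from T2D onset to
#'   complications (clock resets at onset).
#' @param life_table a [life_table()].
#' @param adjustment a [mortality_adjustment()].
#' @param natural_history which incidence model generates the actual onset
#'   events; default `"with_prs"` (the PRS carries real signal, both arms
#'   share the same disease process and differ only in screening).
#' @return Object of class `model_set`.
#' @export
model_set <- function(incidence_no_prs, incidence_with_prs, complications,
                      life_table = default_life_table(),
                      adjustment = mortality_adjustment(),
                      natural_history = c("with_prs", "no_prs")) {
  natural_history <- match.arg(natural_history)
  stopifnot(inherits(incidence_no_prs, "weibull_aft"),
            inherits(incidence_with_prs, "weibull_aft"),
            inherits(complications, "weibull_aft"),
            inherits(life_table, "life_table"),
            inherits(adjustment, "mortality_adjustment"))
  structure(
    list(incidence_no_prs = incidence_no_prs,
         incidence_with_prs = incidence_with_prs,
         complications = complications,
         life_table = life_table,
         adjustment = adjustment,
         natural_history = natural_history),
    class = "model_set"
  )
}

# Core vectorised engine: one strategy arm over annual cycles.
# Accrual uses the state occupied at the start of each cycle (no half-cycle
# correction); transitions draw death first, then progression.
simulate_arm_core <- function(cohort, strategy, models, econ, policy, draws,
                              horizon = Inf, discount_rate = 0.03,
                              include_productivity = TRUE,
                              keep_trajectories = FALSE) {
  n <- nrow(cohort)
  if (n == 0L) stop("cohort is empty", call. = FALSE)
  age0 <- cohort$age
  sex <- cohort$sex
  max_cycles <- min(horizon, max(100 - age0))
  stopifnot(ncol(draws$u_death) >= max_cycles, nrow(draws$u_death) == n)

  status <- assign_intervention(cohort, strategy, policy,
                                u = draws$u_uptake,
                                u_adherence = draws$u_adherence)
  status_chr <- as.character(status)

  inc_model <- if (models$natural_history == "with_prs") {
    models$incidence_with_prs
  } else {
    models$incidence_no_prs
  }
  covs <- aft_covariates(cohort)
  lambda_inc <- aft_lambda(inc_model, covs)
  k_inc <- inc_model$shape
  lambda_cmp <- aft_lambda(models$complications, covs)
  k_cmp <- models$complications$shape

  state <- rep(STATE_HEALTHY, n)
  onset_cycle <- rep(NA_integer_, n)
  cost_d <- qaly_d <- numeric(n)
  life_years <- t2d_free <- compl_free <- numeric(n)
  if (keep_trajectories) {
    tr_state <- matrix(NA_integer_, n, max_cycles)
    tr_cost <- tr_util <- matrix(NA_real_, n, max_cycles)
  }

  for (t in seq_len(max_cycles)) {
    age_t <- age0 + t - 1L
    idx <- which(state != STATE_DEAD & age_t <= 99L)
    if (length(idx) == 0L) break
    df <- discount_factor(t, discount_rate)

    cost_t <- annual_cost(state[idx], age_t[idx], sex[idx], status_chr[idx],
                          t, econ$costs, include_productivity, policy)
    if (strategy == "prs" && t == 1L) {
      cost_t <- cost_t + econ$costs$prs_test
    }
    util_t <- annual_utility(state[idx], age_t[idx], sex[idx],
                             econ$utilities)
    cost_d[idx] <- cost_d[idx] + cost_t * df
    qaly_d[idx] <- qaly_d[idx] + util_t * df
    life_years[idx] <- life_years[idx] + 1
    t2d_free[idx] <- t2d_free[idx] + (state[idx] == STATE_HEALTHY)
    compl_free[idx] <- compl_free[idx] + (state[idx] != STATE_T2D_COMPL)
    if (keep_trajectories) {
      tr_state[idx, t] <- state[idx]
      tr_cost[idx, t] <- cost_t
      tr_util[idx, t] <- util_t
    }

    p_death <- mortality_prob(models$life_table, age_t[idx], sex[idx],
                              state[idx], models$adjustment)
    p_event <- numeric(length(idx))
    h <- state[idx] == STATE_HEALTHY
    if (any(h)) {
      pb <- annual_event_prob_lambda(lambda_inc[idx][h], k_inc, t - 1)
      p_event[h] <- effective_t2d_prob(pb, status_chr[idx][h], t - 1, policy)
    }
    d <- state[idx] == STATE_T2D
    if (any(d)) {
      s_onset <- t - onset_cycle[idx][d] - 1L
      p_event[d] <- annual_event_prob_lambda(lambda_cmp[idx][d], k_cmp,
                                             s_onset)
    }
    new <- step_state(state[idx], p_death, p_event,
                      draws$u_death[idx, t], draws$u_event[idx, t])
    onset_cycle[idx][new == STATE_T2D & state[idx] == STATE_HEALTHY] <- t
    state[idx] <- new
  }

  per_person <- data.frame(
    id = cohort$id, cost = cost_d, qaly = qaly_d,
    life_years = life_years, t2d_free_years = t2d_free,
    compl_free_years = compl_free,
    final_state = health_states()[state],
    status = status_chr
  )
  reclass <- if ("risk10_with_prs" %in% names(cohort)) {
    mean(cohort$risk10_with_prs >= policy$risk_threshold)
  } else NA_real_

  out <- list(
    strategy = strategy, n = n, horizon = horizon,
    discount_rate = discount_rate,
    include_productivity = include_productivity,
    mean_cost = mean(cost_d), mean_qaly = mean(qaly_d),
    mean_life_years = mean(life_years),
    mean_t2d_free_years = mean(t2d_free),
    mean_compl_free_years = mean(compl_free),
    death_fraction = mean(state == STATE_DEAD),
    reclassified_fraction = reclass,
    intervention_counts = table(status),
    per_person = per_person
  )
  if (keep_trajectories) {
    out$trajectories <- list(state = tr_state, cost = tr_cost,
                             utility = tr_util, age0 = age0,
                             onset_cycle = onset_cycle,
                             status = status_chr)
  }
  structure(out, class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm '%s': n = %d, horizon = %s, discount = %.0f%%\n",
              x$strategy, x$n,
              if (is.finite(x$horizon)) x$horizon else "lifetime",
              100 * x$discount_rate))
  cat(sprintf("  mean cost %.0f EUR, mean QALY %.3f, life-years %.2f\n",
              x$mean_cost, x$mean_qaly, x$mean_life_years))
  cat(sprintf("  T2D-free %.2f y, complication-free %.2f y, died %.1f%%\n",
              x$mean_t2d_free_years, x$mean_compl_free_years,
              100 * x$death_fraction))
  invisible(x)
}

#' Run one strategy arm over a cohort
#'
#' Simulates every individual of the target cohort through the four-state
#' model under one screening strategy and aggregates per-person discounted
#' costs, QALYs and event outcomes.
#'
#' @param cohort target-population cohort with risk columns.
#' @param strategy `"usual"` or `"prs"`.
#' @param models a [model_set()].
#' @param econ list with `costs` ([cost_parameters()]) and `utilities`
#'   ([utility_parameters()]).
#' @param policy an [intervention_policy()].
#' @param seed integer RNG seed (drives the per-person uniform streams).
#' @param horizon simulation horizon in years (`Inf` = lifetime, i.e. to
#'   death or age 100).
#' @param discount_rate annual discount rate (applies from year 2 onward).
#' @param include_productivity include productivity losses.
#' @return Object of class `arm_result`.
#' @export
run_arm <- function(cohort, strategy, models, econ = default_econ(),
                    policy = intervention_policy(), seed,
                    horizon = Inf, discount_rate = 0.03,
                    include_productivity = TRUE) {
  n <- nrow(cohort)
  if (is.null(n) || n == 0L) stop("cohort is empty", call. = FALSE)
  n_cycles <- min(horizon, max(100 - cohort$age))
  draws <- make_crn_draws(n, n_cycles, seed)
  simulate_arm_core(cohort, strategy, models, econ, policy, draws,
                    horizon, discount_rate, include_productivity)
}

#' Run both strategy arms under common random numbers
#'
#' Generates one set of per-person uniform streams and runs the usual and
#' PRS arms on it, so the two arms are paired and their increment is
#' estimated with reduced Monte-Carlo variance. Returns both arm results
#' and the incremental analysis.
#'
#' @inheritParams run_arm
#' @return List of class `strategy_comparison` with `usual`, `prs`,
#'   `incremental` (see [incremental_analysis()]) and run settings.
#' @export
compare_strategies <- function(cohort, models, econ = default_econ(),
                               policy = intervention_policy(), seed,
                               horizon = Inf, discount_rate = 0.03,
                               include_productivity = TRUE) {
  n <- nrow(cohort)
  if (is.null(n) || n == 0L) stop("cohort is empty", call. = FALSE)
  n_cycles <- min(horizon, max(100 - cohort$age))
  draws <- make_crn_draws(n, n_cycles, seed)
  usual <- simulate_arm_core(cohort, "usual", models, econ, policy, draws,
                             horizon, discount_rate, include_productivity)
  prs <- simulate_arm_core(cohort, "prs", models, econ, policy, draws,
                           horizon, discount_rate, include_productivity)
  inc <- incremental_analysis(usual$mean_cost, usual$mean_qaly,
                              prs$mean_cost, prs$mean_qaly)
  structure(
    list(usual = usual, prs = prs, incremental = inc, seed = seed,
         horizon = horizon, discount_rate = discount_rate,
         include_productivity = include_productivity),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("Strategy comparison (usual vs targeted PRS)\n")
  cat(sprintf("  usual: cost %.0f, QALY %.3f | PRS: cost %.0f, QALY %.3f\n",
              x$usual$mean_cost, x$usual$mean_qaly,
              x$prs$mean_cost, x$prs$mean_qaly))
  i <- x$incremental
  cat(sprintf("  dC = %.1f, dE = %.4f, %s\n", i$delta_cost, i$delta_qaly,
              if (is.na(i$icer)) i$label else
                sprintf("ICER = %.0f EUR/QALY", i$icer)))
  invisible(x)
}

#' Simulate a single individual and return the annual trajectory
#'
#' Runs the engine for one person (with its own random stream) and returns
#' the year-by-year record: age, state at the start of the year, years
#' since T2D onset, whether the intervention effect is active, and the
#' undiscounted annual cost and utility. The trajectory terminates at
#' death or age 100.
#'
#' @param individual one-row cohort data frame (with risk columns).
#' @inheritParams run_arm
#' @return Data frame of class `trajectory` with one row per simulated
#'   year; the arm-level summary is attached as attribute `"result"`.
#' @export
simulate_individual <- function(individual, strategy, models,
                                econ = default_econ(),
                                policy = intervention_policy(), seed,
                                horizon = Inf, discount_rate = 0.03,
                                include_productivity = TRUE) {
  stopifnot(nrow(individual) == 1L)
  n_cycles <- min(horizon, 100 - individual$age)
  draws <- make_crn_draws(1L, n_cycles, seed)
  res <- simulate_arm_core(individual, strategy, models, econ, policy,
                           draws, horizon, discount_rate,
                           include_productivity, keep_trajectories = TRUE)
  tr <- res$trajectories
  yrs <- which(!is.na(tr$state[1, ]))
  onset <- tr$onset_cycle[1]
  st <- tr$state[1, yrs]
  out <- data.frame(
    year = yrs,
    age = tr$age0[1] + yrs - 1L,
    state = health_states()[st],
    years_since_onset = ifelse(!is.na(onset) & yrs > onset,
                               yrs - onset - 1L, NA_integer_),
    intervention_active = tr$status[1] != "none" &
      (yrs - 1) < policy$effect_duration,
    cost = tr$cost[1, yrs],
    utility = tr$utility[1, yrs]
  )
  class(out) <- c("trajectory", "data.frame")
  attr(out, "result") <- res
  out
}

#' Fraction of the target population reclassified to very-high risk
#'
#' Share of target-population members whose 10-year risk including PRS
#' reaches the intervention threshold -- the individuals the PRS strategy
#' moves into the very-high-risk category that usual screening misses.
#'
#' @param cohort cohort with `risk10_with_prs`.
#' @param threshold risk threshold (default 0.20).
#' @return Fraction in `[0, 1]`.
#' @export
reclassification_rate <- function(cohort, threshold = 0.20) {
  if (!"risk10_with_prs" %in% names(cohort)) {
    stop("cohort lacks 'risk10_with_prs'", call. = FALSE)
  }
  mean(cohort$risk10_with_prs >= threshold)
}
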