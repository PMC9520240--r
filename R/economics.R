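#' Annual cost parameters (2021 euros)
#'
#' Per-state annual and one-off cost inputs: productivity losses apply only
#' while age < 65, the extra complications cost is added on top of the T2D
#' state costs, the lifestyle-intervention cost is a one-off and the medical
#' therapy an annual cost (its charging duration is a policy setting, see
#' [intervention_policy()]).
#'
#' @param productivity_t2d annual productivity loss while in a T2D state and
#'   aged under 65.
#' @param complications_extra annual extra cost of the complications state.
#' @param t2d_secondary_care annual secondary-care cost of T2D.
#' @param medical_therapy_annual annual cost of the medical weight-loss
#'   therapy.
#' @param lifestyle_intervention one-off cost of the lifestyle intervention.
#' @param prs_test unit price of the PRS test.
#' @param t2d_primary_care_male,t2d_primary_care_female annual primary-care
#'   cost of T2D by sex.
#' @param t2d_medication annual T2D medication cost.
#' @return Object of class `cost_parameters`.
#' @export
cost_parameters <- function(productivity_t2d = 7632,
                            complications_extra = 4401,
                            t2d_secondary_care = 3315,
                            medical_therapy_annual = 1965,
                            lifestyle_intervention = 650,
                            prs_test = 50,
                            t2d_primary_care_male = 562,
                            t2d_primary_care_female = 542,
                            t2d_medication = 584) {
  out <- list(productivity_t2d = productivity_t2d,
              complications_extra = complications_extra,
              t2d_secondary_care = t2d_secondary_care,
              medical_therapy_annual = medical_therapy_annual,
              lifestyle_intervention = lifestyle_intervention,
              prs_test = prs_test,
              t2d_primary_care_male = t2d_primary_care_male,
              t2d_primary_care_female = t2d_primary_care_female,
              t2d_medication = t2d_medication)
  if (any(unlist(out) < 0)) stop("costs must be non-negative", call. = FALSE)
  structure(out, class = "cost_parameters")
}

#' Utility parameters (EQ-5D-3L)
#'
#' Age-band and sex specific baseline population utilities with additive
#' disease disutilities. Bands are 30-44, 45-54, 55-64 and 65+, resolved
#' from the current (simulated) age each cycle. In the complications state
#' the two disutilities combine additively by default
#' (`baseline - disutility_t2d - disutility_complications`); set
#' `combine = "replace"` to subtract only the complications disutility.
#' Utilities are floored at 0 after subtraction.
#'
#' @param baseline_male,baseline_female numeric length-4 vectors of baseline
#'   utilities for bands 30-44, 45-54, 55-64, 65+.
#' @param disutility_t2d,disutility_complications non-negative decrements.
#' @param combine `"additive"` or `"replace"` (complications state rule).
#' @return Object of class `utility_parameters`.
#' @export
utility_parameters <- function(baseline_male = c(0.917, 0.876, 0.821, 0.781),
                               baseline_female = c(0.906, 0.865, 0.810, 0.770),
                               disutility_t2d = 0.041,
                               disutility_complications = 0.119,
                               combine = c("additive", "replace")) {
  combine <- match.arg(combine)
  stopifnot(length(baseline_male) == 4L, length(baseline_female) == 4L,
            all(baseline_male >= 0 & baseline_male <= 1),
            all(baseline_female >= 0 & baseline_female <= 1),
            disutility_t2d >= 0, disutility_complications >= 0)
  structure(
    list(baseline_male = baseline_male, baseline_female = baseline_female,
         disutility_t2d = disutility_t2d,
         disutility_complications = disutility_complications,
         combine = combine),
    class = "utility_parameters"
  )
}

# Age band index: 1 = 30-44, 2 = 45-54, 3 = 55-64, 4 = 65+.
utility_band <- function(age) findInterval(age, c(45, 55, 65)) + 1L

#' Baseline (healthy) utility by age and sex
#'
#' @param age age(s) in years.
#' @param sex `"male"`/`"female"` (recycled).
#' @param params [utility_parameters()].
#' @return Baseline utility weight(s).
#' @export
baseline_utility <- function(age, sex, params = utility_parameters()) {
  n <- max(length(age), length(sex))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  b <- utility_band(age)
  ifelse(sex == "male", params$baseline_male[b], params$baseline_female[b])
}

#' Annual cost of a person-cycle
#'
#' State costs: healthy 0; T2D = primary care (by sex) + medication +
#' secondary care + productivity loss (if aged under 65 and
#' `include_productivity`); complications add `complications_extra` on top;
#' dead 0. Intervention costs are added per policy timing: the one-off
#' lifestyle cost in year 1 for anyone on an intervention, and the annual
#' medical-therapy cost for `policy$medical_cost_years` years for those on
#' combined therapy. The PRS test price is a strategy-level charge applied
#' by the engine, not here.
#'
#' @param state health state(s) (names or engine codes).
#' @param age current age(s).
#' @param sex `"male"`/`"female"`.
#' @param status intervention status: `"none"`, `"lifestyle"`,
#'   `"lifestyle_medical"`.
#' @param year_index 1-based simulation year (scalar or vector).
#' @param params [cost_parameters()].
#' @param include_productivity include productivity losses (societal
#'   perspective) or not (health-care perspective scenario).
#' @param policy [intervention_policy()] (for cost timing).
#' @return Cost(s) in euros for the cycle.
#' @export
#' @examples
#' annual_cost("t2d", 70, "male", "none", 2)            # 562 + 584 + 3315
#' annual_cost("t2d", 60, "female", "none", 2)          # + 7632 productivity
annual_cost <- function(state, age, sex, status = "none", year_index = 1,
                        params = cost_parameters(),
                        include_productivity = TRUE,
                        policy = intervention_policy()) {
  state <- normalize_state(state)
  n <- max(length(state), length(age), length(sex), length(status),
           length(year_index))
  state <- rep_len(state, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  status <- rep_len(as.character(status), n)
  year_index <- rep_len(year_index, n)
  cost <- numeric(n)
  diseased <- state %in% c(STATE_T2D, STATE_T2D_COMPL)
  if (any(diseased)) {
    pc <- ifelse(sex[diseased] == "male",
                 params$t2d_primary_care_male, params$t2d_primary_care_female)
    cost[diseased] <- pc + params$t2d_medication + params$t2d_secondary_care
    if (include_productivity) {
      cost[diseased] <- cost[diseased] +
        ifelse(age[diseased] < 65, params$productivity_t2d, 0)
    }
    cmp <- state == STATE_T2D_COMPL
    cost[cmp] <- cost[cmp] + params$complications_extra
  }
  alive <- state != STATE_DEAD
  cost[alive & status != "none" & year_index == 1] <-
    cost[alive & status != "none" & year_index == 1] +
    params$lifestyle_intervention
  med <- alive & status == "lifestyle_medical" &
    year_index <= policy$medical_cost_years
  cost[med] <- cost[med] + params$medical_therapy_annual
  cost
}

#' Annual utility weight of a person-cycle
#'
#' Healthy: baseline utility for the current age band and sex; T2D:
#' baseline minus the T2D disutility; complications: per the combination
#' rule of [utility_parameters()]; dead: 0. Floored at 0.
#'
#' @inheritParams annual_cost
#' @param params [utility_parameters()].
#' @return Utility weight(s) in `[0, 1]`.
#' @export
#' @examples
#' annual_utility("t2d", 67, "female")  # 0.770 - 0.041
annual_utility <- function(state, age, sex, params = utility_parameters()) {
  state <- normalize_state(state)
  n <- max(length(state), length(age), length(sex))
  state <- rep_len(state, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  u <- baseline_utility(age, sex, params)
  u[state == STATE_T2D] <- u[state == STATE_T2D] - params$disutility_t2d
  cmp <- state == STATE_T2D_COMPL
  u[cmp] <- if (params$combine == "additive") {
    u[cmp] - params$disutility_t2d - params$disutility_complications
  } else {
    u[cmp] - params$disutility_complications
  }
  u[state == STATE_DEAD] <- 0
  pmax(u, 0)
}

#' Discount factor for a simulation year
#'
#' Discounting applies from the second year onward: year 1 has factor 1,
#' year `t` has `(1 + rate)^-(t - 1)`.
#'
#' @param year_index 1-based simulation year(s).
#' @param rate non-negative annual discount rate.
#' @return Discount multiplier(s).
#' @export
#' @examples
#' discount_factor(1, 0.03)  # 1
#' discount_factor(2, 0.03)  # 1 / 1.03
discount_factor <- function(year_index, rate) {
  if (any(rate < 0)) stop("discount rate must be non-negative", call. = FALSE)
  if (any(year_index < 1)) stop("'year_index' must be >= 1", call. = FALSE)
  (1 + rate)^(-(year_index - 1))
}

#' Discounted totals of a trajectory
#'
#' Sums the per-year costs and utilities of a trajectory (as produced by
#' [simulate_individual()]) weighted by [discount_factor()].
#'
#' @param trajectory data frame with columns `year`, `cost`, `utility`
#'   (zero rows allowed).
#' @param rate non-negative annual discount rate.
#' @return Named numeric vector `c(cost = ..., qaly = ...)`.
#' @export
aggregate_trajectory <- function(trajectory, rate = 0.03) {
  if (nrow(trajectory) == 0L) return(c(cost = 0, qaly = 0))
  df <- discount_factor(trajectory$year, rate)
  c(cost = sum(trajectory$cost * df), qaly = sum(trajectory$utility * df))
}
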