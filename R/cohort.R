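#' Specification of a synthetic FINRISK-like cohort
#'
#' Defines the covariate distributions from which [generate_cohort()] draws
#' adults aged 30-79 with the risk-factor structure the FINDRISC and the
#' incidence models need. Defaults emulate the screened high-risk Finnish
#' adult population (mean age 61.5, 63.9% men); age is sampled from a
#' truncated normal over `age_range`.
#'
#' @param n cohort size (positive integer).
#' @param age_mean,age_sd mean/SD of the (truncated) age distribution.
#' @param age_range integer age bounds, default `c(30, 79)`.
#' @param proportion_male fraction male in `[0, 1]`.
#' @param bmi_mean,bmi_sd body-mass-index distribution (kg/m^2, truncated
#'   below at 16).
#' @param waist_sd residual SD of waist (cm) around its BMI regression.
#' @param p_bp_medication,p_high_glucose,p_physically_active,p_daily_vegetables
#'   Bernoulli probabilities of the binary FINDRISC items.
#' @param p_family_history named probabilities over `none`,
#'   `second_degree`, `first_degree` (must sum to 1).
#' @param prs_sd SD of the raw polygenic score before sample
#'   standardization (must be positive).
#' @param seed default RNG seed used by [generate_cohort()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n,
                        age_mean = 61.5, age_sd = 10, age_range = c(30L, 79L),
                        proportion_male = 0.639,
                        bmi_mean = 28, bmi_sd = 4.5,
                        waist_sd = 7,
                        p_bp_medication = 0.35,
                        p_high_glucose = 0.15,
                        p_physically_active = 0.55,
                        p_daily_vegetables = 0.45,
                        p_family_history = c(none = 0.55,
                                             second_degree = 0.20,
                                             first_degree = 0.25),
                        prs_sd = 1,
                        seed = NULL) {
  stopifnot(length(n) == 1L, n >= 1, proportion_male >= 0,
            proportion_male <= 1, age_range[1] < age_range[2])
  if (age_sd <= 0 || bmi_sd <= 0) {
    stop("age and BMI distributions require positive variance", call. = FALSE)
  }
  if (prs_sd <= 0) {
    stop("'prs_sd' must be positive (degenerate PRS distribution)",
         call. = FALSE)
  }
  if (abs(sum(p_family_history) - 1) > 1e-8 ||
      !setequal(names(p_family_history),
                c("none", "second_degree", "first_degree"))) {
    stop("'p_family_history' must be named probabilities over ",
         "none/second_degree/first_degree summing to 1", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
         age_range = as.integer(age_range),
         proportion_male = proportion_male,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd, waist_sd = waist_sd,
         p_bp_medication = p_bp_medication,
         p_high_glucose = p_high_glucose,
         p_physically_active = p_physically_active,
         p_daily_vegetables = p_daily_vegetables,
         p_family_history = p_family_history,
         prs_sd = prs_sd, seed = seed),
    class = "cohort_spec"
  )
}

# Truncated-normal draws via inverse-CDF; exact truncation, no rejection.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic cohort of individuals
#'
#' Draws `spec$n` individuals with FINDRISC covariates, computes their
#' FINDRISC scores and a standardized polygenic risk score. The PRS is
#' drawn `Normal(0, prs_sd)` and then sample-standardized, so the returned
#' scores have sample mean exactly 0 and sample SD exactly 1. Reproducible:
#' the same spec and seed give a bit-identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed; defaults to `spec$seed` (required).
#' @param items FINDRISC item table, see [findrisc_items()].
#' @return Data frame of class `t2d_cohort`, one row per individual, with
#'   columns `id`, `age`, `sex`, `bmi`, `waist`, `bp_medication`,
#'   `history_high_glucose`, `physically_active`, `daily_vegetables`,
#'   `family_history`, `findrisc`, `prs`.
#' @export
generate_cohort <- function(spec, seed = spec$seed, items = findrisc_items()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) stop("a seed is required for cohort generation",
                          call. = FALSE)
  set.seed(seed)
  n <- spec$n
  if (n < 2L) stop("PRS standardization requires n >= 2", call. = FALSE)
  age <- round(rtruncnorm(n, spec$age_mean, spec$age_sd,
                          spec$age_range[1] - 0.5, spec$age_range[2] + 0.5))
  age <- as.integer(pmin(pmax(age, spec$age_range[1]), spec$age_range[2]))
  sex <- ifelse(stats::runif(n) < spec$proportion_male, "male", "female")
  bmi <- round(rtruncnorm(n, spec$bmi_mean, spec$bmi_sd, 16, Inf), 1)
  waist <- round(2.5 * bmi + ifelse(sex == "male", 28, 18) +
                   stats::rnorm(n, 0, spec$waist_sd), 1)
  bp_medication <- stats::runif(n) < spec$p_bp_medication
  history_high_glucose <- stats::runif(n) < spec$p_high_glucose
  physically_active <- stats::runif(n) < spec$p_physically_active
  daily_vegetables <- stats::runif(n) < spec$p_daily_vegetables
  family_history <- sample(names(spec$p_family_history), n, replace = TRUE,
                           prob = spec$p_family_history)
  prs_raw <- stats::rnorm(n, 0, spec$prs_sd)
  s <- stats::sd(prs_raw)
  if (!is.finite(s) || s == 0) {
    stop("degenerate PRS draw: zero sample variance", call. = FALSE)
  }
  prs <- (prs_raw - mean(prs_raw)) / s
  out <- data.frame(
    id = seq_len(n), age = age, sex = sex, bmi = bmi, waist = waist,
    bp_medication = bp_medication,
    history_high_glucose = history_high_glucose,
    physically_active = physically_active,
    daily_vegetables = daily_vegetables,
    family_history = family_history,
    prs = prs,
    stringsAsFactors = FALSE
  )
  out$findrisc <- findrisc_score(out, items)
  class(out) <- c("t2d_cohort", "data.frame")
  attr(out, "spec") <- spec
  out
}

# Design frame consumed by the incidence models: age, male indicator,
# FINDRISC points and standardized PRS.
aft_covariates <- function(cohort) {
  data.frame(age = cohort$age,
             male = as.numeric(cohort$sex == "male"),
             findrisc = cohort$findrisc,
             prs = cohort$prs)
}

#' Attach 10-year T2D risks to a cohort
#'
#' Evaluates the incidence models with and without PRS for each individual
#' and stores `risk10_no_prs` and `risk10_with_prs`.
#'
#' @param cohort a `t2d_cohort` (or compatible data frame).
#' @param model_no_prs,model_with_prs [weibull_aft()] incidence models; the
#'   no-PRS model uses age, sex and FINDRISC, the with-PRS model adds the
#'   standardized PRS.
#' @param horizon risk horizon in years (default 10).
#' @return The cohort with the two risk columns added.
#' @export
compute_risks <- function(cohort, model_no_prs, model_with_prs, horizon = 10) {
  covs <- aft_covariates(cohort)
  cohort$risk10_no_prs <- risk_over(model_no_prs, covs, horizon)
  cohort$risk10_with_prs <- risk_over(model_with_prs, covs, horizon)
  cohort
}

#' Select the high-risk target population
#'
#' Retains individuals whose 10-year risk without PRS lies in the half-open
#' band `[band[1], band[2])` -- by default 10% to (but excluding) 20%, the
#' screened high-risk group eligible for PRS testing. The retention
#' fraction is stored in the `"retention"` attribute. Idempotent.
#'
#' @param cohort cohort with a `risk10_no_prs` column (see
#'   [compute_risks()]).
#' @param band length-2 numeric, half-open risk interval.
#' @return The retained subset (possibly empty, with a warning).
#' @export
select_target_population <- function(cohort, band = c(0.10, 0.20)) {
  if (!"risk10_no_prs" %in% names(cohort)) {
    stop("cohort lacks 'risk10_no_prs'; run compute_risks() first",
         call. = FALSE)
  }
  keep <- cohort$risk10_no_prs >= band[1] & cohort$risk10_no_prs < band[2]
  if (!any(keep)) {
    warning("no individuals fall in the risk band [", band[1], ", ",
            band[2], ")", call. = FALSE)
  }
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retention") <- mean(keep)
  attr(out, "spec") <- attr(cohort, "spec")
  class(out) <- class(cohort)
  out
}

#' Simulate right-censored follow-up from a known incidence model
#'
#' Draws event times from a true Weibull AFT model for each cohort member
#' and right-censors them at `years`. Used to generate survival data whose
#' refit recovers the true coefficients (parameter-recovery testing of
#' [fit_aft()]).
#'
#' @param cohort a `t2d_cohort`.
#' @param true_model a [weibull_aft()] generating the event times.
#' @param years censoring horizon (default 10).
#' @param seed integer RNG seed.
#' @return Data frame with `id`, `time` in `(0, years]` and `event`
#'   (1 = event, 0 = censored).
#' @export
simulate_followup <- function(cohort, true_model, years = 10, seed) {
  stopifnot(inherits(true_model, "weibull_aft"))
  set.seed(seed)
  lambda <- aft_lambda(true_model, aft_covariates(cohort))
  u <- stats::runif(nrow(cohort))
  tt <- lambda * (-log(u))^true_model$scale  # S(T) = U inversion
  event <- as.integer(tt <= years)
  data.frame(id = cohort$id, time = pmin(tt, years), event = event)
}

#' Generate a cohort already restricted to the target risk band
#'
#' Repeatedly generates raw cohorts, computes risks and applies
#' [select_target_population()] until `n_target` members of the band have
#' accumulated; the result is trimmed to exactly `n_target` rows and given
#' fresh ids. The overall retention fraction observed while generating is
#' stored in the `"retention"` attribute.
#'
#' @param n_target number of target-population members required.
#' @param spec a [cohort_spec()] (its `n` is ignored; batch sizes are
#'   chosen adaptively).
#' @param model_no_prs,model_with_prs incidence models for
#'   [compute_risks()].
#' @param seed integer RNG seed.
#' @param band risk band, see [select_target_population()].
#' @param max_batches safety bound on the number of generation rounds.
#' @return A `t2d_cohort` of exactly `n_target` rows with risk columns.
#' @export
generate_target_cohort <- function(n_target, spec, model_no_prs,
                                   model_with_prs, seed,
                                   band = c(0.10, 0.20),
                                   max_batches = 50L) {
  stopifnot(n_target >= 1)
  set.seed(seed)
  got <- list(); n_got <- 0L; n_raw <- 0L
  retention <- 0.105  # initial guess, updated from observed batches
  for (b in seq_len(max_batches)) {
    batch_n <- max(200L, ceiling(1.2 * (n_target - n_got) /
                                   max(retention, 0.005)))
    bs <- spec; bs$n <- as.integer(batch_n)
    raw <- generate_cohort(bs, seed = sample.int(.Machine$integer.max, 1))
    raw <- compute_risks(raw, model_no_prs, model_with_prs)
    sel <- suppressWarnings(select_target_population(raw, band))
    n_raw <- n_raw + nrow(raw)
    if (nrow(sel) > 0) {
      got[[length(got) + 1L]] <- sel
      n_got <- n_got + nrow(sel)
    }
    retention <- max(n_got / n_raw, 0.001)
    if (n_got >= n_target) break
  }
  if (n_got < n_target) {
    stop("could not accumulate ", n_target, " target individuals in ",
         max_batches, " batches (retention ", signif(retention, 3), ")",
         call. = FALSE)
  }
  out <- do.call(rbind, got)[seq_len(n_target), , drop = FALSE]
  out$id <- seq_len(n_target)
  rownames(out) <- NULL
  class(out) <- c("t2d_cohort", "data.frame")
  attr(out, "retention") <- n_got / n_raw
  attr(out, "spec") <- spec
  out
}
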