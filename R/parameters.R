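#' Load the structured model parameter file
#'
#' Reads a YAML document mirroring the model's input tables: clinical
#' hazard ratios, costs, utilities (each with its PSA distribution family,
#' SE and, where published, CI), the intervention policy and the discount
#' rate. With `path = NULL` the packaged default file
#' (`extdata/default_parameters.yaml`) is loaded.
#'
#' @param path path to a YAML parameter file, or `NULL` for the default.
#' @return Nested named list of parameters.
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_parameters.yaml",
                        package = "prsmicrosim", mustWork = TRUE)
  }
  yaml::read_yaml(path)
}

#' @rdname load_parameters
#' @export
default_parameters <- function() load_parameters(NULL)

#' Build the economics inputs from a parameter list
#'
#' @param par parameter list from [load_parameters()].
#' @return List with `costs` ([cost_parameters()]) and `utilities`
#'   ([utility_parameters()]).
#' @export
econ_from_parameters <- function(par = default_parameters()) {
  co <- par$costs
  ut <- par$utilities
  list(
    costs = cost_parameters(
      productivity_t2d = co$productivity_t2d$value,
      complications_extra = co$complications_extra$value,
      t2d_secondary_care = co$t2d_secondary_care$value,
      medical_therapy_annual = co$medical_therapy_annual$value,
      lifestyle_intervention = co$lifestyle_intervention$value,
      prs_test = co$prs_test$value,
      t2d_primary_care_male = co$t2d_primary_care_male$value,
      t2d_primary_care_female = co$t2d_primary_care_female$value,
      t2d_medication = co$t2d_medication$value
    ),
    utilities = utility_parameters(
      baseline_male = vapply(ut$baseline$male, `[[`, numeric(1), "value"),
      baseline_female = vapply(ut$baseline$female, `[[`, numeric(1), "value"),
      disutility_t2d = ut$disutility_t2d$value,
      disutility_complications = ut$disutility_complications$value
    )
  )
}

#' @rdname econ_from_parameters
#' @export
default_econ <- function() econ_from_parameters(default_parameters())

#' Build the intervention policy from a parameter list
#'
#' @inheritParams econ_from_parameters
#' @return An [intervention_policy()].
#' @export
policy_from_parameters <- function(par = default_parameters()) {
  p <- par$policy
  intervention_policy(
    risk_threshold = p$risk_threshold,
    hr_lifestyle = par$clinical$hr_lifestyle$value,
    hr_combined = par$clinical$hr_combined$value,
    effect_duration = p$effect_duration_years,
    medical_uptake = p$medical_uptake,
    adherence = p$adherence,
    medical_cost_years = p$medical_cost_years
  )
}

#' Build the mortality adjustment from a parameter list
#'
#' @inheritParams econ_from_parameters
#' @return A [mortality_adjustment()].
#' @export
adjustment_from_parameters <- function(par = default_parameters()) {
  cl <- par$clinical
  mortality_adjustment(
    hr_t2d_female = cl$hr_mortality_t2d_female$value,
    hr_t2d_male = cl$hr_mortality_t2d_male$value,
    hr_complications = cl$hr_mortality_complications$value,
    complications_on_top = isTRUE(par$policy$complications_hr_on_top)
  )
}

#' Load AFT model coefficient sets from a YAML document
#'
#' The document must carry the parameterization tag
#' `weibull_aft_logtime` (the convention of [weibull_aft()]) and one entry
#' per model with `intercept`, `scale` and a `coefficients` map. With
#' `path = NULL` the packaged synthetic default
#' (`extdata/aft_models_synthetic.yaml`) is loaded: stipulated synthetic
#' coefficients calibrated to the generator, not estimates from any
#' registry dataset.
#'
#' @param path path to a YAML model file, or `NULL` for the default.
#' @return Named list of [weibull_aft()] models (`incidence_no_prs`,
#'   `incidence_with_prs`, `complications`).
#' @export
load_aft_models <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aft_models_synthetic.yaml",
                        package = "prsmicrosim", mustWork = TRUE)
  }
  doc <- yaml::read_yaml(path)
  if (!identical(doc$parameterization, "weibull_aft_logtime")) {
    stop("model file must declare parameterization 'weibull_aft_logtime'",
         call. = FALSE)
  }
  nm <- setdiff(names(doc), c("parameterization", "note"))
  out <- lapply(doc[nm], function(m) {
    weibull_aft(m$intercept, unlist(m$coefficients), m$scale)
  })
  names(out) <- nm
  out
}

#' Default model set (synthetic coefficients + synthetic life table)
#'
#' @return A [model_set()] built from the packaged synthetic AFT
#'   coefficient sets, the synthetic life table and the default mortality
#'   adjustment.
#' @param par parameter list from [load_parameters()].
#' @export
default_models <- function(par = default_parameters()) {
  m <- load_aft_models(NULL)
  model_set(m$incidence_no_prs, m$incidence_with_prs, m$complications,
            life_table = default_life_table(),
            adjustment = adjustment_from_parameters(par))
}

#' PSA distributions for every uncertain parameter
#'
#' Builds the full list of [param_distribution()] objects from a parameter
#' list: lognormal for hazard ratios, gamma for costs, beta for utilities
#' and disutilities (explicit shape parameters where the source publishes
#' them), fixed for the medical-therapy cost and the PRS test price.
#'
#' @inheritParams econ_from_parameters
#' @return Named list of [param_distribution()] objects.
#' @export
psa_distributions <- function(par = default_parameters()) {
  cl <- par$clinical; co <- par$costs; ut <- par$utilities
  mk <- function(name, row) {
    param_distribution(name, row$family, row$value, row$se,
                       ci = row$ci,
                       shape1 = row$shape1, shape2 = row$shape2)
  }
  out <- list(
    hr_lifestyle = mk("hr_lifestyle", cl$hr_lifestyle),
    hr_combined = mk("hr_combined", cl$hr_combined),
    hr_mortality_t2d_female = mk("hr_mortality_t2d_female",
                                 cl$hr_mortality_t2d_female),
    hr_mortality_t2d_male = mk("hr_mortality_t2d_male",
                               cl$hr_mortality_t2d_male),
    hr_mortality_complications = mk("hr_mortality_complications",
                                    cl$hr_mortality_complications),
    cost_productivity_t2d = mk("cost_productivity_t2d", co$productivity_t2d),
    cost_complications_extra = mk("cost_complications_extra",
                                  co$complications_extra),
    cost_t2d_secondary_care = mk("cost_t2d_secondary_care",
                                 co$t2d_secondary_care),
    cost_medical_therapy_annual = mk("cost_medical_therapy_annual",
                                     co$medical_therapy_annual),
    cost_lifestyle_intervention = mk("cost_lifestyle_intervention",
                                     co$lifestyle_intervention),
    cost_prs_test = mk("cost_prs_test", co$prs_test),
    cost_t2d_primary_care_male = mk("cost_t2d_primary_care_male",
                                    co$t2d_primary_care_male),
    cost_t2d_primary_care_female = mk("cost_t2d_primary_care_female",
                                      co$t2d_primary_care_female),
    cost_t2d_medication = mk("cost_t2d_medication", co$t2d_medication),
    disutility_t2d = mk("disutility_t2d", ut$disutility_t2d),
    disutility_complications = mk("disutility_complications",
                                  ut$disutility_complications)
  )
  for (sx in c("male", "female")) {
    for (band in names(ut$baseline[[sx]])) {
      nm <- paste0("u_", sx, "_", band)
      out[[nm]] <- mk(nm, c(ut$baseline[[sx]][[band]], family = "beta"))
    }
  }
  out
}

# Rebuild the engine inputs (econ, policy, adjustment) from one PSA draw,
# keeping non-sampled policy settings from the base policy.
psa_inputs_from_draw <- function(draw, base_policy = intervention_policy(),
                                 complications_on_top = FALSE) {
  bands <- c("30-44", "45-54", "55-64", "65+")
  list(
    econ = list(
      costs = cost_parameters(
        productivity_t2d = draw[["cost_productivity_t2d"]],
        complications_extra = draw[["cost_complications_extra"]],
        t2d_secondary_care = draw[["cost_t2d_secondary_care"]],
        medical_therapy_annual = draw[["cost_medical_therapy_annual"]],
        lifestyle_intervention = draw[["cost_lifestyle_intervention"]],
        prs_test = draw[["cost_prs_test"]],
        t2d_primary_care_male = draw[["cost_t2d_primary_care_male"]],
        t2d_primary_care_female = draw[["cost_t2d_primary_care_female"]],
        t2d_medication = draw[["cost_t2d_medication"]]
      ),
      utilities = utility_parameters(
        baseline_male = unname(draw[paste0("u_male_", bands)]),
        baseline_female = unname(draw[paste0("u_female_", bands)]),
        disutility_t2d = draw[["disutility_t2d"]],
        disutility_complications = draw[["disutility_complications"]]
      )
    ),
    policy = intervention_policy(
      risk_threshold = base_policy$risk_threshold,
      hr_lifestyle = draw[["hr_lifestyle"]],
      hr_combined = draw[["hr_combined"]],
      effect_duration = base_policy$effect_duration,
      medical_uptake = base_policy$medical_uptake,
      adherence = base_policy$adherence,
      medical_cost_years = base_policy$medical_cost_years
    ),
    adjustment = mortality_adjustment(
      hr_t2d_female = draw[["hr_mortality_t2d_female"]],
      hr_t2d_male = draw[["hr_mortality_t2d_male"]],
      hr_complications = draw[["hr_mortality_complications"]],
      complications_on_top = complications_on_top
    )
  )
}
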