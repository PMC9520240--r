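# Shared fixtures: small deterministic models and cohorts built in code.

# Half-up rounding, matching how published tables round .5 values.
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# A profile scoring zero on every FINDRISC item.
zero_profile <- function() {
  list(age = 40, sex = "male", bmi = 22, waist = 90,
       physically_active = TRUE, daily_vegetables = TRUE,
       bp_medication = FALSE, history_high_glucose = FALSE,
       family_history = "none")
}

# Flat life table: constant annual death probability at every age/sex.
flat_life_table <- function(q = 0.01, ages = 30:100) {
  life_table(data.frame(
    age = rep(ages, 2),
    sex = rep(c("male", "female"), each = length(ages)),
    qx = q
  ))
}

# Cohort-shaped data frame with directly stipulated risks (no generation).
stub_cohort <- function(risk_no_prs, risk_with_prs = risk_no_prs,
                        age = 60, sex = "male") {
  n <- length(risk_no_prs)
  data.frame(id = seq_len(n), age = rep_len(age, n),
             sex = rep_len(sex, n), findrisc = 12, prs = 0,
             risk10_no_prs = risk_no_prs,
             risk10_with_prs = risk_with_prs)
}

# Default synthetic model bundle plus a variant with the PRS effect nulled
# (used for the common-random-numbers equivalence checks).
default_bundle <- function() {
  m <- load_aft_models()
  list(
    raw = m,
    models = model_set(m$incidence_no_prs, m$incidence_with_prs,
                       m$complications),
    econ = default_econ(),
    policy = policy_from_parameters(default_parameters())
  )
}

null_prs_models <- function(m = load_aft_models()) {
  mnull <- weibull_aft(m$incidence_with_prs$intercept,
                       replace(m$incidence_with_prs$coefficients, "prs", 0),
                       m$incidence_with_prs$scale)
  model_set(m$incidence_no_prs, mnull, m$complications)
}

# Target cohort under the default generator and synthetic models.
default_target_cohort <- function(n, seed) {
  m <- load_aft_models()
  generate_target_cohort(n, cohort_spec(n = 1000), m$incidence_no_prs,
                         m$incidence_with_prs, seed = seed)
}
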