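#' Run configuration for the simulation pipeline
#'
#' Bundles everything a full run needs: the master seed, cohort sizes, the
#' discounting and horizon settings, the costing perspective, the PRS test
#' price, the WTP grid and (optionally) paths to a parameter file and an
#' output directory. All downstream randomness derives from `seed`.
#'
#' @param seed master integer seed.
#' @param n_per_arm individuals per strategy arm (one shared cohort is
#'   simulated through both arms under common random numbers).
#' @param n_draws number of PSA parameter draws.
#' @param discount_rate annual discount rate (base case 0.03).
#' @param horizon `Inf` for lifetime, or a year count (e.g. 10, 20).
#' @param include_productivity include productivity losses (societal
#'   perspective).
#' @param prs_test_price unit price of the PRS test in euros.
#' @param wtp_grid willingness-to-pay grid for CEAC/EVPI (EUR/QALY).
#' @param parameter_file optional path to a YAML parameter file
#'   (default: packaged values).
#' @param model_file optional path to a YAML AFT coefficient file
#'   (default: packaged synthetic coefficients).
#' @param output_dir optional directory for CSV/JSON artifacts.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_per_arm = 1000L, n_draws = 100L,
                       discount_rate = 0.03, horizon = Inf,
                       include_productivity = TRUE,
                       prs_test_price = 50,
                       wtp_grid = seq(0, 100000, by = 2500),
                       parameter_file = NULL, model_file = NULL,
                       output_dir = NULL) {
  stopifnot(n_per_arm >= 1, n_draws >= 1, discount_rate >= 0,
            horizon > 0, prs_test_price >= 0, all(wtp_grid >= 0),
            !is.unsorted(wtp_grid))
  if (!is.null(parameter_file) && !file.exists(parameter_file)) {
    stop("parameter_file does not exist: ", parameter_file, call. = FALSE)
  }
  if (!is.null(model_file) && !file.exists(model_file)) {
    stop("model_file does not exist: ", model_file, call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_per_arm = as.integer(n_per_arm),
         n_draws = as.integer(n_draws), discount_rate = discount_rate,
         horizon = horizon, include_productivity = include_productivity,
         prs_test_price = prs_test_price, wtp_grid = wtp_grid,
         parameter_file = parameter_file, model_file = model_file,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Unknown fields are rejected with an error naming the field.
#'
#' @param path path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vals$horizon) && identical(vals$horizon, "lifetime")) {
    vals$horizon <- Inf
  }
  do.call(run_config, vals)
}

# Deterministic sub-seeds derived from the master seed, all < 2^31.
derive_seeds <- function(seed, n, salt = 0L) {
  set.seed(seed + salt)
  sample.int(.Machine$integer.max - 1L, n)
}

# Assemble models/econ/policy/spec for a config at base-case values.
build_inputs <- function(config) {
  par <- load_parameters(config$parameter_file)
  par$costs$prs_test$value <- config$prs_test_price
  m <- load_aft_models(config$model_file)
  models <- model_set(m$incidence_no_prs, m$incidence_with_prs,
                      m$complications,
                      life_table = default_life_table(),
                      adjustment = adjustment_from_parameters(par))
  list(par = par, models = models, econ = econ_from_parameters(par),
       policy = policy_from_parameters(par), spec = cohort_spec(n = 1000))
}

run_metadata <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL  # hash the analytic settings, not where they land
  cfg$horizon <- if (is.finite(cfg$horizon)) cfg$horizon else "lifetime"
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  list(seed = config$seed,
       config_hash = unname(tools::md5sum(tmp)),
       horizon = if (is.finite(config$horizon)) config$horizon else "lifetime",
       discount_rate = config$discount_rate,
       include_productivity = config$include_productivity,
       n_per_arm = config$n_per_arm)
}

write_json_artifact <- function(x, dir, name) {
  jsonlite::write_json(x, file.path(dir, name), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
}

#' Base-case deterministic analysis
#'
#' Generates the target cohort, simulates both strategy arms at the
#' base-case parameter values under common random numbers, and returns the
#' expected costs, QALYs, incremental results and the cost-neutral PRS
#' price. With `output_dir` set, writes `base_case.json` (aggregates plus
#' seed and config hash) and `base_case_individuals.csv` (one row per
#' individual and arm).
#'
#' @param config a [run_config()].
#' @return List of class `base_case_result` with `table` (one row per
#'   strategy), `comparison` (a [compare_strategies()] result),
#'   `reclassification`, `cost_neutral_price` and `metadata`.
#' @export
run_base_case <- function(config = run_config()) {
  inp <- build_inputs(config)
  seeds <- derive_seeds(config$seed, 2L, salt = 101L)
  cohort <- generate_target_cohort(config$n_per_arm, inp$spec,
                                   inp$models$incidence_no_prs,
                                   inp$models$incidence_with_prs,
                                   seed = seeds[1])
  comp <- compare_strategies(cohort, inp$models, inp$econ, inp$policy,
                             seed = seeds[2], horizon = config$horizon,
                             discount_rate = config$discount_rate,
                             include_productivity = config$include_productivity)
  inc <- comp$incremental
  tab <- data.frame(
    strategy = c("usual", "prs"),
    cost = c(comp$usual$mean_cost, comp$prs$mean_cost),
    qaly = c(comp$usual$mean_qaly, comp$prs$mean_qaly),
    t2d_free_years = c(comp$usual$mean_t2d_free_years,
                       comp$prs$mean_t2d_free_years),
    compl_free_years = c(comp$usual$mean_compl_free_years,
                         comp$prs$mean_compl_free_years),
    death_fraction = c(comp$usual$death_fraction, comp$prs$death_fraction)
  )
  out <- structure(
    list(table = tab, comparison = comp,
         reclassification = reclassification_rate(cohort,
                                                  inp$policy$risk_threshold),
         cost_neutral_price = cost_neutral_price(inc$delta_cost,
                                                 config$prs_test_price),
         metadata = run_metadata(config)),
    class = "base_case_result"
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    agg <- list(metadata = out$metadata, strategies = tab,
                incremental = inc[c("delta_cost", "delta_qaly", "label")],
                icer = inc$icer,
                reclassification = out$reclassification,
                cost_neutral_price = out$cost_neutral_price)
    write_json_artifact(agg, config$output_dir, "base_case.json")
    pp <- rbind(cbind(arm = "usual", comp$usual$per_person),
                cbind(arm = "prs", comp$prs$per_person))
    utils::write.csv(pp,
                     file.path(config$output_dir, "base_case_individuals.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.base_case_result <- function(x, ...) {
  print(x$comparison)
  cat(sprintf("  reclassified to very-high risk: %.1f%%\n",
              100 * x$reclassification))
  cat(sprintf("  cost-neutral PRS price: %.0f EUR\n", x$cost_neutral_price))
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Outer loop over parameter draws: each draw samples one complete
#' parameter set from the PSA distributions, generates a fresh target
#' cohort, simulates both arms under common random numbers and records the
#' per-arm expected costs and QALYs (individual-level noise is averaged
#' within the draw). CEAC and EVPI are then computed on the WTP grid. With
#' `output_dir` set, writes `psa_draws.csv`, `ceac.csv`, `evpi.csv` and
#' `psa_summary.json`.
#'
#' @param config a [run_config()].
#' @return List of class `psa_run` with `psa` (a [psa_result()]), `ceac`,
#'   `evpi`, `prob_dominant` (CEAC at WTP 0), `mean_incremental` and
#'   `metadata`.
#' @export
run_psa <- function(config = run_config()) {
  inp <- build_inputs(config)
  dists <- psa_distributions(inp$par)
  nd <- config$n_draws
  seeds <- matrix(derive_seeds(config$seed, 3L * nd, salt = 202L), ncol = 3)
  cu <- qu <- cp <- qp <- numeric(nd)
  for (d in seq_len(nd)) {
    set.seed(seeds[d, 1])
    draw <- sample_parameters(dists)
    di <- psa_inputs_from_draw(draw, inp$policy,
                               inp$models$adjustment$complications_on_top)
    di$econ$costs$prs_test <- config$prs_test_price
    models_d <- inp$models
    models_d$adjustment <- di$adjustment
    cohort <- generate_target_cohort(config$n_per_arm, inp$spec,
                                     inp$models$incidence_no_prs,
                                     inp$models$incidence_with_prs,
                                     seed = seeds[d, 2])
    comp <- compare_strategies(cohort, models_d, di$econ, di$policy,
                               seed = seeds[d, 3], horizon = config$horizon,
                               discount_rate = config$discount_rate,
                               include_productivity =
                                 config$include_productivity)
    cu[d] <- comp$usual$mean_cost; qu[d] <- comp$usual$mean_qaly
    cp[d] <- comp$prs$mean_cost; qp[d] <- comp$prs$mean_qaly
  }
  psa <- psa_result(cu, qu, cp, qp)
  ce <- ceac(psa, config$wtp_grid)
  ev <- evpi(psa, config$wtp_grid)
  out <- structure(
    list(psa = psa, ceac = ce, evpi = ev,
         prob_dominant = ce$probability[ce$wtp == 0],
         mean_incremental = incremental_analysis(mean(cu), mean(qu),
                                                 mean(cp), mean(qp)),
         metadata = run_metadata(config)),
    class = "psa_run"
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(psa, file.path(config$output_dir, "psa_draws.csv"),
                     row.names = FALSE)
    utils::write.csv(ce, file.path(config$output_dir, "ceac.csv"),
                     row.names = FALSE)
    utils::write.csv(ev, file.path(config$output_dir, "evpi.csv"),
                     row.names = FALSE)
    write_json_artifact(
      list(metadata = out$metadata, n_draws = nd,
           prob_dominant_at_wtp0 = out$prob_dominant,
           evpi_at_wtp0 = ev$evpi[ev$wtp == 0],
           mean_incremental = out$mean_incremental[
             c("delta_cost", "delta_qaly", "label")]),
      config$output_dir, "psa_summary.json")
  }
  out
}

#' @export
print.psa_run <- function(x, ...) {
  cat(sprintf("PSA: %d draws\n", nrow(x$psa)))
  mi <- x$mean_incremental
  cat(sprintf("  mean dC = %.1f EUR, mean dE = %.4f QALY (%s)\n",
              mi$delta_cost, mi$delta_qaly, mi$label))
  cat(sprintf("  P(PRS cost-effective | WTP 0) = %.1f%%, EVPI(0) = %.0f EUR\n",
              100 * x$prob_dominant, x$evpi$evpi[x$evpi$wtp == 0]))
  invisible(x)
}

#' Deterministic scenario analyses
#'
#' Reruns the base-case comparison under the prespecified scenario grid:
#' base case, 0% and 5% discounting, exclusion of productivity costs, and
#' 10- and 20-year horizons. Every row reports the incremental cost and
#' QALYs, the ICER or dominance label, and the cost-neutral PRS price
#' (which satisfies `cost_neutral = test_price - delta_cost` by
#' construction). A failing scenario is reported with its error message
#' without aborting the rest. With `output_dir` set, writes
#' `scenarios.csv`.
#'
#' @param config a [run_config()] (its `discount_rate`, `horizon` and
#'   `include_productivity` define the base case).
#' @return Data frame of class `scenario_table`, one row per scenario.
#' @export
run_scenarios <- function(config = run_config()) {
  scen <- list(
    base_case = list(),
    discount_0 = list(discount_rate = 0),
    discount_5 = list(discount_rate = 0.05),
    no_productivity = list(include_productivity = FALSE),
    horizon_10 = list(horizon = 10),
    horizon_20 = list(horizon = 20)
  )
  rows <- lapply(names(scen), function(nm) {
    cfg <- config
    for (f in names(scen[[nm]])) cfg[[f]] <- scen[[nm]][[f]]
    res <- tryCatch(run_base_case(cfg), error = identity)
    if (inherits(res, "error")) {
      return(data.frame(scenario = nm, delta_cost = NA_real_,
                        delta_qaly = NA_real_, icer = NA_real_,
                        label = NA_character_,
                        cost_neutral_price = NA_real_,
                        seed = cfg$seed, error = conditionMessage(res)))
    }
    inc <- res$comparison$incremental
    data.frame(scenario = nm, delta_cost = inc$delta_cost,
               delta_qaly = inc$delta_qaly, icer = inc$icer,
               label = inc$label,
               cost_neutral_price = res$cost_neutral_price,
               seed = cfg$seed, error = NA_character_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_table", "data.frame")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config$output_dir, "scenarios.csv"),
                     row.names = FALSE)
  }
  out
}
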