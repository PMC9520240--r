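#' Weibull accelerated-failure-time survival model
#'
#' Container for a Weibull AFT model in the log-time parameterization
#' `S(t | x) = exp(-(t / lambda(x))^k)` with scale function
#' `lambda(x) = exp(intercept + x . beta)` and shape `k = 1 / scale`,
#' where `scale` is the AFT log-time scale parameter (as reported by
#' [survival::survreg()]). `scale = 1` gives the exponential special case.
#'
#' @param intercept real; intercept of the linear predictor on log-time.
#' @param coefficients named numeric vector of covariate effects on
#'   log-time (negative values accelerate failure, i.e. increase risk).
#' @param scale positive real; AFT scale parameter, shape is `1/scale`.
#' @return Object of class `weibull_aft`.
#' @export
#' @examples
#' m <- weibull_aft(intercept = log(20), scale = 1 / 1.5)
#' survival_at(m, NULL, 10)  # exp(-0.5^1.5)
weibull_aft <- function(intercept, coefficients = numeric(0), scale = 1) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(scale), length(scale) == 1L)
  if (!is.finite(scale) || scale <= 0) {
    stop("'scale' must be a positive number", call. = FALSE)
  }
  coefficients <- unlist(coefficients)
  if (length(coefficients) > 0) {
    if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
      stop("'coefficients' must be named", call. = FALSE)
    }
    if (anyDuplicated(names(coefficients))) {
      stop("covariate names must be unique", call. = FALSE)
    }
  }
  structure(
    list(intercept = intercept,
         coefficients = coefficients,
         scale = scale,
         shape = 1 / scale),
    class = "weibull_aft"
  )
}

#' @export
print.weibull_aft <- function(x, ...) {
  cat("Weibull AFT model: S(t|x) = exp(-(t/lambda)^k)\n")
  cat("  intercept:", format(x$intercept), "  scale:", format(x$scale),
      " (shape k =", format(x$shape), ")\n")
  if (length(x$coefficients)) {
    cat("  log-time coefficients:\n")
    print(x$coefficients)
  } else cat("  (intercept only)\n")
  invisible(x)
}

# Per-row AFT time-scale lambda(x) = exp(intercept + x.beta).
# `covariates` may be NULL (intercept-only), a named list/vector, or a data
# frame; a missing covariate is an error naming the covariate.
aft_lambda <- function(model, covariates = NULL) {
  stopifnot(inherits(model, "weibull_aft"))
  if (length(model$coefficients) == 0L) {
    return(exp(model$intercept))
  }
  if (is.null(covariates)) {
    stop("covariate '", names(model$coefficients)[1], "' is missing",
         call. = FALSE)
  }
  if (!is.data.frame(covariates)) covariates <- as.data.frame(as.list(covariates))
  lp <- model$intercept
  for (nm in names(model$coefficients)) {
    if (!nm %in% names(covariates)) {
      stop("covariate '", nm, "' is missing", call. = FALSE)
    }
    lp <- lp + model$coefficients[[nm]] * as.numeric(covariates[[nm]])
  }
  exp(lp)
}

#' Survival function of a Weibull AFT model
#'
#' @param model a [weibull_aft()] model.
#' @param covariates named list, vector or data frame with one column per
#'   model covariate; `NULL` for an intercept-only model.
#' @param t non-negative time(s) in years.
#' @return `S(t | x)` in `(0, 1]`; `S(0) = 1`.
#' @export
survival_at <- function(model, covariates = NULL, t) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  lambda <- aft_lambda(model, covariates)
  exp(-(t / lambda)^model$shape)
}

#' Cumulative event risk over a horizon
#'
#' `1 - S(horizon | x)`, e.g. the 10-year risk of T2D given baseline
#' age, sex and FINDRISC (and optionally PRS).
#'
#' @inheritParams survival_at
#' @param horizon non-negative horizon in years.
#' @return Probability in `[0, 1)`.
#' @export
risk_over <- function(model, covariates = NULL, horizon) {
  1 - survival_at(model, covariates, horizon)
}

# Shared formula for the conditional annual event probability
# 1 - S(t+1)/S(t) with precomputed lambda; used by both the public
# operation and the simulation engine so there is a single code path.
annual_event_prob_lambda <- function(lambda, shape, t) {
  st <- exp(-(t / lambda)^shape)
  if (any(st == 0)) {
    stop("survival is zero at t = ", t[which(st == 0)[1]],
         "; model degenerate at this time", call. = FALSE)
  }
  st1 <- exp(-((t + 1) / lambda)^shape)
  1 - st1 / st
}

#' Annual (cycle) event probability from extrapolated survival
#'
#' Probability of the event occurring in `(t, t+1]` conditional on being
#' event-free at `t`: `1 - S(t+1)/S(t)`. This converts the fitted and
#' extrapolated incidence curve into the annual transition probabilities
#' used by the state-transition engine; the product of `1 - p_t` over years
#' telescopes back to `S(T)` exactly.
#'
#' @inheritParams survival_at
#' @param t years since baseline (start of the cycle), `t >= 0`.
#' @return Probability in `[0, 1)`.
#' @export
annual_event_prob <- function(model, covariates = NULL, t) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  lambda <- aft_lambda(model, covariates)
  annual_event_prob_lambda(lambda, model$shape, t)
}

#' Apply a hazard ratio to an annual probability
#'
#' Converts the probability to a rate, scales the rate by `hr`, and
#' converts back, assuming a constant hazard within the 1-year cycle:
#' `1 - (1 - p)^hr`. Identity at `hr = 1`; composing adjustments by
#' `hr1` then `hr2` equals one adjustment by `hr1 * hr2`.
#'
#' @param p annual probability(ies) in `[0, 1]`.
#' @param hr hazard ratio(s), `> 0`.
#' @return Adjusted probability in `[0, 1]`.
#' @export
#' @examples
#' apply_hazard_ratio(1 - exp(-0.1), 2)  # 1 - exp(-0.2)
apply_hazard_ratio <- function(p, hr) {
  stopifnot(is.numeric(p), is.numeric(hr))
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]", call. = FALSE)
  if (any(hr <= 0)) stop("'hr' must be positive", call. = FALSE)
  1 - (1 - p)^hr
}

#' Fit a parametric AFT survival model to right-censored data
#'
#' Thin wrapper over [survival::survreg()] maximizing the right-censored
#' parametric log-likelihood, returning the fit in the package's log-time
#' AFT parameterization.
#'
#' @param time positive event/censoring times.
#' @param event event indicator (1 = event, 0 = right-censored).
#' @param covariates data frame of covariates, or `NULL` for an
#'   intercept-only fit.
#' @param family one of `"weibull"`, `"exponential"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @return Object of class `aft_fit` with elements `family`, `intercept`,
#'   `coefficients`, `scale`, `se` (including `(Intercept)`), `loglik`,
#'   `df` (number of estimated parameters), `n`, `n_events`, `converged`,
#'   and the underlying `survreg` fit.
#' @export
fit_aft <- function(time, event,
                    covariates = NULL,
                    family = c("weibull", "exponential", "lognormal",
                               "loglogistic")) {
  family <- match.arg(family)
  stopifnot(length(time) == length(event))
  event <- as.integer(event)
  if (sum(event) == 0L) {
    stop("cannot fit a survival model with no events (all censored)",
         call. = FALSE)
  }
  dat <- data.frame(.time = time, .event = event)
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == length(time))
    dat <- cbind(dat, covariates)
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::survreg(survival::Surv(.time, .event) ~ ., data = dat,
                      dist = family),
    warning = function(w) {
      if (grepl("iteration|converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- fit$coefficients
  np <- length(cf) + as.integer(family != "exponential")
  se <- sqrt(diag(fit$var))
  names(se) <- c(names(cf), if (family != "exponential") "Log(scale)")
  structure(
    list(family = family,
         intercept = unname(cf["(Intercept)"]),
         coefficients = cf[setdiff(names(cf), "(Intercept)")],
         scale = fit$scale,
         se = se,
         loglik = fit$loglik[2],
         df = np,
         n = length(time),
         n_events = sum(event),
         converged = converged,
         survreg = fit),
    class = "aft_fit"
  )
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf("AFT fit (%s): n = %d, events = %d, logLik = %.2f, df = %d%s\n",
              x$family, x$n, x$n_events, x$loglik, x$df,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(c("(Intercept)" = x$intercept, x$coefficients))
  cat("scale:", format(x$scale), "\n")
  invisible(x)
}

#' Convert a Weibull/exponential AFT fit to a `weibull_aft` model
#'
#' @param fit an `aft_fit` from [fit_aft()] with family `weibull` or
#'   `exponential`.
#' @return A [weibull_aft()] model usable by the simulation engine.
#' @export
as_weibull_aft <- function(fit) {
  stopifnot(inherits(fit, "aft_fit"))
  if (!fit$family %in% c("weibull", "exponential")) {
    stop("only weibull/exponential fits map to a weibull_aft model",
         call. = FALSE)
  }
  weibull_aft(fit$intercept, fit$coefficients, fit$scale)
}

#' Compare parametric survival families by AIC/BIC
#'
#' Fits each requested family with [fit_aft()] and tabulates
#' `AIC = 2k - 2 lnL` and `BIC = k ln(n) - 2 lnL`. The selected family has
#' the lowest AIC; ties are broken by the lowest BIC. A family whose fit
#' fails is reported with its error message and does not abort the others.
#'
#' @inheritParams fit_aft
#' @param families character vector of two or more families.
#' @return List of class `aft_family_comparison` with `table` (one row per
#'   family), `selected` (family name), `fits` (successful `aft_fit`s).
#' @export
compare_families <- function(time, event, covariates = NULL,
                             families = c("exponential", "weibull",
                                          "lognormal", "loglogistic")) {
  if (length(families) < 2L) {
    stop("at least two families are required for a comparison", call. = FALSE)
  }
  fits <- list()
  rows <- lapply(families, function(fam) {
    f <- tryCatch(fit_aft(time, event, covariates, fam), error = identity)
    if (inherits(f, "error")) {
      return(data.frame(family = fam, df = NA_integer_, loglik = NA_real_,
                        aic = NA_real_, bic = NA_real_, converged = NA,
                        error = conditionMessage(f)))
    }
    fits[[fam]] <<- f
    data.frame(family = fam, df = f$df, loglik = f$loglik,
               aic = 2 * f$df - 2 * f$loglik,
               bic = f$df * log(f$n) - 2 * f$loglik,
               converged = f$converged, error = NA_character_)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$aic))
  if (length(ok) == 0L) stop("all family fits failed", call. = FALSE)
  sel <- ok[order(tab$aic[ok], tab$bic[ok])][1]
  structure(
    list(table = tab, selected = tab$family[sel], fits = fits),
    class = "aft_family_comparison"
  )
}

#' @export
print.aft_family_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("selected:", x$selected, "(lowest AIC, ties by BIC)\n")
  invisible(x)
}
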