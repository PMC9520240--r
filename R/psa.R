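#' Standard error from a 95% confidence interval
#'
#' `SE = (upper - lower) / (2 * 1.96)`, the rule used to recover sampling
#' uncertainty from published interval estimates.
#'
#' @param lower,upper interval bounds with `upper > lower`.
#' @return Positive standard error.
#' @export
#' @examples
#' se_from_ci(3301, 5501)  # ~561
se_from_ci <- function(lower, upper) {
  if (any(upper <= lower)) {
    stop("'upper' must exceed 'lower'", call. = FALSE)
  }
  (upper - lower) / (2 * 1.96)
}

#' Plus/minus 25% uncertainty bounds for a point estimate
#'
#' For parameters published without a confidence interval, a symmetric
#' variation of +/- 25% around the mean is assumed; the implied SE follows
#' from [se_from_ci()] on those bounds.
#'
#' @param mean positive point estimate.
#' @return List with `lower` (0.75 mean), `upper` (1.25 mean) and `se`.
#' @export
#' @examples
#' pm25_bounds(650)  # bounds 487.5, 812.5
pm25_bounds <- function(mean) {
  if (any(mean <= 0)) stop("'mean' must be positive", call. = FALSE)
  lower <- 0.75 * mean
  upper <- 1.25 * mean
  list(lower = lower, upper = upper, se = se_from_ci(lower, upper))
}

#' Method-of-moments Beta parameters
#'
#' `nu = m(1-m)/se^2 - 1`, `alpha = m nu`, `beta = (1-m) nu`; the fitted
#' Beta has mean `m` exactly and SD `se` exactly.
#'
#' @param mean mean in `(0, 1)`.
#' @param se standard error with `se^2 < mean(1-mean)`.
#' @return Named vector `c(alpha, beta)`.
#' @export
#' @examples
#' beta_mom(0.041, 0.012)  # alpha ~11.15, beta ~260.9
beta_mom <- function(mean, se) {
  stopifnot(mean > 0, mean < 1, se > 0)
  if (se^2 >= mean * (1 - mean)) {
    stop("variance too large for a Beta distribution with this mean",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments Gamma parameters
#'
#' `shape = (mean/se)^2`, `rate = mean/se^2`; round-trips exactly
#' (`shape/rate = mean`, `sqrt(shape)/rate = se`).
#'
#' @param mean,se positive mean and standard error.
#' @return Named vector `c(shape, rate)`.
#' @export
gamma_mom <- function(mean, se) {
  stopifnot(mean > 0, se > 0)
  c(shape = (mean / se)^2, rate = mean / se^2)
}

#' Natural-scale moment-matched lognormal parameters
#'
#' `sigma^2 = log(1 + (se/mean)^2)`, `mu = log(mean) - sigma^2/2`; the
#' implied lognormal has mean and SD equal to the inputs exactly.
#'
#' @param mean,se positive mean and standard error on the natural scale.
#' @return Named vector `c(mu, sigma)` (log-scale parameters).
#' @export
#' @examples
#' lognormal_mom(0.74, 0.17)
lognormal_mom <- function(mean, se) {
  stopifnot(mean > 0, se > 0)
  s2 <- log(1 + (se / mean)^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Declare one uncertain model parameter
#'
#' A parameter with its PSA sampling family: `lognormal` and `gamma` use
#' moment matching on the printed mean/SE, `beta` uses [beta_mom()] unless
#' explicit `shape1`/`shape2` are given, `fixed` passes the mean through.
#' An optional published CI is carried along for provenance.
#'
#' @param name parameter name.
#' @param family `"lognormal"`, `"gamma"`, `"beta"` or `"fixed"`.
#' @param mean point estimate / distribution mean.
#' @param se standard error (required unless fixed).
#' @param ci optional length-2 published interval.
#' @param shape1,shape2 optional explicit Beta shape parameters overriding
#'   the moment fit.
#' @return Object of class `param_distribution`.
#' @export
param_distribution <- function(name,
                               family = c("lognormal", "gamma", "beta",
                                          "fixed"),
                               mean, se = NULL, ci = NULL,
                               shape1 = NULL, shape2 = NULL) {
  family <- match.arg(family)
  if (family != "fixed" && is.null(shape1) && (is.null(se) || se <= 0)) {
    stop("parameter '", name, "': a positive 'se' is required for family '",
         family, "'", call. = FALSE)
  }
  structure(
    list(name = name, family = family, mean = mean, se = se, ci = ci,
         shape1 = shape1, shape2 = shape2),
    class = "param_distribution"
  )
}

# Draw one value from a param_distribution using the current RNG stream.
draw_parameter <- function(d) {
  switch(d$family,
    fixed = d$mean,
    lognormal = {
      p <- lognormal_mom(d$mean, d$se)
      stats::rlnorm(1, p["mu"], p["sigma"])
    },
    gamma = {
      p <- gamma_mom(d$mean, d$se)
      stats::rgamma(1, shape = p["shape"], rate = p["rate"])
    },
    beta = {
      if (!is.null(d$shape1)) {
        stats::rbeta(1, d$shape1, d$shape2)
      } else {
        p <- beta_mom(d$mean, d$se)
        stats::rbeta(1, p["alpha"], p["beta"])
      }
    }
  )
}

#' Sample one complete parameter set for the PSA
#'
#' Draws every declared parameter independently from its distribution
#' (fixed parameters pass through), producing one probabilistic
#' sensitivity analysis replicate.
#'
#' @param distributions named list of [param_distribution()] objects.
#' @return Named numeric vector, one value per parameter.
#' @export
sample_parameters <- function(distributions) {
  stopifnot(length(distributions) > 0)
  vapply(distributions, draw_parameter, numeric(1))
}
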