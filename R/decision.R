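#' Incremental cost-effectiveness analysis of two strategies
#'
#' Computes the incremental cost and QALYs of the PRS strategy versus the
#' usual strategy and labels the result: `"dominant"` (cheaper and more
#' effective, no ICER), `"dominated"` (costlier and less effective),
#' `"undefined"` (zero QALY difference with nonzero cost difference, no
#' division), `"equivalent"` (both differences zero), otherwise an ICER
#' `= delta_cost / delta_qaly`.
#'
#' @param cost_usual,qaly_usual,cost_prs,qaly_prs per-person expected
#'   discounted costs and QALYs of the two strategies.
#' @return List with `delta_cost`, `delta_qaly`, `icer` (`NA` when not
#'   applicable) and `label`.
#' @export
#' @examples
#' incremental_analysis(13619, 12.13, 13373, 12.15)  # dominant
incremental_analysis <- function(cost_usual, qaly_usual, cost_prs, qaly_prs) {
  dc <- cost_prs - cost_usual
  de <- qaly_prs - qaly_usual
  if (dc < 0 && de > 0) {
    return(list(delta_cost = dc, delta_qaly = de, icer = NA_real_,
                label = "dominant"))
  }
  if (dc > 0 && de < 0) {
    return(list(delta_cost = dc, delta_qaly = de, icer = NA_real_,
                label = "dominated"))
  }
  if (de == 0) {
    lab <- if (dc == 0) "equivalent" else "undefined"
    return(list(delta_cost = dc, delta_qaly = de, icer = NA_real_,
                label = lab))
  }
  list(delta_cost = dc, delta_qaly = de, icer = dc / de, label = "icer")
}

#' Net monetary benefit
#'
#' `NMB = wtp * qaly - cost`, linear in all arguments.
#'
#' @param cost,qaly per-person cost and QALYs.
#' @param wtp non-negative willingness-to-pay threshold (EUR/QALY).
#' @return Net monetary benefit(s).
#' @export
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("'wtp' must be non-negative", call. = FALSE)
  wtp * qaly - cost
}

#' Collect paired PSA replicates
#'
#' @param cost_usual,qaly_usual,cost_prs,qaly_prs equal-length vectors of
#'   per-draw expected values (individual-level noise already averaged out
#'   within each draw).
#' @return Data frame of class `psa_result`, one row per draw.
#' @export
psa_result <- function(cost_usual, qaly_usual, cost_prs, qaly_prs) {
  n <- length(cost_usual)
  stopifnot(n >= 1, length(qaly_usual) == n, length(cost_prs) == n,
            length(qaly_prs) == n)
  out <- data.frame(draw = seq_len(n),
                    cost_usual = cost_usual, qaly_usual = qaly_usual,
                    cost_prs = cost_prs, qaly_prs = qaly_prs)
  class(out) <- c("psa_result", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability (across PSA draws)
#' that the PRS strategy has the higher net monetary benefit; exact NMB
#' ties count 0.5 so the null comparison is symmetric. At `wtp = 0` the
#' value equals the fraction of draws in which the PRS strategy saves
#' costs.
#'
#' @param psa a [psa_result()].
#' @param wtp_grid non-negative, increasing WTP values (EUR/QALY).
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 2500)) {
  stopifnot(inherits(psa, "psa_result"), all(wtp_grid >= 0),
            !is.unsorted(wtp_grid))
  prob <- vapply(wtp_grid, function(w) {
    dn <- nmb(psa$cost_prs, psa$qaly_prs, w) -
      nmb(psa$cost_usual, psa$qaly_usual, w)
    mean(dn > 0) + 0.5 * mean(dn == 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Expected value of perfect information
#'
#' Per WTP value: the mean over draws of the best strategy's NMB minus the
#' best strategy's mean NMB -- the expected opportunity loss of deciding
#' under parameter uncertainty. Always non-negative; zero when one
#' strategy wins in every draw.
#'
#' @inheritParams ceac
#' @return Data frame with columns `wtp` and `evpi` (EUR per person).
#' @export
evpi <- function(psa, wtp_grid = seq(0, 100000, by = 2500)) {
  stopifnot(inherits(psa, "psa_result"), all(wtp_grid >= 0))
  ev <- vapply(wtp_grid, function(w) {
    nu <- nmb(psa$cost_usual, psa$qaly_usual, w)
    np <- nmb(psa$cost_prs, psa$qaly_prs, w)
    mean(pmax(nu, np)) - max(mean(nu), mean(np))
  }, numeric(1))
  data.frame(wtp = wtp_grid, evpi = ev)
}

#' Cost-neutral PRS test price
#'
#' The test price at which the incremental cost of the PRS strategy is
#' zero. Because every PRS-arm member is tested exactly once (in year 1,
#' undiscounted), the incremental cost moves one-for-one with the test
#' price, so the cost-neutral point is
#' `base_test_price - delta_cost`. A negative result is reported as 0 with
#' a warning (a test cannot be paid to be given).
#'
#' @param delta_cost incremental cost (PRS minus usual) at the base test
#'   price.
#' @param base_test_price test price used when `delta_cost` was computed.
#' @return Cost-neutral price in euros.
#' @export
#' @examples
#' cost_neutral_price(-253, 50)  # 303
cost_neutral_price <- function(delta_cost, base_test_price = 50) {
  if (any(base_test_price < 0)) {
    stop("'base_test_price' must be non-negative", call. = FALSE)
  }
  out <- base_test_price - delta_cost
  if (any(out < 0)) {
    warning("cost-neutral price is negative; reporting 0", call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}
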