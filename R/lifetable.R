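#' Life table of annual death probabilities by age and sex
#'
#' @param data data frame with columns `age` (integer), `sex`
#'   (`"male"`/`"female"`) and `qx` (annual death probability in `[0,1]`),
#'   covering every age in the table's range for both sexes.
#' @return Object of class `life_table`.
#' @export
life_table <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("age", "sex", "qx") %in% names(data)))
  if (any(data$qx < 0 | data$qx > 1)) {
    stop("life-table qx values must lie in [0, 1]", call. = FALSE)
  }
  if (!all(data$sex %in% c("male", "female"))) {
    stop("life-table sex must be 'male' or 'female'", call. = FALSE)
  }
  ages <- sort(unique(data$age))
  if (!identical(ages, seq(min(ages), max(ages)))) {
    stop("life-table ages must form a contiguous range", call. = FALSE)
  }
  q <- matrix(NA_real_, nrow = length(ages), ncol = 2,
              dimnames = list(ages, c("male", "female")))
  for (sx in c("male", "female")) {
    d <- data[data$sex == sx, ]
    if (!setequal(d$age, ages)) {
      stop("life table must cover all ages for both sexes", call. = FALSE)
    }
    q[match(d$age, ages), sx] <- d$qx
  }
  structure(list(ages = ages, q = q), class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table: ages %d-%d, both sexes\n",
              min(x$ages), max(x$ages)))
  invisible(x)
}

#' Read a life table from CSV
#'
#' Expects columns `age`, `sex`, `qx`.
#'
#' @param path path to a CSV file.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  life_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Bundled synthetic all-cause life table
#'
#' A Gompertz-shaped synthetic stand-in for national all-cause life tables
#' (ages 30-100, both sexes). It is generated, not observed, and shipped so
#' the model runs self-contained; see the file
#' `extdata/life_table_synthetic.csv`.
#'
#' @return A [life_table()].
#' @export
default_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_synthetic.csv",
                              package = "prsmicrosim", mustWork = TRUE))
}

# Base q(age, sex) lookup, vectorised; errors outside the tabulated range.
lifetable_q <- function(lt, age, male) {
  stopifnot(inherits(lt, "life_table"))
  i <- match(age, lt$ages)
  if (anyNA(i)) {
    stop("age ", age[which(is.na(i))[1]], " outside life-table range ",
         min(lt$ages), "-", max(lt$ages), call. = FALSE)
  }
  lt$q[cbind(i, ifelse(male, 1L, 2L))]
}

#' State-specific mortality hazard-ratio adjustments
#'
#' Hazard ratios applied to the all-cause annual death probability in the
#' diseased states: sex-specific HRs for the T2D state and a single HR for
#' the T2D-with-complications state. By default the complications HR is
#' interpreted relative to the general population (applied alone in that
#' state); set `complications_on_top = TRUE` to apply it multiplicatively
#' on top of the sex-specific T2D HR instead.
#'
#' @param hr_t2d_female,hr_t2d_male,hr_complications positive hazard ratios.
#' @param complications_on_top logical interpretation switch (see above).
#' @return Object of class `mortality_adjustment`.
#' @export
mortality_adjustment <- function(hr_t2d_female = 2.47,
                                 hr_t2d_male = 1.93,
                                 hr_complications = 2.36,
                                 complications_on_top = FALSE) {
  stopifnot(hr_t2d_female > 0, hr_t2d_male > 0, hr_complications > 0,
            is.logical(complications_on_top))
  structure(
    list(hr_t2d_female = hr_t2d_female, hr_t2d_male = hr_t2d_male,
         hr_complications = hr_complications,
         complications_on_top = complications_on_top),
    class = "mortality_adjustment"
  )
}

#' Annual death probability by age, sex and health state
#'
#' Looks up the all-cause life-table probability and applies the
#' state-specific hazard-ratio adjustment via [apply_hazard_ratio()]:
#' healthy individuals get the unadjusted `q(age, sex)`.
#'
#' @param lt a [life_table()].
#' @param age age(s) within the table range.
#' @param sex `"male"`/`"female"` (recycled).
#' @param state health state(s): `"healthy"`, `"t2d"`,
#'   `"t2d_complications"` (or the engine's integer codes).
#' @param adjustment a [mortality_adjustment()].
#' @return Annual death probability(ies) in `[0, 1]`.
#' @export
#' @examples
#' lt <- life_table(data.frame(
#'   age = rep(60:61, 2), sex = rep(c("male", "female"), each = 2), qx = 0.01
#' ))
#' mortality_prob(lt, 60, "female", "t2d")  # 1 - 0.99^2.47
mortality_prob <- function(lt, age, sex, state = "healthy",
                           adjustment = mortality_adjustment()) {
  n <- max(length(age), length(sex), length(state))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  state <- rep_len(normalize_state(state), n)
  male <- sex == "male"
  q <- lifetable_q(lt, age, male)
  hr <- rep(1, n)
  t2d <- state == STATE_T2D
  hr[t2d] <- ifelse(male[t2d], adjustment$hr_t2d_male, adjustment$hr_t2d_female)
  cmp <- state == STATE_T2D_COMPL
  if (adjustment$complications_on_top) {
    hr[cmp] <- adjustment$hr_complications *
      ifelse(male[cmp], adjustment$hr_t2d_male, adjustment$hr_t2d_female)
  } else {
    hr[cmp] <- adjustment$hr_complications
  }
  out <- q
  adj <- hr != 1
  out[adj] <- apply_hazard_ratio(q[adj], hr[adj])
  out[state == STATE_DEAD] <- 1
  out
}
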