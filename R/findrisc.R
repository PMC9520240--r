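#' Default FINDRISC item table
#'
#' The published 8-item FINDRISC scoring table (age, BMI, waist
#' circumference, physical activity, daily vegetable/fruit/berry intake,
#' blood-pressure medication, history of high blood glucose, family history
#' of diabetes), packaged as a versioned constant. Total score ranges 0-26.
#' Interval items are scored with half-open intervals `[break, next)`:
#' e.g. age 45 scores 2 points, age 64 scores 3, age 65 scores 4.
#'
#' The table can be replaced wholesale (e.g. loaded from a configuration
#' file) wherever a `items` argument is accepted; a table that omits the
#' `waist` entry makes the waist measurement optional.
#'
#' @return A named list, one entry per scored item, each entry describing the
#'   item type (`interval`, `interval_by_sex`, `binary`, `categorical`) and
#'   its point values.
#' @export
#' @examples
#' names(findrisc_items())
findrisc_items <- function() {
  list(
    age = list(type = "interval", breaks = c(45, 55, 65), points = c(0L, 2L, 3L, 4L)),
    bmi = list(type = "interval", breaks = c(25, 30), points = c(0L, 1L, 3L)),
    waist = list(
      type = "interval_by_sex",
      male = list(breaks = c(94, 102), points = c(0L, 3L, 4L)),
      female = list(breaks = c(80, 88), points = c(0L, 3L, 4L))
    ),
    physically_active = list(type = "binary", yes = 0L, no = 2L),
    daily_vegetables = list(type = "binary", yes = 0L, no = 1L),
    bp_medication = list(type = "binary", yes = 2L, no = 0L),
    history_high_glucose = list(type = "binary", yes = 5L, no = 0L),
    family_history = list(
      type = "categorical",
      points = c(none = 0L, second_degree = 3L, first_degree = 5L)
    )
  )
}

#' FINDRISC score for a collection of risk-factor profiles
#'
#' Vectorised scoring over the rows of a data frame holding the risk-factor
#' columns named in the item table (plus `sex` for sex-specific items).
#'
#' @param data data frame of risk-factor profiles; binary items must be
#'   logical, `family_history` one of `"none"`, `"second_degree"`,
#'   `"first_degree"`, `sex` one of `"male"`, `"female"`.
#' @param items item table, see [findrisc_items()].
#' @return Integer vector of scores, one per row.
#' @export
findrisc_score <- function(data, items = findrisc_items()) {
  n <- nrow(data)
  score <- integer(n)
  for (nm in names(items)) {
    it <- items[[nm]]
    if (!nm %in% names(data)) {
      stop("FINDRISC item '", nm, "' is required but missing", call. = FALSE)
    }
    v <- data[[nm]]
    if (anyNA(v)) {
      stop("FINDRISC item '", nm, "' contains missing values", call. = FALSE)
    }
    pts <- switch(it$type,
      interval = it$points[findInterval(v, it$breaks) + 1L],
      interval_by_sex = {
        if (!"sex" %in% names(data)) {
          stop("FINDRISC item 'sex' is required but missing", call. = FALSE)
        }
        p <- integer(n)
        for (sx in c("male", "female")) {
          i <- data$sex == sx
          tab <- it[[sx]]
          p[i] <- tab$points[findInterval(v[i], tab$breaks) + 1L]
        }
        p
      },
      binary = ifelse(as.logical(v), it$yes, it$no),
      categorical = {
        v <- as.character(v)
        bad <- !v %in% names(it$points)
        if (any(bad)) {
          stop("FINDRISC item '", nm, "' has unknown level '", v[bad][1], "'",
               call. = FALSE)
        }
        unname(it$points[v])
      },
      stop("unknown FINDRISC item type: ", it$type)
    )
    score <- score + as.integer(pts)
  }
  score
}

#' FINDRISC score and risk category for one profile
#'
#' @param profile named list (or one-row data frame) with the risk-factor
#'   fields used by the item table: `age`, `sex`, `bmi`, `waist`,
#'   `physically_active`, `daily_vegetables`, `bp_medication`,
#'   `history_high_glucose`, `family_history`.
#' @inheritParams findrisc_score
#' @return List with elements `score` (integer points) and `category`
#'   (the instrument's five-level band: `low` < 7, `slightly_elevated` 7-11,
#'   `moderate` 12-14, `high` 15-20, `very_high` > 20).
#' @export
#' @examples
#' compute_findrisc(list(
#'   age = 62, sex = "male", bmi = 31, waist = 103,
#'   physically_active = FALSE, daily_vegetables = FALSE,
#'   bp_medication = TRUE, history_high_glucose = TRUE,
#'   family_history = "first_degree"
#' ))
compute_findrisc <- function(profile, items = findrisc_items()) {
  if (!is.data.frame(profile)) {
    profile <- as.data.frame(profile[lengths(profile) == 1L],
                             stringsAsFactors = FALSE)
  }
  stopifnot(nrow(profile) == 1L)
  s <- findrisc_score(profile, items)
  list(score = s, category = findrisc_category(s))
}

#' Instrument risk band for a FINDRISC score
#'
#' @param score integer score(s).
#' @return Ordered factor with levels `low`, `slightly_elevated`,
#'   `moderate`, `high`, `very_high`.
#' @export
findrisc_category <- function(score) {
  cut(score, breaks = c(-Inf, 6, 11, 14, 20, Inf),
      labels = c("low", "slightly_elevated", "moderate", "high", "very_high"),
      ordered_result = TRUE)
}
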