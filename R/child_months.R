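#' Age groups used for under-5 survival
#'
#' The six age intervals over which the monthly survival probability is
#' assumed constant: 0 months, 1-11, 12-23, 24-35, 36-47 and 48-59 months.
#' Their lengths (1, 11, 12, 12, 12, 12 months) partition ages 0-59.
#'
#' @format A data.table with columns `age_group` (factor level label) and
#'   `n_months` (interval length in months).
#' @export
age_group_table <- function() {
  data.table::data.table(
    age_group = factor(age_group_levels(), levels = age_group_levels()),
    n_months = c(1L, 11L, 12L, 12L, 12L, 12L)
  )
}

age_group_levels <- function() {
  c("m0", "m1_11", "m12_23", "m24_35", "m36_47", "m48_59")
}

#' Assign an age in months to its age group
#'
#' @param age_months Integer vector of ages in completed months, each in
#'   \[0, 59\].
#' @return A factor with levels `m0, m1_11, m12_23, m24_35, m36_47, m48_59`.
#' @examples
#' assign_age_group(c(0, 11, 12, 59))
#' @export
assign_age_group <- function(age_months) {
  if (any(age_months < 0L | age_months > 59L)) {
    stop("age_months must be in [0, 59]")
  }
  idx <- findInterval(age_months, c(0L, 1L, 12L, 24L, 36L, 48L))
  factor(age_group_levels()[idx], levels = age_group_levels())
}

#' Expand one child record into child-months
#'
#' Produces one row per month the child lived and was observed under age 5:
#' fewer than 60 rows if the child died before age 5 or was born less than
#' five years before the interview. The interview month itself is excluded
#' (a month contributes only once its end-state is known). A child dead at
#' completed age `d` contributes months 0..d with `ends_alive = FALSE`
#' exactly at the death month; a death at `d >= 60` counts as survival
#' through all under-5 months.
#'
#' @param child A list or one-row data.frame with `birth_cmc`,
#'   `alive_at_survey` and `death_age_months`.
#' @param interview_cmc Integer interview month of the mother.
#' @return A data.table with columns `calendar_cmc`, `age_months`,
#'   `age_group`, `ends_alive` (possibly zero rows).
#' @examples
#' expand_child(list(birth_cmc = 60, alive_at_survey = FALSE,
#'                   death_age_months = 2), interview_cmc = 120)
#' @export
expand_child <- function(child, interview_cmc) {
  expand_children(
    birth_cmc = as.integer(child$birth_cmc),
    alive = as.logical(child$alive_at_survey),
    death_age_months = as.integer(child$death_age_months),
    interview_cmc = as.integer(interview_cmc)
  )[, list(calendar_cmc, age_months, age_group, ends_alive)]
}

# Vectorised child-month expansion over parallel child vectors.
# Returns a data.table with a row index `child` back into the inputs.
expand_children <- function(birth_cmc, alive, death_age_months,
                            interview_cmc) {
  stopifnot(length(alive) == length(birth_cmc),
            length(interview_cmc) == length(birth_cmc))
  if (!length(birth_cmc)) {
    return(data.table::data.table(
      child = integer(), calendar_cmc = integer(), age_months = integer(),
      age_group = factor(character(), levels = age_group_levels()),
      ends_alive = logical()
    ))
  }
  censor_bound <- interview_cmc - birth_cmc - 1L   # last fully observed age
  dead_u5 <- !alive & !is.na(death_age_months) & death_age_months <= 59L
  last_age <- ifelse(dead_u5,
                     pmin(death_age_months, censor_bound),
                     pmin(59L, censor_bound))
  n_obs <- pmax(0L, last_age + 1L)
  child <- rep.int(seq_along(birth_cmc), n_obs)
  age <- sequence(n_obs) - 1L
  death_month <- dead_u5[child] & age == death_age_months[child]
  data.table::data.table(
    child = child,
    calendar_cmc = birth_cmc[child] + age,
    age_months = age,
    age_group = assign_age_group(age),
    ends_alive = !death_month
  )
}

#' Expand a survey into child-months
#'
#' Applies [expand_child()] to every child of every woman and concatenates
#' the result; the row count equals the sum of per-child counts. This table
#' is the shared substrate of all complete-birth-history estimators.
#'
#' @param ds A [bh_survey()].
#' @return A data.table with columns `woman_id`, `child_id`,
#'   `calendar_cmc`, `age_months`, `age_group`, `ends_alive`.
#' @export
expand_dataset <- function(ds) {
  validate_bh_survey(ds)
  ch <- ds$children
  icmc <- ds$women$interview_cmc[match(ch$woman_id, ds$women$woman_id)]
  cm <- expand_children(ch$birth_cmc, ch$alive_at_survey,
                        ch$death_age_months, icmc)
  cm[, `:=`(woman_id = ch$woman_id[child], child_id = ch$child_id[child])]
  cm[, child := NULL]
  data.table::setcolorder(cm, c("woman_id", "child_id", "calendar_cmc",
                                "age_months", "age_group", "ends_alive"))
  cm[]
}
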