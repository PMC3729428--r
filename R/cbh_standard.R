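#' Under-5 mortality from (weighted) child-months
#'
#' The synthetic-cohort calculation at the heart of every estimator here.
#' For each age group g the monthly survival probability is the weighted
#' proportion of that group's child-months ending with the child alive,
#' `p_g = sum(w * alive) / sum(w)`; raising `p_g` to the number of months
#' in the interval gives the probability of surviving the whole interval,
#' and `q5 = 1 - prod_g p_g^{n_g}`. Age groups with zero total weight
#' contribute survival 1 (no information implies no estimated mortality in
#' that band).
#'
#' @param child_months A data.table as returned by [expand_dataset()] (only
#'   `age_group` and `ends_alive` are used).
#' @param weights Optional nonnegative per-row weights; defaults to unit
#'   weights. All-zero weights yield no estimate (`q5 = NA`).
#' @return A list with `q5` (probability, `NA` if no positive weight) and
#'   `exposure` (total weight, i.e. the number of child-months under unit
#'   weights).
#' @examples
#' ds <- toy_survey()
#' cm <- expand_dataset(ds)
#' q5_from_child_months(cm)  # 1 - (12/13)^11
#' @export
q5_from_child_months <- function(child_months, weights = NULL) {
  cm <- data.table::as.data.table(child_months)
  if (is.null(weights)) {
    gs <- cm[, list(tot = .N, alive = sum(ends_alive)), by = "age_group"]
  } else {
    stopifnot(length(weights) == nrow(cm), all(weights >= 0))
    w <- weights
    gs <- cm[, list(tot = sum(w[.I]), alive = sum(w[.I] * ends_alive)),
             by = "age_group"]
    gs <- gs[tot > 0]
  }
  if (nrow(gs) == 0L || sum(gs$tot) == 0) {
    return(list(q5 = NA_real_, exposure = 0))
  }
  res <- q5_from_group_stats(gs, by = character())
  list(q5 = res$q5, exposure = res$n_child_months)
}

# Collapse per-(key, age_group) exposure/alive tallies into q5 per key.
# gs: data.table with columns <by...>, age_group, tot, alive (tot > 0).
# Groups are combined in fixed m0..m48_59 order so independent
# implementations can reproduce results bitwise.
q5_from_group_stats <- function(gs, by) {
  gs <- merge(gs, age_group_table(), by = "age_group", sort = FALSE)
  data.table::setorderv(gs, c(by, "age_group"))
  gs[, list(q5 = 1 - prod((alive / tot)^n_months),
            n_child_months = sum(tot)),
     by = by]
}

# Tally child-months by calendar month and age group (plus optional extra
# keys such as a replicate id). The compact substrate for all estimators.
monthly_counts <- function(cm, by = character()) {
  cm[, list(tot = .N, alive = sum(ends_alive)),
     by = c(by, "calendar_cmc", "age_group")]
}

# Standard period estimator on monthly tallies. Periods of 12*length_years
# months tile backwards from anchor_cmc: period k covers months
# (anchor - 12L(k+1), anchor - 12L*k], so the newest period ends with the
# anchor month. Estimates are placed at the period midpoint in decimal
# years.
q5_standard_from_counts <- function(counts, length_years, anchor_cmc,
                                    by = character()) {
  pl <- 12L * as.integer(length_years)
  counts <- counts[calendar_cmc <= anchor_cmc]
  if (nrow(counts) == 0L) {
    return(data.table::data.table(period = integer(), time_years = numeric(),
                                  q5 = numeric(), n_child_months = numeric()))
  }
  counts[, period := (anchor_cmc - calendar_cmc) %/% pl]
  gs <- counts[, list(tot = sum(tot), alive = sum(alive)),
               by = c(by, "period", "age_group")]
  est <- q5_from_group_stats(gs, by = c(by, "period"))
  est[, time_years := 1900 + (anchor_cmc - pl * period - pl / 2) / 12]
  data.table::setorderv(est, c(by, "time_years"))
  est[]
}

#' Standard complete-birth-history estimator
#'
#' Expands the survey into child-months, bins them into non-overlapping
#' periods of equal length tiling backwards from the most recent interview
#' month, and computes one under-5 mortality estimate per non-empty period
#' via the synthetic-cohort formula of [q5_from_child_months()]. Each
#' estimate is assigned to the midpoint of its period in decimal years.
#'
#' @param ds A [bh_survey()].
#' @param length_years Period length in years; 1, 2 and 5 are the
#'   conventional choices.
#' @param anchor_cmc Month the newest period ends with (inclusive);
#'   defaults to the latest interview month of the survey.
#' @param child_months Optional pre-computed [expand_dataset()] table, to
#'   avoid repeated expansion when several estimators run on one survey.
#' @return An estimate series: a data.table with columns `survey_id`,
#'   `method_tag` (`"CBH[<L>]"`), `time_years`, `q5`, `n_child_months`,
#'   ordered by time. Periods with no child-months yield no row.
#' @export
estimate_standard <- function(ds, length_years, anchor_cmc = NULL,
                              child_months = NULL) {
  stopifnot(length_years >= 1)
  if (is.null(child_months)) child_months <- expand_dataset(ds)
  if (is.null(anchor_cmc)) anchor_cmc <- ds$interview_cmc_max
  est <- q5_standard_from_counts(monthly_counts(child_months),
                                 length_years, anchor_cmc)
  data.table::data.table(
    survey_id = ds$survey_id,
    method_tag = sprintf("CBH[%d]", as.integer(length_years)),
    time_years = est$time_years,
    q5 = est$q5,
    n_child_months = est$n_child_months
  )
}

#' Build the full-sample truth series
#'
#' The validation's gold standard: the standard estimator with two-year
#' periods applied to the full (unsampled) survey, linearly interpolated
#' between period midpoints. The truth is never extrapolated: queries
#' outside the knot span return `NA`.
#'
#' @param ds A [bh_survey()] (or pooled dataset from [pool_surveys()]).
#' @param child_months Optional pre-computed [expand_dataset()] table.
#' @return An object of class `bh_truth` with elements `survey_id` and
#'   `knots` (the two-year estimate series). Evaluate it with
#'   [truth_q5()].
#' @export
build_truth <- function(ds, child_months = NULL) {
  knots <- estimate_standard(ds, length_years = 2,
                             child_months = child_months)
  if (nrow(knots) < 2L) {
    stop("truth undefined: fewer than 2 non-empty two-year periods")
  }
  structure(list(survey_id = ds$survey_id, knots = knots),
            class = "bh_truth")
}

#' Evaluate a truth series at given times
#'
#' Linear interpolation between the two-year-period knots of a
#' [build_truth()] object; times outside the knot span give `NA`.
#'
#' @param truth A `bh_truth` object.
#' @param years Numeric vector of decimal calendar years.
#' @return Numeric vector of true under-5 mortality values (`NA` outside
#'   the span).
#' @export
truth_q5 <- function(truth, years) {
  stopifnot(inherits(truth, "bh_truth"))
  stats::approx(truth$knots$time_years, truth$knots$q5, xout = years,
                method = "linear", rule = 1, ties = "ordered")$y
}

#' @export
print.bh_truth <- function(x, ...) {
  cat(sprintf("<bh_truth> %s: %d knots spanning %.2f-%.2f, q5 %.3f-%.3f\n",
              x$survey_id, nrow(x$knots), min(x$knots$time_years),
              max(x$knots$time_years), min(x$knots$q5), max(x$knots$q5)))
  invisible(x)
}

#' A two-child worked example
#'
#' The minimal dataset used throughout the documentation: two women
#' interviewed at month 120, each with one child born at month 60; one
#' child died at age 2 completed months, the other survived. Its 63
#' child-months give `q5 = 1 - (12/13)^11 = 0.585414` (one death among the
#' 13 child-months aged 1-11; every other age group is fully survived).
#'
#' @return A [bh_survey()] with 2 women and 2 children.
#' @export
toy_survey <- function() {
  bh_survey(
    survey_id = "toy", country_id = "TOY",
    women = data.frame(woman_id = c("A", "B"), interview_cmc = c(120L, 120L)),
    children = data.frame(
      woman_id = c("A", "B"), child_id = c("a1", "b1"),
      birth_cmc = c(60L, 60L), alive_at_survey = c(FALSE, TRUE),
      death_age_months = c(2L, NA_integer_)
    )
  )
}
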