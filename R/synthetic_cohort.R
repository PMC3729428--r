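#' Define an under-5 mortality schedule
#'
#' A mortality schedule couples an age *pattern* — relative monthly hazards
#' across the six age groups of [age_group_table()] — with a target level
#' of under-5 mortality over calendar time. At any year the pattern is
#' rescaled by a common factor so that the implied period 5q0 equals the
#' target exactly (see [hazards_at()]), making the simulated truth known
#' analytically.
#'
#' The target is constant when `q5_end` is omitted, otherwise log-linear in
#' calendar year between `(year_start, q5_start)` and `(year_end, q5_end)`
#' and held flat outside that span.
#'
#' @param q5_start Target 5q0 at `year_start` (probability in (0,1)).
#' @param q5_end Target 5q0 at `year_end`; default `q5_start` (constant).
#' @param year_start,year_end Calendar years anchoring the trend; ignored
#'   when the target is constant.
#' @param pattern Six nonnegative relative monthly hazards, one per age
#'   group. The default `(28, 8, 3, 2, 1.5, 1)` front-loads infant
#'   mortality, the qualitative shape of observed under-5 schedules; only
#'   the ratios matter.
#' @return An object of class `mortality_schedule`.
#' @export
mortality_schedule <- function(q5_start, q5_end = q5_start,
                               year_start = 1975, year_end = 2010,
                               pattern = c(28, 8, 3, 2, 1.5, 1)) {
  stopifnot(length(pattern) == 6L, all(pattern >= 0), any(pattern > 0),
            q5_start > 0, q5_start < 1, q5_end > 0, q5_end < 1)
  if (q5_end != q5_start) stopifnot(year_end > year_start)
  structure(
    list(q5_start = q5_start, q5_end = q5_end,
         year_start = year_start, year_end = year_end, pattern = pattern),
    class = "mortality_schedule"
  )
}

#' Target under-5 mortality of a schedule at given years
#'
#' @param sched A [mortality_schedule()].
#' @param year Numeric vector of decimal calendar years.
#' @return The target 5q0 at each year (log-linear between the schedule's
#'   endpoints, clamped outside).
#' @export
target_q5 <- function(sched, year) {
  stopifnot(inherits(sched, "mortality_schedule"))
  if (sched$q5_end == sched$q5_start) {
    return(rep(sched$q5_start, length(year)))
  }
  frac <- (year - sched$year_start) / (sched$year_end - sched$year_start)
  frac <- pmin(1, pmax(0, frac))
  exp(log(sched$q5_start) + frac * (log(sched$q5_end) - log(sched$q5_start)))
}

#' Age-specific monthly hazards at a given year
#'
#' Scales the schedule's age pattern by the common factor
#' `k = -log(1 - q5(year)) / sum_g n_g * h0_g`, so that the period
#' survival `prod_g exp(-k * h0_g)^{n_g}` equals `1 - q5(year)` exactly —
#' the construction identity `analytic_q5(hazards_at(y)) == target_q5(y)`.
#'
#' @param sched A [mortality_schedule()].
#' @param year Decimal calendar year (scalar or vector).
#' @return For scalar `year`, a length-6 vector of monthly hazards (one
#'   per age group); for vector `year`, a matrix with one row per year.
#' @export
hazards_at <- function(sched, year) {
  stopifnot(inherits(sched, "mortality_schedule"))
  k <- hazard_scale(sched, year)
  if (length(year) == 1L) {
    k * sched$pattern
  } else {
    outer(k, sched$pattern)
  }
}

# Common hazard scale factor k(year).
hazard_scale <- function(sched, year) {
  q5 <- target_q5(sched, year)
  -log(1 - q5) / sum(age_group_table()$n_months * sched$pattern)
}

#' Analytic under-5 mortality implied by monthly hazards
#'
#' Inverse of the estimator's synthetic-cohort formula under monthly
#' survival `exp(-h)`: `1 - prod_g exp(-h_g)^{n_g}`, which collapses to
#' `1 - exp(-sum_g n_g h_g)`.
#'
#' @param hazards Length-6 vector of nonnegative monthly hazards, ordered
#'   as in [age_group_table()].
#' @return The implied 5q0.
#' @export
analytic_q5 <- function(hazards) {
  stopifnot(length(hazards) == 6L, all(hazards >= 0))
  1 - exp(-sum(age_group_table()$n_months * hazards))
}

#' Define a fertility schedule
#'
#' Monthly birth hazards by five-year maternal age band (15-19 through
#' 45-49), with a minimum inter-birth interval during which the hazard is
#' suppressed. The default hazards correspond to age-specific fertility
#' rates of roughly 0.12, 0.25, 0.25, 0.20, 0.15, 0.07 and 0.02 births per
#' woman-year — a high-fertility schedule with a total fertility rate near
#' 5, typical of the settings where birth-history surveys are fielded.
#'
#' @param monthly_hazard Seven nonnegative monthly birth hazards, one per
#'   age band 15-19, 20-24, ..., 45-49.
#' @param min_interval_months Minimum number of months between consecutive
#'   births (default 9, a gestation).
#' @return An object of class `fertility_schedule`.
#' @export
fertility_schedule <- function(
    monthly_hazard = c(0.010, 0.021, 0.021, 0.017, 0.0125, 0.006, 0.0017),
    min_interval_months = 9L) {
  stopifnot(length(monthly_hazard) == 7L, all(monthly_hazard >= 0),
            min_interval_months >= 1L)
  structure(
    list(monthly_hazard = monthly_hazard,
         min_interval_months = as.integer(min_interval_months)),
    class = "fertility_schedule"
  )
}

#' Microsimulate a DHS-like birth-history survey
#'
#' Generates a survey with known true mortality: each woman draws an age
#' at interview (uniform over 15-49 years), lives through her reproductive
#' months with the fertility schedule's monthly birth hazard (suppressed
#' for `min_interval_months` after each birth), and each child faces a
#' monthly death probability `1 - exp(-h)` where `h` is the age-group
#' hazard of [hazards_at()] evaluated at the calendar year of that month —
#' period mortality, so the generator and the estimators agree on what
#' 5q0 means. Children are followed to death, to age 60 months, or to the
#' month before interview; survivors past either bound are recorded alive.
#' Mortality above age 5 is not modelled.
#'
#' The simulation advances month by month with all women (then all
#' children) updated in vectorised sweeps from a single seeded stream, so
#' results are exactly reproducible given `seed`.
#'
#' @param mort A [mortality_schedule()].
#' @param fert A [fertility_schedule()].
#' @param n_women Number of women to interview.
#' @param interview_cmc Interview month (shared by all women).
#' @param survey_id,country_id Identifiers for the resulting dataset.
#' @param seed Integer master seed; the caller's RNG state is preserved.
#' @return A [bh_survey()].
#' @examples
#' ds <- simulate_survey(mortality_schedule(0.15), fertility_schedule(),
#'                       n_women = 200, interview_cmc = 1212, seed = 1)
#' @export
simulate_survey <- function(mort, fert, n_women, interview_cmc,
                            survey_id = "sim", country_id = "SIM",
                            seed = 1L) {
  stopifnot(inherits(mort, "mortality_schedule"),
            inherits(fert, "fertility_schedule"),
            n_women >= 1L)
  interview_cmc <- as.integer(interview_cmc)
  withr_seed(seed, {
    age_at_interview <- sample(180:599, n_women, replace = TRUE)
    woman_birth_cmc <- interview_cmc - age_at_interview

    # Fertility sweep: one Bernoulli draw per woman per calendar month of
    # the oldest possible reproductive span.
    p_birth <- 1 - exp(-fert$monthly_hazard)
    last_birth <- rep(-100000L, n_women)  # sentinel: no birth yet
    births_mother <- list(); births_cmc <- list(); bi <- 0L
    for (m in seq.int(interview_cmc - 420L, interview_cmc - 1L)) {
      age_m <- m - woman_birth_cmc
      u <- stats::runif(n_women)
      band <- pmin(pmax(age_m %/% 60L - 2L, 1L), 7L)  # 180-239 months -> band 1
      eligible <- age_m >= 180L & age_m < 600L &
        (m - last_birth) >= fert$min_interval_months
      born <- eligible & u < p_birth[band]
      if (any(born)) {
        bi <- bi + 1L
        births_mother[[bi]] <- which(born)
        births_cmc[[bi]] <- rep.int(m, sum(born))
        last_birth[born] <- m
      }
    }
    mother <- unlist(births_mother, use.names = FALSE)
    birth_cmc <- unlist(births_cmc, use.names = FALSE)
    n_child <- length(mother)

    # Survival sweep: one Bernoulli draw per child per month of age still
    # at risk and completed before the interview.
    group_of_age <- as.integer(assign_age_group(0:59))
    alive <- rep(TRUE, n_child)
    death_age <- rep(NA_integer_, n_child)
    if (n_child) {
      for (a in 0:59) {
        at_risk <- which(alive & (birth_cmc + a) < interview_cmc)
        if (!length(at_risk)) next
        yr <- cmc_to_year(birth_cmc[at_risk] + a)
        h <- hazard_scale(mort, yr) * mort$pattern[group_of_age[a + 1L]]
        dies <- stats::runif(length(at_risk)) < (1 - exp(-h))
        if (any(dies)) {
          idx <- at_risk[dies]
          alive[idx] <- FALSE
          death_age[idx] <- a
        }
      }
    }

    women <- data.table::data.table(
      woman_id = sprintf("w%06d", seq_len(n_women)),
      interview_cmc = interview_cmc
    )
    children <- if (n_child) {
      ord <- order(mother, birth_cmc)
      data.table::data.table(
        woman_id = sprintf("w%06d", mother[ord]),
        child_id = sprintf("c%07d", seq_len(n_child)),
        birth_cmc = birth_cmc[ord],
        alive_at_survey = alive[ord],
        death_age_months = death_age[ord]
      )
    } else {
      data.table::data.table(
        woman_id = character(), child_id = character(),
        birth_cmc = integer(), alive_at_survey = logical(),
        death_age_months = integer()
      )
    }
    bh_survey(survey_id, country_id, women, children)
  })
}

#' Simulate a survey from a YAML configuration
#'
#' Reads a YAML file with keys `n_women`, `interview_cmc`, `seed`,
#' optional `survey_id`/`country_id`, a `mortality` block (`q5_start`,
#' optional `q5_end`, `year_start`, `year_end`, `pattern`) and an optional
#' `fertility` block (`monthly_hazard`, `min_interval_months`), and runs
#' [simulate_survey()].
#'
#' @param path Path to the YAML configuration.
#' @return A [bh_survey()].
#' @export
simulate_survey_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  mort <- do.call(mortality_schedule, cfg$mortality)
  fert <- if (is.null(cfg$fertility)) {
    fertility_schedule()
  } else {
    do.call(fertility_schedule, cfg$fertility)
  }
  simulate_survey(
    mort, fert,
    n_women = cfg$n_women, interview_cmc = cfg$interview_cmc,
    survey_id = cfg$survey_id %||% "sim",
    country_id = cfg$country_id %||% "SIM",
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
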