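#' Kernel weight of a child-month relative to a target year
#'
#' A target year `T` is represented by its mid-year `T + 0.5`; with
#' `u = |t - (T + 0.5)|` the flat kernel gives weight 1 when `u <= x/2` and
#' 0 otherwise, and the triangle kernel decreases linearly from 1 at the
#' centre to exactly 0 at `x/2` years on either side:
#' `max(0, 1 - u / (x/2))`.
#'
#' @param t Decimal year(s) of the child-month(s) (see [cmc_to_year()]).
#' @param target_year Integer calendar year the estimate is for.
#' @param window_years Window length `x` in years (the window spans
#'   `x/2` on either side of the target).
#' @param kernel `"flat"` or `"triangle"`.
#' @return Numeric weights in \[0, 1\].
#' @examples
#' kernel_weight(2000.5, 2000, 10, "flat")      # 1 at the centre
#' kernel_weight(2003.0, 2000, 10, "triangle")  # 0.5 halfway out
#' @export
kernel_weight <- function(t, target_year, window_years,
                          kernel = c("flat", "triangle")) {
  kernel <- match.arg(kernel)
  stopifnot(window_years > 0)
  u <- abs(t - (target_year + 0.5))
  half <- window_years / 2
  if (kernel == "flat") {
    as.numeric(u <= half)
  } else {
    pmax(0, 1 - u / half)
  }
}

# Moving-window estimator on monthly tallies. One pass per target year:
# cells inside the window are aggregated by age group (integer sums for
# the flat kernel so results coincide bitwise with the period estimator on
# aligned data; weighted sums for the triangle kernel).
q5_mw_from_counts <- function(counts, window_years, kernel, target_years,
                              by = character()) {
  half <- window_years / 2
  yr <- cmc_to_year(counts$calendar_cmc)
  out <- vector("list", length(target_years))
  for (i in seq_along(target_years)) {
    tt <- target_years[i] + 0.5
    u <- abs(yr - tt)
    if (kernel == "flat") {
      sub <- counts[u <= half]
      if (nrow(sub) == 0L) next
      gs <- sub[, list(tot = sum(tot), alive = sum(alive)),
                by = c(by, "age_group")]
    } else {
      keep <- u < half
      if (!any(keep)) next
      sub <- counts[keep]
      w <- 1 - u[keep] / half
      gs <- sub[, list(tot = sum(tot * w[.I]), alive = sum(alive * w[.I])),
                by = c(by, "age_group")]
      gs <- gs[tot > 0]
      if (nrow(gs) == 0L) next
    }
    est <- q5_from_group_stats(gs, by = by)
    est[, time_years := tt]
    out[[i]] <- est
  }
  out <- data.table::rbindlist(out)
  if (nrow(out)) data.table::setorderv(out, c(by, "time_years"))
  out
}

#' Moving-window complete-birth-history estimator
#'
#' Produces one under-5 mortality estimate per calendar year, each pooling
#' all child-months within a window of `window_years` around that year,
#' weighted by a flat or triangle kernel ([kernel_weight()]). Child-months
#' are reused across overlapping windows, trading temporal resolution
#' against sampling noise. The estimator is a weighted proportion, so
#' windows truncated at the edge of the data need no renormalisation;
#' estimates are emitted for every target year with positive total weight,
#' with the exposure recorded so users can filter thin tails.
#'
#' @param ds A [bh_survey()].
#' @param window_years Window length in years; 5 and 10 are conventional
#'   for both kernels, 20 for the triangle kernel.
#' @param kernel `"flat"` or `"triangle"`.
#' @param target_years Integer years to estimate for; default is the 25
#'   years up to and including the year of the latest interview.
#' @param child_months Optional pre-computed [expand_dataset()] table.
#' @return An estimate series (same shape as [estimate_standard()]) with
#'   `method_tag` `"CBH-MW-F[<x>]"` or `"CBH-MW-T[<x>]"`; estimates sit at
#'   mid-year (`T + 0.5`). `n_child_months` is the total kernel weight
#'   (the plain child-month count under the flat kernel).
#' @export
estimate_moving_window <- function(ds, window_years,
                                   kernel = c("flat", "triangle"),
                                   target_years = NULL,
                                   child_months = NULL) {
  kernel <- match.arg(kernel)
  if (is.null(child_months)) child_months <- expand_dataset(ds)
  if (is.null(target_years)) {
    target_years <- default_target_years(ds$interview_cmc_max)
  }
  est <- q5_mw_from_counts(monthly_counts(child_months), window_years,
                           kernel, target_years)
  data.table::data.table(
    survey_id = ds$survey_id,
    method_tag = sprintf("CBH-MW-%s[%d]",
                         if (kernel == "flat") "F" else "T",
                         as.integer(window_years)),
    time_years = if (nrow(est)) est$time_years else numeric(),
    q5 = if (nrow(est)) est$q5 else numeric(),
    n_child_months = if (nrow(est)) est$n_child_months else numeric()
  )
}

#' Default target years for annual estimates
#'
#' The 25 calendar years up to and including the year of the latest
#' interview — the span over which annual birth-history estimates are
#' conventionally produced.
#'
#' @param interview_cmc_max Integer month index of the latest interview.
#' @return Integer vector of 25 calendar years.
#' @export
default_target_years <- function(interview_cmc_max) {
  y <- floor(cmc_to_year(interview_cmc_max))
  seq.int(y - 24L, y)
}
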