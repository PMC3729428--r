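#' Error metrics comparing estimates to truth
#'
#' The four metrics of the validation: error `e = q5_hat - q5_true`
#' (signed bias, absolute terms), relative error `e / q5_true`, absolute
#' error `|e|` and absolute relative error `|e| / q5_true` (magnitudes).
#' Relative metrics are `NA` when `q5_true` is 0.
#'
#' @param q5_hat Estimated under-5 mortality (vector).
#' @param q5_true True under-5 mortality (vector, recycled).
#' @return A data.table with columns `error`, `relative_error`,
#'   `absolute_error`, `absolute_relative_error`.
#' @examples
#' error_metrics(0.12, 0.10)  # 0.02, 0.2, 0.02, 0.2
#' @export
error_metrics <- function(q5_hat, q5_true) {
  e <- q5_hat - q5_true
  rel <- ifelse(q5_true > 0, e / q5_true, NA_real_)
  data.table::data.table(
    error = e,
    relative_error = rel,
    absolute_error = abs(e),
    absolute_relative_error = abs(rel)
  )
}

#' Match an estimate series to a truth series
#'
#' Evaluates the interpolated truth at each estimate's time; estimates
#' outside the truth's knot span are excluded (the truth is never
#' extrapolated).
#'
#' @param series An estimate series from [estimate_standard()] or
#'   [estimate_moving_window()].
#' @param truth A [build_truth()] object.
#' @return A data.table with columns `year`, `q5_hat`, `q5_true`.
#' @export
match_to_truth <- function(series, truth) {
  tv <- truth_q5(truth, series$time_years)
  keep <- !is.na(tv)
  if (!any(keep) && nrow(series)) {
    warning("no estimates fall within the truth span")
  }
  data.table::data.table(
    year = series$time_years[keep],
    q5_hat = series$q5[keep],
    q5_true = tv[keep]
  )
}

#' Configuration of a subsampling validation study
#'
#' @param sample_sizes Numbers of women per sample; default
#'   `c(10, 50, 100, 500, 1000)`.
#' @param replicates Samples per size (default 500, for 2,500 samples per
#'   survey at the default sizes).
#' @param methods Character vector of method tags: `"CBH[L]"` for the
#'   standard estimator with L-year periods, `"CBH-MW-F[x]"` /
#'   `"CBH-MW-T[x]"` for the moving-window estimator with flat / triangle
#'   weights and an x-year window. The default is the full tested set:
#'   periods 1, 2, 5; flat windows 5, 10; triangle windows 5, 10, 20.
#' @param seed Master seed; every sample's seed derives from it together
#'   with the survey, size and replicate indices, so any single cell of
#'   the study is independently re-runnable.
#' @return A list of class `validation_config`.
#' @export
validation_config <- function(sample_sizes = c(10, 50, 100, 500, 1000),
                              replicates = 500,
                              methods = default_methods(),
                              seed = 1L) {
  stopifnot(all(sample_sizes >= 1), replicates >= 1, length(methods) >= 1)
  lapply(methods, parse_method_tag)  # fail fast on malformed tags
  structure(
    list(sample_sizes = as.integer(sample_sizes),
         replicates = as.integer(replicates),
         methods = methods, seed = as.integer(seed)),
    class = "validation_config"
  )
}

#' The default set of complete-birth-history method tags
#' @return Character vector of the eight tested configurations.
#' @export
default_methods <- function() {
  c("CBH[1]", "CBH[2]", "CBH[5]",
    "CBH-MW-F[5]", "CBH-MW-F[10]",
    "CBH-MW-T[5]", "CBH-MW-T[10]", "CBH-MW-T[20]")
}

# "CBH[2]" -> standard, L = 2; "CBH-MW-T[10]" -> moving window, triangle,
# x = 10. Flat windows are tested at 5 and 10 years, triangle at 5/10/20.
parse_method_tag <- function(tag) {
  m <- regmatches(tag, regexec("^CBH(-MW-([FT]))?\\[([0-9]+)\\]$", tag))[[1]]
  if (length(m) == 0L) {
    stop("malformed method tag: '", tag,
         "' (expected e.g. CBH[2] or CBH-MW-T[10])")
  }
  len <- as.integer(m[4])
  if (m[2] == "") {
    list(type = "standard", length_years = len)
  } else {
    list(type = "mw", window_years = len,
         kernel = if (m[3] == "F") "flat" else "triangle")
  }
}

#' Estimate under-5 mortality by method tag
#'
#' Convenience dispatcher from a method tag (see [validation_config()]) to
#' [estimate_standard()] or [estimate_moving_window()].
#'
#' @param ds A [bh_survey()].
#' @param tag Method tag, e.g. `"CBH[2]"` or `"CBH-MW-T[10]"`.
#' @param anchor_cmc Period anchor for standard methods (ignored by
#'   moving-window methods); defaults to the survey's latest interview.
#' @param target_years Target years for moving-window methods (ignored by
#'   standard methods); defaults to the 25 years up to the interview.
#' @param child_months Optional pre-computed [expand_dataset()] table.
#' @return An estimate series.
#' @export
estimate_by_tag <- function(ds, tag, anchor_cmc = NULL, target_years = NULL,
                            child_months = NULL) {
  spec <- parse_method_tag(tag)
  if (spec$type == "standard") {
    estimate_standard(ds, spec$length_years, anchor_cmc = anchor_cmc,
                      child_months = child_months)
  } else {
    estimate_moving_window(ds, spec$window_years, spec$kernel,
                           target_years = target_years,
                           child_months = child_months)
  }
}

# Deterministic per-cell seed below 2^31.
replicate_seed <- function(master, survey_idx, size, replicate) {
  (as.double(master) * 1000003 + survey_idx * 97003 +
     as.double(size) * 131 + replicate) %% 2147483647
}

#' Run the subsampling validation study
#'
#' For each survey: the truth series is built from the full data
#' ([build_truth()]); then for every sample size and replicate a simple
#' random sample of women is drawn without replacement, every configured
#' method is run on it, estimates are matched to the truth and the four
#' error metrics are recorded. Deterministic given `cfg$seed`.
#'
#' @param surveys A [bh_survey()] or list of them.
#' @param cfg A [validation_config()].
#' @param target_years Optional integer years for the moving-window
#'   methods; default, per survey, the 25 years up to its latest
#'   interview.
#' @return A data.table of error records with columns `survey_id`,
#'   `method_tag`, `sample_size`, `replicate`, `year`, `q5_hat`,
#'   `q5_true`, `error`, `relative_error`, `absolute_error`,
#'   `absolute_relative_error`, `years_prior` (time before the survey),
#'   `n_surveys` (1 here; see [run_pooled_validation()]). Samples that
#'   yield no estimates inside the truth span contribute no rows.
#' @export
run_validation <- function(surveys, cfg, target_years = NULL) {
  if (inherits(surveys, "bh_survey")) surveys <- list(surveys)
  stopifnot(inherits(cfg, "validation_config"))
  out <- vector("list", length(surveys))
  for (si in seq_along(surveys)) {
    ds <- surveys[[si]]
    cm <- expand_dataset(ds)
    truth <- build_truth(ds, child_months = cm)
    out[[si]] <- validate_one(
      survey_id = ds$survey_id, truth = truth, cfg = cfg,
      anchor_cmc = ds$interview_cmc_max,
      target_years = target_years %||%
        default_target_years(ds$interview_cmc_max),
      survey_idx = si, n_surveys = 1L,
      cm = cm, draw_replicate = sampler_single(ds)
    )
  }
  data.table::rbindlist(out)
}

#' Run the pooled multi-survey validation
#'
#' The multi-survey design: the truth is computed from all surveys of one
#' country pooled together, and each estimation sample concatenates an
#' independent draw of `n` women from *each* survey — samples are still
#' drawn at the survey level, so with `k` surveys a nominal size `n`
#' sample contains `k * n` women. Records carry `n_surveys = k` for
#' stratified summaries. With a single survey this reduces to
#' [run_validation()].
#'
#' @param surveys List of [bh_survey()] objects sharing `country_id`.
#' @param cfg A [validation_config()]; `sample_sizes` are per-survey.
#' @param target_years As in [run_validation()]; default spans the 25
#'   years up to the latest interview across the pooled surveys.
#' @return A data.table of error records (same shape as
#'   [run_validation()]); `survey_id` is the pooled id and `sample_size`
#'   the per-survey size.
#' @export
run_pooled_validation <- function(surveys, cfg, target_years = NULL) {
  if (inherits(surveys, "bh_survey")) surveys <- list(surveys)
  if (length(surveys) == 1L) return(run_validation(surveys, cfg, target_years))
  pooled <- pool_surveys(surveys)
  cm <- expand_dataset(pooled)
  truth <- build_truth(pooled, child_months = cm)
  validate_one(
    survey_id = pooled$survey_id, truth = truth, cfg = cfg,
    anchor_cmc = pooled$interview_cmc_max,
    target_years = target_years %||%
      default_target_years(pooled$interview_cmc_max),
    survey_idx = 1L, n_surveys = length(surveys),
    cm = cm, draw_replicate = sampler_pooled(surveys)
  )
}

# A sampler closure returns, for (size, seed), the woman_ids (as they
# appear in the expanded child-month table) of one replicate sample.
sampler_single <- function(ds) {
  ids_pop <- ds$women$woman_id
  function(n, seed) {
    if (n > length(ids_pop)) {
      stop("sample size ", n, " exceeds ", length(ids_pop), " women")
    }
    withr_seed(seed, sample(ids_pop, n))
  }
}

sampler_pooled <- function(surveys) {
  pops <- lapply(surveys, function(s) {
    paste(s$survey_id, s$women$woman_id, sep = ":")
  })
  function(n, seed) {
    withr_seed(seed, {
      unlist(lapply(pops, function(ids) {
        if (n > length(ids)) {
          stop("sample size ", n, " exceeds ", length(ids), " women")
        }
        sample(ids, n)
      }), use.names = FALSE)
    })
  }
}

# Core engine shared by single-survey and pooled validation. Samples are
# materialised as a (replicate, woman_id) table in memory-bounded blocks,
# joined once against the pre-expanded child-months and tallied by
# (replicate, calendar month, age group); every method then runs on the
# tallies for all replicates at once. This is algebraically identical to
# calling the public estimators sample by sample (the unit tests assert
# so), just without re-expanding children.
validate_one <- function(survey_id, truth, cfg, anchor_cmc, target_years,
                         survey_idx, n_surveys, cm, draw_replicate) {
  cm_slim <- cm[, list(woman_id, calendar_cmc, age_group, ends_alive)]
  data.table::setkey(cm_slim, woman_id)
  interview_year <- cmc_to_year(anchor_cmc)
  out <- list()
  for (n in cfg$sample_sizes) {
    # Tally child-months per replicate in blocks of ~50k sampled women.
    block <- max(1L, 50000L %/% n)
    counts <- list()
    r <- 1L
    while (r <= cfg$replicates) {
      reps <- seq.int(r, min(r + block - 1L, cfg$replicates))
      rw <- data.table::rbindlist(lapply(reps, function(rep_i) {
        ids <- draw_replicate(n, replicate_seed(cfg$seed, survey_idx, n, rep_i))
        data.table::data.table(replicate = rep_i, woman_id = ids)
      }))
      joined <- cm_slim[rw, on = "woman_id", allow.cartesian = TRUE,
                        nomatch = NULL]
      counts[[length(counts) + 1L]] <-
        joined[, list(tot = .N, alive = sum(ends_alive)),
               by = c("replicate", "calendar_cmc", "age_group")]
      r <- r + block
    }
    counts <- data.table::rbindlist(counts)
    for (tag in cfg$methods) {
      spec <- parse_method_tag(tag)
      est <- if (spec$type == "standard") {
        q5_standard_from_counts(counts, spec$length_years, anchor_cmc,
                                by = "replicate")
      } else {
        q5_mw_from_counts(counts, spec$window_years, spec$kernel,
                          target_years, by = "replicate")
      }
      if (nrow(est) == 0L) next
      tv <- truth_q5(truth, est$time_years)
      keep <- !is.na(tv)
      if (!any(keep)) next
      rec <- data.table::data.table(
        survey_id = survey_id, method_tag = tag, sample_size = n,
        replicate = est$replicate[keep], year = est$time_years[keep],
        q5_hat = est$q5[keep], q5_true = tv[keep]
      )
      rec <- cbind(rec, error_metrics(rec$q5_hat, rec$q5_true))
      rec[, years_prior := interview_year - year]
      rec[, n_surveys := n_surveys]
      out[[length(out) + 1L]] <- rec
    }
  }
  data.table::rbindlist(out)
}

#' Summarise validation error records
#'
#' Computes, per method and sample size (optionally further stratified),
#' the mean of each error metric over all matched records, plus the 2.5th
#' and 97.5th percentiles of the signed error and the record count.
#' Records where the truth is exactly 0 are excluded from the relative
#' metrics' means (their count is reported in `n_rel_dropped`).
#'
#' @param records Error records from [run_validation()] or
#'   [run_pooled_validation()].
#' @param stratifier One of `"none"`, `"mortality"` (true mortality bins
#'   <50, 50-100, 100-150, 150-200, >200 deaths per 1,000 births, bins
#'   half-open on the right), `"time_prior"` (two-year bins 0-1, 2-3, ...,
#'   24-25 years before the survey) or `"n_surveys"` (number of pooled
#'   surveys).
#' @return A data.table with grouping columns, `mean_error`,
#'   `mean_rel_error`, `mean_abs_error`, `mean_abs_rel_error`, `p2_5`,
#'   `p97_5` (percentiles of the signed error), `n_records`,
#'   `n_rel_dropped`.
#' @export
summarize_errors <- function(records,
                             stratifier = c("none", "mortality",
                                            "time_prior", "n_surveys")) {
  stratifier <- match.arg(stratifier)
  stopifnot(nrow(records) > 0L)
  rec <- data.table::as.data.table(records)
  keys <- c("method_tag", "sample_size")
  if (stratifier == "mortality") {
    rec[, stratum := mortality_bin(q5_true)]
    keys <- c(keys, "stratum")
  } else if (stratifier == "time_prior") {
    rec[, stratum := time_prior_bin(years_prior)]
    keys <- c(keys, "stratum")
  } else if (stratifier == "n_surveys") {
    keys <- c(keys, "n_surveys")
  }
  out <- rec[, list(
    mean_error = mean(error),
    mean_rel_error = mean(relative_error, na.rm = TRUE),
    mean_abs_error = mean(absolute_error),
    mean_abs_rel_error = mean(absolute_relative_error, na.rm = TRUE),
    p2_5 = stats::quantile(error, 0.025, names = FALSE),
    p97_5 = stats::quantile(error, 0.975, names = FALSE),
    n_records = .N,
    n_rel_dropped = sum(is.na(relative_error))
  ), by = keys]
  data.table::setorderv(out, keys)
  out[]
}

# <50, [50,100), [100,150), [150,200), >=200 deaths per 1,000 births.
mortality_bin <- function(q5_true) {
  per1000 <- q5_true * 1000
  labs <- c("<50", "50-100", "100-150", "150-200", ">200")
  idx <- findInterval(per1000, c(50, 100, 150, 200)) + 1L
  factor(labs[idx], levels = labs)
}

# Half-open two-year bins [0,2) -> "0-1", ..., [24,26) -> "24-25";
# anything earlier is pooled into ">25". Estimates nominally after the
# interview date (a mid-year placement can slightly postdate a survey
# fielded early in the year) count as time prior 0.
time_prior_bin <- function(years_prior) {
  b <- pmin(floor(pmax(years_prior, 0) / 2), 13)
  labs <- c(sprintf("%d-%d", seq(0, 24, 2), seq(1, 25, 2)), ">25")
  factor(labs[b + 1L], levels = labs)
}

#' Write an estimate series or error-record table to CSV
#'
#' Thin wrappers over [data.table::fwrite()] kept for a stable on-disk
#' schema.
#'
#' @param x The table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  data.table::fwrite(x, path, na = "")
  invisible(path)
}
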