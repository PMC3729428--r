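#' Construct a birth-history survey dataset
#'
#' A `bh_survey` holds one survey: a table of interviewed women and a table
#' of their children, in the form a complete birth history records them —
#' each child's month of birth and, if the child died, the age at death in
#' completed months. All dates are integer CMC-style month indices (months
#' since January 1900; see [cmc_to_year()]).
#'
#' @param survey_id Character scalar identifying the survey.
#' @param country_id Character scalar identifying the country (used when
#'   pooling surveys; see [pool_surveys()]).
#' @param women A data.frame with columns `woman_id` (unique within the
#'   survey) and `interview_cmc` (integer month of interview).
#' @param children A data.frame with columns `woman_id`, `child_id`,
#'   `birth_cmc`, `alive_at_survey` (logical) and `death_age_months`
#'   (integer completed months lived, `NA` for children alive at survey).
#'   May have zero rows; childless women are legitimate and contribute
#'   sample size but no exposure.
#' @return An object of class `bh_survey` with elements `survey_id`,
#'   `country_id`, `women`, `children` and `interview_cmc_max` (the latest
#'   interview month across women, the anchor for period construction).
#' @details Invariants enforced: `woman_id` unique among women; every
#'   child's `woman_id` refers to an interviewed woman; `death_age_months`
#'   is present exactly for dead children; no child is born after the
#'   mother's interview month. `death_age_months = d` means the child died
#'   during their month of age `d`, so `d = 0` is a death in the month of
#'   birth.
#' @seealso [read_birth_history_csv()], [simulate_survey()]
#' @export
bh_survey <- function(survey_id, country_id, women, children) {
  women <- data.table::as.data.table(women)
  children <- data.table::as.data.table(children)
  if (nrow(children) == 0L) {
    children <- data.table::data.table(
      woman_id = character(), child_id = character(),
      birth_cmc = integer(), alive_at_survey = logical(),
      death_age_months = integer()
    )
  }
  women[, woman_id := as.character(woman_id)]
  women[, interview_cmc := as.integer(interview_cmc)]
  children[, woman_id := as.character(woman_id)]
  children[, child_id := as.character(child_id)]
  children[, birth_cmc := as.integer(birth_cmc)]
  children[, alive_at_survey := as.logical(alive_at_survey)]
  children[, death_age_months := as.integer(death_age_months)]
  ds <- structure(
    list(
      survey_id = as.character(survey_id),
      country_id = as.character(country_id),
      women = women[, list(woman_id, interview_cmc)],
      children = children[, list(woman_id, child_id, birth_cmc,
                                 alive_at_survey, death_age_months)],
      interview_cmc_max = if (nrow(women)) max(women$interview_cmc) else NA_integer_
    ),
    class = "bh_survey"
  )
  validate_bh_survey(ds)
  ds
}

#' Validate a birth-history survey dataset
#'
#' Checks the `bh_survey` invariants and stops with an informative error
#' naming the offending rows on the first violation.
#'
#' @param ds A [bh_survey()] object.
#' @return `ds`, invisibly, if valid.
#' @export
validate_bh_survey <- function(ds) {
  stopifnot(inherits(ds, "bh_survey"))
  w <- ds$women
  ch <- ds$children
  if (nrow(w) == 0L) {
    stop("survey '", ds$survey_id, "' contains no women")
  }
  if (anyDuplicated(w$woman_id)) {
    stop("duplicated woman_id in survey '", ds$survey_id, "': ",
         paste(unique(w$woman_id[duplicated(w$woman_id)])[1:3], collapse = ", "))
  }
  if (anyNA(w$interview_cmc)) stop("missing interview_cmc")
  if (nrow(ch)) {
    bad <- !(ch$woman_id %in% w$woman_id)
    if (any(bad)) {
      stop("child rows reference unknown woman_id: ",
           paste(utils::head(unique(ch$woman_id[bad]), 3), collapse = ", "))
    }
    if (anyNA(ch$birth_cmc) || anyNA(ch$alive_at_survey)) {
      stop("missing birth_cmc or alive_at_survey in children table")
    }
    bad <- ch$alive_at_survey & !is.na(ch$death_age_months)
    if (any(bad)) {
      stop("death_age_months present for living child: ",
           paste(utils::head(ch$child_id[bad], 3), collapse = ", "))
    }
    bad <- !ch$alive_at_survey & is.na(ch$death_age_months)
    if (any(bad)) {
      stop("death_age_months missing for dead child: ",
           paste(utils::head(ch$child_id[bad], 3), collapse = ", "))
    }
    if (any(!is.na(ch$death_age_months) & ch$death_age_months < 0L)) {
      stop("negative death_age_months")
    }
    icmc <- w$interview_cmc[match(ch$woman_id, w$woman_id)]
    bad <- ch$birth_cmc > icmc
    if (any(bad)) {
      stop("child born after mother's interview month: ",
           paste(utils::head(ch$child_id[bad], 3), collapse = ", "))
    }
  }
  if (!identical(ds$interview_cmc_max, max(w$interview_cmc))) {
    stop("interview_cmc_max does not match women table")
  }
  invisible(ds)
}

#' @export
print.bh_survey <- function(x, ...) {
  n_dead <- sum(!x$children$alive_at_survey)
  cat(sprintf(
    "<bh_survey> %s (%s): %d women, %d children (%d dead), interviews up to %s (%.2f)\n",
    x$survey_id, x$country_id, nrow(x$women), nrow(x$children), n_dead,
    x$interview_cmc_max, cmc_to_year(x$interview_cmc_max)
  ))
  invisible(x)
}

bh_csv_columns <- c("survey_id", "country_id", "woman_id", "interview_cmc",
                    "child_id", "birth_cmc", "alive_at_survey",
                    "death_age_months")

#' Read a birth-history survey from CSV
#'
#' The expected schema has one row per child plus one row (with empty child
#' fields) per childless woman, UTF-8, with header columns exactly
#' `survey_id, country_id, woman_id, interview_cmc, child_id, birth_cmc,
#' alive_at_survey, death_age_months`. `alive_at_survey` is `true`/`false`;
#' `death_age_months` is empty for living children. Conversion from raw DHS
#' recode files to this schema is the user's responsibility.
#'
#' @param path Path to a CSV file in the schema above.
#' @return A validated [bh_survey()].
#' @export
read_birth_history_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- names(data.table::fread(path, nrows = 0L))
  missing_cols <- setdiff(bh_csv_columns, hdr)
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dt <- data.table::fread(path, colClasses = list(
    character = c("survey_id", "country_id", "woman_id", "child_id"),
    integer = c("interview_cmc", "birth_cmc", "death_age_months"),
    logical = "alive_at_survey"
  ), na.strings = "")
  if (length(unique(dt$survey_id)) != 1L) {
    stop("file must contain exactly one survey_id")
  }
  women <- unique(dt[, list(woman_id, interview_cmc)])
  has_child <- !is.na(dt$child_id) & dt$child_id != ""
  children <- dt[has_child,
                 list(woman_id, child_id, birth_cmc, alive_at_survey,
                      death_age_months)]
  bh_survey(dt$survey_id[1L], dt$country_id[1L], women, children)
}

#' Write a birth-history survey to CSV
#'
#' Inverse of [read_birth_history_csv()]: writing then reading reproduces
#' the dataset exactly.
#'
#' @param ds A [bh_survey()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_birth_history_csv <- function(ds, path) {
  validate_bh_survey(ds)
  rows <- merge(ds$women, ds$children, by = "woman_id", all.x = TRUE,
                sort = FALSE)
  rows[, `:=`(survey_id = ds$survey_id, country_id = ds$country_id)]
  data.table::setcolorder(rows, bh_csv_columns)
  data.table::setorder(rows, woman_id, child_id, na.last = FALSE)
  data.table::fwrite(rows, path, na = "", logical01 = FALSE)
  invisible(path)
}

#' Sample women without replacement
#'
#' Draws a simple random sample of `n` women (with all their children) from
#' a survey, mirroring the subsampling design of the validation study:
#' sampling is of women, not children, so childless women count toward `n`.
#'
#' @param ds A [bh_survey()].
#' @param n Number of women to draw; must not exceed the number of women.
#' @param seed Optional integer; when given, the draw is deterministic and
#'   the caller's RNG state is untouched. When `NULL` the current RNG
#'   stream is used.
#' @return A new [bh_survey()] with exactly `n` distinct women; survey
#'   metadata is preserved and `interview_cmc_max` is recomputed for the
#'   sample.
#' @export
sample_women <- function(ds, n, seed = NULL) {
  validate_bh_survey(ds)
  n_pop <- nrow(ds$women)
  if (n < 1L || n > n_pop) {
    stop("n must be in [1, ", n_pop, "], got ", n)
  }
  ids <- if (is.null(seed)) {
    sample(ds$women$woman_id, n)
  } else {
    withr_seed(seed, sample(ds$women$woman_id, n))
  }
  subset_women(ds, ids)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Subset a survey to the given woman_ids (kept in the given order).
subset_women <- function(ds, ids) {
  women <- ds$women[match(ids, woman_id)]
  children <- ds$children[woman_id %in% ids]
  bh_survey(ds$survey_id, ds$country_id, women, children)
}

#' Pool surveys from one country into a single dataset
#'
#' Concatenates several surveys (normally repeated surveys of one country)
#' into one `bh_survey`, disambiguating woman and child identifiers with a
#' survey prefix. Periods anchored on the pooled dataset start at the most
#' recent interview month across surveys.
#'
#' @param surveys A list of [bh_survey()] objects sharing `country_id`.
#' @param survey_id Identifier for the pooled dataset; defaults to
#'   `"<country>_pooled"`.
#' @return A [bh_survey()] containing all women and children.
#' @export
pool_surveys <- function(surveys, survey_id = NULL) {
  stopifnot(length(surveys) >= 1L)
  country <- unique(vapply(surveys, function(s) s$country_id, character(1)))
  if (length(country) != 1L) {
    stop("surveys to pool must share country_id; got: ",
         paste(country, collapse = ", "))
  }
  if (is.null(survey_id)) survey_id <- paste0(country, "_pooled")
  women <- data.table::rbindlist(lapply(surveys, function(s) {
    w <- data.table::copy(s$women)
    w[, woman_id := paste(s$survey_id, woman_id, sep = ":")]
  }))
  children <- data.table::rbindlist(lapply(surveys, function(s) {
    ch <- data.table::copy(s$children)
    if (nrow(ch)) {
      ch[, woman_id := paste(s$survey_id, woman_id, sep = ":")]
      ch[, child_id := paste(s$survey_id, child_id, sep = ":")]
    }
    ch
  }))
  bh_survey(survey_id, country, women, children)
}
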