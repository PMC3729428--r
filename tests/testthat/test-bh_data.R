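test_that("construction and validation enforce the survey invariants", {
  ds <- toy_survey()
  expect_s3_class(ds, "bh_survey")
  expect_equal(nrow(ds$women), 2L)
  expect_equal(nrow(ds$children), 2L)
  expect_equal(ds$interview_cmc_max, 120L)

  women <- data.frame(woman_id = c("a", "b"), interview_cmc = c(100L, 110L))
  # dead child without an age at death
  expect_error(
    bh_survey("s", "c", women, data.frame(
      woman_id = "a", child_id = "k1", birth_cmc = 90L,
      alive_at_survey = FALSE, death_age_months = NA_integer_
    )),
    "death_age_months missing"
  )
  # living child with an age at death
  expect_error(
    bh_survey("s", "c", women, data.frame(
      woman_id = "a", child_id = "k1", birth_cmc = 90L,
      alive_at_survey = TRUE, death_age_months = 3L
    )),
    "death_age_months present"
  )
  # born after the interview
  expect_error(
    bh_survey("s", "c", women, data.frame(
      woman_id = "a", child_id = "k1", birth_cmc = 101L,
      alive_at_survey = TRUE, death_age_months = NA_integer_
    )),
    "born after"
  )
  # duplicated woman
  expect_error(
    bh_survey("s", "c", data.frame(woman_id = c("a", "a"),
                                   interview_cmc = 100L),
              data.frame()[0, ]),
    "duplicated woman_id"
  )
  # childless women are fine
  ds0 <- bh_survey("s", "c", women, data.frame(
    woman_id = character(), child_id = character(), birth_cmc = integer(),
    alive_at_survey = logical(), death_age_months = integer()
  ))
  expect_equal(nrow(ds0$children), 0L)
})

test_that("CSV schema round-trips exactly, including childless women", {
  ds <- simulate_survey(mortality_schedule(0.2), fertility_schedule(),
                        n_women = 150, interview_cmc = 1200, seed = 42)
  expect_gt(sum(!ds$women$woman_id %in% ds$children$woman_id), 0)
  path <- tempfile(fileext = ".csv")
  write_birth_history_csv(ds, path)
  back <- read_birth_history_csv(path)
  expect_equal(back$survey_id, ds$survey_id)
  expect_equal(back$country_id, ds$country_id)
  expect_equal(
    data.table::setorder(data.table::copy(back$women), woman_id),
    data.table::setorder(data.table::copy(ds$women), woman_id)
  )
  expect_equal(
    data.table::setorder(data.table::copy(back$children), child_id),
    data.table::setorder(data.table::copy(ds$children), child_id)
  )
  # one row per child plus one per childless woman
  n_childless <- sum(!ds$women$woman_id %in% ds$children$woman_id)
  expect_equal(nrow(data.table::fread(path)),
               nrow(ds$children) + n_childless)
})

test_that("reading rejects missing columns and inconsistent rows", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("survey_id,woman_id,interview_cmc", "s,a,100"), path)
  expect_error(read_birth_history_csv(path), "missing column")

  writeLines(c(
    paste(c("survey_id", "country_id", "woman_id", "interview_cmc",
            "child_id", "birth_cmc", "alive_at_survey",
            "death_age_months"), collapse = ","),
    "s,c,a,100,k1,90,false,"
  ), path)
  expect_error(read_birth_history_csv(path), "death_age_months missing")
})

test_that("sampling women is without replacement and seed-deterministic", {
  ds <- simulate_survey(mortality_schedule(0.2), fertility_schedule(),
                        n_women = 200, interview_cmc = 1200, seed = 3)
  s1 <- sample_women(ds, 50, seed = 9)
  s2 <- sample_women(ds, 50, seed = 9)
  s3 <- sample_women(ds, 50, seed = 10)
  expect_equal(nrow(s1$women), 50L)
  expect_equal(anyDuplicated(s1$women$woman_id), 0L)
  expect_identical(s1$women$woman_id, s2$women$woman_id)
  expect_false(identical(s1$women$woman_id, s3$women$woman_id))
  # all children of each sampled woman come along
  expect_equal(
    nrow(s1$children),
    sum(ds$children$woman_id %in% s1$women$woman_id)
  )
  # exhaustive draw is a permutation
  sall <- sample_women(ds, nrow(ds$women), seed = 1)
  expect_setequal(sall$women$woman_id, ds$women$woman_id)
  expect_error(sample_women(ds, nrow(ds$women) + 1, seed = 1), "n must be")
})

test_that("pooling prefixes identifiers and concatenates surveys", {
  a <- simulate_survey(mortality_schedule(0.2), fertility_schedule(),
                       n_women = 40, interview_cmc = 1200,
                       survey_id = "A1", country_id = "AA", seed = 1)
  b <- simulate_survey(mortality_schedule(0.2), fertility_schedule(),
                       n_women = 60, interview_cmc = 1260,
                       survey_id = "A2", country_id = "AA", seed = 2)
  p <- pool_surveys(list(a, b))
  expect_equal(nrow(p$women), 100L)
  expect_equal(nrow(p$children), nrow(a$children) + nrow(b$children))
  expect_equal(p$interview_cmc_max, 1260L)
  expect_true(all(grepl("^A[12]:", p$women$woman_id)))
  c_ <- simulate_survey(mortality_schedule(0.2), fertility_schedule(),
                        n_women = 10, interview_cmc = 1200,
                        country_id = "BB", seed = 3)
  expect_error(pool_surveys(list(a, c_)), "share country_id")
})
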