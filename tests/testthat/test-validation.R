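test_that("error metrics follow the four formulas, rowwise", {
  m <- error_metrics(0.12, 0.10)
  expect_equal(unlist(m),
               c(error = 0.02, relative_error = 0.2,
                 absolute_error = 0.02, absolute_relative_error = 0.2))
  m <- error_metrics(0.05, 0.10)  # underestimates are negative
  expect_equal(m$error, -0.05)
  expect_equal(m$relative_error, -0.5)
  expect_equal(m$absolute_error, 0.05)
  expect_equal(m$absolute_relative_error, 0.5)
  expect_equal(unname(unlist(error_metrics(0.3, 0.3))), rep(0, 4))
  # identities hold on arbitrary vectors; relative metrics undefined at 0
  set.seed(1)
  hat <- runif(50); tru <- c(0, runif(49))
  m <- error_metrics(hat, tru)
  expect_equal(m$absolute_error, abs(m$error))
  expect_equal(m$absolute_relative_error, abs(m$relative_error))
  expect_true(is.na(m$relative_error[1]))
})

test_that("estimates are matched to interpolated truth, never extrapolated", {
  knots <- data.table::data.table(
    survey_id = "s", method_tag = "CBH[2]",
    time_years = c(1990, 1992), q5 = c(0.10, 0.20),
    n_child_months = c(10L, 10L))
  truth <- structure(list(survey_id = "s", knots = knots),
                     class = "bh_truth")
  series <- data.table::data.table(
    survey_id = "s", method_tag = "CBH[1]",
    time_years = c(1987, 1990, 1991, 1992.5), q5 = c(0.5, 0.1, 0.3, 0.2),
    n_child_months = 1L)
  matched <- match_to_truth(series, truth)
  expect_equal(matched$year, c(1990, 1991))
  expect_equal(matched$q5_true, c(0.10, 0.15))
  expect_warning(
    out <- match_to_truth(series[time_years < 1989], truth),
    "no estimates"
  )
  expect_equal(nrow(out), 0L)
})

test_that("stratum bins sit at the stated boundaries", {
  # mortality bins are per-1,000, half-open on the right
  expect_equal(
    as.character(smallbh:::mortality_bin(c(0.049, 0.050, 0.0999, 0.100,
                                           0.150, 0.199, 0.200, 0.250))),
    c("<50", "50-100", "50-100", "100-150", "150-200", "150-200",
      ">200", ">200"))
  # two-year time-prior bins, estimates after the survey clamp to "0-1"
  expect_equal(
    as.character(smallbh:::time_prior_bin(c(-0.3, 0, 1.9, 2.0, 3.9, 24.0,
                                            25.9, 26.0))),
    c("0-1", "0-1", "0-1", "2-3", "2-3", "24-25", "24-25", ">25"))
})

test_that("method tags parse to estimator configurations", {
  expect_equal(smallbh:::parse_method_tag("CBH[2]"),
               list(type = "standard", length_years = 2L))
  expect_equal(smallbh:::parse_method_tag("CBH-MW-T[20]"),
               list(type = "mw", window_years = 20L, kernel = "triangle"))
  expect_equal(smallbh:::parse_method_tag("CBH-MW-F[5]"),
               list(type = "mw", window_years = 5L, kernel = "flat"))
  expect_error(smallbh:::parse_method_tag("SBH"), "malformed")
  ds <- toy_survey()
  expect_identical(estimate_by_tag(ds, "CBH[10]"),
                   estimate_standard(ds, 10))
})

test_that("the validation engine equals per-sample use of the public API", {
  ds <- simulate_survey(mortality_schedule(0.25, 0.12, 1980, 2010),
                        fertility_schedule(), n_women = 600,
                        interview_cmc = 1332, seed = 13)
  cfg <- validation_config(sample_sizes = c(25, 60), replicates = 4,
                           methods = c("CBH[2]", "CBH-MW-T[10]"), seed = 5)
  rec <- run_validation(ds, cfg)
  expect_true(all(rec$absolute_error == abs(rec$error)))
  expect_true(all(rec$sample_size %in% c(25, 60)))
  expect_true(all(rec$n_surveys == 1L))

  # reproduce one cell by hand with the public building blocks
  truth <- build_truth(ds)
  for (n in c(25, 60)) {
    for (r in 1:4) {
      seed_r <- smallbh:::replicate_seed(5, 1, n, r)
      samp <- sample_women(ds, n, seed = seed_r)
      for (tag in c("CBH[2]", "CBH-MW-T[10]")) {
        est <- estimate_by_tag(samp, tag,
                               anchor_cmc = ds$interview_cmc_max,
                               target_years =
                                 default_target_years(ds$interview_cmc_max))
        matched <- match_to_truth(est, truth)
        cell <- rec[rec$method_tag == tag & rec$sample_size == n &
                      rec$replicate == r]
        expect_equal(cell$year, matched$year)
        expect_equal(cell$q5_hat, matched$q5_hat, tolerance = 1e-12)
        expect_equal(cell$q5_true, matched$q5_true)
      }
    }
  }

  # determinism: same config twice gives identical records
  expect_identical(rec, run_validation(ds, cfg))
})

test_that("summaries average matched records per cell", {
  rec <- data.table::data.table(
    survey_id = "s", method_tag = "CBH[1]", sample_size = 10L,
    replicate = 1:4, year = 2000.5,
    q5_hat = c(0.12, 0.08, 0.12, 0.08), q5_true = 0.10,
    years_prior = 3, n_surveys = 1L)
  rec <- cbind(rec, error_metrics(rec$q5_hat, rec$q5_true))
  s <- summarize_errors(rec)
  expect_equal(s$mean_error, 0)
  expect_equal(s$mean_abs_error, 0.02)
  expect_equal(s$mean_abs_rel_error, 0.2)
  expect_equal(s$n_records, 4L)
  # all-identical records collapse to their common value
  rec2 <- rec[c(1, 1, 1)]
  s2 <- summarize_errors(rec2)
  expect_equal(s2$mean_error, 0.02)
  expect_equal(s2$p2_5, 0.02)
  expect_equal(s2$p97_5, 0.02)
  # stratified summaries add the stratum key
  s3 <- summarize_errors(rec, "mortality")
  expect_true("stratum" %in% names(s3))
  expect_equal(as.character(s3$stratum), "100-150")
  s4 <- summarize_errors(rec, "time_prior")
  expect_equal(as.character(s4$stratum), "2-3")
})

test_that("pooled validation draws per-survey samples and tags n_surveys", {
  mort <- mortality_schedule(0.25, 0.12, 1980, 2010)
  surveys <- list(
    simulate_survey(mort, fertility_schedule(), 300, 1272,
                    survey_id = "S1", country_id = "CC", seed = 41),
    simulate_survey(mort, fertility_schedule(), 300, 1332,
                    survey_id = "S2", country_id = "CC", seed = 42)
  )
  # the sampler draws n women from each survey: 2 surveys x n=10 -> 20
  samp <- smallbh:::sampler_pooled(surveys)
  ids <- samp(10, seed = 1)
  expect_length(ids, 20L)
  expect_equal(sum(startsWith(ids, "S1:")), 10L)
  expect_equal(sum(startsWith(ids, "S2:")), 10L)
  expect_equal(anyDuplicated(ids), 0L)

  cfg <- validation_config(sample_sizes = 10, replicates = 3,
                           methods = "CBH[2]", seed = 2)
  rec <- run_pooled_validation(surveys, cfg)
  expect_true(all(rec$n_surveys == 2L))
  expect_true(all(rec$survey_id == "CC_pooled"))
  expect_identical(rec, run_pooled_validation(surveys, cfg))
  # single survey falls back to the plain validation
  expect_identical(run_pooled_validation(surveys[1], cfg),
                   run_validation(surveys[[1]], cfg))
})
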