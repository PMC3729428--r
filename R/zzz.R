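#' @importFrom data.table := .N .I .SD data.table as.data.table
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "woman_id", "interview_cmc", "child_id", "birth_cmc",
  "alive_at_survey", "death_age_months", "survey_id", "country_id",
  "calendar_cmc", "age_months", "age_group", "ends_alive", "child",
  "tot", "alive", "n_months", "period", "time_years", "q5",
  "n_child_months", "replicate", "years_prior", "year", "n_surveys",
  "q5_hat", "q5_true", "error", "relative_error", "absolute_error",
  "absolute_relative_error", "stratum", "method_tag", "sample_size"
))
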