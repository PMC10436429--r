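# Shared fixtures, built in code.

# resolved default generator parameters are expensive (disturbance
# calibration + intercept roots), so they are computed once per session
.param_cache <- new.env(parent = emptyenv())

resolved_default_params <- function() {
  if (is.null(.param_cache$default)) {
    .param_cache$default <- solve_intercepts(generator_params())
  }
  .param_cache$default
}

# a small hand-built cohort data frame with valid columns
make_cohort_df <- function(n = 12L, seed = 42L) {
  set.seed(seed)
  df <- data.frame(
    education_raw = sample(1:8, n, replace = TRUE),
    financial_raw = sample(1:7, n, replace = TRUE),
    instrumental_raw = sample(0:2, n, replace = TRUE),
    confidant_raw = sample(0:2, n, replace = TRUE),
    language_raw = rbinom(n, 1, 0.1),
    efficacy_info = sample(1:5, n, replace = TRUE),
    efficacy_health = sample(1:5, n, replace = TRUE),
    selfmgmt_between = sample(1:5, n, replace = TRUE),
    selfmgmt_nohelp = sample(1:5, n, replace = TRUE),
    chronic_count = rpois(n, 1.5)
  )
  df$ed_visits_2plus <- rbinom(n, 1, 0.2)
  df
}

# wrap arbitrary extra numeric columns into a valid cohort table so model
# fitters can be pointed at them
cohort_with_columns <- function(extra, seed = 7L) {
  base <- make_cohort_df(nrow(extra), seed = seed)
  cohort_table(cbind(base, extra))
}

# plant a pure step-function outcome on an existing cohort: prevalence
# p_low below the threshold, p_high at or above it
plant_step_outcome <- function(table, threshold = 2L, p_low = 0.05,
                               p_high = 0.20, seed = 1L) {
  idx <- compute_index(table)
  set.seed(seed)
  table$ed_visits_2plus <- rbinom(nrow(table), 1,
                                  ifelse(idx >= threshold, p_high, p_low))
  table
}
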