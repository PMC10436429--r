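test_that("similar model weights collapse to unit fixed weights", {
  w <- fixed_weights(c(education_code = 0.42, financial_code = 0.38,
                       instrumental_code = 0.33, confidant_code = 0.51))
  expect_identical(unname(w$fixed_weights), rep(1L, 4))
  expect_equal(w$base_value, 0.33)
  # forced integer rounding beyond the spread threshold
  w2 <- fixed_weights(c(a = 0.4, b = 0.8), ratio_threshold = 1.75)
  expect_identical(unname(w2$fixed_weights), c(1L, 2L))
  # equal weights are unit for any magnitude
  for (c0 in c(0.05, 0.4, 3)) {
    w3 <- fixed_weights(c(a = c0, b = c0, c = c0))
    expect_identical(unname(w3$fixed_weights), rep(1L, 3))
  }
  # scale invariance of the rule
  w4 <- fixed_weights(c(a = 0.42, b = 0.38, c = 0.33, d = 0.51) * 13)
  expect_identical(w4$fixed_weights, w$fixed_weights,
                   ignore_attr = TRUE)
  expect_error(fixed_weights(c(a = 0.4, b = -0.3)), "mixed-sign")
})

test_that("index arithmetic follows the published coding", {
  rec <- function(edu, fin, ins, con, lang = 0L) {
    data.frame(education_code = edu, financial_code = fin,
               instrumental_code = ins, confidant_code = con,
               language_code = lang)
  }
  expect_equal(compute_index(rec(-1L, -1L, -1L, 0L)), -3)
  expect_equal(compute_index(rec(1L, 1L, 1L, 2L)), 5)
  expect_equal(compute_index(rec(0L, 0L, 0L, 0L)), 0)
  expect_equal(compute_index(rec(1L, 1L, 1L, 2L, 1L)), 6)
  expect_gte(compute_index(rec(1L, 1L, 1L, 2L)), 2) # classified vulnerable
  # missing indicator gives a missing index, never zero
  expect_true(is.na(compute_index(rec(NA, 0L, 0L, 0L))))
})

test_that("the index is additive and monotone in each indicator", {
  p <- resolved_default_params()
  coh <- generate_cohort(p, n = 500, seed = 101)
  idx <- compute_index(coh)
  # additivity: sum of per-indicator contributions
  manual <- coh$education_code + coh$financial_code +
    coh$instrumental_code + coh$confidant_code + coh$language_code
  expect_equal(idx, manual)
  # worsening one indicator never rescues a vulnerable record
  worse <- coh
  worse$financial_code <- pmin(worse$financial_code + 1L, 1L)
  idx_w <- compute_index(worse)
  expect_true(all(idx_w >= idx))
  expect_true(all((idx >= 2) <= (idx_w >= 2)))
})

test_that("weight equivalence behaves at its boundary cases", {
  df <- make_cohort_df(6)
  df$education_raw <- c(2L, 4L, 8L, 8L, 2L, 4L)       # codes -1 0 1 1 -1 0
  df$financial_raw <- c(2L, 4L, 6L, 4L, 6L, 2L)       # codes -1 0 1 0 1 -1
  df$instrumental_raw <- c(1L, 2L, 0L, 2L, 1L, 0L)    # codes  0 1 -1 1 0 -1
  df$confidant_raw <- c(0L, 1L, 2L, 0L, 2L, 1L)
  tab <- cohort_table(df)
  # identical model and fixed weights: r = 1 exactly
  w <- index_weights(model_weights = c(education_code = 1,
                                       financial_code = 1,
                                       instrumental_code = 1,
                                       confidant_code = 1),
                     fixed_weights = c(education_code = 1,
                                       financial_code = 1,
                                       instrumental_code = 1,
                                       confidant_code = 1),
                     base_value = 1)
  w <- weight_equivalence(tab, w)
  expect_equal(w$equivalence_r, 1, tolerance = 1e-12)
  # zero variance is reported undefined
  df0 <- make_cohort_df(5)
  df0$education_raw <- 2L
  df0$financial_raw <- 2L
  df0$instrumental_raw <- 0L
  df0$confidant_raw <- 0L
  tab0 <- cohort_table(df0)
  expect_warning(w0 <- weight_equivalence(tab0, w), "zero variance")
  expect_true(is.na(w0$equivalence_r))
})

test_that("fixed and model-weighted indices are nearly equivalent on the calibrated generator", {
  p <- resolved_default_params()
  coh <- generate_cohort(p, n = 2039, seed = 111)
  fit <- fit_pls_path(coh)
  w <- fixed_weights(fit$w$vulnerability)
  w <- weight_equivalence(coh, w)
  expect_gte(w$equivalence_r, 0.97)
})

test_that("cut-point search returns refit objectives and recovers planted bins", {
  p <- resolved_default_params()
  coh <- generate_cohort(p, n = 1200, seed = 121)
  # single candidate: returned with its refit objective
  sol <- search_cutpoints(coh, list(education = list(c(3.5, 5.5))))
  fit <- fit_pls_path(coh)
  expect_equal(sol$objective_value, fit$r_squared, tolerance = 1e-9)
  expect_equal(sol$cut_points$education, c(3.5, 5.5))
  # planted truth: the generating binning should win most of the time
  grids <- list(education = list(c(1.5, 5.5), c(3.5, 5.5), c(3.5, 6.5)))
  hits <- 0L
  for (s in 1:10) {
    coh_s <- generate_cohort(p, n = 2000, seed = 2200 + s)
    sol_s <- search_cutpoints(coh_s, grids)
    if (identical(sol_s$cut_points$education, c(3.5, 5.5))) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("greedy and exhaustive search agree on a small grid", {
  p <- resolved_default_params()
  coh <- generate_cohort(p, n = 1500, seed = 131)
  grids <- list(education = list(c(2.5, 5.5), c(3.5, 5.5), c(4.5, 6.5)),
                financial = list(c(1.5, 4.5), c(2.5, 5.5), c(3.5, 5.5)))
  ex <- search_cutpoints(coh, grids, max_exhaustive = 100L)
  gr <- search_cutpoints(coh, grids, max_exhaustive = 1L)
  expect_identical(gr$method, "greedy")
  expect_identical(ex$method, "exhaustive")
  expect_equal(gr$objective_value, ex$objective_value, tolerance = 1e-9)
  expect_identical(gr$cut_points, ex$cut_points)
})

test_that("scoring card writes a readable text export", {
  w <- fixed_weights(c(education_code = 0.42, financial_code = 0.38,
                       instrumental_code = 0.33, confidant_code = 0.51))
  path <- withr::local_tempfile(fileext = ".txt")
  write_scoring_card(w, path = path)
  card <- readLines(path)
  expect_true(any(grepl("EDUCATION \\(weight 1\\)", card)))
  expect_true(any(grepl("Index >= 2", card)))
})
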