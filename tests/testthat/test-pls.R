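test_that("degenerate one-indicator blocks reduce to the Pearson correlation", {
  set.seed(5)
  extra <- data.frame(a = rnorm(200))
  extra$b <- -0.6 * extra$a + rnorm(200, 0, 0.8)
  tab <- cohort_with_columns(extra)
  for (scheme in c("centroid", "factorial", "path")) {
    spec <- pls_model_spec(blocks = list(first = "a", second = "b"),
                           modes = c("B", "A"), inner_scheme = scheme)
    fit <- fit_pls_path(tab, spec)
    expect_equal(fit$beta, cor(extra$a, extra$b), tolerance = 1e-10)
  }
})

test_that("fit invariants hold: unit-variance scores, R2 = beta^2, loadings", {
  p <- resolved_default_params()
  coh <- generate_cohort(p, n = 1500, seed = 31)
  fit <- fit_pls_path(coh)
  expect_true(fit$converged)
  for (b in 1:2) {
    expect_equal(mean(fit$scores[, b]), 0, tolerance = 1e-8)
    expect_equal(sd(fit$scores[, b]), 1, tolerance = 1e-6)
  }
  expect_lte(abs(fit$beta), 1)
  expect_equal(fit$r_squared, fit$beta^2, tolerance = 1e-12)
  expect_equal(unname(explained_variance(fit)), fit$beta^2,
               tolerance = 1e-12)
  # loadings are indicator-latent correlations
  cc <- complete_cases(coh)
  for (it in reflective_items()) {
    expect_equal(fit$loadings$efficacy[[it]],
                 cor(cc[[it]], fit$scores[, 2]), tolerance = 1e-8)
  }
  # explained variance equals the brute-force squared score correlation
  expect_equal(unname(explained_variance(fit)),
               cor(fit$scores[, 1], fit$scores[, 2])^2, tolerance = 1e-10)
})

test_that("outer updates satisfy the Mode A/Mode B fixed-point equations", {
  p <- resolved_default_params()
  coh <- generate_cohort(p, n = 2000, seed = 37)
  fit <- fit_pls_path(coh)
  cc <- as.data.frame(complete_cases(coh))
  X <- scale(as.matrix(cc[, formative_indicators()]))
  Y <- scale(as.matrix(cc[, reflective_items()]))
  # inner proxies at the fixed point (centroid: sign of latent correlation)
  zx <- sign(fit$beta) * fit$scores[, 2]
  zy <- sign(fit$beta) * fit$scores[, 1]
  # Mode B: normal-equation solution, rescaled to unit-variance latent
  wb <- solve(cor(X), drop(cor(X, zx)))
  wb <- wb / sd(drop(X %*% wb))
  expect_equal(unname(fit$w$vulnerability), unname(wb), tolerance = 1e-4)
  # Mode A: correlations with the inner proxy, same normalization
  wa <- drop(cor(Y, zy))
  wa <- wa / sd(drop(Y %*% wa))
  expect_equal(unname(fit$w$efficacy), unname(wa), tolerance = 1e-4)
})

test_that("weights are scale-invariant and sign-equivariant in the indicators", {
  p <- resolved_default_params()
  coh <- generate_cohort(p, n = 1200, seed = 41)
  fit <- fit_pls_path(coh)
  scaled <- coh
  scaled$financial_code <- scaled$financial_code * 7.5
  fit2 <- fit_pls_path(scaled)
  expect_equal(fit2$w$vulnerability, fit$w$vulnerability, tolerance = 1e-8)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-8)
  flipped <- coh
  flipped$financial_code <- -flipped$financial_code
  fit3 <- fit_pls_path(flipped)
  expect_equal(unname(fit3$w$vulnerability[["financial_code"]]),
               -unname(fit$w$vulnerability[["financial_code"]]),
               tolerance = 1e-8)
  expect_equal(abs(fit3$beta), abs(fit$beta), tolerance = 1e-8)
})

test_that("centroid and factorial schemes agree on the path magnitude", {
  p <- resolved_default_params()
  coh <- generate_cohort(p, n = 2500, seed = 43)
  b1 <- fit_pls_path(coh, pls_model_spec(inner_scheme = "centroid"))$beta
  b2 <- fit_pls_path(coh, pls_model_spec(inner_scheme = "factorial"))$beta
  expect_lt(abs(abs(b1) - abs(b2)), 0.01)
})

test_that("generating weights and path are recovered on synthetic cohorts", {
  p <- resolved_default_params()
  gamma <- p$gamma
  betas <- numeric(15)
  W <- matrix(0, 15, 4)
  for (s in 1:15) {
    coh <- generate_cohort(p, n = 5000, seed = 600 + s)
    fit <- fit_pls_path(coh)
    betas[s] <- fit$beta
    W[s, ] <- fit$w$vulnerability
  }
  w_mean <- colMeans(W)
  # compare directions: rescale the estimate to the generating norm
  w_cmp <- w_mean * sqrt(sum(gamma^2)) / sqrt(sum(w_mean^2))
  expect_true(all(abs(w_cmp - gamma) < 0.05))
  expect_lt(abs(mean(betas) - p$path_target), 0.04)
})

test_that("non-convergence is flagged, not raised", {
  p <- resolved_default_params()
  coh <- generate_cohort(p, n = 500, seed = 51)
  spec <- pls_model_spec(max_iter = 1L, tol = 1e-12)
  fit <- fit_pls_path(coh, spec)
  expect_false(fit$converged)
  expect_warning(explained_variance(fit), "converge")
})

test_that("collinear formative indicators raise an informative error", {
  set.seed(8)
  extra <- data.frame(a1 = rnorm(100))
  extra$a2 <- extra$a1
  extra$b <- rnorm(100)
  tab <- cohort_with_columns(extra)
  spec <- pls_model_spec(blocks = list(f = c("a1", "a2"), r = "b"),
                         modes = c("B", "A"))
  expect_error(fit_pls_path(tab, spec), "collinear|singular")
})
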