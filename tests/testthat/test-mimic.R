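test_that("near-deterministic identity structure is recovered exactly", {
  set.seed(2)
  n <- 800
  x <- rnorm(n)
  extra <- data.frame(x1 = x,
                      y1 = x + rnorm(n, 0, 0.05),
                      y2 = x + rnorm(n, 0, 0.05))
  tab <- cohort_with_columns(extra)
  fit <- suppressWarnings(
    fit_mimic(tab, mimic_spec(causes = "x1", indicators = c("y1", "y2"))))
  expect_equal(unname(fit$gamma), 1, tolerance = 0.02)
  expect_equal(unname(fit$lambda[2]), 1, tolerance = 0.02)
  expect_lt(fit$psi, 0.01)
  # the three-variable model is saturated, so the misfit is negligible
  expect_lt(fit$chi_square, 1)
})

test_that("the optimum satisfies the first-order conditions", {
  p <- resolved_default_params()
  for (s in c(61, 62)) {
    coh <- generate_cohort(p, n = 1200, seed = s)
    fit <- fit_mimic(coh)
    expect_true(fit$converged)
    expect_lt(fit$gradient_norm, 1e-5)
    fit0 <- fit_mimic(coh, mimic_spec(disturbance = FALSE))
    expect_lt(fit0$gradient_norm, 1e-5)
    # freeing the disturbance can only improve the fit
    expect_lte(fit$chi_square, fit0$chi_square + 1e-6)
    # df bookkeeping: p(p+1)/2 - q
    expect_identical(fit$df, 36 - 22)
    expect_identical(fit0$df, 36 - 21)
  }
})

test_that("quasi-Newton estimates agree with an independent EM estimator", {
  dat <- simulate_mimic_data(
    n = 500, gamma = c(0.5, 0.3, -0.2), lambda = c(1, 0.8, 1.2, 0.9),
    psi = 0.4, theta = c(0.5, 0.6, 0.4, 0.7),
    phi = diag(3) * 0.8 + 0.2, seed = 99)
  tab <- cohort_with_columns(dat)
  fit <- fit_mimic(tab, mimic_spec(causes = paste0("x", 1:3),
                                   indicators = paste0("y", 1:4)))
  S <- cov(as.matrix(dat))
  em <- oracle_mimic_em(S, px = 3, py = 4)
  expect_equal(unname(fit$gamma), unname(em$gamma), tolerance = 1e-3)
  expect_equal(unname(fit$lambda), unname(em$lambda), tolerance = 1e-3)
  expect_equal(unname(fit$psi), unname(em$psi), tolerance = 1e-3)
  expect_equal(unname(fit$theta), unname(em$theta), tolerance = 1e-3)
})

test_that("parameters are recovered from data generated by the model", {
  truth <- list(gamma = c(0.45, 0.35, 0.25), lambda = c(1, 0.9, 1.1),
                psi = 0.5, theta = c(0.6, 0.5, 0.7))
  phi <- diag(3) * 0.75 + 0.25
  n_seeds <- 20
  est <- array(NA_real_, c(n_seeds, 9))
  for (s in seq_len(n_seeds)) {
    dat <- simulate_mimic_data(2000, truth$gamma, truth$lambda, truth$psi,
                               truth$theta, phi, seed = 700 + s)
    tab <- cohort_with_columns(dat)
    fit <- fit_mimic(tab, mimic_spec(causes = paste0("x", 1:3),
                                     indicators = paste0("y", 1:3)))
    est[s, ] <- c(fit$gamma, fit$lambda[-1], fit$psi, fit$theta)
  }
  target <- c(truth$gamma, truth$lambda[-1], truth$psi, truth$theta)
  se_emp <- apply(est, 2, sd)
  within <- sweep(abs(sweep(est, 2, target)), 2, 3 * se_emp, `<=`)
  expect_gte(mean(rowMeans(within) == 1), 0.9)
})

test_that("rescaling the anchor indicator leaves the fit invariant", {
  dat <- simulate_mimic_data(600, c(0.5, 0.3), c(1, 0.8), 0.3,
                             c(0.5, 0.6), diag(2), seed = 55)
  tab <- cohort_with_columns(dat)
  spec <- mimic_spec(causes = c("x1", "x2"), indicators = c("y1", "y2"))
  fit <- fit_mimic(tab, spec)
  dat2 <- dat
  dat2$y1 <- dat2$y1 * 2
  fit2 <- fit_mimic(cohort_with_columns(dat2), spec)
  expect_equal(fit2$chi_square, fit$chi_square, tolerance = 1e-4)
  expect_equal(unname(fit2$gamma), unname(fit$gamma) * 2, tolerance = 1e-3)
  expect_equal(unname(fit2$lambda[2]), unname(fit$lambda[2]) / 2,
               tolerance = 1e-3)
  expect_equal(fit2$psi, fit$psi * 4, tolerance = 1e-2)
})

test_that("fit indices follow their defining identities", {
  p <- resolved_default_params()
  coh <- generate_cohort(p, n = 1500, seed = 71)
  fit <- fit_mimic(coh)
  idx <- fit_indices(fit)
  expect_true(idx$cfi >= 0 && idx$cfi <= 1)
  expect_equal(idx$aic, -2 * fit$logLik + 2 * fit$n_free_parameters)
  # a model identical to its baseline has CFI 0 (when misfit is positive)
  fake <- fit
  fake$chi_square <- 150
  fake$df <- 10
  idx0 <- fit_indices(fake, baseline = list(chi_square = 150, df = 10))
  expect_equal(idx0$cfi, 0)
  # baseline no worse than the model: CFI pinned at 1 with a note
  idx1 <- fit_indices(fit, baseline = list(chi_square = 5, df = 10))
  expect_equal(idx1$cfi, 1)
  expect_match(idx1$note, "baseline")
  # the independence baseline is closed-form: -(n-1) log |R|
  S <- fit$S
  expect_equal(idx$baseline_chi_square,
               -(fit$n - 1) * determinant(cov2cor(S))$modulus[1],
               tolerance = 1e-8)
})

test_that("latent scores behave like the construct", {
  # psi ~ 0, theta ~ 0: scores collapse onto gamma'x
  set.seed(3)
  n <- 500
  X <- matrix(rnorm(2 * n), n)
  eta <- drop(X %*% c(0.7, 0.4))
  dat <- data.frame(x1 = X[, 1], x2 = X[, 2],
                    y1 = eta + rnorm(n, 0, 1e-3),
                    y2 = eta + rnorm(n, 0, 1e-3))
  tab <- cohort_with_columns(dat)
  fit <- suppressWarnings(
    fit_mimic(tab, mimic_spec(causes = c("x1", "x2"),
                              indicators = c("y1", "y2"))))
  sc <- suppressWarnings(score_latent(fit, tab))
  expect_gt(abs(cor(sc, eta)), 0.999)
  expect_equal(sd(sc), 1, tolerance = 1e-8)
  # affine transformation of a cause leaves the ranks unchanged
  dat2 <- dat
  dat2$x1 <- 3 * dat2$x1 + 10
  tab2 <- cohort_with_columns(dat2)
  fit2 <- suppressWarnings(
    fit_mimic(tab2, mimic_spec(causes = c("x1", "x2"),
                               indicators = c("y1", "y2"))))
  sc2 <- suppressWarnings(score_latent(fit2, tab2))
  expect_gt(cor(sc2, sc), 0.9999)
  # on data drawn from the model itself, scores track the true construct
  set.seed(6)
  n2 <- 2000
  X2 <- matrix(rnorm(2 * n2), n2)
  eta2 <- drop(X2 %*% c(0.6, 0.5)) + rnorm(n2, 0, sqrt(0.3))
  dat3 <- data.frame(x1 = X2[, 1], x2 = X2[, 2],
                     y1 = eta2 + rnorm(n2, 0, sqrt(0.25)),
                     y2 = 0.9 * eta2 + rnorm(n2, 0, sqrt(0.3)),
                     y3 = 1.1 * eta2 + rnorm(n2, 0, sqrt(0.25)))
  tab3 <- cohort_with_columns(dat3)
  fit3 <- fit_mimic(tab3, mimic_spec(causes = c("x1", "x2"),
                                     indicators = c("y1", "y2", "y3")))
  sc3 <- score_latent(fit3, tab3)
  expect_gt(abs(cor(sc3, eta2)), 0.95)
})

test_that("no-disturbance MIMIC agrees with PLS on shared synthetic data", {
  p <- resolved_default_params()
  coh <- generate_cohort(p, n = 2039, seed = 91)
  m0 <- fit_mimic(coh, mimic_spec(disturbance = FALSE))
  pls <- fit_pls_path(coh)
  sc <- score_latent(m0, coh)
  expect_gte(abs(cor(sc, pls$scores[, 1])), 0.99)
  # on continuous disturbance-free data (the PLS-consistent condition,
  # where the exactly-determined construct assumption of both methods
  # holds on the observed scale) the formative coefficient direction
  # matches the PLS outer weights
  dat <- simulate_mimic_data(4000, gamma = c(0.42, 0.38, 0.33, 0.51),
                             lambda = c(1, 0.9, 1.1, 1), psi = 0,
                             theta = c(0.5, 0.6, 0.5, 0.6),
                             phi = diag(4) * 0.8 + 0.2, seed = 92)
  tab0 <- cohort_with_columns(dat)
  m00 <- fit_mimic(tab0, mimic_spec(causes = paste0("x", 1:4),
                                    indicators = paste0("y", 1:4),
                                    disturbance = FALSE))
  spec0 <- pls_model_spec(blocks = list(f = paste0("x", 1:4),
                                        r = paste0("y", 1:4)),
                          modes = c("B", "A"))
  pls0 <- fit_pls_path(tab0, spec0)
  expect_gte(abs(cor(unname(m00$gamma), unname(pls0$w$f))), 0.99)
  sc0 <- score_latent(m00, tab0)
  expect_gte(abs(cor(sc0, pls0$scores[, 1])), 0.99)
})
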