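#' @title Synthetic cohort generation
#' @description
#' The generator emulates the statistical structure the index analysis
#' assumes: ordinal social indicators with published marginal distributions
#' and Gaussian-copula dependence; a latent vulnerability construct that is a
#' weighted sum of the coded indicators plus a disturbance; Likert reflective
#' self-efficacy items loading (negatively) on the construct; a Poisson
#' chronic-disease burden confounded with the construct; and binary
#' twelve-month outcomes whose logits carry specified odds ratios for the
#' vulnerability flag and per-chronic-disease effect at specified marginal
#' prevalences.
#' @name synthetic_cohort
NULL

# run code under a private RNG stream, restoring the caller's stream after
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# mean/sd of a coded indicator implied by its marginal category probabilities
code_moments <- function(codes, probs) {
  m <- sum(codes * probs)
  v <- sum((codes - m)^2 * probs)
  c(mean = m, sd = sqrt(v))
}

# Likert discretization of a standard-normal item latent: observed category
# is round(mu + s * z) clipped to 1..5, i.e. thresholds (k + 0.5 - mu)/s.
likert_cut <- function(mu, s) ((1:4) + 0.5 - mu) / s

likert_probs <- function(mu, s) diff(c(0, stats::pnorm(likert_cut(mu, s)), 1))

# attenuation of corr(latent, item) induced by discretization:
# cov(d(z), z) telescopes to sum of normal densities at the thresholds
likert_attenuation <- function(mu, s) {
  pr <- likert_probs(mu, s)
  m <- sum((1:5) * pr)
  sdd <- sqrt(sum(((1:5) - m)^2 * pr))
  sum(stats::dnorm(likert_cut(mu, s))) / sdd
}

# solve (mu, s) so the discretized item matches a target mean and SD
solve_item_cutoffs <- function(target_mean, target_sd) {
  obj <- function(p) {
    pr <- likert_probs(p[1], exp(p[2]))
    m <- sum((1:5) * pr)
    v <- sum(((1:5) - m)^2 * pr)
    (m - target_mean)^2 + (sqrt(v) - target_sd)^2
  }
  o <- stats::optim(c(target_mean, log(target_sd)), obj)
  c(mu = o$par[1], s = exp(o$par[2]))
}

# one-factor least-squares loadings for a 4x4 correlation matrix
one_factor_loadings <- function(R) {
  ut <- upper.tri(R)
  obj <- function(l) sum((outer(l, l)[ut] - R[ut])^2)
  stats::optim(rep(0.5, ncol(R)), obj, method = "L-BFGS-B",
               lower = 0.05, upper = 0.95)$par
}

#' Published reflective-item statistics used to calibrate the generator
#'
#' Means, standard deviations and pairwise Spearman correlations of the four
#' self-efficacy items in the study sample, used as calibration targets for
#' the item discretization and loadings.
#'
#' @return List with `mean`, `sd` (length-4 vectors) and `rho` (4x4 matrix),
#'   named by the reflective items.
#' @export
reference_item_stats <- function() {
  items <- reflective_items()
  rho <- matrix(1, 4, 4, dimnames = list(items, items))
  rho[1, 2] <- rho[2, 1] <- 0.40
  rho[1, 3] <- rho[3, 1] <- 0.20
  rho[1, 4] <- rho[4, 1] <- 0.22
  rho[2, 3] <- rho[3, 2] <- 0.31
  rho[2, 4] <- rho[4, 2] <- 0.31
  rho[3, 4] <- rho[4, 3] <- 0.54
  list(mean = stats::setNames(c(3.78, 4.04, 4.29, 4.09), items),
       sd = stats::setNames(c(1.09, 0.92, 0.87, 0.92), items),
       rho = rho)
}

#' Published outcome rows used as generator defaults
#'
#' For each negative healthcare event: the adjusted odds ratio for the
#' vulnerability flag (index at or above the threshold), the odds ratio per
#' additional chronic disease, the twelve-month marginal prevalence, and the
#' analytic sample size behind the published row. The SF-12 decline row
#' additionally carries a per-point odds ratio on the baseline SF-12 score
#' (the published model controlled for baseline SF-12).
#'
#' @return Data frame with one row per outcome; the `intercept` column is
#'   `NA` until solved by [solve_intercepts()].
#' @export
default_outcome_specs <- function() {
  data.frame(
    outcome = outcome_names(),
    or_vulnerable = c(2.18, 1.50, 2.95, 1.61, 1.26, 2.00, 1.37, 1.16),
    or_chronic = c(1.19, 1.24, 1.38, 1.04, 1.32, 1.17, 1.09, 1.08),
    or_sf12 = c(1, 1, 1, 1, 0.97, 1, 1, 1),
    prevalence = c(0.111, 0.163, 0.047, 0.169, 0.231, 0.086, 0.231, 0.115),
    n_reference = c(1769L, 1769L, 1368L, 1685L, 1377L, 1837L, 1453L, 1774L),
    intercept = NA_real_
  )
}

#' Generator parameter set
#'
#' Bundles every tunable of the synthetic cohort generator. Defaults are the
#' published study conditions: the indicator marginals of the analytic
#' sample, exchangeable latent-normal indicator correlation 0.2, formative
#' coefficients (0.42, 0.38, 0.33, 0.51) for
#' education/financial/instrumental/confidant, reflective loadings from a
#' one-factor least-squares fit to the published item correlations (inflated
#' for Likert attenuation), item cut-offs matching the published item
#' means/SDs, Poisson chronic counts with log-mean slope 0.25 in the
#' construct and 25.5% prevalence of 3+ conditions, a 1% minority-language
#' flag excluded from the construct, and outcome odds ratios / prevalences
#' from the published regression table.
#'
#' The latent disturbance variance `psi` defaults to `NULL`, meaning it is
#' solved by [calibrate_disturbance()] so that the population value of the
#' PLS path coefficient on the observable (coded, discretized) scale equals
#' `path_target`.
#'
#' @param n Cohort size.
#' @param seed Integer RNG seed.
#' @param marginals Named list of category-probability vectors on the raw
#'   scale of each indicator (must sum to 1).
#' @param copula_corr Exchangeable latent-normal correlation among the four
#'   modelled indicators (scalar in [0, 1)), or a full 4x4 positive-definite
#'   correlation matrix.
#' @param gamma Formative coefficients on the standardized coded indicators.
#' @param psi Disturbance variance of the construct before standardization;
#'   `NULL` to calibrate against `path_target`.
#' @param path_target Target population PLS path coefficient between the
#'   vulnerability and self-efficacy composites (negative: vulnerability
#'   lowers self-efficacy).
#' @param lambda Reflective loadings (positive magnitudes) of the four items
#'   on the construct; applied with a negative sign.
#' @param item_cutoffs 4x2 matrix (`mu`, `s`) of Likert discretization
#'   parameters per item.
#' @param chronic_slope Slope of the Poisson log-mean in the standardized
#'   construct.
#' @param chronic_p3plus Target marginal probability of 3+ chronic
#'   conditions.
#' @param chronic_max Upper truncation of the chronic count (list of 14
#'   diagnoses).
#' @param language_prev Prevalence of the minority-language flag.
#' @param outcome_specs Data frame as returned by [default_outcome_specs()].
#' @param index_threshold Index value at or above which a record counts as
#'   vulnerable in outcome generation.
#' @param attrition_probs Named list (indicator -> per-category dropout
#'   probability vector on the coded categories) used by [apply_attrition()].
#' @param specs Indicator specs (coding schemes).
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n = 2039L,
                             seed = 1L,
                             marginals = default_raw_marginals(),
                             copula_corr = 0.2,
                             gamma = c(education = 0.42, financial = 0.38,
                                       instrumental = 0.33, confidant = 0.51),
                             psi = NULL,
                             path_target = -0.38,
                             lambda = NULL,
                             item_cutoffs = NULL,
                             chronic_slope = 0.25,
                             chronic_p3plus = 0.255,
                             chronic_max = 14L,
                             language_prev = 0.01,
                             outcome_specs = default_outcome_specs(),
                             index_threshold = 2L,
                             attrition_probs = default_attrition_probs(),
                             specs = default_indicator_specs()) {
  stopifnot(n >= 1, is.numeric(seed))
  ref <- reference_item_stats()
  if (is.null(item_cutoffs)) {
    item_cutoffs <- t(mapply(solve_item_cutoffs, ref$mean, ref$sd))
    colnames(item_cutoffs) <- c("mu", "s")
  }
  if (is.null(lambda)) {
    # observed-scale loadings, inflated so the *discretized* items
    # reproduce the published correlations
    att <- mapply(likert_attenuation, item_cutoffs[, "mu"],
                  item_cutoffs[, "s"])
    lambda <- pmin(one_factor_loadings(ref$rho) / att, 0.95)
    names(lambda) <- reflective_items()
  }
  modelled <- names(gamma)
  for (nm in c(modelled, "language")) {
    p <- marginals[[nm]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-9) {
      stop("generator_params: marginals for '", nm, "' must sum to 1")
    }
    if (length(p) != length(specs[[nm]]$raw_scale)) {
      stop("generator_params: marginals for '", nm,
           "' must cover the raw scale")
    }
  }
  if (is.matrix(copula_corr)) {
    R <- copula_corr
  } else {
    R <- matrix(copula_corr, length(modelled), length(modelled))
    diag(R) <- 1
  }
  if (!isSymmetric(R) || any(eigen(R, symmetric = TRUE,
                                   only.values = TRUE)$values <= 1e-10)) {
    stop("generator_params: copula correlation matrix must be symmetric ",
         "positive-definite")
  }
  dimnames(R) <- list(modelled, modelled)
  if (!is.null(psi) && psi < 0) stop("generator_params: psi must be >= 0")
  stopifnot(all(outcome_specs$or_vulnerable > 0),
            all(outcome_specs$or_chronic > 0),
            all(outcome_specs$prevalence > 0 & outcome_specs$prevalence < 1))
  structure(
    list(n = as.integer(n), seed = seed, marginals = marginals,
         copula_corr = R, gamma = gamma, psi = psi,
         path_target = path_target, lambda = lambda,
         item_cutoffs = item_cutoffs, chronic_slope = chronic_slope,
         chronic_p3plus = chronic_p3plus, chronic_max = chronic_max,
         language_prev = language_prev, outcome_specs = outcome_specs,
         index_threshold = as.integer(index_threshold),
         attrition_probs = attrition_probs, specs = specs),
    class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Synthetic cohort generator parameters\n")
  cat(sprintf("  n = %d, seed = %s\n", x$n, format(x$seed)))
  cat("  gamma:", paste(sprintf("%s=%.2f", names(x$gamma), x$gamma),
                        collapse = ", "), "\n")
  cat(sprintf("  psi = %s (path target %.2f)\n",
              if (is.null(x$psi)) "to be calibrated" else format(x$psi),
              x$path_target))
  cat("  lambda:", paste(sprintf("%.2f", x$lambda), collapse = ", "), "\n")
  cat(sprintf("  outcomes: %d specs, index threshold >= %d\n",
              nrow(x$outcome_specs), x$index_threshold))
  invisible(x)
}

#' Default raw-scale marginal distributions
#'
#' Category probabilities on each indicator's raw scale. Binned through the
#' default coding they reproduce the published coded marginals
#' (education 24.5/55.7/19.8, financial 31.0/60.1/8.9,
#' instrumental 49.4/33.1/17.5, confidant 73.4/21.5/5.1, language 99/1,
#' in percent, asset to deficit). The within-bin splits on the 8- and
#' 7-point raw scales are not published; the defaults spread mass over the
#' detailed levels in proportions plausible for an adult primary-care
#' population.
#'
#' @return Named list of probability vectors.
#' @export
default_raw_marginals <- function() {
  list(
    education = c(0.050, 0.125, 0.070,  0.307, 0.250,  0.120, 0.055, 0.023),
    financial = c(0.090, 0.220,  0.280, 0.200, 0.121,  0.060, 0.029),
    instrumental = c(0.494, 0.331, 0.175),
    confidant = c(0.734, 0.215, 0.051),
    language = c(0.99, 0.01)
  )
}

#' Default differential attrition probabilities
#'
#' Per-category dropout probabilities on the coded categories of financial
#' status and education, increasing with vulnerability so that completers
#' are less likely to be poor or low-educated, with overall retention near
#' the published 81%.
#'
#' @return Named list of dropout-probability vectors (asset to deficit).
#' @export
default_attrition_probs <- function() {
  list(financial = c(0.09, 0.10, 0.17),
       education = c(0.08, 0.10, 0.16))
}

# coded-category probabilities implied by raw marginals and a spec
coded_marginals <- function(p_raw, spec) {
  bins <- findInterval(spec$raw_scale, spec$cut_points) + 1L
  vapply(seq_along(spec$codes), function(i) sum(p_raw[bins == i]), numeric(1))
}

# draw the modelled ordinal indicators through the Gaussian copula;
# returns list(raw = matrix of raw values, z = latent normals)
draw_indicators <- function(params, n) {
  modelled <- names(params$gamma)
  L <- chol(params$copula_corr)
  Z <- matrix(stats::rnorm(n * length(modelled)), n) %*% L
  raw <- matrix(NA_integer_, n, length(modelled),
                dimnames = list(NULL, modelled))
  U <- stats::pnorm(Z)
  for (j in seq_along(modelled)) {
    nm <- modelled[j]
    cum <- cumsum(params$marginals[[nm]])
    cum[length(cum)] <- 1
    raw[, j] <- params$specs[[nm]]$raw_scale[
      findInterval(U[, j], cum, left.open = TRUE) + 1L]
  }
  list(raw = raw, z = Z)
}

# standardized coded indicator matrix using the marginals' implied moments
standardize_codes <- function(code_mat, params) {
  modelled <- colnames(code_mat)
  out <- code_mat
  for (nm in modelled) {
    cm <- code_moments(params$specs[[nm]]$codes,
                       coded_marginals(params$marginals[[nm]],
                                       params$specs[[nm]]))
    out[, nm] <- (code_mat[, nm] - cm["mean"]) / cm["sd"]
  }
  out
}

# internal engine shared by generate_cohort and the calibrators:
# draws everything up to the Likert items for a given psi
draw_structural <- function(params, n, psi) {
  modelled <- names(params$gamma)
  ind <- draw_indicators(params, n)
  codes <- ind$raw
  for (nm in modelled) {
    codes[, nm] <- recode_indicator(ind$raw[, nm], params$specs[[nm]])
  }
  xs <- standardize_codes(codes, params)
  systematic <- drop(xs %*% params$gamma)
  zeta <- if (psi > 0) stats::rnorm(n, 0, sqrt(psi)) else numeric(n)
  eta_raw <- systematic + zeta
  eta <- (eta_raw - mean(eta_raw)) / stats::sd(eta_raw)
  eps <- matrix(stats::rnorm(n * 4L), n)
  item_lat <- sweep(eps, 2L, sqrt(1 - params$lambda^2), `*`) -
    outer(eta, params$lambda)
  items <- matrix(NA_integer_, n, 4L,
                  dimnames = list(NULL, reflective_items()))
  for (j in 1:4) {
    obs <- round(params$item_cutoffs[j, "mu"] +
                   params$item_cutoffs[j, "s"] * item_lat[, j])
    items[, j] <- pmin(pmax(obs, 1L), 5L)
  }
  list(raw = ind$raw, codes = codes, eta = eta, items = items)
}

#' Calibrate the construct disturbance to a target PLS path
#'
#' The disturbance variance controls how strongly the self-efficacy items
#' are tied to the vulnerability composite. Because the PLS path coefficient
#' is defined on the observable scale (coded ordinal indicators, discretized
#' Likert items), the generator calibrates `psi` so that the two-block PLS
#' estimate on a large calibration draw equals the target path. Common
#' random numbers across candidate `psi` values make the objective smooth;
#' the calibration uses a fixed private seed, so it is a deterministic
#' function of the parameter set.
#'
#' @param params A [generator_params()] object.
#' @param n_cal Calibration draw size.
#' @return The calibrated `psi` (scalar).
#' @export
calibrate_disturbance <- function(params, n_cal = 150000L) {
  target <- params$path_target
  stopifnot(target < 0, target > -1)
  with_private_seed(202306L, {
    ind <- draw_indicators(params, n_cal)
    codes <- ind$raw
    for (nm in names(params$gamma)) {
      codes[, nm] <- recode_indicator(ind$raw[, nm], params$specs[[nm]])
    }
    xs <- standardize_codes(codes, params)
    systematic <- drop(xs %*% params$gamma)
    zeta0 <- stats::rnorm(n_cal)
    eps <- matrix(stats::rnorm(n_cal * 4L), n_cal)
    beta_at <- function(psi) {
      eta_raw <- systematic + sqrt(psi) * zeta0
      eta <- (eta_raw - mean(eta_raw)) / stats::sd(eta_raw)
      item_lat <- sweep(eps, 2L, sqrt(1 - params$lambda^2), `*`) -
        outer(eta, params$lambda)
      items <- matrix(0L, n_cal, 4L)
      for (j in 1:4) {
        obs <- round(params$item_cutoffs[j, "mu"] +
                       params$item_cutoffs[j, "s"] * item_lat[, j])
        items[, j] <- pmin(pmax(obs, 1L), 5L)
      }
      fit <- pls_engine(list(vulnerability = codes, efficacy = items),
                        modes = c("B", "A"))
      fit$beta
    }
    b0 <- beta_at(0)
    if (b0 > target) {
      stop("calibrate_disturbance: target path ", target,
           " steeper than attainable (", round(b0, 3), " at psi = 0)")
    }
    stats::uniroot(function(p) beta_at(p) - target, c(0, 30),
                   tol = 1e-4)$root
  })
}

# fill psi if it was left to calibration
resolve_psi <- function(params) {
  if (is.null(params$psi)) params$psi <- calibrate_disturbance(params)
  params
}

# population chronic-count intercept: P(count >= 3) = target when
# log-mean = c + slope * eta, eta ~ N(0, 1)
solve_chronic_intercept <- function(slope, p3plus) {
  p3 <- function(cc) {
    stats::integrate(function(e) {
      (1 - stats::ppois(2, exp(cc + slope * e))) * stats::dnorm(e)
    }, -8, 8, rel.tol = 1e-9)$value
  }
  stats::uniroot(function(cc) p3(cc) - p3plus, c(-4, 4), tol = 1e-8)$root
}

# draw of covariates entering outcome logits, used both for cohort assembly
# and intercept calibration
draw_covariates <- function(params, n) {
  st <- draw_structural(params, n, params$psi)
  language_raw <- stats::rbinom(n, 1L, params$language_prev)
  cc_int <- solve_chronic_intercept(params$chronic_slope, params$chronic_p3plus)
  chronic <- pmin(stats::rpois(n, exp(cc_int + params$chronic_slope * st$eta)),
                  params$chronic_max)
  sf12 <- round(51 - 1.2 * chronic - 1.0 * st$eta + stats::rnorm(n, 0, 8.5), 1)
  lang_code <- recode_indicator(language_raw, params$specs$language)
  index <- rowSums(st$codes) + lang_code
  list(structural = st, language_raw = language_raw, chronic = chronic,
       sf12 = sf12, vulnerable = as.integer(index >= params$index_threshold))
}

#' Solve an outcome intercept for a target marginal prevalence
#'
#' Finds the logistic intercept `alpha` such that the population-averaged
#' event probability under the generator equals the target prevalence, by
#' monotone root-finding of the mixture
#' `mean(plogis(alpha + log(OR_v) * vulnerable + log(OR_c) * chronic + ...))`
#' over a large fixed-seed draw of covariate patterns.
#'
#' @param target_prevalence Target marginal event probability in (0, 1).
#' @param params A [generator_params()] (with `psi` resolved or resolvable).
#' @param outcome Outcome name (row of `params$outcome_specs`).
#' @param n_cal Size of the covariate-pattern draw.
#' @return The intercept `alpha` (scalar).
#' @export
solve_intercept <- function(target_prevalence, params, outcome,
                            n_cal = 200000L) {
  stopifnot(target_prevalence > 0, target_prevalence < 1)
  spec <- params$outcome_specs[params$outcome_specs$outcome == outcome, ]
  if (nrow(spec) != 1L) stop("solve_intercept: unknown outcome: ", outcome)
  params <- resolve_psi(params)
  cov <- with_private_seed(700001L, draw_covariates(params, n_cal))
  lp0 <- log(spec$or_vulnerable) * cov$vulnerable +
    log(spec$or_chronic) * cov$chronic +
    log(spec$or_sf12) * (cov$sf12 - 50)
  f <- function(a) mean(stats::plogis(a + lp0)) - target_prevalence
  lo <- stats::qlogis(target_prevalence) - max(abs(lp0)) - 1
  hi <- stats::qlogis(target_prevalence) + max(abs(lp0)) + 1
  if (f(lo) > 0 || f(hi) < 0) {
    stop("solve_intercept: no root in bounds for outcome ", outcome)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Resolve the generator's calibrated quantities once
#'
#' Fills the disturbance variance (if left `NULL`) and every outcome
#' intercept. Calling this once before repeated [generate_cohort()] runs
#' avoids re-solving the same roots per replicate; `generate_cohort()`
#' resolves on the fly otherwise.
#'
#' @param params A [generator_params()] object.
#' @return The params with `psi` and `outcome_specs$intercept` filled.
#' @export
solve_intercepts <- function(params) {
  params <- resolve_psi(params)
  for (i in seq_len(nrow(params$outcome_specs))) {
    if (is.na(params$outcome_specs$intercept[i])) {
      params$outcome_specs$intercept[i] <- solve_intercept(
        params$outcome_specs$prevalence[i], params,
        params$outcome_specs$outcome[i])
    }
  }
  params
}

#' Generate a synthetic cohort
#'
#' Reproducible given the seed in `params`: indicators are drawn through a
#' latent-normal copula thresholded at the stated marginals; the
#' vulnerability construct is the weighted sum of standardized coded
#' indicators plus a disturbance, standardized to unit variance; reflective
#' items discretize negative loadings on the construct; the chronic count is
#' Poisson with log-mean linear in the construct; outcomes are Bernoulli
#' with logit `alpha + log(OR_v) I(index >= threshold) +
#' log(OR_c) chronic (+ log(OR_sf12) (sf12 - 50))`.
#'
#' @param params A [generator_params()] object.
#' @param n,seed Optional overrides of `params$n` / `params$seed`.
#' @return A `cohort_table` with raw and coded indicators, items, chronic
#'   count, baseline SF-12, outcome flags and a true-construct column
#'   `eta_true` (for recovery studies; not part of the file schema).
#' @export
generate_cohort <- function(params, n = NULL, seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (!is.null(n)) params$n <- as.integer(n)
  if (!is.null(seed)) params$seed <- seed
  params <- solve_intercepts(params)
  with_private_seed(params$seed, {
    cov <- draw_covariates(params, params$n)
    df <- as.data.frame(cov$structural$raw)
    names(df) <- paste0(names(params$gamma), "_raw")
    df$language_raw <- cov$language_raw
    it <- as.data.frame(cov$structural$items)
    df <- cbind(df, it)
    df$chronic_count <- cov$chronic
    df$baseline_sf12 <- cov$sf12
    os <- params$outcome_specs
    for (i in seq_len(nrow(os))) {
      lp <- os$intercept[i] +
        log(os$or_vulnerable[i]) * cov$vulnerable +
        log(os$or_chronic[i]) * cov$chronic +
        log(os$or_sf12[i]) * (cov$sf12 - 50)
      df[[os$outcome[i]]] <- stats::rbinom(params$n, 1L, stats::plogis(lp))
    }
    df$complete <- TRUE
    df$eta_true <- cov$structural$eta
    cohort_table(df, specs = params$specs)
  })
}

#' Mark records incomplete with category-dependent probability
#'
#' Emulates differential attrition: each record drops out with probability
#' `1 - prod(1 - p[indicator, category])` over the indicators listed in
#' `attrition_probs`. Original rows are retained; only the `complete` flag
#' changes.
#'
#' @param table A `cohort_table`.
#' @param attrition_probs Named list: indicator name -> dropout probability
#'   per coded category (asset to deficit order).
#' @param seed RNG seed.
#' @return The `cohort_table` with an updated `complete` flag.
#' @export
apply_attrition <- function(table, attrition_probs = default_attrition_probs(),
                            seed = 1L) {
  stopifnot(inherits(table, "cohort_table"))
  specs <- attr(table, "indicator_specs")
  retain <- rep(1, nrow(table))
  for (nm in names(attrition_probs)) {
    p <- attrition_probs[[nm]]
    if (any(p < 0 | p > 1)) stop("apply_attrition: probabilities outside [0,1]")
    codes <- specs[[nm]]$codes
    if (length(p) != length(codes)) {
      stop("apply_attrition: need one probability per category of '", nm, "'")
    }
    cat_idx <- match(table[[paste0(nm, "_code")]], codes)
    retain <- retain * (1 - p[cat_idx])
  }
  with_private_seed(seed, {
    table$complete <- stats::runif(nrow(table)) < retain
  })
  table
}
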