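#' Specify a MIMIC model
#'
#' A single latent construct with observed causes (formative side) and at
#' least two reflective indicators, `eta = gamma' x + zeta`,
#' `y = lambda eta + eps`. Identification fixes the first loading to 1; the
#' cause covariance matrix Phi is free, so misfit is concentrated in the
#' cause-indicator and indicator-indicator structure.
#'
#' @param causes Cause (x) column names.
#' @param indicators Reflective indicator (y) column names (>= 2).
#' @param disturbance Include the latent disturbance `zeta` (free
#'   `psi = Var(zeta)`), or fix `psi = 0` (the no-disturbance variant that
#'   mirrors the PLS assumption of an exactly determined construct).
#' @param maxit Optimizer iteration cap.
#' @return A `mimic_spec`.
#' @export
mimic_spec <- function(causes = formative_indicators(),
                       indicators = reflective_items(),
                       disturbance = TRUE,
                       maxit = 1000L) {
  stopifnot(length(causes) >= 1L, length(indicators) >= 2L,
            !anyDuplicated(c(causes, indicators)))
  structure(list(causes = causes, indicators = indicators,
                 disturbance = isTRUE(disturbance),
                 maxit = as.integer(maxit)),
            class = "mimic_spec")
}

# implied covariance of (x, y) given parameter list
mimic_sigma <- function(par, px, py) {
  lambda <- c(1, par$lambda_free)
  v_eta <- drop(crossprod(par$gamma, par$phi %*% par$gamma)) + par$psi
  sxy <- (par$phi %*% par$gamma) %*% t(lambda)
  syy <- v_eta * tcrossprod(lambda) + diag(par$theta, py)
  rbind(cbind(par$phi, sxy), cbind(t(sxy), syy))
}

# pack/unpack the free parameter vector
mimic_pack <- function(par, disturbance) {
  c(par$gamma, par$lambda_free, if (disturbance) par$psi, par$theta,
    par$phi[lower.tri(par$phi, diag = TRUE)])
}

mimic_unpack <- function(v, px, py, disturbance) {
  i <- 0L
  take <- function(k) {
    out <- v[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  gamma <- take(px)
  lambda_free <- take(py - 1L)
  psi <- if (disturbance) take(1L) else 0
  theta <- take(py)
  phi <- matrix(0, px, px)
  phi[lower.tri(phi, diag = TRUE)] <- take(px * (px + 1L) / 2L)
  phi <- phi + t(phi) - diag(diag(phi), px)
  list(gamma = gamma, lambda_free = lambda_free, psi = psi, theta = theta,
       phi = phi)
}

# ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p and its
# analytic gradient via dF = tr(G dSigma), G = Sigma^-1 (Sigma - S) Sigma^-1
mimic_objective <- function(S, px, py, disturbance) {
  p <- px + py
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  ix <- seq_len(px)
  iy <- px + seq_len(py)
  fn <- function(v) {
    par <- mimic_unpack(v, px, py, disturbance)
    sigma <- mimic_sigma(par, px, py)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    inv <- chol2inv(ch)
    2 * sum(log(diag(ch))) + sum(inv * S) - logdetS - p
  }
  gr <- function(v) {
    par <- mimic_unpack(v, px, py, disturbance)
    sigma <- mimic_sigma(par, px, py)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(v)))
    inv <- chol2inv(ch)
    G <- inv %*% (sigma - S) %*% inv
    lambda <- c(1, par$lambda_free)
    phg <- drop(par$phi %*% par$gamma)
    v_eta <- sum(par$gamma * phg) + par$psi
    Gxy <- G[ix, iy, drop = FALSE]
    Gyy <- G[iy, iy, drop = FALSE]
    Gxx <- G[ix, ix, drop = FALSE]
    Gl <- drop(Gyy %*% lambda)
    lGl <- sum(lambda * Gl)
    # gamma_k: dSxy = Phi e_k lambda', dSyy = 2 (Phi gamma)_k lambda lambda'
    g_gamma <- 2 * drop(par$phi %*% (Gxy %*% lambda)) + 2 * phg * lGl
    # lambda_j (j >= 2): dSxy = Phi gamma e_j', dSyy = v (e_j l' + l e_j')
    g_lambda <- (2 * drop(crossprod(Gxy, phg)) + 2 * v_eta * Gl)[-1L]
    g_psi <- lGl
    g_theta <- diag(Gyy)
    # phi_ab (a >= b): dSxx = E_ab + E_ba (a != b), dSxy = E_ab gamma l',
    # dSyy = (gamma' E_ab gamma) l l'
    M <- Gxx + 2 * tcrossprod(drop(Gxy %*% lambda), par$gamma) +
      lGl * tcrossprod(par$gamma)
    Msym <- M + t(M)
    g_phi <- Msym[lower.tri(Msym, diag = TRUE)]
    diag_idx <- which(lower.tri(par$phi, diag = TRUE), arr.ind = TRUE)
    on_diag <- diag_idx[, 1L] == diag_idx[, 2L]
    g_phi[on_diag] <- g_phi[on_diag] / 2
    c(g_gamma, g_lambda, if (disturbance) g_psi, g_theta, g_phi)
  }
  list(fn = fn, gr = gr)
}

#' Fit a MIMIC model by maximum likelihood
#'
#' Minimizes the normal-theory covariance discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p` over the
#' structured covariance implied by `eta = gamma' x + zeta`,
#' `y = lambda eta + eps` with free cause covariance Phi, using
#' quasi-Newton (L-BFGS-B) optimization with an analytic gradient and
#' documented start values (gamma from OLS of the first indicator on the
#' causes; loadings from covariance ratios against the first indicator;
#' variances at 10% of the observed variances). The chi-square statistic is
#' `(n - 1) F` at the optimum.
#'
#' Variance parameters are bounded at zero: a Heywood case is returned
#' bounded with a warning, not an error. Non-convergence flags the fit and
#' records the gradient norm.
#'
#' @param table A `cohort_table` (complete cases are used).
#' @param spec A [mimic_spec()].
#' @return A `mimic_fit` with elements `gamma`, `lambda` (first fixed at 1),
#'   `psi`, `theta`, `phi`, `chi_square`, `df`, `logLik`, `aic`,
#'   `n_free_parameters`, `gradient_norm`, `converged`, `S`, `n`, `spec`.
#' @export
fit_mimic <- function(table, spec = mimic_spec()) {
  stopifnot(inherits(table, "cohort_table"), inherits(spec, "mimic_spec"))
  table <- complete_cases(table)
  df <- as.data.frame(table)
  vars <- c(spec$causes, spec$indicators)
  missing <- setdiff(vars, names(df))
  if (length(missing)) {
    stop("fit_mimic: missing column(s): ", paste(missing, collapse = ", "))
  }
  Z <- as.matrix(df[, vars, drop = FALSE])
  n <- nrow(Z)
  S <- stats::cov(Z)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("fit_mimic: sample covariance matrix is not positive-definite")
  }
  px <- length(spec$causes)
  py <- length(spec$indicators)
  ix <- seq_len(px)
  iy <- px + seq_len(py)
  # start values
  Sxx <- S[ix, ix, drop = FALSE]
  gamma0 <- drop(solve(Sxx, S[ix, iy[1L]]))
  eta0 <- drop(scale(Z[, ix, drop = FALSE], scale = FALSE) %*% gamma0)
  cov_eta_y <- drop(stats::cov(eta0, Z[, iy, drop = FALSE]))
  lambda0 <- cov_eta_y / cov_eta_y[1L]
  lambda0[!is.finite(lambda0)] <- 1
  start <- list(gamma = gamma0, lambda_free = lambda0[-1L],
                psi = 0.1 * S[iy[1L], iy[1L]],
                theta = 0.1 * diag(S)[iy], phi = Sxx)
  v0 <- mimic_pack(start, spec$disturbance)
  obj <- mimic_objective(S, px, py, spec$disturbance)
  q <- length(v0)
  lower <- rep(-Inf, q)
  var_idx <- px + (py - 1L) + seq_len(py + spec$disturbance)
  lower[var_idx] <- 0
  opt <- stats::optim(v0, obj$fn, obj$gr, method = "L-BFGS-B", lower = lower,
                      control = list(maxit = spec$maxit, factr = 10))
  # polishing pass from the first optimum
  opt2 <- stats::optim(opt$par, obj$fn, obj$gr, method = "L-BFGS-B",
                       lower = lower,
                       control = list(maxit = spec$maxit, factr = 10))
  if (opt2$value <= opt$value) opt <- opt2
  par <- mimic_unpack(opt$par, px, py, spec$disturbance)
  grad <- obj$gr(opt$par)
  at_bound <- lower > -Inf & opt$par <= lower + 1e-12
  grad_free <- grad
  grad_free[at_bound & grad > 0] <- 0 # projected gradient at active bounds
  gradient_norm <- max(abs(grad_free))
  converged <- opt$convergence == 0 && gradient_norm < 1e-4
  if (any(at_bound[var_idx[var_idx %in% which(at_bound)]])) {
    warning("fit_mimic: variance parameter bounded at 0 (Heywood case)")
  }
  p <- px + py
  fmin <- obj$fn(opt$par)
  chi_square <- max((n - 1) * fmin, 0)
  dof <- p * (p + 1) / 2 - q
  sigma_hat <- mimic_sigma(par, px, py)
  S_ml <- S * (n - 1) / n
  ll <- -(n / 2) * (p * log(2 * pi) +
                      determinant(sigma_hat, logarithm = TRUE)$modulus +
                      sum(solve(sigma_hat) * S_ml))
  fit <- structure(
    list(gamma = stats::setNames(par$gamma, spec$causes),
         lambda = stats::setNames(c(1, par$lambda_free), spec$indicators),
         psi = par$psi, theta = stats::setNames(par$theta, spec$indicators),
         phi = par$phi, chi_square = chi_square, df = dof,
         logLik = as.numeric(ll), aic = -2 * as.numeric(ll) + 2 * q,
         n_free_parameters = q, gradient_norm = gradient_norm,
         fmin = fmin, converged = converged, S = S, n = n, spec = spec),
    class = "mimic_fit")
  fit
}

#' @export
print.mimic_fit <- function(x, ...) {
  cat(sprintf("MIMIC fit (n = %d%s%s)\n", x$n,
              if (x$spec$disturbance) ", with disturbance"
              else ", psi fixed at 0",
              if (x$converged) "" else ", NOT converged"))
  cat("  gamma:", paste(sprintf("%s=%.3f", names(x$gamma), x$gamma),
                        collapse = ", "), "\n")
  cat("  lambda:", paste(sprintf("%.3f", x$lambda), collapse = ", "),
      " psi:", format(round(x$psi, 4)), "\n")
  cat(sprintf("  chi-square = %.3f on %d df; AIC = %.1f\n",
              x$chi_square, x$df, x$aic))
  invisible(x)
}

#' Comparative fit indices for a MIMIC fit
#'
#' CFI compares the model's non-centrality with an independence baseline
#' (all covariances zero, variances free, fitted in closed form on the same
#' sample covariance):
#' `CFI = 1 - max(chi_m - df_m, 0) / max(chi_m - df_m, chi_b - df_b, 0)`.
#' AIC is `-2 logLik + 2 q` (only AIC differences between models fit to the
#' same data are meaningful).
#'
#' @param fit A `mimic_fit`.
#' @param baseline Optional `mimic_fit` or list with `chi_square` and `df`
#'   to use as the baseline; by default the independence model on `fit`'s
#'   own sample covariance.
#' @return List with `chi_square`, `df`, `cfi`, `aic`, `baseline_chi_square`,
#'   `baseline_df` and an optional `note`.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  stopifnot(inherits(fit, "mimic_fit"))
  if (is.null(baseline)) {
    S <- fit$S
    p <- ncol(S)
    f_b <- sum(log(diag(S))) -
      as.numeric(determinant(S, logarithm = TRUE)$modulus)
    baseline <- list(chi_square = (fit$n - 1) * f_b, df = p * (p - 1) / 2)
  }
  d_m <- fit$chi_square - fit$df
  d_b <- baseline$chi_square - baseline$df
  note <- NULL
  if (d_b <= 0) {
    cfi <- 1
    note <- "baseline no worse than model (chi_b - df_b <= 0); CFI set to 1"
  } else {
    cfi <- 1 - max(d_m, 0) / max(d_m, d_b, 0)
  }
  list(chi_square = fit$chi_square, df = fit$df, cfi = cfi, aic = fit$aic,
       baseline_chi_square = baseline$chi_square, baseline_df = baseline$df,
       note = note)
}

#' Regression-method factor scores from a MIMIC fit
#'
#' `E[eta | z] = Cov(eta, z) Sigma^-1 (z - mean)`, standardized to unit
#' variance over the scored records. With a zero disturbance and zero
#' residual variances the scores reduce to `gamma' x` up to scale.
#'
#' @param fit A converged `mimic_fit`.
#' @param table A `cohort_table` containing the model's variables.
#' @return Numeric vector of standardized latent scores (one per complete
#'   record).
#' @export
score_latent <- function(fit, table) {
  stopifnot(inherits(fit, "mimic_fit"), inherits(table, "cohort_table"))
  if (!fit$converged) {
    warning("score_latent: scoring a non-converged fit")
  }
  table <- complete_cases(table)
  vars <- c(fit$spec$causes, fit$spec$indicators)
  Z <- as.matrix(as.data.frame(table)[, vars, drop = FALSE])
  px <- length(fit$spec$causes)
  py <- length(fit$spec$indicators)
  par <- list(gamma = unname(fit$gamma), lambda_free = unname(fit$lambda[-1L]),
              psi = fit$psi, theta = unname(fit$theta), phi = fit$phi)
  sigma <- mimic_sigma(par, px, py)
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop("score_latent: implied covariance is singular")
  })
  v_eta <- drop(crossprod(par$gamma, par$phi %*% par$gamma)) + par$psi
  cvec <- c(drop(par$phi %*% par$gamma), v_eta * c(1, par$lambda_free))
  w <- backsolve(ch, forwardsolve(t(ch), cvec))
  sc <- drop(scale(Z, scale = FALSE) %*% w)
  s <- stats::sd(sc)
  if (!is.finite(s) || s < 1e-12) {
    stop("score_latent: degenerate scores (zero variance)")
  }
  sc / s
}
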