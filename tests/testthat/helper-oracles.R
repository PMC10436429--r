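# Independent oracles used across the suite. These deliberately re-derive
# the statistics from first principles (double loops, explicit rank
# formulae, Newton iterations, EM) and never call the package's own code
# paths for the quantity they check.

# Pearson chi-square by explicit double loop over cells
oracle_pearson_chisq <- function(observed) {
  rs <- rowSums(observed)
  cs <- colSums(observed)
  tot <- sum(observed)
  stat <- 0
  for (i in seq_len(nrow(observed))) {
    for (j in seq_len(ncol(observed))) {
      e <- rs[i] * cs[j] / tot
      stat <- stat + (observed[i, j] - e)^2 / e
    }
  }
  stat
}

# midranks by the explicit formula: (# smaller) + (# equal + 1) / 2
oracle_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Spearman rho = Pearson correlation of midranks, from raw sums
oracle_spearman <- function(x, y) {
  rx <- oracle_midranks(x)
  ry <- oracle_midranks(y)
  n <- length(x)
  sxy <- sum(rx * ry) - n * mean(rx) * mean(ry)
  sxx <- sum(rx^2) - n * mean(rx)^2
  syy <- sum(ry^2) - n * mean(ry)^2
  sxy / sqrt(sxx * syy)
}

# logistic regression by damped Newton-Raphson on the score equations
oracle_newton_logistic <- function(X, y, tol = 1e-12, maxit = 100L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * W, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# EM estimator for the MIMIC model, operating on the sample covariance so
# it maximizes the same discrepancy as the quasi-Newton fit; first loading
# fixed at 1, Phi free (= S_xx at the optimum)
oracle_mimic_em <- function(S, px, py, disturbance = TRUE, iters = 5000L) {
  ix <- seq_len(px)
  iy <- px + seq_len(py)
  Sxx <- S[ix, ix, drop = FALSE]
  gamma <- drop(solve(Sxx, S[ix, iy[1]]))
  lambda <- drop(S[iy, iy[1]] / S[iy[1], iy[1]])
  psi <- if (disturbance) 0.1 * S[iy[1], iy[1]] else 0
  theta <- 0.5 * diag(S)[iy]
  phi <- Sxx
  for (it in seq_len(iters)) {
    v_eta <- drop(crossprod(gamma, phi %*% gamma)) + psi
    cvec <- c(drop(phi %*% gamma), v_eta * lambda)
    sigma <- rbind(cbind(phi, (phi %*% gamma) %*% t(lambda)),
                   cbind(t((phi %*% gamma) %*% t(lambda)),
                         v_eta * tcrossprod(lambda) + diag(theta, py)))
    b <- solve(sigma, cvec)
    e_zeta <- drop(S %*% b)          # Cov(E[eta|z], z) under the data law
    e_eta2 <- drop(crossprod(b, S %*% b)) + v_eta - sum(cvec * b)
    e_xeta <- e_zeta[ix]
    e_yeta <- e_zeta[iy]
    gamma <- drop(solve(Sxx, e_xeta))
    if (disturbance) {
      psi <- max(e_eta2 - sum(e_xeta * gamma), 0)
    }
    lambda <- c(1, e_yeta[-1] / e_eta2)
    theta <- pmax(diag(S)[iy] - 2 * lambda * e_yeta + lambda^2 * e_eta2,
                  1e-10)
    phi <- Sxx
  }
  list(gamma = gamma, lambda = lambda, psi = psi, theta = theta, phi = phi)
}

# direct draw from the MIMIC data-generating model with continuous
# indicators (used for parameter-recovery checks)
simulate_mimic_data <- function(n, gamma, lambda, psi, theta, phi, seed) {
  set.seed(seed)
  px <- length(gamma)
  py <- length(lambda)
  X <- matrix(rnorm(n * px), n) %*% chol(phi)
  eta <- drop(X %*% gamma) + rnorm(n, 0, sqrt(psi))
  Y <- outer(eta, lambda) +
    matrix(rnorm(n * py), n) %*% diag(sqrt(theta), py)
  colnames(X) <- paste0("x", seq_len(px))
  colnames(Y) <- paste0("y", seq_len(py))
  cbind(as.data.frame(X), as.data.frame(Y))
}
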