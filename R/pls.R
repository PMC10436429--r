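#' Specify a two-block PLS path model
#'
#' The model of interest links a formative (Mode B) social-vulnerability
#' block to a reflective (Mode A) healthcare-self-efficacy block through a
#' single inner path. Blocks are given in causal order; the inner model is
#' the chain from each block to the next.
#'
#' @param blocks Named list mapping block name to indicator column names.
#' @param modes Character vector, one of `"A"` (reflective: outer weights
#'   are indicator/inner-proxy correlations) or `"B"` (formative: outer
#'   weights are multiple-regression coefficients of the inner proxy on the
#'   block) per block.
#' @param inner_scheme `"centroid"` (sign of latent correlations, the
#'   classic Wold scheme), `"factorial"` (correlations), or `"path"`
#'   (regression-based; equals factorial for a single path).
#' @param tol Convergence tolerance on the maximum absolute outer-weight
#'   change.
#' @param max_iter Iteration cap.
#' @param anchors Optional character vector, one indicator per block, fixing
#'   the sign of each latent (the latent is oriented to correlate
#'   positively with its anchor). Defaults to each block's first indicator.
#' @return A `pls_model_spec`.
#' @export
pls_model_spec <- function(blocks = list(vulnerability = formative_indicators(),
                                         efficacy = reflective_items()),
                           modes = c("B", "A"),
                           inner_scheme = c("centroid", "factorial", "path"),
                           tol = 1e-6, max_iter = 300L,
                           anchors = NULL) {
  inner_scheme <- match.arg(inner_scheme)
  stopifnot(is.list(blocks), length(blocks) >= 2L,
            length(modes) == length(blocks),
            all(modes %in% c("A", "B")), tol > 0, max_iter >= 1)
  if (any(!nzchar(names(blocks)))) stop("pls_model_spec: blocks must be named")
  if (any(lengths(blocks) < 1L)) {
    stop("pls_model_spec: every block needs at least one indicator")
  }
  if (is.null(anchors)) {
    anchors <- vapply(blocks, `[`, character(1), 1L)
  }
  for (b in seq_along(blocks)) {
    if (!anchors[b] %in% blocks[[b]]) {
      stop("pls_model_spec: anchor '", anchors[b], "' is not in block '",
           names(blocks)[b], "'")
    }
  }
  structure(list(blocks = blocks, modes = modes, inner_scheme = inner_scheme,
                 tol = tol, max_iter = max_iter, anchors = anchors),
            class = "pls_model_spec")
}

# core Wold algorithm on a list of numeric matrices (one per block, columns
# = indicators); blocks form a chain in the given order
pls_engine <- function(block_mats, modes,
                       inner_scheme = "centroid",
                       tol = 1e-6, max_iter = 300L,
                       anchor_idx = rep(1L, length(block_mats))) {
  B <- length(block_mats)
  n <- nrow(block_mats[[1]])
  Xs <- lapply(block_mats, function(X) {
    X <- scale(as.matrix(X))
    if (any(!is.finite(X))) {
      stop("pls_engine: constant indicator column in a block")
    }
    X
  })
  adjacent <- function(b) {
    nb <- c(b - 1L, b + 1L)
    nb[nb >= 1L & nb <= B]
  }
  orient <- function(w, X, b) {
    y <- drop(X %*% w)
    s <- stats::sd(y)
    if (s < 1e-12) stop("pls_engine: degenerate latent proxy")
    w <- w / s
    if (drop(stats::cor(drop(X %*% w), X[, anchor_idx[b]])) < 0) w <- -w
    w
  }
  w <- vector("list", B)
  for (b in seq_len(B)) {
    w[[b]] <- orient(rep(1, ncol(Xs[[b]])), Xs[[b]], b)
  }
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w_old <- w
    scores <- mapply(function(X, wb) drop(X %*% wb), Xs, w, SIMPLIFY = FALSE)
    for (b in seq_len(B)) {
      z <- numeric(n)
      for (q in adjacent(b)) {
        r <- stats::cor(scores[[b]], scores[[q]])
        e <- switch(inner_scheme,
                    centroid = sign(r),
                    factorial = r,
                    path = r) # single-path chain: regression slope = r
        z <- z + e * scores[[q]]
      }
      z <- z / stats::sd(z)
      if (modes[b] == "A") {
        wb <- drop(stats::cor(Xs[[b]], z))
      } else {
        Rb <- stats::cor(Xs[[b]])
        rz <- drop(stats::cor(Xs[[b]], z))
        wb <- tryCatch(solve(Rb, rz), error = function(e) {
          stop("pls_engine: singular formative block (collinear indicators: ",
               paste(colnames(Xs[[b]]), collapse = ", "), ")")
        })
      }
      w[[b]] <- orient(wb, Xs[[b]], b)
      scores[[b]] <- drop(Xs[[b]] %*% w[[b]])
    }
    delta <- max(mapply(function(a, o) max(abs(a - o)), w, w_old))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  scores <- mapply(function(X, wb) drop(X %*% wb), Xs, w, SIMPLIFY = FALSE)
  loadings <- mapply(function(X, sc) drop(stats::cor(X, sc)), Xs, scores,
                     SIMPLIFY = FALSE)
  list(weights = w, scores = scores, loadings = loadings,
       beta = if (B == 2L) stats::cor(scores[[1]], scores[[2]]) else NA_real_,
       iterations = iter, converged = converged)
}

#' Fit the two-block PLS path model
#'
#' Iterative partial-least-squares estimation: indicators are standardized;
#' outer weights start equal; the algorithm alternates outer proxies
#' (weighted sums rescaled to unit variance), inner proxies under the chosen
#' scheme, and outer-weight updates (Mode B: multiple-regression
#' coefficients of the inner proxy on the block; Mode A: correlations of the
#' indicators with the inner proxy) until the largest weight change falls
#' below `tol`. The path coefficient is then the least-squares slope of the
#' downstream latent on the upstream latent (equal to their correlation,
#' both latents having unit variance), and loadings are
#' indicator-own-latent correlations.
#'
#' Non-convergence is flagged on the result, not raised. Latent signs are
#' fixed by the block anchors; with the default anchors the vulnerability
#' latent loads positively on the education code, giving a negative path
#' against self-efficacy.
#'
#' @param table A `cohort_table` (complete cases are used).
#' @param spec A [pls_model_spec()].
#' @return A `pls_fit`: outer weights `w` per block (on the standardized
#'   indicator scale, latent unit-variance normalization), `loadings`,
#'   `beta`, unit-variance latent `scores`, `r_squared`, `iterations`,
#'   `converged`, `n`.
#' @export
fit_pls_path <- function(table, spec = pls_model_spec()) {
  stopifnot(inherits(table, "cohort_table"), inherits(spec, "pls_model_spec"))
  table <- complete_cases(table)
  df <- as.data.frame(table)
  p_total <- sum(lengths(spec$blocks))
  if (nrow(df) < 10L * p_total) {
    warning("fit_pls_path: fewer than 10 records per indicator (n = ",
            nrow(df), ")")
  }
  block_mats <- lapply(spec$blocks, function(cols) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      stop("fit_pls_path: missing column(s): ", paste(missing, collapse = ", "))
    }
    as.matrix(df[, cols, drop = FALSE])
  })
  anchor_idx <- mapply(function(cols, a) match(a, cols),
                       spec$blocks, spec$anchors)
  eng <- pls_engine(block_mats, spec$modes, spec$inner_scheme,
                    spec$tol, spec$max_iter, anchor_idx)
  names(eng$weights) <- names(eng$scores) <- names(eng$loadings) <-
    names(spec$blocks)
  for (b in names(spec$blocks)) {
    names(eng$weights[[b]]) <- names(eng$loadings[[b]]) <- spec$blocks[[b]]
  }
  structure(list(w = eng$weights, loadings = eng$loadings, beta = eng$beta,
                 scores = do.call(cbind, eng$scores),
                 r_squared = eng$beta^2,
                 iterations = eng$iterations, converged = eng$converged,
                 spec = spec, n = nrow(df)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("PLS path model fit (n = %d, %d iterations%s)\n", x$n,
              x$iterations, if (x$converged) "" else ", NOT converged"))
  for (b in names(x$w)) {
    cat(sprintf("  block '%s' (%s): weights %s\n", b,
                x$spec$modes[match(b, names(x$spec$blocks))],
                paste(sprintf("%s=%.3f", names(x$w[[b]]), x$w[[b]]),
                      collapse = ", ")))
  }
  cat(sprintf("  path coefficient beta = %.3f (R^2 = %.3f)\n",
              x$beta, x$r_squared))
  invisible(x)
}

#' Explained variance of the endogenous block
#'
#' For the single-path two-block model the downstream latent's R-squared
#' equals the squared path coefficient.
#'
#' @param fit A `pls_fit`.
#' @return Named numeric vector of R-squared per endogenous latent.
#' @export
explained_variance <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  if (!fit$converged) {
    warning("explained_variance: fit did not converge; value may be unstable")
  }
  stats::setNames(fit$beta^2, names(fit$w)[length(fit$w)])
}
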