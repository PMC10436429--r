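#' Prevalence of a negative healthcare event by index level
#'
#' Exact counts and proportions of the event per index level across the full
#' theoretical index range, with exact (Clopper-Pearson) binomial confidence
#' intervals and the overall mean event rate (the reference line of the
#' prevalence-by-index plot). Empty levels are reported with `n = 0` and an
#' undefined prevalence.
#'
#' @param table A `cohort_table`.
#' @param outcome Outcome column name (binary, may contain `NA`).
#' @param weights Optional [index_weights()]; default unit weights.
#' @param include_language Include the language deficit in the index.
#' @param conf_level Confidence level for the per-level intervals.
#' @return A `prevalence_curve`: data frame `levels` (index, n, events,
#'   prevalence, lower, upper) plus `overall` mean prevalence and totals.
#' @export
prevalence_by_index <- function(table, outcome, weights = NULL,
                                include_language = TRUE,
                                conf_level = 0.95) {
  stopifnot(inherits(table, "cohort_table"))
  if (!outcome %in% names(table)) {
    stop("prevalence_by_index: no such outcome column: ", outcome)
  }
  idx <- compute_index(table, weights, include_language = include_language)
  y <- table[[outcome]]
  ok <- !is.na(idx) & !is.na(y)
  idx <- idx[ok]
  y <- y[ok]
  if (!all(y %in% c(0, 1))) {
    stop("prevalence_by_index: outcome must be binary 0/1")
  }
  specs <- attr(table, "indicator_specs")
  cols <- formative_indicators()
  if (!is.null(weights)) cols <- names(weights$fixed_weights)
  nms <- sub("_code$", "", cols)
  lo <- sum(vapply(nms, function(nm) min(specs[[nm]]$codes), numeric(1)))
  hi <- sum(vapply(nms, function(nm) max(specs[[nm]]$codes), numeric(1)))
  if (include_language) {
    lo <- lo + min(specs$language$codes)
    hi <- hi + max(specs$language$codes)
  }
  levels <- seq(lo, hi)
  rows <- lapply(levels, function(l) {
    sel <- idx == l
    n <- sum(sel)
    ev <- sum(y[sel])
    if (n == 0L) {
      data.frame(index = l, n = 0L, events = 0L, prevalence = NA_real_,
                 lower = NA_real_, upper = NA_real_)
    } else {
      ci <- stats::binom.test(ev, n, conf.level = conf_level)$conf.int
      data.frame(index = l, n = n, events = ev, prevalence = ev / n,
                 lower = ci[1], upper = ci[2])
    }
  })
  levels_df <- do.call(rbind, rows)
  structure(list(levels = levels_df, overall = mean(y),
                 n = length(y), events = sum(y), outcome = outcome),
            class = "prevalence_curve")
}

#' @export
print.prevalence_curve <- function(x, ...) {
  cat(sprintf("Prevalence of '%s' by index level (n = %d, overall %.1f%%)\n",
              x$outcome, x$n, 100 * x$overall))
  df <- x$levels
  df$prevalence <- round(100 * df$prevalence, 1)
  df$lower <- round(100 * df$lower, 1)
  df$upper <- round(100 * df$upper, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

# build the analysis frame for the outcome regressions
outcome_frame <- function(table, outcome, threshold, weights,
                          include_language, covariates) {
  idx <- compute_index(table, weights, include_language = include_language)
  df <- data.frame(y = table[[outcome]],
                   vulnerable = as.integer(idx >= threshold),
                   chronic_count = table$chronic_count)
  for (cv in covariates) {
    if (!cv %in% names(table)) {
      stop("fit_outcome_logistic: missing covariate column: ", cv)
    }
    df[[cv]] <- table[[cv]]
  }
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Logistic validation model for one outcome
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) of a binary negative-event flag on the vulnerability flag
#' `I(index >= threshold)` and the chronic-disease count, optionally with
#' their interaction and extra covariates (e.g. the baseline SF-12 score for
#' the functional-decline outcome). Odds ratios are `exp(coef)` with Wald
#' confidence intervals.
#'
#' @param table A `cohort_table` with the outcome computed.
#' @param outcome Outcome column name.
#' @param threshold Index threshold defining the vulnerability flag.
#' @param weights Optional [index_weights()] for the index; default unit.
#' @param include_language Include the language deficit in the index.
#' @param covariates Extra covariate column names (default none beyond the
#'   chronic count).
#' @param interaction Add the vulnerable-by-chronic interaction and report
#'   its Wald p-value.
#' @param conf_level Wald interval level.
#' @return A `logistic_fit`: `coefficients`, `vcov`, a `table` of OR with
#'   CI and p per term, `n`, `outcome`, `converged`, and `interaction_p`
#'   when requested.
#' @export
fit_outcome_logistic <- function(table, outcome, threshold = 2L,
                                 weights = NULL, include_language = TRUE,
                                 covariates = character(0),
                                 interaction = FALSE, conf_level = 0.95) {
  stopifnot(inherits(table, "cohort_table"))
  if (!outcome %in% names(table)) {
    stop("fit_outcome_logistic: no such outcome column: ", outcome)
  }
  df <- outcome_frame(table, outcome, threshold, weights, include_language,
                      covariates)
  if (!all(df$y %in% c(0, 1))) {
    stop("fit_outcome_logistic: outcome must be binary 0/1")
  }
  rhs <- c("vulnerable", "chronic_count", covariates,
           if (interaction) "vulnerable:chronic_count")
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-12))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) {
    stop("fit_outcome_logistic: unestimable coefficient for predictor(s) ",
         paste(names(cf)[!is.finite(cf)], collapse = ", "))
  }
  mu <- stats::fitted(fit)
  sep <- abs(cf) > 12 & (any(mu < 1e-10) || any(mu > 1 - 1e-10))
  if (any(sep)) {
    stop("fit_outcome_logistic: complete separation on predictor(s) ",
         paste(names(cf)[sep], collapse = ", "))
  }
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- cf / se
  tab <- data.frame(term = names(cf), estimate = unname(cf),
                    se = unname(se), or = exp(unname(cf)),
                    or_lower = exp(unname(cf - zq * se)),
                    or_upper = exp(unname(cf + zq * se)),
                    z = unname(z),
                    p_value = 2 * stats::pnorm(-abs(unname(z))))
  res <- structure(
    list(coefficients = cf, vcov = V, table = tab, n = nrow(df),
         outcome = outcome, threshold = threshold,
         converged = fit$converged,
         interaction_p = if (interaction)
           tab$p_value[tab$term == "vulnerable:chronic_count"] else NULL),
    class = "logistic_fit")
  res
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic model for '%s' (n = %d%s)\n", x$outcome, x$n,
              if (x$converged) "" else ", NOT converged"))
  df <- x$table
  df$or <- round(df$or, 3)
  df$or_lower <- round(df$or_lower, 3)
  df$or_upper <- round(df$or_upper, 3)
  df$p_value <- signif(df$p_value, 3)
  print(df[, c("term", "or", "or_lower", "or_upper", "p_value")],
        row.names = FALSE)
  invisible(x)
}

#' Detect the vulnerability threshold
#'
#' Two complementary diagnostics: (i) a model comparison that fits
#' `outcome ~ I(index >= k) + chronic_count` for each candidate `k` and a
#' no-threshold reference model `outcome ~ chronic_count`, choosing the `k`
#' with the smallest AIC provided it beats the reference; and (ii) a curve
#' diagnostic, the smallest level whose per-level prevalence exceeds the
#' overall mean rate by a configurable relative margin. Candidates causing
#' complete separation are flagged and excluded from the comparison. Both
#' choices are reported.
#'
#' @param table A `cohort_table`.
#' @param outcome Outcome column name.
#' @param candidate_ks Candidate thresholds (default 1..4).
#' @param margin Relative excess over the overall rate for the curve
#'   diagnostic (default 0.2, i.e. 20% above the mean rate).
#' @param weights,include_language Index options, as elsewhere.
#' @return A `threshold_detection`: `aic_choice` (chosen `k` or `NA` when no
#'   threshold model beats the reference), `curve_choice`, the per-candidate
#'   `comparison` table, and the `curve` used.
#' @export
detect_threshold <- function(table, outcome, candidate_ks = 1:4,
                             margin = 0.2, weights = NULL,
                             include_language = TRUE) {
  stopifnot(length(candidate_ks) >= 2L)
  curve <- prevalence_by_index(table, outcome, weights,
                               include_language = include_language)
  idx <- compute_index(table, weights, include_language = include_language)
  df0 <- data.frame(y = table[[outcome]], idx = idx,
                    chronic_count = table$chronic_count)
  df0 <- df0[stats::complete.cases(df0), ]
  null_fit <- stats::glm(y ~ chronic_count, family = stats::binomial(),
                         data = df0,
                         control = stats::glm.control(epsilon = 1e-12))
  rows <- lapply(candidate_ks, function(k) {
    df0$flag <- as.integer(df0$idx >= k)
    if (length(unique(df0$flag)) < 2L) {
      return(data.frame(k = k, aic = NA_real_, status = "empty group"))
    }
    fit <- stats::glm(y ~ flag + chronic_count, family = stats::binomial(),
                      data = df0,
                      control = stats::glm.control(epsilon = 1e-12))
    cf <- stats::coef(fit)["flag"]
    mu <- stats::fitted(fit)
    if (!is.finite(cf) ||
        (abs(cf) > 12 && (any(mu < 1e-10) || any(mu > 1 - 1e-10)))) {
      return(data.frame(k = k, aic = NA_real_, status = "separation"))
    }
    data.frame(k = k, aic = stats::AIC(fit), status = "ok")
  })
  comparison <- do.call(rbind, rows)
  usable <- comparison[comparison$status == "ok", ]
  aic_choice <- NA_integer_
  if (nrow(usable) && min(usable$aic) < stats::AIC(null_fit)) {
    aic_choice <- usable$k[which.min(usable$aic)]
  }
  lv <- curve$levels
  exceeds <- !is.na(lv$prevalence) &
    lv$prevalence > curve$overall * (1 + margin)
  curve_choice <- if (any(exceeds)) {
    min(lv$index[exceeds])
  } else NA_integer_
  structure(list(aic_choice = aic_choice, curve_choice = curve_choice,
                 comparison = comparison, null_aic = stats::AIC(null_fit),
                 curve = curve, margin = margin, outcome = outcome),
            class = "threshold_detection")
}

#' @export
print.threshold_detection <- function(x, ...) {
  cat(sprintf("Threshold detection for '%s'\n", x$outcome))
  print(x$comparison, row.names = FALSE)
  cat(sprintf("  no-threshold AIC %.1f; AIC choice k = %s; curve choice k = %s\n",
              x$null_aic, format(x$aic_choice), format(x$curve_choice)))
  invisible(x)
}

#' Crude versus chronic-adjusted odds ratio
#'
#' Reports the crude odds ratio for the vulnerability flag, the odds ratio
#' adjusted for the chronic-disease count, and their ratio (attenuation
#' below 1 indicates confounding of the social effect by health status).
#'
#' @inheritParams fit_outcome_logistic
#' @return List with `crude_or`, `adjusted_or`, `attenuation_ratio` and the
#'   two fits.
#' @export
compare_adjusted_unadjusted <- function(table, outcome, threshold = 2L,
                                        weights = NULL,
                                        include_language = TRUE) {
  df <- outcome_frame(table, outcome, threshold, weights, include_language,
                      character(0))
  ctl <- stats::glm.control(epsilon = 1e-12)
  crude <- stats::glm(y ~ vulnerable, family = stats::binomial(), data = df,
                      control = ctl)
  adjusted <- stats::glm(y ~ vulnerable + chronic_count,
                         family = stats::binomial(), data = df,
                         control = ctl)
  or_c <- exp(stats::coef(crude)["vulnerable"])
  or_a <- exp(stats::coef(adjusted)["vulnerable"])
  list(crude_or = unname(or_c), adjusted_or = unname(or_a),
       attenuation_ratio = unname(or_a / or_c),
       crude_fit = crude, adjusted_fit = adjusted)
}
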