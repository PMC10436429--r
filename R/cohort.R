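#' @title Cohort table: column schema
#' @description Fixed column names of the cohort schema. Raw indicator
#'   columns are `<indicator>_raw`, coded columns `<indicator>_code`; the
#'   four reflective healthcare self-efficacy items are Likert 1-5; the
#'   chronic-disease burden is a count of stable diagnoses (0-14); outcomes
#'   are 0/1 flags for negative healthcare events in the following twelve
#'   months; `complete` marks records retained for complete-case analysis.
#' @name cohort_schema
NULL

#' @rdname cohort_schema
#' @return `reflective_items()`: names of the four self-efficacy items.
#' @export
reflective_items <- function() {
  c("efficacy_info", "efficacy_health", "selfmgmt_between", "selfmgmt_nohelp")
}

#' @rdname cohort_schema
#' @return `outcome_names()`: names of the eight negative-event flags.
#' @export
outcome_names <- function() {
  c("ed_visits_2plus", "any_admission", "admission_via_ed",
    "ed_system_reasons", "sf12_decline", "problem_worse_delay",
    "felt_abandoned", "unmet_need")
}

#' @rdname cohort_schema
#' @return `formative_indicators()`: default coded-indicator column names
#'   used in model fitting (language excluded by default: at ~1% prevalence
#'   there is no power to estimate its weight).
#' @export
formative_indicators <- function(include_language = FALSE) {
  base <- c("education_code", "financial_code", "instrumental_code",
            "confidant_code")
  if (include_language) c(base, "language_code") else base
}

required_cohort_columns <- function(specs) {
  c(paste0(names(specs), "_raw"), reflective_items(), "chronic_count")
}

#' Construct and validate a cohort table
#'
#' Wraps a data frame of per-participant records in a validated
#' `cohort_table`. Coded indicator columns are (re)derived from the raw
#' columns via the specs. Validation failures are collected and reported
#' together (row and field), never silently dropped.
#'
#' @param data Data frame with the raw indicator columns
#'   (`education_raw`, ...), the four reflective items, `chronic_count`, and
#'   optionally outcome flags, `baseline_sf12` and `complete`.
#' @param specs Named list of [indicator_spec()]s; defaults to
#'   [default_indicator_specs()].
#' @return A `cohort_table` (a data frame with the specs attached).
#' @export
cohort_table <- function(data, specs = default_indicator_specs()) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  missing_cols <- setdiff(required_cohort_columns(specs), names(data))
  if (length(missing_cols)) {
    stop("cohort_table: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  problems <- character(0)
  for (nm in names(specs)) {
    col <- paste0(nm, "_raw")
    v <- data[[col]]
    bad <- which(!is.na(v) & !(v %in% specs[[nm]]$raw_scale))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "field '%s': value %s out of range in row %d", col, v[bad], bad))
    }
  }
  for (it in reflective_items()) {
    v <- data[[it]]
    bad <- which(!is.na(v) & !(v %in% 1:5))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "field '%s': value %s outside 1..5 in row %d", it, v[bad], bad))
    }
  }
  bad <- which(!is.na(data$chronic_count) & data$chronic_count < 0)
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "field 'chronic_count': negative value in row %d", bad))
  }
  for (oc in intersect(outcome_names(), names(data))) {
    v <- data[[oc]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "field '%s': non-binary value in row %d", oc, bad))
    }
  }
  if (length(problems)) {
    stop("cohort_table: ", length(problems), " validation failure(s):\n  ",
         paste(utils::head(problems, 20L), collapse = "\n  "))
  }
  for (nm in names(specs)) {
    data[[paste0(nm, "_code")]] <-
      recode_indicator(data[[paste0(nm, "_raw")]], specs[[nm]])
  }
  if (is.null(data$complete)) data$complete <- TRUE
  structure(data, indicator_specs = specs,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  n_complete <- if (is.null(x$complete)) nrow(x) else sum(x$complete)
  cat(sprintf("Cohort table: %d records (%d complete), %d columns\n",
              nrow(x), n_complete, ncol(x)))
  NextMethod()
}

#' @export
`[.cohort_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "indicator_specs") <- attr(x, "indicator_specs")
    class(out) <- class(x)
  }
  out
}

#' Restrict a cohort to complete-case records
#'
#' Complete-case analysis keeps records flagged complete with no missing
#' values in the coded indicators, reflective items and chronic count.
#'
#' @param table A `cohort_table`.
#' @return The filtered `cohort_table`.
#' @export
complete_cases <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  specs <- attr(table, "indicator_specs")
  need <- c(paste0(names(specs), "_code"), reflective_items(), "chronic_count")
  keep <- table$complete & stats::complete.cases(table[, need, drop = FALSE])
  out <- table[keep, , drop = FALSE]
  attr(out, "indicator_specs") <- specs
  class(out) <- class(table)
  out
}

#' Read a cohort file
#'
#' Cohort files are UTF-8 comma-separated text with one header row and empty
#' fields for missing values.
#'
#' @param path Path to a CSV cohort file.
#' @param specs Indicator specs defining the schema.
#' @return A validated `cohort_table`.
#' @export
load_cohort <- function(path, specs = default_indicator_specs()) {
  if (!file.exists(path)) stop("load_cohort: file not found: ", path)
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  cohort_table(df, specs = specs)
}

#' Write a cohort file
#'
#' @param table A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Spearman screening of reflective items against formative indicators
#'
#' Computes the rank-correlation matrix (midrank tie handling) among the
#' reflective self-efficacy items and between reflective items and coded
#' formative indicators, with asymptotic p-values, and flags pairs whose
#' absolute correlation or significance fails the screening thresholds.
#' Reflective items of a common construct should intercorrelate; formative
#' indicators should each correlate (negatively, under the vulnerability
#' orientation) with every reflective item at similar magnitude -- the
#' proportional-effect screening used before MIMIC fitting.
#'
#' @param table A `cohort_table` (complete cases are used).
#' @param reflective Reflective item column names.
#' @param formative Coded formative indicator column names.
#' @param min_abs_rho Screening floor on |rho| (default 0.1).
#' @param alpha Significance threshold for the screening flag (default 0.001,
#'   the reporting level used for the published correlations).
#' @return A `correlation_report`: list with `rho` and `p_value` matrices
#'   over `c(reflective, formative)`, a `flagged` data frame of failing
#'   reflective-formative pairs, and `undefined` pairs (constant columns,
#'   reported as undefined rather than 0).
#' @export
spearman_screen <- function(table,
                            reflective = reflective_items(),
                            formative = formative_indicators(),
                            min_abs_rho = 0.1, alpha = 0.001) {
  stopifnot(inherits(table, "cohort_table"))
  table <- complete_cases(table)
  vars <- c(reflective, formative)
  X <- as.data.frame(table)[, vars, drop = FALSE]
  if (nrow(X) < 3L) stop("spearman_screen: need at least 3 complete records")
  k <- length(vars)
  rho <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  pval <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1
  diag(pval) <- 0
  constant <- vapply(X, function(v) stats::var(v) == 0, logical(1))
  undefined <- character(0)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (constant[i] || constant[j]) {
        undefined <- c(undefined, paste(vars[i], vars[j], sep = " ~ "))
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(X[[i]], X[[j]], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pval[i, j] <- pval[j, i] <- ct$p.value
    }
  }
  flagged <- data.frame(reflective = character(0), formative = character(0),
                        rho = numeric(0), p_value = numeric(0),
                        reason = character(0))
  for (r in reflective) {
    for (f in formative) {
      rr <- rho[r, f]
      pp <- pval[r, f]
      if (is.na(rr)) next
      if (abs(rr) < min_abs_rho || pp > alpha) {
        flagged <- rbind(flagged, data.frame(
          reflective = r, formative = f, rho = rr, p_value = pp,
          reason = if (abs(rr) < min_abs_rho) "weak" else "not significant"))
      }
    }
  }
  structure(list(rho = rho, p_value = pval, flagged = flagged,
                 undefined = undefined, n = nrow(X),
                 min_abs_rho = min_abs_rho, alpha = alpha),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Spearman screening over %d complete records\n", x$n))
  print(round(x$rho, 3))
  if (nrow(x$flagged)) {
    cat("Flagged pairs (|rho| <", x$min_abs_rho, "or p >", x$alpha, "):\n")
    print(x$flagged, row.names = FALSE)
  } else {
    cat("No reflective-formative pair fails the screening thresholds.\n")
  }
  if (length(x$undefined)) {
    cat("Undefined (constant column):", paste(x$undefined, collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Baseline-versus-completer attrition chi-square
#'
#' Compares the categorical make-up of cohort completers with that of
#' non-completers. Non-completer counts are formed by subtracting completer
#' counts from baseline counts; the Pearson chi-square is then computed on
#' the completers x non-completers contingency table with
#' `(categories - 1)` degrees of freedom and no continuity correction.
#'
#' @param baseline_counts Integer category counts in the full baseline
#'   sample.
#' @param completer_counts Integer category counts among completers; must
#'   not exceed the baseline counts category-wise.
#' @return A `chi_square_result`: statistic, df, p_value, observed and
#'   expected tables.
#' @examples
#' # self-perceived financial status, completers vs baseline
#' attrition_chi_square(c(238, 1476, 751), c(181, 1225, 633))
#' @export
attrition_chi_square <- function(baseline_counts, completer_counts) {
  if (length(baseline_counts) != length(completer_counts)) {
    stop("attrition_chi_square: count vectors differ in length")
  }
  if (length(baseline_counts) < 2L) {
    stop("attrition_chi_square: need at least 2 categories")
  }
  non_completers <- baseline_counts - completer_counts
  if (any(non_completers < 0)) {
    stop("attrition_chi_square: completer count exceeds baseline count in ",
         "category ", paste(which(non_completers < 0), collapse = ", "))
  }
  observed <- rbind(completers = completer_counts,
                    non_completers = non_completers)
  ct <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, observed = observed,
                 expected = ct$expected),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.3f, %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Descriptive cohort summary
#'
#' Per-variable counts and percentages over non-missing denominators for the
#' coded indicators, the index distribution, reflective item means/SDs,
#' multimorbidity, and outcome prevalences.
#'
#' @param table A `cohort_table`.
#' @param weights Optional [index_weights()] used for the index distribution;
#'   defaults to unit weights.
#' @return A `cohort_summary`: list of data frames (`indicators`, `index`,
#'   `items`, `health`, `outcomes`).
#' @export
summarize_cohort <- function(table, weights = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  if (nrow(table) == 0L) stop("summarize_cohort: empty table")
  specs <- attr(table, "indicator_specs")
  ind <- do.call(rbind, lapply(names(specs), function(nm) {
    v <- table[[paste0(nm, "_code")]]
    v <- v[!is.na(v)]
    codes <- specs[[nm]]$codes
    cnt <- vapply(codes, function(cc) sum(v == cc), integer(1))
    data.frame(indicator = nm, code = codes,
               label = if (is.null(specs[[nm]]$labels)) NA_character_
                       else specs[[nm]]$labels,
               n = cnt,
               percent = if (length(v)) 100 * cnt / length(v) else 0)
  }))
  idx <- compute_index(table, weights = weights)
  iv <- idx[!is.na(idx)]
  lv <- sort(unique(iv))
  index_df <- data.frame(index = lv,
                         n = vapply(lv, function(l) sum(iv == l), integer(1)))
  index_df$percent <- 100 * index_df$n / max(1L, length(iv))
  items <- do.call(rbind, lapply(reflective_items(), function(it) {
    v <- table[[it]]
    data.frame(item = it, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE), n = sum(!is.na(v)))
  }))
  cc <- table$chronic_count
  health <- data.frame(
    measure = c("mean_chronic_count", "percent_3plus_chronic"),
    value = c(mean(cc, na.rm = TRUE),
              100 * mean(cc >= 3, na.rm = TRUE)))
  ocs <- intersect(outcome_names(), names(table))
  outcomes <- do.call(rbind, lapply(ocs, function(oc) {
    v <- table[[oc]]
    n <- sum(!is.na(v))
    data.frame(outcome = oc, n = n, events = sum(v, na.rm = TRUE),
               percent = if (n) 100 * mean(v, na.rm = TRUE) else 0)
  }))
  structure(list(indicators = ind, index = index_df, items = items,
                 health = health, outcomes = outcomes,
                 n = nrow(table)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n\nIndicator coding:\n", x$n))
  print(transform(x$indicators, percent = round(percent, 1)),
        row.names = FALSE)
  cat("\nIndex distribution:\n")
  print(transform(x$index, percent = round(percent, 1)), row.names = FALSE)
  cat("\nReflective items:\n")
  print(transform(x$items, mean = round(mean, 2), sd = round(sd, 2)),
        row.names = FALSE)
  if (!is.null(x$outcomes) && nrow(x$outcomes)) {
    cat("\nOutcome prevalence:\n")
    print(transform(x$outcomes, percent = round(percent, 1)),
          row.names = FALSE)
  }
  invisible(x)
}
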