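#' Index weight sets
#'
#' Holds model-generated weights (from a PLS or MIMIC fit) alongside their
#' fixed-weight simplification, the reference magnitude the fixed weights
#' are expressed against, and (once measured) the Pearson correlation
#' between the model-weighted and fixed-weight index on a reference table.
#'
#' @param model_weights Named numeric vector of model-generated weights over
#'   coded indicator columns (same sign after orientation).
#' @param fixed_weights Named positive-integer weights over the same
#'   indicators.
#' @param base_value Reference weight magnitude (the model-weight magnitude
#'   mapped to a fixed weight of 1).
#' @param equivalence_r Optional Pearson correlation between the two index
#'   variants.
#' @return An `index_weights` object.
#' @export
index_weights <- function(model_weights, fixed_weights, base_value,
                          equivalence_r = NA_real_) {
  stopifnot(length(model_weights) == length(fixed_weights),
            !is.null(names(model_weights)))
  if (any(fixed_weights <= 0) || any(fixed_weights != round(fixed_weights))) {
    stop("index_weights: fixed weights must be positive integers")
  }
  if (!is.na(equivalence_r) && abs(equivalence_r) > 1) {
    stop("index_weights: equivalence correlation outside [-1, 1]")
  }
  structure(list(model_weights = model_weights,
                 fixed_weights = stats::setNames(as.integer(fixed_weights),
                                                 names(model_weights)),
                 base_value = base_value, equivalence_r = equivalence_r),
            class = "index_weights")
}

#' @export
print.index_weights <- function(x, ...) {
  cat("Index weights\n")
  print(data.frame(indicator = names(x$model_weights),
                   model = round(x$model_weights, 3),
                   fixed = x$fixed_weights), row.names = FALSE)
  cat(sprintf("  base value %.3f; equivalence r = %s\n", x$base_value,
              if (is.na(x$equivalence_r)) "not measured"
              else sprintf("%.3f", x$equivalence_r)))
  invisible(x)
}

#' Simplify model weights to fixed integer weights
#'
#' Model-generated weights are specific to a model and sample; for a
#' generalizable bedside score they are collapsed to integers. When the
#' weights are of approximately similar magnitude
#' (`max|w| / min|w| <= ratio_threshold`) every indicator receives a fixed
#' weight of 1; otherwise integer weights are `round(|w| / min|w|)`. The
#' default threshold 1.75 treats a spread such as 0.51 vs 0.33 (ratio 1.55)
#' as equivalent.
#'
#' @param model_weights Named numeric weights, all of the same sign after
#'   orientation (mixed signs indicate an orientation problem upstream).
#' @param ratio_threshold Spread above which weights stop collapsing to 1.
#' @return An [index_weights()] object.
#' @examples
#' fixed_weights(c(education_code = 0.42, financial_code = 0.38,
#'                 instrumental_code = 0.33, confidant_code = 0.51))
#' @export
fixed_weights <- function(model_weights, ratio_threshold = 1.75) {
  if (is.null(names(model_weights))) {
    stop("fixed_weights: model weights must be named")
  }
  if (any(model_weights == 0)) {
    stop("fixed_weights: zero model weight for ",
         paste(names(model_weights)[model_weights == 0], collapse = ", "))
  }
  s <- sign(model_weights)
  if (length(unique(s)) > 1L) {
    stop("fixed_weights: mixed-sign model weights (",
         paste(sprintf("%s=%.3f", names(model_weights), model_weights),
               collapse = ", "),
         "); orient the latent so all indicator weights share a sign ",
         "(see the orientation anchor of the model spec)")
  }
  a <- abs(model_weights)
  base <- min(a)
  fw <- if (max(a) / base <= ratio_threshold) {
    rep(1L, length(a))
  } else {
    pmax(1L, as.integer(round(a / base)))
  }
  index_weights(model_weights, stats::setNames(fw, names(model_weights)),
                base_value = base)
}

#' Compute the social vulnerability index per record
#'
#' The index is the weighted sum of coded indicator values. With the default
#' unit weights and the standard coding (education/financial/instrumental
#' at -1/0/+1, confidant at 0/+1/+2) the theoretical range is -3..5, or
#' -3..6 when the binary language deficit is included. Records missing any
#' required indicator get an explicitly missing index (`NA`), never 0.
#'
#' @param table A `cohort_table` (or any data frame with the coded columns).
#' @param weights An [index_weights()] (fixed weights are used), or `NULL`
#'   for unit weights over the four modelled indicators.
#' @param include_language Add the language deficit code with weight 1
#'   (default `TRUE`: the bedside score sums five indicators even though
#'   only four carry model-estimated weights).
#' @param use_model_weights Use the model weights instead of the fixed ones.
#' @return Numeric vector (integer-valued under integer weights).
#' @export
compute_index <- function(table, weights = NULL, include_language = TRUE,
                          use_model_weights = FALSE) {
  if (is.null(weights)) {
    cols <- formative_indicators()
    w <- stats::setNames(rep(1, length(cols)), cols)
  } else {
    stopifnot(inherits(weights, "index_weights"))
    w <- if (use_model_weights) abs(weights$model_weights)
         else weights$fixed_weights
  }
  if (include_language && !"language_code" %in% names(w)) {
    w <- c(w, language_code = 1)
  }
  missing_cols <- setdiff(names(w), names(table))
  if (length(missing_cols)) {
    stop("compute_index: missing indicator column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  M <- as.matrix(as.data.frame(table)[, names(w), drop = FALSE])
  unname(drop(M %*% w)) # NA propagates for records with missing indicators
}

#' Correlation between model-weighted and fixed-weight index
#'
#' Pearson correlation, over the records of `table`, between the index
#' computed with the model-generated weights and the one computed with the
#' fixed integer weights. High values justify the fixed-weight
#' simplification.
#'
#' @param table A `cohort_table`.
#' @param weights An [index_weights()] object.
#' @param include_language Include the language deficit in both variants.
#' @return The updated `index_weights` with `equivalence_r` set; the
#'   correlation itself is in `$equivalence_r`.
#' @export
weight_equivalence <- function(table, weights, include_language = FALSE) {
  stopifnot(inherits(weights, "index_weights"))
  im <- compute_index(table, weights, include_language = include_language,
                      use_model_weights = TRUE)
  if_ <- compute_index(table, weights, include_language = include_language)
  ok <- stats::complete.cases(cbind(im, if_))
  if (sum(ok) < 3L) stop("weight_equivalence: need >= 3 complete records")
  if (stats::sd(im[ok]) < 1e-12 || stats::sd(if_[ok]) < 1e-12) {
    warning("weight_equivalence: zero variance in an index; ",
            "correlation undefined")
    weights$equivalence_r <- NA_real_
    return(weights)
  }
  weights$equivalence_r <- stats::cor(im[ok], if_[ok])
  weights
}

#' Search indicator cut-points by refitting the measurement model
#'
#' Raw survey scales are collapsed to the coded ordinal categories at cut
#' points chosen to preserve the most construct information: the search
#' refits the chosen model for every candidate binning and keeps the one
#' with the highest explained variance of the downstream latent (PLS) or
#' the best comparative fit index (MIMIC). The search is exhaustive over
#' the grid product up to `max_exhaustive` combinations and coordinate-wise
#' greedy beyond that. Candidates where the model fails to converge are
#' skipped and logged in the trace.
#'
#' @param table A `cohort_table` carrying raw indicator columns.
#' @param grids Named list: indicator name -> list of candidate `cut_points`
#'   vectors.
#' @param objective `"pls_r2"` or `"mimic_cfi"`.
#' @param pls_spec,mimic_model Model specs used for refitting.
#' @param max_exhaustive Combination cap for the exhaustive search.
#' @return A `cutpoint_solution`: chosen `cut_points` per indicator, the
#'   `objective_value` at the optimum (a re-fit value, by construction),
#'   the full `trace`, and the search `method`.
#' @export
search_cutpoints <- function(table, grids,
                             objective = c("pls_r2", "mimic_cfi"),
                             pls_spec = pls_model_spec(),
                             mimic_model = mimic_spec(),
                             max_exhaustive = 256L) {
  objective <- match.arg(objective)
  stopifnot(inherits(table, "cohort_table"), is.list(grids),
            length(grids) >= 1L, all(lengths(grids) >= 1L))
  specs <- attr(table, "indicator_specs")
  unknown <- setdiff(names(grids), names(specs))
  if (length(unknown)) {
    stop("search_cutpoints: unknown indicator(s): ",
         paste(unknown, collapse = ", "))
  }
  evaluate <- function(choice) {
    tab <- table
    for (nm in names(choice)) {
      sp <- specs[[nm]]
      new_spec <- tryCatch(
        indicator_spec(sp$name, sp$raw_scale, choice[[nm]], sp$codes,
                       direction = sp$direction),
        error = function(e) NULL)
      if (is.null(new_spec)) return(list(value = NA_real_,
                                         status = "invalid binning"))
      tab[[paste0(nm, "_code")]] <-
        recode_indicator(tab[[paste0(nm, "_raw")]], new_spec)
    }
    out <- tryCatch({
      if (objective == "pls_r2") {
        fit <- fit_pls_path(tab, pls_spec)
        if (!fit$converged) list(value = NA_real_, status = "non-convergence")
        else list(value = fit$r_squared, status = "ok")
      } else {
        fit <- fit_mimic(tab, mimic_model)
        if (!fit$converged) list(value = NA_real_, status = "non-convergence")
        else list(value = fit_indices(fit)$cfi, status = "ok")
      }
    }, error = function(e) list(value = NA_real_,
                                status = paste("error:", conditionMessage(e))))
    out
  }
  describe <- function(choice) {
    paste(vapply(names(choice), function(nm) {
      sprintf("%s=(%s)", nm, paste(choice[[nm]], collapse = ","))
    }, character(1)), collapse = "; ")
  }
  trace <- data.frame(candidate = character(0), objective = numeric(0),
                      status = character(0))
  log_eval <- function(choice) {
    r <- evaluate(choice)
    trace <<- rbind(trace, data.frame(candidate = describe(choice),
                                      objective = r$value,
                                      status = r$status))
    r$value
  }
  n_comb <- prod(lengths(grids))
  if (n_comb <= max_exhaustive) {
    method <- "exhaustive"
    idx_grid <- do.call(expand.grid, lapply(lengths(grids), seq_len))
    best_val <- -Inf
    best <- NULL
    for (r in seq_len(nrow(idx_grid))) {
      choice <- stats::setNames(
        lapply(names(grids),
               function(nm) grids[[nm]][[idx_grid[r, nm]]]), names(grids))
      val <- log_eval(choice)
      if (!is.na(val) && val > best_val) {
        best_val <- val
        best <- choice
      }
    }
  } else {
    method <- "greedy"
    current <- stats::setNames(lapply(grids, `[[`, 1L), names(grids))
    best_val <- log_eval(current)
    repeat {
      improved <- FALSE
      for (nm in names(grids)) {
        for (cand in grids[[nm]]) {
          if (identical(cand, current[[nm]])) next
          trial <- current
          trial[[nm]] <- cand
          val <- log_eval(trial)
          if (!is.na(val) && (is.na(best_val) || val > best_val)) {
            best_val <- val
            current <- trial
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    best <- current
  }
  if (is.null(best) || is.na(best_val) || best_val == -Inf) {
    stop("search_cutpoints: no candidate produced a converged fit")
  }
  structure(list(cut_points = best, objective = objective,
                 objective_value = best_val, trace = trace, method = method),
            class = "cutpoint_solution")
}

#' @export
print.cutpoint_solution <- function(x, ...) {
  cat(sprintf("Cut-point search (%s, objective %s): best value %.4f\n",
              x$method, x$objective, x$objective_value))
  for (nm in names(x$cut_points)) {
    cat(sprintf("  %s: cut points (%s)\n", nm,
                paste(x$cut_points[[nm]], collapse = ", ")))
  }
  cat(sprintf("  %d candidates evaluated (%d usable)\n", nrow(x$trace),
              sum(x$trace$status == "ok")))
  invisible(x)
}

#' Write a one-page scoring card
#'
#' Exports the indicator coding and weights as a plain-text card (question,
#' coding, weight per indicator, plus the vulnerability threshold) for
#' clinical reuse.
#'
#' @param weights An [index_weights()] object.
#' @param specs Indicator specs.
#' @param path Output text file.
#' @param threshold Index value flagging vulnerability.
#' @return `path`, invisibly.
#' @export
write_scoring_card <- function(weights, specs = default_indicator_specs(),
                               path, threshold = 2L) {
  lines <- c("INDIVIDUAL SOCIAL VULNERABILITY SCORING CARD",
             strrep("-", 44))
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    col <- paste0(nm, "_code")
    w <- if (col %in% names(weights$fixed_weights)) {
      weights$fixed_weights[[col]]
    } else if (identical(nm, "language")) 1L else NA_integer_
    if (is.na(w)) next
    lines <- c(lines, sprintf("%s (weight %d):", toupper(nm), w))
    bins <- findInterval(sp$raw_scale, sp$cut_points) + 1L
    for (i in seq_along(sp$codes)) {
      lab <- if (is.null(sp$labels)) "" else paste0(" ", sp$labels[i])
      lines <- c(lines, sprintf("  %+d =%s [raw %s]", sp$codes[i], lab,
                                paste(sp$raw_scale[bins == i],
                                      collapse = ",")))
    }
  }
  lines <- c(lines, strrep("-", 44),
             sprintf("Index = weighted sum of codes; Index >= %d flags",
                     threshold),
             "vulnerability to negative healthcare events.")
  writeLines(lines, path)
  invisible(path)
}
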