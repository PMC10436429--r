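#' Pipeline run configuration
#'
#' One object drives the full analysis: generate (or load) a cohort, recode
#' and summarize, screen the reflective items, fit the PLS path and MIMIC
#' models, optionally search cut-points, derive fixed index weights, score
#' every record, and validate the index against the outcome list.
#'
#' @param input Either a file path to a cohort CSV or a
#'   [generator_params()] object (exactly one source).
#' @param outdir Output directory (created if absent).
#' @param seed Master seed; overrides the generator seed and is recorded in
#'   the manifest.
#' @param outcomes Outcome columns to validate.
#' @param cutpoint_grids Optional grids for [search_cutpoints()]; `NULL`
#'   skips the search stage.
#' @param cutpoint_objective Objective for the cut-point search.
#' @param ratio_threshold Spread threshold for [fixed_weights()].
#' @param threshold_candidates Candidate index thresholds for
#'   [detect_threshold()].
#' @param include_language Include the language deficit when scoring.
#' @param pls_spec,mimic_model Model specifications.
#' @return A `run_config`.
#' @export
run_config <- function(input = generator_params(),
                       outdir = tempfile("svindex_run_"),
                       seed = 1L,
                       outcomes = outcome_names(),
                       cutpoint_grids = NULL,
                       cutpoint_objective = "pls_r2",
                       ratio_threshold = 1.75,
                       threshold_candidates = 1:4,
                       include_language = TRUE,
                       pls_spec = pls_model_spec(),
                       mimic_model = mimic_spec()) {
  is_path <- is.character(input) && length(input) == 1L
  if (!is_path && !inherits(input, "generator_params")) {
    stop("run_config: input must be a file path or generator_params")
  }
  structure(list(input = input, outdir = outdir, seed = as.integer(seed),
                 outcomes = outcomes, cutpoint_grids = cutpoint_grids,
                 cutpoint_objective = cutpoint_objective,
                 ratio_threshold = ratio_threshold,
                 threshold_candidates = threshold_candidates,
                 include_language = include_language,
                 pls_spec = pls_spec, mimic_model = mimic_model),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Supported keys: `input.file` (cohort CSV path) or `input.generator`
#' (fields of [generator_params()]: `n`, `seed`, `copula_corr`,
#' `language_prev`, `path_target`, `chronic_slope`), plus `outdir`, `seed`,
#' `outcomes`, `ratio_threshold`, `threshold_candidates`,
#' `include_language`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  # YAML 1.1 would read a bare `n` key (the cohort-size field) as a
  # boolean; keep y/n as literal strings and only true/false/yes/no as
  # booleans
  handlers <- list(
    "bool#no" = function(x) if (tolower(x) %in% c("false", "no")) FALSE else x,
    "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes")) TRUE else x)
  y <- yaml::read_yaml(path, handlers = handlers)
  input <- if (!is.null(y$input$file)) {
    y$input$file
  } else {
    g <- y$input$generator
    if (is.null(g)) g <- list()
    allowed <- c("n", "seed", "copula_corr", "language_prev", "path_target",
                 "chronic_slope", "chronic_p3plus")
    do.call(generator_params, g[intersect(names(g), allowed)])
  }
  args <- list(input = input)
  for (k in c("outdir", "seed", "outcomes", "ratio_threshold",
              "threshold_candidates", "include_language")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

write_table <- function(df, outdir, name) {
  p <- file.path(outdir, name)
  utils::write.csv(df, p, row.names = FALSE, na = "")
  p
}

#' Run the full index-construction pipeline
#'
#' Executes every stage in order, writes all intermediate tables as CSV
#' under the output directory, and writes a JSON manifest recording the
#' seed, a hash of the configuration, per-stage timings and convergence
#' flags. Identical configuration and seed give identical numeric outputs.
#' A stage failure keeps earlier outputs and records the failing stage in
#' the manifest (the error is then re-raised).
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly; side effect: files in
#'   `config$outdir` (`cohort_scored.csv`, `screening_rho.csv`,
#'   `pls_parameters.csv`, `mimic_parameters.csv`, `index_weights.csv`,
#'   `outcomes_table.csv`, `prevalence_curves.csv`, `thresholds.csv`,
#'   `manifest.json`, and `cutpoint_trace.csv` when a grid is given).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$outdir, "config.json")
  cfg_json <- jsonlite::serializeJSON(config[setdiff(names(config), "outdir")])
  writeLines(cfg_json, cfg_path)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   stages = list(), files = character(0), failed_stage = NULL)
  finish <- function() {
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[svindex] stage %-14s ...", name))
    res <- tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      manifest$stages[[name]] <<- list(
        seconds = round(proc.time()[["elapsed"]] - t0, 3),
        error = conditionMessage(e))
      finish()
      stop("run_pipeline: stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    info <- manifest$stages[[name]]
    info$seconds <- round(proc.time()[["elapsed"]] - t0, 3)
    manifest$stages[[name]] <<- info
    res
  }

  cohort <- stage("input", {
    if (is.character(config$input)) {
      load_cohort(config$input)
    } else {
      generate_cohort(config$input, seed = config$seed)
    }
  })
  stage("summarize", {
    smry <- summarize_cohort(cohort)
    manifest$files <- c(manifest$files,
                        write_table(smry$indicators, config$outdir,
                                    "indicator_summary.csv"),
                        write_table(smry$index, config$outdir,
                                    "index_distribution.csv"))
  })
  screen <- stage("screen", {
    sc <- spearman_screen(cohort)
    manifest$files <- c(manifest$files,
                        write_table(as.data.frame(round(sc$rho, 6)),
                                    config$outdir, "screening_rho.csv"))
    sc
  })
  pls <- stage("pls", {
    fit <- fit_pls_path(cohort, config$pls_spec)
    manifest$stages$pls$converged <- fit$converged
    params <- rbind(
      data.frame(parameter = paste0("w_", names(fit$w[[1]])),
                 value = unname(fit$w[[1]])),
      data.frame(parameter = paste0("lambda_", names(fit$loadings[[2]])),
                 value = unname(fit$loadings[[2]])),
      data.frame(parameter = c("beta", "r_squared"),
                 value = c(fit$beta, fit$r_squared)))
    manifest$files <- c(manifest$files,
                        write_table(params, config$outdir,
                                    "pls_parameters.csv"))
    fit
  })
  mimic <- stage("mimic", {
    fit <- fit_mimic(cohort, config$mimic_model)
    idx <- fit_indices(fit)
    manifest$stages$mimic$converged <- fit$converged
    params <- rbind(
      data.frame(parameter = paste0("gamma_", names(fit$gamma)),
                 value = unname(fit$gamma)),
      data.frame(parameter = paste0("lambda_", names(fit$lambda)),
                 value = unname(fit$lambda)),
      data.frame(parameter = c("psi", "chi_square", "df", "cfi", "aic"),
                 value = c(fit$psi, idx$chi_square, idx$df, idx$cfi,
                           idx$aic)))
    manifest$files <- c(manifest$files,
                        write_table(params, config$outdir,
                                    "mimic_parameters.csv"))
    fit
  })
  if (!is.null(config$cutpoint_grids)) {
    stage("cutpoints", {
      sol <- search_cutpoints(cohort, config$cutpoint_grids,
                              objective = config$cutpoint_objective,
                              pls_spec = config$pls_spec,
                              mimic_model = config$mimic_model)
      manifest$files <- c(manifest$files,
                          write_table(sol$trace, config$outdir,
                                      "cutpoint_trace.csv"))
      sol
    })
  }
  weights <- stage("weights", {
    w <- fixed_weights(pls$w$vulnerability, config$ratio_threshold)
    w <- weight_equivalence(cohort, w)
    manifest$stages$weights$equivalence_r <- w$equivalence_r
    manifest$files <- c(manifest$files,
                        write_table(
                          data.frame(indicator = names(w$model_weights),
                                     model_weight = w$model_weights,
                                     fixed_weight = w$fixed_weights,
                                     equivalence_r = w$equivalence_r),
                          config$outdir, "index_weights.csv"))
    w
  })
  cohort <- stage("score", {
    scored <- as.data.frame(cohort)
    scored$index <- compute_index(cohort, weights,
                                  include_language = config$include_language)
    scored$vulnerable <- as.integer(scored$index >= 2)
    manifest$files <- c(manifest$files,
                        write_table(scored, config$outdir,
                                    "cohort_scored.csv"))
    cohort
  })
  stage("outcomes", {
    ocs <- intersect(config$outcomes, names(cohort))
    rows <- list()
    curves <- list()
    thr_rows <- list()
    for (oc in ocs) {
      covs <- if (identical(oc, "sf12_decline") &&
                  "baseline_sf12" %in% names(cohort)) "baseline_sf12"
              else character(0)
      lf <- fit_outcome_logistic(cohort, oc, weights = weights,
                                 include_language = config$include_language,
                                 covariates = covs)
      tb <- lf$table
      vul <- tb[tb$term == "vulnerable", ]
      chr <- tb[tb$term == "chronic_count", ]
      pc <- prevalence_by_index(cohort, oc, weights,
                                include_language = config$include_language)
      rows[[oc]] <- data.frame(
        outcome = oc, n = lf$n, prevalence = pc$overall,
        or_vulnerable = vul$or, or_vul_lower = vul$or_lower,
        or_vul_upper = vul$or_upper, or_chronic = chr$or,
        or_chr_lower = chr$or_lower, or_chr_upper = chr$or_upper)
      cv <- pc$levels
      cv$outcome <- oc
      cv$overall <- pc$overall
      curves[[oc]] <- cv
      td <- detect_threshold(cohort, oc,
                             candidate_ks = config$threshold_candidates,
                             weights = weights,
                             include_language = config$include_language)
      thr_rows[[oc]] <- data.frame(outcome = oc,
                                   aic_choice = td$aic_choice,
                                   curve_choice = td$curve_choice)
    }
    manifest$files <- c(
      manifest$files,
      write_table(do.call(rbind, rows), config$outdir, "outcomes_table.csv"),
      write_table(do.call(rbind, curves), config$outdir,
                  "prevalence_curves.csv"),
      write_table(do.call(rbind, thr_rows), config$outdir, "thresholds.csv"))
  })
  finish()
  invisible(manifest)
}
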