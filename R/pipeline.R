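#' Pipeline configuration
#'
#' Settings for the five-stage analysis flow: chi-square screening,
#' bagged-forest importance ranking, cross-validated L1 selection, logistic
#' modelling, and concentration-index decomposition. Input is either a
#' delimited-text file (`input`) or a simulate block (`simulate`, a
#' [generator_config()]).
#'
#' @param input path to a survey file, or `NULL` to simulate.
#' @param simulate a [generator_config()] used when `input` is `NULL`.
#' @param factors candidate factor columns.
#' @param references factor -> reference code map.
#' @param chi2_alpha significance level of the univariate screen.
#' @param forest a [forest_config()] used for the importance forest.
#' @param search_iter randomized-search draws (0 skips the search and uses
#'   `forest` as-is).
#' @param search_subsample rows subsampled for the hyperparameter search
#'   (`Inf` uses all rows).
#' @param lasso_k folds for the L1 cross-validation.
#' @param lambda_choice `"lambda_min"` or `"lambda_1se"` for downstream
#'   selection.
#' @param rank_income column used for the equity income ranks.
#' @param output_dir directory for artifacts (`NULL` writes nothing).
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulate = generator_config(),
                            factors = covariate_factors(),
                            references = default_references(factors),
                            chi2_alpha = 0.05,
                            forest = forest_config(n_estimators = 100,
                                                   max_depth = 10,
                                                   min_samples_leaf = 5),
                            search_iter = 0, search_subsample = 4000,
                            lasso_k = 10,
                            lambda_choice = c("lambda_min", "lambda_1se"),
                            rank_income = "income_raw",
                            output_dir = NULL, seed = 1L) {
  lambda_choice <- match.arg(lambda_choice)
  structure(list(input = input, simulate = simulate, factors = factors,
                 references = references, chi2_alpha = chi2_alpha,
                 forest = forest, search_iter = search_iter,
                 search_subsample = search_subsample, lasso_k = lasso_k,
                 lambda_choice = lambda_choice, rank_income = rank_income,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default synthetic-study pipeline configuration
#'
#' The configuration used for synthetic end-to-end validation: 20,000
#' respondents generated with the published logit coefficients as truth and
#' the income-education dependence enabled (so factor concentration indices
#' are non-zero and the decomposition has signal to attribute).
#'
#' @param n respondents.
#' @param seed master seed.
#' @param ... overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
default_pipeline_config <- function(n = 20000, seed = 1L, ...) {
  pipeline_config(
    simulate = generator_config(n = n, income_by_education = 0.15,
                                income_gradient = 0.3,
                                seed = seed %% 1000003L + 11L),
    seed = seed, ...)
}

# derive a stage seed from the master seed, kept below 2^31
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + stage
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (1) load or simulate the microdata and clean it;
#' (2) chi-square screening at `chi2_alpha` — factors failing the screen
#' are excluded from everything downstream; (3) bagged-forest OOB
#' permutation importance (with optional randomized hyperparameter search)
#' on the surviving factors, integer-coded; (4) cross-validated L1-penalized
#' logistic selection over the surviving factors' dummies; (5) logistic fit
#' on the selected factors with odds-ratio table; (6) concentration index,
#' curve, and Wagstaff decomposition over the selected factors. Artifacts
#' are written under `output_dir` when set.
#'
#' @param config a [pipeline_config()].
#' @return A `report_bundle`: list with `data` (cleaned table),
#'   `cleaning_report`, `screen`, `importance`, `search`, `lasso`,
#'   `selected`, `fit`, `or_table`, `equity` (list: `ci`, `mu`,
#'   `residual_term`, `decomposition`, `curve`), `log` (seeds and stage
#'   timings), `config`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  log <- list(seed = config$seed, timings = c(), r_version = R.version.string)
  tick <- function(stage) {
    log$timings[stage] <<- proc.time()[["elapsed"]] - t0
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # 1. data
  dat <- stage("data", {
    if (!is.null(config$input)) {
      tab <- read_survey(config$input, quiet = TRUE)
    } else {
      tab <- simulate_survey(config$simulate)$table
    }
    clean_survey(tab)
  })
  tab <- dat$table
  if (!"income_quintile" %in% names(tab) && "income_raw" %in% names(tab)) {
    tab <- assign_income_quintiles(tab)
  }
  tick("data")

  # 2. univariate screen
  factors <- intersect(config$factors, names(tab))
  screen <- stage("chi2_screen",
                  chisq_screen(tab, factors, alpha = config$chi2_alpha))
  kept <- screen$factor[screen$keep]
  if (length(kept) == 0) {
    stop("pipeline stage 'chi2_screen' failed: no factor passed the screen",
         call. = FALSE)
  }
  tick("chi2_screen")

  # 3. forest importance on integer-coded factors
  y <- tab$health_education
  Xf <- as.data.frame(tab)[, kept, drop = FALSE]
  search <- NULL
  fcfg <- config$forest
  if (config$search_iter > 0) {
    sub <- seq_len(nrow(Xf))
    if (is.finite(config$search_subsample) &&
        config$search_subsample < nrow(Xf)) {
      set.seed(stage_seed(config$seed, 31L))
      sub <- sample.int(nrow(Xf), config$search_subsample)
    }
    search <- stage("random_search",
      random_search_forest(Xf[sub, , drop = FALSE], y[sub],
                           n_iter = config$search_iter,
                           seed = stage_seed(config$seed, 32L)))
    fcfg <- forest_config(search$best$n_estimators, search$best$max_depth,
                          search$best$min_samples_split,
                          search$best$min_samples_leaf,
                          mode = config$forest$mode,
                          seed = stage_seed(config$seed, 33L))
  } else {
    fcfg$seed <- stage_seed(config$seed, 33L)
  }
  forest <- stage("forest", fit_forest(Xf, y, fcfg))
  importance <- stage("importance",
                      oob_importance(forest, Xf, y,
                                     seed = stage_seed(config$seed, 34L)))
  tick("importance")

  # 4. L1 selection over the screened factors' dummies
  X_all <- dummy_encode(tab, kept, config$references[kept])
  cv <- stage("lasso",
              cv_select(X_all, y, k = config$lasso_k,
                        seed = stage_seed(config$seed, 35L)))
  lambda <- cv[[config$lambda_choice]]
  selected <- stage("lasso", selected_factors(cv$path, lambda,
                                              column_factor_map(X_all)))
  if (length(selected) == 0) selected <- kept  # degenerate all-zero path
  tick("lasso")

  # 5. logistic model on the selected factors
  X_sel <- dummy_encode(tab, selected, config$references[selected])
  fit <- stage("logit", fit_logit(X_sel, y))
  or_tab <- odds_ratio_table(fit)
  tick("logit")

  # 6. equity
  equity <- stage("equity", {
    ranks <- fractional_rank(tab[[config$rank_income]])
    conc <- concentration_index(y, ranks)
    dec <- wagstaff_decompose(fit, X_sel, ranks, y)
    list(ci = conc$ci, mu = conc$mu, direction = conc$direction,
         residual_term = attr(dec, "residual_term"),
         decomposition = dec, curve = conc$curve)
  })
  tick("equity")

  bundle <- structure(
    list(data = tab, cleaning_report = dat$report, screen = screen,
         importance = importance, search = search, lasso = cv,
         lambda = lambda, selected = selected, fit = fit,
         or_table = or_tab, equity = equity, log = log, config = config),
    class = "report_bundle")
  if (!is.null(config$output_dir)) write_report_bundle(bundle,
                                                       config$output_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat(sprintf("  n = %d, outcome rate = %.4f\n", nrow(x$data),
              mean(x$data$health_education)))
  cat("  screened-in factors:", paste(x$screen$factor[x$screen$keep],
                                      collapse = ", "), "\n")
  cat("  importance ranking:", paste(x$importance$ranking, collapse = " > "),
      "\n")
  cat("  selected factors:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  concentration index: %.6f (%s)\n", x$equity$ci,
              x$equity$direction))
  invisible(x)
}

#' Report-bundle summary as a plain list (JSON-ready)
#'
#' @param bundle a `report_bundle`.
#' @return list of plain vectors/tables mirroring the bundle, suitable for
#'   [jsonlite::write_json()].
#' @export
report_summary <- function(bundle) {
  list(
    n = nrow(bundle$data),
    outcome_rate = mean(bundle$data$health_education),
    cleaning_report = as.list(bundle$cleaning_report),
    screen = bundle$screen,
    importance = importance_table(bundle$importance),
    lambda = unname(bundle$lambda),
    selected_factors = bundle$selected,
    coefficients = as.list(bundle$fit$beta),
    odds_ratios = bundle$or_table,
    equity = list(ci = bundle$equity$ci, mu = bundle$equity$mu,
                  direction = bundle$equity$direction,
                  residual_term = bundle$equity$residual_term),
    decomposition = as.data.frame(bundle$equity$decomposition),
    seed = bundle$log$seed
  )
}

#' Validate a report summary against the shipped schema
#'
#' Checks that every required component of the report-bundle summary is
#' present with the right type, per `inst/schema/report_schema.json`.
#'
#' @param summary list from [report_summary()] (or parsed JSON).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(summary) {
  schema <- jsonlite::read_json(system.file("schema", "report_schema.json",
                                            package = "healthequity"))
  for (req in schema$required) {
    if (is.null(summary[[req]])) stop("report missing field: ", req,
                                      call. = FALSE)
  }
  eq <- summary$equity
  for (req in c("ci", "mu", "residual_term")) {
    if (is.null(eq[[req]]) || !is.numeric(eq[[req]])) {
      stop("report equity block missing numeric field: ", req, call. = FALSE)
    }
  }
  if (!is.numeric(summary$outcome_rate)) stop("outcome_rate must be numeric",
                                              call. = FALSE)
  invisible(TRUE)
}

#' Write all pipeline artifacts
#'
#' Writes the report JSON, screen/importance/decomposition/odds-ratio CSVs,
#' the CV curve, and the concentration-curve points under `dir`.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  smry <- report_summary(bundle)
  jsonlite::write_json(smry, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  utils::write.csv(bundle$screen, file.path(dir, "chi2_screen.csv"),
                   row.names = FALSE)
  importance_table(bundle$importance, file.path(dir, "importance.csv"))
  utils::write.csv(data.frame(lambda = bundle$lasso$lambdas,
                              cv_mean = bundle$lasso$cv_mean,
                              cv_se = bundle$lasso$cv_se),
                   file.path(dir, "cv_curve.csv"), row.names = FALSE)
  utils::write.csv(bundle$or_table, file.path(dir, "odds_ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$equity$decomposition),
                   file.path(dir, "decomposition.csv"), row.names = FALSE)
  utils::write.csv(bundle$equity$curve,
                   file.path(dir, "concentration_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(bundle$cleaning_report),
                       file.path(dir, "cleaning_report.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
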