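#' Default marginal category probabilities
#'
#' Category probabilities for every categorical covariate, taken from the
#' published descriptive distribution of the 2018 migrant-survey respondents
#' (counts over 103,910 respondents), normalized to sum to one. These are
#' the generator's default marginals.
#'
#' @return Named list; each element is a named probability vector over the
#'   factor's codes. `income_quintile` is included for reference although
#'   the generator derives quintiles from simulated income, not by sampling.
#' @export
table2_marginals <- function() {
  counts <- list(
    health_level       = c("1" = 2384,  "2" = 12080, "3" = 89446),
    health_education   = c("0" = 18821, "1" = 85089),
    health_record      = c("0" = 70226, "1" = 33684),
    family_doctor      = c("0" = 88235, "1" = 15675),
    gender             = c("0" = 50899, "1" = 53011),
    age_group          = c("1" = 29641, "2" = 48358, "3" = 21396, "4" = 4515),
    education          = c("1" = 2542,  "2" = 14179, "3" = 43614,
                           "4" = 22890, "5" = 20685),
    marital            = c("0" = 16618, "1" = 87292),
    working            = c("0" = 17723, "1" = 86187),
    hukou              = c("1" = 70248, "2" = 33662),
    mobility_range     = c("1" = 18533, "2" = 35347, "3" = 50030),
    mobility_reason    = c("1" = 14985, "2" = 87036, "3" = 1889),
    income_quintile    = c("1" = 22866, "2" = 21207, "3" = 21216,
                           "4" = 20038, "5" = 18563),
    insurance_location = c("1" = 72588, "2" = 31322),
    sick               = c("0" = 91544, "1" = 12366)
  )
  lapply(counts, function(v) v / sum(v))
}

#' Published logit coefficients used as generator defaults
#'
#' The dummy-level coefficients of the published binary logistic model of
#' health-education receipt (seven factors, reference level = lowest code),
#' used as the synthetic generator's default true coefficients.
#'
#' @return Named numeric vector; names are design-matrix column names
#'   (`<factor><code>`).
#' @export
table5_coefficients <- function() {
  c(income_quintile2 = 0.140, income_quintile3 = 0.151,
    income_quintile4 = 0.229, income_quintile5 = 0.088,
    age_group2 = -0.038, age_group3 = -0.280, age_group4 = -0.557,
    education2 = 0.143, education3 = 0.369,
    education4 = 0.629, education5 = 0.628,
    health_record1 = 1.413,
    mobility_range2 = 0.428, mobility_range3 = 0.432,
    mobility_reason2 = 0.051, mobility_reason3 = 0.283,
    gender1 = 0.083)
}

# Expected value of each dummy column under the generator's marginals;
# income-quintile dummies have expectation 0.2 by construction of the
# within-province quintile split.
.dummy_expectations <- function(true_beta, marginal_probs) {
  vapply(names(true_beta), function(nm) {
    m <- regmatches(nm, regexec("^(.*?)([0-9]+)$", nm))[[1]]
    f <- m[2]; lv <- m[3]
    if (f == "income_quintile") return(0.2)
    p <- marginal_probs[[f]]
    if (is.null(p) || !(lv %in% names(p))) {
      stop("config error: no marginal probability for dummy column ", nm,
           call. = FALSE)
    }
    unname(p[[lv]])
  }, numeric(1))
}

#' Generator configuration
#'
#' Parameters of the synthetic microdata generator. Covariates are drawn
#' independently from `marginal_probs`; household income is log-normal with
#' a province-specific location (plus an optional shift per education level,
#' which induces the income-covariate association that makes factor
#' concentration indices non-zero); the outcome is Bernoulli with
#' `logit(p) = beta0 + sum(beta_j x_j) + income_gradient * r`, where `r` is
#' the respondent's within-province fractional income rank.
#'
#' @param n number of respondents.
#' @param n_provinces number of provinces.
#' @param marginal_probs per-factor category probabilities; defaults to
#'   [table2_marginals()].
#' @param true_beta named coefficients on dummy columns; defaults to
#'   [table5_coefficients()].
#' @param beta0 intercept; `NULL` chooses the value for which the expected
#'   linear predictor equals `qlogis(target_rate)` under the marginals, so
#'   the realized outcome rate sits near `target_rate`.
#' @param target_rate outcome rate used to auto-set `beta0` (published
#'   receipt rate 0.8189).
#' @param income_gradient extra logit slope on the within-province
#'   fractional income rank (0.5 means the richest gain 0.5 logits over the
#'   poorest beyond what the quintile dummies give).
#' @param income_by_education shift of the income log-location per education
#'   level above the middle (`meanlog + income_by_education * (edu - 3)`);
#'   0 disables the income-education dependence hook.
#' @param income_meanlog,income_sdlog base log-normal income parameters.
#' @param province_sd standard deviation of province effects on `meanlog`.
#' @param seed integer seed fixing the output byte-for-byte.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 1e5, n_provinces = 31,
                             marginal_probs = table2_marginals(),
                             true_beta = table5_coefficients(),
                             beta0 = NULL, target_rate = 0.8189,
                             income_gradient = 0,
                             income_by_education = 0,
                             income_meanlog = log(60000),
                             income_sdlog = 0.6,
                             province_sd = 0.2,
                             seed = 1L) {
  stopifnot(n >= 1, n_provinces >= 1)
  for (f in names(marginal_probs)) {
    p <- marginal_probs[[f]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("config error: marginal probabilities for '", f,
           "' must be non-negative and sum to 1", call. = FALSE)
    }
  }
  if (is.null(beta0)) {
    ex <- .dummy_expectations(true_beta, marginal_probs)
    beta0 <- stats::qlogis(target_rate) - sum(true_beta * ex) -
      income_gradient * 0.5
  }
  structure(list(n = as.integer(n), n_provinces = as.integer(n_provinces),
                 marginal_probs = marginal_probs, true_beta = true_beta,
                 beta0 = beta0, target_rate = target_rate,
                 income_gradient = income_gradient,
                 income_by_education = income_by_education,
                 income_meanlog = income_meanlog,
                 income_sdlog = income_sdlog,
                 province_sd = province_sd, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate synthetic survey microdata with known truth
#'
#' Draws a synthetic respondent table from a [generator_config()] and
#' returns it together with a truth record holding every generative
#' parameter and each respondent's linear predictor, so downstream
#' estimates can be checked against ground truth.
#'
#' @param config a [generator_config()].
#' @return list with `table` (a `survey_table`) and `truth` (list:
#'   `beta0`, `true_beta`, `income_gradient`, `linear_predictor`,
#'   `p`, `config`).
#' @examples
#' sim <- simulate_survey(generator_config(n = 500, seed = 7))
#' mean(sim$table$health_education)
#' @export
simulate_survey <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n
  mp <- config$marginal_probs

  draw <- function(p) {
    sample(as.numeric(names(p)), n, replace = TRUE, prob = p)
  }
  factors <- setdiff(names(mp), c("health_education", "income_quintile"))
  tab <- as.data.frame(lapply(stats::setNames(factors, factors),
                              function(f) draw(mp[[f]])))

  prov_idx <- sample.int(config$n_provinces, n, replace = TRUE)
  tab$province <- sprintf("P%02d", prov_idx)
  prov_effect <- stats::rnorm(config$n_provinces, 0, config$province_sd)
  meanlog <- config$income_meanlog + prov_effect[prov_idx] +
    config$income_by_education * (tab$education - 3)
  tab$income_raw <- round(stats::rlnorm(n, meanlog, config$income_sdlog), 2)

  tab <- assign_income_quintiles(tab)

  # within-province fractional income rank for the optional direct gradient
  r <- numeric(n)
  for (g in unique(tab$province)) {
    idx <- which(tab$province == g)
    r[idx] <- fractional_rank(tab$income_raw[idx])$r
  }

  X <- dummy_encode(tab, unique(sub("[0-9]+$", "", names(config$true_beta))),
                    intercept = FALSE)
  bt <- config$true_beta[colnames(X)]
  if (anyNA(bt)) {
    stop("config error: true_beta names do not match dummy columns: ",
         paste(setdiff(colnames(X), names(config$true_beta)), collapse = ", "),
         call. = FALSE)
  }
  lp <- config$beta0 + as.numeric(X %*% bt) + config$income_gradient * r
  p <- stats::plogis(lp)
  tab$health_education <- stats::rbinom(n, 1L, p)

  list(table = survey_table(tab),
       truth = list(beta0 = config$beta0, true_beta = config$true_beta,
                    income_gradient = config$income_gradient,
                    income_rank = r, linear_predictor = lp, p = p,
                    config = config))
}

#' Write a truth record as JSON
#'
#' @param truth the `truth` element returned by [simulate_survey()].
#' @param path output path.
#' @param include_vectors keep the per-respondent vectors (linear predictor,
#'   probabilities); drop them for a compact parameter-only record.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, include_vectors = FALSE) {
  rec <- truth
  rec$config <- unclass(rec$config)
  rec$config$marginal_probs <- lapply(rec$config$marginal_probs, as.list)
  rec$true_beta <- as.list(rec$true_beta)
  rec$config$true_beta <- as.list(rec$config$true_beta)
  if (!include_vectors) {
    rec$linear_predictor <- NULL; rec$p <- NULL; rec$income_rank <- NULL
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
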