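#' Cross-tabulate a factor against the binary outcome
#'
#' Counts respondents by factor level (rows) and outcome (columns 0/1),
#' with margins and within-outcome-column percentages, the layout used for
#' univariate screening tables.
#'
#' @param x survey_table.
#' @param factor name of the factor column.
#' @param outcome name of the binary outcome column.
#' @return A `contingency_table`: list with `factor`, `levels`, `counts`
#'   (levels x 2 matrix), `row_margins`, `col_margins`, `col_percent`, `n`.
#' @export
crosstab <- function(x, factor, outcome = "health_education") {
  stopifnot(factor %in% names(x), outcome %in% names(x))
  if (nrow(x) == 0L) stop("degenerate data: empty table", call. = FALSE)
  f <- x[[factor]]; y <- x[[outcome]]
  keep <- !is.na(f) & !is.na(y)
  f <- f[keep]; y <- y[keep]
  levs <- sort(unique(f))
  counts <- t(vapply(levs, function(l) c(sum(f == l & y == 0),
                                         sum(f == l & y == 1)),
                     numeric(2)))
  dimnames(counts) <- list(as.character(levs), c("0", "1"))
  new_contingency_table(factor, counts)
}

new_contingency_table <- function(factor, counts, flag = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- as.character(seq_len(nrow(counts)))
  }
  structure(list(factor = factor,
                 levels = rownames(counts),
                 counts = counts,
                 row_margins = rowSums(counts),
                 col_margins = colSums(counts),
                 col_percent = sweep(counts, 2, colSums(counts), "/") * 100,
                 n = sum(counts),
                 flag = flag),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s (n = %d)%s\n", x$factor, x$n,
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  print(cbind(x$counts, total = x$row_margins))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic on the level x outcome counts, without continuity
#' correction, with `(levels - 1)` degrees of freedom against the upper
#' tail of the chi-square distribution.
#'
#' @param ct a [crosstab()] result, or a counts matrix.
#' @return A `chi2_result`: list with `statistic`, `df`, `p_value`,
#'   `factor`.
#' @export
chi2_test <- function(ct) {
  if (is.matrix(ct)) ct <- new_contingency_table("counts", ct)
  stopifnot(inherits(ct, "contingency_table"))
  zero_r <- which(ct$row_margins == 0)
  if (length(zero_r)) {
    stop("empty level in contingency table: ", ct$levels[zero_r[1]],
         call. = FALSE)
  }
  if (any(ct$col_margins == 0)) {
    stop("empty outcome column in contingency table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(ct$counts, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 factor = ct$factor),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("chi-square(%s): X2 = %.3f, df = %d, p = %.3g\n",
              x$factor, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Screen factors by chi-square independence tests
#'
#' Runs [crosstab()] + [chi2_test()] for each factor against the outcome
#' and flags which factors pass the significance screen.
#'
#' @param x survey_table.
#' @param factors factor columns; default: all codebook covariates present.
#' @param outcome outcome column.
#' @param alpha significance level for the screen.
#' @return data.frame with `factor`, `statistic`, `df`, `p_value`, `keep`.
#' @export
chisq_screen <- function(x, factors = intersect(covariate_factors(), names(x)),
                         outcome = "health_education", alpha = 0.05) {
  rows <- lapply(factors, function(f) {
    res <- chi2_test(crosstab(x, f, outcome))
    data.frame(factor = f, statistic = res$statistic, df = res$df,
               p_value = res$p_value, keep = res$p_value < alpha)
  })
  do.call(rbind, rows)
}

#' Published univariate screening counts (reproduction fixture)
#'
#' The level-by-outcome counts of the published univariate analysis of
#' health-education receipt (columns: not received, received). Panels whose
#' printed cells are internally consistent with the descriptive table and
#' whose printed statistic is given to three decimals carry
#' `flag = NULL`; the others are flagged `"inconsistent-margins"` (cells do
#' not add up across the published tables), `"rounded-statistic"` (the
#' statistic is only printed in scientific shorthand), or
#' `"statistic-mismatch"` (cells are consistent but the printed statistic
#' does not match direct computation).
#'
#' @param consistent_only return only the unflagged panels.
#' @return Named list of `contingency_table` objects with a
#'   `printed_statistic` attribute where one was published to full
#'   precision.
#' @export
table3_counts <- function(consistent_only = FALSE) {
  panel <- function(factor, m, printed = NA_real_, flag = NULL) {
    ct <- new_contingency_table(factor, m, flag = flag)
    attr(ct, "printed_statistic") <- printed
    ct
  }
  m <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                            dimnames = list(NULL, c("0", "1")))
  panels <- list(
    marital = panel("marital",
      m(2671, 13947, 16150, 71142), 55.496),
    working = panel("working",
      m(3956, 13767, 14865, 71322), 255.154),
    hukou = panel("hukou",
      m(13491, 56757, 5330, 28332), 174.348),
    mobility_range = panel("mobility_range",
      m(2823, 15710, 5329, 30018, 10669, 39361), 671.508),
    mobility_reason = panel("mobility_reason",
      m(3021, 11964, 15405, 71631, 395, 1494), 62.338),
    income_quintile = panel("income_quintile",
      m(4942, 17944, 3878, 17329, 3721, 17495, 3140, 16898, 3140, 15423),
      290.686),
    insurance_location = panel("insurance_location",
      m(14412, 58176, 4409, 26913), 492.533),
    health_level = panel("health_level",
      m(746, 1638, 2880, 9200, 15195, 74251), 622.733),
    gender = panel("gender",
      m(9001, 41989, 9820, 43191), 12.365, flag = "inconsistent-margins"),
    age_group = panel("age_group",
      m(4561, 25080, 8172, 40186, 4869, 16257, 1219, 3296), 747.923,
      flag = "inconsistent-margins"),
    education = panel("education",
      m(757, 1785, 3528, 10651, 8288, 35326, 3343, 19547, 2905, 17780),
      1.1e3, flag = "rounded-statistic"),
    health_record = panel("health_record",
      m(16428, 53744, 2339, 31345), 4.2e3, flag = "inconsistent-margins"),
    family_doctor = panel("family_doctor",
      m(18164, 70071, 657, 15018), 2.4e3, flag = "rounded-statistic"),
    sick = panel("sick",
      m(15841, 75703, 2980, 9386), 399.049, flag = "statistic-mismatch")
  )
  if (consistent_only) panels <- Filter(function(p) is.null(p$flag), panels)
  panels
}
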