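#' Construct a validated survey table
#'
#' Wraps a data.frame of respondent-level microdata as a `survey_table`,
#' checking every categorical column against the codebook. Missing values
#' are allowed (they are handled by [clean_survey()]); out-of-code values
#' are not.
#'
#' @param df data.frame with one row per respondent.
#' @param codebook codebook list, see [survey_codebook()].
#' @param require character vector of columns that must be present; defaults
#'   to every codebook column found plus none — columns absent from `df` are
#'   simply not validated unless listed here.
#' @return A `survey_table` (a data.frame subclass).
#' @export
survey_table <- function(df, codebook = survey_codebook(), require = NULL) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df)
  if (!is.null(require)) {
    missing_cols <- setdiff(require, names(df))
    if (length(missing_cols)) {
      stop("schema error: missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  for (col in intersect(names(codebook$codes), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(v <- as.numeric(as.character(v)))
      df[[col]] <- v
    }
    bad <- which(!is.na(v) & !(v %in% codebook$codes[[col]]))
    if (length(bad)) {
      stop(sprintf(
        "validation error: field '%s' has value %s outside code set {%s} at row %d",
        col, format(v[bad[1]]), paste(codebook$codes[[col]], collapse = ","),
        bad[1]), call. = FALSE)
    }
  }
  if ("income_raw" %in% names(df)) {
    df$income_raw <- as.numeric(df$income_raw)
    neg <- which(!is.na(df$income_raw) & df$income_raw < 0)
    if (length(neg)) {
      stop(sprintf("validation error: field 'income_raw' negative at row %d",
                   neg[1]), call. = FALSE)
    }
  }
  class(df) <- c("survey_table", "data.frame")
  df
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("<survey_table> %d respondents, %d columns\n", nrow(x), ncol(x)))
  cb <- survey_codebook()
  fac <- intersect(names(cb$codes), names(x))
  cat("  coded columns:", paste(fac, collapse = ", "), "\n")
  if ("health_education" %in% names(x)) {
    r <- mean(x$health_education, na.rm = TRUE)
    cat(sprintf("  outcome rate (health_education = 1): %.2f%%\n", 100 * r))
  }
  invisible(x)
}

# Sniff the delimiter of a delimited text file from its header line.
detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
              ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

#' Read survey microdata from a delimited text file
#'
#' Reads CSV/TSV (delimiter auto-detected from the header line), validates
#' every value against the codebook, and reports the row count. Empty
#' strings and the literal `"NA"` are both treated as missing.
#'
#' @param path file path.
#' @param codebook codebook list, see [survey_codebook()].
#' @param require columns that must be present; default: outcome column.
#' @param quiet suppress the row-count message.
#' @return A `survey_table`.
#' @seealso [write_survey()]
#' @export
read_survey <- function(path, codebook = survey_codebook(),
                        require = codebook$outcome, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  out <- survey_table(df, codebook = codebook, require = require)
  if (!quiet) message(sprintf("read %d respondents from %s", nrow(out), path))
  out
}

#' Write a survey table to CSV
#'
#' @param x survey_table or data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Cleaning rule set
#'
#' Configurable rules applied by [clean_survey()]: drop rows with a missing
#' required field, drop rows with non-positive income, and drop rows whose
#' income exceeds a configurable upper quantile (a simple outlier screen).
#'
#' @param required columns that must be non-missing; `NULL` means every
#'   codebook column present in the data plus `income_raw`.
#' @param drop_nonpositive_income drop rows with `income_raw <= 0`.
#' @param income_upper_quantile rows above this quantile of `income_raw`
#'   are dropped; `1` disables the rule.
#' @return A list of class `cleaning_rules`.
#' @export
cleaning_rules <- function(required = NULL,
                           drop_nonpositive_income = TRUE,
                           income_upper_quantile = 0.999) {
  stopifnot(income_upper_quantile > 0, income_upper_quantile <= 1)
  structure(list(required = required,
                 drop_nonpositive_income = drop_nonpositive_income,
                 income_upper_quantile = income_upper_quantile),
            class = "cleaning_rules")
}

#' Clean a survey table
#'
#' Applies the [cleaning_rules()] in order (missing-field rule first, then
#' income rules) and reports how many rows each rule removed.
#'
#' @param x survey_table.
#' @param rules a [cleaning_rules()] object.
#' @return list with `table` (the cleaned `survey_table`) and `report`
#'   (named integer vector: rows dropped per rule, plus `rows_in`/`rows_out`).
#' @export
clean_survey <- function(x, rules = cleaning_rules()) {
  stopifnot(inherits(x, "survey_table") || is.data.frame(x))
  n_in <- nrow(x)
  required <- rules$required
  if (is.null(required)) {
    required <- intersect(c(names(survey_codebook()$codes), "income_raw",
                            "province"), names(x))
  }
  report <- c(missing_required = 0L, nonpositive_income = 0L,
              income_outlier = 0L)

  keep <- rep(TRUE, nrow(x))
  if (length(required)) {
    miss <- Reduce(`|`, lapply(required, function(col) is.na(x[[col]])))
    report["missing_required"] <- sum(keep & miss)
    keep <- keep & !miss
  }
  if (rules$drop_nonpositive_income && "income_raw" %in% names(x)) {
    bad <- !is.na(x$income_raw) & x$income_raw <= 0
    report["nonpositive_income"] <- sum(keep & bad)
    keep <- keep & !bad
  }
  if (rules$income_upper_quantile < 1 && "income_raw" %in% names(x)) {
    cap <- stats::quantile(x$income_raw[keep], rules$income_upper_quantile,
                           na.rm = TRUE, names = FALSE, type = 7)
    bad <- !is.na(x$income_raw) & x$income_raw > cap
    report["income_outlier"] <- sum(keep & bad)
    keep <- keep & !bad
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    stop("degenerate data: cleaning removed every row", call. = FALSE)
  }
  class(out) <- c("survey_table", "data.frame")
  report <- c(report, rows_in = n_in, rows_out = nrow(out))
  list(table = out, report = report)
}

#' Assign within-province income quintiles
#'
#' Partitions respondents into five income bands within each province, by
#' the percentile of household income: below the 20th percentile, 20th-39th,
#' 40th-59th, 60th-79th, and at or above the 80th. The percentile of a
#' respondent is the proportion of respondents in the same province with
#' income less than or equal to theirs, so tied incomes always share a band
#' and a value sitting exactly on a band boundary falls in the upper band
#' (income at exactly the 20th percentile is "20th-39th").
#'
#' @param x survey_table with `income_raw`; a `province` column groups the
#'   ranking (absent: one national group).
#' @param income_var column holding the income amount.
#' @param by grouping column, or `NULL` for a single group.
#' @return `x` with an `income_quintile` column (codes 1-5).
#' @export
assign_income_quintiles <- function(x, income_var = "income_raw",
                                    by = if ("province" %in% names(x)) "province" else NULL) {
  stopifnot(income_var %in% names(x))
  inc <- x[[income_var]]
  if (anyNA(inc)) stop("income must be non-missing to assign quintiles",
                       call. = FALSE)
  grp <- if (is.null(by)) rep(1L, nrow(x)) else x[[by]]
  q <- integer(nrow(x))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    v <- inc[idx]
    if (length(unique(v)) < 5) {
      warning(sprintf("group '%s' has fewer than 5 distinct incomes; %s",
                      format(g), "quintiles assigned by the percentile rule"),
              call. = FALSE)
    }
    # percentile = share of the group with income <= v (ties share a value)
    pct <- rank(v, ties.method = "max") / length(v) * 100
    q[idx] <- findInterval(pct, c(20, 40, 60, 80)) + 1L
  }
  x$income_quintile <- as.integer(q)
  if (inherits(x, "survey_table")) class(x) <- c("survey_table", "data.frame")
  x
}
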