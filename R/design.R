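#' Dummy-encode categorical factors into a design matrix
#'
#' Builds a 0/1 indicator matrix with an intercept column, one indicator per
#' non-reference level of each factor, factors in the order given and levels
#' in ascending code order. Column names are `<factor><code>`, matching the
#' layout of a regression table with "(reference group)" rows omitted.
#'
#' @param x survey_table or data.frame.
#' @param factors character vector of factor columns to encode.
#' @param references named vector mapping factor -> reference code; defaults
#'   to the lowest code of each factor.
#' @param intercept include a leading column of ones.
#' @return A `design_matrix`: a numeric matrix with attributes
#'   `assign` (factor name per column, `"(Intercept)"` for the intercept),
#'   `references` (the reference map), and `levels` (code per column).
#' @examples
#' tab <- data.frame(gender = c(0, 1, 1), education = c(1, 3, 5))
#' dummy_encode(tab, c("gender", "education"))
#' @export
dummy_encode <- function(x, factors,
                         references = default_references(factors),
                         intercept = TRUE) {
  stopifnot(all(factors %in% names(x)))
  cb <- survey_codebook()$codes
  cols <- list()
  assign <- character(0)
  levs <- numeric(0)
  for (f in factors) {
    codes <- if (f %in% names(cb)) cb[[f]] else sort(unique(x[[f]]))
    ref <- if (f %in% names(references)) references[[f]] else NA_real_
    if (is.na(ref)) ref <- min(codes)
    if (!(ref %in% codes)) {
      stop(sprintf("config error: reference level '%s' not in code set of '%s'",
                   format(references[[f]]), f), call. = FALSE)
    }
    nonref <- setdiff(sort(codes), ref)
    if (length(nonref) == 0L) {
      warning(sprintf("factor '%s' has a single level; no columns emitted", f),
              call. = FALSE)
      next
    }
    for (lv in nonref) {
      cols[[paste0(f, lv)]] <- as.numeric(x[[f]] == lv)
      assign <- c(assign, f)
      levs <- c(levs, lv)
    }
  }
  m <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(x), ncol = 0)
  if (intercept) {
    m <- cbind("(Intercept)" = rep(1, nrow(x)), m)
    assign <- c("(Intercept)", assign)
    levs <- c(NA_real_, levs)
  }
  structure(m, assign = assign, references = references, levels = levs,
            class = c("design_matrix", class(m)))
}

#' Non-intercept columns of a design matrix
#' @param X design_matrix.
#' @return character vector of column names excluding the intercept.
#' @export
predictor_columns <- function(X) {
  colnames(X)[attr(X, "assign") != "(Intercept)"]
}

#' Map design-matrix columns back to their factors
#' @param X design_matrix.
#' @return named character vector: column name -> factor name (intercept
#'   excluded).
#' @export
column_factor_map <- function(X) {
  keep <- attr(X, "assign") != "(Intercept)"
  stats::setNames(attr(X, "assign")[keep], colnames(X)[keep])
}
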