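#' Fit an L1-penalized logistic path
#'
#' Solves the penalized binomial likelihood over a descending log-spaced
#' lambda grid starting at the smallest lambda with an all-zero solution
#' (the intercept is never penalized). Predictors are standardized
#' internally; coefficients are reported on the original scale.
#'
#' @param X `design_matrix` (intercept column is dropped; \pkg{glmnet}
#'   supplies its own) or plain matrix.
#' @param y binary 0/1 outcome.
#' @param n_lambdas grid length.
#' @param standardize standardize predictors before penalizing.
#' @param family `"binomial"` (the default, logistic loss) or `"gaussian"`
#'   (linear least squares, used for closed-form cross-checks).
#' @param lambda_min_ratio smallest lambda as a fraction of the all-zero
#'   lambda; `NULL` keeps the \pkg{glmnet} default.
#' @param maxit solver iteration cap.
#' @return A `lasso_path`: list with `lambdas`, `coef_matrix` (rows =
#'   predictors, columns = lambdas, no intercept), `intercepts`, `fit` (the
#'   underlying \pkg{glmnet} object), `column_names`.
#' @export
fit_lasso_path <- function(X, y, n_lambdas = 100, standardize = TRUE,
                           family = "binomial", lambda_min_ratio = NULL,
                           maxit = 1e5) {
  Xm <- .lasso_matrix(X)
  if (ncol(Xm) < 1) stop("need at least one non-intercept column",
                         call. = FALSE)
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("outcome must be binary 0/1", call. = FALSE)
  }
  # glmnet requires >= 2 columns; pad single-predictor problems with an
  # all-zero column that can never enter the active set
  padded <- ncol(Xm) == 1
  if (padded) Xm <- cbind(Xm, .pad = 0)
  fit <- if (is.null(lambda_min_ratio)) {
    glmnet::glmnet(Xm, y, family = family, nlambda = n_lambdas,
                   standardize = standardize, maxit = maxit)
  } else {
    # an explicit grid: the default path stops early once the deviance
    # saturates, which would never reach the requested smallest lambda
    lmax <- max(glmnet::glmnet(Xm, y, family = family, nlambda = 5,
                               standardize = standardize)$lambda)
    grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = n_lambdas))
    glmnet::glmnet(Xm, y, family = family, lambda = grid,
                   standardize = standardize, maxit = maxit, thresh = 1e-12)
  }
  keep_rows <- if (padded) seq_len(ncol(Xm) - 1) else seq_len(ncol(Xm))
  structure(list(lambdas = fit$lambda,
                 coef_matrix = as.matrix(fit$beta)[keep_rows, , drop = FALSE],
                 intercepts = fit$a0,
                 fit = fit,
                 column_names = colnames(Xm)[keep_rows]),
            class = "lasso_path")
}

.lasso_matrix <- function(X) {
  if (inherits(X, "design_matrix")) {
    keep <- attr(X, "assign") != "(Intercept)"
    Xm <- unclass(X)[, keep, drop = FALSE]
  } else {
    Xm <- as.matrix(X)
  }
  Xm
}

#' Cross-validated lambda selection
#'
#' Stratified k-fold cross-validation of the penalized path, returning the
#' loss-minimizing lambda and the largest lambda within one standard error
#' of the minimum.
#'
#' @param X,y as in [fit_lasso_path()].
#' @param k number of folds.
#' @param seed seed for fold assignment.
#' @param loss `"deviance"` (binomial deviance) or `"mse"`.
#' @param n_lambdas,standardize passed through.
#' @return list with `lambda_min`, `lambda_1se`, `lambdas`, `cv_mean`,
#'   `cv_se`, `path` (a `lasso_path` on the full data), `foldid`.
#' @export
cv_select <- function(X, y, k = 10, seed = 1L,
                      loss = c("deviance", "mse"), n_lambdas = 100,
                      standardize = TRUE) {
  loss <- match.arg(loss)
  Xm <- .lasso_matrix(X)
  if (min(table(y)) < k) {
    stop("fold error: a class has fewer rows than folds", call. = FALSE)
  }
  set.seed(seed)
  foldid <- stratified_folds(y, k)
  measure <- if (loss == "deviance") "deviance" else "mse"
  cv <- glmnet::cv.glmnet(Xm, y, family = "binomial", foldid = foldid,
                          type.measure = measure, nlambda = n_lambdas,
                          standardize = standardize)
  path <- fit_lasso_path(Xm, y, n_lambdas = n_lambdas,
                         standardize = standardize)
  list(lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
       lambdas = cv$lambda, cv_mean = cv$cvm, cv_se = cv$cvsd,
       path = path, foldid = foldid, cv = cv)
}

#' Coefficients of a path at a given lambda
#'
#' @param path a `lasso_path`.
#' @param lambda penalty value (interpolated by \pkg{glmnet} if off-grid).
#' @return named coefficient vector (no intercept).
#' @export
path_coefficients <- function(path, lambda) {
  b <- stats::coef(path$fit, s = lambda)
  out <- stats::setNames(as.numeric(b)[-1], rownames(b)[-1])
  out[path$column_names]
}

#' Factors selected at a lambda
#'
#' A factor is selected iff any of its dummy columns has a nonzero
#' coefficient at the given lambda.
#'
#' @param path a `lasso_path`.
#' @param lambda penalty value.
#' @param grouping named vector column -> factor (see
#'   [column_factor_map()]); columns missing from it are treated as their
#'   own factor.
#' @param tol absolute threshold below which a coefficient counts as zero.
#' @return character vector of selected factor names, in grouping order.
#' @export
selected_factors <- function(path, lambda, grouping = NULL, tol = 0) {
  b <- path_coefficients(path, lambda)
  nz <- names(b)[abs(b) > tol]
  if (is.null(grouping)) {
    grouping <- stats::setNames(sub("[0-9]+$", "", path$column_names),
                                path$column_names)
  }
  fac <- grouping[nz]
  fac[is.na(fac)] <- nz[is.na(fac)]
  unique(unname(grouping))[unique(unname(grouping)) %in% fac]
}
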