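#' Weighted fractional income ranks
#'
#' Computes each respondent's fractional rank in the income distribution:
#' after a stable sort by income, the rank of respondent i is the cumulative
#' weight of everyone strictly poorer plus half their own weight, divided by
#' total weight. Tied incomes share the midpoint of their tied block. With
#' unit weights the weighted mean rank is exactly 0.5 by construction.
#'
#' @param income numeric vector of (finite) income values.
#' @param weights positive weights, default all one.
#' @return A `rank_vector`: list with `r` (ranks in (0,1), in input order)
#'   and `weights`.
#' @examples
#' fractional_rank(c(10, 20, 30))$r   # 1/6, 3/6, 5/6
#' @export
fractional_rank <- function(income, weights = NULL) {
  n <- length(income)
  if (n == 0L) stop("empty income vector", call. = FALSE)
  if (any(!is.finite(income))) stop("income must be finite", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  ord <- order(income)                      # stable in R
  w <- weights[ord]
  W <- sum(w)
  cum_before <- cumsum(w) - w
  r_sorted <- (cum_before + w / 2) / W
  # tied incomes share the weighted mean rank of their tied block
  inc_sorted <- income[ord]
  blocks <- cumsum(!duplicated(inc_sorted))
  r_sorted <- as.numeric(tapply(r_sorted * w, blocks, sum)[blocks] /
                           tapply(w, blocks, sum)[blocks])
  r <- numeric(n)
  r[ord] <- r_sorted
  structure(list(r = r, weights = weights), class = "rank_vector")
}

# weighted population mean / covariance (divide by total weight, not n-1)
.wmean <- function(x, w) sum(x * w) / sum(w)
.wcov <- function(x, y, w) {
  mx <- .wmean(x, w); my <- .wmean(y, w)
  sum(w * (x - mx) * (y - my)) / sum(w)
}

#' Concentration index of an outcome over income ranks
#'
#' The income-related concentration index `CI = 2 cov(y, r) / mu`, with `r`
#' the fractional income rank and `mu` the mean outcome; the covariance is
#' the population (divide-by-n) form. `CI > 0` indicates pro-rich
#' concentration of the outcome, `CI < 0` pro-poor.
#'
#' @param y numeric outcome vector (binary or continuous, `mean(y) > 0`).
#' @param ranks a [fractional_rank()] object, or a raw income vector from
#'   which ranks are computed.
#' @return A `concentration_result`: list with `ci`, `mu`, `direction`,
#'   and `curve` (the concentration-curve points, see
#'   [concentration_curve_points()]).
#' @examples
#' r <- fractional_rank(1:4)
#' concentration_index(c(0, 0, 1, 1), r)$ci   # 0.5
#' @export
concentration_index <- function(y, ranks) {
  if (!inherits(ranks, "rank_vector")) ranks <- fractional_rank(ranks)
  stopifnot(length(y) == length(ranks$r))
  w <- ranks$weights
  mu <- .wmean(y, w)
  if (mu == 0) stop("undefined index: outcome mean is zero", call. = FALSE)
  ci <- 2 * .wcov(y, ranks$r, w) / mu
  structure(list(ci = ci, mu = mu,
                 direction = if (ci > 0) "pro-rich" else if (ci < 0)
                   "pro-poor" else "neutral",
                 curve = concentration_curve_points(y, ranks)),
            class = "concentration_result")
}

#' @export
print.concentration_result <- function(x, ...) {
  cat(sprintf("Concentration index: %.6f (%s), outcome mean %.4f\n",
              x$ci, x$direction, x$mu))
  invisible(x)
}

#' Concentration-curve points
#'
#' Cumulative outcome share against cumulative population share, stepping
#' through respondents from poorest to richest. Starts at (0,0), ends at
#' (1,1); the curve lies below the diagonal when the index is positive.
#'
#' @inheritParams concentration_index
#' @return data.frame with columns `pop_share` and `outcome_share`.
#' @export
concentration_curve_points <- function(y, ranks) {
  if (!inherits(ranks, "rank_vector")) ranks <- fractional_rank(ranks)
  stopifnot(length(y) == length(ranks$r))
  ord <- order(ranks$r)
  w <- ranks$weights[ord]
  ys <- y[ord]
  data.frame(pop_share = c(0, cumsum(w) / sum(w)),
             outcome_share = c(0, cumsum(ys * w) / sum(ys * w)))
}

#' Plot a concentration curve
#'
#' @param x a `concentration_result`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.concentration_result <- function(x, ...) {
  graphics::plot(x$curve$pop_share, x$curve$outcome_share, type = "l",
                 xlab = "cumulative population share (poorest to richest)",
                 ylab = "cumulative outcome share", ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  invisible(x)
}

# Signed area between the diagonal and the curve, times two; equals the
# concentration index up to O(1/n) discreteness. Trapezoidal integration.
curve_area_index <- function(curve) {
  xs <- curve$pop_share; ys <- curve$outcome_share
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  2 * (0.5 - auc)
}

#' Wagstaff decomposition of the concentration index
#'
#' Decomposes the outcome concentration index into per-determinant
#' contributions: for each non-reference dummy column j,
#' `contribution_j = elasticity_j * C_j`, where
#' `elasticity_j = AME_j * mean(x_j) / mu` (the logit model's average
#' marginal effect standing in for the linear regression coefficient) and
#' `C_j` is the concentration index of the column over the same income
#' ranks. The residual term closes the identity
#' `C = sum_j contribution_j + residual`.
#'
#' @param fit a [fit_logit()] fit on `X`.
#' @param X the `design_matrix` the model was fitted on.
#' @param ranks a [fractional_rank()] over the same respondents.
#' @param y the outcome vector.
#' @return A `decomposition_table`: data.frame with one row per dummy column
#'   (`column`, `factor`, `mean`, `ame`, `elasticity`, `factor_ci`,
#'   `contribution`, `contribution_rate`), with attributes `ci` (total
#'   index), `mu`, and `residual_term`.
#' @export
wagstaff_decompose <- function(fit, X, ranks, y) {
  stopifnot(inherits(fit, "logit_fit"))
  if (!inherits(ranks, "rank_vector")) ranks <- fractional_rank(ranks)
  cols <- predictor_columns(X)
  stopifnot(all(cols %in% names(fit$beta)))
  total <- concentration_index(y, ranks)
  mu <- total$mu
  ame <- average_marginal_effects(fit, X)
  w <- ranks$weights

  rows <- lapply(cols, function(j) {
    xj <- X[, j]
    mj <- .wmean(xj, w)
    if (mj == 0) {
      return(data.frame(column = j, factor = column_factor_map(X)[[j]],
                        mean = 0, ame = ame[[j]], elasticity = 0,
                        factor_ci = NA_real_, contribution = 0,
                        flagged = TRUE))
    }
    cj <- 2 * .wcov(xj, ranks$r, w) / mj
    el <- ame[[j]] * mj / mu
    data.frame(column = j, factor = column_factor_map(X)[[j]], mean = mj,
               ame = ame[[j]], elasticity = el, factor_ci = cj,
               contribution = el * cj, flagged = FALSE)
  })
  tab <- do.call(rbind, rows)
  residual <- total$ci - sum(tab$contribution)
  tab$contribution_rate <- tab$contribution / total$ci * 100
  structure(tab, ci = total$ci, mu = mu, residual_term = residual,
            class = c("decomposition_table", "data.frame"))
}

#' @export
print.decomposition_table <- function(x, digits = 4, ...) {
  cat(sprintf("Concentration index decomposition: C = %.6f (mu = %.4f)\n",
              attr(x, "ci"), attr(x, "mu")))
  df <- as.data.frame(x)
  df$mean <- round(df$mean, digits); df$ame <- round(df$ame, digits)
  df$elasticity <- round(df$elasticity, digits)
  df$factor_ci <- round(df$factor_ci, digits)
  df$contribution <- round(df$contribution, digits)
  df$contribution_rate <- round(df$contribution_rate, 3)
  print(df[, c("column", "elasticity", "factor_ci", "contribution",
               "contribution_rate")], row.names = FALSE)
  cat(sprintf("residual term (unexplained): %.6f\n", attr(x, "residual_term")))
  invisible(x)
}
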