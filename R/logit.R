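#' Fit a binary logistic regression
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares,
#' with Wald standard errors from the observed information. Collinear
#' columns and (quasi-)complete separation are detected and raised as
#' errors rather than silently returning unstable estimates.
#'
#' @param X `design_matrix` (with intercept column) or numeric matrix.
#' @param y binary 0/1 outcome.
#' @param tol IRLS convergence tolerance.
#' @return A `logit_fit`: list with `beta`, `se`, `z`, `p_value`, `or_`
#'   (`exp(beta)`), `ci95` (matrix of `exp(beta +/- 1.96 se)`), `mu_hat`,
#'   `fitted`, `loglik`, `n`, `converged`, `X_attrs` (design-matrix
#'   attributes for table layout).
#' @export
fit_logit <- function(X, y, tol = 1e-10) {
  Xm <- if (inherits(X, "design_matrix")) unclass(X) else as.matrix(X)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  qr_x <- qr(Xm)
  if (qr_x$rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qr_x$pivot[(qr_x$rank + 1):ncol(Xm)]]
    stop("collinear design: column(s) ", paste(dropped, collapse = ", "),
         " are linearly dependent", call. = FALSE)
  }
  has_icpt <- "(Intercept)" %in% colnames(Xm)
  fml <- if (has_icpt) y ~ . - 1 else y ~ . - 1   # intercept already a column
  dat <- as.data.frame(Xm)
  dat$y <- y
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = tol, maxit = 100)))
  beta <- stats::coef(fit)
  names(beta) <- colnames(Xm)
  mu <- stats::fitted(fit)
  if (any(mu < 1e-10 | mu > 1 - 1e-10) && max(abs(beta)) > 15) {
    stop("separation detected: fitted probabilities numerically 0 or 1",
         call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- colnames(Xm)
  z <- beta / se
  ci95 <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  structure(list(beta = beta, se = se, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 or_ = exp(beta), ci95 = ci95,
                 mu_hat = mean(mu), fitted = mu,
                 loglik = as.numeric(stats::logLik(fit)),
                 n = length(y), converged = fit$converged,
                 X_attrs = if (inherits(X, "design_matrix"))
                   attributes(X)[c("assign", "references", "levels")]
                 else NULL,
                 glm = fit),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> n = %d, loglik = %.2f, mean fitted = %.4f\n",
              x$n, x$loglik, x$mu_hat))
  print(round(data.frame(beta = x$beta, se = x$se, p = x$p_value,
                         OR = x$or_), 4))
  invisible(x)
}

#' Odds-ratio table in regression-report layout
#'
#' One row per dummy level with beta, p, OR and 95% CI, plus annotated
#' "(reference group)" rows for each factor, in the order the factors enter
#' the design matrix.
#'
#' @param fit a [fit_logit()] result fitted on a `design_matrix`.
#' @param digits rounding for display columns (`NULL` keeps full precision).
#' @return data.frame with `factor`, `level`, `reference`, `beta`, `p`,
#'   `or`, `ci_lower`, `ci_upper`.
#' @export
odds_ratio_table <- function(fit, digits = 3) {
  stopifnot(inherits(fit, "logit_fit"))
  at <- fit$X_attrs
  if (is.null(at)) stop("fit was not made from a design_matrix", call. = FALSE)
  labs <- survey_codebook()$labels
  rows <- list()
  for (f in unique(at$assign[at$assign != "(Intercept)"])) {
    ref <- at$references[[f]]
    ref_lab <- if (f %in% names(labs)) {
      codes <- survey_codebook()$codes[[f]]
      labs[[f]][match(ref, codes)]
    } else as.character(ref)
    rows[[length(rows) + 1]] <- data.frame(
      factor = f, level = ref_lab, reference = TRUE, beta = NA_real_,
      p = NA_real_, or = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_)
    for (i in which(at$assign == f)) {
      nm <- names(fit$beta)[i]
      lv <- at$levels[i]
      lab <- if (f %in% names(labs)) {
        codes <- survey_codebook()$codes[[f]]
        labs[[f]][match(lv, codes)]
      } else as.character(lv)
      rows[[length(rows) + 1]] <- data.frame(
        factor = f, level = lab, reference = FALSE, beta = fit$beta[[nm]],
        p = fit$p_value[[nm]], or = fit$or_[[nm]],
        ci_lower = fit$ci95[nm, "lower"], ci_upper = fit$ci95[nm, "upper"])
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    for (col in c("beta", "or", "ci_lower", "ci_upper")) {
      out[[col]] <- round(out[[col]], digits)
    }
  }
  rownames(out) <- NULL
  out
}

#' Average marginal effects on the probability scale
#'
#' For each 0/1 dummy column j, the discrete-change AME: the mean over
#' respondents of `p_hat(x with x_j = 1) - p_hat(x with x_j = 0)` (other
#' columns held at observed values). Columns that are not 0/1 indicators
#' use the density approximation `mean(p_hat (1 - p_hat)) * beta_j`.
#'
#' @param fit a [fit_logit()] result.
#' @param X the design matrix the model was fitted on.
#' @return named numeric vector of AMEs for each non-intercept column.
#' @export
average_marginal_effects <- function(fit, X) {
  stopifnot(inherits(fit, "logit_fit"))
  Xm <- if (inherits(X, "design_matrix")) unclass(X) else as.matrix(X)
  beta <- fit$beta
  stopifnot(identical(colnames(Xm), names(beta)))
  eta <- as.numeric(Xm %*% beta)
  cols <- setdiff(colnames(Xm), "(Intercept)")
  ame <- vapply(cols, function(j) {
    xj <- Xm[, j]
    bj <- beta[[j]]
    if (all(xj %in% c(0, 1))) {
      eta0 <- eta - xj * bj           # column forced to 0
      mean(stats::plogis(eta0 + bj) - stats::plogis(eta0))
    } else {
      d <- stats::plogis(eta)
      mean(d * (1 - d)) * bj
    }
  }, numeric(1))
  ame
}
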