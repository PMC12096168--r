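test_that("all penalized coefficients are zero at the top of the path", {
  sim <- simulate_survey(generator_config(n = 800, seed = 41))
  X <- dummy_encode(sim$table, c("education", "gender", "health_record"))
  path <- fit_lasso_path(X, sim$table$health_education)
  expect_true(all(path$coef_matrix[, 1] == 0))
  # and at any lambda above it
  expect_true(all(path_coefficients(path, max(path$lambdas) * 2) == 0))
})

test_that("a single standardized predictor follows the soft-threshold form", {
  set.seed(6)
  n <- 200
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))   # population-sd scale
  y <- 0.7 * x + rnorm(n, sd = 0.5)
  y <- y - mean(y)
  y <- y / sqrt(mean(y^2))   # unit population variance, so the reported
                             # lambdas are on the same scale as cov(x, y)
  path <- fit_lasso_path(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y,
                         family = "gaussian", standardize = FALSE,
                         lambda_min_ratio = 1e-3)
  rho <- mean(x * y)
  soft <- function(z, l) sign(z) * pmax(abs(z) - l, 0)
  for (l in path$lambdas[c(5, 20, 50, 80)]) {
    expect_equal(unname(path_coefficients(path, l)[["x"]]), soft(rho, l),
                 tolerance = 1e-6)
  }
})

test_that("the path approaches the unpenalized logistic fit as lambda -> 0", {
  sim <- simulate_survey(generator_config(n = 3000, seed = 43))
  X <- dummy_encode(sim$table, c("education", "health_record", "gender"))
  y <- sim$table$health_education
  path <- fit_lasso_path(X, y, lambda_min_ratio = 1e-7)
  mle <- fit_logit(X, y)
  b_path <- path_coefficients(path, min(path$lambdas))
  expect_equal(unname(b_path), unname(mle$beta[names(b_path)]),
               tolerance = 1e-3)
})

test_that("cross-validation is deterministic and returns aligned curves", {
  sim <- simulate_survey(generator_config(n = 1200, seed = 44))
  X <- dummy_encode(sim$table, c("education", "gender"))
  y <- sim$table$health_education
  a <- cv_select(X, y, k = 5, seed = 10)
  b <- cv_select(X, y, k = 5, seed = 10)
  expect_identical(a$foldid, b$foldid)
  expect_equal(a$cv_mean, b$cv_mean)
  expect_length(a$cv_mean, length(a$lambdas))
  expect_gte(a$lambda_1se, a$lambda_min)
  expect_error(cv_select(X, c(rep(0, 3), rep(1, length(y) - 3)), k = 10),
               "fold error")
})

test_that("factor selection groups dummy columns", {
  sim <- simulate_survey(generator_config(n = 800, seed = 45))
  X <- dummy_encode(sim$table, c("education", "gender", "health_record"))
  path <- fit_lasso_path(X, sim$table$health_education)
  grouping <- column_factor_map(X)
  # all-zero solution selects nothing
  expect_length(selected_factors(path, max(path$lambdas), grouping), 0)
  # any nonzero education dummy selects "education" once
  sel <- selected_factors(path, min(path$lambdas), grouping)
  b <- path_coefficients(path, min(path$lambdas))
  for (f in unique(grouping)) {
    any_nz <- any(b[names(grouping)[grouping == f]] != 0)
    expect_equal(f %in% sel, any_nz, label = f)
  }
  expect_false(anyDuplicated(sel) > 0)
})

test_that("zero patterns are monotone along the path on orthogonal designs", {
  set.seed(12)
  n <- 256
  # orthogonal +/-1 design (Hadamard-like columns)
  X <- cbind(a = rep(c(1, -1), each = n / 2),
             b = rep(c(1, -1), times = n / 2),
             c = rep(c(1, -1, -1, 1), times = n / 4))
  y <- X %*% c(1.5, 0.8, 0.2) + rnorm(n, sd = 0.3)
  path <- fit_lasso_path(X, as.numeric(y), family = "gaussian",
                         standardize = FALSE)
  nnz <- colSums(abs(path$coef_matrix) > 1e-10)
  expect_true(all(diff(nnz) >= 0))  # lambdas descend along the path
})
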