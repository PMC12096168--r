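test_that("fractional ranks follow the midpoint construction", {
  expect_equal(fractional_rank(c(10, 20, 30))$r, c(1, 3, 5) / 6)
  expect_equal(fractional_rank(rep(5, 8))$r, rep(0.5, 8))
  # weighted mean rank is 0.5 by construction
  set.seed(61)
  w <- runif(50, 0.5, 2)
  rv <- fractional_rank(rnorm(50), w)
  expect_equal(sum(rv$r * w) / sum(w), 0.5, tolerance = 1e-12)

  # brute-force sort-based oracle, with ties
  set.seed(62)
  inc <- sample(round(rlnorm(200, 10, 1), -2))  # rounding forces ties
  r <- fractional_rank(inc)$r
  n <- length(inc)
  oracle <- vapply(seq_len(n), function(i) {
    below <- sum(inc < inc[i])
    tied <- sum(inc == inc[i])
    (below + tied / 2) / n
  }, numeric(1))
  expect_equal(r, oracle, tolerance = 1e-12)
  expect_error(fractional_rank(numeric(0)), "empty")
})

test_that("the concentration index matches its covariance definition", {
  r4 <- fractional_rank(1:4)
  expect_equal(r4$r, c(1, 3, 5, 7) / 8)
  res <- concentration_index(c(0, 0, 1, 1), r4)
  expect_equal(res$ci, 0.5)
  expect_equal(res$direction, "pro-rich")

  # constant outcome: zero covariance
  expect_equal(concentration_index(rep(1, 10), fractional_rank(1:10))$ci, 0)

  # outcome anti-sorted against income: pro-poor sign
  inc <- 1:50
  y <- as.numeric(inc <= 25)
  expect_lt(concentration_index(y, fractional_rank(inc))$ci, 0)

  expect_error(concentration_index(rep(0, 5), fractional_rank(1:5)),
               "undefined index")
})

test_that("index is invariant to income rescaling and weight scaling", {
  set.seed(63)
  inc <- rlnorm(300, 10, 0.8)
  y <- rbinom(300, 1, plogis(scale(log(inc))[, 1]))
  ci0 <- concentration_index(y, fractional_rank(inc))$ci
  expect_equal(concentration_index(y, fractional_rank(inc * 7.3))$ci, ci0)
  expect_equal(concentration_index(y, fractional_rank(log(inc)))$ci, ci0)
  w <- rep(2.5, 300)
  expect_equal(concentration_index(y, fractional_rank(inc, w))$ci, ci0)
})

test_that("binary-outcome index respects the 1 - mu bound", {
  set.seed(64)
  inc <- rlnorm(2000, 10, 0.7)
  for (mu in seq(0.1, 0.9, by = 0.1)) {
    y <- rbinom(2000, 1, plogis(qlogis(mu) + 0.8 * scale(log(inc))[, 1]))
    if (mean(y) == 0) next
    res <- concentration_index(y, fractional_rank(inc))
    expect_lte(abs(res$ci), 1 - res$mu + 1e-12)
    expect_gt(res$ci, -1); expect_lt(res$ci, 1)
  }
})

test_that("the concentration curve ties out with the index", {
  # constant outcome: the curve is the diagonal
  curve <- concentration_curve_points(rep(1, 20), fractional_rank(1:20))
  expect_equal(curve$outcome_share, curve$pop_share, tolerance = 1e-12)
  expect_equal(curve$pop_share[1], 0)
  expect_equal(curve$outcome_share[nrow(curve)], 1)

  # outcome concentrated in top ranks: strictly below the diagonal inside
  y <- as.numeric(1:100 > 60)
  curve <- concentration_curve_points(y, fractional_rank(1:100))
  interior <- curve$pop_share > 0 & curve$pop_share < 1
  expect_true(all(curve$outcome_share[interior] <
                    curve$pop_share[interior]))

  # twice the signed area between diagonal and curve approximates the index
  set.seed(65)
  inc <- rlnorm(10000, 10, 0.6)
  y <- rbinom(10000, 1, plogis(1 + 0.5 * scale(log(inc))[, 1]))
  res <- concentration_index(y, fractional_rank(inc))
  expect_equal(healthequity:::curve_area_index(res$curve), res$ci,
               tolerance = 1e-3 / abs(res$ci))
})

test_that("the decomposition identity closes and attributes truthfully", {
  sim <- simulate_survey(generator_config(n = 4000, seed = 66,
                                          income_by_education = 0.15))
  tab <- sim$table
  X <- dummy_encode(tab, c("income_quintile", "education", "gender"))
  y <- tab$health_education
  fit <- fit_logit(X, y)
  ranks <- fractional_rank(tab$income_raw)
  dec <- wagstaff_decompose(fit, X, ranks, y)
  expect_equal(sum(dec$contribution) + attr(dec, "residual_term"),
               attr(dec, "ci"), tolerance = 1e-12)
  expect_equal(sum(dec$contribution_rate),
               100 * (1 - attr(dec, "residual_term") / attr(dec, "ci")),
               tolerance = 1e-8)
  # income-quintile dummies have factor CIs ordered with affluence
  inc_rows <- dec[dec$factor == "income_quintile", ]
  expect_true(all(diff(inc_rows$factor_ci) > 0))

  # null case: outcome independent of income and covariates
  zero <- table5_coefficients() * 0
  null_sim <- simulate_survey(generator_config(n = 20000, true_beta = zero,
                                               beta0 = 0, seed = 67))
  ntab <- null_sim$table
  Xn <- dummy_encode(ntab, c("income_quintile", "gender"))
  yn <- ntab$health_education
  fitn <- fit_logit(Xn, yn)
  rn <- fractional_rank(ntab$income_raw)
  decn <- wagstaff_decompose(fitn, Xn, rn, yn)
  expect_lt(abs(attr(decn, "ci")), 4 / sqrt(20000))
  expect_true(all(abs(decn$contribution) < 4 / sqrt(20000)))
})
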