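test_that("survey files round-trip through write and read", {
  tab <- survey_table(tiny_survey())
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(tab, path)
  back <- read_survey(path, quiet = TRUE)
  expect_equal(nrow(back), 3)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  # larger, generator-written file loads with identical values
  sim <- simulate_survey(generator_config(n = 1000, seed = 11))
  write_survey(sim$table, path)
  back <- read_survey(path, quiet = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(sim$table))

  # tab-delimited files are auto-detected
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tiny_survey(), tsv, sep = "\t", row.names = FALSE)
  expect_equal(nrow(read_survey(tsv, quiet = TRUE)), 3)
})

test_that("out-of-code values and missing columns are rejected with location", {
  bad <- tiny_survey()
  bad$gender[2] <- 7
  expect_error(survey_table(bad), "gender.*row 2")
  expect_error(survey_table(tiny_survey()[, -1], require = "gender"),
               "missing column")
  neg <- tiny_survey(); neg$income_raw[3] <- -5
  expect_error(survey_table(neg), "income_raw.*row 3")
})

test_that("cleaning drops exactly the rows its rules name and counts them", {
  tab <- survey_table(tiny_survey())
  out <- clean_survey(tab, cleaning_rules(income_upper_quantile = 1))
  expect_equal(nrow(out$table), 3)
  expect_equal(unname(out$report[c("missing_required", "nonpositive_income",
                                   "income_outlier")]), c(0L, 0L, 0L))

  tab10 <- tiny_survey()[rep(1:3, length.out = 10), ]
  tab10$health_education[c(2, 5, 9)] <- NA
  out <- clean_survey(survey_table(tab10),
                      cleaning_rules(income_upper_quantile = 1))
  expect_equal(nrow(out$table), 7)
  expect_equal(unname(out$report[["missing_required"]]), 3L)

  # seeded 5% random masking: retained count equals a brute-force row scan
  sim <- simulate_survey(generator_config(n = 1000, seed = 21))
  tab <- as.data.frame(sim$table)
  set.seed(99)
  required <- setdiff(names(tab), "province")
  for (col in required) {
    tab[[col]][stats::runif(1000) < 0.05] <- NA
  }
  full_rows <- sum(stats::complete.cases(tab[required]))
  out <- clean_survey(survey_table(tab),
                      cleaning_rules(income_upper_quantile = 1))
  expect_equal(nrow(out$table), full_rows)

  all_na <- tiny_survey(); all_na$health_education <- NA
  expect_error(clean_survey(survey_table(all_na)), "degenerate")
})

test_that("income quintiles follow the within-province percentile bands", {
  one <- data.frame(province = "P", income_raw = 1:100)
  q <- assign_income_quintiles(one)$income_quintile
  expect_equal(q[1:19], rep(1L, 19))
  expect_equal(q[20:39], rep(2L, 20))
  expect_equal(q[40:59], rep(3L, 20))
  expect_equal(q[60:79], rep(4L, 20))
  expect_equal(q[80:100], rep(5L, 21))

  # degenerate ties: one band for everyone, with a warning
  same <- data.frame(province = "P", income_raw = rep(7, 10))
  expect_warning(q <- assign_income_quintiles(same)$income_quintile,
                 "distinct incomes")
  expect_equal(length(unique(q)), 1L)

  # two shifted provinces against an independent per-province sort-and-cut
  set.seed(5)
  two <- data.frame(province = rep(c("A", "B"), each = 200),
                    income_raw = c(rlnorm(200, 10, 0.5),
                                   rlnorm(200, 11, 0.5)))
  q <- assign_income_quintiles(two)$income_quintile
  oracle <- integer(400)
  for (p in c("A", "B")) {
    idx <- which(two$province == p)
    v <- two$income_raw[idx]
    for (i in seq_along(idx)) {
      pct <- sum(v <= v[i]) / length(v) * 100
      oracle[idx[i]] <-
        if (pct < 20) 1L else if (pct < 40) 2L else if (pct < 60) 3L
        else if (pct < 80) 4L else 5L
    }
  }
  expect_equal(q, oracle)

  # invariant to monotone transforms of income within a province
  two$income_raw <- exp(two$income_raw / 1e5) * 3
  expect_equal(assign_income_quintiles(two)$income_quintile, oracle)
})

test_that("dummy encoding has one indicator per non-reference level", {
  tab <- survey_table(tiny_survey())
  X <- dummy_encode(tab, c("gender", "education"))
  expect_equal(colnames(X), c("(Intercept)", "gender1", paste0("education",
                                                               2:5)))
  expect_true(all(X[, "(Intercept)"] == 1))

  # the seven-factor model layout: 17 non-intercept columns
  tab <- assign_income_quintiles(tab)
  seven <- c("income_quintile", "age_group", "education", "health_record",
             "mobility_range", "mobility_reason", "gender")
  X <- dummy_encode(tab, seven)
  expect_equal(length(predictor_columns(X)), 17)
  expect_equal(unname(attr(X, "references")[seven]), c(1, 1, 1, 0, 1, 1, 0))

  # per factor per row, indicators sum to 1 - [row is reference]
  for (f in seven) {
    block <- X[, attr(X, "assign") == f, drop = FALSE]
    is_ref <- tab[[f]] == attr(X, "references")[[f]]
    expect_equal(rowSums(block), as.numeric(!is_ref))
  }

  expect_error(dummy_encode(tab, "gender", references = c(gender = 9)),
               "config error")
  onelev <- data.frame(z = rep(1, 3))
  expect_warning(X1 <- dummy_encode(onelev, "z"), "single level")
  expect_equal(length(predictor_columns(X1)), 0)
})
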