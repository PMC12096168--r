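# Small in-code fixtures shared across test files.

# A tiny fully valid respondent table (3 rows).
tiny_survey <- function() {
  data.frame(
    gender = c(0, 1, 1), age_group = c(1, 2, 4), education = c(3, 5, 1),
    marital = c(0, 1, 1), working = c(1, 1, 0), hukou = c(1, 2, 1),
    mobility_range = c(3, 2, 1), mobility_reason = c(2, 2, 1),
    insurance_location = c(1, 2, 1), sick = c(0, 0, 1),
    health_level = c(3, 3, 1), health_record = c(0, 1, 0),
    family_doctor = c(0, 0, 1), province = c("PA", "PA", "PB"),
    income_raw = c(30000, 85000, 12000), health_education = c(1, 1, 0))
}

# Expand printed level-by-outcome counts into respondent rows.
counts_to_rows <- function(counts) {
  levs <- suppressWarnings(as.numeric(rownames(counts)))
  if (length(levs) == 0 || anyNA(levs)) levs <- seq_len(nrow(counts))
  f <- rep(rep(levs, 2), times = as.vector(counts))
  y <- rep(rep(c(0, 1), each = nrow(counts)), times = as.vector(counts))
  data.frame(f = f, y = y)
}

# Independent brute-force Pearson statistic from a counts matrix.
brute_chi2 <- function(counts) {
  n <- sum(counts)
  E <- outer(rowSums(counts), colSums(counts)) / n
  sum((counts - E)^2 / E)
}
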