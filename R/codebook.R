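#' Survey codebook
#'
#' The coding scheme for the respondent-level microdata used throughout the
#' package. Each categorical variable carries a fixed set of integer codes;
#' `income_raw` is a non-negative currency amount and `province` is a free
#' categorical label. `income_quintile` is derived within province from
#' `income_raw` (see [assign_income_quintiles()]).
#'
#' @return A list with components:
#'   \describe{
#'     \item{codes}{named list mapping each categorical column to its set of
#'       valid integer codes.}
#'     \item{labels}{named list of human-readable level labels, parallel to
#'       `codes`.}
#'     \item{outcome}{name of the binary outcome column
#'       (`"health_education"`).}
#'     \item{numeric}{columns that are numeric rather than coded
#'       (`"income_raw"`).}
#'     \item{id_like}{columns that are labels, not codes (`"province"`).}
#'   }
#' @examples
#' cb <- survey_codebook()
#' cb$codes$gender
#' @export
survey_codebook <- function() {
  codes <- list(
    gender             = 0:1,
    age_group          = 1:4,
    education          = 1:5,
    marital            = 0:1,
    working            = 0:1,
    hukou              = 1:2,
    mobility_range     = 1:3,
    mobility_reason    = 1:3,
    income_quintile    = 1:5,
    insurance_location = 1:2,
    sick               = 0:1,
    health_level       = 1:3,
    health_record      = 0:1,
    family_doctor      = 0:1,
    health_education   = 0:1
  )
  labels <- list(
    gender             = c("female", "male"),
    age_group          = c("15-30", "31-45", "46-60", ">=61"),
    education          = c("illiterate", "elementary", "middle school",
                           "high school", "university+"),
    marital            = c("not in marriage", "in marriage"),
    working            = c("no occupation", "employed"),
    hukou              = c("rural", "urban"),
    mobility_range     = c("cross-county", "cross-city", "cross-province"),
    mobility_reason    = c("family", "work", "other"),
    income_quintile    = c("lowest (<20%)", "lower (20-39%)",
                           "medium (40-59%)", "higher (60-79%)",
                           "highest (>=80%)"),
    insurance_location = c("domicile", "inflow"),
    sick               = c("no", "yes"),
    health_level       = c("unhealthy", "basically healthy", "healthy"),
    health_record      = c("no", "yes"),
    family_doctor      = c("no", "yes"),
    health_education   = c("no", "yes")
  )
  list(
    codes   = codes,
    labels  = labels,
    outcome = "health_education",
    numeric = "income_raw",
    id_like = "province"
  )
}

# Categorical covariates in the canonical (reporting) order; the outcome is
# excluded. income_quintile is listed where the income ranking enters models.
covariate_factors <- function() {
  c("gender", "age_group", "education", "marital", "working", "hukou",
    "mobility_range", "mobility_reason", "income_quintile",
    "insurance_location", "sick", "health_level", "health_record",
    "family_doctor")
}

# Default reference level per factor: the lowest code, which matches the
# "(reference group)" rows of the regression table layout. Factors outside
# the codebook get NA here and fall back to their lowest observed level.
default_references <- function(factors = covariate_factors()) {
  cb <- survey_codebook()$codes
  stats::setNames(
    vapply(factors,
           function(f) if (f %in% names(cb)) min(cb[[f]]) else NA_real_,
           numeric(1)),
    factors)
}
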