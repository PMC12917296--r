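#' @import data.table
#' @importFrom stats plogis qnorm pnorm runif rbinom quantile binomial coef
#'   glm pchisq predict model.matrix reformulate as.formula setNames
#'   complete.cases fitted sd vcov qnorm
#' @importFrom utils head
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".SD", "patient_id", "day", "atc", "days_supplied", "start",
  "end", "episode", "pos", "runout", "index_day", "horizon", "year",
  "adherence", "covered", "persistence_days", "index_class", "eligible",
  "study_class", "gap_after", "next_start", "J", "date", "high"
))

# internal: Date -> integer day count (days since 1970-01-01)
.day <- function(d) as.integer(as.Date(d))

# internal: integer day -> Date
.as_date <- function(x) as.Date(x, origin = "1970-01-01")

# age in whole years at `at` for someone born `birth`
age_at <- function(birth, at) {
  as.integer(floor(as.numeric(.day(at) - .day(birth)) / 365.25))
}
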