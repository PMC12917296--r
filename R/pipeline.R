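#' Run the full trajectory-analysis pipeline
#'
#' Convenience wrapper chaining cohort construction, exclusions, baseline
#' flags, coverage reconstruction, pattern classification, follow-up
#' termination and adherence profiling, in that order.
#'
#' @inheritParams identify_new_users
#' @return list with `cohort` (entries with strata, flags and follow-up),
#'   `coverage`, `patterns`, `adherence` (yearly profiles), and
#'   `attrition`.
#' @export
run_pipeline <- function(records, patients, vocab = atc_vocabulary(),
                         config = cohort_config()) {
  entries <- identify_new_users(records, patients, vocab, config)
  entries <- apply_exclusions(entries, records, vocab, config)
  entries <- baseline_flags(entries, records, vocab, config)
  coverage <- coverage_all(entries, records, vocab, config)
  patterns <- classify_patterns_all(entries, records, vocab, config, coverage)
  entries <- determine_followup_end(entries, records, vocab, config,
                                    patterns, coverage)
  adherence <- adherence_profiles(entries, coverage, patterns, config)
  list(cohort = entries, coverage = coverage, patterns = patterns,
       adherence = adherence, attrition = attr(entries, "attrition"))
}

#' Assemble the year-1 risk-model frame
#'
#' Joins the cohort entries, the year-1 binary adherence level and the
#' pattern flags into one modelling frame with the study's reference
#' levels applied (see [prepare_model_data()]). Restricted to
#' pattern-eligible patients (on the original monotherapy beyond 1 year).
#'
#' @param pipeline output of [run_pipeline()].
#' @return a `data.frame`, one row per eligible patient, with
#'   `adherence_level` (`low`/`high` in year 1), the four pattern flags and
#'   all entry covariates.
#' @export
model_frame_year1 <- function(pipeline) {
  ent <- pipeline$cohort
  pat <- pipeline$patterns
  adh1 <- pipeline$adherence[pipeline$adherence$year == 1, , drop = FALSE]
  keep <- pat$eligible[match(ent$patient_id, pat$patient_id)]
  df <- ent[keep, , drop = FALSE]
  m <- match(df$patient_id, adh1$patient_id)
  df$adherence_year1 <- adh1$adherence[m]
  df$adherence_level <- ifelse(adh1$high[m], "high", "low")
  pm <- match(df$patient_id, pat$patient_id)
  for (col in c("continuation", "discontinuation", "switch", "add_on")) {
    df[[col]] <- pat[[col]][pm]
  }
  df$high_adherence <- df$adherence_level == "high"
  rownames(df) <- NULL
  prepare_model_data(df)
}
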