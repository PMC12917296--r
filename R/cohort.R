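#' Analysis configuration
#'
#' One object holds every tunable threshold of the trajectory analysis, all
#' expressed in days. A "year" is 360 days and a half-year 180 days
#' throughout, so yearly windows partition follow-up exactly.
#'
#' @param min_age minimum age (years) at index, inclusive.
#' @param history_days required database history before index (2 x 360).
#' @param post_days required database presence after index (1 x 360).
#' @param min_fills_year1 minimum dispensings of the index class within the
#'   first year (new-user exposure rule).
#' @param year_days days per analysis year.
#' @param study_end administrative end of observation.
#' @param followup_cap_days observation cap after index (about ten years).
#' @param baseline_window_days window after index for baseline co-medication
#'   flags, half-open.
#' @param exclusion_year1_days window after index in which antihypertensive
#'   or fixed-combination dispensings exclude the patient, half-open.
#' @param cardiac_lookback_days,cardiac_lookahead_days window around index
#'   (`[-lookback, +lookahead)`) for the cardiac exclusion list.
#' @param stockpile_cap_days maximum days of early-refill supply carried
#'   forward; 0 means truncation (a refill never starts before its own
#'   dispensing runs the previous supply out).
#' @param disc_gap_days a supply gap strictly greater than this is a
#'   discontinuation.
#' @param switch_window_days a different study drug dispensed within this
#'   many days after the discontinuation runout (inclusive) is a switch.
#' @param addon_requires_coverage if `TRUE` (default) an add-on must fall
#'   inside an active coverage interval; if `FALSE`, any second-class
#'   dispensing before the discontinuation date counts.
#' @param gap_from_runout measure gaps from supply runout (default) rather
#'   than from the dispensing date.
#' @param cv_event_proxy if `TRUE`, a dispensing from the cardiac exclusion
#'   list after index ends follow-up (proxy for a cardiovascular event);
#'   dispensing databases carry no diagnoses, so this is off by default.
#' @param adherence_threshold high/low adherence cut, inclusive on high.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(min_age = 18L,
                          history_days = 720L,
                          post_days = 360L,
                          min_fills_year1 = 3L,
                          year_days = 360L,
                          study_end = as.Date("2020-12-31"),
                          followup_cap_days = 3780L,
                          baseline_window_days = 180L,
                          exclusion_year1_days = 360L,
                          cardiac_lookback_days = 720L,
                          cardiac_lookahead_days = 90L,
                          stockpile_cap_days = 90L,
                          disc_gap_days = 180L,
                          switch_window_days = 180L,
                          addon_requires_coverage = TRUE,
                          gap_from_runout = TRUE,
                          cv_event_proxy = FALSE,
                          adherence_threshold = 0.8) {
  stopifnot(min_age >= 0, history_days >= 0, post_days >= 0,
            min_fills_year1 >= 1, year_days > 0, followup_cap_days > 0,
            stockpile_cap_days >= 0, adherence_threshold > 0)
  structure(as.list(environment()), class = "cohort_config")
}

# internal: dispensing df -> data.table with integer day and study class
.prep_records <- function(records, vocab) {
  dt <- data.table::as.data.table(records)
  dt[, day := .day(date)]
  dt[, study_class := classify_atc(atc, vocab)]
  data.table::setkey(dt, patient_id, day)
  dt
}

#' Identify new users of anti-hyperlipidemic monotherapy
#'
#' Applies the inception-cohort inclusion rules: the index date is the
#' first-ever dispensing of any study class; the patient must initiate a
#' single class on that day (same-day initiation of two classes is not
#' monotherapy and is excluded), be at least `min_age` years old, have at
#' least `history_days` of database records before index and `post_days`
#' after, and receive at least `min_fills_year1` dispensings of the index
#' class within the first year (half-open `[index, index + 360)`).
#'
#' Rules are applied sequentially; the attrition table (rule, n_excluded,
#' n_remaining) is attached as `attr(, "attrition")`.
#'
#' @param records dispensing table (see [read_dispensing_table()]).
#' @param patients patient table; every patient in `records` must appear.
#' @param vocab an [atc_vocabulary()].
#' @param config a [cohort_config()].
#' @return a `data.frame` of cohort entries: `patient_id`, `index_date`,
#'   `index_class`, `age_at_index`, `sex`, `age_group`, `calendar_period`,
#'   `record_span_days` (last record minus index), `horizon_days`
#'   (observation cap, `min(study_end, index + followup_cap) - index`).
#' @export
identify_new_users <- function(records, patients, vocab = atc_vocabulary(),
                               config = cohort_config()) {
  dt <- .prep_records(records, vocab)
  unknown <- setdiff(unique(dt$patient_id), patients$patient_id)
  if (length(unknown)) {
    stop("patient(s) present in dispensing table but absent from patient ",
         "table: ", paste(head(unknown, 10), collapse = ", "))
  }
  span <- dt[, .(first_any = min(day), last_any = max(day)), by = patient_id]

  attrition <- data.frame(rule = character(), n_excluded = integer(),
                          n_remaining = integer(), stringsAsFactors = FALSE)
  n0 <- nrow(patients)
  note <- function(rule, kept_n) {
    prev <- if (nrow(attrition)) attrition$n_remaining[nrow(attrition)] else n0
    attrition <<- rbind(attrition, data.frame(
      rule = rule, n_excluded = prev - kept_n, n_remaining = kept_n,
      stringsAsFactors = FALSE))
  }

  study <- dt[!is.na(study_class)]
  idx <- study[, .(index_day = min(day)), by = patient_id]
  note("no_study_dispensing", nrow(idx))
  if (nrow(idx) == 0) {
    out <- data.frame(patient_id = character(), index_date = as.Date(character()),
                      index_class = character(), age_at_index = integer(),
                      sex = character(), age_group = character(),
                      calendar_period = character(),
                      record_span_days = integer(), horizon_days = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "attrition") <- attrition
    return(out)
  }

  at_index <- study[idx, on = .(patient_id, day = index_day)]
  ncls <- at_index[, .(n_classes = data.table::uniqueN(study_class)),
                   by = patient_id]
  idx <- idx[ncls[n_classes == 1L], on = "patient_id"][, n_classes := NULL]
  note("multi_class_at_index", nrow(idx))

  idx[at_index[, .(index_class = study_class[1L]), by = patient_id],
      index_class := i.index_class, on = "patient_id"]
  idx <- merge(idx, data.table::as.data.table(patients), by = "patient_id")
  idx[, age_at_index := age_at(birth_date, .as_date(index_day))]
  idx <- idx[age_at_index >= config$min_age]
  note("age_below_minimum", nrow(idx))

  idx <- idx[span, on = "patient_id", nomatch = 0]
  idx <- idx[index_day - first_any >= config$history_days]
  note("insufficient_history", nrow(idx))
  idx <- idx[last_any - index_day >= config$post_days]
  note("insufficient_followup_records", nrow(idx))

  fills <- study[idx[, .(patient_id, index_day, index_class)],
                 on = .(patient_id), nomatch = 0][
    study_class == index_class & day >= index_day &
      day < index_day + config$year_days,
    .(n_fills = .N), by = patient_id]
  idx <- idx[fills[n_fills >= config$min_fills_year1], on = "patient_id",
             nomatch = 0][, n_fills := NULL]
  note("fewer_index_fills_than_required", nrow(idx))

  strata <- assign_strata(idx$age_at_index, .as_date(idx$index_day))
  out <- data.frame(
    patient_id = idx$patient_id,
    index_date = .as_date(idx$index_day),
    index_class = idx$index_class,
    age_at_index = idx$age_at_index,
    sex = idx$sex,
    age_group = strata$age_group,
    calendar_period = strata$calendar_period,
    record_span_days = as.integer(idx$last_any - idx$index_day),
    horizon_days = as.integer(pmin(.day(config$study_end) - idx$index_day,
                                   config$followup_cap_days)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attrition") <- attrition
  out
}

#' Assign age and calendar-period strata
#'
#' Age bands 18-39, 40-69, >= 70; calendar periods by index year with
#' half-open bins `[1996, 2000)`, `[2000, 2010)`, `[2010, 2021)` (the printed
#' period labels overlap at the boundary years; boundary years go to the
#' later period).
#'
#' @param age_at_index integer ages.
#' @param index_date `Date` vector.
#' @return `data.frame` with `age_group` and `calendar_period`.
#' @export
assign_strata <- function(age_at_index, index_date) {
  stopifnot(all(age_at_index >= 18))
  yr <- as.integer(format(as.Date(index_date), "%Y"))
  data.frame(
    age_group = as.character(cut(age_at_index, c(18, 40, 70, Inf),
                                 right = FALSE,
                                 labels = c("18-39", "40-69", "70+"))),
    calendar_period = ifelse(yr < 2000, "1996-2000",
                             ifelse(yr < 2010, "2000-2010", "2010-2020")),
    stringsAsFactors = FALSE
  )
}

#' Apply cohort exclusion rules
#'
#' Removes entries with (1) any antihypertensive or fixed-dose-combination
#' dispensing in the first year after index (`[index, index + 360)`), or
#' (2) any dispensing from the cardiac list within `[index - 720,
#' index + 90)`. Extends the attrition table.
#'
#' @inheritParams identify_new_users
#' @param entries output of [identify_new_users()].
#' @return the retained entries with an extended `attr(, "attrition")`.
#' @export
apply_exclusions <- function(entries, records, vocab = atc_vocabulary(),
                             config = cohort_config()) {
  dt <- .prep_records(records, vocab)
  attrition <- attr(entries, "attrition")
  if (is.null(attrition)) {
    attrition <- data.frame(rule = character(), n_excluded = integer(),
                            n_remaining = integer(), stringsAsFactors = FALSE)
  }
  ent <- data.table::as.data.table(entries)
  ent[, index_day := .day(index_date)]

  hits_in_window <- function(prefixes, lo_off, hi_off) {
    sub <- dt[matches_any_prefix(atc, prefixes),
              .(patient_id, day)]
    if (nrow(sub) == 0) return(character())
    x <- sub[ent[, .(patient_id, index_day)], on = "patient_id",
             nomatch = 0, allow.cartesian = TRUE]
    unique(x[day >= index_day + lo_off & day < index_day + hi_off, patient_id])
  }

  p1 <- unique(c(config_prefixes(vocab, "antihypertensive"),
                 config_prefixes(vocab, "fixed_combination")))
  bad1 <- hits_in_window(p1, 0L, config$exclusion_year1_days)
  ent <- ent[!patient_id %in% bad1]
  attrition <- rbind(attrition, data.frame(
    rule = "antihypertensive_or_fixed_combo_year1",
    n_excluded = length(intersect(bad1, entries$patient_id)),
    n_remaining = nrow(ent), stringsAsFactors = FALSE))

  bad2 <- hits_in_window(config_prefixes(vocab, "cardiac"),
                         -config$cardiac_lookback_days,
                         config$cardiac_lookahead_days)
  kept_before <- nrow(ent)
  ent <- ent[!patient_id %in% bad2]
  attrition <- rbind(attrition, data.frame(
    rule = "cardiac_therapy_window",
    n_excluded = kept_before - nrow(ent),
    n_remaining = nrow(ent), stringsAsFactors = FALSE))

  out <- as.data.frame(ent[, index_day := NULL])
  attr(out, "attrition") <- attrition
  out
}

# internal: pull a prefix list out of the vocabulary's exclusion map
config_prefixes <- function(vocab, rule) {
  p <- vocab$exclusion_map[[rule]]
  if (is.null(p)) character() else p
}

#' Baseline drug-treated comorbidity flags
#'
#' One logical flag per co-medication group in the vocabulary: `TRUE` iff
#' the patient has at least one dispensing with a mapped ATC prefix within
#' the half-open window `[index, index + 180)`.
#'
#' @inheritParams apply_exclusions
#' @return `entries` with one `flag_<group>` logical column per group.
#' @export
baseline_flags <- function(entries, records, vocab = atc_vocabulary(),
                           config = cohort_config()) {
  dt <- .prep_records(records, vocab)
  ent <- data.table::as.data.table(entries)
  ent[, index_day := .day(index_date)]
  for (nm in names(vocab$comedication_map)) {
    sub <- dt[matches_any_prefix(atc, vocab$comedication_map[[nm]]),
              .(patient_id, day)]
    flagged <- if (nrow(sub)) {
      x <- sub[ent[, .(patient_id, index_day)], on = "patient_id",
               nomatch = 0, allow.cartesian = TRUE]
      unique(x[day >= index_day & day < index_day + config$baseline_window_days,
               patient_id])
    } else character()
    ent[, paste0("flag_", nm) := patient_id %in% flagged]
  }
  out <- as.data.frame(ent[, index_day := NULL])
  attr(out, "attrition") <- attr(entries, "attrition")
  out
}

#' Determine per-patient follow-up end
#'
#' Follow-up ends at the earliest of: the administrative study end (already
#' capped at `index + followup_cap_days`), the first cardiac-proxy
#' dispensing after index (only if `config$cv_event_proxy`), the supply
#' runout of the final index-class dispensing, or the first treatment
#' change (switch or add-on date). Ties are resolved in that order.
#'
#' @inheritParams apply_exclusions
#' @param patterns output of [classify_patterns_all()]; computed on the fly
#'   when `NULL`.
#' @param coverage output of [coverage_all()]; computed on the fly when
#'   `NULL`.
#' @return `entries` with `followup_end` (`Date`), `followup_days` and
#'   `end_reason` columns.
#' @export
determine_followup_end <- function(entries, records, vocab = atc_vocabulary(),
                                   config = cohort_config(),
                                   patterns = NULL, coverage = NULL) {
  if (is.null(coverage)) coverage <- coverage_all(entries, records, vocab, config)
  if (is.null(patterns)) {
    patterns <- classify_patterns_all(entries, records, vocab, config, coverage)
  }
  index_day <- .day(entries$index_date)
  cand_study <- pmin(.day(config$study_end),
                     index_day + config$followup_cap_days)

  last_runout <- attr(coverage, "last_runout")
  lr <- last_runout$last_runout[match(entries$patient_id, last_runout$patient_id)]
  cand_last <- index_day + lr

  pm <- patterns[match(entries$patient_id, patterns$patient_id), , drop = FALSE]
  ev <- pmin(ifelse(is.na(pm$switch_day), Inf, pm$switch_day),
             ifelse(is.na(pm$addon_day), Inf, pm$addon_day))
  cand_pattern <- index_day + ev

  cand_cv <- rep(Inf, nrow(entries))
  if (isTRUE(config$cv_event_proxy)) {
    dt <- .prep_records(records, vocab)
    sub <- dt[matches_any_prefix(atc, config_prefixes(vocab, "cardiac")),
              .(patient_id, day)]
    if (nrow(sub)) {
      ent <- data.table::data.table(patient_id = entries$patient_id,
                                    index_day = index_day)
      x <- sub[ent, on = "patient_id", nomatch = 0, allow.cartesian = TRUE]
      first_cv <- x[day > index_day, .(cv = min(day)), by = patient_id]
      cand_cv <- first_cv$cv[match(entries$patient_id, first_cv$patient_id)]
      cand_cv[is.na(cand_cv)] <- Inf
    }
  }

  cand <- cbind(study_end = cand_study, cv_event_proxy = cand_cv,
                pattern_change = cand_pattern, last_prescription = cand_last)
  best <- apply(cand, 1, which.min)  # first minimum wins => priority order
  fu <- cand[cbind(seq_len(nrow(cand)), best)]
  entries$followup_end <- .as_date(as.integer(fu))
  entries$followup_days <- as.integer(fu - index_day)
  entries$end_reason <- colnames(cand)[best]
  entries
}
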