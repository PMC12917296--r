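#' Classify drug-utilisation patterns for a whole cohort
#'
#' Implements the four non-exclusive trajectory outcomes against each
#' entry's observation horizon (`min(study_end, index + cap)`):
#'
#' * **discontinuation** — a supply gap of the index class strictly longer
#'   than `disc_gap_days` (180), measured from a coverage-interval runout to
#'   the next index-class dispensing, or from the final runout to the
#'   horizon; the discontinuation date is the runout opening the first such
#'   gap.
#' * **switch** — a dispensing of a different study class or a fixed-dose
#'   combination within `(disc, disc + 180]` days of the discontinuation
#'   runout; implies discontinuation.
#' * **add-on** — a dispensing of a second study class or fixed-dose
#'   combination while index coverage is active (strictly inside a coverage
#'   interval) and before any discontinuation date.
#' * **continuation** — an eligible patient with none of the above through
#'   the horizon.
#'
#' A patient is *eligible* (in the Table-style time-risk window) when still
#' on the original monotherapy beyond one year: no discontinuation or
#' add-on event on or before day 360. `persistence_days` is the day of the
#' first such event, or the horizon when there is none. Dose changes of the
#' same compound never break continuation; dose-level transitions are
#' handled by the equivalent-dose module.
#'
#' @inheritParams apply_exclusions
#' @param coverage output of [coverage_all()]; recomputed when `NULL`.
#' @return `data.frame` with one row per entry: logical flags
#'   `continuation`, `discontinuation`, `switch`, `add_on`, `eligible`;
#'   event days relative to index (`disc_day`, `switch_day`, `addon_day`,
#'   `NA` when absent); `switch_target` and `addon_class`;
#'   `persistence_days`.
#' @export
classify_patterns_all <- function(entries, records, vocab = atc_vocabulary(),
                                  config = cohort_config(), coverage = NULL) {
  if (is.null(coverage)) coverage <- coverage_all(entries, records, vocab, config)
  ent <- data.table::data.table(patient_id = entries$patient_id,
                                index_day = .day(entries$index_date),
                                index_class = entries$index_class,
                                horizon = entries$horizon_days)

  # --- discontinuation from coverage gaps ---
  # copy: gap bookkeeping must not modify the caller's coverage by reference
  ivs <- data.table::copy(data.table::as.data.table(coverage))
  if (!isTRUE(config$gap_from_runout)) {
    # alternative convention: measure the gap from the last dispensing date
    # of the episode instead of its runout
    dtb <- .prep_records(records, vocab)[ent, on = "patient_id", nomatch = 0,
                                         allow.cartesian = TRUE]
    dtb <- dtb[study_class == index_class & day >= index_day]
    dtb[, day := day - index_day]
    lastd <- dtb[ivs, on = .(patient_id, day >= start, day < end),
                 .(last_disp = max(x.day)), by = .EACHI]
    ivs[, end := lastd$last_disp]
  }
  data.table::setorder(ivs, patient_id, start)
  ivs[ent, horizon := i.horizon, on = "patient_id"]
  ivs[, next_start := data.table::shift(start, -1L), by = patient_id]
  ivs[, gap_after := data.table::fifelse(is.na(next_start),
                                         horizon - end, next_start - end)]
  disc <- ivs[gap_after > config$disc_gap_days,
              .(disc_day = end[1L]), by = patient_id]

  # --- dispensings of other study classes / fixed combinations ---
  dt <- .prep_records(records, vocab)
  oth <- dt[ent, on = "patient_id", nomatch = 0, allow.cartesian = TRUE]
  oth[, rel := day - index_day]
  oth <- oth[rel >= 0 & rel < horizon]
  oth[, other_class := data.table::fifelse(
    is_fixed_combination(atc, vocab), "fixed_combination", study_class)]
  oth <- oth[!is.na(other_class) & other_class != index_class,
             .(patient_id, rel, other_class)]
  oth[disc, disc_day := i.disc_day, on = "patient_id"]

  sw <- oth[!is.na(disc_day) & rel > disc_day &
              rel <= disc_day + config$switch_window_days]
  data.table::setorder(sw, patient_id, rel)
  sw <- sw[, .(switch_day = rel[1L], switch_target = other_class[1L]),
           by = patient_id]

  ao <- oth[is.na(disc_day) | rel < disc_day]
  if (isTRUE(config$addon_requires_coverage)) {
    x <- data.table::as.data.table(coverage)[
      ao, on = .(patient_id, start <= rel, end > rel), nomatch = 0,
      .(patient_id, rel = i.rel, other_class = i.other_class)]
    ao <- x
  }
  data.table::setorder(ao, patient_id, rel)
  ao <- ao[, .(addon_day = rel[1L], addon_class = other_class[1L]),
           by = patient_id]

  out <- data.frame(patient_id = entries$patient_id, stringsAsFactors = FALSE)
  out$disc_day <- disc$disc_day[match(out$patient_id, disc$patient_id)]
  out$switch_day <- sw$switch_day[match(out$patient_id, sw$patient_id)]
  out$switch_target <- sw$switch_target[match(out$patient_id, sw$patient_id)]
  out$addon_day <- ao$addon_day[match(out$patient_id, ao$patient_id)]
  out$addon_class <- ao$addon_class[match(out$patient_id, ao$patient_id)]

  out$discontinuation <- !is.na(out$disc_day)
  out$switch <- !is.na(out$switch_day)
  out$add_on <- !is.na(out$addon_day)
  first_event <- pmin(ifelse(is.na(out$disc_day), Inf, out$disc_day),
                      ifelse(is.na(out$addon_day), Inf, out$addon_day))
  out$persistence_days <- pmin(first_event, entries$horizon_days)
  out$eligible <- out$persistence_days > config$year_days
  out$continuation <- out$eligible & !out$discontinuation & !out$switch &
    !out$add_on
  out
}

# run the cohort classifier on a single entry and return its row
.classify_one <- function(entry, records, vocab, config, coverage = NULL) {
  stopifnot(nrow(entry) == 1)
  if (!is.null(coverage)) {
    coverage <- data.table::data.table(patient_id = entry$patient_id,
                                       start = coverage$start,
                                       end = coverage$end)
  }
  classify_patterns_all(entry, records, vocab, config, coverage)
}

#' Pattern classification for a single cohort entry
#'
#' Single-entry wrappers around [classify_patterns_all()]; all four share
#' its gap, window and coverage conventions exactly.
#'
#' @inheritParams classify_patterns_all
#' @param entry a one-row cohort entry.
#' @param coverage optional coverage intervals for this entry (as from
#'   [build_coverage()], days relative to index).
#' @return `classify_patterns()` returns the one-row assessment;
#'   `detect_discontinuation()`, `detect_switch()` and `detect_addon()`
#'   return lists with the flag, event day and (where relevant) the target
#'   class.
#' @export
classify_patterns <- function(entry, records, vocab = atc_vocabulary(),
                              config = cohort_config(), coverage = NULL) {
  .classify_one(entry, records, vocab, config, coverage)
}

#' @rdname classify_patterns
#' @export
detect_discontinuation <- function(entry, records, vocab = atc_vocabulary(),
                                   config = cohort_config(), coverage = NULL) {
  r <- .classify_one(entry, records, vocab, config, coverage)
  list(discontinuation = r$discontinuation, date = r$disc_day)
}

#' @rdname classify_patterns
#' @export
detect_switch <- function(entry, records, vocab = atc_vocabulary(),
                          config = cohort_config(), coverage = NULL) {
  r <- .classify_one(entry, records, vocab, config, coverage)
  list(switch = r$switch, date = r$switch_day, target = r$switch_target)
}

#' @rdname classify_patterns
#' @export
detect_addon <- function(entry, records, vocab = atc_vocabulary(),
                         config = cohort_config(), coverage = NULL) {
  r <- .classify_one(entry, records, vocab, config, coverage)
  list(add_on = r$add_on, date = r$addon_day, added = r$addon_class)
}

#' Tabulate pattern rates by index drug class
#'
#' Counts and percentages of each pattern flag among eligible patients, per
#' index class and overall, formatted as `"n (p%)"` with the percentage
#' rounded to one decimal.
#'
#' @param assessments output of [classify_patterns_all()].
#' @param entries the matching cohort entries (for `index_class`).
#' @param class_order display order of classes; defaults to descending
#'   class size.
#' @return long `data.frame`: `class`, `N`, `pattern`, `n`, `pct`, `label`.
#' @export
pattern_rate_table <- function(assessments, entries, class_order = NULL) {
  cls <- entries$index_class[match(assessments$patient_id, entries$patient_id)]
  keep <- assessments$eligible
  a <- assessments[keep, , drop = FALSE]
  cls <- cls[keep]
  if (is.null(class_order)) {
    class_order <- names(sort(table(cls), decreasing = TRUE))
  }
  groups <- c(list(Overall = rep(TRUE, nrow(a))),
              stats::setNames(lapply(class_order, function(cl) cls == cl),
                              class_order))
  patterns <- c(continuation = "continuation",
                discontinuation = "discontinuation",
                switch = "switch", add_on = "add_on")
  rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    N <- sum(sel)
    for (p in names(patterns)) {
      n <- sum(a[[patterns[[p]]]][sel])
      pct <- if (N > 0) round(100 * n / N, 1) else NA_real_
      label <- if (N > 0) sprintf("%d (%.1f%%)", n, pct) else sprintf("%d", n)
      rows[[length(rows) + 1L]] <- data.frame(
        class = g, N = N, pattern = p, n = n, pct = pct, label = label,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
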