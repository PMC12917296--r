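#' Build supply-coverage intervals for one patient
#'
#' Each dispensing contributes `days_supplied` covered days. A refill
#' dispensed before the previous supply runs out starts at the previous
#' runout (carryover), with the carried stockpile capped at
#' `stockpile_cap` days: at each dispensing the remaining supply is first
#' clipped to the cap, then the new supply is added. `stockpile_cap = 0`
#' gives pure truncation. Intervals are returned as disjoint half-open
#' `[start, end)` day ranges; coverage within an unbroken refill chain is
#' continuous even when excess stock is discarded.
#'
#' @param days integer dispensing days (any origin), sorted ascending.
#' @param days_supplied supply per dispensing (recycled if scalar).
#' @param stockpile_cap carryover cap in days (default 90).
#' @param horizon optional clip: intervals are truncated at this day.
#' @return `data.frame` with `start` and `end` columns.
#' @examples
#' build_coverage(c(0, 60), 90)   # carryover: one interval [0, 180)
#' build_coverage(c(0, 200), 30)  # two intervals, 170-day gap
#' @export
build_coverage <- function(days, days_supplied, stockpile_cap = 90,
                           horizon = NULL) {
  stopifnot(!is.unsorted(days), all(days_supplied >= 1))
  n <- length(days)
  if (n == 0) return(data.frame(start = integer(), end = integer()))
  s <- rep_len(as.numeric(days_supplied), n)
  d <- as.numeric(days)
  starts <- numeric(0); ends <- numeric(0)
  cur_start <- d[1]; r <- d[1] + s[1]
  if (n > 1) {
    for (j in 2:n) {
      if (d[j] > r) {  # gap: close the episode (a refill exactly at runout
                       # keeps coverage continuous)
        starts <- c(starts, cur_start); ends <- c(ends, r)
        cur_start <- d[j]
        r <- d[j] + s[j]
      } else {
        r <- d[j] + min(r - d[j], stockpile_cap) + s[j]
      }
    }
  }
  starts <- c(starts, cur_start); ends <- c(ends, r)
  out <- data.frame(start = starts, end = ends)
  if (!is.null(horizon)) {
    out$end <- pmin(out$end, horizon)
    out <- out[out$start < out$end, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Build coverage intervals for a whole cohort
#'
#' Vectorised equivalent of [build_coverage()] applied to every cohort
#' entry's index-class dispensings, relative to the index date and clipped
#' at each entry's observation horizon. The sequential carryover recursion
#' is evaluated position-wise across patients, so run time scales with the
#' maximum number of refills, not the number of patients.
#'
#' @inheritParams apply_exclusions
#' @return a `data.table` with columns `patient_id`, `start`, `end`
#'   (days relative to index, half-open, clipped at the horizon). The
#'   unclipped runout of each patient's final dispensing chain is attached
#'   as `attr(, "last_runout")` (used for follow-up termination).
#' @export
coverage_all <- function(entries, records, vocab = atc_vocabulary(),
                         config = cohort_config()) {
  dt <- .prep_records(records, vocab)
  ent <- data.table::data.table(patient_id = entries$patient_id,
                                index_day = .day(entries$index_date),
                                index_class = entries$index_class,
                                horizon = entries$horizon_days)
  x <- dt[ent, on = "patient_id", nomatch = 0, allow.cartesian = TRUE]
  x <- x[study_class == index_class & day >= index_day]
  x[, day := day - index_day]
  data.table::setorder(x, patient_id, day)
  x[, pos := seq_len(.N), by = patient_id]

  cap <- config$stockpile_cap_days
  nr <- nrow(x)
  if (nr == 0) {
    ep <- data.table::data.table(patient_id = character(), start = numeric(),
                                 end = numeric())
    attr(ep, "last_runout") <- data.frame(patient_id = character(),
                                          last_runout = numeric())
    return(ep)
  }
  r <- numeric(nr)
  d <- as.numeric(x$day); s <- as.numeric(x$days_supplied)
  idx_by_pos <- split(seq_len(nr), x$pos)
  p1 <- idx_by_pos[[1]]
  r[p1] <- d[p1] + s[p1]
  if (length(idx_by_pos) > 1) {
    for (p in 2:length(idx_by_pos)) {
      i <- idx_by_pos[[p]]
      rp <- r[i - 1L]  # previous row of the same patient (sorted by pos)
      gap <- d[i] > rp
      r[i] <- ifelse(gap, d[i] + s[i],
                     d[i] + pmin(rp - d[i], cap) + s[i])
    }
  }
  x[, runout := r]
  x[, episode := cumsum(pos == 1L | d > data.table::shift(r, fill = -Inf))]
  ep <- x[, .(start = day[1L], end = runout[.N], horizon = horizon[1L]),
          by = .(patient_id, episode)]
  last_runout <- ep[, .(last_runout = end[.N]), by = patient_id]
  ep[, end := pmin(end, horizon)]
  ep <- ep[start < end, .(patient_id, start, end)]
  data.table::setorder(ep, patient_id, start)
  attr(ep, "last_runout") <- as.data.frame(last_runout)
  ep[]
}

#' Yearly proportion-of-days-covered adherence
#'
#' Covered days of the index drug within analysis year `k` (the half-open
#' window `[(k-1)*360, k*360)` days after index) divided by the fixed
#' 360-day denominator. Under stockpile carryover a year's value can exceed
#' 1; values are not clipped.
#'
#' @param coverage `data.frame` of `[start, end)` intervals in days since
#'   index (one patient).
#' @param k analysis year (1-based).
#' @param year_days days per year (360).
#' @return adherence value in `[0, (year_days + cap) / year_days]`.
#' @export
yearly_adherence <- function(coverage, k, year_days = 360) {
  stopifnot(k >= 1)
  lo <- (k - 1) * year_days; hi <- k * year_days
  sum(pmax(0, pmin(coverage$end, hi) - pmax(coverage$start, lo))) / year_days
}

#' Per-patient, per-year adherence profiles
#'
#' Computes yearly adherence for every cohort entry and every analysis year
#' in which the patient is in the time-risk window: a patient contributes
#' year `k` only while persisting on the original monotherapy beyond
#' `k * 360` days (no discontinuation, switch or add-on event before the
#' end of year `k`, and the observation horizon itself exceeds `k` years).
#' Patients outside the risk window are excluded from that year, not
#' counted as zero.
#'
#' @inheritParams apply_exclusions
#' @param coverage output of [coverage_all()].
#' @param patterns output of [classify_patterns_all()] (supplies the
#'   persistence time).
#' @param max_years largest analysis year reported.
#' @return `data.frame` with `patient_id`, `year`, `adherence`, `high`
#'   (adherence at or above the configured 0.8 threshold).
#' @export
adherence_profiles <- function(entries, coverage, patterns,
                               config = cohort_config(), max_years = 10L) {
  per <- patterns$persistence_days[match(entries$patient_id,
                                         patterns$patient_id)]
  cov <- data.table::as.data.table(coverage)
  out <- vector("list", max_years)
  yd <- config$year_days
  for (k in seq_len(max_years)) {
    at_risk <- entries$patient_id[!is.na(per) & per > k * yd]
    if (!length(at_risk)) next
    sub <- cov[patient_id %in% at_risk]
    covk <- sub[, .(covered = sum(pmax(0, pmin(end, k * yd) -
                                         pmax(start, (k - 1) * yd)))),
                by = patient_id]
    # at-risk patients with no interval in the year have zero covered days
    adh <- covk$covered[match(at_risk, covk$patient_id)] / yd
    adh[is.na(adh)] <- 0
    out[[k]] <- data.frame(patient_id = at_risk, year = k, adherence = adh,
                           high = adh >= config$adherence_threshold,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(patient_id = character(), year = integer(),
                      adherence = numeric(), high = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Prevalence of high adherence in year k
#'
#' Denominator: patients persisting on the original monotherapy beyond `k`
#' years (present in the year-`k` profile rows); numerator: those with
#' year-`k` adherence at or above the threshold.
#'
#' @param profiles output of [adherence_profiles()].
#' @param k analysis year.
#' @return list with `n_high`, `n_at_risk`, `proportion` (`NA` when the
#'   denominator is empty).
#' @export
prevalence_high_adherence <- function(profiles, k) {
  sub <- profiles[profiles$year == k, , drop = FALSE]
  n <- nrow(sub)
  list(n_high = sum(sub$high), n_at_risk = n,
       proportion = if (n == 0) NA_real_ else sum(sub$high) / n)
}

#' Follow-up-window (3-year) binary adherence
#'
#' For the 3-year transition analysis the adherence denominator is the
#' individual follow-up time rather than a fixed year: covered days during
#' follow-up divided by total follow-up days, dichotomised at the
#' threshold. The eligible subset holds patients whose overall database
#' records span more than 3 years after index while their time on the
#' original monotherapy is at most 3 years.
#'
#' @inheritParams adherence_profiles
#' @param window_years width of the analysis window (3).
#' @return `data.frame` with `patient_id`, `followup_days`, `adherence`,
#'   `high` for the eligible subset.
#' @export
window_adherence_3yr <- function(entries, coverage, patterns,
                                 config = cohort_config(), window_years = 3L) {
  wd <- window_years * config$year_days
  pm <- patterns[match(entries$patient_id, patterns$patient_id), , drop = FALSE]
  keep <- entries$record_span_days > wd & pm$persistence_days <= wd
  sub <- entries[keep, , drop = FALSE]
  fu <- if ("followup_days" %in% names(sub) && !anyNA(sub$followup_days)) {
    sub$followup_days
  } else pm$persistence_days[keep]
  if (any(fu <= 0)) stop("zero-length follow-up for patient(s): ",
                         paste(head(sub$patient_id[fu <= 0], 5), collapse = ", "))
  cov <- data.table::as.data.table(coverage)[patient_id %in% sub$patient_id]
  lim <- data.table::data.table(patient_id = sub$patient_id, fu = fu)
  cov <- cov[lim, on = "patient_id", nomatch = 0]
  covd <- cov[, .(covered = sum(pmax(0, pmin(end, fu) - pmax(start, 0)))),
              by = patient_id]
  covered <- covd$covered[match(sub$patient_id, covd$patient_id)]
  covered[is.na(covered)] <- 0
  val <- covered / fu
  data.frame(patient_id = sub$patient_id, followup_days = fu,
             adherence = val, high = val >= config$adherence_threshold,
             stringsAsFactors = FALSE)
}
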