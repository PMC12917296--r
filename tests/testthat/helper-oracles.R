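# Independent brute-force oracles: these re-derive every quantity with a
# different algorithm (day-by-day simulation, exhaustive enumeration, hand
# arithmetic) and must stay independent of the package's interval-based
# implementations they check.

# Day-by-day pill-supply simulation. On a dispensing day the remaining
# stock is first clipped to `cap`, then the new supply is added; each
# covered day consumes one day of stock. Returns a logical vector over
# days 0..horizon-1.
oracle_covered <- function(days, supplies, cap = 90, horizon) {
  supplies <- rep_len(supplies, length(days))
  keep <- days < horizon
  days <- days[keep]; supplies <- supplies[keep]
  stock <- 0
  covered <- logical(horizon)
  for (t in seq_len(horizon) - 1L) {
    for (h in which(days == t)) stock <- min(stock, cap) + supplies[h]
    if (stock > 0) {
      covered[t + 1L] <- TRUE
      stock <- stock - 1
    }
  }
  covered
}

# expand [start, end) intervals into the same day-indexed logical vector
intervals_to_covered <- function(iv, horizon) {
  v <- logical(horizon)
  for (r in seq_len(nrow(iv))) {
    lo <- max(iv$start[r], 0); hi <- min(iv$end[r], horizon)
    if (lo < hi) v[(lo + 1):hi] <- TRUE
  }
  v
}

# Day-level scan for the pattern outcomes: gaps > disc_gap from a supply
# runout to the next index dispensing (or the horizon), switch inside
# (disc, disc + switch_win], add-on on a covered day before discontinuation.
oracle_patterns <- function(index_days, supply, other_days, horizon,
                            cap = 90, disc_gap = 180, switch_win = 180,
                            year_days = 360) {
  cov <- oracle_covered(index_days, supply, cap, horizon)
  fills <- sort(index_days[index_days < horizon])
  disc_day <- NA_real_
  for (d in seq_len(horizon - 1)) {      # day d uncovered, day d-1 covered
    if (cov[d] && !cov[d + 1]) {
      nxt <- fills[fills >= d]
      gap <- (if (length(nxt)) min(nxt, horizon) else horizon) - d
      if (gap > disc_gap) { disc_day <- d; break }
    }
  }
  other_days <- sort(other_days[other_days >= 0 & other_days < horizon])
  sw_day <- NA_real_
  if (!is.na(disc_day)) {
    hits <- other_days[other_days > disc_day &
                         other_days <= disc_day + switch_win]
    if (length(hits)) sw_day <- hits[1]
  }
  ao_day <- NA_real_
  cand <- other_days[is.na(disc_day) | other_days < disc_day]
  cand <- cand[vapply(cand, function(d) cov[d + 1], logical(1))]
  if (length(cand)) ao_day <- cand[1]
  persistence <- min(disc_day, ao_day, horizon, na.rm = TRUE)
  eligible <- persistence > year_days
  list(disc_day = disc_day, switch_day = sw_day, addon_day = ao_day,
       discontinuation = !is.na(disc_day), switch = !is.na(sw_day),
       add_on = !is.na(ao_day), persistence_days = persistence,
       eligible = eligible,
       continuation = eligible && is.na(disc_day) && is.na(sw_day) &&
         is.na(ao_day))
}

# exhaustive pairwise concordance AUC (ties count one half)
oracle_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# manual Kaplan-Meier product-limit estimate at each event time
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# 2x2 odds ratio from ground-truth labels
oracle_or_2x2 <- function(exposed, outcome) {
  a <- sum(exposed & outcome); b <- sum(exposed & !outcome)
  c_ <- sum(!exposed & outcome); d <- sum(!exposed & !outcome)
  (a * d) / (b * c_)
}

# --- fixtures built in code -------------------------------------------------

# a minimal one-patient cohort entry for trace-level pattern tests
make_entry <- function(pid = "T1", index_date = as.Date("2005-01-06"),
                       index_class = "simvastatin", horizon = 1080L) {
  data.frame(patient_id = pid, index_date = index_date,
             index_class = index_class, age_at_index = 55L, sex = "female",
             age_group = "40-69", calendar_period = "2000-2010",
             record_span_days = horizon + 400L, horizon_days = horizon,
             stringsAsFactors = FALSE)
}

# dispensing rows from relative days
make_records <- function(pid, index_date, day, atc, days_supplied = 30L,
                         strength_mg = 20, units = 30) {
  data.frame(patient_id = pid, date = index_date + day, atc = atc,
             strength_mg = strength_mg, units = units,
             days_supplied = days_supplied, stringsAsFactors = FALSE)
}

# wrap an archetype trace into (entries, records) for one synthetic patient
trace_to_tables <- function(trace, pid = "T1",
                            index_date = as.Date("2005-01-06"),
                            index_class = "simvastatin", horizon = 1080L) {
  list(entry = make_entry(pid, index_date, index_class, horizon),
       records = make_records(pid, index_date, trace$day, trace$atc,
                              trace$days_supplied, trace$strength_mg,
                              trace$units))
}
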