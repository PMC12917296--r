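#' Planted covariate effects for the synthetic generator
#'
#' Odds ratios on the latent probability of being a high adherer (yearly
#' proportion of days covered >= 0.8). Defaults are the adherence effects the
#' generator is calibrated to emulate: male sex 0.79, age 40-69 1.68,
#' age >= 70 2.46, diabetes co-medication 1.17. The intercept (logit scale,
#' default 1.19) is calibrated so that, under the default covariate mix, the
#' marginal year-1 prevalence of high adherence is 0.836.
#'
#' `class_pattern_or` optionally skews the archetype mix per drug class: a
#' numeric matrix with one row per study class and one column per archetype
#' (`continuer`, `discontinuer`, `switcher`, `addon`, `intermittent`),
#' holding multiplicative odds applied to the base `pattern_mix` before
#' renormalisation. `NULL` leaves the mix identical across classes.
#'
#' @param intercept_logit baseline log-odds of high adherence (female, age
#'   18-39, no diabetes co-medication).
#' @param or_male,or_age_40_69,or_age_70plus,or_diabetes odds ratios (> 0).
#' @param class_pattern_or optional class-by-archetype odds multiplier matrix.
#' @return an object of class `planted_effects`.
#' @export
planted_effects <- function(intercept_logit = 1.19,
                            or_male = 0.79,
                            or_age_40_69 = 1.68,
                            or_age_70plus = 2.46,
                            or_diabetes = 1.17,
                            class_pattern_or = NULL) {
  ors <- c(or_male = or_male, or_age_40_69 = or_age_40_69,
           or_age_70plus = or_age_70plus, or_diabetes = or_diabetes)
  if (any(!is.finite(ors)) || any(ors <= 0)) {
    stop("all planted odds ratios must be positive and finite")
  }
  if (!is.null(class_pattern_or)) {
    stopifnot(is.matrix(class_pattern_or), all(class_pattern_or > 0))
  }
  structure(list(intercept_logit = intercept_logit,
                 or_male = or_male, or_age_40_69 = or_age_40_69,
                 or_age_70plus = or_age_70plus, or_diabetes = or_diabetes,
                 class_pattern_or = class_pattern_or),
            class = "planted_effects")
}

#' Configuration of the synthetic dispensing-record generator
#'
#' The generator emulates a community-pharmacy dispensing database of new
#' users of anti-hyperlipidemic monotherapy over 1996-2020. Each simulated
#' patient receives: an index dispensing of one study class, a refill
#' sequence whose density encodes a latent binary adherence level, a
#' trajectory archetype that determines later pattern events
#' (discontinuation, switch, add-on, a mid-therapy refill hole), anchor
#' dispensings of a non-study drug that establish database presence before
#' and after the index date, and baseline co-medication dispensings within
#' the first 180 days.
#'
#' Latent adherence is realised by *thinning refills*: high adherers refill
#' every `refill_interval_high` (+/- jitter) days and low adherers every
#' `refill_interval_low` days, with a fixed `days_supplied` per fill. With
#' the defaults (30/46 +/- 3 days, 30-day supplies) year-1 proportion of
#' days covered is always >= 0.917 for high adherers and <= 0.75 for low
#' adherers, so the emitted ground-truth adherence label and the
#' classification at the 0.8 cut agree deterministically.
#'
#' Index dates are drawn so that at least `index_margin_days` days remain
#' before the end of the study window, guaranteeing that every archetype's
#' defining event (including a > 180-day terminal gap) is observable.
#'
#' @param n_patients number of patients to simulate.
#' @param date_range study window (two `Date`s).
#' @param drug_class_probs named probability vector over the six study
#'   classes; the default mirrors the market-share-like mix of Dutch statin
#'   initiation (simvastatin-dominated).
#' @param pattern_mix named probability vector over the five trajectory
#'   archetypes.
#' @param refill_interval_high,refill_interval_low target refill gap (days)
#'   for latent high / low adherers.
#' @param refill_jitter uniform jitter (+/- days) added to each refill gap.
#' @param days_supplied_choices vector of days-supplied values; if several,
#'   one is drawn per patient and refill gaps are rescaled proportionally so
#'   the planted adherence level is preserved.
#' @param comed_prev named vector of baseline co-medication prevalences
#'   (independent Bernoulli draws; `diabetes` feeds the planted diabetes
#'   effect).
#' @param age_mean,age_sd,age_range truncated-normal age-at-index model.
#' @param prob_male probability of male sex.
#' @param planted_effects a [planted_effects()] object.
#' @param planted_exclusions named vector: probability per patient of
#'   planting an exclusion-triggering dispensing (`antihypertensive` within
#'   the first year, `cardiac` within [-720, +90) days of index).
#' @param followup_cap_days observation cap after index (default 3780,
#'   roughly ten 360-day years).
#' @param index_margin_days minimum days between index and study end.
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_patients,
                             date_range = as.Date(c("1996-01-01", "2020-12-31")),
                             drug_class_probs = c(
                               simvastatin = 10475, atorvastatin = 1530,
                               rosuvastatin = 594, pravastatin = 501,
                               fluvastatin = 73, fibrates = 97
                             ) / 13270,
                             pattern_mix = c(continuer = 0.30,
                                             discontinuer = 0.32,
                                             switcher = 0.18,
                                             addon = 0.12,
                                             intermittent = 0.08),
                             refill_interval_high = 30L,
                             refill_interval_low = 46L,
                             refill_jitter = 3L,
                             days_supplied_choices = 30L,
                             comed_prev = c(diabetes = 0.20, ra = 0.02,
                                            asthma_copd = 0.06,
                                            antiepileptics = 0.03,
                                            antiparkinson = 0.012,
                                            psycholeptics = 0.10,
                                            psychoanaleptics = 0.08,
                                            addictive_disorders = 0.01,
                                            antineoplastics = 0.005),
                             age_mean = 58, age_sd = 12,
                             age_range = c(18, 90),
                             prob_male = 0.5,
                             planted_effects = rxtraject::planted_effects(),
                             planted_exclusions = c(antihypertensive = 0,
                                                    cardiac = 0),
                             followup_cap_days = 3780L,
                             index_margin_days = 780L,
                             seed = 1L) {
  stopifnot(n_patients >= 0, length(date_range) == 2)
  date_range <- as.Date(date_range)
  if (!(date_range[1] < date_range[2])) stop("date_range start must precede end")
  if (abs(sum(drug_class_probs) - 1) > 1e-9) {
    stop("drug_class_probs must sum to 1")
  }
  if (abs(sum(pattern_mix) - 1) > 1e-9) {
    stop("pattern_mix must sum to 1")
  }
  need <- c("continuer", "discontinuer", "switcher", "addon", "intermittent")
  if (!setequal(names(pattern_mix), need)) {
    stop("pattern_mix must be named over: ", paste(need, collapse = ", "))
  }
  stopifnot(inherits(planted_effects, "planted_effects"),
            refill_interval_high > 0, refill_interval_low > 0,
            refill_jitter >= 0, all(days_supplied_choices >= 1),
            followup_cap_days > 0, index_margin_days >= 780)
  structure(as.list(environment()), class = "generator_config")
}

# sample() that treats a length-1 x as a constant, not as 1:x
.rsample <- function(x, n, prob = NULL) {
  if (length(x) == 1L) rep(x, n) else sample(x, n, TRUE, prob = prob)
}

# representative full ATC code dispensed for each study class
.class_atc <- c(simvastatin = "C10AA01", pravastatin = "C10AA03",
                fluvastatin = "C10AA04", atorvastatin = "C10AA05",
                rosuvastatin = "C10AA07", fibrates = "C10AB05")

# per-class strength menus (mg per unit) and the default strength used for
# switch / add-on dispensings
.class_strengths <- list(
  simvastatin  = list(mg = c(10, 20, 40), p = c(0.25, 0.55, 0.20), default = 20),
  atorvastatin = list(mg = c(10, 20, 40), p = c(0.40, 0.40, 0.20), default = 20),
  rosuvastatin = list(mg = c(5, 10, 20),  p = c(0.40, 0.40, 0.20), default = 10),
  pravastatin  = list(mg = c(20, 40),     p = c(0.50, 0.50),       default = 40),
  fluvastatin  = list(mg = c(40, 80),     p = c(0.50, 0.50),       default = 80),
  fibrates     = list(mg = 200,           p = 1,                   default = 200)
)

# representative co-medication codes per comorbidity group
.comed_atc <- c(diabetes = "A10BA02", ra = "M01AE01", asthma_copd = "R03AC02",
                antiepileptics = "N03AX09", antiparkinson = "N04BA02",
                psycholeptics = "N05BA01", psychoanaleptics = "N06AB04",
                addictive_disorders = "N07BA01", antineoplastics = "L01XA01")

.empty_dispensing <- function() {
  data.frame(patient_id = character(), date = as.Date(character()),
              atc = character(), strength_mg = numeric(),
              units = numeric(), days_supplied = integer(),
              stringsAsFactors = FALSE)
}

#' Generate a synthetic patient table and dispensing history
#'
#' Simulates `config$n_patients` new users of anti-hyperlipidemic
#' monotherapy with known ground truth. See [generator_config()] for the
#' generative model. The returned ground-truth labels are kept in a separate
#' table and never leak into the analysis inputs.
#'
#' @param config a [generator_config()].
#' @return a list with elements `patients`
#'   (`patient_id, birth_date, sex`), `dispensing`
#'   (`patient_id, date, atc, strength_mg, units, days_supplied`, sorted by
#'   patient and date), and `labels` (ground truth per patient: index date
#'   and class, archetype, latent adherence class, and covariate truth).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(config$n_patients)
  if (n == 0L) {
    return(list(
      patients = data.frame(patient_id = character(),
                            birth_date = as.Date(character()),
                            sex = character(), stringsAsFactors = FALSE),
      dispensing = .empty_dispensing(),
      labels = data.frame(patient_id = character(), stringsAsFactors = FALSE)
    ))
  }
  set.seed(config$seed)
  pe <- config$planted_effects
  start_day <- .day(config$date_range[1])
  end_day <- .day(config$date_range[2])
  last_index <- end_day - config$index_margin_days
  stopifnot(last_index > start_day)

  pid <- sprintf("P%06d", seq_len(n))
  index_day <- start_day + sample.int(last_index - start_day + 1L, n, TRUE) - 1L

  # covariates
  lo <- pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- qnorm(runif(n, lo, hi), config$age_mean, config$age_sd)
  male <- runif(n) < config$prob_male
  comed_names <- names(config$comed_prev)
  comed <- vapply(comed_names,
                  function(nm) runif(n) < config$comed_prev[[nm]],
                  logical(n))
  if (n == 1L) comed <- matrix(comed, nrow = 1, dimnames = list(NULL, comed_names))
  diabetes <- if ("diabetes" %in% comed_names) comed[, "diabetes"] else rep(FALSE, n)

  # index drug class and archetype
  classes <- names(config$drug_class_probs)
  cls <- sample(classes, n, TRUE, prob = config$drug_class_probs)
  arch_names <- c("continuer", "discontinuer", "switcher", "addon", "intermittent")
  mix <- config$pattern_mix[arch_names]
  arch <- character(n)
  for (cl in classes) {
    sel <- cls == cl
    if (!any(sel)) next
    p <- mix
    if (!is.null(pe$class_pattern_or) && cl %in% rownames(pe$class_pattern_or)) {
      p <- p * pe$class_pattern_or[cl, arch_names]
    }
    arch[sel] <- sample(arch_names, sum(sel), TRUE, prob = p / sum(p))
  }

  # latent adherence
  lp <- pe$intercept_logit +
    log(pe$or_male) * male +
    log(pe$or_age_40_69) * (age >= 40 & age < 70) +
    log(pe$or_age_70plus) * (age >= 70) +
    log(pe$or_diabetes) * diabetes
  high <- runif(n) < plogis(lp)

  supply <- if (length(config$days_supplied_choices) > 1L) {
    sample(config$days_supplied_choices, n, TRUE)
  } else rep(as.integer(config$days_supplied_choices), n)
  scale <- supply / 30
  interval <- as.integer(round(
    ifelse(high, config$refill_interval_high, config$refill_interval_low) * scale))
  jit <- as.integer(round(config$refill_jitter * scale))
  horizon <- pmin(end_day - index_day, as.integer(config$followup_cap_days))

  # refill gap matrix -> cumulative refill days (row = patient)
  maxm <- max(ceiling(horizon / pmax(interval - jit, 1L))) + 4L
  jmax <- max(jit)
  jdraw <- if (jmax > 0) sample(-jmax:jmax, n * (maxm - 1L), TRUE) else 0L
  gaps <- matrix(rep(interval, maxm - 1L), nrow = n) + jdraw
  if (jmax > 0) {
    # clamp per-patient jitter to each patient's own +/- jit
    gaps <- pmax(gaps, interval - jit)
    gaps <- pmin(gaps, interval + jit)
  }
  D <- t(apply(cbind(0L, gaps), 1, cumsum))

  # number of index refills per patient
  m_horizon <- rowSums(D <= horizon - 1L)
  m <- m_horizon
  stop_target <- 366L  # first runout strictly past year 1
  is_stop <- arch %in% c("discontinuer", "switcher")
  m_stop <- rowSums(D + supply <= stop_target) + 1L + sample(0:2, n, TRUE)
  # never stop so late that the terminal gap could close below 181 days;
  # the margin allows for up to 90 days of stockpile carryover extending
  # the true runout past the naive last-fill + supply estimate
  m_gap <- rowSums(D + supply + 271L <= horizon)
  m[is_stop] <- pmin(m_stop, m_gap, m_horizon)[is_stop]

  sel_mat <- col(D) <= m
  # intermittent: drop refills inside a 60-110 day hole placed after year 1
  inter <- arch == "intermittent"
  g_len <- sample(60:110, n, TRUE)
  g_upper <- pmin(900L, horizon - g_len - 60L)
  g_start <- 370L + as.integer(floor(runif(n) * (g_upper - 370L + 1L)))
  if (any(inter)) {
    hole <- D[inter, , drop = FALSE] >= g_start[inter] &
      D[inter, , drop = FALSE] < (g_start + g_len)[inter]
    sel_mat[inter, ] <- sel_mat[inter, , drop = FALSE] & !hole
  }

  # switch and add-on events
  is_switch <- arch == "switcher"
  # offsets start at 100 days so the switch fill always lands after the true
  # (carryover-extended, <= +90 days) runout yet within 180 days of it
  disc_runout <- D[cbind(seq_len(n), m)] + supply
  switch_day <- disc_runout + sample(100:166, n, TRUE)
  is_addon <- arch == "addon"
  t_a <- sample(367:600, n, TRUE)
  first_ge <- max.col(sel_mat & D >= t_a, ties.method = "first")
  addon_day <- D[cbind(seq_len(n), first_ge)]

  other_class <- function(idx) {
    # a study class different from the index class, uniformly
    k <- length(classes)
    r <- sample.int(k - 1L, length(idx), TRUE)
    own <- match(cls[idx], classes)
    classes[r + (r >= own)]
  }

  # ---- assemble dispensing rows ----
  rows_pid <- list(); rows_day <- list(); rows_atc <- list()
  rows_mg <- list(); rows_units <- list(); rows_ds <- list()
  push <- function(i, day_abs, atc, mg, units, ds) {
    k <- length(rows_pid) + 1L
    rows_pid[[k]] <<- i; rows_day[[k]] <<- day_abs; rows_atc[[k]] <<- atc
    rows_mg[[k]] <<- mg; rows_units[[k]] <<- units; rows_ds[[k]] <<- ds
  }

  # index drug refills
  sel_idx <- which(sel_mat, arr.ind = TRUE)
  ord <- order(sel_idx[, 1L], sel_idx[, 2L])
  ri <- sel_idx[ord, 1L]
  rday <- D[sel_idx][ord]
  strength <- numeric(n)
  for (cl in classes) {
    s <- .class_strengths[[cl]]
    sel <- cls == cl
    if (any(sel)) strength[sel] <- .rsample(s$mg, sum(sel), prob = s$p)
  }
  push(ri, index_day[ri] + rday, .class_atc[cls[ri]], strength[ri],
       as.numeric(supply[ri]), supply[ri])

  # switch dispensings: 3 fills of the new class starting <= 180 d after the
  # discontinuation runout
  if (any(is_switch)) {
    sw <- which(is_switch)
    tgt <- other_class(sw)
    for (off in c(0L, 30L, 60L)) {
      push(sw, index_day[sw] + switch_day[sw] + off, .class_atc[tgt],
           vapply(tgt, function(cl) .class_strengths[[cl]]$default, 0),
           30, 30L)
    }
  }

  # add-on dispensings: 3 fills of a second class starting on an index refill
  # day (index coverage active by construction)
  if (any(is_addon)) {
    ad <- which(is_addon)
    tgt <- other_class(ad)
    for (off in c(0L, 30L, 60L)) {
      push(ad, index_day[ad] + addon_day[ad] + off, .class_atc[tgt],
           vapply(tgt, function(cl) .class_strengths[[cl]]$default, 0),
           30, 30L)
    }
  }

  # database-presence anchors (non-study analgesic)
  all_i <- seq_len(n)
  push(all_i, index_day - 720L - sample(10:300, n, TRUE), "N02BE01", 500, 20, 10L)
  push(all_i, index_day + 720L + sample(0:60, n, TRUE), "N02BE01", 500, 20, 10L)

  # baseline co-medication dispensings within the first 180 days
  for (nm in comed_names) {
    w <- which(comed[, nm])
    if (length(w)) {
      push(w, index_day[w] + sample(0:179, length(w), TRUE), .comed_atc[[nm]],
           NA_real_, 30, 30L)
    }
  }

  # planted exclusion violations (off by default)
  pex <- config$planted_exclusions
  if (!is.na(pex["antihypertensive"]) && pex[["antihypertensive"]] > 0) {
    w <- which(runif(n) < pex[["antihypertensive"]])
    if (length(w)) push(w, index_day[w] + sample(0:359, length(w), TRUE),
                        "C07AB02", 50, 30, 30L)
  }
  if (!is.na(pex["cardiac"]) && pex[["cardiac"]] > 0) {
    w <- which(runif(n) < pex[["cardiac"]])
    if (length(w)) push(w, index_day[w] + sample(-720:89, length(w), TRUE),
                        "C01DA14", 40, 30, 30L)
  }

  len <- vapply(rows_pid, length, 0L)
  rep_each <- function(lst, lens) unlist(Map(function(x, l) rep_len(x, l), lst, lens),
                                          use.names = FALSE)
  dispensing <- data.frame(
    patient_id = pid[unlist(rows_pid, use.names = FALSE)],
    date = .as_date(unlist(rows_day, use.names = FALSE)),
    atc = rep_each(rows_atc, len),
    strength_mg = rep_each(rows_mg, len),
    units = rep_each(rows_units, len),
    days_supplied = rep_each(rows_ds, len),
    stringsAsFactors = FALSE
  )
  dispensing <- dispensing[order(dispensing$patient_id, dispensing$date), ,
                           drop = FALSE]
  rownames(dispensing) <- NULL

  patients <- data.frame(
    patient_id = pid,
    birth_date = .as_date(index_day - as.integer(round(age * 365.25))),
    sex = ifelse(male, "male", "female"),
    stringsAsFactors = FALSE
  )

  labels <- data.frame(
    patient_id = pid,
    index_date = .as_date(index_day),
    index_class = cls,
    archetype = arch,
    adherence_class = ifelse(high, "high", "low"),
    sex = patients$sex,
    age_at_index = as.integer(floor(age)),
    age_group = as.character(cut(floor(age), c(18, 40, 70, Inf), right = FALSE,
                                 labels = c("18-39", "40-69", "70+"))),
    stringsAsFactors = FALSE
  )
  for (nm in comed_names) labels[[nm]] <- comed[, nm]

  list(patients = patients, dispensing = dispensing, labels = labels)
}

#' Build a deterministic dispensing trace for one trajectory archetype
#'
#' Produces a dispensing-table fragment (days relative to index) whose
#' classification by the pattern module is the named archetype *by
#' construction*: a `continuer` refills to the end of the horizon, a
#' `discontinuer` stops after `stop_after` days leaving a > 180-day gap, a
#' `switcher` additionally receives a different class `switch_offset` days
#' after the discontinuation runout (<= 180), an `addon` receives a second
#' class on an index refill day while covered, and an `intermittent` user
#' has a `gap_len`-day refill hole (<= 180 days, so still a continuation).
#' No randomness: identical arguments give identical fragments.
#'
#' @param archetype one of `continuer`, `discontinuer`, `switcher`, `addon`,
#'   `intermittent`.
#' @param index_atc ATC code of the index drug.
#' @param interval refill interval in days.
#' @param days_supplied supply per fill.
#' @param horizon observation horizon (days after index).
#' @param stop_after target runout day of the final fill for
#'   discontinuer/switcher (must exceed 360 for pattern eligibility).
#' @param switch_offset days after the discontinuation runout at which the
#'   switch target is dispensed (1-180).
#' @param second_atc ATC code of the switch / add-on drug.
#' @param addon_day day of the add-on dispensing; rounded down to the
#'   nearest index refill day so coverage is active.
#' @param gap_start,gap_len the intermittent refill hole.
#' @return a `data.frame` with columns `day`, `atc`, `strength_mg`, `units`,
#'   `days_supplied`.
#' @export
generate_archetype_trace <- function(archetype,
                                     index_atc = "C10AA01",
                                     interval = 30L,
                                     days_supplied = 30L,
                                     horizon = 1080L,
                                     stop_after = 390L,
                                     switch_offset = 60L,
                                     second_atc = "C10AA05",
                                     addon_day = 420L,
                                     gap_start = 450L,
                                     gap_len = 90L) {
  ok <- c("continuer", "discontinuer", "switcher", "addon", "intermittent")
  if (!archetype %in% ok) {
    stop("unknown archetype: ", archetype, " (expected one of ",
         paste(ok, collapse = ", "), ")")
  }
  stopifnot(interval >= 1, days_supplied >= 1, horizon > 540,
            switch_offset >= 1, switch_offset <= 180, gap_len <= 110)
  refills <- seq(0L, horizon - 1L, by = interval)
  runout <- NULL
  if (archetype %in% c("discontinuer", "switcher")) {
    refills <- refills[refills <= stop_after - days_supplied]
    if (max(refills) + days_supplied <= 360) {
      stop("stop_after too early: the final runout must exceed day 360 for ",
           "the trace to stay pattern-eligible")
    }
    # the true runout includes stockpile carryover from early refills
    runout <- max(build_coverage(refills, days_supplied)$end)
    stopifnot(horizon - runout > 180 + switch_offset)
  }
  if (archetype == "intermittent") {
    stopifnot(gap_start > 360, gap_start + gap_len + interval < horizon)
    refills <- refills[!(refills >= gap_start & refills < gap_start + gap_len)]
  }
  day <- refills
  atc <- rep(index_atc, length(refills))
  if (archetype == "switcher") {
    day <- c(day, runout + switch_offset)
    atc <- c(atc, second_atc)
  }
  if (archetype == "addon") {
    stopifnot(addon_day > 360, addon_day < horizon)
    ad <- max(refills[refills <= addon_day])
    if (ad <= 360) stop("addon_day must round down to a refill day past year 1")
    day <- c(day, ad)
    atc <- c(atc, second_atc)
  }
  ord <- order(day)
  data.frame(day = as.integer(day[ord]), atc = atc[ord],
             strength_mg = 20, units = as.numeric(days_supplied),
             days_supplied = as.integer(days_supplied),
             stringsAsFactors = FALSE)
}
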