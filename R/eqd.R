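#' Default equivalent-dose (EQD) tier table
#'
#' Maps (study class, daily dose in mg) to three tiers corresponding to
#' expected LDL-cholesterol reduction bands: `low` (< 30%), `medium`
#' (30-45%) and `high` (> 45%). The shipped cut-offs are a reconstruction
#' from standard statin-intensity banding (e.g., simvastatin 10 mg = low;
#' simvastatin 20-40, atorvastatin 10-20, rosuvastatin 5-10, pravastatin
#' 40-80, fluvastatin 80 = medium; atorvastatin 40-80, rosuvastatin
#' 20-40 = high) and should be overridden when a protocol-specific
#' equivalence table is available. Fibrates have no LDL-equivalence and
#' default to a single `low` tier.
#'
#' @return `data.frame` with columns `class`, `dose_min`, `dose_max`
#'   (mg/day, inclusive) and `tier`.
#' @export
default_eqd_table <- function() {
  tab <- rbind(
    data.frame(class = "simvastatin",  dose_min = 0,  dose_max = 10,  tier = "low"),
    data.frame(class = "simvastatin",  dose_min = 20, dose_max = 40,  tier = "medium"),
    data.frame(class = "atorvastatin", dose_min = 10, dose_max = 20,  tier = "medium"),
    data.frame(class = "atorvastatin", dose_min = 40, dose_max = 80,  tier = "high"),
    data.frame(class = "rosuvastatin", dose_min = 5,  dose_max = 10,  tier = "medium"),
    data.frame(class = "rosuvastatin", dose_min = 20, dose_max = 40,  tier = "high"),
    data.frame(class = "pravastatin",  dose_min = 10, dose_max = 20,  tier = "low"),
    data.frame(class = "pravastatin",  dose_min = 40, dose_max = 80,  tier = "medium"),
    data.frame(class = "fluvastatin",  dose_min = 20, dose_max = 40,  tier = "low"),
    data.frame(class = "fluvastatin",  dose_min = 80, dose_max = 80,  tier = "medium"),
    data.frame(class = "fibrates",     dose_min = 0,  dose_max = Inf, tier = "low")
  )
  validate_eqd_table(tab)
  tab
}

#' @rdname default_eqd_table
#' @param table a candidate EQD table.
#' @export
validate_eqd_table <- function(table) {
  stopifnot(all(c("class", "dose_min", "dose_max", "tier") %in% names(table)),
            all(table$tier %in% c("low", "medium", "high")),
            all(table$dose_min <= table$dose_max))
  for (cl in unique(table$class)) {
    sub <- table[table$class == cl, , drop = FALSE]
    sub <- sub[order(sub$dose_min), , drop = FALSE]
    if (nrow(sub) > 1 &&
        any(sub$dose_min[-1] <= sub$dose_max[-nrow(sub)])) {
      stop("overlapping dose ranges for class ", cl)
    }
    ranks <- match(sub$tier, c("low", "medium", "high"))
    if (is.unsorted(ranks)) stop("tiers not monotone in dose for class ", cl)
  }
  invisible(table)
}

#' Daily dose of a dispensing
#'
#' `strength_mg * units / days_supplied`, in mg per day. Records with a
#' missing strength or unit count cannot be dosed; they return `NA` and the
#' number of such exclusions is attached as `attr(, "n_excluded")`.
#'
#' @param records dispensing rows with `strength_mg`, `units`,
#'   `days_supplied`.
#' @return numeric mg/day vector with an `n_excluded` attribute.
#' @export
daily_dose <- function(records) {
  dose <- records$strength_mg * records$units / records$days_supplied
  structure(dose, n_excluded = sum(is.na(dose)))
}

#' Equivalent-dose tier of a (class, daily dose) pair
#'
#' Looks the dose up in the tier table. Doses above a class's highest range
#' map to `high`, below its lowest to `low`; a dose falling in a gap
#' between ranges takes the tier of the nearest range boundary (ties to the
#' lower tier). Tier assignment is therefore monotone in dose within a
#' class.
#'
#' @param class study class label (vectorised with `dose_mg_day`).
#' @param dose_mg_day daily dose in mg.
#' @param table an EQD table (see [default_eqd_table()]).
#' @return character vector of tiers (`NA` for `NA` doses).
#' @export
eqd_level <- function(class, dose_mg_day, table = default_eqd_table()) {
  n <- max(length(class), length(dose_mg_day))
  class <- rep_len(class, n); dose <- rep_len(dose_mg_day, n)
  unknown <- setdiff(unique(class), unique(table$class))
  if (length(unknown)) stop("class(es) absent from EQD table: ",
                            paste(unknown, collapse = ", "))
  out <- rep(NA_character_, n)
  for (cl in unique(class)) {
    sub <- table[table$class == cl, , drop = FALSE]
    sub <- sub[order(sub$dose_min), , drop = FALSE]
    sel <- which(class == cl & !is.na(dose))
    for (i in sel) {
      d <- dose[i]
      hit <- which(d >= sub$dose_min & d <= sub$dose_max)
      if (length(hit)) {
        out[i] <- sub$tier[hit[1L]]
      } else if (d > max(sub$dose_max)) {
        out[i] <- "high"
      } else if (d < min(sub$dose_min)) {
        out[i] <- "low"
      } else {
        # gap between two ranges: nearest boundary, ties to the lower tier
        below <- max(which(sub$dose_max < d))
        dist_lo <- d - sub$dose_max[below]
        dist_hi <- sub$dose_min[below + 1L] - d
        out[i] <- if (dist_lo <= dist_hi) sub$tier[below] else sub$tier[below + 1L]
      }
    }
  }
  out
}

#' Label a dose-level transition between two regimens
#'
#' Used to stratify switch and add-on events by equivalent-dose movement:
#' the label combines class scope (`same-class` / `cross-class`) with tier
#' direction (`escalation`, `de-escalation`, `same-tier`).
#'
#' @param baseline_class,baseline_tier the baseline regimen.
#' @param new_class,new_tier the switched-to or added regimen.
#' @return character label, e.g. `"cross-class escalation"`.
#' @export
transition_class <- function(baseline_class, baseline_tier,
                             new_class, new_tier) {
  rank <- c(low = 1L, medium = 2L, high = 3L)
  stopifnot(baseline_tier %in% names(rank), new_tier %in% names(rank))
  dir <- sign(rank[[new_tier]] - rank[[baseline_tier]])
  scope <- ifelse(baseline_class == new_class, "same-class", "cross-class")
  move <- c("de-escalation", "same-tier", "escalation")[dir + 2L]
  paste(scope, move)
}
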