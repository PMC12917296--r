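#' Prepare a modelling frame with the study's reference levels
#'
#' Converts cohort columns to factors with the fixed reference structure of
#' the risk-prediction models: treatment reference simvastatin, adherence
#' reference low, sex reference female, age group reference 18-39, calendar
#' period reference 1996-2000; baseline co-medication flags stay logical
#' (reference absent). Columns not present are skipped.
#'
#' @param data cohort-shaped `data.frame`.
#' @return the same `data.frame` with releveled factors.
#' @export
prepare_model_data <- function(data) {
  relevel_to <- function(x, levels) {
    x <- as.character(x)
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad)) stop("unexpected level(s): ", paste(bad, collapse = ", "))
    factor(x, levels = levels)
  }
  if ("index_class" %in% names(data)) {
    lev <- c("simvastatin", "atorvastatin", "fibrates", "fluvastatin",
             "pravastatin", "rosuvastatin")
    data$index_class <- relevel_to(data$index_class,
                                   c(lev, setdiff(unique(data$index_class), lev)))
    data$index_class <- droplevels(data$index_class)
  }
  if ("adherence_level" %in% names(data)) {
    data$adherence_level <- relevel_to(data$adherence_level, c("low", "high"))
  }
  if ("sex" %in% names(data)) {
    data$sex <- relevel_to(data$sex, c("female", "male"))
  }
  if ("age_group" %in% names(data)) {
    data$age_group <- relevel_to(data$age_group, c("18-39", "40-69", "70+"))
  }
  if ("calendar_period" %in% names(data)) {
    data$calendar_period <- relevel_to(
      data$calendar_period, c("1996-2000", "2000-2010", "2010-2020"))
  }
  data
}

#' Default covariate sets for the risk-prediction models
#'
#' The adherence model uses treatment class, sex, age group, the baseline
#' co-medication flags and calendar period; the four pattern models add the
#' year-1 adherence level. Only columns present in `data` are used.
#'
#' @param outcome outcome name.
#' @param data modelling frame.
#' @return character vector of covariate column names.
#' @export
model_covariates <- function(outcome, data) {
  base <- c("index_class", "sex", "age_group",
            grep("^flag_", names(data), value = TRUE), "calendar_period")
  if (!outcome %in% c("high_adherence", "high_adherence_3yr")) {
    base <- c(base[1], "adherence_level", base[-1])
  }
  intersect(unique(base), names(data))
}

#' Split a table into training and test sets
#'
#' Disjoint, exhaustive, seed-reproducible split with
#' `round(ratio * n)` training rows.
#'
#' @param data a `data.frame` with at least 10 rows.
#' @param ratio training fraction (default 0.7).
#' @param seed RNG seed.
#' @return list with `train` and `test`.
#' @export
split_train_test <- function(data, ratio = 0.7, seed = 1L) {
  n <- nrow(data)
  if (n < 10) stop("need at least 10 rows to split, got ", n)
  set.seed(seed)
  idx <- sample.int(n, round(ratio * n))
  list(train = data[idx, , drop = FALSE],
       test = data[-idx, , drop = FALSE])
}

#' Fit a multivariable logistic risk-prediction model
#'
#' Maximum-likelihood logistic regression with Wald 95% confidence
#' intervals on the odds-ratio scale. The outcome column may be logical,
#' 0/1, or a two-level factor (second level = event). Complete separation
#' is detected (non-convergence or absurd coefficient magnitudes) and
#' flagged with a warning rather than silently reported; collinear terms
#' abort with their names.
#'
#' @param data modelling frame (see [prepare_model_data()]).
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate columns; defaults to
#'   [model_covariates()].
#' @param conf_level confidence level for the Wald intervals.
#' @return an object of class `rx_logit`: list with the `glm` fit, a tidy
#'   `table` (`term`, `or`, `ci_lo`, `ci_hi`, `p`), and a `separation`
#'   flag.
#' @export
fit_logistic <- function(data, outcome, covariates = NULL,
                         conf_level = 0.95) {
  if (is.null(covariates)) covariates <- model_covariates(outcome, data)
  y <- data[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("outcome '", outcome, "' is constant; cannot fit")
  }
  df <- data[, covariates, drop = FALSE]
  df$.y <- y
  fml <- reformulate(covariates, ".y")
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("singular design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  separation <- !fit$converged || any(abs(cf[-1]) > 15)
  if (separation) {
    warning("possible complete separation detected; estimates unreliable")
  }
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    term = names(cf),
    or = exp(cf),
    ci_lo = exp(cf - z * se),
    ci_hi = exp(cf + z * se),
    p = 2 * pnorm(-abs(cf / se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(model = fit, table = tab, outcome = outcome,
                 covariates = covariates, separation = separation),
            class = "rx_logit")
}

#' @export
print.rx_logit <- function(x, ...) {
  cat("Logistic risk model for '", x$outcome, "' (n = ",
      length(x$model$y), ")\n", sep = "")
  tab <- x$table
  tab$or <- round(tab$or, 3); tab$ci_lo <- round(tab$ci_lo, 3)
  tab$ci_hi <- round(tab$ci_hi, 3); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

# rank-based AUC; ties count one half (equals exhaustive pairwise
# concordance)
.auc_rank <- function(y, p) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted risk model on a test set
#'
#' AUC by pairwise concordance (ties count one half), and sensitivity and
#' specificity at a probability cutoff. With a single-class test set the
#' AUC is undefined and reported as `NA`.
#'
#' @param fit an `rx_logit`.
#' @param test test `data.frame`.
#' @param cutoff probability cutoff for the binary prediction (default
#'   0.5).
#' @param hl_groups groups for the Hosmer-Lemeshow statistic.
#' @return list with `auc`, `sensitivity`, `specificity`, `cutoff`,
#'   `hosmer_lemeshow` (statistic, df, p_value), `n`.
#' @export
evaluate_model <- function(fit, test, cutoff = 0.5, hl_groups = 10L) {
  stopifnot(inherits(fit, "rx_logit"))
  y <- test[[fit$outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  p <- predict(fit$model, newdata = test, type = "response")
  pred <- as.integer(p >= cutoff)
  sens <- if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_
  spec <- if (any(y == 0)) mean(pred[y == 0] == 0) else NA_real_
  hl <- if (length(unique(y)) == 2) hosmer_lemeshow(y, p, g = hl_groups) else
    list(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  list(auc = .auc_rank(y, p), sensitivity = sens, specificity = spec,
       cutoff = cutoff, hosmer_lemeshow = hl, n = length(y))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Observations are grouped by quantiles of predicted risk (ties kept
#' together; empty groups collapse with a warning). The statistic is
#' `sum((O - E)^2 / (E * (1 - E / n_g)))` over groups, referred to a
#' chi-square distribution with `g - 2` degrees of freedom.
#'
#' @param y 0/1 outcomes.
#' @param p predicted probabilities.
#' @param g requested number of groups (default 10).
#' @return list with `statistic`, `df`, `p_value`, `n_groups`, and the
#'   per-group `table` (n, observed, expected).
#' @export
hosmer_lemeshow <- function(y, p, g = 10L) {
  stopifnot(length(y) == length(p), g >= 2)
  y <- as.integer(y)
  br <- unique(quantile(p, probs = seq(0, 1, length.out = g + 1), names = FALSE))
  if (length(br) - 1 < g) {
    warning("tied predicted risks: grouping reduced to ", length(br) - 1,
            " groups")
  }
  if (length(br) < 2) br <- c(min(p) - 1e-9, max(p) + 1e-9)
  grp <- cut(p, breaks = br, include.lowest = TRUE)
  n_g <- tapply(y, grp, length)
  keep <- !is.na(n_g) & n_g > 0
  O <- tapply(y, grp, sum)[keep]
  E <- tapply(p, grp, sum)[keep]
  n_g <- n_g[keep]
  if (any(n_g < 5)) {
    warning("sparse Hosmer-Lemeshow groups (fewer than 5 observations); ",
            "the chi-square reference is unreliable")
  }
  denom <- E * (1 - E / n_g)
  term <- ifelse(O == E, 0, (O - E)^2 / denom)
  stat <- sum(term)
  df <- max(length(n_g) - 2, 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       n_groups = length(n_g),
       table = data.frame(n = as.vector(n_g), observed = as.vector(O),
                          expected = as.vector(E)))
}

#' Lasso logistic regression with cross-validated penalty
#'
#' L1-penalised logistic path on the standardised dummy-coded design;
#' the penalty is chosen by k-fold cross-validated deviance (seeded folds)
#' unless a numeric `lambda` is supplied. The covariates with any selected
#' dummy are then refit unpenalised for interpretable odds ratios; an
#' all-zero selection yields an intercept-only report.
#'
#' @inheritParams fit_logistic
#' @param nfolds cross-validation folds (default 10).
#' @param seed fold seed.
#' @param lambda `"lambda.min"`, `"lambda.1se"`, or a fixed numeric value.
#' @return list with `selected` (covariate names), `lambda`, the `cv`
#'   object (when cross-validated) and `fit` (an `rx_logit` refit, or
#'   `NULL` for an empty selection).
#' @export
fit_lasso <- function(data, outcome, covariates = NULL, nfolds = 10L,
                      seed = 1L, lambda = "lambda.min") {
  if (is.null(covariates)) covariates <- model_covariates(outcome, data)
  y <- data[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  x <- model.matrix(reformulate(covariates), data = data)[, -1, drop = FALSE]
  cvfit <- NULL
  if (is.numeric(lambda)) {
    gfit <- glmnet::glmnet(x, y, family = "binomial", standardize = TRUE)
    beta <- as.matrix(coef(gfit, s = lambda, exact = TRUE, x = x, y = y,
                           family = "binomial", standardize = TRUE))
    lam <- lambda
  } else {
    set.seed(seed)
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", nfolds = nfolds,
                               type.measure = "deviance", standardize = TRUE)
    lam <- cvfit[[lambda]]
    beta <- as.matrix(coef(cvfit, s = lambda))
  }
  nz <- rownames(beta)[beta[, 1] != 0]
  nz <- setdiff(nz, "(Intercept)")
  assign_map <- attr(model.matrix(reformulate(covariates), data = data),
                     "assign")[-1]
  colnames_x <- colnames(x)
  sel_cov <- unique(covariates[assign_map[match(nz, colnames_x)]])
  refit <- if (length(sel_cov)) {
    fit_logistic(data, outcome, covariates = sel_cov)
  } else NULL
  list(selected = sel_cov, lambda = lam, cv = cvfit, fit = refit)
}

#' Build the 3-year adherence-transition dataset
#'
#' Subjects: cohort entries whose overall database records span more than
#' `window_years` (3) years after index while their time on the original
#' monotherapy is at most that long. Everyone enters in the low-adherence
#' state; the event is the transition to high adherence, timed at the end
#' of the first 360-day year with adherence at or above the threshold.
#' Subjects without such a year are censored at the end of persistence.
#'
#' @inheritParams adherence_profiles
#' @param profiles output of [adherence_profiles()].
#' @param window_years analysis window (default 3).
#' @return `data.frame` with `patient_id`, `time` (days), `event` (0/1)
#'   and the entry covariates.
#' @export
build_transition_data <- function(entries, profiles, patterns,
                                  config = cohort_config(),
                                  window_years = 3L) {
  yd <- config$year_days
  wd <- window_years * yd
  per <- patterns$persistence_days[match(entries$patient_id,
                                         patterns$patient_id)]
  keep <- entries$record_span_days > wd & per <= wd
  sub <- entries[keep, , drop = FALSE]
  per <- per[keep]
  pr <- profiles[profiles$patient_id %in% sub$patient_id &
                   profiles$year <= window_years & profiles$high, , drop = FALSE]
  first_high <- tapply(pr$year, pr$patient_id, min)
  k <- first_high[match(sub$patient_id, names(first_high))]
  event <- !is.na(k)
  time <- ifelse(event, as.numeric(k) * yd, pmax(per, 1))
  out <- sub
  out$time <- time
  out$event <- as.integer(event)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier curve of remaining in low adherence
#'
#' Product-limit estimate of the probability of not yet having transitioned
#' to high adherence, per treatment class (or overall when `by_class =
#' FALSE`).
#'
#' @param transitions output of [build_transition_data()].
#' @param by_class stratify by `index_class`.
#' @return `data.frame` with `class`, `time`, `n_risk`, `n_event`,
#'   `survival`; the underlying `survfit` object is attached as
#'   `attr(, "survfit")`.
#' @export
km_low_adherence <- function(transitions, by_class = TRUE) {
  fml <- if (by_class && length(unique(transitions$index_class)) > 1) {
    survival::Surv(time, event) ~ index_class
  } else survival::Surv(time, event) ~ 1
  sf <- survival::survfit(fml, data = transitions)
  strata <- if (is.null(sf$strata)) {
    rep("overall", length(sf$time))
  } else {
    rep(sub("^index_class=", "", names(sf$strata)), sf$strata)
  }
  out <- data.frame(class = strata, time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, survival = sf$surv,
                    stringsAsFactors = FALSE)
  attr(out, "survfit") <- sf
  out
}

# weighted / unweighted standardized mean difference of a numeric column
# across treatment groups: maximum over all group pairs
.smd_max <- function(x, g, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  lv <- unique(g)
  m <- v <- numeric(length(lv))
  for (i in seq_along(lv)) {
    sel <- g == lv[i]
    wi <- w[sel]; xi <- x[sel]
    m[i] <- sum(wi * xi) / sum(wi)
    v[i] <- sum(wi * (xi - m[i])^2) / sum(wi)
  }
  best <- 0
  for (i in seq_along(lv)) for (j in seq_len(i - 1)) {
    denom <- sqrt((v[i] + v[j]) / 2)
    d <- if (denom == 0) 0 else abs(m[i] - m[j]) / denom
    best <- max(best, d)
  }
  best
}

#' Stabilised inverse-probability-of-treatment weights
#'
#' Multinomial-logistic propensity model for treatment class given baseline
#' covariates; stabilised weights are the marginal class probability
#' divided by the fitted conditional probability, truncated at configurable
#' percentiles. Classes with fewer than 25 subjects are flagged as having
#' unstable propensities. Post-weighting covariate balance is reported as
#' maximum pairwise standardised mean differences per design column.
#'
#' @param data modelling frame.
#' @param treatment treatment column name (a factor or character with at
#'   least 2 classes).
#' @param covariates baseline covariate columns.
#' @param truncate lower/upper weight-truncation percentiles.
#' @return list with `weights`, `smd` (covariate, unweighted, weighted),
#'   `model` and `flagged_classes`.
#' @export
ipw_weights <- function(data, treatment = "index_class", covariates,
                        truncate = c(0.01, 0.99)) {
  g <- factor(data[[treatment]])
  g <- droplevels(g)
  small <- names(which(table(g) < 25))
  if (length(small)) {
    warning("treatment class(es) with fewer than 25 subjects; propensities ",
            "unstable: ", paste(small, collapse = ", "))
  }
  df <- data[, covariates, drop = FALSE]
  df$.treat <- g
  fit <- nnet::multinom(reformulate(covariates, ".treat"), data = df,
                        trace = FALSE, maxit = 500, MaxNWts = 5000)
  pr <- fitted(fit)
  if (is.null(dim(pr)) || ncol(pr) == 1) {
    # two classes: multinom returns P(second level) only
    pr <- cbind(1 - as.numeric(pr), as.numeric(pr))
    colnames(pr) <- levels(g)
  }
  p_own <- pr[cbind(seq_along(g), match(as.character(g), colnames(pr)))]
  marg <- prop.table(table(g))
  w <- as.numeric(marg[as.character(g)]) / p_own
  lim <- quantile(w, truncate)
  w <- pmin(pmax(w, lim[1]), lim[2])

  xm <- model.matrix(reformulate(covariates), data = df)[, -1, drop = FALSE]
  smd <- data.frame(
    covariate = colnames(xm),
    unweighted = apply(xm, 2, .smd_max, g = g),
    weighted = apply(xm, 2, .smd_max, g = g, w = w),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(weights = w, smd = smd, model = fit, flagged_classes = small)
}

#' IPW-adjusted Cox regression of the adherence transition
#'
#' Weighted Cox partial-likelihood fit of transition to high adherence on
#' treatment class (reference simvastatin), with robust (sandwich)
#' standard errors. `time_dependent = TRUE` adds treatment-by-log(time)
#' interactions to probe non-proportional hazards; a Schoenfeld-residual
#' diagnostic (`survival::cox.zph`) is attached in either mode. Classes
#' with no events get `NA` hazard ratios.
#'
#' @param data output of [build_transition_data()], passed through
#'   [prepare_model_data()] so that simvastatin is the reference.
#' @param weights observation weights (e.g., from [ipw_weights()]); `NULL`
#'   for a crude fit.
#' @param time_dependent add treatment-by-log(time) interactions.
#' @return an object of class `rx_cox`: list with the `coxph` fit, a tidy
#'   `table` (`term`, `hr`, `ci_lo`, `ci_hi`, `p`), and `zph`.
#' @export
fit_cox_ipw <- function(data, weights = NULL, time_dependent = FALSE) {
  stopifnot(all(c("time", "event", "index_class") %in% names(data)))
  stopifnot(all(data$time > 0))
  data <- prepare_model_data(data)
  data$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  if (time_dependent) {
    fit <- survival::coxph(
      survival::Surv(time, event) ~ index_class + tt(index_class),
      data = data, weights = .w, robust = TRUE,
      tt = function(x, t, ...) {
        mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
        colnames(mm) <- paste0(sub("^x", "", colnames(mm)), ":log(t)")
        mm * log(t)
      })
  } else {
    fit <- survival::coxph(survival::Surv(time, event) ~ index_class,
                           data = data, weights = .w, robust = TRUE)
  }
  sm <- summary(fit)
  cf <- sm$coefficients
  se <- cf[, "robust se"]
  est <- cf[, "coef"]
  z <- qnorm(0.975)
  term <- rownames(cf)
  # normalise time-transform names: coxph drops the column label when the
  # tt() matrix has a single column
  is_tt <- grepl("^tt\\(", term)
  term[is_tt] <- sub("^tt\\(([^)]*)\\)", "\\1", term[is_tt])
  fixup <- is_tt & !grepl(":log\\(t\\)$", term)
  term[fixup] <- paste0(term[fixup], ":log(t)")
  tab <- data.frame(term = term, hr = exp(est),
                    ci_lo = exp(est - z * se), ci_hi = exp(est + z * se),
                    p = 2 * pnorm(-abs(est / se)),
                    row.names = NULL, stringsAsFactors = FALSE)
  # classes without events cannot support a hazard ratio
  ev_by_class <- tapply(data$event, data$index_class, sum)
  none <- names(ev_by_class)[!is.na(ev_by_class) & ev_by_class == 0]
  for (cl in none) {
    tab[grepl(cl, tab$term, fixed = TRUE),
        c("hr", "ci_lo", "ci_hi", "p")] <- NA_real_
  }
  zph <- tryCatch(survival::cox.zph(fit, transform = "log"),
                  error = function(e) NULL)
  structure(list(model = fit, table = tab, zph = zph,
                 time_dependent = time_dependent),
            class = "rx_cox")
}

#' @export
print.rx_cox <- function(x, ...) {
  cat("IPW/weighted Cox model",
      if (x$time_dependent) "(with treatment-by-log(time) effects)", "\n")
  tab <- x$table
  tab$hr <- round(tab$hr, 3); tab$ci_lo <- round(tab$ci_lo, 3)
  tab$ci_hi <- round(tab$ci_hi, 3); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
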