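sim_logit_frame <- function(n, beta_male = 0, seed = 1) {
  set.seed(seed)
  sex <- ifelse(runif(n) < 0.5, "male", "female")
  p <- plogis(0.3 + beta_male * (sex == "male"))
  data.frame(sex = factor(sex, levels = c("female", "male")),
             y = as.integer(runif(n) < p), stringsAsFactors = FALSE)
}

test_that("the 7:3 split is exhaustive, disjoint and seed-stable", {
  df <- data.frame(i = 1:10)
  sp <- split_train_test(df, seed = 4)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  expect_setequal(c(sp$train$i, sp$test$i), 1:10)
  sp2 <- split_train_test(df, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_train_test(df[1:5, , drop = FALSE]), "at least 10")
})

test_that("logistic fits recover effects and flag degenerate designs", {
  df <- sim_logit_frame(6000, beta_male = log(2), seed = 9)
  fit <- fit_logistic(df, "y", covariates = "sex")
  or <- fit$table$or[fit$table$term == "sexmale"]
  expect_lt(abs(log(or) - log(2)), 0.2)
  expect_true(all(fit$table$ci_lo <= fit$table$or &
                    fit$table$or <= fit$table$ci_hi))

  df$y <- 1L
  expect_error(fit_logistic(df, "y", covariates = "sex"), "constant")

  df <- sim_logit_frame(200, seed = 9)
  df$sex2 <- df$sex
  expect_error(fit_logistic(df, "y", covariates = c("sex", "sex2")),
               "collinear")

  # perfectly separated outcome
  df <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                   y = c(rep(0, 20), rep(1, 20)))
  expect_warning(fit_logistic(df, "y", covariates = "x"), "separation")
})

test_that("re-levelling the treatment factor flips log-odds consistently", {
  set.seed(12)
  n <- 3000
  cls <- sample(c("simvastatin", "atorvastatin", "pravastatin"), n, TRUE)
  sexv <- sample(c("female", "male"), n, TRUE)
  p <- plogis(0.2 + 0.4 * (cls == "atorvastatin") - 0.2 * (sexv == "male"))
  df <- data.frame(index_class = cls, sex = sexv,
                   y = as.integer(runif(n) < p), stringsAsFactors = FALSE)
  d1 <- prepare_model_data(df)
  f1 <- fit_logistic(d1, "y", covariates = c("index_class", "sex"))
  d2 <- d1
  d2$index_class <- stats::relevel(d2$index_class, ref = "atorvastatin")
  f2 <- fit_logistic(d2, "y", covariates = c("index_class", "sex"))
  b1 <- log(f1$table$or[f1$table$term == "index_classatorvastatin"])
  b2 <- log(f2$table$or[f2$table$term == "index_classsimvastatin"])
  expect_equal(b1, -b2, tolerance = 1e-6)
})

test_that("AUC equals exhaustive pairwise concordance, with tie handling", {
  # perfectly separating score
  y <- c(0, 0, 0, 1, 1); p <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  expect_equal(rxtraject:::.auc_rank(y, p), 1)
  # six-row toy with a tie, against the exhaustive oracle
  y <- c(0, 1, 0, 1, 1, 0); p <- c(0.2, 0.2, 0.5, 0.7, 0.5, 0.1)
  expect_equal(rxtraject:::.auc_rank(y, p), oracle_auc(y, p))
  # random tables up to n = 50
  set.seed(5)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- sample(seq(0, 1, 0.1), n, TRUE)  # coarse grid forces ties
    expect_equal(rxtraject:::.auc_rank(y, p), oracle_auc(y, p),
                 info = sprintf("case %d", i))
  }
  # score independent of outcome
  set.seed(6)
  y <- rbinom(4000, 1, 0.5); p <- runif(4000)
  expect_lt(abs(rxtraject:::.auc_rank(y, p) - 0.5), 0.04)
})

test_that("model evaluation reports cutoff metrics and handles one-class sets", {
  df <- sim_logit_frame(2000, beta_male = log(3), seed = 10)
  sp <- split_train_test(df, seed = 2)
  fit <- fit_logistic(sp$train, "y", covariates = "sex")
  ev <- suppressWarnings(evaluate_model(fit, sp$test))
  expect_true(ev$auc > 0.4 && ev$auc <= 1)
  expect_true(ev$sensitivity >= 0 && ev$sensitivity <= 1)
  expect_equal(ev$cutoff, 0.5)

  one <- sp$test
  one$y <- 1L
  ev1 <- suppressWarnings(evaluate_model(fit, one))
  expect_true(is.na(ev1$auc))
})

test_that("Hosmer-Lemeshow matches hand arithmetic and flags sparse groups", {
  # perfect calibration in every group -> statistic 0, p = 1
  y <- c(rep(c(0, 0, 0, 0, 1), 4), rep(c(0, 1, 1, 1, 1), 4))
  p <- c(rep(0.2, 20), rep(0.8, 20))
  hl <- hosmer_lemeshow(y, p, g = 2)
  expect_equal(hl$statistic, 0)
  expect_equal(hl$p_value, 1)

  # two-group toy, hand arithmetic:
  # group 1: n=4, O=2, E=1.2 -> 0.8^2 / (1.2 * (1 - 0.3)) = 0.7619048
  # group 2: n=4, O=3, E=2.8 -> 0.2^2 / (2.8 * (1 - 0.7)) = 0.0476190
  y <- c(1, 0, 0, 1, 1, 1, 0, 1)
  p <- c(rep(0.3, 4), rep(0.7, 4))
  hl <- suppressWarnings(hosmer_lemeshow(y, p, g = 2))
  expect_equal(hl$statistic, 0.8^2 / (1.2 * 0.7) + 0.2^2 / (2.8 * 0.3),
               tolerance = 1e-12)

  # sparse groups produce a warning
  set.seed(3)
  y <- rbinom(30, 1, 0.5); p <- runif(30)
  expect_warning(hosmer_lemeshow(y, p, g = 10), "sparse")
  # heavy ties collapse groups with a warning
  expect_warning(hosmer_lemeshow(rep(c(0, 1), 50), rep(0.5, 100), g = 10),
                 "reduced")
})

test_that("lasso limits: no penalty keeps all terms, heavy penalty none", {
  set.seed(8)
  n <- 1500
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  p <- plogis(0.2 + 0.8 * df$x1 - 0.6 * df$x2)
  df$y <- as.integer(runif(n) < p)
  res0 <- fit_lasso(df, "y", covariates = c("x1", "x2", "x3"), lambda = 1e-7)
  expect_setequal(res0$selected, c("x1", "x2", "x3"))
  ref <- fit_logistic(df, "y", covariates = c("x1", "x2", "x3"))
  expect_equal(log(res0$fit$table$or), log(ref$table$or), tolerance = 1e-4)

  res_inf <- fit_lasso(df, "y", covariates = c("x1", "x2", "x3"), lambda = 10)
  expect_length(res_inf$selected, 0)
  expect_null(res_inf$fit)
})

test_that("cross-validated lasso keeps planted signals", {
  # 3 true effects among 12 covariates; selection repeated over replicates
  hits <- 0L
  reps <- 15L
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    n <- 2500
    x <- matrix(rnorm(n * 12), n)
    colnames(x) <- paste0("x", 1:12)
    p <- plogis(0.1 + 0.7 * x[, 1] - 0.7 * x[, 2] + 0.5 * x[, 3])
    df <- data.frame(x, y = as.integer(runif(n) < p))
    res <- fit_lasso(df, "y", covariates = colnames(x), seed = r)
    if (all(c("x1", "x2", "x3") %in% res$selected)) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * reps))
})

test_that("Kaplan-Meier estimates equal the manual product-limit", {
  tr <- data.frame(index_class = "simvastatin",
                   time = c(360, 360, 720, 720, 1080),
                   event = c(1, 0, 1, 0, 0))
  km <- km_low_adherence(tr)
  man <- oracle_km(tr$time, tr$event)
  got <- km[km$n_event > 0, c("time", "survival")]
  rownames(got) <- NULL
  expect_equal(got, man, tolerance = 1e-12, ignore_attr = TRUE)

  # no events -> flat at 1
  tr$event <- 0
  km <- km_low_adherence(tr)
  expect_true(all(km$survival == 1))

  # all events at one time -> step to 0
  tr <- data.frame(index_class = "simvastatin", time = 100, event = 1)
  tr <- tr[rep(1, 6), ]
  km <- km_low_adherence(tr)
  expect_equal(km$survival[km$time == 100], 0)

  # a larger toy (<= 10 subjects) with mixed censoring
  tr <- data.frame(index_class = "simvastatin",
                   time = c(50, 120, 120, 200, 260, 260, 300, 310, 420, 500),
                   event = c(1, 1, 0, 0, 1, 1, 0, 1, 0, 0))
  km <- km_low_adherence(tr)
  man <- oracle_km(tr$time, tr$event)
  got <- km[km$n_event > 0, c("time", "survival")]
  rownames(got) <- NULL
  expect_equal(got, man, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("stabilised IPW weights behave under the null and balance confounding", {
  set.seed(14)
  n <- 4000
  # null: covariate unrelated to treatment
  df <- data.frame(index_class = sample(c("simvastatin", "atorvastatin",
                                          "pravastatin"), n, TRUE),
                   sex = sample(c("female", "male"), n, TRUE),
                   stringsAsFactors = FALSE)
  w <- ipw_weights(prepare_model_data(df), covariates = "sex")
  expect_lt(abs(mean(w$weights) - 1), 0.02)
  expect_lt(max(abs(w$weights - 1)), 0.25)
  # stabilisation: weights sum per class close to the class size
  for (cl in unique(df$index_class)) {
    sel <- df$index_class == cl
    expect_lt(abs(sum(w$weights[sel]) / sum(sel) - 1), 0.05)
  }

  # planted confounding: z raises both treatment probability and outcome
  z <- rbinom(n, 1, 0.5)
  cls <- ifelse(runif(n) < plogis(-1.2 + 2.2 * z), "atorvastatin",
                "simvastatin")
  df2 <- data.frame(index_class = cls, z = z,
                    time = rexp(n, 0.002 * exp(0.8 * z)), event = 1L)
  df2$time <- pmin(df2$time, 1500)
  df2$event[df2$time == 1500] <- 0L
  w2 <- ipw_weights(prepare_model_data(df2), covariates = "z")
  smd <- w2$smd
  expect_lt(smd$weighted, smd$unweighted)

  crude <- fit_cox_ipw(df2)
  adj <- fit_cox_ipw(df2, weights = w2$weights)
  hr_crude <- crude$table$hr[1]
  hr_adj <- adj$table$hr[1]
  # truth: no treatment effect; weighting must remove most of the bias
  expect_lt(abs(log(hr_adj)), abs(log(hr_crude)))
  expect_lt(abs(log(hr_adj)), 0.15)

  # small classes are flagged
  df$index_class[1:10] <- "fluvastatin"
  expect_warning(ipw_weights(prepare_model_data(df), covariates = "sex"),
                 "fewer than 25")
})

test_that("weighted Cox under the null gives a hazard ratio near 1", {
  set.seed(15)
  n <- 3000
  df <- data.frame(index_class = rep(c("simvastatin", "atorvastatin"),
                                     each = n / 2),
                   time = rexp(n, 0.003), event = 1L)
  df$event[df$time > 900] <- 0L
  df$time <- pmin(df$time, 900)
  fit <- fit_cox_ipw(df)
  tab <- fit$table
  expect_lt(abs(log(tab$hr[1])), 0.15)
  expect_true(tab$ci_lo[1] < 1 & tab$ci_hi[1] > 1)
  # time-dependent mode adds treatment-by-log(time) terms
  fit_td <- fit_cox_ipw(df, time_dependent = TRUE)
  expect_true(any(grepl("log\\(t\\)", fit_td$table$term)))

  # a class without events reports NA hazard ratios
  df2 <- df
  df2$event[df2$index_class == "atorvastatin"] <- 0L
  fit2 <- suppressWarnings(fit_cox_ipw(df2))
  expect_true(is.na(fit2$table$hr[grepl("atorvastatin", fit2$table$term)]))
})

test_that("the transition dataset times events at the first high year", {
  pop <- generate_population(generator_config(n_patients = 500, seed = 71))
  pl <- run_pipeline(pop$dispensing, pop$patients)
  tr <- build_transition_data(pl$cohort, pl$adherence, pl$patterns)
  expect_true(all(tr$time > 0))
  expect_true(all(tr$time[tr$event == 1] %in% c(360, 720, 1080)))
  # subjects must have records beyond 3 years but persistence within it
  per <- pl$patterns$persistence_days[match(tr$patient_id,
                                            pl$patterns$patient_id)]
  expect_true(all(per <= 1080))
  span <- pl$cohort$record_span_days[match(tr$patient_id,
                                           pl$cohort$patient_id)]
  expect_true(all(span > 1080))
})
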