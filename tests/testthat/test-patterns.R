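classify_trace <- function(records, entry, cfg = cohort_config()) {
  classify_patterns_all(entry, records, config = cfg)
}

test_that("discontinuation requires a gap strictly longer than 180 days", {
  ent <- make_entry(horizon = 700L)
  base_days <- seq(0, 360, 30)  # runout at day 390

  # next fill 180 days after runout: gap == 180 -> no discontinuation
  rec <- make_records("T1", ent$index_date, c(base_days, 390 + 180), "C10AA01")
  r <- classify_trace(rec, ent)
  expect_false(r$discontinuation)

  # next fill 181 days after runout -> discontinuation at the runout
  rec <- make_records("T1", ent$index_date, c(base_days, 390 + 181), "C10AA01")
  r <- classify_trace(rec, ent)
  expect_true(r$discontinuation)
  expect_equal(r$disc_day, 390)

  # uninterrupted refills to the end -> nothing
  rec <- make_records("T1", ent$index_date, seq(0, 690, 30), "C10AA01")
  r <- classify_trace(rec, ent)
  expect_true(r$continuation)
  expect_false(any(r$discontinuation, r$switch, r$add_on))
})

test_that("a switch must land within 180 days after the discontinuation", {
  ent <- make_entry(horizon = 1080L)
  base_days <- seq(0, 360, 30)  # runout 390

  rec <- rbind(make_records("T1", ent$index_date, base_days, "C10AA01"),
               make_records("T1", ent$index_date, 390 + 180, "C10AA05"))
  r <- classify_trace(rec, ent)
  expect_true(r$switch)
  expect_equal(r$switch_day, 570)
  expect_equal(r$switch_target, "atorvastatin")
  expect_true(r$discontinuation)  # switch implies discontinuation

  rec <- rbind(make_records("T1", ent$index_date, base_days, "C10AA01"),
               make_records("T1", ent$index_date, 390 + 181, "C10AA05"))
  r <- classify_trace(rec, ent)
  expect_true(r$discontinuation)
  expect_false(r$switch)

  # no discontinuation -> no switch regardless of other dispensings after
  # coverage (fills continue; other drug appears during a short mid-gap)
  rec <- rbind(make_records("T1", ent$index_date, seq(0, 1050, 30), "C10AA01"),
               make_records("T1", ent$index_date, 500, "C10BX01"))
  r <- classify_trace(rec, ent)
  expect_false(r$switch)
  expect_true(r$add_on)  # fixed combination during coverage is an add-on
  expect_equal(r$addon_class, "fixed_combination")
})

test_that("add-on needs active coverage under the strict default", {
  ent <- make_entry(horizon = 800L)
  # fills every 90 days with 30-day supplies: 60-day holes, discontinuation
  # only at the terminal runout (390)
  days <- seq(0, 360, 90)
  rec0 <- make_records("T1", ent$index_date, days, "C10AA01")

  # during a mid-treatment hole (day 70): not covered -> no add-on
  rec <- rbind(rec0, make_records("T1", ent$index_date, 70, "C10AA05"))
  r <- classify_trace(rec, ent)
  expect_false(r$add_on)
  # the permissive convention counts it
  r2 <- classify_patterns_all(ent, rec,
                              config = cohort_config(addon_requires_coverage = FALSE))
  expect_true(r2$add_on)

  # during coverage (day 95, inside [90, 120)) -> add-on
  rec <- rbind(rec0, make_records("T1", ent$index_date, 95, "C10AA05"))
  r <- classify_trace(rec, ent)
  expect_true(r$add_on)
  expect_equal(r$addon_day, 95)
  expect_equal(r$addon_class, "atorvastatin")
})

test_that("classification ignores dispensings beyond the horizon", {
  ent <- make_entry(horizon = 720L)
  rec <- make_records("T1", ent$index_date, seq(0, 690, 30), "C10AA01")
  r0 <- classify_trace(rec, ent)
  rec2 <- rbind(rec,
                make_records("T1", ent$index_date, c(750, 900), "C10AA05"))
  r1 <- classify_trace(rec2, ent)
  expect_equal(r0[, c("continuation", "discontinuation", "switch", "add_on")],
               r1[, c("continuation", "discontinuation", "switch", "add_on")])
})

test_that("interval classification equals the day-level brute-force scan", {
  set.seed(77)
  cfg <- cohort_config()
  for (i in 1:200) {
    horizon <- sample(c(800L, 1080L, 1440L), 1)
    supply <- sample(15:45, 1)
    gaps <- sample(c(20:70, 160:260), sample(6:14, 1), replace = TRUE)
    days <- cumsum(c(0, gaps))
    days <- days[days < horizon - 50]
    n_oth <- sample(0:4, 1)
    oth_days <- sort(sample(0:(horizon - 1), n_oth))
    ent <- make_entry(horizon = horizon)
    rec <- rbind(
      make_records("T1", ent$index_date, days, "C10AA01", supply),
      if (n_oth) make_records("T1", ent$index_date, oth_days, "C10AA05", 30)
    )
    got <- classify_trace(rec, ent, cfg)
    want <- oracle_patterns(days, supply, oth_days, horizon,
                            cap = cfg$stockpile_cap_days)
    for (f in c("discontinuation", "switch", "add_on", "continuation",
                "eligible")) {
      expect_equal(got[[f]], want[[f]],
                   info = sprintf("case %d field %s", i, f))
    }
    expect_equal(got$persistence_days, want$persistence_days,
                 info = sprintf("case %d persistence", i))
    if (want$discontinuation) expect_equal(got$disc_day, want$disc_day)
    if (want$switch) expect_equal(got$switch_day, want$switch_day)
    if (want$add_on) expect_equal(got$addon_day, want$addon_day)
  }
})

test_that("flag implications hold on generated cohorts", {
  pop <- generate_population(generator_config(n_patients = 600, seed = 51))
  pl <- run_pipeline(pop$dispensing, pop$patients)
  p <- pl$patterns
  expect_true(all(!p$switch | p$discontinuation))
  expect_true(all(!p$continuation |
                    (!p$discontinuation & !p$switch & !p$add_on)))
  # continuation and discontinuation are disjoint
  expect_equal(sum(p$continuation & p$discontinuation), 0)
})

test_that("the gap convention can be switched to last-dispensing mode", {
  ent <- make_entry(horizon = 700L)
  # fills to day 360 (runout 390); next fill at day 545:
  # runout gap = 155 (no discontinuation), dispensing gap = 185 (yes);
  # the 700-day horizon keeps the terminal gap after day 545 short
  rec <- make_records("T1", ent$index_date, c(seq(0, 360, 30), 545), "C10AA01")
  r_runout <- classify_trace(rec, ent)
  expect_false(r_runout$discontinuation)
  r_disp <- classify_patterns_all(
    ent, rec, config = cohort_config(gap_from_runout = FALSE))
  expect_true(r_disp$discontinuation)
})

test_that("pattern rate table formats counts and percentages", {
  ids <- sprintf("X%03d", 1:10)
  ass <- data.frame(
    patient_id = ids,
    continuation = c(rep(TRUE, 3), rep(FALSE, 7)),
    discontinuation = c(rep(FALSE, 3), rep(TRUE, 6), FALSE),
    switch = c(rep(FALSE, 3), rep(TRUE, 2), rep(FALSE, 5)),
    add_on = c(rep(FALSE, 8), TRUE, FALSE),
    eligible = TRUE, stringsAsFactors = FALSE
  )
  ent <- data.frame(patient_id = ids,
                    index_class = rep(c("simvastatin", "fibrates"), 5),
                    stringsAsFactors = FALSE)
  tab <- pattern_rate_table(ass, ent)
  ov <- tab[tab$class == "Overall", ]
  expect_equal(ov$n[ov$pattern == "continuation"], 3)
  expect_equal(ov$label[ov$pattern == "continuation"], "3 (30.0%)")
  expect_equal(ov$label[ov$pattern == "discontinuation"], "6 (60.0%)")
  # ineligible rows are excluded from the denominator
  ass$eligible[1] <- FALSE
  tab2 <- pattern_rate_table(ass, ent)
  expect_equal(tab2$N[tab2$class == "Overall"][1], 9)
  # empty class
  tab3 <- pattern_rate_table(ass, ent, class_order = c("simvastatin",
                                                       "fibrates",
                                                       "rosuvastatin"))
  ros <- tab3[tab3$class == "rosuvastatin", ]
  expect_true(all(ros$N == 0))
  expect_true(all(is.na(ros$pct)))
})
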