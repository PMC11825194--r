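test_that("dose levels resolve weights through the fallback chain", {
  expect_equal(dose_level(350, 70), 5)
  expect_equal(dose_level(525, 70), 7.5)
  expect_error(dose_level(0, 70), "dose_mg")
  expect_error(dose_level(350, NA), "weight_kg")

  inf <- make_infusions(c(0, 14, 42), dose_mg = c(400, 400, 400),
                        weight_kg = c(80, NA, 79))
  out <- resolve_dose_levels(inf)
  expect_equal(out$dose_mg_kg, c(5, 5, round(400 / 79, 2)))
  # leading missing weight falls back to the first recorded weight
  inf2 <- make_infusions(c(0, 14), dose_mg = 400, weight_kg = c(NA, 80))
  expect_equal(resolve_dose_levels(inf2)$dose_mg_kg, c(5, 5))
  inf3 <- make_infusions(c(0, 14), weight_kg = NA)
  expect_error(resolve_dose_levels(inf3), "no recorded weight")
})

test_that("worked escalation examples fire the intended thresholds", {
  # interval decrease 8 -> 6 weeks at constant dose: low only
  ev <- detect_dose_optimizations(make_history(c(70, 126, 182, 224)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$trigger, "interval")
  expect_equal(ev$date, day0 + 224)
  expect_equal(ev$prior_interval_days, 56)
  expect_equal(ev$posterior_interval_days, 42)
  expect_true(ev$meets_low); expect_false(ev$meets_high)

  # dose increase 5 -> 7.5 mg/kg at constant interval: low only
  ev <- detect_dose_optimizations(
    make_history(c(70, 126, 182), levels_mg_kg = c(5, 5, 7.5)))
  expect_equal(ev$trigger, "dose")
  expect_equal(ev$date, day0 + 182)
  expect_equal(ev$posterior_dose_mg_kg, 7.5)
  expect_true(ev$meets_low); expect_false(ev$meets_high)

  # interval 8 -> 4 weeks, and dose 5 -> 10 mg/kg: high threshold
  ev <- detect_dose_optimizations(make_history(c(70, 126, 182, 210)))
  expect_true(ev$meets_high)
  ev <- detect_dose_optimizations(
    make_history(c(70, 126, 182), levels_mg_kg = c(5, 5, 10)))
  expect_true(ev$meets_high)

  # sub-threshold changes never fire
  ev <- detect_dose_optimizations(make_history(c(70, 126, 182, 231)))
  expect_equal(nrow(ev), 0)   # decrease 7 < 11 days
  ev <- detect_dose_optimizations(
    make_history(c(70, 126, 182), levels_mg_kg = c(5, 5, 6.4)))
  expect_equal(nrow(ev), 0)   # increase 1.4 < 1.5 mg/kg
})

test_that("the induction step-up is never flagged and posterior infusions date events", {
  # induction gaps 14 -> 28 -> 56 would trivially violate interval rules if
  # the first 63 days were not excluded
  ev <- detect_dose_optimizations(make_history(c(98, 154, 210)))
  expect_equal(nrow(ev), 0)
  # simultaneous interval and dose escalation is a single "both" event
  ev <- detect_dose_optimizations(
    make_history(c(70, 126, 182, 224), levels_mg_kg = c(5, 5, 5, 7.5)))
  expect_equal(ev$trigger, "both")
  expect_equal(ev$date, day0 + 224)
})

test_that("day- and week-denominated thresholds detect identically on integer days", {
  expect_identical(do_thresholds_weeks(), do_thresholds())
  set.seed(13)
  for (k in 1:30) {
    n <- sample(4:10, 1)
    gaps <- sample(21:84, n, replace = TRUE)
    levels <- round(sample(c(5, 6.5, 7.5, 9, 10), n + 1, replace = TRUE), 2)
    hist <- make_history(70 + cumsum(c(0, gaps)), levels_mg_kg = levels)
    a <- detect_dose_optimizations(hist, do_thresholds())
    b <- detect_dose_optimizations(hist, do_thresholds_weeks())
    expect_identical(a, b)
    # high-threshold events are a subset of low-threshold events
    expect_true(all(a$meets_low))
    expect_true(all(!a$meets_high | a$meets_low))
    # idempotence: the same history always yields the same events
    expect_identical(a, detect_dose_optimizations(hist))
  }
})

test_that("prior and windowed dose-optimization queries respect their boundaries", {
  hist <- make_history(c(70, 126, 182, 224))        # low event at day 224
  ev <- detect_dose_optimizations(hist)
  expect_true(prior_do_flag(ev, day0 + 250, "low"))
  expect_false(prior_do_flag(ev, day0 + 224, "low"))  # strict precedence
  expect_false(prior_do_flag(ev, day0 + 250, "high")) # no high event
  expect_false(prior_do_flag(ev[0, ], day0 + 250, "low"))

  # window (tdm, tdm + w*7]: day tdm+63 is in, day tdm itself is out
  w <- do_within_window(ev, day0 + 161, window_weeks = 9)
  expect_true(w$hit)
  expect_equal(w$first_do_date, day0 + 224)
  expect_true(do_within_window(ev, day0 + 224 - 63, 9)$hit)   # right edge
  expect_false(do_within_window(ev, day0 + 224, 9)$hit)       # left edge
  expect_false(do_within_window(ev, day0 + 100, 9)$hit)       # 124 > 63
  expect_true(do_within_window(ev, day0 + 110, 17)$hit)       # 114 <= 119
  expect_warning(do_within_window(ev, day0 + 161, 10), "non-standard")
})
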