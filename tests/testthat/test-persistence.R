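test_that("the gap rule places discontinuation 8 weeks after the last pre-gap infusion", {
  # infusions at days 0 and 56, censor at day 400: the 344-day gap to the
  # censoring date exceeds 20 weeks, so discontinuation lands at 56 + 56
  out <- derive_persistence(day0 + c(0, 56), day0, day0 + 400, gap_weeks = 20)
  expect_true(out$discontinued)
  expect_equal(out$discontinuation_date, day0 + 112)
  expect_equal(out$duration_days, 112L)

  # uninterrupted q8w dosing through day 392 is censored at day 400
  out <- derive_persistence(day0 + seq(0, 392, by = 56), day0, day0 + 400)
  expect_false(out$discontinued)
  expect_equal(out$duration_days, 400L)

  # hand-trace at both gap settings: infusions 0/100/290
  d <- day0 + c(0, 100, 290)
  out20 <- derive_persistence(d, day0, day0 + 400, gap_weeks = 20)
  expect_equal(out20$duration_days, 156L)   # 190-day gap: 100 + 56
  out12 <- derive_persistence(d, day0, day0 + 400, gap_weeks = 12)
  expect_equal(out12$duration_days, 56L)    # first gap 100 > 84: 0 + 56
})

test_that("gap comparison is strict and the 8-week offset cannot pass the censor date", {
  # a gap of exactly 140 days does not trigger
  out <- derive_persistence(day0 + c(0, 140), day0, day0 + 140)
  expect_false(out$discontinued)
  # history extending past the censor date: qualifying gap whose offset
  # lands after data end leaves the patient censored
  out <- derive_persistence(day0 + c(0, 80, 260), day0, day0 + 100)
  expect_false(out$discontinued)
  expect_equal(out$duration_days, 100L)
})

test_that("pre-index history participates in gap finding but not in duration", {
  d <- day0 + c(0, 56, 112, 168)
  out <- derive_persistence(d, index_date = day0 + 112,
                            censor_date = day0 + 600)
  expect_true(out$discontinued)                    # final gap 432 > 140
  expect_equal(out$discontinuation_date, day0 + 224)
  expect_equal(out$duration_days, 112L)            # 224 - 112
})

test_that("precondition violations raise errors", {
  expect_error(derive_persistence(as.Date(character()), day0, day0 + 10),
               "at least one infusion")
  expect_error(derive_persistence(day0, day0 + 10, day0), "on/before")
  expect_error(derive_persistence(day0, day0 + 5, day0 + 10),
               "on/after index_date")
})

test_that("shorter grace periods never lengthen persistence, and shifts are equivariant", {
  set.seed(31)
  for (k in 1:40) {
    n <- sample(2:12, 1)
    d <- day0 + sort(sample.int(700, n))
    censor <- max(d) + sample.int(300, 1)
    o20 <- derive_persistence(d, d[1], censor, gap_weeks = 20)
    o12 <- derive_persistence(d, d[1], censor, gap_weeks = 12)
    expect_lte(o12$duration_days, o20$duration_days)
    shift <- sample.int(200, 1)
    os <- derive_persistence(d + shift, d[1] + shift, censor + shift,
                             gap_weeks = 20)
    expect_equal(os$duration_days, o20$duration_days)
    expect_equal(os$discontinued, o20$discontinued)
    if (o20$discontinued) {
      expect_equal(os$discontinuation_date, o20$discontinuation_date + shift)
    }
  }
})

test_that("the cohort-level deriver agrees with the single-patient rule", {
  sim <- simulate_cohort(sim_config(n_patients = 80, seed = 21))
  tab <- derive_persistence_table(sim$infusions, "2019-07-31", 20)
  for (i in sample.int(nrow(tab), 20)) {
    pid <- tab$patient_id[i]
    d <- sim$infusions$date[sim$infusions$patient_id == pid]
    one <- derive_persistence(d, min(d), as.Date("2019-07-31"), 20, pid)
    expect_equal(tab$duration_days[i], one$duration_days)
    expect_equal(tab$discontinued[i], one$discontinued)
    expect_equal(tab$discontinuation_date[i], one$discontinuation_date)
  }
})

test_that("Kaplan-Meier estimates match closed forms", {
  none <- data.frame(duration_days = c(10, 20, 30, 40, 50),
                     discontinued = FALSE)
  km <- km_estimate(none)
  expect_true(all(km$surv == 1))
  expect_equal(km_survival_at(km, c(0, 25, 60)), c(1, 1, 1))

  two <- data.frame(duration_days = c(10, 20), discontinued = c(TRUE, FALSE))
  km2 <- km_estimate(two)
  expect_equal(km_survival_at(km2, 10), 0.5)

  expect_error(km_estimate(two[0, ]), "at least one")
  expect_error(km_estimate(data.frame(duration_days = -1,
                                      discontinued = TRUE)), "negative")
})

test_that("Kaplan-Meier estimator matches the brute-force product limit", {
  set.seed(77)
  for (k in 1:25) {
    out <- random_outcomes(sample(5:60, 1))
    km <- km_estimate(out)
    oracle <- km_oracle(out$duration_days, out$discontinued)
    got <- km_survival_at(km, oracle$time)
    expect_lt(max(abs(got - oracle$surv)), 1e-12)
  }
})
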