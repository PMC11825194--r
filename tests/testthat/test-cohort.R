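test_that("overall inclusion rules apply with their stated boundaries", {
  patients <- make_patients(sprintf("P%d", 1:6),
                            age = c(17, 40, 40, 40, 91, 40))
  infusions <- rbind(
    make_infusions(c(0, 56), pid = "P1", origin = as.Date("2015-06-01")),
    make_infusions(c(0, 56), pid = "P2", origin = as.Date("2015-06-01"),
                   weight_kg = 130.0),
    make_infusions(c(0, 56), pid = "P3", origin = as.Date("2015-06-01"),
                   weight_kg = 129.9),
    make_infusions(c(0, 120), pid = "P4", origin = as.Date("2014-11-01")),
    make_infusions(c(0, 56), pid = "P5", origin = as.Date("2015-06-01")),
    make_infusions(c(0, 56), pid = "P6", origin = as.Date("2019-02-01"))
  )
  sel <- select_overall(patients, infusions)
  expect_setequal(sel$included$patient_id, "P3")
  rules <- setNames(sel$ledger$rule, sel$ledger$patient_id)
  expect_equal(rules[["P1"]], "age")
  expect_equal(rules[["P2"]], "first_weight")          # 130.0 excluded, strict <
  expect_equal(rules[["P4"]], "prior_treatment_lookback")
  expect_equal(rules[["P5"]], "age")
  expect_equal(rules[["P6"]], "initiation_outside_window")
  # ledger completeness
  expect_equal(nrow(patients), nrow(sel$included) + nrow(sel$ledger))
})

test_that("subgroup selection requires a maintenance-phase first TDM with a result", {
  origin <- as.Date("2016-03-01")
  patients <- make_patients(sprintf("P%d", 1:5))
  infusions <- do.call(rbind, lapply(sprintf("P%d", 1:5), function(p)
    make_infusions(seq(0, 392, by = 56), pid = p, origin = origin)))
  censor <- as.Date("2019-07-31")
  tdm <- rbind(
    make_tdm("P1", origin + 63, 2.0),                # day 63: not after week 9
    make_tdm("P2", origin + 64, 2.0),                # day 64: included
    make_tdm("P3", c(origin + 70, origin + 126), c(NA, 2.0)),  # first has no result
    make_tdm("P4", origin + 900, 2.0),               # after discontinuation
    make_tdm("P5", origin + 100, 4.0)
  )
  # give P4 a qualifying gap so discontinuation precedes the late TDM
  infusions <- infusions[!(infusions$patient_id == "P4" &
                           infusions$date > origin + 112), ]
  sel <- select_overall(patients, infusions)
  outcomes <- derive_persistence_table(infusions, censor, 20)
  sub <- select_subgroup(sel$included, validate_tdm(tdm), outcomes)
  expect_setequal(sub$subgroup$patient_id, c("P2", "P5"))
  rules <- setNames(sub$ledger$rule, sub$ledger$patient_id)
  expect_equal(rules[["P1"]], "tdm_not_in_maintenance")
  expect_equal(rules[["P3"]], "first_tdm_no_result")
  expect_equal(rules[["P4"]], "tdm_after_discontinuation")
  expect_equal(sub$subgroup$days_to_tdm,
               c(64L, 100L)[order(c("P2", "P5"))])
})

test_that("subset labels split on threshold, window and prior optimization", {
  origin <- as.Date("2016-03-01")
  censor <- as.Date("2019-07-31")
  # P1: conc 2.5, low DO 40 days post-TDM -> B
  # P2: conc 3.0 at threshold 3 -> above threshold, subset none
  # P3: conc 2.5, no DO -> A
  # P4: conc 2.5, DO before TDM -> prior-DO subpopulation
  # P5: conc 2.5, no infusion after TDM (dropped under the exclusion flag)
  ids <- sprintf("P%d", 1:5)
  patients <- make_patients(ids)
  mk <- function(p, maintenance) make_history(maintenance, pid = p,
                                              origin = origin)
  infusions <- rbind(
    mk("P1", c(70, 126, 182, 224, 266)),     # escalation at day 224
    mk("P2", c(70, 126, 182, 238)),
    mk("P3", c(70, 126, 182, 238, 294)),
    mk("P4", c(70, 126, 182, 224, 266)),
    make_history(c(70, 126), pid = "P5", origin = origin)
  )
  tdm <- rbind(
    make_tdm("P1", origin + 184, 2.5),
    make_tdm("P2", origin + 184, 3.0),
    make_tdm("P3", origin + 184, 2.5),
    make_tdm("P4", origin + 250, 2.5),
    make_tdm("P5", origin + 126, 2.5)
  )
  sel <- select_overall(patients, infusions)
  outcomes <- derive_persistence_table(infusions, censor, 20)
  events <- detect_dose_optimizations(infusions)
  sub <- select_subgroup(sel$included, validate_tdm(tdm), outcomes)
  labels <- assign_subsets(sub$subgroup, events, infusions,
                           conc_threshold = 3, window_weeks = 9,
                           level = "low")
  lab <- setNames(labels$subset, labels$patient_id)
  pop <- setNames(labels$subpopulation, labels$patient_id)
  expect_equal(lab[["P1"]], "B")
  expect_equal(labels$do_exposure_day[labels$patient_id == "P1"], 40L)
  expect_equal(lab[["P2"]], "none")
  expect_false(labels$below_threshold[labels$patient_id == "P2"])
  expect_equal(lab[["P3"]], "A")
  expect_equal(pop[["P4"]], "prior_do_low")
  expect_equal(pop[["P1"]], "no_prior_do_low")
  # exclusion of patients with no treatment after TDM
  labels2 <- assign_subsets(sub$subgroup, events, infusions,
                            exclude_no_post_tdm_treatment = TRUE)
  expect_false("P5" %in% labels2$patient_id)
  expect_true("P5" %in% labels$patient_id)
})

test_that("subset labeling partitions the subgroup on simulated data", {
  sim <- simulate_cohort(sim_config(n_patients = 400, seed = 8))
  prep <- prepare_subgroup(sim, conc_threshold = 3, window_weeks = 9)
  labels <- prep$labels
  # every subgroup patient gets exactly one subpopulation and one subset
  expect_setequal(unique(labels$subpopulation),
                  intersect(c("no_prior_do_low", "prior_do_low"),
                            unique(labels$subpopulation)))
  expect_true(all(labels$subset %in% c("A", "B", "none")))
  # A/B only among below-threshold patients
  expect_true(all(labels$below_threshold[labels$subset %in% c("A", "B")]))
  expect_true(all(labels$subset[!labels$below_threshold] == "none"))
  # |A| + |B| equals the below-threshold count
  expect_equal(sum(labels$subset %in% c("A", "B")),
               sum(labels$below_threshold))
  # B exactly when an in-window dose optimization exists
  expect_true(all(!is.na(labels$do_exposure_day[labels$subset == "B"])))
  expect_true(all(labels$do_exposure_day[labels$subset == "B"] > 0))
  expect_true(all(labels$do_exposure_day[labels$subset == "B"] <= 63))
  # ledger completeness across both selection stages
  expect_equal(nrow(sim$patients),
               nrow(prep$subgroup) + nrow(prep$ledgers$overall) +
                 nrow(prep$ledgers$subgroup))
})
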