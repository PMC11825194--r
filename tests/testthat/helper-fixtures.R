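# Small programmatic fixtures used across test files.

day0 <- as.Date("2016-01-04")

# Infusion table for one patient from relative days.
make_infusions <- function(days, pid = "P1", origin = day0, dose_mg = 375,
                           weight_kg = 75) {
  n <- length(days)
  data.frame(patient_id = rep(pid, n), date = origin + days,
             dose_mg = rep_len(dose_mg, n),
             weight_kg = rep_len(weight_kg, n), stringsAsFactors = FALSE)
}

# Maintenance-phase infusion history with an induction prefix at 0/14/42 so
# dose-optimization detection operates on the post-week-9 rows only.
make_history <- function(maintenance_days, levels_mg_kg = 5, pid = "P1",
                         origin = day0, weight_kg = 75) {
  days <- c(0, 14, 42, maintenance_days)
  lev <- c(5, 5, 5, rep_len(levels_mg_kg, length(maintenance_days)))
  make_infusions(days, pid = pid, origin = origin,
                 dose_mg = lev * weight_kg, weight_kg = weight_kg)
}

make_patients <- function(ids, diagnosis = "CD", age = 40, gender = "female",
                          province = "Ontario") {
  n <- length(ids)
  data.frame(patient_id = ids, diagnosis = rep_len(diagnosis, n),
             age_at_initiation = rep_len(age, n),
             gender = rep_len(gender, n),
             province_region = rep_len(province, n), stringsAsFactors = FALSE)
}

make_tdm <- function(pid, dates, conc, ati = "missing") {
  n <- length(dates)
  data.frame(patient_id = rep_len(pid, n), date = as.Date(dates),
             ifx_conc_ug_ml = rep_len(conc, n),
             ati_status = rep_len(ati, n), stringsAsFactors = FALSE)
}

# Random right-censored outcomes in the package's persistence schema.
random_outcomes <- function(n, max_t = 400) {
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    duration_days = sample.int(max_t, n, replace = TRUE),
    discontinued = runif(n) < 0.6,
    stringsAsFactors = FALSE
  )
}

# Random small counting-process instance (single binary covariate, possibly
# tied event times) for partial-likelihood oracle checks.
random_cox_instance <- function(n = 8) {
  stopifnot(n <= 10)
  data.frame(
    patient_id = sprintf("S%02d", seq_len(n)),
    start = 0,
    stop = sample.int(12, n, replace = TRUE),
    event = runif(n) < 0.7,
    exposure = rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  )
}

# Integer-type columns read back from CSV may legitimately come back as
# integer where the original was double; normalise before comparison.
normalize_types <- function(df) {
  for (j in seq_along(df)) if (is.integer(df[[j]])) df[[j]] <- as.numeric(df[[j]])
  df
}
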