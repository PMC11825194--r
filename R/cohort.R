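# Cohort construction: overall-population inclusion rules, TDM subgroup
# selection, and the A/B subset labels used in every comparison.

#' Apply the overall-population inclusion rules
#'
#' Keeps patients whose first infusion falls in the initiation window, whose
#' age at initiation is within 18--90 years, whose first recorded weight is
#' strictly below 130 kg, and who have no infusion during the lookback
#' window (prior treatment).  Every excluded patient is recorded in an
#' exclusion ledger with the first rule that removed them, so
#' `|input| = |included| + sum(exclusions)`.
#'
#' @param patients validated patient table.
#' @param infusions validated infusion table.
#' @param window_start,window_end treatment-initiation window.
#' @param lookback_start start of the prior-treatment lookback window (the
#'   lookback runs from here to `window_start`).
#' @param age_range inclusive age bounds.
#' @param max_weight_kg exclusive upper bound on the first recorded weight.
#' @return list with `included` (data.frame: `patient_id`,
#'   `initiation_date`, `initiation_year`, `first_weight_kg`, patient
#'   covariates) and `ledger` (data.frame: `patient_id`, `rule`).
#' @export
select_overall <- function(patients, infusions,
                           window_start = "2015-01-01",
                           window_end = "2018-12-31",
                           lookback_start = "2014-05-01",
                           age_range = c(18, 90),
                           max_weight_kg = 130) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  lookback_start <- as.Date(lookback_start)

  by_pat <- split(infusions[c("date", "weight_kg")], infusions$patient_id)
  first_date <- rep(as.Date(NA), nrow(patients))
  first_weight <- rep(NA_real_, nrow(patients))
  any_lookback <- rep(FALSE, nrow(patients))
  for (i in seq_len(nrow(patients))) {
    chunk <- by_pat[[patients$patient_id[i]]]
    if (is.null(chunk) || nrow(chunk) == 0) next
    ord <- order(chunk$date)
    first_date[i] <- chunk$date[ord[1]]
    w <- chunk$weight_kg[ord]
    w <- w[!is.na(w)]
    if (length(w)) first_weight[i] <- w[1]
    any_lookback[i] <- any(chunk$date >= lookback_start &
                           chunk$date < window_start)
  }

  rule <- rep(NA_character_, nrow(patients))
  rule[is.na(first_date)] <- "no_infusions"
  sel <- is.na(rule) & any_lookback
  rule[sel] <- "prior_treatment_lookback"
  sel <- is.na(rule) & (first_date < window_start | first_date > window_end)
  rule[sel] <- "initiation_outside_window"
  age <- patients$age_at_initiation
  sel <- is.na(rule) & (is.na(age) | age < age_range[1] | age > age_range[2])
  rule[sel] <- "age"
  sel <- is.na(rule) & (is.na(first_weight) | first_weight >= max_weight_kg)
  rule[sel] <- "first_weight"

  keep <- is.na(rule)
  included <- data.frame(
    patient_id = patients$patient_id[keep],
    initiation_date = first_date[keep],
    initiation_year = as.integer(format(first_date[keep], "%Y")),
    first_weight_kg = first_weight[keep],
    diagnosis = patients$diagnosis[keep],
    age_at_initiation = age[keep],
    gender = patients$gender[keep],
    province_region = patients$province_region[keep],
    stringsAsFactors = FALSE
  )
  ledger <- data.frame(patient_id = patients$patient_id[!keep],
                       rule = rule[!keep], stringsAsFactors = FALSE)
  rownames(included) <- rownames(ledger) <- NULL
  list(included = included, ledger = ledger)
}

#' Select the TDM subgroup
#'
#' Keeps included patients whose chronologically first TDM record (a) falls
#' strictly after initiation + 63 days (maintenance phase, "after Week 9"),
#' (b) itself carries a recorded concentration, and (c) occurs on/before the
#' patient's discontinuation-or-censoring date under the production gap
#' rule.  A first TDM without a recorded result excludes the patient (the
#' record is not rolled forward to a later TDM).  The first-TDM date becomes
#' the subgroup index date.
#'
#' @param included the `included` table from [select_overall()].
#' @param tdm validated TDM table.
#' @param outcomes persistence outcomes from treatment initiation computed
#'   with the production gap rule (see [derive_persistence_table()]).
#' @return list with `subgroup` (data.frame: `patient_id`,
#'   `tdm_index_date`, `first_conc_ug_ml`, `first_ati_status`,
#'   `days_to_tdm`, plus initiation info) and `ledger` of exclusions.
#' @export
select_subgroup <- function(included, tdm, outcomes) {
  tdm <- tdm[tdm$patient_id %in% included$patient_id, , drop = FALSE]
  by_pat <- split(tdm, tdm$patient_id)
  end_date <- ifelse(outcomes$discontinued,
                     as.numeric(outcomes$discontinuation_date),
                     as.numeric(outcomes$censor_date))
  end_date <- as.Date(end_date, origin = "1970-01-01")
  names(end_date) <- outcomes$patient_id

  n <- nrow(included)
  rule <- rep(NA_character_, n)
  tdm_date <- rep(as.Date(NA), n)
  conc <- rep(NA_real_, n)
  ati <- rep(NA_character_, n)
  days_to <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pid <- included$patient_id[i]
    chunk <- by_pat[[pid]]
    if (is.null(chunk) || nrow(chunk) == 0) {
      rule[i] <- "no_tdm"
      next
    }
    first <- chunk[which.min(chunk$date), , drop = FALSE]
    dt <- as.integer(first$date - included$initiation_date[i])
    if (dt <= 63L) {
      rule[i] <- "tdm_not_in_maintenance"
    } else if (is.na(first$ifx_conc_ug_ml)) {
      rule[i] <- "first_tdm_no_result"
    } else if (first$date > end_date[[pid]]) {
      rule[i] <- "tdm_after_discontinuation"
    } else {
      tdm_date[i] <- first$date
      conc[i] <- first$ifx_conc_ug_ml
      ati[i] <- first$ati_status
      days_to[i] <- dt
    }
  }
  keep <- is.na(rule)
  subgroup <- cbind(
    included[keep, , drop = FALSE],
    data.frame(tdm_index_date = tdm_date[keep],
               first_conc_ug_ml = conc[keep],
               first_ati_status = ati[keep],
               days_to_tdm = days_to[keep], stringsAsFactors = FALSE)
  )
  ledger <- data.frame(patient_id = included$patient_id[!keep],
                       rule = rule[!keep], stringsAsFactors = FALSE)
  rownames(subgroup) <- rownames(ledger) <- NULL
  list(subgroup = subgroup, ledger = ledger)
}

#' Label the analysis subsets
#'
#' Splits the subgroup by the prior-dose-optimization flag into
#' subpopulations, then, among patients whose first concentration is
#' strictly below `conc_threshold`, labels subset `B` if a dose optimization
#' at the given level occurs within the post-TDM window and subset `A`
#' otherwise.  At-threshold and above-threshold patients get subset
#' `"none"`.  With `exclude_no_post_tdm_treatment`, patients with zero
#' infusions after the TDM date are dropped before labeling.
#'
#' @param subgroup the `subgroup` table from [select_subgroup()].
#' @param events dose-optimization events ([detect_dose_optimizations()]).
#' @param infusions validated infusion table (used by the post-TDM-treatment
#'   filter).
#' @param conc_threshold concentration threshold in ug/mL (3, 5 or 10).
#' @param window_weeks post-TDM window in weeks (9 or 17).
#' @param level threshold level, `"low"` or `"high"`.
#' @param exclude_no_post_tdm_treatment drop patients with no infusion after
#'   the TDM date before labeling.
#' @return data.frame of subset labels: `subpopulation`, `conc_threshold`,
#'   `below_threshold`, `window_weeks`, `subset`, `first_do_post_tdm_date`,
#'   `do_exposure_day` (days from TDM to the in-window dose optimization),
#'   plus the subgroup columns.
#' @export
assign_subsets <- function(subgroup, events, infusions,
                           conc_threshold = 3, window_weeks = 9,
                           level = c("low", "high"),
                           exclude_no_post_tdm_treatment = FALSE) {
  level <- match.arg(level)
  if (!conc_threshold %in% c(3, 5, 10)) {
    warning(sprintf("non-standard concentration threshold %s ug/mL",
                    conc_threshold), call. = FALSE)
  }
  out <- subgroup
  if (exclude_no_post_tdm_treatment && nrow(out)) {
    by_pat <- split(infusions$date, infusions$patient_id)
    has_post <- vapply(seq_len(nrow(out)), function(i) {
      d <- by_pat[[out$patient_id[i]]]
      !is.null(d) && any(d > out$tdm_index_date[i])
    }, logical(1))
    out <- out[has_post, , drop = FALSE]
  }
  n <- nrow(out)
  ev_by_pat <- split(events, events$patient_id)
  no_events <- .empty_do_events()
  prior <- logical(n)
  hit <- logical(n)
  first_do <- rep(as.Date(NA), n)
  for (i in seq_len(n)) {
    ev <- ev_by_pat[[out$patient_id[i]]]
    if (is.null(ev)) ev <- no_events
    prior[i] <- prior_do_flag(ev, out$tdm_index_date[i], level)
    w <- do_within_window(ev, out$tdm_index_date[i], window_weeks, level)
    hit[i] <- w$hit
    first_do[i] <- w$first_do_date
  }
  below <- out$first_conc_ug_ml < conc_threshold
  out$subpopulation <- paste0(ifelse(prior, "prior_do_", "no_prior_do_"),
                              level)
  out$conc_threshold <- conc_threshold
  out$below_threshold <- below
  out$window_weeks <- as.integer(window_weeks)
  out$subset <- ifelse(!below, "none", ifelse(hit, "B", "A"))
  out$first_do_post_tdm_date <- first_do
  out$first_do_post_tdm_date[!below | !hit] <- as.Date(NA)
  out$do_exposure_day <- as.integer(out$first_do_post_tdm_date -
                                    out$tdm_index_date)
  rownames(out) <- NULL
  out
}
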