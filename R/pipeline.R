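# Glue between cohort construction and model fitting: covariate coding and
# assembly of analysis-ready datasets for the overall and subgroup analyses.

#' Code the fixed covariates for an analysis population
#'
#' Age group (18 to <65, 65--90), gender, first-recorded-weight quartiles
#' (computed *within* the population being analysed), province/region, and
#' the year-of-initiation stratum.
#'
#' @param df data.frame with `age_at_initiation`, `gender`,
#'   `first_weight_kg`, `province_region`, `initiation_year`.
#' @return `df` with `age_group`, `weight_quartile` factors added and
#'   `gender`/`province_region` as factors.
#' @export
code_covariates <- function(df) {
  df$age_group <- factor(ifelse(df$age_at_initiation < 65, "18-<65",
                                "65-90"), levels = c("18-<65", "65-90"))
  df$gender <- factor(df$gender, levels = c("female", "male"))
  qs <- stats::quantile(df$first_weight_kg, probs = c(0.25, 0.5, 0.75),
                        na.rm = TRUE)
  df$weight_quartile <- cut(df$first_weight_kg,
                            breaks = c(-Inf, qs, Inf),
                            labels = c("Q1", "Q2", "Q3", "Q4"))
  df$province_region <- factor(df$province_region, levels = pk_provinces)
  df$province_region <- droplevels(df$province_region)
  df$stratum <- df$initiation_year
  df
}

#' Assemble the overall-population analysis dataset
#'
#' Persistence from treatment initiation under the gap rule, with TDM use
#' (first TDM of any kind) as the time-dependent exposure.
#'
#' @param tables list with validated `patients`, `infusions`, `tdm`.
#' @param censor_date administrative censoring date.
#' @param gap_weeks grace period (weeks).
#' @param ... passed to [select_overall()].
#' @return list: `included`, `ledger`, `outcomes`, `data` (patient-level
#'   analysis rows with `exposure_day`), `cp` (counting-process table).
#' @export
prepare_overall <- function(tables, censor_date = "2019-07-31",
                            gap_weeks = 20, ...) {
  sel <- select_overall(tables$patients, tables$infusions, ...)
  inc <- sel$included
  infusions <- tables$infusions[tables$infusions$patient_id %in%
                                inc$patient_id, , drop = FALSE]
  outcomes <- derive_persistence_table(infusions, censor_date, gap_weeks)
  dat <- code_covariates(inc)
  m <- match(dat$patient_id, outcomes$patient_id)
  dat$duration_days <- outcomes$duration_days[m]
  dat$discontinued <- outcomes$discontinued[m]
  tdm <- tables$tdm[tables$tdm$patient_id %in% inc$patient_id, , drop = FALSE]
  first_tdm <- tapply(as.numeric(tdm$date), tdm$patient_id, min)
  ftd <- as.Date(first_tdm[dat$patient_id], origin = "1970-01-01")
  exp_day <- as.numeric(ftd - dat$initiation_date)
  exp_day[!is.na(exp_day) & exp_day <= 0] <- NA  # pre-index TDM: not post-index exposure
  dat$exposure_day <- exp_day
  cp <- build_counting_process_table(
    dat[c("patient_id", "duration_days", "discontinued", "exposure_day",
          "age_group", "gender", "weight_quartile", "province_region",
          "stratum")]
  )
  list(included = inc, ledger = sel$ledger, outcomes = outcomes, data = dat,
       cp = cp)
}

#' Assemble a subgroup analysis dataset
#'
#' Full chain: overall inclusion, persistence from initiation (production
#' gap rule), dose-optimization detection, first-TDM subgroup selection,
#' subset labeling at the requested threshold/window/level, then
#' re-derivation of persistence indexed at the first-TDM date and
#' counting-process construction for the below-threshold A/B comparison.
#' Exposure is the first in-window post-TDM dose optimization; subset A
#' contributes unexposed person-time throughout.
#'
#' @param tables list with validated `patients`, `infusions`, `tdm`.
#' @param conc_threshold concentration threshold (ug/mL).
#' @param window_weeks post-TDM dose-optimization window (weeks).
#' @param level threshold level, `"low"` or `"high"`.
#' @param subpopulation which prior-dose-optimization subpopulation to
#'   analyse (default: patients with no prior dose optimization at `level`).
#' @param exclude_no_post_tdm_treatment drop patients with no treatment
#'   after TDM before labeling.
#' @param censor_date administrative censoring date.
#' @param gap_weeks grace period (weeks) for the production rule.
#' @param thresholds dose-optimization [do_thresholds()].
#' @param ... passed to [select_overall()].
#' @return list: `labels` (all subset labels), `data` (analysis rows for
#'   the A/B comparison with covariates, `log_days_to_tdm`, exposure and
#'   outcome), `cp` (counting-process table), plus the intermediate
#'   `outcomes_init`, `events`, `subgroup`, `ledgers`.
#' @export
prepare_subgroup <- function(tables, conc_threshold = 3, window_weeks = 9,
                             level = "low",
                             subpopulation = NULL,
                             exclude_no_post_tdm_treatment = FALSE,
                             censor_date = "2019-07-31", gap_weeks = 20,
                             thresholds = do_thresholds(), ...) {
  if (is.null(subpopulation)) subpopulation <- paste0("no_prior_do_", level)
  sel <- select_overall(tables$patients, tables$infusions, ...)
  inc <- sel$included
  infusions <- tables$infusions[tables$infusions$patient_id %in%
                                inc$patient_id, , drop = FALSE]
  outcomes_init <- derive_persistence_table(infusions, censor_date, gap_weeks)
  events <- detect_dose_optimizations(infusions, thresholds)
  sub <- select_subgroup(inc, tables$tdm, outcomes_init)
  labels <- assign_subsets(sub$subgroup, events, infusions,
                           conc_threshold = conc_threshold,
                           window_weeks = window_weeks, level = level,
                           exclude_no_post_tdm_treatment =
                             exclude_no_post_tdm_treatment)
  ab <- labels[labels$subpopulation == subpopulation &
               labels$subset %in% c("A", "B"), , drop = FALSE]
  if (nrow(ab)) {
    out_tdm <- derive_persistence_table(
      infusions[infusions$patient_id %in% ab$patient_id, , drop = FALSE],
      censor_date, gap_weeks,
      index = data.frame(patient_id = ab$patient_id,
                         index_date = ab$tdm_index_date)
    )
    m <- match(ab$patient_id, out_tdm$patient_id)
    ab$duration_days <- out_tdm$duration_days[m]
    ab$discontinued <- out_tdm$discontinued[m]
  } else {
    out_tdm <- NULL
    ab$duration_days <- integer()
    ab$discontinued <- logical()
  }
  ab$exposure_day <- as.numeric(ab$do_exposure_day)
  ab$log_days_to_tdm <- log(ab$days_to_tdm)
  dat <- code_covariates(ab)
  cp <- if (nrow(dat)) {
    suppressWarnings(build_counting_process_table(
      dat[c("patient_id", "duration_days", "discontinued", "exposure_day",
            "age_group", "gender", "weight_quartile", "province_region",
            "log_days_to_tdm", "stratum")]
    ))
  } else NULL
  list(labels = labels, data = dat, cp = cp, outcomes_init = outcomes_init,
       outcomes_tdm = out_tdm, events = events, subgroup = sub$subgroup,
       ledgers = list(overall = sel$ledger, subgroup = sub$ledger))
}

#' Contrast naive ever-exposed and time-dependent exposure coding
#'
#' Fits two unadjusted Cox models for the effect of dose optimization on
#' persistence from treatment initiation: one coding exposure as a baseline
#' ever-exposed indicator (the classification requires surviving to the
#' exposure, so unexposed person-time of exposed patients is misclassified
#' — immortal-time bias), and one coding it as a time-dependent covariate in
#' counting-process form.  On a cohort where the exposure is truly null the
#' naive estimate is biased below 1 while the time-dependent estimate
#' centres on 1.
#'
#' @param tables list with validated `patients`, `infusions`, `tdm`.
#' @param censor_date administrative censoring date.
#' @param gap_weeks grace period (weeks).
#' @return data.frame with one row per coding (`naive`, `time_dependent`):
#'   `hr`, `hr_lo`, `hr_hi`, `p`, `coef`, `se`, `n_exposed`.
#' @export
naive_vs_timedep <- function(tables, censor_date = "2019-07-31",
                             gap_weeks = 20) {
  outcomes <- derive_persistence_table(tables$infusions, censor_date,
                                       gap_weeks)
  events <- detect_dose_optimizations(tables$infusions)
  init <- tapply(as.numeric(tables$infusions$date),
                 tables$infusions$patient_id, min)
  first_do <- tapply(as.numeric(events$date), events$patient_id, min)
  exp_day <- as.numeric(first_do[outcomes$patient_id]) -
    as.numeric(init[outcomes$patient_id])
  df <- data.frame(patient_id = outcomes$patient_id,
                   duration_days = outcomes$duration_days,
                   discontinued = outcomes$discontinued,
                   exposure_day = exp_day,
                   stringsAsFactors = FALSE)
  df <- df[df$duration_days > 0, , drop = FALSE]
  exposed <- !is.na(df$exposure_day) & df$exposure_day < df$duration_days

  naive_cp <- data.frame(patient_id = df$patient_id, start = 0,
                         stop = df$duration_days, event = df$discontinued,
                         exposure = as.integer(exposed))
  fit_naive <- fit_cox(naive_cp, strata_col = NULL, model_id = "naive")
  td_cp <- build_counting_process_table(
    df[c("patient_id", "duration_days", "discontinued", "exposure_day")])
  fit_td <- fit_cox(td_cp, strata_col = NULL, model_id = "time_dependent")

  out <- rbind(cbind(coding = "naive", exposure_hr(fit_naive)),
               cbind(coding = "time_dependent", exposure_hr(fit_td)))
  out$n_exposed <- sum(exposed)
  rownames(out) <- NULL
  out
}

#' Standard covariate sets
#'
#' Fixed covariates of the overall analysis, plus `log_days_to_tdm` for
#' subgroup analyses.
#'
#' @param population `"overall"` or `"subgroup"`.
#' @return character vector of covariate column names.
#' @export
standard_covariates <- function(population = c("overall", "subgroup")) {
  population <- match.arg(population)
  base <- c("age_group", "gender", "weight_quartile", "province_region")
  if (population == "subgroup") c(base, "log_days_to_tdm") else base
}
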