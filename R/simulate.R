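# Synthetic patient-support-program cohort generator.  Emulates the data
# source the pipeline is designed for: induction infusions at weeks 0/2/6,
# q8w maintenance with jitter, trough TDM draws with a low-concentration /
# antibody-positive stratum, physician-driven dose escalation after a low
# result, and a latent discontinuation hazard that may change when the
# regimen is escalated.  Ground truth (stratum, latent event time, true
# escalation date and hazard ratio) is returned alongside the observable
# tables so every downstream estimator can be checked against it.

#' Build a simulation configuration
#'
#' All arguments have defaults describing the study conditions the generator
#' emulates: 5 mg/kg at days 0/14/42 then every 56 days, right-censoring on
#' 2019-07-31, initiation during 2015--2018, and an exposure hazard ratio
#' `theta_do` applied from the (detectable) dose-optimization date.
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer seed; each patient gets an RNG stream derived from
#'   `(seed, patient index)` so cohorts are extensible without disturbing
#'   existing patients.
#' @param initiation_start,initiation_end first-infusion window (ISO dates).
#' @param censor_date administrative right-censoring date.
#' @param induction_offsets_days induction schedule in days from initiation.
#' @param maintenance_interval_days target maintenance interval (days).
#' @param interval_jitter_sd_days SD of the rounded-normal jitter applied to
#'   every maintenance gap (days).
#' @param min_interval_days floor applied to jittered gaps.
#' @param base_dose_mg_per_kg starting dose level.
#' @param weight_mean_kg,weight_sd_kg,weight_min_kg,weight_max_kg truncated
#'   normal for body weight.
#' @param age_mean,age_sd,age_min,age_max truncated normal for age at
#'   initiation (tails outside 18--90 deliberately exercise the inclusion
#'   rules).
#' @param prob_male,prob_cd marginal probabilities for gender and diagnosis.
#' @param province_probs named probabilities over [pk_provinces].
#' @param ati_fraction mixing fraction of the latent low-concentration /
#'   antibody-positive stratum.
#' @param conc_meanlog,conc_sdlog log-normal trough concentration for the
#'   antibody-negative stratum (ug/mL).
#' @param ati_conc_max upper bound of the assay-floor concentrations drawn
#'   for the antibody-positive stratum (ug/mL).
#' @param prob_tdm_missing_result probability a TDM order carries no recorded
#'   concentration.
#' @param prob_ati_reported_pos,prob_ati_reported_neg probability the ATI
#'   status is actually reported (rather than missing) in each stratum.
#' @param tdm_prob_per_cycle per-maintenance-infusion probability of a trough
#'   TDM order.
#' @param tdm_earliest_week earliest week a TDM order may be placed.
#' @param do_trigger_conc concentration (ug/mL) below which a recorded TDM
#'   result may trigger physician-driven dose optimization.
#' @param do_prob_given_low probability a low first result triggers
#'   escalation at the next infusion.
#' @param do_spontaneous_prob_per_cycle per-cycle probability of empirical
#'   (non-TDM-driven) escalation.
#' @param do_dose_mg_per_kg escalated dose level.
#' @param do_interval_days escalated maintenance interval.
#' @param do_type_probs named probabilities over escalation types
#'   `dose`/`interval`/`both`.
#' @param baseline_hazard_per_day baseline discontinuation hazard scale; with
#'   `hazard_shape = 1` the latent event time is exponential.  Zero disables
#'   discontinuation.
#' @param hazard_shape Weibull shape of the cumulative baseline hazard
#'   `(lambda * t)^shape`.
#' @param hr_low_conc multiplicative hazard of the low-concentration stratum.
#' @param theta_do true hazard ratio applied from the dose-optimization date.
#' @param prob_weight_recorded probability a weight is recorded at an
#'   infusion (the first infusion always records one).
#' @param weight_jitter_sd_kg SD of recorded-weight fluctuation around the
#'   true weight.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 1000,
                       seed = 1,
                       initiation_start = "2015-01-01",
                       initiation_end = "2018-12-31",
                       censor_date = "2019-07-31",
                       induction_offsets_days = c(0L, 14L, 42L),
                       maintenance_interval_days = 56,
                       interval_jitter_sd_days = 3,
                       min_interval_days = 21,
                       base_dose_mg_per_kg = 5,
                       weight_mean_kg = 75,
                       weight_sd_kg = 17,
                       weight_min_kg = 40,
                       weight_max_kg = 150,
                       age_mean = 43,
                       age_sd = 16,
                       age_min = 16,
                       age_max = 95,
                       prob_male = 0.5,
                       prob_cd = 0.59,
                       province_probs = c(Alberta = 0.128, Atlantic = 0.117,
                                          BritishColumbia = 0.117,
                                          Ontario = 0.314, Quebec = 0.268,
                                          SaskatchewanManitoba = 0.056),
                       ati_fraction = 0.30,
                       conc_meanlog = log(5),
                       conc_sdlog = 0.7,
                       ati_conc_max = 0.035,
                       prob_tdm_missing_result = 0.08,
                       prob_ati_reported_pos = 0.8,
                       prob_ati_reported_neg = 0.6,
                       tdm_prob_per_cycle = 0.12,
                       tdm_earliest_week = 10,
                       do_trigger_conc = 3,
                       do_prob_given_low = 0.6,
                       do_spontaneous_prob_per_cycle = 0.01,
                       do_dose_mg_per_kg = 8,
                       do_interval_days = 42,
                       do_type_probs = c(dose = 0.5, interval = 0.3,
                                         both = 0.2),
                       baseline_hazard_per_day = 8e-4,
                       hazard_shape = 1,
                       hr_low_conc = 2,
                       theta_do = 0.36,
                       prob_weight_recorded = 0.9,
                       weight_jitter_sd_kg = 1) {
  cfg <- list(
    n_patients = n_patients, seed = seed,
    initiation_start = as.Date(initiation_start),
    initiation_end = as.Date(initiation_end),
    censor_date = as.Date(censor_date),
    induction_offsets_days = as.integer(induction_offsets_days),
    maintenance_interval_days = maintenance_interval_days,
    interval_jitter_sd_days = interval_jitter_sd_days,
    min_interval_days = min_interval_days,
    base_dose_mg_per_kg = base_dose_mg_per_kg,
    weight_mean_kg = weight_mean_kg, weight_sd_kg = weight_sd_kg,
    weight_min_kg = weight_min_kg, weight_max_kg = weight_max_kg,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min, age_max = age_max,
    prob_male = prob_male, prob_cd = prob_cd,
    province_probs = province_probs,
    ati_fraction = ati_fraction,
    conc_meanlog = conc_meanlog, conc_sdlog = conc_sdlog,
    ati_conc_max = ati_conc_max,
    prob_tdm_missing_result = prob_tdm_missing_result,
    prob_ati_reported_pos = prob_ati_reported_pos,
    prob_ati_reported_neg = prob_ati_reported_neg,
    tdm_prob_per_cycle = tdm_prob_per_cycle,
    tdm_earliest_week = tdm_earliest_week,
    do_trigger_conc = do_trigger_conc,
    do_prob_given_low = do_prob_given_low,
    do_spontaneous_prob_per_cycle = do_spontaneous_prob_per_cycle,
    do_dose_mg_per_kg = do_dose_mg_per_kg,
    do_interval_days = do_interval_days,
    do_type_probs = do_type_probs,
    baseline_hazard_per_day = baseline_hazard_per_day,
    hazard_shape = hazard_shape,
    hr_low_conc = hr_low_conc,
    theta_do = theta_do,
    prob_weight_recorded = prob_weight_recorded,
    weight_jitter_sd_kg = weight_jitter_sd_kg
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every field; an invalid field raises an error naming it.
#'
#' @param cfg a `sim_config` object.
#' @return `cfg`, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why),
         call. = FALSE)
  }
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v %% 1 != 0)
      fail(field, "must be a non-negative integer")
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1))
      fail(field, "probabilities must lie in [0, 1]")
  }
  chk_pos <- function(field, strict = TRUE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        (strict && v <= 0) || (!strict && v < 0))
      fail(field, if (strict) "must be > 0" else "must be >= 0")
  }
  chk_count("n_patients")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    fail("seed", "must be a single number")
  for (f in c("initiation_start", "initiation_end", "censor_date")) {
    if (!inherits(cfg[[f]], "Date") || is.na(cfg[[f]])) fail(f, "must be a date")
  }
  if (cfg$initiation_end < cfg$initiation_start)
    fail("initiation_end", "must be on/after initiation_start")
  if (cfg$censor_date < cfg$initiation_end)
    fail("censor_date", "must be on/after initiation_end")
  if (anyNA(cfg$induction_offsets_days) ||
      is.unsorted(cfg$induction_offsets_days, strictly = TRUE) ||
      cfg$induction_offsets_days[1] != 0L)
    fail("induction_offsets_days", "must be strictly increasing, starting at 0")
  chk_pos("maintenance_interval_days")
  chk_pos("interval_jitter_sd_days", strict = FALSE)
  chk_pos("min_interval_days")
  chk_pos("base_dose_mg_per_kg")
  chk_pos("weight_mean_kg"); chk_pos("weight_sd_kg", strict = FALSE)
  chk_pos("weight_min_kg"); chk_pos("weight_max_kg")
  for (f in c("prob_male", "prob_cd", "ati_fraction",
              "prob_tdm_missing_result", "prob_ati_reported_pos",
              "prob_ati_reported_neg", "tdm_prob_per_cycle",
              "do_prob_given_low", "do_spontaneous_prob_per_cycle",
              "prob_weight_recorded")) chk_prob(f)
  pp <- cfg$province_probs
  if (is.null(names(pp)) || !setequal(names(pp), pk_provinces))
    fail("province_probs", "must be named with every province/region level")
  chk_prob("province_probs")
  if (abs(sum(pp) - 1) > 1e-6) fail("province_probs", "must sum to 1")
  tp <- cfg$do_type_probs
  if (is.null(names(tp)) || !setequal(names(tp), c("dose", "interval", "both")))
    fail("do_type_probs", "must be named dose/interval/both")
  chk_prob("do_type_probs")
  if (abs(sum(tp) - 1) > 1e-6) fail("do_type_probs", "must sum to 1")
  chk_pos("conc_sdlog", strict = FALSE)
  chk_pos("ati_conc_max")
  chk_pos("do_trigger_conc")
  chk_pos("do_dose_mg_per_kg")
  chk_pos("do_interval_days")
  chk_pos("baseline_hazard_per_day", strict = FALSE)
  chk_pos("hazard_shape")
  chk_pos("hr_low_conc")
  chk_pos("theta_do")
  chk_pos("weight_jitter_sd_kg", strict = FALSE)
  chk_pos("tdm_earliest_week", strict = FALSE)
  invisible(cfg)
}

# Inverse of the piecewise cumulative hazard
#   H(t) = m1 * H0(min(t, d)) + m2 * (H0(t) - H0(d)) * 1[t > d]
# with H0(t) = (lambda * t)^shape; d = Inf when no regimen change occurs.
# Returns Inf when lambda == 0.
.draw_event_time <- function(lambda, shape, m1, m2, d) {
  if (lambda <= 0) return(Inf)
  h0 <- function(t) (lambda * t)^shape
  h0inv <- function(h) h^(1 / shape) / lambda
  target <- stats::rexp(1)
  if (!is.finite(d) || target <= m1 * h0(d)) {
    h0inv(target / m1)
  } else {
    h0inv(h0(d) + (target - m1 * h0(d)) / m2)
  }
}

.rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:50) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  min(max(mean, lo), hi)
}

# One patient's trajectory; all days are relative to the initiation date.
.simulate_patient <- function(cfg, idx) {
  set.seed(derive_patient_seed(cfg$seed, idx))
  span <- as.integer(cfg$initiation_end - cfg$initiation_start)
  init_date <- cfg$initiation_start + sample.int(span + 1L, 1L) - 1L
  horizon <- as.integer(cfg$censor_date - init_date)

  weight <- .rtruncnorm1(cfg$weight_mean_kg, cfg$weight_sd_kg,
                         cfg$weight_min_kg, cfg$weight_max_kg)
  age <- round(.rtruncnorm1(cfg$age_mean, cfg$age_sd, cfg$age_min, cfg$age_max))
  gender <- if (stats::runif(1) < cfg$prob_male) "male" else "female"
  diagnosis <- if (stats::runif(1) < cfg$prob_cd) "CD" else "UC"
  province <- sample(names(cfg$province_probs), 1L,
                     prob = cfg$province_probs)
  ati <- stats::runif(1) < cfg$ati_fraction

  # --- schedule under the starting regimen -------------------------------
  ind <- cfg$induction_offsets_days
  n_gap <- ceiling((horizon + 120) / cfg$min_interval_days) + 2L
  gaps <- pmax(cfg$min_interval_days,
               round(stats::rnorm(n_gap, cfg$maintenance_interval_days,
                                  cfg$interval_jitter_sd_days)))
  days0 <- c(ind, ind[length(ind)] + cumsum(gaps))
  days0 <- days0[days0 <= horizon]
  n_ind <- length(ind)

  # --- TDM orders on the starting schedule -------------------------------
  elig0 <- which(seq_along(days0) > n_ind &
                 days0 >= cfg$tdm_earliest_week * 7 & days0 > 63)
  flag0 <- elig0[stats::runif(length(elig0)) < cfg$tdm_prob_per_cycle]
  k0 <- length(flag0)
  conc0 <- if (ati) stats::runif(k0, 0, cfg$ati_conc_max)
           else stats::rlnorm(k0, cfg$conc_meanlog, cfg$conc_sdlog)
  miss0 <- stats::runif(k0) < cfg$prob_tdm_missing_result

  # --- dose-optimization decision ----------------------------------------
  # Empirical (spontaneous) escalation: first maintenance infusion whose
  # per-cycle coin lands; TDM-triggered escalation: the first recorded low
  # result prompts the physician (prob do_prob_given_low) to escalate.  The
  # earlier decision wins.  The new regimen starts with the *next* scheduled
  # visit: a shortened interval means the next infusion arrives sooner, a
  # dose increase applies from the next infusion onward.
  m_all <- which(seq_along(days0) > n_ind)
  sp_hit <- m_all[stats::runif(length(m_all)) < cfg$do_spontaneous_prob_per_cycle]
  sp_day <- if (length(sp_hit)) days0[sp_hit[1]] else Inf

  trig_day <- Inf
  low0 <- which(!miss0 & conc0 < cfg$do_trigger_conc)
  if (length(low0)) {
    if (stats::runif(1) < cfg$do_prob_given_low) {
      trig_day <- days0[flag0[low0[1]]]   # the low-TDM infusion itself
    }
  }
  decision_day <- min(sp_day, trig_day)
  do_type <- NA_character_
  if (is.finite(decision_day)) {
    do_type <- sample(names(cfg$do_type_probs), 1L, prob = cfg$do_type_probs)
  }

  # --- rebuild the schedule after an interval-changing escalation --------
  days <- days0
  if (is.finite(decision_day) && do_type %in% c("interval", "both")) {
    pre <- days0[days0 <= decision_day]
    n2 <- ceiling((horizon - decision_day) / cfg$min_interval_days) + 2L
    g2 <- pmax(cfg$min_interval_days,
               round(stats::rnorm(n2, cfg$do_interval_days,
                                  cfg$interval_jitter_sd_days)))
    post <- decision_day + cumsum(g2)
    days <- c(pre, post[post <= horizon])
  }

  # The escalated regimen is in effect (and observable) from the first
  # infusion after the decision visit; the hazard ratio theta_do applies
  # from that date.
  do_day <- NA_real_
  if (is.finite(decision_day)) {
    nxt <- days[days > decision_day]
    if (length(nxt)) do_day <- nxt[1]
  }

  # --- latent discontinuation time ---------------------------------------
  m1 <- if (ati) cfg$hr_low_conc else 1
  m2 <- m1 * cfg$theta_do
  latent_t <- .draw_event_time(cfg$baseline_hazard_per_day, cfg$hazard_shape,
                               m1, m2, if (is.na(do_day)) Inf else do_day)

  keep <- days < latent_t & days <= horizon
  days <- days[keep]
  do_applied <- !is.na(do_day) && do_day < latent_t && do_day <= horizon
  if (!do_applied) do_day <- NA_real_

  # --- TDM rows: starting-schedule draws that survived, plus fresh draws
  #     for post-escalation infusions when the schedule changed ------------
  tdm_days <- days0[flag0]
  tdm_conc <- conc0
  tdm_miss <- miss0
  if (is.finite(decision_day) && do_type %in% c("interval", "both")) {
    keep0 <- tdm_days <= decision_day
    tdm_days <- tdm_days[keep0]; tdm_conc <- tdm_conc[keep0]
    tdm_miss <- tdm_miss[keep0]
    post_inf <- days[days > decision_day &
                     days >= cfg$tdm_earliest_week * 7 & days > 63]
    post_flag <- post_inf[stats::runif(length(post_inf)) <
                          cfg$tdm_prob_per_cycle]
    kp <- length(post_flag)
    if (kp) {
      cp <- if (ati) stats::runif(kp, 0, cfg$ati_conc_max)
            else stats::rlnorm(kp, cfg$conc_meanlog, cfg$conc_sdlog)
      mp <- stats::runif(kp) < cfg$prob_tdm_missing_result
      tdm_days <- c(tdm_days, post_flag)
      tdm_conc <- c(tdm_conc, cp)
      tdm_miss <- c(tdm_miss, mp)
    }
  }
  keep_tdm <- tdm_days %in% days
  tdm_days <- tdm_days[keep_tdm]
  tdm_conc <- tdm_conc[keep_tdm]
  tdm_miss <- tdm_miss[keep_tdm]
  tdm_conc[tdm_miss] <- NA_real_
  kt <- length(tdm_days)
  ati_status <- rep("missing", kt)
  if (kt) {
    reported <- stats::runif(kt) < (if (ati) cfg$prob_ati_reported_pos
                                    else cfg$prob_ati_reported_neg)
    reported[tdm_miss] <- FALSE
    ati_status[reported] <- if (ati) "positive" else "negative"
  }

  # --- administered doses and recorded weights ---------------------------
  level <- rep(cfg$base_dose_mg_per_kg, length(days))
  if (is.finite(decision_day) && !is.na(do_type) &&
      do_type %in% c("dose", "both")) {
    level[days > decision_day] <- cfg$do_dose_mg_per_kg
  }
  dose_mg <- round(level * weight, 1)
  rec <- stats::runif(length(days)) < cfg$prob_weight_recorded
  if (length(rec)) rec[1] <- TRUE
  wt_rec <- ifelse(rec, round(weight + stats::rnorm(length(days), 0,
                                                    cfg$weight_jitter_sd_kg), 1),
                   NA_real_)

  list(
    init_date = init_date,
    age = age, gender = gender, diagnosis = diagnosis, province = province,
    inf_days = days, dose_mg = dose_mg, weight_kg = wt_rec,
    tdm_days = tdm_days, tdm_conc = tdm_conc, ati_status = ati_status,
    ati_stratum = ati,
    latent_disc_day = if (is.finite(latent_t)) latent_t else NA_real_,
    do_day = do_day, do_applied = do_applied,
    do_type = if (do_applied) do_type else NA_character_
  )
}

.empty_cohort <- function() {
  list(
    patients = data.frame(patient_id = character(), diagnosis = character(),
                          age_at_initiation = numeric(), gender = character(),
                          province_region = character(),
                          stringsAsFactors = FALSE),
    infusions = data.frame(patient_id = character(),
                           date = as.Date(character()), dose_mg = numeric(),
                           weight_kg = numeric(), stringsAsFactors = FALSE),
    tdm = data.frame(patient_id = character(), date = as.Date(character()),
                     ifx_conc_ug_ml = numeric(), ati_status = character(),
                     stringsAsFactors = FALSE),
    truth = data.frame(patient_id = character(),
                       initiation_date = as.Date(character()),
                       ati_stratum = logical(), latent_disc_day = numeric(),
                       do_day = numeric(), do_applied = logical(),
                       do_type = character(), theta_do = numeric(),
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a patient-support-program cohort
#'
#' Generates the three observable tables (patients, infusions, TDM results)
#' plus a ground-truth table recording each patient's latent stratum, latent
#' discontinuation time, and whether/when dose optimization was applied.  No
#' infusion occurs on/after the latent discontinuation time and all dates are
#' capped at the censoring date; the same config and seed always reproduce
#' identical tables.
#'
#' @param cfg a [sim_config()] object.
#' @return named list with `patients`, `infusions`, `tdm`, `truth`
#'   data.frames conforming to the package schemas.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_patients
  if (n == 0) return(.empty_cohort())
  sims <- vector("list", n)
  for (i in seq_len(n)) sims[[i]] <- .simulate_patient(cfg, i)
  ids <- sprintf("P%05d", seq_len(n))

  n_inf <- vapply(sims, function(s) length(s$inf_days), integer(1))
  n_tdm <- vapply(sims, function(s) length(s$tdm_days), integer(1))
  init <- as.Date(vapply(sims, function(s) as.numeric(s$init_date),
                         numeric(1)), origin = "1970-01-01")

  patients <- data.frame(
    patient_id = ids,
    diagnosis = vapply(sims, `[[`, character(1), "diagnosis"),
    age_at_initiation = vapply(sims, `[[`, numeric(1), "age"),
    gender = vapply(sims, `[[`, character(1), "gender"),
    province_region = vapply(sims, `[[`, character(1), "province"),
    stringsAsFactors = FALSE
  )
  infusions <- data.frame(
    patient_id = rep(ids, n_inf),
    date = rep(init, n_inf) +
      unlist(lapply(sims, `[[`, "inf_days"), use.names = FALSE),
    dose_mg = unlist(lapply(sims, `[[`, "dose_mg"), use.names = FALSE),
    weight_kg = unlist(lapply(sims, `[[`, "weight_kg"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  tdm <- data.frame(
    patient_id = rep(ids, n_tdm),
    date = rep(init, n_tdm) +
      unlist(lapply(sims, `[[`, "tdm_days"), use.names = FALSE),
    ifx_conc_ug_ml = unlist(lapply(sims, `[[`, "tdm_conc"),
                            use.names = FALSE),
    ati_status = unlist(lapply(sims, `[[`, "ati_status"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient_id = ids,
    initiation_date = init,
    ati_stratum = vapply(sims, `[[`, logical(1), "ati_stratum"),
    latent_disc_day = vapply(sims, `[[`, numeric(1), "latent_disc_day"),
    do_day = vapply(sims, `[[`, numeric(1), "do_day"),
    do_applied = vapply(sims, `[[`, logical(1), "do_applied"),
    do_type = vapply(sims, `[[`, character(1), "do_type"),
    theta_do = cfg$theta_do,
    stringsAsFactors = FALSE
  )
  list(patients = patients, infusions = infusions, tdm = tdm, truth = truth)
}

#' Simulate a null cohort for the immortal-time-bias demonstration
#'
#' Requires a configuration under which dose optimization has no causal
#' effect on discontinuation (`theta_do = 1`); by construction exposure still
#' occurs only after a waiting time, so exposed patients necessarily survived
#' to exposure.  Two further pathways are closed so that exposure is null
#' with respect to the *observable* outcome as well: the low-concentration
#' stratum's hazard multiplier is forced to 1 (no confounding through the
#' TDM trigger), and escalations are forced to be dose-only (an interval
#' decrease would shorten the visit schedule and thereby shift the
#' gap-rule's detected discontinuation date for exposed person-time — a
#' measurement pathway, not a hazard pathway).  A correctly specified
#' time-dependent model must then centre on HR = 1.
#'
#' @param cfg a [sim_config()] with `theta_do = 1`.
#' @return same structure as [simulate_cohort()].
#' @export
simulate_null_cohort <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$theta_do != 1) {
    stop("invalid sim_config field 'theta_do': must be 1 for a null cohort",
         call. = FALSE)
  }
  cfg$hr_low_conc <- 1
  cfg$do_type_probs <- c(dose = 1, interval = 0, both = 0)
  simulate_cohort(cfg)
}
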