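# Dose-optimization detection: interval decreases and dose-level increases
# against predefined low and high thresholds, evaluated on consecutive
# maintenance-phase infusion pairs.

#' Detection thresholds, in days and mg/kg
#'
#' Low criteria: an interval decrease of at least `interval_decrease_min`
#' days with a posterior interval of at most `interval_post_max_low` days,
#' and/or a dose-level increase of at least `dose_increase_min` mg/kg with a
#' posterior dose level of at least `dose_post_min_low` mg/kg.  High criteria
#' tighten the posterior interval to `interval_post_max_high` days and the
#' posterior dose level to `dose_post_min_high` mg/kg, so every
#' high-threshold event is also a low-threshold event.
#'
#' @param interval_decrease_min_days minimum interval decrease (days).
#' @param interval_post_max_low_days,interval_post_max_high_days maximum
#'   posterior interval (days) for the low / high criterion.
#' @param dose_increase_min_mg_kg minimum dose-level increase (mg/kg).
#' @param dose_post_min_low_mg_kg,dose_post_min_high_mg_kg minimum posterior
#'   dose level (mg/kg) for the low / high criterion.
#' @return named list of thresholds.
#' @export
do_thresholds <- function(interval_decrease_min_days = 11,
                          interval_post_max_low_days = 46,
                          interval_post_max_high_days = 35,
                          dose_increase_min_mg_kg = 1.5,
                          dose_post_min_low_mg_kg = 7,
                          dose_post_min_high_mg_kg = 9) {
  list(interval_decrease_min_days = interval_decrease_min_days,
       interval_post_max_low_days = interval_post_max_low_days,
       interval_post_max_high_days = interval_post_max_high_days,
       dose_increase_min_mg_kg = dose_increase_min_mg_kg,
       dose_post_min_low_mg_kg = dose_post_min_low_mg_kg,
       dose_post_min_high_mg_kg = dose_post_min_high_mg_kg)
}

#' Week-denominated thresholds
#'
#' Convenience wrapper converting week thresholds (1.57 / 6.57 / 5 weeks) to
#' their day equivalents (11 / 46 / 35 days) by rounding `weeks * 7` to the
#' nearest integer day, so detection on either denomination is identical for
#' integer-day intervals.
#'
#' @param interval_decrease_min_weeks,interval_post_max_low_weeks,interval_post_max_high_weeks
#'   interval thresholds in weeks.
#' @param ... forwarded to [do_thresholds()] (dose thresholds).
#' @return named list of thresholds in days and mg/kg.
#' @export
do_thresholds_weeks <- function(interval_decrease_min_weeks = 1.57,
                                interval_post_max_low_weeks = 6.57,
                                interval_post_max_high_weeks = 5,
                                ...) {
  do_thresholds(
    interval_decrease_min_days =
      as.numeric(weeks_to_days(interval_decrease_min_weeks)),
    interval_post_max_low_days =
      as.numeric(weeks_to_days(interval_post_max_low_weeks)),
    interval_post_max_high_days =
      as.numeric(weeks_to_days(interval_post_max_high_weeks)),
    ...
  )
}

#' Dose level in mg/kg
#'
#' @param dose_mg administered dose (mg), positive.
#' @param weight_kg resolved body weight (kg), positive.
#' @return dose level `dose_mg / weight_kg` (mg/kg).
#' @export
dose_level <- function(dose_mg, weight_kg) {
  if (any(is.na(dose_mg)) || any(dose_mg <= 0)) {
    stop("dose_mg must be positive", call. = FALSE)
  }
  if (any(is.na(weight_kg)) || any(weight_kg <= 0)) {
    stop("weight_kg must be positive (resolve missing weights first)",
         call. = FALSE)
  }
  dose_mg / weight_kg
}

#' Resolve dose levels for an infusion table
#'
#' Weight at each infusion is the recorded weight, else the most recent
#' prior recorded weight, else the patient's first recorded weight anywhere;
#' a patient with no recorded weight at all is an error.  The resulting
#' mg/kg dose level is rounded to 2 decimals before any thresholding, to
#' suppress float noise from the mg/weight division.
#'
#' @param infusions validated infusion table.
#' @return `infusions` with `dose_mg_kg` added.
#' @export
resolve_dose_levels <- function(infusions) {
  out <- infusions[order(infusions$patient_id, infusions$date), , drop = FALSE]
  resolved <- unlist(lapply(split(out$weight_kg, out$patient_id), function(w) {
    if (all(is.na(w))) return(w)
    f <- locf_fill(w)
    f[is.na(f)] <- f[!is.na(f)][1]
    f
  }), use.names = FALSE)
  if (anyNA(resolved)) {
    bad <- unique(out$patient_id[is.na(resolved)])
    stop(sprintf("no recorded weight anywhere for patient(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  out$dose_mg_kg <- round(dose_level(out$dose_mg, resolved), 2)
  rownames(out) <- NULL
  out
}

.empty_do_events <- function() {
  data.frame(patient_id = character(), date = as.Date(character()),
             trigger = character(), prior_interval_days = numeric(),
             posterior_interval_days = numeric(), prior_dose_mg_kg = numeric(),
             posterior_dose_mg_kg = numeric(), meets_low = logical(),
             meets_high = logical(), stringsAsFactors = FALSE)
}

#' Detect dose-optimization events
#'
#' Evaluates consecutive interval pairs and consecutive dose-level pairs in
#' the maintenance phase (infusions strictly more than `maintenance_after_days`
#' days after the patient's first infusion, so the induction step-up from a
#' 2-week to a 4-week gap is never flagged).  An event is emitted at the
#' posterior infusion date whenever the low criteria fire; `meets_high`
#' flags events that also satisfy the high criteria.
#'
#' @param infusions infusion table; `dose_mg_kg` is computed via
#'   [resolve_dose_levels()] if absent.
#' @param thresholds a [do_thresholds()] list.
#' @param maintenance_after_days maintenance phase starts strictly after this
#'   many days from the first infusion (default 63 = after Week 9).
#' @return data.frame of dose-optimization events sorted by patient and
#'   date: trigger (`interval`/`dose`/`both`), prior/posterior interval and
#'   dose level, and the threshold level(s) met.
#' @export
detect_dose_optimizations <- function(infusions,
                                      thresholds = do_thresholds(),
                                      maintenance_after_days = 63) {
  if (!"dose_mg_kg" %in% names(infusions)) {
    infusions <- resolve_dose_levels(infusions)
  }
  th <- thresholds
  ord <- order(infusions$patient_id, infusions$date)
  all_dates <- as.numeric(infusions$date)[ord]
  all_lev <- infusions$dose_mg_kg[ord]
  idx_by_pat <- split(seq_along(ord), infusions$patient_id[ord])
  res <- list()
  for (pid in names(idx_by_pat)) {
    rows <- idx_by_pat[[pid]]
    first_day <- all_dates[rows[1]]
    keep <- all_dates[rows] > first_day + maintenance_after_days
    k <- sum(keep)
    if (k < 2) next
    d <- all_dates[rows][keep] - first_day
    lev <- all_lev[rows][keep]
    m_dates <- all_dates[rows][keep]

    # candidate events live at infusions 2..k (posterior of a dose pair) and
    # 3..k (posterior of an interval pair)
    dose_lo <- dose_hi <- int_lo <- int_hi <- rep(FALSE, k)
    pri_int <- post_int <- pri_dose <- post_dose <- rep(NA_real_, k)

    dd <- diff(lev)
    dose_lo[-1] <- dd >= th$dose_increase_min_mg_kg &
      lev[-1] >= th$dose_post_min_low_mg_kg
    dose_hi[-1] <- dd >= th$dose_increase_min_mg_kg &
      lev[-1] >= th$dose_post_min_high_mg_kg
    pri_dose[-1] <- lev[-k]
    post_dose[-1] <- lev[-1]

    if (k >= 3) {
      v <- diff(d)                       # k-1 intervals
      dec <- v[-length(v)] - v[-1]       # k-2 decreases
      post_v <- v[-1]
      idx <- 3:k
      int_lo[idx] <- dec >= th$interval_decrease_min_days &
        post_v <= th$interval_post_max_low_days
      int_hi[idx] <- dec >= th$interval_decrease_min_days &
        post_v <= th$interval_post_max_high_days
      pri_int[idx] <- v[-length(v)]
      post_int[idx] <- post_v
    }

    fire <- dose_lo | int_lo
    if (!any(fire)) next
    j <- which(fire)
    res[[length(res) + 1L]] <- list(
      patient_id = rep(pid, length(j)),
      date = m_dates[j],
      trigger = ifelse(dose_lo[j] & int_lo[j], "both",
                       ifelse(dose_lo[j], "dose", "interval")),
      prior_interval_days = pri_int[j],
      posterior_interval_days = post_int[j],
      prior_dose_mg_kg = pri_dose[j],
      posterior_dose_mg_kg = post_dose[j],
      meets_high = int_hi[j] | dose_hi[j]
    )
  }
  if (!length(res)) return(.empty_do_events())
  pull <- function(f) unlist(lapply(res, `[[`, f), use.names = FALSE)
  out <- data.frame(
    patient_id = pull("patient_id"),
    date = as.Date(pull("date"), origin = "1970-01-01"),
    trigger = pull("trigger"),
    prior_interval_days = pull("prior_interval_days"),
    posterior_interval_days = pull("posterior_interval_days"),
    prior_dose_mg_kg = pull("prior_dose_mg_kg"),
    posterior_dose_mg_kg = pull("posterior_dose_mg_kg"),
    meets_low = TRUE,
    meets_high = pull("meets_high"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.events_at_level <- function(events, level) {
  level <- match.arg(level, c("low", "high"))
  if (level == "high") events[events$meets_high, , drop = FALSE] else events
}

#' Did a dose optimization precede a TDM date?
#'
#' @param events dose-optimization events for one patient.
#' @param tdm_date the TDM blood-draw date.
#' @param level threshold level, `"low"` or `"high"`.
#' @return `TRUE` iff an event at the given level has date strictly before
#'   `tdm_date`.
#' @export
prior_do_flag <- function(events, tdm_date, level = "low") {
  ev <- .events_at_level(events, level)
  any(ev$date < as.Date(tdm_date))
}

#' First dose optimization within a post-TDM window
#'
#' The window is `(tdm_date, tdm_date + window_weeks * 7]`: exclusive of the
#' TDM day itself (a same-day pre-draw dose change is not post-TDM) and
#' inclusive of the right edge.
#'
#' @param events dose-optimization events for one patient.
#' @param tdm_date the TDM blood-draw date.
#' @param window_weeks post-TDM window; 9 is the production setting and 17
#'   the sensitivity setting (others allowed with a warning).
#' @param level threshold level, `"low"` or `"high"`.
#' @return list with `hit` (logical) and `first_do_date` (`Date` or `NA`).
#' @export
do_within_window <- function(events, tdm_date, window_weeks = 9,
                             level = "low") {
  if (!window_weeks %in% c(9, 17)) {
    warning(sprintf("non-standard post-TDM window of %s weeks", window_weeks),
            call. = FALSE)
  }
  tdm_date <- as.Date(tdm_date)
  ev <- .events_at_level(events, level)
  sel <- ev$date > tdm_date & ev$date <= tdm_date + window_weeks * 7L
  if (any(sel)) {
    list(hit = TRUE, first_do_date = min(ev$date[sel]))
  } else {
    list(hit = FALSE, first_do_date = as.Date(NA))
  }
}
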