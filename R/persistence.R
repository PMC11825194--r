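# Treatment persistence: the grace-period discontinuation rule and
# Kaplan-Meier estimation.

#' Derive a persistence outcome from an infusion history
#'
#' Scans consecutive inter-infusion gaps (and the final infusion-to-censor
#' gap) over the *full* treatment history.  The first gap strictly greater
#' than `gap_weeks * 7` days deems the patient discontinued as of 8 weeks
#' (56 days) after the last infusion preceding the gap; otherwise the
#' patient is right-censored at `censor_date`.  When the 8-week offset lands
#' after the censoring date the patient is censored at `censor_date` instead
#' (a discontinuation cannot be placed after the end of data).  Only time
#' after `index_date` contributes to the duration, so subgroup analyses can
#' index at a later date while gaps are still judged on the whole history.
#'
#' @param dates infusion dates (`Date` vector, any order; duplicates
#'   collapsed).
#' @param index_date index date the duration is measured from.
#' @param censor_date administrative censoring date.
#' @param gap_weeks grace period in weeks; 20 is the production rule and 12
#'   the sensitivity rule.
#' @param patient_id optional id carried into the result.
#' @return one-row data.frame: `patient_id`, `index_date`, `duration_days`,
#'   `discontinued`, `discontinuation_date`, `censor_date`,
#'   `gap_rule_weeks`.
#' @export
derive_persistence <- function(dates, index_date, censor_date,
                               gap_weeks = 20, patient_id = NA_character_) {
  dates <- sort(unique(as.Date(dates)))
  index_date <- as.Date(index_date)
  censor_date <- as.Date(censor_date)
  if (length(dates) == 0) {
    stop("at least one infusion is required", call. = FALSE)
  }
  if (index_date > censor_date) {
    stop("index_date must be on/before censor_date", call. = FALSE)
  }
  if (!any(dates >= index_date)) {
    stop("at least one infusion on/after index_date is required",
         call. = FALSE)
  }
  gap_days <- as.integer(c(diff(dates), censor_date - dates[length(dates)]))
  hit <- which(gap_days > gap_weeks * 7L)
  discontinued <- FALSE
  disc_date <- as.Date(NA)
  end_date <- censor_date
  if (length(hit)) {
    candidate <- dates[hit[1]] + 56L
    if (candidate <= censor_date) {
      discontinued <- TRUE
      disc_date <- candidate
      end_date <- candidate
    }
  }
  data.frame(
    patient_id = patient_id,
    index_date = index_date,
    duration_days = as.integer(end_date - index_date),
    discontinued = discontinued,
    discontinuation_date = disc_date,
    censor_date = censor_date,
    gap_rule_weeks = as.integer(gap_weeks),
    stringsAsFactors = FALSE
  )
}

#' Derive persistence outcomes for a whole cohort
#'
#' Applies [derive_persistence()] per patient.  By default each patient is
#' indexed at their first infusion (treatment initiation); pass `index` to
#' use other index dates (e.g. the first-TDM date for subgroup analyses).
#'
#' @param infusions validated infusion table.
#' @param censor_date administrative censoring date.
#' @param gap_weeks grace period in weeks.
#' @param index optional data.frame `patient_id`, `index_date`; patients not
#'   listed are skipped when `index` is supplied.
#' @return data.frame of persistence outcomes, one row per patient.
#' @export
derive_persistence_table <- function(infusions, censor_date, gap_weeks = 20,
                                     index = NULL) {
  censor_date <- as.Date(censor_date)
  by_pat <- split(infusions$date, infusions$patient_id)
  if (is.null(index)) {
    ids <- names(by_pat)
    idx_dates <- as.Date(vapply(by_pat, function(d) min(as.numeric(d)),
                                numeric(1)), origin = "1970-01-01")
  } else {
    ids <- as.character(index$patient_id)
    missing_ids <- setdiff(ids, names(by_pat))
    if (length(missing_ids)) {
      stop(sprintf("no infusions for indexed patient(s): %s",
                   paste(utils::head(missing_ids, 5), collapse = ", ")),
           call. = FALSE)
    }
    idx_dates <- as.Date(index$index_date)
  }
  n <- length(ids)
  duration <- integer(n)
  discontinued <- logical(n)
  disc_date <- rep(as.Date(NA), n)
  cnum <- as.numeric(censor_date)
  for (i in seq_len(n)) {
    d <- sort(unique(as.numeric(by_pat[[ids[i]]])))
    idx <- as.numeric(idx_dates[i])
    if (idx > cnum) {
      stop(sprintf("index_date after censor_date for patient %s", ids[i]),
           call. = FALSE)
    }
    if (!any(d >= idx)) {
      stop(sprintf("no infusion on/after index_date for patient %s", ids[i]),
           call. = FALSE)
    }
    gaps <- c(diff(d), cnum - d[length(d)])
    hit <- which(gaps > gap_weeks * 7)
    end <- cnum
    if (length(hit)) {
      candidate <- d[hit[1]] + 56
      if (candidate <= cnum) {
        discontinued[i] <- TRUE
        disc_date[i] <- as.Date(candidate, origin = "1970-01-01")
        end <- candidate
      }
    }
    duration[i] <- as.integer(end - idx)
  }
  data.frame(
    patient_id = ids, index_date = idx_dates, duration_days = duration,
    discontinued = discontinued, discontinuation_date = disc_date,
    censor_date = censor_date, gap_rule_weeks = as.integer(gap_weeks),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Kaplan-Meier persistence curve
#'
#' Unstratified, unadjusted product-limit estimator with right censoring
#' (events processed before censorings at tied times), computed by
#' [survival::survfit()].
#'
#' @param outcomes persistence-outcome data.frame with `duration_days` and
#'   `discontinued`.
#' @return object of class `km_curve`: event-time grid, survival estimates,
#'   at-risk/event/censor counts, and the underlying `survfit` fit.
#' @export
km_estimate <- function(outcomes) {
  if (nrow(outcomes) < 1) stop("at least one outcome required", call. = FALSE)
  if (any(outcomes$duration_days < 0)) {
    stop("negative duration_days in outcomes", call. = FALSE)
  }
  fit <- survival::survfit(
    survival::Surv(duration_days, discontinued) ~ 1,
    data = outcomes, conf.type = "log-log"
  )
  structure(
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event, n_censor = fit$n.censor, n = nrow(outcomes),
         fit = fit),
    class = "km_curve"
  )
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve a `km_curve`.
#' @param times numeric vector of times (days).
#' @return survival probabilities at `times` (1 before the first event).
#' @export
km_survival_at <- function(curve, times) {
  s <- c(1, curve$surv)
  s[findInterval(times, curve$time) + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier persistence curve: %d subjects, %d events\n",
              x$n, sum(x$n_event)))
  if (length(x$time)) {
    cat(sprintf("  follow-up %d..%d days; S(last event time) = %.4f\n",
                min(x$time), max(x$time), min(x$surv)))
  }
  invisible(x)
}
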