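# Counting-process construction and stratified proportional-hazards
# modelling with a time-dependent exposure.  Exposure is coded as a
# right-continuous 0/1 step function that switches at most once, so person-
# time before the exposure date is correctly classified as unexposed and
# immortal-time bias is avoided.

#' Build counting-process rows for one subject
#'
#' One `(start, stop]` row if the subject is never exposed during follow-up
#' (or the exposure lands on/after the end of follow-up: exposure must
#' precede any risk-set contribution), otherwise two rows split at the
#' exposure day with exposure 0 then 1.  The terminal row carries the event
#' indicator.
#'
#' @param duration_days follow-up duration (> 0).
#' @param discontinued event indicator at `duration_days`.
#' @param exposure_day day the exposure switches on (strictly positive), or
#'   `NA` for never exposed.
#' @param covariates named list of fixed covariate values.
#' @param stratum stratum value (year of treatment initiation).
#' @param patient_id optional id.
#' @return data.frame of counting-process rows.
#' @export
build_counting_process <- function(duration_days, discontinued,
                                   exposure_day = NA, covariates = list(),
                                   stratum = NA, patient_id = NA_character_) {
  if (is.na(duration_days) || duration_days <= 0) {
    stop("duration_days must be > 0", call. = FALSE)
  }
  if (!is.na(exposure_day) && exposure_day <= 0) {
    stop("exposure_day must be strictly positive (same-day exposure is not a",
         " post-index exposure)", call. = FALSE)
  }
  exposed <- !is.na(exposure_day) && exposure_day < duration_days
  if (exposed) {
    rows <- data.frame(
      patient_id = patient_id,
      start = c(0, exposure_day),
      stop = c(exposure_day, duration_days),
      event = c(FALSE, isTRUE(discontinued)),
      exposure = c(0L, 1L),
      stringsAsFactors = FALSE
    )
  } else {
    rows <- data.frame(patient_id = patient_id, start = 0,
                       stop = duration_days, event = isTRUE(discontinued),
                       exposure = 0L, stringsAsFactors = FALSE)
  }
  for (nm in names(covariates)) rows[[nm]] <- covariates[[nm]]
  rows$stratum <- stratum
  rows
}

#' Build a counting-process table for a cohort
#'
#' Vectorised version of [build_counting_process()].  Subjects with
#' non-positive durations cannot contribute risk time and are dropped with a
#' warning.
#'
#' @param df data.frame with `patient_id`, `duration_days`, `discontinued`,
#'   `exposure_day` (`NA` = never exposed), a `stratum` column, and any
#'   fixed covariate columns (passed through unchanged).
#' @return counting-process data.frame with `start`, `stop`, `event`,
#'   `exposure` plus the covariate and stratum columns.
#' @export
build_counting_process_table <- function(df) {
  if (any(!is.na(df$exposure_day) & df$exposure_day <= 0)) {
    stop("exposure_day must be strictly positive", call. = FALSE)
  }
  zero <- df$duration_days <= 0
  if (any(zero)) {
    warning(sprintf("%d subject(s) with zero follow-up dropped", sum(zero)),
            call. = FALSE)
    df <- df[!zero, , drop = FALSE]
  }
  covar_cols <- setdiff(names(df), c("duration_days", "discontinued",
                                     "exposure_day"))
  e <- !is.na(df$exposure_day) & df$exposure_day < df$duration_days
  first <- df[covar_cols]
  first$start <- 0
  first$stop <- ifelse(e, df$exposure_day, df$duration_days)
  first$event <- ifelse(e, FALSE, df$discontinued)
  first$exposure <- 0L
  second <- df[e, covar_cols, drop = FALSE]
  second$start <- df$exposure_day[e]
  second$stop <- df$duration_days[e]
  second$event <- df$discontinued[e]
  second$exposure <- 1L
  out <- rbind(first, second)
  out <- out[order(out$patient_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split counting-process rows at a set of times
#'
#' Episode-splits every `(start, stop]` row at the supplied cut times that
#' fall strictly inside it, preserving covariates; the event indicator moves
#' to the terminal piece.  Splitting at all event times makes a covariate of
#' the form `f(stop)` an exact time-varying covariate in the partial
#' likelihood.
#'
#' @param cp counting-process data.frame.
#' @param cut_times numeric vector of times.
#' @return expanded counting-process data.frame.
#' @export
split_counting_process <- function(cp, cut_times) {
  cuts <- sort(unique(cut_times))
  if (!length(cuts) || !nrow(cp)) return(cp)
  pieces <- vector("list", nrow(cp))
  for (i in seq_len(nrow(cp))) {
    s <- cp$start[i]; e <- cp$stop[i]
    inner <- cuts[cuts > s & cuts < e]
    if (!length(inner)) {
      pieces[[i]] <- cp[i, , drop = FALSE]
      next
    }
    bounds <- c(s, inner, e)
    k <- length(bounds) - 1L
    block <- cp[rep(i, k), , drop = FALSE]
    block$start <- bounds[-length(bounds)]
    block$stop <- bounds[-1]
    block$event <- c(rep(FALSE, k - 1L), cp$event[i])
    pieces[[i]] <- block
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

.coef_table <- function(fit) {
  s <- summary(fit)$coefficients
  data.frame(
    term = rownames(s),
    coef = s[, "coef"],
    se = s[, "se(coef)"],
    hr = exp(s[, "coef"]),
    hr_lo = exp(s[, "coef"] - 1.96 * s[, "se(coef)"]),
    hr_hi = exp(s[, "coef"] + 1.96 * s[, "se(coef)"]),
    p = s[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fit a stratified Cox model on counting-process data
#'
#' Partial-likelihood fit of
#' `Surv(start, stop, event) ~ exposure + covariates + strata(stratum)` with
#' the Efron tie approximation by default.  A constant exposure column
#' (e.g. nobody exposed) makes the exposure effect inestimable; the term is
#' dropped with a warning and the remaining fit returned.  Monotone
#' likelihood (complete separation) is flagged in `notes`.
#'
#' @param cp counting-process data.frame.
#' @param covariates character vector of fixed covariate column names.
#' @param strata_col name of the stratum column, or `NULL` for unstratified.
#' @param exposure name of the exposure column (`NULL` to omit).
#' @param extra_terms additional model terms (column names or interaction
#'   expressions) appended to the formula.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param model_id label carried into the result.
#' @return object of class `cox_model_fit`: coefficient table with HRs and
#'   95% CIs, log-likelihoods, counts, notes, and the underlying `coxph`
#'   fit.
#' @export
fit_cox <- function(cp, covariates = character(), strata_col = "stratum",
                    exposure = "exposure", extra_terms = character(),
                    ties = c("efron", "breslow"), model_id = "M1") {
  ties <- match.arg(ties)
  notes <- character()
  exposure_dropped <- FALSE
  if (!is.null(exposure)) {
    if (length(unique(cp[[exposure]])) < 2) {
      warning(sprintf("exposure column '%s' is constant; term dropped",
                      exposure), call. = FALSE)
      exposure_dropped <- TRUE
      notes <- c(notes, "exposure term dropped (constant column)")
      exposure <- NULL
    }
  }
  terms <- c(exposure, covariates, extra_terms)
  if (!is.null(strata_col)) {
    terms <- c(terms, sprintf("strata(%s)", strata_col))
  }
  if (!length(terms)) stop("no model terms", call. = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(start, stop, event) ~",
                                 paste(terms, collapse = " + ")))
  warn <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = cp, ties = ties),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (length(warn)) notes <- c(notes, warn)
  ct <- .coef_table(fit)
  if (any(is.na(ct$coef))) {
    notes <- c(notes, sprintf("collinear term(s) dropped: %s",
                              paste(ct$term[is.na(ct$coef)], collapse = ", ")))
  }
  sep <- !is.na(ct$coef) & (abs(ct$coef) > 12 | ct$se > 100)
  if (any(sep)) {
    notes <- c(notes, sprintf(
      "possible monotone likelihood (complete separation) for: %s",
      paste(ct$term[sep], collapse = ", ")))
  }
  structure(
    list(model_id = model_id, formula = fml, coefficients = ct,
         loglik = fit$loglik, n = fit$n, nevent = fit$nevent,
         exposure_term = if (exposure_dropped) NA_character_ else "exposure",
         exposure_dropped = exposure_dropped, ties = ties, notes = notes,
         fit = fit),
    class = "cox_model_fit"
  )
}

#' @export
print.cox_model_fit <- function(x, ...) {
  cat(sprintf("Cox model %s (%s ties): n = %d rows, %d events\n",
              x$model_id, x$ties, x$n, x$nevent))
  ct <- x$coefficients
  ct[c("coef", "se", "hr", "hr_lo", "hr_hi")] <-
    lapply(ct[c("coef", "se", "hr", "hr_lo", "hr_hi")], round, 4)
  ct$p <- signif(ct$p, 3)
  print(ct, row.names = FALSE)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Exposure hazard ratio of a fitted model
#'
#' @param fit a `cox_model_fit`.
#' @return one-row data.frame `hr`, `hr_lo`, `hr_hi`, `p`, `coef`, `se`, or
#'   `NULL` if the exposure term was dropped.
#' @export
exposure_hr <- function(fit) {
  if (fit$exposure_dropped) return(NULL)
  ct <- fit$coefficients
  row <- ct[ct$term == "exposure", , drop = FALSE]
  if (!nrow(row)) return(NULL)
  row[c("hr", "hr_lo", "hr_hi", "p", "coef", "se")]
}

#' Fit the four-model ladder and select a model
#'
#' * `M1`: exposure + fixed covariates (main effects);
#' * `M2`: `M1` + exposure-by-covariate interactions;
#' * `M3`: `M1` + exposure-by-log(time) interaction (the proportional-hazards
#'   check for the exposure);
#' * `M4`: both extensions.
#'
#' Interactions are retained only if jointly significant (likelihood-ratio
#' test of `M2` vs `M1` at `alpha`); the proportional-hazards assumption is
#' declared violated for the exposure if the exposure-by-log(time) Wald test
#' in `M3` is significant at `alpha`.  The selected model is the simplest one
#' consistent with those two tests.  The log(time) interaction is fitted
#' exactly by episode-splitting the data at every event time and adding
#' `exposure * log(stop)` as a row-level covariate.  A model that fails to
#' fit is recorded and the ladder continues; all four failing is an error.
#'
#' @inheritParams fit_cox
#' @param alpha significance level for both tests.
#' @return object of class `model_ladder`: the four fits (or error
#'   messages), the two test p-values, `ph_violated`, `selected_id` and the
#'   selected fit.
#' @export
model_ladder <- function(cp, covariates = character(),
                         strata_col = "stratum", alpha = 0.05,
                         ties = "efron") {
  fits <- list()
  safe_fit <- function(expr) tryCatch(expr, error = function(e) e)

  fits$M1 <- safe_fit(fit_cox(cp, covariates, strata_col, ties = ties,
                              model_id = "M1"))
  if (inherits(fits$M1, "error")) {
    stop("ladder error: baseline model M1 failed: ",
         conditionMessage(fits$M1), call. = FALSE)
  }
  inter <- if (length(covariates)) paste0("exposure:", covariates)
           else character()
  fits$M2 <- if (length(inter)) {
    safe_fit(fit_cox(cp, covariates, strata_col, extra_terms = inter,
                     ties = ties, model_id = "M2"))
  } else NULL

  cps <- split_counting_process(cp, sort(unique(cp$stop[cp$event])))
  cps$exposure_x_logt <- cps$exposure * log(cps$stop)
  fits$M3 <- safe_fit(fit_cox(cps, covariates, strata_col,
                              extra_terms = "exposure_x_logt", ties = ties,
                              model_id = "M3"))
  fits$M4 <- if (length(inter)) {
    safe_fit(fit_cox(cps, covariates, strata_col,
                     extra_terms = c(inter, "exposure_x_logt"), ties = ties,
                     model_id = "M4"))
  } else NULL

  p_int <- NA_real_
  if (!is.null(fits$M2) && !inherits(fits$M2, "error")) {
    l1 <- fits$M1$loglik[2]
    l2 <- fits$M2$loglik[2]
    df <- sum(!is.na(fits$M2$coefficients$coef)) -
      sum(!is.na(fits$M1$coefficients$coef))
    if (df > 0) p_int <- stats::pchisq(2 * (l2 - l1), df, lower.tail = FALSE)
  }
  p_ph <- NA_real_
  if (!inherits(fits$M3, "error")) {
    ct <- fits$M3$coefficients
    p_ph <- ct$p[ct$term == "exposure_x_logt"]
    if (!length(p_ph)) p_ph <- NA_real_
  }
  int_sig <- isTRUE(p_int < alpha)
  ph_violated <- isTRUE(p_ph < alpha)
  selected_id <- if (int_sig && ph_violated) "M4"
    else if (int_sig) "M2"
    else if (ph_violated) "M3"
    else "M1"
  selected <- fits[[selected_id]]
  if (is.null(selected) || inherits(selected, "error")) {
    selected_id <- "M1"
    selected <- fits$M1
  }
  structure(
    list(models = fits, p_interactions = p_int, p_ph = p_ph,
         ph_violated = ph_violated, alpha = alpha,
         selected_id = selected_id, selected = selected),
    class = "model_ladder"
  )
}

#' @export
print.model_ladder <- function(x, ...) {
  cat("Four-model ladder\n")
  cat(sprintf("  joint interaction test p = %s\n",
              format(x$p_interactions, digits = 3)))
  cat(sprintf("  exposure x log(time) p = %s (PH %s)\n",
              format(x$p_ph, digits = 3),
              if (x$ph_violated) "violated" else "not violated"))
  cat(sprintf("  selected model: %s\n", x$selected_id))
  invisible(x)
}

#' Hazard ratio of the exposure at a fixed time
#'
#' For a fit with an exposure-by-log(time) interaction, the exposure hazard
#' ratio at time `t` is `exp(b_exposure + b_interaction * log(t_days))`; its
#' CI follows from the delta method on the linear combination (which is
#' exact here, the combination being linear in the coefficients).
#'
#' @param fit a `cox_model_fit` containing `exposure` and `exposure_x_logt`
#'   terms, or a list with elements `coef` (named numeric, names `exposure`
#'   and `exposure_x_logt`) and `vcov` (their 2x2 covariance).
#' @param t_weeks evaluation times in weeks (the study settings are 4 and 6).
#' @return data.frame with `t_weeks`, `t_days`, `hr`, `hr_lo`, `hr_hi`.
#' @export
hr_at_time <- function(fit, t_weeks = c(4, 6)) {
  if (inherits(fit, "cox_model_fit")) {
    b <- stats::coef(fit$fit)
    V <- stats::vcov(fit$fit)
  } else {
    b <- fit$coef
    V <- fit$vcov
    if (is.null(V)) stop("covariance of the two coefficients is required",
                         call. = FALSE)
    if (is.null(dimnames(V))) dimnames(V) <- list(names(b), names(b))
  }
  need <- c("exposure", "exposure_x_logt")
  if (!all(need %in% names(b)) || !all(need %in% rownames(V))) {
    stop("fit must contain 'exposure' and 'exposure_x_logt' terms with their",
         " covariance", call. = FALSE)
  }
  t_days <- t_weeks * 7
  lt <- log(t_days)
  est <- b["exposure"] + b["exposure_x_logt"] * lt
  se <- sqrt(V["exposure", "exposure"] +
             lt^2 * V["exposure_x_logt", "exposure_x_logt"] +
             2 * lt * V["exposure", "exposure_x_logt"])
  data.frame(t_weeks = t_weeks, t_days = t_days, hr = exp(est),
             hr_lo = exp(est - 1.96 * se), hr_hi = exp(est + 1.96 * se),
             row.names = NULL)
}
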