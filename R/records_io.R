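# Reading, validation and writing of the three input tables (patients,
# infusions, TDM results) and of derived analysis tables.  These schemas are
# the contract every downstream module consumes.

#' Canonical province/region levels
#' @export
pk_provinces <- c("Alberta", "Atlantic", "BritishColumbia",
                  "Ontario", "Quebec", "SaskatchewanManitoba")

pk_schemas <- list(
  patients  = c("patient_id", "diagnosis", "age_at_initiation", "gender",
                "province_region"),
  infusions = c("patient_id", "date", "dose_mg", "weight_kg"),
  tdm       = c("patient_id", "date", "ifx_conc_ug_ml", "ati_status")
)

.read_raw <- function(path, table) {
  if (!file.exists(path)) {
    stop(sprintf("input file for '%s' table not found: %s", table, path),
         call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  names(df) <- tolower(trimws(names(df)))
  missing_cols <- setdiff(pk_schemas[[table]], names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error in '%s' table (%s): missing column(s) %s",
                 table, path, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  df
}

.collect_row_errors <- function(errors, table, skip_bad_rows) {
  if (!length(errors)) return(invisible(NULL))
  msg <- sprintf("%d invalid row(s) in '%s' table:\n%s", length(errors), table,
                 paste(utils::head(unlist(errors), 10), collapse = "\n"))
  if (skip_bad_rows) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  invisible(NULL)
}

.num_or_na <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  out[!nzchar(x)] <- NA_real_
  out
}

#' Validate a patient table
#'
#' Coerces types, enforces invariants (unique `patient_id`, diagnosis in
#' CD/UC, gender male/female, province in [pk_provinces], non-negative age)
#' and either aborts or drops offending rows.
#'
#' @param df data.frame with (at least) the patient schema columns.
#' @param skip_bad_rows drop invalid rows with a warning instead of aborting.
#' @return validated data.frame.
#' @export
validate_patients <- function(df, skip_bad_rows = FALSE) {
  df <- as.data.frame(df)
  names(df) <- tolower(names(df))
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    dup <- unique(df$patient_id[duplicated(df$patient_id)])
    stop(sprintf("schema error: duplicate patient_id in patient table: %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  df$diagnosis <- toupper(trimws(as.character(df$diagnosis)))
  df$gender <- tolower(trimws(as.character(df$gender)))
  df$age_at_initiation <- .num_or_na(df$age_at_initiation)
  df$province_region <- as.character(df$province_region)
  errors <- list()
  bad <- rep(FALSE, nrow(df))
  flag <- function(i, what) {
    errors[[length(errors) + 1L]] <<- sprintf("row %d (patient %s): %s", i,
                                              df$patient_id[i], what)
    bad[i] <<- TRUE
  }
  for (i in seq_len(nrow(df))) {
    if (!df$diagnosis[i] %in% c("CD", "UC")) flag(i, "diagnosis not CD/UC")
    if (!df$gender[i] %in% c("male", "female")) flag(i, "gender not male/female")
    if (is.na(df$age_at_initiation[i]) || df$age_at_initiation[i] < 0) {
      flag(i, "age_at_initiation missing or negative")
    }
    if (!df$province_region[i] %in% pk_provinces) {
      flag(i, "unknown province_region")
    }
  }
  .collect_row_errors(errors, "patients", skip_bad_rows)
  df[!bad, , drop = FALSE]
}

#' Validate an infusion table
#'
#' Parses ISO-8601 dates, enforces positive doses and weights, collapses
#' same-day duplicate administrations per patient by summing `dose_mg`
#' (split-bag administrations; preserves the total administered dose and
#' avoids zero-length intervals) and returns rows sorted by patient and date.
#'
#' @inheritParams validate_patients
#' @return validated data.frame sorted by `patient_id`, `date`.
#' @export
validate_infusions <- function(df, skip_bad_rows = FALSE) {
  df <- as.data.frame(df)
  names(df) <- tolower(names(df))
  df$patient_id <- as.character(df$patient_id)
  raw_date <- as.character(df$date)
  df$date <- parse_iso_date(df$date)
  df$dose_mg <- .num_or_na(df$dose_mg)
  df$weight_kg <- .num_or_na(df$weight_kg)
  errors <- list()
  bad <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (is.na(df$date[i])) {
      errors[[length(errors) + 1L]] <-
        sprintf("row %d (patient %s): unparseable date '%s'", i,
                df$patient_id[i], raw_date[i])
      bad[i] <- TRUE
    } else if (is.na(df$dose_mg[i]) || df$dose_mg[i] <= 0) {
      errors[[length(errors) + 1L]] <-
        sprintf("row %d (patient %s): dose_mg missing or non-positive", i,
                df$patient_id[i])
      bad[i] <- TRUE
    } else if (!is.na(df$weight_kg[i]) && df$weight_kg[i] <= 0) {
      errors[[length(errors) + 1L]] <-
        sprintf("row %d (patient %s): weight_kg non-positive", i,
                df$patient_id[i])
      bad[i] <- TRUE
    }
  }
  .collect_row_errors(errors, "infusions", skip_bad_rows)
  df <- df[!bad, , drop = FALSE]
  if (nrow(df)) {
    key <- paste(df$patient_id, format(df$date, "%Y-%m-%d"))
    if (anyDuplicated(key)) {
      dose <- tapply(df$dose_mg, key, sum)
      wt <- tapply(df$weight_kg, key, function(w) {
        w <- w[!is.na(w)]
        if (length(w)) w[1] else NA_real_
      })
      first <- !duplicated(key)
      df <- df[first, , drop = FALSE]
      key1 <- key[first]
      df$dose_mg <- as.numeric(dose[key1])
      df$weight_kg <- as.numeric(wt[key1])
    }
    df <- df[order(df$patient_id, df$date), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Validate a TDM table
#'
#' Parses dates, enforces non-negative concentrations (empty cell = no
#' recorded result), and normalises `ati_status` to
#' positive/negative/missing.  Rows are sorted by patient and blood-draw date.
#'
#' @inheritParams validate_patients
#' @return validated data.frame sorted by `patient_id`, `date`.
#' @export
validate_tdm <- function(df, skip_bad_rows = FALSE) {
  df <- as.data.frame(df)
  names(df) <- tolower(names(df))
  df$patient_id <- as.character(df$patient_id)
  raw_date <- as.character(df$date)
  df$date <- parse_iso_date(df$date)
  df$ifx_conc_ug_ml <- .num_or_na(df$ifx_conc_ug_ml)
  ati <- tolower(trimws(as.character(df$ati_status)))
  ati[is.na(ati) | !nzchar(ati)] <- "missing"
  df$ati_status <- ati
  errors <- list()
  bad <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (is.na(df$date[i])) {
      errors[[length(errors) + 1L]] <-
        sprintf("row %d (patient %s): unparseable date '%s'", i,
                df$patient_id[i], raw_date[i])
      bad[i] <- TRUE
    } else if (!is.na(df$ifx_conc_ug_ml[i]) && df$ifx_conc_ug_ml[i] < 0) {
      errors[[length(errors) + 1L]] <-
        sprintf("row %d (patient %s): negative ifx_conc_ug_ml", i,
                df$patient_id[i])
      bad[i] <- TRUE
    } else if (!df$ati_status[i] %in% c("positive", "negative", "missing")) {
      errors[[length(errors) + 1L]] <-
        sprintf("row %d (patient %s): ati_status must be positive/negative/missing",
                i, df$patient_id[i])
      bad[i] <- TRUE
    }
  }
  .collect_row_errors(errors, "tdm", skip_bad_rows)
  df <- df[!bad, , drop = FALSE]
  if (nrow(df)) {
    df <- df[order(df$patient_id, df$date), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read and validate the three cohort input tables
#'
#' Reads `patients.csv`, `infusions.csv` and `tdm.csv` (headers matched
#' case-insensitively, dates ISO-8601, empty cells = missing), applies all
#' schema invariants, and returns typed tables.  Any row-level violation
#' aborts the run unless `skip_bad_rows = TRUE`, in which case offending rows
#' are dropped with a warning carrying row-level diagnostics.
#'
#' @param patients_file,infusions_file,tdm_file CSV file paths.
#' @param skip_bad_rows drop invalid rows instead of aborting.
#' @return named list with elements `patients`, `infusions`, `tdm`.
#' @export
read_cohort_tables <- function(patients_file, infusions_file, tdm_file,
                               skip_bad_rows = FALSE) {
  list(
    patients  = validate_patients(.read_raw(patients_file, "patients"),
                                  skip_bad_rows),
    infusions = validate_infusions(.read_raw(infusions_file, "infusions"),
                                   skip_bad_rows),
    tdm       = validate_tdm(.read_raw(tdm_file, "tdm"), skip_bad_rows)
  )
}

#' Write an analysis table to CSV
#'
#' Stable column order, dates as ISO-8601, missing values as empty cells
#' (never sentinel numerics).  [read_analysis_table()] reproduces the table;
#' the round trip is bit-exact for all non-float fields.
#'
#' @param tab data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_analysis_table <- function(tab, path) {
  if (is.null(tab)) stop("table must not be NULL", call. = FALSE)
  tab <- as.data.frame(tab)
  for (j in seq_along(tab)) {
    if (inherits(tab[[j]], "Date")) tab[[j]] <- format(tab[[j]], "%Y-%m-%d")
  }
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("could not write table to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' Read an analysis table written by [write_analysis_table()]
#'
#' Column types are restored by inspection: ISO dates become `Date`,
#' TRUE/FALSE become logical, numeric-looking columns become integer or
#' double; anything else stays character with empty cells read as missing.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_analysis_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  for (j in seq_along(df)) {
    x <- df[[j]]
    present <- nzchar(x)
    if (!any(present)) {
      df[[j]] <- ifelse(present, x, NA_character_)
      next
    }
    v <- x[present]
    if (all(grepl("^\\d{4}-\\d{2}-\\d{2}$", v))) {
      out <- parse_iso_date(x)
      out[!present] <- as.Date(NA)
      df[[j]] <- out
    } else if (all(v %in% c("TRUE", "FALSE"))) {
      out <- as.logical(x)
      out[!present] <- NA
      df[[j]] <- out
    } else if (!anyNA(suppressWarnings(as.numeric(v)))) {
      num <- suppressWarnings(as.numeric(x))
      num[!present] <- NA_real_
      if (all(grepl("^-?\\d+$", v)) && max(abs(num), na.rm = TRUE) < 2^31) {
        num <- as.integer(num)
      }
      df[[j]] <- num
    } else {
      x[!present] <- NA_character_
      df[[j]] <- x
    }
  }
  df
}
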