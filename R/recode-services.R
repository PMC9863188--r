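# Health-service outcome recoding from linked administrative records:
# GP/specialist visit bins over the 12 months after survey return, unique
# dispensed medicines (ATC level 5) over a fixed April-September window, and
# hospital admission flags excluding pregnancy-related primary diagnoses.

GP_BINS <- c("<2", "2-3", "4-6", "7-9", "10-12", ">12")
SPECIALIST_BINS <- c("0", "1-2", "3+")
MEDICATION_BINS <- c("0", "1", "2", "3+")

#' Categorise a count of GP visits
#'
#' Bins: less than 2, 2-3, 4-6, 7-9, 10-12, more than 12 visits.
#'
#' @param n Non-negative integer vector of visit counts.
#' @return Factor with levels `<2`, `2-3`, `4-6`, `7-9`, `10-12`, `>12`.
#' @export
bin_gp_visits <- function(n) {
  check_count(n)
  cut(n, breaks = c(-Inf, 1, 3, 6, 9, 12, Inf), labels = GP_BINS)
}

#' Categorise a count of specialist visits
#'
#' Bins: no visits, 1-2 visits, 3 or more visits.
#'
#' @inheritParams bin_gp_visits
#' @return Factor with levels `0`, `1-2`, `3+`.
#' @export
bin_specialist_visits <- function(n) {
  check_count(n)
  cut(n, breaks = c(-Inf, 0, 2, Inf), labels = SPECIALIST_BINS)
}

#' Categorise a count of unique medications
#'
#' Bins: none, 1, 2, 3 or more distinct medicines.
#'
#' @inheritParams bin_gp_visits
#' @return Factor with levels `0`, `1`, `2`, `3+`.
#' @export
bin_medications <- function(n) {
  check_count(n)
  cut(n, breaks = c(-Inf, 0, 1, 2, Inf), labels = MEDICATION_BINS)
}

check_count <- function(n) {
  if (any(is.na(n)) || any(n < 0) || any(n != floor(n))) {
    abort("counts must be non-negative integers")
  }
  invisible(n)
}

check_date <- function(x, what) {
  x <- as.Date(x)
  if (any(is.na(x))) abort(sprintf("invalid %s date(s)", what))
  x
}

#' Validate level-5 ATC codes
#'
#' Level-5 (chemical substance) ATC codes are 7 characters:
#' letter, 2 digits, 2 letters, 2 digits (e.g. `N02BE01`).
#'
#' @param code Character vector of codes.
#' @return Invisibly, `code`; errors naming the offending records otherwise.
#' @export
check_atc5 <- function(code) {
  bad <- !grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", code)
  if (any(bad)) {
    abort(sprintf("malformed ATC level-5 code(s) in record(s) %s: %s",
                  paste(which(bad)[seq_len(min(5, sum(bad)))], collapse = ", "),
                  paste(unique(code[bad])[seq_len(min(5, length(unique(code[bad]))))],
                        collapse = ", ")))
  }
  invisible(code)
}

#' Test whether an ICD-10 primary diagnosis is pregnancy-related (O00-O9A)
#'
#' The exclusion range is tested on the three-character category prefix using
#' the ICD-10 ordering in which digits precede letters in the third position,
#' so the upper bound `O9A` is included while e.g. `O9B` (were it to exist)
#' would not be.
#'
#' @param code Character vector of ICD-10 codes (category or full code).
#' @return Logical vector.
#' @export
#' @examples
#' icd10_is_pregnancy(c("O80", "O9A", "K35", "N39"))
icd10_is_pregnancy <- function(code) {
  code <- toupper(as.character(code))
  if (any(!grepl("^[A-Z][0-9][0-9A-Z]", code))) {
    abort("unparseable ICD-10 code(s): category must be letter, digit, digit-or-letter")
  }
  c1 <- substr(code, 1, 1)
  c2 <- substr(code, 2, 2)
  c3 <- substr(code, 3, 3)
  # in [O00, O9A]: second char any digit; at O9x the third char may be a digit
  # or exactly "A" (digits sort before letters in position 3)
  c1 == "O" & (c2 != "9" | grepl("[0-9A]", c3))
}

count_in_window <- function(dates, start, end) {
  # half-open [start, end)
  vapply(seq_along(start), function(i) {
    sum(dates >= start[i] & dates < end[i])
  }, numeric(1))
}

#' Recode linked service records into categorical outcome variables
#'
#' Counts GP and specialist visits in the 12 months after survey return
#' (half-open window of `window_days` days), counts unique dispensed
#' medicines (distinct level-5 ATC codes) in the fixed 1 April - 30 September
#' window of the survey year, and derives hospital admission flags from
#' admissions in the 12-month window after excluding pregnancy-related
#' primary diagnoses (ICD-10 O00-O9A). Participants with no records in a
#' source contribute zero counts.
#'
#' @param survey_dates Data frame with columns `participant_id` and
#'   `return_date` (survey return date).
#' @param visits Data frame with columns `participant_id`, `provider_type`
#'   (`"gp"` or `"specialist"`) and `date`. May be `NULL`.
#' @param dispensings Data frame with columns `participant_id`, `atc_code`
#'   (level-5 ATC) and `date`. May be `NULL`.
#' @param admissions Data frame with columns `participant_id`,
#'   `admission_date`, `same_day` (logical) and `primary_icd10`. May be
#'   `NULL`.
#' @param window_days Length of the service-use window in days (default 365,
#'   i.e. `[return_date, return_date + 365)`).
#' @return Tibble with one row per participant: `participant_id`,
#'   `gp_category`, `specialist_category`, `medication_category`,
#'   `any_admission`, `same_day_admission`, `overnight_admission`.
#' @export
recode_service_use <- function(survey_dates, visits = NULL, dispensings = NULL,
                               admissions = NULL, window_days = 365L) {
  ids <- survey_dates$participant_id
  if (anyDuplicated(ids)) abort("duplicate participant_id in `survey_dates`")
  ret <- check_date(survey_dates$return_date, "survey return")
  win_end <- ret + window_days

  n_gp <- n_sp <- n_med <- integer(length(ids))
  same_day <- overnight <- logical(length(ids))

  if (!is.null(visits) && nrow(visits) > 0L) {
    vd <- check_date(visits$date, "visit")
    idx <- match(visits$participant_id, ids)
    if (anyNA(idx)) abort("visit record(s) for unknown participant_id")
    in_win <- vd >= ret[idx] & vd < win_end[idx]
    gp <- in_win & visits$provider_type == "gp"
    sp <- in_win & visits$provider_type == "specialist"
    n_gp <- tabulate_ids(idx[gp], length(ids))
    n_sp <- tabulate_ids(idx[sp], length(ids))
  }

  if (!is.null(dispensings) && nrow(dispensings) > 0L) {
    check_atc5(dispensings$atc_code)
    dd <- check_date(dispensings$date, "dispensing")
    idx <- match(dispensings$participant_id, ids)
    if (anyNA(idx)) abort("dispensing record(s) for unknown participant_id")
    yr <- as.integer(format(ret[idx], "%Y"))
    med_start <- as.Date(sprintf("%d-04-01", yr))
    med_end <- as.Date(sprintf("%d-10-01", yr))  # half-open: through 30 Sep
    in_win <- dd >= med_start & dd < med_end
    # distinct codes among in-window dispensings only
    key <- paste(idx[in_win], dispensings$atc_code[in_win])
    tab <- table(factor(idx[in_win][!duplicated(key)], levels = seq_along(ids)))
    n_med <- as.integer(tab)
  }

  if (!is.null(admissions) && nrow(admissions) > 0L) {
    ad <- check_date(admissions$admission_date, "admission")
    preg <- icd10_is_pregnancy(admissions$primary_icd10)
    idx <- match(admissions$participant_id, ids)
    if (anyNA(idx)) abort("admission record(s) for unknown participant_id")
    in_win <- ad >= ret[idx] & ad < win_end[idx] & !preg
    sd_flag <- as.logical(admissions$same_day)
    same_day <- tabulate_ids(idx[in_win & sd_flag], length(ids)) > 0
    overnight <- tabulate_ids(idx[in_win & !sd_flag], length(ids)) > 0
  }

  tibble::tibble(
    participant_id = ids,
    gp_category = bin_gp_visits(n_gp),
    specialist_category = bin_specialist_visits(n_sp),
    medication_category = bin_medications(n_med),
    any_admission = same_day | overnight,
    same_day_admission = same_day,
    overnight_admission = overnight
  )
}

tabulate_ids <- function(idx, n) tabulate(idx, nbins = n)
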