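# Symptom recoding: 19 four-level survey items -> 16 three-category indicators.
#
# The survey asks about 19 recurring symptoms with response options
# never/rarely/sometimes/often. Two low-prevalence urinary items are combined
# into "any urinary symptoms" and three bowel items into "any bowel symptoms"
# with a worst-response priority rule; all items are then collapsed to three
# categories (never/rarely = 0, sometimes = 1, often = 2) for the latent
# class analysis.

RESPONSE_LEVELS <- c("never", "rarely", "sometimes", "often")

#' Names of the raw survey symptom items
#'
#' The 19 four-level frequency items expected by [recode_symptoms()], in
#' canonical column order.
#'
#' @return Character vector of length 19.
#' @export
#' @examples
#' symptom_items()
symptom_items <- function() {
  c("allergies", "headaches_migraines", "severe_tiredness", "back_pain",
    "vaginal_discharge", "premenstrual_tension", "irregular_periods",
    "heavy_periods", "severe_period_pain", "skin_problems",
    "difficulty_sleeping", "depression", "intense_anxiety", "palpitations",
    "urine_burns", "urine_leak", "constipation", "haemorrhoids", "other_bowel")
}

#' Names of the 16 recoded indicator variables
#'
#' The 14 retained single items plus the combined `any_urinary` and
#' `any_bowel` indicators, in the order produced by [recode_symptoms()].
#'
#' @return Character vector of length 16.
#' @export
indicator_names <- function() {
  singles <- setdiff(symptom_items(),
                     c("urine_burns", "urine_leak",
                       "constipation", "haemorrhoids", "other_bowel"))
  c(singles, "any_urinary", "any_bowel")
}

urinary_items <- function() c("urine_burns", "urine_leak")
bowel_items <- function() c("constipation", "haemorrhoids", "other_bowel")

check_response_domain <- function(x, arg = "response") {
  bad <- !is.na(x) & !(x %in% RESPONSE_LEVELS)
  if (any(bad)) {
    abort(sprintf("invalid %s value(s): %s (must be one of %s, or NA)",
                  arg, paste(unique(x[bad]), collapse = ", "),
                  paste(RESPONSE_LEVELS, collapse = "/")))
  }
  invisible(x)
}

#' Combine 2-3 symptom items into an "any symptom" response
#'
#' Applies the priority rule used to build the combined urinary and bowel
#' indicators: if every observed source response is "never" the combined
#' response is "never"; otherwise if any observed response is "often" it is
#' "often"; otherwise if any is "sometimes" it is "sometimes"; otherwise
#' "rarely". Missing source items are ignored; if all sources are missing the
#' result is missing.
#'
#' @param ... Two or three character vectors of equal length with values in
#'   `never/rarely/sometimes/often` or `NA`. A single list of such vectors is
#'   also accepted.
#' @return Character vector of combined four-level responses (`NA` where all
#'   sources are missing).
#' @export
#' @examples
#' combine_any_symptom(c("never", "never", "rarely"),
#'                     c("never", "often", "sometimes"))
combine_any_symptom <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  if (length(parts) < 2L || length(parts) > 3L) {
    abort("combine_any_symptom() takes 2 or 3 source items")
  }
  parts <- lapply(parts, function(p) {
    p <- as.character(p)
    check_response_domain(p)
    p
  })
  lens <- vapply(parts, length, integer(1))
  if (length(unique(lens)) != 1L) abort("source items must have equal length")
  if (lens[1] == 0L) abort("empty input")
  m <- do.call(cbind, parts)
  # ordinal codes 1..4; priority rule on observed entries only
  code <- matrix(match(m, RESPONSE_LEVELS), nrow = nrow(m))
  out <- apply(code, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) return(NA_character_)
    if (all(r == 1L)) return("never")
    if (any(r == 4L)) return("often")
    if (any(r == 3L)) return("sometimes")
    "rarely"
  })
  out
}

#' Collapse a four-level response to the three-category indicator scale
#'
#' `never` and `rarely` map to 0, `sometimes` to 1, `often` to 2; missing
#' stays missing.
#'
#' @param response Character vector with values in
#'   `never/rarely/sometimes/often` or `NA`.
#' @return Integer vector with values 0, 1, 2 or `NA`.
#' @export
#' @examples
#' collapse_to_three(c("never", "rarely", "sometimes", "often", NA))
collapse_to_three <- function(response) {
  response <- as.character(response)
  check_response_domain(response)
  code <- match(response, RESPONSE_LEVELS)
  out <- as.integer(pmax(code - 2L, 0L))
  out[is.na(response)] <- NA_integer_
  out
}

decode_responses <- function(x, dialect) {
  if (dialect == "codes") {
    x <- suppressWarnings(as.integer(as.character(x)))
    bad <- !is.na(x) & !(x %in% 0:3)
    if (any(bad)) abort("integer response codes must be in 0..3")
    RESPONSE_LEVELS[x + 1L]
  } else {
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA_character_
    check_response_domain(x)
    x
  }
}

#' Recode raw survey responses into the 16-indicator matrix
#'
#' Builds the latent-class input: combines the two urinary items and three
#' bowel items with the [combine_any_symptom()] priority rule, collapses all
#' 16 resulting items to three categories with [collapse_to_three()], and
#' drops participants whose indicators are all missing.
#'
#' @param survey Data frame with one row per participant, containing the 19
#'   columns named by [symptom_items()] (extra columns such as identifiers
#'   are carried through).
#' @param id_col Name of the identifier column carried into the output
#'   (`NULL` to keep none). Default `"participant_id"` if present.
#' @param dialect `"labels"` for `never/rarely/sometimes/often` strings,
#'   `"codes"` for integers 0-3 in that order.
#' @return A tibble with the identifier column (if any) and the 16 integer
#'   indicator columns named by [indicator_names()], values 0/1/2/`NA`.
#'   The number of all-missing rows dropped is reported via a message and
#'   stored in attribute `"n_dropped"`.
#' @export
recode_symptoms <- function(survey, id_col = "participant_id",
                            dialect = c("labels", "codes")) {
  dialect <- match.arg(dialect)
  if (!is.data.frame(survey) || nrow(survey) == 0L) {
    abort("`survey` must be a non-empty data frame")
  }
  missing_items <- setdiff(symptom_items(), names(survey))
  if (length(missing_items) > 0L) {
    abort(sprintf("`survey` is missing symptom item column(s): %s",
                  paste(missing_items, collapse = ", ")))
  }
  raw <- lapply(symptom_items(), function(it) decode_responses(survey[[it]], dialect))
  names(raw) <- symptom_items()

  singles <- setdiff(indicator_names(), c("any_urinary", "any_bowel"))
  ind <- lapply(raw[singles], collapse_to_three)
  ind$any_urinary <- collapse_to_three(combine_any_symptom(raw[urinary_items()]))
  ind$any_bowel <- collapse_to_three(combine_any_symptom(raw[bowel_items()]))
  ind <- tibble::as_tibble(ind[indicator_names()])

  all_missing <- rowSums(!is.na(as.matrix(ind))) == 0L
  n_dropped <- sum(all_missing)
  if (n_dropped > 0L) {
    inform(sprintf("dropped %d participant(s) with missing data on all symptoms",
                   n_dropped))
  }
  keep_id <- !is.null(id_col) && id_col %in% names(survey)
  out <- if (keep_id) {
    dplyr::bind_cols(survey[!all_missing, id_col, drop = FALSE], ind[!all_missing, ])
  } else {
    ind[!all_missing, ]
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
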