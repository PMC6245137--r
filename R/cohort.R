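## Cohort logic: index-date detection, complication detection, quartile
## fast/slow labeling, and the second-year feature window.
##
## Low-level operations work on one patient's streams: `events` is a
## data.frame with columns `day` (integer offset) and `code` (ICD string);
## `labs` has `day`, `variable`, `value`. Table-level orchestration lives in
## prepare_cohort() (see evaluation.R).

#' Find the diabetes index day for one patient
#'
#' The index day is the earliest day on which any inclusion criterion holds:
#' a diagnosis code prefix-matching the type-2-diabetes list
#' ([t2dm_codes()]), a glycated-hemoglobin (HbA1C) laboratory value at or
#' above `hba1c_threshold`, or an externally supplied anti-diabetes
#' medication day. All downstream day offsets are re-zeroed so this day
#' becomes day 0.
#'
#' @param events data.frame with columns `day`, `code` for one patient.
#' @param labs data.frame with columns `day`, `variable`, `value`.
#' @param med_days integer vector of medication-flag days (the medication
#'   inclusion arm; empty vector deactivates it).
#' @param hba1c_threshold inclusion threshold on HbA1C, percent (default 6.5).
#' @param hba1c_variable name of the HbA1C column/variable in the lab panel.
#' @return the index day as an integer, or `NA` if no criterion is ever met.
#' @examples
#' find_index_day(data.frame(day = 10, code = "250.01"),
#'                data.frame(day = integer(), variable = character(),
#'                           value = numeric()))
#' @export
find_index_day <- function(events, labs, med_days = integer(0),
                           hba1c_threshold = 6.5, hba1c_variable = "hba1c") {
  days <- integer(0)
  if (nrow(events)) {
    hit <- matches_any_prefix(as.character(events$code), .t2dm_codes)
    days <- c(days, events$day[hit])
  }
  if (nrow(labs)) {
    hit <- tolower(as.character(labs$variable)) == tolower(hba1c_variable) &
      !is.na(labs$value) & labs$value >= hba1c_threshold
    days <- c(days, labs$day[hit])
  }
  days <- c(days, med_days)
  if (!length(days)) return(NA_integer_)
  as.integer(min(days))
}

#' First day a complication is diagnosed
#'
#' Scans one patient's diagnosis stream for the earliest event whose full,
#' untruncated code prefix-matches the complication's ICD list.
#'
#' @inheritParams find_index_day
#' @param complication one of [complications()].
#' @return earliest matching day (integer) or `NA` if never diagnosed.
#' @examples
#' detect_complication(
#'   data.frame(day = c(411L, 487L), code = c("244.9", "I50.22")),
#'   "heart_failure")
#' @export
detect_complication <- function(events, complication) {
  prefixes <- complication_codes(complication)
  if (!nrow(events)) return(NA_integer_)
  hit <- matches_any_prefix(as.character(events$code), prefixes)
  if (!any(hit)) return(NA_integer_)
  as.integer(min(events$day[hit]))
}

## nearest-rank empirical quantile: value at index ceiling(q * n) of the
## sorted sample
nearest_rank_quantile <- function(x, q) {
  x <- sort(x)
  x[max(1L, ceiling(q * length(x)))]
}

#' Label patients as fast or slow progressors by time-to-complication quartile
#'
#' Patients whose complication occurs within one year of the index day (or
#' before it) are excluded. Among the rest, days at or below the `q_fast`
#' nearest-rank quantile are labeled `"fast"`, days at or above the `q_slow`
#' quantile `"slow"`, everyone else `"excluded"`. A patient qualifying for
#' both groups (possible when the two quantiles coincide, e.g. all-tied
#' inputs) is excluded so the groups stay disjoint.
#'
#' @param days_to_complication named numeric vector (names = patient ids) of
#'   days from index to first complication diagnosis.
#' @param q_fast,q_slow quantiles defining the fast and slow groups.
#' @param min_days exclusion horizon: complications at or before this day are
#'   removed (default 365, i.e. within the first year).
#' @return data.frame with columns `study_id`, `days_to_complication`,
#'   `label` (`fast`/`slow`/`excluded`), one row per input patient, in input
#'   order.
#' @examples
#' label_progressors(setNames(seq(400, 2000, by = 100), paste0("P", 1:17)))
#' @export
label_progressors <- function(days_to_complication, q_fast = 0.25,
                              q_slow = 0.75, min_days = 365) {
  ids <- names(days_to_complication)
  if (is.null(ids)) ids <- as.character(seq_along(days_to_complication))
  out <- data.frame(study_id = ids,
                    days_to_complication = as.numeric(days_to_complication),
                    label = rep("excluded", length(ids)),
                    stringsAsFactors = FALSE)
  if (!nrow(out)) return(out)
  eligible <- !is.na(out$days_to_complication) &
    out$days_to_complication > min_days
  d <- out$days_to_complication[eligible]
  if (!length(d)) return(out)
  cut_fast <- nearest_rank_quantile(d, q_fast)
  cut_slow <- nearest_rank_quantile(d, q_slow)
  is_fast <- eligible & out$days_to_complication <= cut_fast
  is_slow <- eligible & out$days_to_complication >= cut_slow
  out$label[is_fast & !is_slow] <- "fast"
  out$label[is_slow & !is_fast] <- "slow"
  ## both ⇒ excluded (degenerate ties); handled by the two masks above
  out
}

#' Restrict patient facts to the second-year feature window
#'
#' Keeps only events and lab measurements with day offsets in
#' `(window[1], window[2]]` — by default the second year after the diabetes
#' index, days 366 to 730 inclusive. Pre-index and first-year facts are
#' dropped. When `complication` is given, all diagnosis events matching that
#' complication's code list are additionally removed from the feature stream
#' so the predicted outcome never leaks into its own features.
#'
#' @inheritParams find_index_day
#' @param complication optional complication whose defining codes are
#'   stripped from the event stream.
#' @param window two-element numeric, the half-open day interval
#'   `(window[1], window[2]]`.
#' @return list with elements `events` and `labs`, filtered.
#' @examples
#' window_features(data.frame(day = c(365L, 366L, 731L),
#'                            code = c("V70.0", "V70.0", "V70.0")),
#'                 data.frame(day = integer(), variable = character(),
#'                            value = numeric()))
#' @export
window_features <- function(events, labs, complication = NULL,
                            window = c(365, 730)) {
  keep_e <- !is.na(events$day) & events$day > window[1] & events$day <= window[2]
  events <- events[keep_e, , drop = FALSE]
  if (!is.null(complication) && nrow(events)) {
    leak <- matches_any_prefix(as.character(events$code),
                               complication_codes(complication))
    events <- events[!leak, , drop = FALSE]
  }
  keep_l <- !is.na(labs$day) & labs$day > window[1] & labs$day <= window[2]
  list(events = events, labs = labs[keep_l, , drop = FALSE])
}
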