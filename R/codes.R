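## ICD-9 / ICD-10 code lists defining the index condition and the six
## complications. Matching is prefix-based on the full, untruncated code:
## an event code matches a list when some list entry is a leading substring
## of it ("I50.22" matches "I50"; "584.9" matches "584"). Lists are applied
## before 3-character truncation because retinopathy (362) would otherwise
## collide with the 362.0x diabetic-eye inclusion codes.

.t2dm_codes <- c("249", "250", "357.2",
                 sprintf("362.0%d", 1:7),
                 "366.41", "E10", "E11")

.complication_codes <- list(
  kidney = c("584", "586", "585", "403", "404", "581", "583", "588",
             "N18", "N17", "N19", "I12", "I13", "N04", "N05", "N08",
             "N25", "593"),
  heart_failure = c("428", "I50"),
  stroke = c("435", "G45", "430", "431", "I60", "I61", "432", "I62",
             "436", "433", "434"),
  liver = c("571", "572", "573", "K76", "K75"),
  retinopathy = c("362", "H35"),
  myocardial_infarction = c("410", "412", "I21")
)

#' Code lists for the index condition and complications
#'
#' `t2dm_codes()` returns the ICD-9/ICD-10 prefixes whose presence defines a
#' type-2-diabetes diagnosis (one arm of the cohort inclusion criteria);
#' `complication_codes()` returns the prefix list for one of the six tracked
#' complications; `complications()` names them.
#'
#' @param complication one of `complications()`.
#' @return a character vector of code prefixes.
#' @examples
#' t2dm_codes()
#' complication_codes("heart_failure")
#' @export
t2dm_codes <- function() .t2dm_codes

#' @rdname t2dm_codes
#' @export
complications <- function() names(.complication_codes)

#' @rdname t2dm_codes
#' @export
complication_codes <- function(complication) {
  if (length(complication) != 1L || !complication %in% names(.complication_codes)) {
    stop("unknown complication '", paste(complication, collapse = ","),
         "'; expected one of: ", paste(names(.complication_codes), collapse = ", "),
         call. = FALSE)
  }
  .complication_codes[[complication]]
}

## TRUE for each code that prefix-matches any entry of `prefixes`
matches_any_prefix <- function(codes, prefixes) {
  if (!length(codes)) return(logical(0))
  bad <- is.na(codes) | !nzchar(codes)
  if (any(bad)) {
    stop("malformed (empty or NA) diagnosis code at record ",
         which(bad)[1L], call. = FALSE)
  }
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}
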