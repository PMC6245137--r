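## internal helpers

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded package functions never perturb user-level
#' random streams.
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

## scalar-probability check with informative message
check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1], got %s",
                 what, deparse(x)), call. = FALSE)
  }
  invisible(x)
}

## columns required in the three cohort tables
required_columns <- function(table) {
  switch(table,
    diagnoses = c("STUDYID", "DX_INDEX", "DX_CODE"),
    patients  = c("STUDYID", "INDEX_YEAR", "INDEX_AGE", "GENDER", "RACE"),
    labs      = c("STUDYID", "AGE", "DAYS_VIS_INDEX", "INDEX_AGE"),
    truth     = c("STUDYID", "COMPLICATION", "DAYS_TO_COMPLICATION", "LABEL"),
    stop("unknown table: ", table)
  )
}

check_table <- function(df, table) {
  need <- required_columns(table)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s table is missing column(s): %s",
                 table, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
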