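## Feature engineering: ICD truncation, lab QC, quartile fitting, patient
## tokenization, and the cohort-level cleaning filters.
##
## A feature token is a typed network node identified by (kind, name, level):
##   diagnosis          | truncated ICD category      | level ""
##   demographic        | GENDER / RACE / AGE         | value or age quartile
##   clinical_quartile  | lab variable                | quartile 0..3
##   clinical_status    | pre-processed status var    | normal / abnormal
## Tokens are carried as strings "kind|name|level"; string order gives the
## deterministic lexicographic tie-break used throughout.

TOKEN_KINDS <- c("diagnosis", "demographic", "clinical_quartile",
                 "clinical_status")

#' Construct and parse feature tokens
#'
#' A token's identity is its `(kind, name, level)` triple, rendered as the
#' string `"kind|name|level"`.
#'
#' @param kind one of `"diagnosis"`, `"demographic"`, `"clinical_quartile"`,
#'   `"clinical_status"` (vectorized).
#' @param name variable name or diagnosis category.
#' @param level quartile index 0-3, status, category value, or `""` for
#'   diagnosis tokens.
#' @return `make_token()`: character vector of token ids. `parse_tokens()`:
#'   data.frame with columns `token`, `kind`, `name`, `level`.
#' @examples
#' make_token("clinical_quartile", "egfr", 1)
#' parse_tokens(make_token("demographic", "GENDER", "M"))
#' @export
make_token <- function(kind, name, level = "") {
  stopifnot(all(kind %in% TOKEN_KINDS))
  paste(kind, name, level, sep = "|")
}

#' @param tokens character vector of token ids.
#' @rdname make_token
#' @export
parse_tokens <- function(tokens) {
  parts <- strsplit(tokens, "|", fixed = TRUE)
  data.frame(token = tokens,
             kind  = vapply(parts, `[`, "", 1L),
             name  = vapply(parts, `[`, "", 2L),
             level = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
             stringsAsFactors = FALSE)
}

#' Truncate an ICD code to its 3-character category
#'
#' Drops everything from the first `"."` on, then keeps at most the first
#' three characters, collapsing disease subtypes onto the primary diagnosis
#' category ("250.01" -> "250", "I50.22" -> "I50").
#'
#' @param code character vector of ICD-9/ICD-10 codes.
#' @return character vector of categories.
#' @export
truncate_icd <- function(code) {
  code <- as.character(code)
  if (any(is.na(code) | !nzchar(code))) {
    stop("malformed (empty or NA) diagnosis code at record ",
         which(is.na(code) | !nzchar(code))[1L], call. = FALSE)
  }
  substr(sub("\\..*$", "", code), 1L, 3L)
}

#' Quality-control laboratory values
#'
#' Two-stage filter applied per variable: (1) values outside configured
#' physiologic `[min, max]` bounds are dropped; (2) among the range-passed
#' values, any value more than two standard deviations from the median is
#' dropped. The median/SD statistics can be supplied precomputed (e.g. from
#' training patients only) via `stats`; otherwise they are estimated from the
#' range-passed values of `labs` itself.
#'
#' @param labs data.frame with columns `variable`, `value` (other columns are
#'   carried through).
#' @param bounds optional named list, `variable -> c(min, max)`; variables
#'   without bounds pass the range check trivially.
#' @param stats optional data.frame with columns `variable`, `center`,
#'   `spread` (median and SD to use); computed from `labs` when `NULL`.
#' @param n_sd how many SDs from the median are tolerated (default 2).
#' @return list with elements `labs` (the surviving rows), `stats` (the
#'   statistics used, reusable on new data), and `n_dropped`.
#' @export
qc_lab_values <- function(labs, bounds = NULL, stats = NULL, n_sd = 2) {
  n0 <- nrow(labs)
  keep <- !is.na(labs$value)
  if (!is.null(bounds)) {
    for (v in names(bounds)) {
      sel <- labs$variable == v
      keep[sel] <- keep[sel] &
        labs$value[sel] >= bounds[[v]][1] & labs$value[sel] <= bounds[[v]][2]
    }
  }
  labs <- labs[keep, , drop = FALSE]
  if (is.null(stats)) {
    vars <- unique(as.character(labs$variable))
    stats <- data.frame(
      variable = vars,
      center = vapply(vars, function(v) median(labs$value[labs$variable == v]), 0),
      spread = vapply(vars, function(v) sd(labs$value[labs$variable == v]), 0),
      stringsAsFactors = FALSE)
    stats$spread[is.na(stats$spread)] <- 0  # single observation
  }
  keep <- rep(TRUE, nrow(labs))
  for (i in seq_len(nrow(stats))) {
    sel <- labs$variable == stats$variable[i]
    keep[sel] <- abs(labs$value[sel] - stats$center[i]) <= n_sd * stats$spread[i]
  }
  list(labs = labs[keep, , drop = FALSE], stats = stats,
       n_dropped = n0 - sum(keep))
}

#' Fit nearest-rank quartile boundaries
#'
#' Returns the 25th/50th/75th nearest-rank percentiles of the training
#' values; these cuts later map a value `v` to quartile level
#' `0` if `v <= cuts[1]`, `1` if `v <= cuts[2]`, `2` if `v <= cuts[3]`,
#' else `3` (ties go down).
#'
#' @param values numeric vector of training values (at least 4 finite).
#' @return numeric vector of three non-decreasing cut points.
#' @examples
#' fit_quartiles(1:8)   # c(2, 4, 6)
#' @export
fit_quartiles <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) {
    stop("fit_quartiles() needs at least 4 finite values, got ",
         length(values), call. = FALSE)
  }
  vapply(c(0.25, 0.5, 0.75), function(q) nearest_rank_quantile(values, q), 0)
}

#' @param v numeric vector of values to assign.
#' @param cuts three ascending cut points from [fit_quartiles()].
#' @return `quartile_level()`: integer vector of levels 0-3.
#' @rdname fit_quartiles
#' @export
quartile_level <- function(v, cuts) {
  stopifnot(length(cuts) == 3L, !is.unsorted(cuts))
  as.integer((v > cuts[1]) + (v > cuts[2]) + (v > cuts[3]))
}

## per-patient, per-variable summary of in-window lab values
summarize_labs <- function(labs, lab_summary = c("mean", "last", "min", "max")) {
  lab_summary <- match.arg(lab_summary)
  if (!nrow(labs)) return(setNames(numeric(0), character(0)))
  f <- switch(lab_summary,
    mean = function(d) mean(d$value),
    last = function(d) d$value[which.max(d$day)],
    min  = function(d) min(d$value),
    max  = function(d) max(d$value))
  vars <- sort(unique(as.character(labs$variable)))
  setNames(vapply(vars, function(v) f(labs[labs$variable == v, , drop = FALSE]), 0),
           vars)
}

#' Default normal/abnormal rules for pre-processed status variables
#'
#' Status variables (names ending in `_status`) arrive pre-coded; by
#' convention a summarized value of 0.5 or more marks the patient abnormal.
#' These are implementation defaults covering the conventional clinical
#' status panel, not calibrated thresholds; supply your own named list of
#' predicate functions to override.
#'
#' @return named-list factory: `variable -> function(x) "normal"/"abnormal"`.
#'   The default recognizes any variable ending in `_status`.
#' @export
default_status_rules <- function() {
  structure(list(), class = "status_suffix_rule")
}

is_status_variable <- function(variable, status_rules) {
  if (inherits(status_rules, "status_suffix_rule")) {
    grepl("_status$", variable)
  } else {
    variable %in% names(status_rules)
  }
}

status_level <- function(variable, x, status_rules) {
  if (inherits(status_rules, "status_suffix_rule")) {
    if (x >= 0.5) "abnormal" else "normal"
  } else {
    status_rules[[variable]](x)
  }
}

#' Tokenize one patient's windowed history
#'
#' Emits the patient's typed token set: demographic tokens (gender, race,
#' age quartile), one diagnosis token per distinct truncated ICD category,
#' one `clinical_quartile` token per lab variable with fitted boundaries
#' (patient summary = `lab_summary` of in-window QC-passed values), and
#' `clinical_status` tokens for status variables. Set semantics: repeated
#' events contribute one token.
#'
#' @param record list (or one-row data.frame) with fields `gender`, `race`,
#'   `index_age`.
#' @param events,labs windowed, QC-passed streams for this patient (see
#'   [window_features()], [qc_lab_values()]).
#' @param boundaries named list `variable -> cuts` from [fit_quartiles()],
#'   fitted on training patients; the special name `"AGE"` holds the
#'   index-age cuts.
#' @param status_rules named list `variable -> predicate` (see
#'   [default_status_rules()]).
#' @param lab_summary how to reduce a patient's repeated measurements:
#'   `"mean"` (default), `"last"`, `"min"`, or `"max"`.
#' @return sorted character vector of token ids (a set).
#' @export
tokenize_patient <- function(record, events, labs, boundaries,
                             status_rules = default_status_rules(),
                             lab_summary = "mean") {
  tokens <- character(0)
  if (!is.null(record$gender)) {
    tokens <- c(tokens, make_token("demographic", "GENDER", record$gender))
  }
  if (!is.null(record$race)) {
    tokens <- c(tokens, make_token("demographic", "RACE", record$race))
  }
  if (!is.null(record$index_age) && "AGE" %in% names(boundaries)) {
    tokens <- c(tokens, make_token("demographic", "AGE",
                                   quartile_level(record$index_age,
                                                  boundaries[["AGE"]])))
  }
  if (nrow(events)) {
    cats <- unique(truncate_icd(events$code))
    tokens <- c(tokens, make_token("diagnosis", cats, ""))
  }
  if (nrow(labs)) {
    summ <- summarize_labs(labs, lab_summary)
    for (v in names(summ)) {
      if (is_status_variable(v, status_rules)) {
        tokens <- c(tokens, make_token("clinical_status", v,
                                       status_level(v, summ[[v]], status_rules)))
      } else if (v %in% names(boundaries)) {
        tokens <- c(tokens, make_token("clinical_quartile", v,
                                       quartile_level(summ[[v]], boundaries[[v]])))
      }
    }
  }
  sort(unique(tokens))
}

#' Keep tokens shared by at least a fraction of the cohort
#'
#' A token survives when it appears in at least `ceiling(min_frac * N)`
#' of the `N` patients (so with 200 patients and the default 1%, a token
#' needs 2 carriers).
#'
#' @param token_sets list of per-patient token vectors.
#' @param min_frac minimum population share (default 0.01).
#' @return sorted character vector: the retained token universe.
#' @export
prevalence_filter <- function(token_sets, min_frac = 0.01) {
  if (!length(token_sets)) stop("empty cohort", call. = FALSE)
  counts <- table(unlist(lapply(token_sets, unique), use.names = FALSE))
  need <- ceiling(min_frac * length(token_sets))
  sort(names(counts)[counts >= need])
}

#' Drop patients by diagnosis-count rules
#'
#' Removes patients with fewer than `min_count` in-window diagnosis events or
#' more than `median_mult` times the cohort median count (median computed
#' before any removal), limiting bias from patients with too little or an
#' excessive medical history.
#'
#' @param counts named integer vector: in-window diagnosis events per patient.
#' @param min_count minimum events (default 5).
#' @param median_mult cap multiplier on the median (default 2).
#' @return character vector of retained patient ids.
#' @export
patient_filters <- function(counts, min_count = 5, median_mult = 2) {
  if (!length(counts)) return(character(0))
  cap <- median_mult * median(counts)
  names(counts)[counts >= min_count & counts <= cap]
}

#' Downsample the larger class to balance fast and slow groups
#'
#' @param fast,slow character vectors of patient ids.
#' @param seed integer seed making the subsample reproducible.
#' @return list with equal-length elements `fast` and `slow`.
#' @export
balance_classes <- function(fast, slow, seed = 1L) {
  if (!length(fast) || !length(slow)) {
    stop("both classes must be nonempty to balance (fast: ", length(fast),
         ", slow: ", length(slow), ")", call. = FALSE)
  }
  n <- min(length(fast), length(slow))
  with_seed(seed, {
    if (length(fast) > n) fast <- sample(fast, n)
    if (length(slow) > n) slow <- sample(slow, n)
  })
  list(fast = fast, slow = slow)
}
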