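## Evaluation protocol: stratified holdout splits, rank-based AUC,
## sensitivity/specificity, end-to-end repeated experiments, and the
## between-complication fast-progressor correlation matrix.
##
## The train/test contract: every statistic a model needs (QC median/SD,
## quartile boundaries, token universe, diagnosis-count median, network
## counters) is computed from training patients only, so removing a test
## patient can never change the fitted model.

#' Stratified train/test split
#'
#' @param ids patient ids.
#' @param labels class labels parallel to `ids` (fast/slow).
#' @param test_frac test fraction (default 0.2).
#' @param seed RNG seed; the same seed reproduces the same split.
#' @return list with character vectors `train` and `test` (disjoint,
#'   exhaustive, class ratios preserved within one patient).
#' @export
split_patients <- function(ids, labels, test_frac = 0.2, seed = 1L) {
  stopifnot(length(ids) == length(labels), length(ids) > 0)
  labels <- as.character(labels)
  test <- character(0)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      cl_ids <- ids[labels == cl]
      if (length(cl_ids) < 2L) {
        stop("need at least 2 patients per class to split; class '", cl,
             "' has ", length(cl_ids), call. = FALSE)
      }
      n_test <- min(length(cl_ids) - 1L,
                    max(1L, round(test_frac * length(cl_ids))))
      test <- c(test, sample(cl_ids, n_test))
    }
  })
  list(train = setdiff(ids, test), test = test)
}

#' Rank-based AUC (Mann-Whitney with tie credit)
#'
#' Estimates `P(score_fast > score_slow) + 0.5 P(tie)` over all fast/slow
#' pairs via midranks, which is exactly the area under the empirical ROC
#' curve.
#'
#' @param scores numeric scores (higher = more fast-like).
#' @param labels parallel labels; `positive` marks the fast class.
#' @param positive the positive-class label (default `"fast"`).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, positive = "fast") {
  pos <- as.character(labels) == positive
  n1 <- as.numeric(sum(pos)); n0 <- as.numeric(sum(!pos))
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a score threshold
#'
#' Fast is the positive class; a score at or above `threshold` predicts
#' fast. Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).
#'
#' @inheritParams auc_score
#' @param threshold classification threshold on the score (default 0.5).
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(scores, labels, threshold = 0.5, positive = "fast") {
  pos <- as.character(labels) == positive
  if (!any(pos) || all(pos)) {
    stop("sensitivity/specificity undefined: both classes must be present",
         call. = FALSE)
  }
  pred <- scores >= threshold
  c(sensitivity = sum(pred & pos) / sum(pos),
    specificity = sum(!pred & !pos) / sum(!pos))
}

#' ROC curve points
#'
#' Emits the full (1 - specificity, sensitivity) staircase over every
#' distinct score threshold so any operating point can be inspected.
#'
#' @inheritParams auc_score
#' @return data.frame with columns `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
roc_points <- function(scores, labels, positive = "fast") {
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  out <- t(vapply(thresholds,
                  function(t) sens_spec(scores, labels, t, positive),
                  c(sensitivity = 0, specificity = 0)))
  data.frame(threshold = thresholds, out)
}

## vectorized index-day detection over the whole diagnoses/labs tables;
## equivalent to per-patient find_index_day() (property-tested)
index_days <- function(diagnoses, labs_long, med_days = list(),
                       hba1c_threshold = 6.5, hba1c_variable = "hba1c") {
  cand <- list()
  if (nrow(diagnoses)) {
    hit <- matches_any_prefix(as.character(diagnoses$DX_CODE), .t2dm_codes)
    cand[[1]] <- data.frame(id = diagnoses$STUDYID[hit],
                            day = diagnoses$DX_INDEX[hit])
  }
  if (nrow(labs_long)) {
    hit <- tolower(labs_long$variable) == tolower(hba1c_variable) &
      !is.na(labs_long$value) & labs_long$value >= hba1c_threshold
    cand[[2]] <- data.frame(id = labs_long$study_id[hit],
                            day = labs_long$day[hit])
  }
  if (length(med_days)) {
    cand[[3]] <- data.frame(id = rep(names(med_days), lengths(med_days)),
                            day = unlist(med_days, use.names = FALSE))
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) return(setNames(integer(0), character(0)))
  tapply(cand$day, cand$id, min)
}

## wide clinical table -> long (study_id, day, variable, value), NA dropped
labs_to_long <- function(labs) {
  meta <- c("STUDYID", "AGE", "DAYS_VIS_INDEX", "INDEX_AGE")
  vars <- setdiff(names(labs), meta)
  if (!length(vars) || !nrow(labs)) {
    return(data.frame(study_id = character(0), day = integer(0),
                      variable = character(0), value = numeric(0)))
  }
  dt <- data.table::melt(as.data.table(labs), id.vars = c("STUDYID", "DAYS_VIS_INDEX"),
                         measure.vars = vars, variable.name = "variable",
                         value.name = "value", variable.factor = FALSE)
  dt <- dt[!is.na(value)]
  data.frame(study_id = dt$STUDYID, day = as.integer(dt$DAYS_VIS_INDEX),
             variable = dt$variable, value = as.numeric(dt$value),
             stringsAsFactors = FALSE)
}

#' Prepare a cohort for modeling
#'
#' Table-level orchestration of the cohort logic: finds each patient's
#' diabetes index day, re-zeroes all day offsets to it, detects the first
#' diagnosis of the target complication, labels fast/slow progressors by
#' nearest-rank time-to-complication quantiles, and restricts each labeled
#' patient's facts to the second-year feature window with the complication's
#' own codes removed.
#'
#' @param cohort list with tables `patients`, `diagnoses`, `labs` (see
#'   [read_cohort()]).
#' @param complication target complication, one of [complications()].
#' @param q_fast,q_slow labeling quantiles (defaults 0.25 / 0.75).
#' @param med_days optional named list, patient id -> integer vector of
#'   anti-diabetes medication days (the medication inclusion arm; `NULL`
#'   deactivates it).
#' @param window feature window, the half-open interval
#'   `(window[1], window[2]]` in days (default `c(365, 730)`).
#' @param max_fast_day optional hard cap: fast labels additionally require
#'   `days_to_complication <= max_fast_day` (off by default).
#' @return a `prepared_cohort` list: `labels` (all patients with a detected
#'   complication and their fast/slow/excluded label), `records`
#'   (per-patient demographics), `events` / `labs` (windowed per-patient
#'   streams, named by id), `complication`.
#' @export
prepare_cohort <- function(cohort, complication, q_fast = 0.25,
                           q_slow = 0.75, med_days = NULL,
                           window = c(365, 730), max_fast_day = NULL) {
  check_table(cohort$patients, "patients")
  check_table(cohort$diagnoses, "diagnoses")
  check_table(cohort$labs, "labs")
  diagnoses <- cohort$diagnoses
  diagnoses$STUDYID <- as.character(diagnoses$STUDYID)
  labs_long <- labs_to_long(cohort$labs)
  idx <- index_days(diagnoses, labs_long,
                    if (is.null(med_days)) list() else med_days)
  ids <- as.character(cohort$patients$STUDYID)
  ids <- ids[ids %in% names(idx)]  # no inclusion criterion met -> out

  ## re-zero offsets to the index day
  diagnoses <- diagnoses[diagnoses$STUDYID %in% ids, , drop = FALSE]
  diagnoses$day <- as.integer(diagnoses$DX_INDEX) -
    as.integer(idx[diagnoses$STUDYID])
  labs_long <- labs_long[labs_long$study_id %in% ids, , drop = FALSE]
  labs_long$day <- labs_long$day - as.integer(idx[labs_long$study_id])

  ## first complication diagnosis per patient
  hit <- matches_any_prefix(as.character(diagnoses$DX_CODE),
                            complication_codes(complication))
  comp_day <- tapply(diagnoses$day[hit], diagnoses$STUDYID[hit], min)
  days <- setNames(rep(NA_real_, length(ids)), ids)
  days[names(comp_day)] <- comp_day
  labels <- label_progressors(days, q_fast = q_fast, q_slow = q_slow,
                              min_days = window[1])
  if (!is.null(max_fast_day)) {
    too_late <- labels$label == "fast" &
      labels$days_to_complication > max_fast_day
    labels$label[too_late] <- "excluded"
  }
  labeled <- labels$study_id[labels$label %in% c("fast", "slow")]

  ## windowed feature streams, outcome codes stripped
  in_win <- diagnoses$day > window[1] & diagnoses$day <= window[2] & !hit
  ev <- diagnoses[in_win & diagnoses$STUDYID %in% labeled, , drop = FALSE]
  events <- split(data.frame(day = ev$day, code = as.character(ev$DX_CODE),
                             stringsAsFactors = FALSE),
                  factor(ev$STUDYID, levels = labeled))
  lw <- labs_long$day > window[1] & labs_long$day <= window[2]
  ll <- labs_long[lw & labs_long$study_id %in% labeled, , drop = FALSE]
  labs <- split(ll[, c("day", "variable", "value")],
                factor(ll$study_id, levels = labeled))

  pt <- cohort$patients[match(labeled, as.character(cohort$patients$STUDYID)), ]
  records <- lapply(seq_along(labeled), function(i) {
    list(gender = as.character(pt$GENDER[i]), race = as.character(pt$RACE[i]),
         index_age = as.numeric(pt$INDEX_AGE[i]))
  })
  names(records) <- labeled

  structure(list(labels = labels, records = records, events = events,
                 labs = labs, complication = complication, window = window),
            class = "prepared_cohort")
}

## ids with label fast/slow, and their labels, from a prepared cohort
labeled_ids <- function(prepared) {
  sel <- prepared$labels$label %in% c("fast", "slow")
  setNames(prepared$labels$label[sel], prepared$labels$study_id[sel])
}

#' Fit the progression model on training patients
#'
#' Runs every training-side stage: lab QC (median +/- 2 SD statistics from
#' training labs), nearest-rank quartile boundaries for age and each lab
#' variable (per-patient summaries, training patients only), tokenization,
#' the diagnosis-count patient filters (>= `min_diag` and <= `median_mult` x
#' training median), the 1% token prevalence filter, class balancing by
#' downsampling, network construction, and Z-test pruning.
#'
#' @param prepared a [prepare_cohort()] result.
#' @param train_ids ids of training patients (must be labeled fast/slow).
#' @param alpha pruning significance level (default 0.05).
#' @param min_frac token prevalence floor (default 0.01).
#' @param min_diag,median_mult patient diagnosis-count filter parameters
#'   (defaults 5 and 2).
#' @param bounds optional physiologic lab bounds (see [qc_lab_values()]).
#' @param status_rules see [default_status_rules()].
#' @param lab_summary per-patient lab summary statistic (default `"mean"`).
#' @param seed seed for the balancing subsample.
#' @return a `progression_model` list: `boundaries`, `qc_stats`, `universe`,
#'   `network` (pruned), `eps`, `n_train`, and the stage parameters.
#' @export
fit_progression_model <- function(prepared, train_ids, alpha = 0.05,
                                  min_frac = 0.01, min_diag = 5,
                                  median_mult = 2, bounds = NULL,
                                  status_rules = default_status_rules(),
                                  lab_summary = "mean", seed = 1L) {
  stopifnot(inherits(prepared, "prepared_cohort"))
  labels <- labeled_ids(prepared)
  train_ids <- intersect(train_ids, names(labels))
  if (!length(train_ids)) stop("no labeled training patients", call. = FALSE)

  ## QC statistics from training labs only
  train_labs <- rbindlist(lapply(prepared$labs[train_ids], as.data.table))
  qc <- qc_lab_values(as.data.frame(train_labs), bounds = bounds)

  ## quartile boundaries from training per-patient summaries
  train_qc_labs <- lapply(prepared$labs[train_ids], function(l) {
    qc_lab_values(l, bounds = bounds, stats = qc$stats)$labs
  })
  summaries <- lapply(train_qc_labs, summarize_labs, lab_summary = lab_summary)
  vars <- sort(unique(unlist(lapply(summaries, names), use.names = FALSE)))
  boundaries <- list()
  ages <- vapply(prepared$records[train_ids], function(r) r$index_age, 0)
  if (sum(is.finite(ages)) >= 4L) boundaries[["AGE"]] <- fit_quartiles(ages)
  for (v in vars) {
    if (is_status_variable(v, status_rules)) next
    vals <- unlist(lapply(summaries, function(s) unname(s[v])),
                   use.names = FALSE)
    if (sum(is.finite(vals)) >= 4L) boundaries[[v]] <- fit_quartiles(vals)
  }

  ## diagnosis-count patient filter (training median)
  counts <- vapply(prepared$events[train_ids], nrow, 0L)
  kept <- patient_filters(setNames(counts, train_ids), min_count = min_diag,
                          median_mult = median_mult)

  ## tokenize retained training patients and fix the token universe
  token_sets <- lapply(kept, function(id) {
    tokenize_patient(prepared$records[[id]], prepared$events[[id]],
                     qc_lab_values(prepared$labs[[id]], bounds = bounds,
                                   stats = qc$stats)$labs,
                     boundaries, status_rules, lab_summary)
  })
  names(token_sets) <- kept
  universe <- prevalence_filter(token_sets, min_frac = min_frac)
  token_sets <- lapply(token_sets, intersect, universe)

  ## balance classes and build the pruned network
  bal <- balance_classes(kept[labels[kept] == "fast"],
                         kept[labels[kept] == "slow"], seed = seed)
  ids_bal <- c(bal$fast, bal$slow)
  network <- build_network(token_sets[ids_bal], labels[ids_bal])
  network <- prune_network(network, alpha = alpha)

  structure(list(boundaries = boundaries, qc_stats = qc$stats,
                 universe = universe, network = network,
                 eps = 1 / (network$n_fast + network$n_slow + 2),
                 n_train = length(ids_bal), alpha = alpha,
                 bounds = bounds, status_rules = status_rules,
                 lab_summary = lab_summary),
            class = "progression_model")
}

## tokenize one patient with a fitted model
tokenize_with_model <- function(model, prepared, id) {
  tokenize_patient(prepared$records[[id]], prepared$events[[id]],
                   qc_lab_values(prepared$labs[[id]], bounds = model$bounds,
                                 stats = model$qc_stats)$labs,
                   model$boundaries, model$status_rules, model$lab_summary)
}

#' Match candidates for each patient against a fitted model
#'
#' @param model a [fit_progression_model()] result.
#' @param prepared the [prepare_cohort()] result the ids come from.
#' @param ids patients to match.
#' @return named list of candidate data.frames (see [match_elements()]).
#' @export
candidate_elements <- function(model, prepared, ids) {
  out <- lapply(ids, function(id) {
    match_elements(model$network, tokenize_with_model(model, prepared, id))
  })
  names(out) <- ids
  out
}

#' Score patients with a fitted model
#'
#' @inheritParams candidate_elements
#' @param n_max element cap for [score_patient()] (default 12).
#' @param ... passed on to [score_patient()].
#' @return data.frame with columns `study_id`, `probability`, `n_used`,
#'   `removed_element`.
#' @export
score_cohort <- function(model, prepared, ids, n_max = 12, ...) {
  cands <- candidate_elements(model, prepared, ids)
  rows <- lapply(ids, function(id) {
    s <- score_patient(cands[[id]], n_max = n_max, eps = model$eps, ...)
    data.frame(study_id = id, probability = s$probability,
               n_used = s$n_used, removed_element = s$removed_element,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the repeated-holdout experiment
#'
#' For each repeat: stratified 80/20 split, model fit on training patients
#' only, test patients scored at every element cap in `n_grid`, and
#' AUC / sensitivity / specificity computed against the fast/slow labels.
#'
#' @param cohort raw cohort tables (see [prepare_cohort()]).
#' @param complication target complication.
#' @param n_grid element-cap grid (default `c(7, 10, 12, 15, 17, 20)`).
#' @param repeats number of independent splits (default 5).
#' @param test_frac test fraction (default 0.2).
#' @param threshold classification threshold for sensitivity/specificity
#'   (default 0.5).
#' @param seed base seed; split r uses `seed + r`.
#' @param q_fast,q_slow labeling quantiles.
#' @param ... further arguments to [fit_progression_model()].
#' @return an `experiment_result` list: `metrics` (one row per split x
#'   `n_grid` value), `summary` (mean and SD per `n_max`), `seeds`.
#' @export
run_experiment <- function(cohort, complication,
                           n_grid = c(7, 10, 12, 15, 17, 20), repeats = 5,
                           test_frac = 0.2, threshold = 0.5, seed = 1L,
                           q_fast = 0.25, q_slow = 0.75, ...) {
  prepared <- prepare_cohort(cohort, complication, q_fast = q_fast,
                             q_slow = q_slow)
  labels <- labeled_ids(prepared)
  seeds <- seed + seq_len(repeats)
  rows <- list()
  for (r in seq_len(repeats)) {
    sp <- split_patients(names(labels), labels, test_frac = test_frac,
                         seed = seeds[r])
    model <- fit_progression_model(prepared, sp$train, seed = seeds[r], ...)
    cands <- candidate_elements(model, prepared, sp$test)
    test_labels <- labels[sp$test]
    for (n in n_grid) {
      probs <- vapply(cands, function(cd) {
        score_patient(cd, n_max = n, eps = model$eps)$probability
      }, 0)
      ss <- sens_spec(probs, test_labels, threshold = threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        complication = complication, n_max = n, split = r, seed = seeds[r],
        auc = auc_score(probs, test_labels),
        sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
        n_test = length(sp$test), stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  agg <- function(col) {
    m <- tapply(metrics[[col]], metrics$n_max, mean)
    s <- tapply(metrics[[col]], metrics$n_max, sd)
    s[is.na(s)] <- 0  # single repeat
    list(mean = m, sd = s)
  }
  a <- agg("auc"); se <- agg("sensitivity"); sp_ <- agg("specificity")
  n_vals <- as.numeric(names(a$mean))
  summary <- data.frame(complication = complication, n_max = n_vals,
                        auc = as.numeric(a$mean), auc_sd = as.numeric(a$sd),
                        sensitivity = as.numeric(se$mean),
                        sensitivity_sd = as.numeric(se$sd),
                        specificity = as.numeric(sp_$mean),
                        specificity_sd = as.numeric(sp_$sd),
                        stringsAsFactors = FALSE)
  summary <- summary[order(summary$n_max), ]
  rownames(summary) <- NULL
  structure(list(metrics = metrics, summary = summary, seeds = seeds),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d splits (seeds %s)\n",
              length(x$seeds), paste(x$seeds, collapse = ", ")))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Correlation of fast-progressor status between complications
#'
#' For each pair of complications, the Pearson correlation (phi coefficient)
#' of the binary fast indicator over patients labeled fast or slow in both
#' cohorts. Pairs with no usable overlap get `NA` rather than an error; the
#' diagonal is `NA` by construction. The matrix is symmetric.
#'
#' @param labels_list named list of label data.frames (columns `study_id`,
#'   `label`), one per complication.
#' @return symmetric numeric matrix with `NA` diagonal.
#' @export
progressor_correlation <- function(labels_list) {
  if (length(labels_list) < 2L) {
    stop("need at least 2 complications", call. = FALSE)
  }
  ks <- names(labels_list)
  m <- matrix(NA_real_, length(ks), length(ks), dimnames = list(ks, ks))
  ind <- lapply(labels_list, function(df) {
    sel <- df$label %in% c("fast", "slow")
    setNames(as.numeric(df$label[sel] == "fast"), df$study_id[sel])
  })
  for (i in seq_along(ks)) {
    for (j in seq_along(ks)) {
      if (i >= j) next
      common <- intersect(names(ind[[i]]), names(ind[[j]]))
      if (length(common) >= 2L &&
          sd(ind[[i]][common]) > 0 && sd(ind[[j]][common]) > 0) {
        m[i, j] <- m[j, i] <- cor(ind[[i]][common], ind[[j]][common])
      }
    }
  }
  m
}
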