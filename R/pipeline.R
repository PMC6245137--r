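## Declarative pipeline runner: one config, staged CSV artifacts, manifest.

#' Load and validate a run configuration
#'
#' A run config is a YAML file (or an equivalent named list) with either a
#' `synthetic:` block (cohort generator parameters: `n_patients`,
#' `complication`, `frac_fast`, `n_planted`, `p_fast`, `p_slow`,
#' `n_background`, `background_prevalence`) or an `input: {dir: ...}` block
#' pointing at existing cohort CSVs, plus stage parameters. Every stage
#' parameter has the pipeline default: feature window (365, 730], labeling
#' quantiles 0.25/0.75, 1% token prevalence, diagnosis-count filter 5 /
#' 2 x median, pruning alpha 0.05, element cap 12, grid
#' (7, 10, 12, 15, 17, 20), test fraction 0.2, 5 repeats, threshold 0.5.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  defaults <- list(complication = "heart_failure", q_fast = 0.25,
                   q_slow = 0.75, min_frac = 0.01, min_diag = 5,
                   median_mult = 2, alpha = 0.05, n_max = 12,
                   n_grid = c(7, 10, 12, 15, 17, 20), repeats = 5,
                   test_frac = 0.2, threshold = 0.5, seed = 1L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$synthetic) && is.null(config$input)) {
    stop("config error: field 'synthetic' or 'input' is required",
         call. = FALSE)
  }
  if (!is.null(config$input) && is.null(config$input$dir)) {
    stop("config error: field 'input.dir' is required", call. = FALSE)
  }
  complication_codes(config$complication)
  for (f in c("q_fast", "q_slow", "min_frac", "alpha", "test_frac",
              "threshold")) {
    check_prob(config[[f]], f)
  }
  config
}

synth_config_from_run <- function(config) {
  s <- config$synthetic
  defaults <- list(n_patients = 2000, frac_fast = 0.5, n_planted = 10,
                   p_fast = 0.8, p_slow = 0.4, n_background = 40,
                   background_prevalence = 0.2)
  for (k in names(defaults)) if (is.null(s[[k]])) s[[k]] <- defaults[[k]]
  synth_config(
    n_patients = s$n_patients, complication = config$complication,
    frac_fast = s$frac_fast,
    planted = default_planted_features(s$n_planted, s$p_fast, s$p_slow),
    n_background = s$n_background,
    background_prevalence = s$background_prevalence,
    seed = config$seed)
}

write_artifact <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the pipeline end to end (or a single stage)
#'
#' Stages: `simulate` writes the four cohort CSVs from the synthetic
#' generator; `label` writes the fast/slow labels CSV; `network` fits the
#' model on all labeled patients and writes the token table, quartile
#' boundaries (JSON) and the pruned node/edge CSVs; `score` performs one
#' stratified train/test split, fits on the training side and writes the
#' test-side risk scores; `evaluate` runs the repeated-holdout experiment
#' and writes the element-cap sweep, the per-complication metric summary and
#' the ROC points of the last split. `all` runs every applicable stage. A
#' `manifest.json` (config, seed, per-file MD5 and row counts) makes reruns
#' checkable: identical config and seed reproduce identical artifacts.
#'
#' @param config a run config (list or YAML path; see [load_run_config()]).
#' @param out_dir artifact directory, created if needed.
#' @param stage one of `"all"`, `"simulate"`, `"label"`, `"network"`,
#'   `"score"`, `"evaluate"`.
#' @return invisibly, a named character vector of artifact paths.
#' @export
run_pipeline <- function(config, out_dir,
                         stage = c("all", "simulate", "label", "network",
                                   "score", "evaluate")) {
  stage <- match.arg(stage)
  config <- load_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)

  ## obtain the cohort
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(synth_config_from_run(config))
    if (stage %in% c("all", "simulate")) {
      paths <- write_cohort(cohort, out_dir)
      artifacts <- c(artifacts, paths)
    }
  } else {
    cohort <- read_cohort(config$input$dir)
  }
  if (stage == "simulate") {
    return(invisible(finalize_manifest(config, out_dir, artifacts)))
  }
  empty_cohort <- nrow(cohort$patients) == 0L

  prepared <- if (!empty_cohort) {
    prepare_cohort(cohort, config$complication, q_fast = config$q_fast,
                   q_slow = config$q_slow)
  }

  if (stage %in% c("all", "label")) {
    lab <- if (empty_cohort) {
      data.frame(STUDYID = character(0), COMPLICATION = character(0),
                 DAYS_TO_COMPLICATION = numeric(0), LABEL = character(0))
    } else {
      data.frame(STUDYID = prepared$labels$study_id,
                 COMPLICATION = config$complication,
                 DAYS_TO_COMPLICATION = prepared$labels$days_to_complication,
                 LABEL = prepared$labels$label, stringsAsFactors = FALSE)
    }
    artifacts <- c(artifacts,
                   labels = write_artifact(lab, file.path(out_dir, "labels.csv")))
    if (stage == "label") {
      return(invisible(finalize_manifest(config, out_dir, artifacts)))
    }
  }
  if (empty_cohort) {
    stop("cohort is empty; stages beyond 'label' need patients", call. = FALSE)
  }
  labels <- labeled_ids(prepared)

  if (stage %in% c("all", "network")) {
    model <- fit_progression_model(prepared, names(labels),
                                   alpha = config$alpha,
                                   min_frac = config$min_frac,
                                   min_diag = config$min_diag,
                                   median_mult = config$median_mult,
                                   seed = config$seed)
    net_paths <- write_network(model$network, out_dir)
    tok <- do.call(rbind, lapply(names(labels), function(id) {
      t <- parse_tokens(tokenize_with_model(model, prepared, id))
      if (!nrow(t)) return(NULL)
      data.frame(STUDYID = id, KIND = t$kind, NAME = t$name, LEVEL = t$level,
                 stringsAsFactors = FALSE)
    }))
    bpath <- file.path(out_dir, "boundaries.json")
    jsonlite::write_json(model$boundaries, bpath, digits = NA)
    artifacts <- c(artifacts, nodes = net_paths[1], edges = net_paths[2],
                   tokens = write_artifact(tok, file.path(out_dir, "tokens.csv")),
                   boundaries = bpath)
    if (stage == "network") {
      return(invisible(finalize_manifest(config, out_dir, artifacts)))
    }
  }

  if (stage %in% c("all", "score")) {
    sp <- split_patients(names(labels), labels, test_frac = config$test_frac,
                         seed = config$seed)
    model <- fit_progression_model(prepared, sp$train, alpha = config$alpha,
                                   min_frac = config$min_frac,
                                   min_diag = config$min_diag,
                                   median_mult = config$median_mult,
                                   seed = config$seed)
    sc <- score_cohort(model, prepared, sp$test, n_max = config$n_max)
    scores <- data.frame(STUDYID = sc$study_id,
                         COMPLICATION = config$complication,
                         N_MAX = config$n_max, PROBABILITY = sc$probability,
                         N_USED = sc$n_used,
                         REMOVED_ELEMENT = sc$removed_element,
                         stringsAsFactors = FALSE)
    artifacts <- c(artifacts,
                   scores = write_artifact(scores,
                                           file.path(out_dir, "scores.csv")))
    if (stage == "score") {
      return(invisible(finalize_manifest(config, out_dir, artifacts)))
    }
  }

  if (stage %in% c("all", "evaluate")) {
    res <- run_experiment(cohort, config$complication,
                          n_grid = config$n_grid, repeats = config$repeats,
                          test_frac = config$test_frac,
                          threshold = config$threshold, seed = config$seed,
                          q_fast = config$q_fast, q_slow = config$q_slow,
                          alpha = config$alpha, min_frac = config$min_frac,
                          min_diag = config$min_diag,
                          median_mult = config$median_mult)
    sweep <- data.frame(N_MAX = res$summary$n_max, AUC = res$summary$auc,
                        AUC_SD = res$summary$auc_sd)
    at_cap <- res$summary[res$summary$n_max == config$n_max, , drop = FALSE]
    if (!nrow(at_cap)) at_cap <- res$summary[1, , drop = FALSE]
    metrics <- data.frame(COMPLICATION = config$complication,
                          AUC = at_cap$auc, SENSITIVITY = at_cap$sensitivity,
                          SPECIFICITY = at_cap$specificity)
    ## ROC of the final split at the default cap
    sp <- split_patients(names(labels), labels, test_frac = config$test_frac,
                         seed = res$seeds[length(res$seeds)])
    model <- fit_progression_model(prepared, sp$train, alpha = config$alpha,
                                   min_frac = config$min_frac,
                                   min_diag = config$min_diag,
                                   median_mult = config$median_mult,
                                   seed = res$seeds[length(res$seeds)])
    sc <- score_cohort(model, prepared, sp$test, n_max = config$n_max)
    roc <- roc_points(sc$probability, labels[sp$test])
    artifacts <- c(
      artifacts,
      sweep = write_artifact(sweep, file.path(out_dir, "auc_by_n.csv")),
      metrics = write_artifact(metrics, file.path(out_dir, "metrics.csv")),
      splits = write_artifact(res$metrics, file.path(out_dir, "split_metrics.csv")),
      roc = write_artifact(roc, file.path(out_dir, "roc.csv")))
  }

  invisible(finalize_manifest(config, out_dir, artifacts))
}

finalize_manifest <- function(config, out_dir, artifacts) {
  files <- unique(unname(artifacts))
  rows <- vapply(files, function(p) {
    n <- tryCatch(length(readLines(p, warn = FALSE)) - 1L, error = function(e) NA_integer_)
    as.integer(n)
  }, 0L)
  info <- data.frame(file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     rows = unname(rows), stringsAsFactors = FALSE)
  rownames(info) <- NULL
  manifest <- list(config = config, seed = config$seed, artifacts = info)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts
}
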