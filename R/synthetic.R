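## Synthetic longitudinal EHR cohorts with planted fast/slow structure.
##
## The generator emits the three flat tables the pipeline consumes
## (diagnosis events, patient demographics, wide clinical-lab panel) plus a
## ground-truth label table, so every downstream stage has a known oracle.
## Day offsets are integers relative to the diabetes index (day 0).

#' Declare a planted feature effect
#'
#' A planted feature is exhibited by fast progressors with probability
#' `p_fast` and by slow progressors with probability `p_slow`, independently
#' across patients and features given the label.
#'
#' Kinds: `"diagnosis"` plants an ICD-like code (`token_id` must be a
#' 3-character category that survives truncation and cannot prefix-match the
#' type-2-diabetes or complication code lists); `"demographic"` plants a
#' demographic value (`token_id` of the form `"GENDER=M"` or `"RACE=..."`);
#' `"clinical"` names a lab-panel variable whose group mean is shifted for
#' exhibiting patients, so the informative quartile arises naturally in the
#' measured values rather than being written directly.
#'
#' @param token_id feature identifier (see kinds above).
#' @param p_fast,p_slow exhibition probabilities in `[0, 1]`.
#' @param kind `"diagnosis"`, `"demographic"`, or `"clinical"`.
#' @return a `planted_feature` list.
#' @export
planted_feature <- function(token_id, p_fast, p_slow,
                            kind = c("diagnosis", "demographic", "clinical")) {
  kind <- match.arg(kind)
  check_prob(p_fast, "p_fast")
  check_prob(p_slow, "p_slow")
  stopifnot(is.character(token_id), length(token_id) == 1L, nzchar(token_id))
  if (kind == "diagnosis") {
    if (truncate_icd(token_id) != token_id) {
      stop("planted diagnosis code '", token_id,
           "' does not survive 3-character ICD truncation", call. = FALSE)
    }
    all_lists <- c(.t2dm_codes, unlist(.complication_codes, use.names = FALSE))
    if (any(startsWith(token_id, all_lists))) {
      stop("planted diagnosis code '", token_id,
           "' collides with the index/complication code lists", call. = FALSE)
    }
  }
  if (kind == "demographic" && !grepl("^(GENDER|RACE)=.+$", token_id)) {
    stop("demographic token_id must look like 'GENDER=M' or 'RACE=...'",
         call. = FALSE)
  }
  structure(list(token_id = token_id, p_fast = p_fast, p_slow = p_slow,
                 kind = kind),
            class = "planted_feature")
}

#' Default planted feature set
#'
#' Ten independent diagnosis features exhibited by 80% of fast and 40% of
#' slow progressors — a strong but imperfect signal on the scale of the
#' 80-90% fast-percentages carried by the top real-cohort conditions, so the
#' pipeline is exercised well away from both chance and perfect separation.
#'
#' @param n_features number of features (default 10).
#' @param p_fast,p_slow per-feature exhibition probabilities.
#' @return list of [planted_feature()] objects.
#' @export
default_planted_features <- function(n_features = 10, p_fast = 0.8,
                                     p_slow = 0.4) {
  lapply(seq_len(n_features), function(i) {
    planted_feature(sprintf("P%02d", i), p_fast, p_slow, "diagnosis")
  })
}

#' Default synthetic laboratory panel
#'
#' A small panel of common metabolic labs with physiologically plausible
#' Gaussian sampling distributions (eGFR in mL/min/1.73m2, HbA1C in %,
#' glucose in mg/dL, BUN in mg/dL, creatinine in mg/dL).
#'
#' @return data.frame with columns `variable`, `mean`, `sd`.
#' @export
default_lab_panel <- function() {
  data.frame(
    variable = c("egfr", "hba1c", "glucose", "bun", "creatinine"),
    mean     = c(85,     7.5,     140,       18,    1.1),
    sd       = c(20,     1.2,     40,        6,     0.3),
    stringsAsFactors = FALSE)
}

## background diagnosis code for index i: letter prefix + two digits, a
## fixed point of ICD truncation, disjoint by construction from the
## index/complication lists (which use only numeric, E/G/H/I/K/N prefixes)
background_code <- function(i) {
  prefixes <- c("Q", "U", "W", "X", "Y", "B", "J", "R", "T", "L")
  stopifnot(all(i >= 1), all(i <= 100 * length(prefixes)))
  paste0(prefixes[(i - 1) %/% 100 + 1], sprintf("%02d", (i - 1) %% 100))
}

#' Configure a synthetic cohort
#'
#' Defaults encode the study conditions the pipeline assumes: a balanced
#' fast/slow population, complication onset for fast progressors inside the
#' second year (days 366-730) and for slow progressors in years 4-5 (days
#' 1096-1825), all planted and background feature facts timestamped inside
#' the second-year feature window, and a sparse five-variable metabolic lab
#' panel.
#'
#' @param n_patients cohort size (0 allowed: empty tables).
#' @param complication which complication the cohort progresses to.
#' @param frac_fast fraction of patients that are fast progressors, in (0,1).
#' @param planted list of [planted_feature()] effects.
#' @param n_background number of uninformative diagnosis features
#'   (exhibited with equal probability by both groups).
#' @param background_prevalence exhibition probability for background
#'   features (default 0.2, the prevalence scale of common chronic
#'   comorbidities).
#' @param t_fast,t_slow inclusive integer day ranges for time from index to
#'   complication; fast must start after day 365 and end at or before the
#'   start of slow.
#' @param lab_panel data.frame `variable`/`mean`/`sd`
#'   (default [default_lab_panel()]).
#' @param n_visits in-window lab visits per patient (default 4; one extra
#'   pre-window visit is always emitted to exercise windowing).
#' @param panel_density probability a panel variable is measured at a visit
#'   (default 0.7, giving the sparse panels typical of routine care).
#' @param planted_shift_sd group-mean shift, in SDs, for exhibited clinical
#'   features (default 2).
#' @param seed integer; together with the config it fully determines the
#'   generated tables.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_patients,
                         complication = "heart_failure",
                         frac_fast = 0.5,
                         planted = default_planted_features(),
                         n_background = 40,
                         background_prevalence = 0.2,
                         t_fast = c(366, 730),
                         t_slow = c(1096, 1825),
                         lab_panel = default_lab_panel(),
                         n_visits = 4,
                         panel_density = 0.7,
                         planted_shift_sd = 2,
                         seed = 1L) {
  stopifnot(is.numeric(n_patients), n_patients >= 0)
  complication_codes(complication)  # validates the name
  check_prob(frac_fast, "frac_fast")
  if (frac_fast <= 0 || frac_fast >= 1) {
    stop("frac_fast must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!length(planted) && n_background == 0) {
    stop("configuration error: no planted features and n_background = 0 ",
         "would generate a featureless cohort", call. = FALSE)
  }
  for (f in planted) {
    if (!inherits(f, "planted_feature")) {
      stop("'planted' must be a list of planted_feature() objects",
           call. = FALSE)
    }
    if (f$kind == "clinical" && !f$token_id %in% lab_panel$variable) {
      stop("planted clinical feature '", f$token_id,
           "' is not in the lab panel", call. = FALSE)
    }
  }
  check_prob(background_prevalence, "background_prevalence")
  check_prob(panel_density, "panel_density")
  stopifnot(length(t_fast) == 2L, length(t_slow) == 2L,
            t_fast[1] > 365, t_fast[1] <= t_fast[2],
            t_slow[1] <= t_slow[2])
  if (t_slow[1] <= t_fast[2]) {
    stop("slow time-to-complication support must start after the fast ",
         "support ends", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 complication = complication, frac_fast = frac_fast,
                 planted = planted, n_background = as.integer(n_background),
                 background_prevalence = background_prevalence,
                 t_fast = as.integer(t_fast), t_slow = as.integer(t_slow),
                 lab_panel = lab_panel, n_visits = as.integer(n_visits),
                 panel_density = panel_density,
                 planted_shift_sd = planted_shift_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

empty_cohort <- function(config) {
  labs <- data.frame(STUDYID = character(0), AGE = integer(0),
                     DAYS_VIS_INDEX = integer(0), INDEX_AGE = integer(0))
  for (v in config$lab_panel$variable) labs[[v]] <- numeric(0)
  list(
    patients = data.frame(STUDYID = character(0), INDEX_YEAR = integer(0),
                          INDEX_AGE = integer(0), GENDER = character(0),
                          RACE = character(0)),
    diagnoses = data.frame(STUDYID = character(0), DX_INDEX = integer(0),
                           DX_CODE = character(0)),
    labs = labs,
    truth = data.frame(STUDYID = character(0), COMPLICATION = character(0),
                       DAYS_TO_COMPLICATION = integer(0), LABEL = character(0))
  )
}

#' Generate a synthetic cohort
#'
#' Each patient receives a fast/slow truth label, a day-0 diabetes index
#' diagnosis, a complication diagnosis at a day drawn uniformly from the
#' label's configured range, three routine-exam events (code V70.0) inside
#' the feature window, planted and background feature facts sampled
#' independently given the label with day offsets in (365, 730], and a
#' sparse longitudinal lab panel (several in-window visits plus one
#' pre-window visit). Identical config and seed reproduce identical tables.
#'
#' @param config a [synth_config()].
#' @return list of data.frames `patients`, `diagnoses`, `labs`, `truth`,
#'   with the column layouts documented in [write_cohort()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_patients
  if (n == 0L) return(empty_cohort(config))
  with_seed(config$seed, {
    ids <- sprintf("S%06d", seq_len(n))
    fast <- rbinom(n, 1L, config$frac_fast) == 1L
    label <- ifelse(fast, "fast", "slow")

    ## demographics (planted demographic features may override)
    gender <- sample(c("M", "F"), n, replace = TRUE)
    race <- rep("UNKNOWN/NOT DOCUMENTED", n)
    index_age <- pmin(90L, pmax(18L, as.integer(round(rnorm(n, 62, 12)))))
    index_year <- sample(1995:2015, n, replace = TRUE)
    for (f in config$planted) {
      if (f$kind != "demographic") next
      p <- ifelse(fast, f$p_fast, f$p_slow)
      present <- rbinom(n, 1L, p) == 1L
      kv <- strsplit(f$token_id, "=", fixed = TRUE)[[1L]]
      if (kv[1] == "GENDER") {
        gender <- ifelse(present, kv[2], setdiff(c("M", "F"), kv[2])[1])
      } else {
        race <- ifelse(present, kv[2], race)
      }
    }

    ## diagnosis events
    dx_id <- list(); dx_day <- list(); dx_code <- list()
    add_dx <- function(id, day, code) {
      k <- length(dx_id) + 1L
      dx_id[[k]] <<- id; dx_day[[k]] <<- rep_len(as.integer(day), length(id))
      dx_code[[k]] <<- rep_len(code, length(id))
    }
    index_codes <- c("250.00", "250.01", "250.02", "E11.9", "E11.65")
    add_dx(ids, rep(0L, n), sample(index_codes, n, replace = TRUE))
    t_comp <- integer(n)
    t_comp[fast] <- sample(seq(config$t_fast[1], config$t_fast[2]),
                           sum(fast), replace = TRUE)
    t_comp[!fast] <- sample(seq(config$t_slow[1], config$t_slow[2]),
                            sum(!fast), replace = TRUE)
    comp_codes <- paste0(complication_codes(config$complication), ".9")
    add_dx(ids, t_comp, sample(comp_codes, n, replace = TRUE))
    for (r in 1:3) add_dx(ids, sample(366:730, n, replace = TRUE), "V70.0")
    for (f in config$planted) {
      if (f$kind != "diagnosis") next
      p <- ifelse(fast, f$p_fast, f$p_slow)
      present <- rbinom(n, 1L, p) == 1L
      if (any(present)) {
        add_dx(ids[present], sample(366:730, sum(present), replace = TRUE),
               f$token_id)
      }
    }
    if (config$n_background > 0) {
      for (j in seq_len(config$n_background)) {
        present <- rbinom(n, 1L, config$background_prevalence) == 1L
        if (any(present)) {
          add_dx(ids[present], sample(366:730, sum(present), replace = TRUE),
                 background_code(j))
        }
      }
    }
    diagnoses <- data.frame(STUDYID = unlist(dx_id),
                            DX_INDEX = unlist(dx_day),
                            DX_CODE = unlist(dx_code),
                            stringsAsFactors = FALSE)
    diagnoses <- diagnoses[order(diagnoses$STUDYID, diagnoses$DX_INDEX,
                                 diagnoses$DX_CODE), , drop = FALSE]
    rownames(diagnoses) <- NULL

    ## clinical lab panel: n_visits in-window + 1 pre-window visit each
    nv <- config$n_visits + 1L
    vis_day <- integer(n * nv)
    for (i in seq_len(n)) {
      vis_day[((i - 1L) * nv + 1L):(i * nv)] <-
        c(sample(30:300, 1L), sort(sample(366:730, config$n_visits,
                                          replace = TRUE)))
    }
    vis_id <- rep(ids, each = nv)
    vis_fast <- rep(fast, each = nv)
    labs <- data.frame(STUDYID = vis_id,
                       AGE = rep(index_age, each = nv) + vis_day %/% 365L,
                       DAYS_VIS_INDEX = vis_day,
                       INDEX_AGE = rep(index_age, each = nv),
                       stringsAsFactors = FALSE)
    shift <- matrix(0, nrow = n, ncol = nrow(config$lab_panel),
                    dimnames = list(NULL, config$lab_panel$variable))
    for (f in config$planted) {
      if (f$kind != "clinical") next
      p <- ifelse(fast, f$p_fast, f$p_slow)
      present <- rbinom(n, 1L, p) == 1L
      sd_v <- config$lab_panel$sd[config$lab_panel$variable == f$token_id]
      shift[present, f$token_id] <- config$planted_shift_sd * sd_v
    }
    for (k in seq_len(nrow(config$lab_panel))) {
      v <- config$lab_panel$variable[k]
      measured <- rbinom(n * nv, 1L, config$panel_density) == 1L
      vals <- rnorm(n * nv,
                    mean = config$lab_panel$mean[k] + rep(shift[, k], each = nv),
                    sd = config$lab_panel$sd[k])
      vals[!measured] <- NA_real_
      labs[[v]] <- round(vals, 2)
    }

    list(
      patients = data.frame(STUDYID = ids, INDEX_YEAR = index_year,
                            INDEX_AGE = index_age, GENDER = gender,
                            RACE = race, stringsAsFactors = FALSE),
      diagnoses = diagnoses,
      labs = labs,
      truth = data.frame(STUDYID = ids, COMPLICATION = config$complication,
                         DAYS_TO_COMPLICATION = t_comp, LABEL = label,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Analytic node weight for a planted feature
#'
#' Under the generative model, the expected network weight of a planted
#' feature's node — the fraction of its carriers who are fast progressors —
#' is `frac_fast * p_fast / (frac_fast * p_fast + (1 - frac_fast) * p_slow)`.
#' Serves as the analytic oracle for parameter-recovery checks.
#'
#' @param p_fast,p_slow exhibition probabilities.
#' @param frac_fast fast-progressor fraction of the cohort.
#' @return the expected weight, a probability.
#' @examples
#' expected_node_weight(0.8, 0.4, 0.5)  # 2/3
#' @export
expected_node_weight <- function(p_fast, p_slow, frac_fast = 0.5) {
  check_prob(p_fast, "p_fast"); check_prob(p_slow, "p_slow")
  check_prob(frac_fast, "frac_fast")
  if (p_fast == 0 && p_slow == 0) {
    stop("undefined weight: feature is never exhibited (p_fast = p_slow = 0)",
         call. = FALSE)
  }
  frac_fast * p_fast / (frac_fast * p_fast + (1 - frac_fast) * p_slow)
}

#' Monte-Carlo AUC of the exact posterior under the generative model
#'
#' Simulates labels and planted-feature vectors from the configured model,
#' scores each draw with the exact Bayes posterior
#' `P(fast | feature vector)`, and returns the rank-based AUC of that score
#' against the true label. In expectation this upper-bounds the AUC any
#' classifier built on the planted features can achieve, making it the
#' end-to-end oracle for the pipeline.
#'
#' @param config a [synth_config()].
#' @param n_mc number of Monte-Carlo draws (default 1e5).
#' @param seed RNG seed (defaults to the config seed).
#' @return AUC estimate in `[0, 1]`.
#' @export
planted_bayes_auc <- function(config, n_mc = 1e5, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"), n_mc >= 1)
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  with_seed(seed, {
    fast <- rbinom(n_mc, 1L, config$frac_fast) == 1L
    log_odds <- rep(log(config$frac_fast / (1 - config$frac_fast)), n_mc)
    for (f in config$planted) {
      p <- ifelse(fast, f$p_fast, f$p_slow)
      x <- rbinom(n_mc, 1L, p) == 1L
      pf <- clamp(f$p_fast); ps <- clamp(f$p_slow)
      log_odds <- log_odds +
        ifelse(x, log(pf / ps), log((1 - pf) / (1 - ps)))
    }
    auc_score(log_odds, ifelse(fast, "fast", "slow"))
  })
}

#' Read and write cohort tables
#'
#' `write_cohort()` writes four comma-separated files into `dir`:
#' `diagnoses.csv` (STUDYID, DX_INDEX, DX_CODE), `patients.csv` (STUDYID,
#' INDEX_YEAR, INDEX_AGE, GENDER, RACE), `clinical.csv` (STUDYID, AGE,
#' DAYS_VIS_INDEX, INDEX_AGE, one column per lab variable, empty cells for
#' unmeasured panels), and `truth.csv` (STUDYID, COMPLICATION,
#' DAYS_TO_COMPLICATION, LABEL; omitted when the cohort has no truth table).
#' `read_cohort()` reads them back.
#'
#' @param cohort list of tables as returned by [generate_cohort()].
#' @param dir directory to write to / read from.
#' @return `write_cohort()`: invisibly, the file paths. `read_cohort()`: a
#'   cohort list (with `truth = NULL` if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(diagnoses = file.path(dir, "diagnoses.csv"),
             patients = file.path(dir, "patients.csv"),
             labs = file.path(dir, "clinical.csv"))
  write.csv(cohort$diagnoses, paths["diagnoses"], row.names = FALSE, na = "")
  write.csv(cohort$patients, paths["patients"], row.names = FALSE, na = "")
  write.csv(cohort$labs, paths["labs"], row.names = FALSE, na = "")
  if (!is.null(cohort$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    write.csv(cohort$truth, paths["truth"], row.names = FALSE, na = "")
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  must <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing cohort file: ", p, call. = FALSE)
    read.csv(p, stringsAsFactors = FALSE, colClasses = c(STUDYID = "character"))
  }
  truth_path <- file.path(dir, "truth.csv")
  out <- list(diagnoses = check_table(must("diagnoses.csv"), "diagnoses"),
              patients = check_table(must("patients.csv"), "patients"),
              labs = check_table(must("clinical.csv"), "labs"),
              truth = if (file.exists(truth_path)) {
                check_table(read.csv(truth_path, stringsAsFactors = FALSE,
                                     colClasses = c(STUDYID = "character")),
                            "truth")
              })
  out
}
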