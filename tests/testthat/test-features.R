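test_that("ICD truncation keeps the 3-character category", {
  expect_identical(truncate_icd("250.01"), "250")
  expect_identical(truncate_icd("I50.22"), "I50")
  expect_identical(truncate_icd("K40"), "K40")
  expect_identical(truncate_icd(c("E11.65", "4019")), c("E11", "401"))
  expect_error(truncate_icd(""), "malformed")
})

test_that("lab QC applies range bounds then the median +/- 2 SD rule", {
  labs <- labs_df(1:5, rep("x", 5), c(1, 2, 3, 4, 100))
  ## direct oracle: median 3, sd of all five values, test each
  ctr <- median(c(1, 2, 3, 4, 100)); spr <- sd(c(1, 2, 3, 4, 100))
  keep <- abs(c(1, 2, 3, 4, 100) - ctr) <= 2 * spr
  out <- qc_lab_values(labs)
  expect_setequal(out$labs$value, c(1, 2, 3, 4)[keep[1:4]])
  expect_false(100 %in% out$labs$value)
  expect_identical(out$n_dropped, 1L)
  ## all identical: SD 0, deviation 0, nothing dropped
  same <- labs_df(1:4, rep("x", 4), rep(7, 4))
  expect_identical(nrow(qc_lab_values(same)$labs), 4L)
  ## range bound dominates regardless of distribution
  out2 <- qc_lab_values(labs_df(1:3, rep("x", 3), c(5, 6, -1)),
                        bounds = list(x = c(0, 10)))
  expect_setequal(out2$labs$value, c(5, 6))
})

test_that("QC never drops an in-range value within median +/- 2 SD", {
  set.seed(8)
  for (i in 1:20) {
    vals <- rnorm(30, 50, 10)
    labs <- labs_df(seq_along(vals), rep("v", length(vals)), vals)
    out <- qc_lab_values(labs, bounds = list(v = c(0, 100)))
    ctr <- out$stats$center; spr <- out$stats$spread
    should_keep <- vals >= 0 & vals <= 100 & abs(vals - ctr) <= 2 * spr
    expect_setequal(out$labs$value, vals[should_keep])
  }
})

test_that("nearest-rank quartile cuts and level assignment", {
  expect_equal(fit_quartiles(1:8), c(2, 4, 6))
  expect_equal(fit_quartiles(1:100), c(25, 50, 75))
  expect_equal(fit_quartiles(rep(3, 6)), c(3, 3, 3))
  expect_error(fit_quartiles(c(1, 2, 3)), "at least 4")
  cuts <- fit_quartiles(1:8)
  expect_identical(quartile_level(c(1, 2, 3, 4, 5, 6, 7), cuts),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 3L))
  ## constant cuts: the <=-lower rule maps everything at the cut to level 0
  expect_identical(quartile_level(3, c(3, 3, 3)), 0L)
  ## partition: every finite value maps to exactly one level 0-3
  set.seed(1)
  lv <- quartile_level(rnorm(500), fit_quartiles(rnorm(100)))
  expect_true(all(lv %in% 0:3))
})

test_that("tokenization has set semantics and the documented kinds", {
  rec <- list(gender = "F", race = "UNKNOWN/NOT DOCUMENTED", index_age = 60)
  boundaries <- list(AGE = c(50, 60, 70), egfr = c(60, 80, 95))
  ev <- events_df(c(400, 500), c("I50.22", "I50.9"))
  toks <- tokenize_patient(rec, ev, labs_df(), boundaries)
  expect_identical(sum(grepl("^diagnosis", toks)), 1L)
  expect_true(make_token("diagnosis", "I50", "") %in% toks)
  expect_true(make_token("demographic", "GENDER", "F") %in% toks)
  ## index_age 60 is at the median cut -> ties go down -> level 1
  expect_true(make_token("demographic", "AGE", 1) %in% toks)
  ## eGFR summary in the 25-50% band maps to level 1
  lb <- labs_df(c(400, 600), c("egfr", "egfr"), c(65, 75))  # mean 70
  toks2 <- tokenize_patient(rec, no_events(), lb, boundaries)
  expect_true(make_token("clinical_quartile", "egfr", 1) %in% toks2)
  ## no labs: demographic + diagnosis tokens only
  expect_false(any(grepl("^clinical", toks)))
  ## status variables get normal/abnormal tokens, not quartiles
  st <- labs_df(400, "hypertension_status", 1)
  toks3 <- tokenize_patient(rec, no_events(), st, boundaries)
  expect_true(make_token("clinical_status", "hypertension_status",
                         "abnormal") %in% toks3)
})

test_that("tokenization is idempotent and order-invariant", {
  rec <- list(gender = "M", race = "W", index_age = 45)
  boundaries <- list(AGE = c(40, 55, 70))
  ev <- events_df(c(400, 420, 440), c("401.9", "250.11", "401.1"))
  t1 <- tokenize_patient(rec, ev, labs_df(), boundaries)
  t2 <- tokenize_patient(rec, ev[c(3, 1, 2), ], labs_df(), boundaries)
  expect_identical(t1, t2)
  expect_identical(t1, sort(unique(t1)))
})

test_that("prevalence filter applies the ceiling rule", {
  sets <- c(list(c("rare", "common")), replicate(199, "common"))
  ## 1 of 200 at the 1% floor needs ceiling(0.01 * 200) = 2 carriers
  kept <- prevalence_filter(sets, min_frac = 0.01)
  expect_identical(kept, "common")
  expect_setequal(prevalence_filter(sets, min_frac = 0),
                  c("rare", "common"))
  ## retained tokens really do reach the floor
  coh_sets <- lapply(1:50, function(i) sample(letters[1:8], 3))
  for (tok in prevalence_filter(coh_sets, 0.1)) {
    expect_gte(sum(vapply(coh_sets, function(s) tok %in% s, TRUE)), 5)
  }
})

test_that("patient diagnosis-count filters follow the median rule", {
  counts <- setNames(c(4, 5, 6, 7, 8), paste0("P", 1:5))
  expect_setequal(patient_filters(counts), paste0("P", 2:5))
  expect_setequal(patient_filters(setNames(rep(5, 3), c("a", "b", "c"))),
                  c("a", "b", "c"))
  ## median of {5, 20} is 12.5 so the cap 25 keeps both
  expect_setequal(patient_filters(setNames(c(5, 20), c("a", "b"))),
                  c("a", "b"))
})

test_that("class balancing downsamples deterministically", {
  fast <- paste0("f", 1:100); slow <- paste0("s", 1:80)
  bal <- balance_classes(fast, slow, seed = 3)
  expect_length(bal$fast, 80)
  expect_length(bal$slow, 80)
  expect_identical(bal, balance_classes(fast, slow, seed = 3))
  expect_identical(balance_classes(fast[1:80], slow, seed = 1),
                   list(fast = fast[1:80], slow = slow))
  expect_error(balance_classes(character(0), slow), "nonempty")
})
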