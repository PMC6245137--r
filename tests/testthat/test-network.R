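test_that("the pooled two-proportion Z statistic matches hand computation", {
  expect_equal(two_proportion_z(80, 100, 60, 100), 3.086067, tolerance = 1e-6)
  expect_identical(two_proportion_z(30, 60, 25, 50), 0)
  expect_identical(two_proportion_z(0, 50, 0, 50), 0)   # degenerate pool
  expect_identical(two_proportion_z(50, 50, 50, 50), 0) # degenerate pool
  expect_error(two_proportion_z(1, 0, 1, 2), "at least 1")
  expect_error(two_proportion_z(5, 4, 1, 2), "0 <= k <= n")
})

test_that("z^2 equals the uncorrected chi-square statistic (prop.test oracle)", {
  set.seed(33)
  for (i in 1:50) {
    n1 <- sample(10:500, 1); n2 <- sample(10:500, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    z <- two_proportion_z(k1, n1, k2, n2)
    chi <- suppressWarnings(
      prop.test(c(k1, k2), c(n1, n2), correct = FALSE)$statistic)
    expect_equal(z^2, unname(chi), tolerance = 1e-8)
  }
})

test_that("build_network counts per-patient cliques by label", {
  ## single fast patient {A, B}
  net <- build_network(list(p1 = c("A", "B")), "fast")
  el <- net$elements
  expect_identical(nrow(el), 3L)
  expect_true(all(el$weight == 1))
  expect_identical(el$k_fast[el$element == "A ~ B"], 1L)
  ## fast {A,B} + slow {A}: weights 0.5, 1, 1
  net2 <- build_network(list(p1 = c("A", "B"), p2 = "A"),
                        c("fast", "slow"))
  el2 <- net2$elements
  expect_equal(el2$weight[el2$element == "A"], 0.5)
  expect_equal(el2$weight[el2$element == "B"], 1)
  expect_equal(el2$weight[el2$element == "A ~ B"], 1)
  ## a patient with t tokens contributes t(t-1)/2 edge increments
  t <- 7L
  net3 <- build_network(list(p = letters[1:t]), "slow")
  expect_identical(sum(net3$elements$type == "edge"), t * (t - 1L) %/% 2L)
  ## repeated tokens count once (set semantics)
  net4 <- build_network(list(p = c("A", "A", "B")), "fast")
  expect_identical(net4$elements$k_fast[net4$elements$element == "A"], 1L)
})

test_that("network counters equal brute-force enumeration on small cohorts", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(3:20, 1)
    token_sets <- lapply(seq_len(n), function(i) {
      sample(LETTERS[1:8], sample(1:6, 1))
    })
    labels <- sample(c("fast", "slow"), n, replace = TRUE)
    net <- build_network(token_sets, labels)
    oracle <- brute_force_network_counts(token_sets, labels)
    expect_identical(sort(net$elements$element), sort(names(oracle)))
    for (i in seq_len(nrow(net$elements))) {
      key <- net$elements$element[i]
      expect_identical(net$elements$k_fast[i], as.integer(oracle[[key]]["fast"]),
                       info = key)
      expect_identical(net$elements$k_slow[i], as.integer(oracle[[key]]["slow"]),
                       info = key)
    }
    ## conservation: k_fast + k_slow = number of carriers
    nodes <- net$elements[net$elements$type == "node", ]
    for (i in seq_len(nrow(nodes))) {
      carriers <- sum(vapply(token_sets,
                             function(s) nodes$token1[i] %in% s, TRUE))
      expect_identical(nodes$k_fast[i] + nodes$k_slow[i], carriers)
    }
  }
})

test_that("pruning applies the two-sided critical value and is monotone in alpha", {
  sets <- list(a = c("A", "B"), b = c("A", "B"), c = c("A"),
               d = c("B"), e = c("A"), f = c("B"))
  labels <- c("fast", "fast", "fast", "slow", "slow", "slow")
  net <- build_network(sets, labels)
  ## alpha = 1: critical value 0, nothing removed
  expect_identical(nrow(prune_network(net, alpha = 1)$elements),
                   nrow(net$elements))
  ## elements straddling the threshold
  net_toy <- net
  net_toy$elements$z <- c(1.0, 2.5, 0.5)[seq_len(nrow(net$elements)) %% 3 + 1]
  pruned <- prune_network(net_toy, alpha = 0.05)
  expect_true(all(abs(pruned$elements$z) >= qnorm(0.975)))
  expect_false(any(pruned$elements$z == 1.0))
  ## monotonicity: stricter alpha keeps a subset
  strict <- prune_network(net_toy, alpha = 0.01)
  expect_true(all(strict$elements$element %in% pruned$elements$element))
})

test_that("top_conditions ranks nodes with lexicographic tie-breaks", {
  net <- toy_network()
  top <- top_conditions(net, m = 1)
  expect_identical(top$by_weight$element, "A")
  expect_identical(top$by_z$element, "A")
  ## no edges in the condition lists
  all5 <- top_conditions(net, m = 5)
  expect_false("A ~ B" %in% all5$by_weight$element)
  ## tie on weight resolves lexicographically
  net$elements$weight[net$elements$element %in% c("B", "C")] <- 0.7
  tie <- top_conditions(net, m = 3)
  expect_identical(tie$by_weight$element, c("A", "B", "C"))
  empty <- top_conditions(net, m = 0)
  expect_identical(nrow(empty$by_weight), 0L)
})

test_that("planted high-effect token ranks first by z on a generated cohort", {
  cfg <- synth_config(2000, planted = list(
    planted_feature("P01", 0.9, 0.3, "diagnosis")), seed = 55)
  coh <- generate_cohort(cfg)
  prep <- prepare_cohort(coh, "heart_failure")
  labels <- prep$labels
  ids <- labels$study_id[labels$label %in% c("fast", "slow")]
  model <- fit_progression_model(prep, ids, seed = 1)
  top <- top_conditions(model$network, m = 1)
  expect_identical(top$by_z$element, make_token("diagnosis", "P01", ""))
})

test_that("network serialization writes nodes and edges CSVs", {
  dir <- withr::local_tempdir()
  net <- prune_network(build_network(
    list(a = c("diagnosis|401|", "demographic|GENDER|M"),
         b = c("diagnosis|401|")),
    c("fast", "slow")), alpha = 1)
  paths <- write_network(net, dir)
  nodes <- read.csv(paths[1])
  expect_identical(names(nodes),
                   c("KIND", "NAME", "LEVEL", "K_FAST", "K_SLOW", "WEIGHT", "Z"))
  edges <- read.csv(paths[2])
  expect_identical(nrow(edges), 1L)
  expect_setequal(c(edges$KIND1, edges$KIND2), c("demographic", "diagnosis"))
})
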