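# small in-code fixtures shared across test files

events_df <- function(days, codes) {
  data.frame(day = as.integer(days), code = codes, stringsAsFactors = FALSE)
}

labs_df <- function(days = integer(0), variables = character(0),
                    values = numeric(0)) {
  data.frame(day = as.integer(days), variable = variables, value = values,
             stringsAsFactors = FALSE)
}

no_events <- function() events_df(integer(0), character(0))

# a tiny pruned network over tokens A, B, C with hand-set statistics;
# counts chosen so weight = k_fast/(k_fast+k_slow) holds exactly
toy_network <- function() {
  elements <- data.frame(
    element = c("A", "B", "C", "A ~ B"),
    type = c("node", "node", "node", "edge"),
    token1 = c("A", "B", "C", "A"),
    token2 = c(NA, NA, NA, "B"),
    k_fast = c(8, 7, 6, 9),
    k_slow = c(2, 3, 4, 1),
    weight = c(0.8, 0.7, 0.6, 0.9),
    z = c(5, 4, 3, 6),
    significant = TRUE,
    stringsAsFactors = FALSE)
  structure(list(n_fast = 10, n_slow = 10, alpha = 0.05,
                 elements = elements),
            class = "hetero_network")
}

# independent brute-force per-patient clique counter (oracle for
# build_network): double loop over patients and token pairs
brute_force_network_counts <- function(token_sets, labels) {
  counts <- list()
  bump <- function(key, lab) {
    if (is.null(counts[[key]])) counts[[key]] <<- c(fast = 0, slow = 0)
    counts[[key]][lab] <<- counts[[key]][lab] + 1
  }
  for (i in seq_along(token_sets)) {
    toks <- sort(unique(token_sets[[i]]))
    for (t in toks) bump(t, labels[i])
    if (length(toks) >= 2) {
      for (a in seq_len(length(toks) - 1)) {
        for (b in (a + 1):length(toks)) {
          bump(paste(toks[a], toks[b], sep = " ~ "), labels[i])
        }
      }
    }
  }
  counts
}

# exhaustive all-pairs AUC oracle with half credit for ties
brute_force_auc <- function(scores, labels, positive = "fast") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
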