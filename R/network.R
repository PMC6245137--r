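## Heterogeneous comorbidity network: per-patient token cliques counted by
## fast/slow label, element weights, and two-proportion Z-test pruning.

#' Two-proportion Z statistic with pooled variance
#'
#' `z = (k1/n1 - k2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with the
#' pooled proportion `phat = (k1 + k2)/(n1 + n2)`. When the pool is
#' degenerate (`phat` 0 or 1, so the two proportions are necessarily equal)
#' the statistic is 0. Vectorized; no continuity correction unless
#' `correct = TRUE`.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return numeric vector of Z statistics.
#' @examples
#' two_proportion_z(80, 100, 60, 100)  # 3.086067
#' @export
two_proportion_z <- function(k1, n1, k2, n2, correct = FALSE) {
  if (any(n1 < 1) || any(n2 < 1)) {
    stop("group sizes must be at least 1", call. = FALSE)
  }
  if (any(k1 < 0) || any(k2 < 0) || any(k1 > n1) || any(k2 > n2)) {
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  phat <- (k1 + k2) / (n1 + n2)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  diff <- k1 / n1 - k2 / n2
  if (correct) {
    cc <- (1 / n1 + 1 / n2) / 2
    diff <- sign(diff) * pmax(0, abs(diff) - cc)
  }
  ifelse(phat <= 0 | phat >= 1, 0, diff / se)
}

#' Build the heterogeneous comorbidity network
#'
#' Every labeled training patient contributes, once each, its tokens (nodes)
#' and all unordered pairs of distinct tokens (edges — the per-patient
#' clique). Counts are kept separately for fast and slow progressors; each
#' element's weight is the fraction of its carriers who are fast,
#' `k_fast / (k_fast + k_slow)`, and its Z score is the pooled two-proportion
#' statistic comparing prevalence between the fast and slow groups.
#'
#' @param token_sets named list of per-patient token vectors (sets).
#' @param labels character vector (`"fast"`/`"slow"`), parallel to
#'   `token_sets` (or named by patient id).
#' @return an object of class `hetero_network`: a list with `n_fast`,
#'   `n_slow`, `alpha` (`NULL` until pruned), and `elements`, a data.frame
#'   with columns `element`, `type` (`node`/`edge`), `token1`, `token2`
#'   (`NA` for nodes), `k_fast`, `k_slow`, `weight`, `z`, `significant`.
#' @export
build_network <- function(token_sets, labels) {
  if (!length(token_sets)) stop("empty cohort", call. = FALSE)
  if (length(labels) != length(token_sets)) {
    stop("labels must parallel token_sets", call. = FALSE)
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("fast", "slow"))) {
    stop("labels must be 'fast' or 'slow'", call. = FALSE)
  }
  per_patient <- lapply(seq_along(token_sets), function(i) {
    toks <- sort(unique(token_sets[[i]]))
    nt <- length(toks)
    if (!nt) return(NULL)
    if (nt >= 2L) {
      idx <- utils::combn(nt, 2L)
      t1 <- c(toks, toks[idx[1L, ]])
      t2 <- c(rep(NA_character_, nt), toks[idx[2L, ]])
    } else {
      t1 <- toks
      t2 <- NA_character_
    }
    data.table(token1 = t1, token2 = t2, label = labels[i])
  })
  dt <- rbindlist(per_patient)
  n_fast <- sum(labels == "fast")
  n_slow <- sum(labels == "slow")
  counts <- dt[, list(k_fast = sum(label == "fast"),
                      k_slow = sum(label == "slow")),
               by = list(token1, token2)]
  counts[, type := ifelse(is.na(token2), "node", "edge")]
  counts[, element := ifelse(is.na(token2), token1,
                             paste(token1, token2, sep = " ~ "))]
  counts[, weight := k_fast / (k_fast + k_slow)]
  counts[, z := two_proportion_z(k_fast, max(n_fast, 1L),
                                 k_slow, max(n_slow, 1L))]
  counts[, significant := NA]
  setorder(counts, element)
  elements <- as.data.frame(counts[, list(element, type, token1, token2,
                                          k_fast, k_slow, weight, z,
                                          significant)])
  structure(list(n_fast = n_fast, n_slow = n_slow, alpha = NULL,
                 elements = elements),
            class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  el <- x$elements
  cat(sprintf("<hetero_network> %d fast + %d slow patients; %d nodes, %d edges",
              x$n_fast, x$n_slow, sum(el$type == "node"),
              sum(el$type == "edge")), "\n")
  if (!is.null(x$alpha)) {
    cat(sprintf("  pruned at alpha = %g: %d nodes, %d edges significant\n",
                x$alpha, sum(el$significant & el$type == "node"),
                sum(el$significant & el$type == "edge")))
  }
  invisible(x)
}

#' Prune a network by two-proportion Z-test significance
#'
#' Removes every node and edge whose |Z| falls below the two-sided critical
#' value `qnorm(1 - alpha/2)` (1.959964 at the default 95% confidence), i.e.
#' every element whose prevalence does not differ significantly between fast
#' and slow progressors. No multiple-testing correction is applied.
#'
#' @param network a [build_network()] result.
#' @param alpha two-sided significance level (default 0.05).
#' @param keep_all keep non-significant elements in the table, flagged
#'   `significant = FALSE`, instead of dropping their rows (default `FALSE`).
#' @return the pruned `hetero_network`.
#' @export
prune_network <- function(network, alpha = 0.05, keep_all = FALSE) {
  stopifnot(inherits(network, "hetero_network"))
  z_crit <- qnorm(1 - alpha / 2)
  sig <- abs(network$elements$z) >= z_crit
  network$elements$significant <- sig
  if (!keep_all) {
    network$elements <- network$elements[sig, , drop = FALSE]
    rownames(network$elements) <- NULL
  }
  network$alpha <- alpha
  network
}

#' Rank the top conditions of a pruned network
#'
#' Mirrors the per-complication condition tables: nodes only, ranked two
#' ways — by weight (fraction of carriers who are fast progressors) and by Z
#' score — with deterministic lexicographic tie-breaking on the token id.
#'
#' @param network a pruned `hetero_network`.
#' @param m how many conditions per list (default 5).
#' @return list of two data.frames, `by_weight` and `by_z`.
#' @export
top_conditions <- function(network, m = 5) {
  stopifnot(inherits(network, "hetero_network"))
  if (m <= 0) {
    empty <- network$elements[0, c("element", "k_fast", "k_slow", "weight", "z")]
    return(list(by_weight = empty, by_z = empty))
  }
  nodes <- network$elements[network$elements$type == "node" &
                              (is.na(network$elements$significant) |
                                 network$elements$significant), , drop = FALSE]
  cols <- c("element", "k_fast", "k_slow", "weight", "z")
  by_w <- nodes[order(-nodes$weight, nodes$element), cols, drop = FALSE]
  by_z <- nodes[order(-nodes$z, nodes$element), cols, drop = FALSE]
  list(by_weight = utils::head(by_w, m), by_z = utils::head(by_z, m))
}

#' Serialize a network to CSV (and optionally GraphML)
#'
#' Writes `nodes.csv` (KIND, NAME, LEVEL, K_FAST, K_SLOW, WEIGHT, Z) and
#' `edges.csv` (the same statistics with the two endpoint tokens split into
#' KIND1/NAME1/LEVEL1 and KIND2/NAME2/LEVEL2). With `graphml = TRUE` (needs
#' the igraph package) also writes `network.graphml` for visualization.
#'
#' @param network a `hetero_network`.
#' @param dir output directory, created if needed.
#' @param graphml also write GraphML (default `FALSE`).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, dir, graphml = FALSE) {
  stopifnot(inherits(network, "hetero_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  el <- network$elements
  nodes <- el[el$type == "node", , drop = FALSE]
  edges <- el[el$type == "edge", , drop = FALSE]
  pn <- parse_tokens(nodes$token1)
  nodes_out <- data.frame(KIND = pn$kind, NAME = pn$name, LEVEL = pn$level,
                          K_FAST = nodes$k_fast, K_SLOW = nodes$k_slow,
                          WEIGHT = nodes$weight, Z = nodes$z)
  p1 <- parse_tokens(edges$token1); p2 <- parse_tokens(edges$token2)
  edges_out <- data.frame(KIND1 = p1$kind, NAME1 = p1$name, LEVEL1 = p1$level,
                          KIND2 = p2$kind, NAME2 = p2$name, LEVEL2 = p2$level,
                          K_FAST = edges$k_fast, K_SLOW = edges$k_slow,
                          WEIGHT = edges$weight, Z = edges$z)
  paths <- file.path(dir, c("nodes.csv", "edges.csv"))
  write.csv(nodes_out, paths[1], row.names = FALSE)
  write.csv(edges_out, paths[2], row.names = FALSE)
  if (graphml) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      stop("GraphML export needs the 'igraph' package", call. = FALSE)
    }
    g <- as_igraph(network)
    gpath <- file.path(dir, "network.graphml")
    igraph::write_graph(g, gpath, format = "graphml")
    paths <- c(paths, gpath)
  }
  invisible(paths)
}

#' Convert a network to an igraph object
#'
#' Vertices carry kind/weight/z attributes; edges carry their own
#' weight/z. Isolated significant nodes are preserved.
#'
#' @param network a `hetero_network`.
#' @return an igraph graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "hetero_network"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("as_igraph() needs the 'igraph' package", call. = FALSE)
  }
  el <- network$elements
  nodes <- el[el$type == "node", , drop = FALSE]
  edges <- el[el$type == "edge", , drop = FALSE]
  vertices <- unique(c(nodes$token1, edges$token1, edges$token2))
  vdf <- data.frame(name = vertices, stringsAsFactors = FALSE)
  vdf$kind <- parse_tokens(vertices)$kind
  idx <- match(vertices, nodes$token1)
  vdf$weight <- nodes$weight[idx]
  vdf$z <- nodes$z[idx]
  edf <- data.frame(from = edges$token1, to = edges$token2,
                    weight = edges$weight, z = edges$z,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}
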