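## Product-form naive-Bayes risk score from the significant elements of a
## patient's personal sub-network.

#' Match a patient's tokens against the pruned network
#'
#' Returns every significant node whose token the patient carries, plus
#' every significant edge both of whose endpoint tokens the patient carries.
#' The matched sub-network may be disconnected; that is acceptable.
#'
#' @param network a pruned [hetero_network][build_network()].
#' @param tokens the patient's token set (character vector).
#' @return data.frame of candidates with columns `element`, `type`,
#'   `weight`, `z`.
#' @export
match_elements <- function(network, tokens) {
  stopifnot(inherits(network, "hetero_network"))
  el <- network$elements
  if (!is.null(network$alpha) && any(!is.na(el$significant))) {
    el <- el[el$significant %in% TRUE, , drop = FALSE]
  }
  hit <- el$token1 %in% tokens & (is.na(el$token2) | el$token2 %in% tokens)
  out <- el[hit, c("element", "type", "weight", "z"), drop = FALSE]
  rownames(out) <- NULL
  out
}

## deterministic candidate ordering: most significant first
## (|z| desc, then weight desc, then lexicographic element id)
order_candidates <- function(candidates) {
  candidates[order(-abs(candidates$z), -candidates$weight,
                   candidates$element), , drop = FALSE]
}

#' Score a patient's probability of fast progression
#'
#' From the matched candidates, takes the `n_max` most significant elements
#' (by |Z|, ties broken by weight then token id), removes the single element
#' with the lowest weight — the element contributing the lowest probability
#' of developing the complication, whose removal boosts the signal of the
#' fast-progression elements — and combines the surviving weights `w_i`
#' assuming independence:
#' `p_t = prod(w_i)`, `p_f = prod(1 - w_i)`, probability `= p_t/(p_t + p_f)`.
#'
#' Weights are clamped to `[eps, 1 - eps]` so that extreme weights of
#' exactly 0 and 1 cannot produce an undefined 0/0 ratio. With fewer than
#' two candidates the removal step is skipped; with no candidates at all the
#' uninformative probability 0.5 is returned and flagged via `n_used = 0`.
#'
#' @param candidates data.frame with columns `element`, `weight`, `z`
#'   (from [match_elements()]).
#' @param n_max maximum number of elements used (default 12).
#' @param drop_lowest remove the lowest-weight selected element
#'   (default `TRUE`).
#' @param eps weight clamp; default `1/(n_fast + n_slow + 2)` in pipeline
#'   use, 1e-6 standalone.
#' @param rank_by rank candidates by absolute (`"abs_z"`, default) or signed
#'   (`"z"`) Z score.
#' @return list with `probability`, `n_used`, `used` (data.frame of the
#'   multiplied elements), and `removed_element` (`NA` if none removed).
#' @examples
#' cand <- data.frame(element = c("a", "b", "c"),
#'                    weight = c(0.8, 0.7, 0.6), z = c(5, 4, 3))
#' score_patient(cand)$probability  # 0.56/0.62 = 0.9032258
#' @export
score_patient <- function(candidates, n_max = 12, drop_lowest = TRUE,
                          eps = 1e-6, rank_by = c("abs_z", "z")) {
  if (!is.numeric(n_max) || n_max < 1) {
    stop("n_max must be a positive count", call. = FALSE)
  }
  rank_by <- match.arg(rank_by)
  if (is.null(candidates) || !nrow(candidates)) {
    return(list(probability = 0.5, n_used = 0L,
                used = data.frame(element = character(0), weight = numeric(0),
                                  z = numeric(0)),
                removed_element = NA_character_))
  }
  candidates$weight <- pmin(pmax(candidates$weight, eps), 1 - eps)
  if (rank_by == "z") {
    ord <- order(-candidates$z, -candidates$weight, candidates$element)
    candidates <- candidates[ord, , drop = FALSE]
  } else {
    candidates <- order_candidates(candidates)
  }
  sel <- utils::head(candidates, n_max)
  removed <- NA_character_
  if (nrow(sel) >= 2L && drop_lowest) {
    h <- which(sel$weight == min(sel$weight))[1L]
    removed <- sel$element[h]
    sel <- sel[-h, , drop = FALSE]
  }
  log_pt <- sum(log(sel$weight))
  log_pf <- sum(log1p(-sel$weight))
  probability <- 1 / (1 + exp(log_pf - log_pt))
  list(probability = probability, n_used = nrow(sel),
       used = sel[, c("element", "weight", "z")],
       removed_element = removed)
}

#' Score one candidate set across a grid of element-count caps
#'
#' Re-scores the same candidates with different `n_max` values to reproduce
#' the node-count sensitivity sweep.
#'
#' @inheritParams score_patient
#' @param n_values integer grid of caps (default `c(7, 10, 12, 15, 17, 20)`).
#' @return named numeric vector of probabilities, one per `n_values` entry.
#' @export
sweep_n <- function(candidates, n_values = c(7, 10, 12, 15, 17, 20), ...) {
  if (!length(n_values)) stop("n_values must be nonempty", call. = FALSE)
  setNames(vapply(n_values,
                  function(n) score_patient(candidates, n_max = n, ...)$probability,
                  0),
           as.character(n_values))
}
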