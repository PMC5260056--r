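# Canonical pair key: lexically ordered "a|b". Used everywhere a set of
# unordered gene pairs is compared.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Construct a gold standard of true interactions
#'
#' The gold standard is symmetrized: a directed edge A->B counts the
#' unordered pair \{A, B\} as positive, because the inference is undirected.
#' The evaluation universe is every unordered non-self pair over `genes`.
#'
#' @param positives Two-column matrix or data frame of gene label pairs, or
#'   a character vector of `"a|b"` keys.
#' @param genes Character vector of all gene labels in the universe.
#' @return A `gold_standard` object.
#' @export
gold_standard <- function(positives, genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene labels", call. = FALSE)
  if (is.matrix(positives)) {
    keys <- pair_key(as.character(positives[, 1L]),
                     as.character(positives[, 2L]))
  } else if (is.data.frame(positives)) {
    keys <- pair_key(as.character(positives[[1L]]),
                     as.character(positives[[2L]]))
  } else {
    keys <- as.character(positives)
  }
  keys <- unique(keys)
  labs <- unique(unlist(strsplit(keys, "|", fixed = TRUE)))
  if (!all(labs %in% genes)) {
    stop("gold pair references unknown gene: ",
         paste(setdiff(labs, genes), collapse = ", "), call. = FALSE)
  }
  self <- vapply(strsplit(keys, "|", fixed = TRUE),
                 function(p) p[1L] == p[2L], logical(1))
  if (any(self)) stop("gold standard contains self-pairs", call. = FALSE)
  structure(list(positive_pairs = sort(keys), genes = genes),
            class = "gold_standard")
}

all_pair_keys <- function(genes) {
  idx <- utils::combn(sort(genes), 2L)
  pair_key(idx[1L, ], idx[2L, ])
}

#' Confusion counts of a predicted edge set against a gold standard
#'
#' Evaluates every unordered non-self pair of the gold universe: a true
#' interaction that is predicted counts as TP, otherwise FN; a
#' non-interacting pair that is predicted counts as FP, otherwise TN.
#'
#' @param predicted_pairs Predicted edges, in any form [gold_standard()]
#'   accepts for `positives`.
#' @param gold A `gold_standard`.
#' @return A `confusion_counts` list with integer fields `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(predicted_pairs, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  pred <- gold_standard(predicted_pairs, gold$genes)$positive_pairs
  universe <- all_pair_keys(gold$genes)
  pos <- universe %in% gold$positive_pairs
  hit <- universe %in% pred
  structure(list(TP = sum(pos & hit), FP = sum(!pos & hit),
                 TN = sum(!pos & !hit), FN = sum(pos & !hit)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' `TPR = TP/(TP+FN)` (recall), `FPR = FP/(TN+FP)`,
#' `PPV = TP/(TP+FP)` (precision), `ACC = (TP+TN)/total`. A metric whose
#' denominator is zero is returned as `NA` (undefined).
#'
#' @param counts A `confusion_counts` or a list with fields TP, FP, TN, FN.
#' @return Named numeric vector `c(TPR, FPR, PPV, ACC)`.
#' @export
classification_metrics <- function(counts) {
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, c(
    TPR = rat(TP, TP + FN),
    FPR = rat(FP, TN + FP),
    PPV = rat(TP, TP + FP),
    ACC = rat(TP + TN, TP + FN + TN + FP)))
}

#' ROC and precision-recall curves over ranked pair scores
#'
#' Ranks candidates by descending score, treats tied scores as a single
#' threshold step, and integrates both curves by the trapezoidal rule.
#'
#' @param scores Numeric vector of pair scores.
#' @param labels Logical vector, `TRUE` for true interactions; same length
#'   as `scores`.
#' @return List with `roc` (FPR, TPR), `pr` (recall, precision) data frames
#'   and scalars `auroc`, `aupr`.
#' @export
roc_pr_curves <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L) {
    stop("need at least one positive and one negative pair", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # threshold steps at the last element of each tied block
  last_of_tie <- c(s[-length(s)] != s[-1L], TRUE)
  cum_tp <- cumsum(l)[last_of_tie]
  cum_fp <- cumsum(!l)[last_of_tie]
  tpr <- c(0, cum_tp / P)
  fpr <- c(0, cum_fp / N)
  auroc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  recall <- cum_tp / P
  precision <- cum_tp / (cum_tp + cum_fp)
  # anchor the PR curve at recall 0 with the first block's precision
  recall <- c(0, recall)
  precision <- c(precision[1L], precision)
  aupr <- sum(diff(recall) * (precision[-1L] + precision[-length(precision)]) / 2)
  list(roc = data.frame(FPR = fpr, TPR = tpr),
       pr = data.frame(recall = recall, precision = precision),
       auroc = auroc, aupr = aupr)
}

#' Full evaluation of an inferred network against a gold standard
#'
#' Combines the confusion-matrix metrics at the retained edge set with the
#' ranking metrics (AUROC/AUPR) computed from the continuous pair weights.
#'
#' @param state A `network_state`.
#' @param gold A `gold_standard` over the same gene labels.
#' @return List with fields `counts` (confusion), `metrics`
#'   (TPR/FPR/PPV/ACC), `auroc`, `aupr`.
#' @export
evaluate_network <- function(state, gold) {
  stopifnot(inherits(state, "network_state"), inherits(gold, "gold_standard"))
  if (!setequal(state$genes, gold$genes)) {
    miss <- c(setdiff(state$genes, gold$genes), setdiff(gold$genes, state$genes))
    stop("gene label mismatch between network and gold standard: ",
         miss[1L], call. = FALSE)
  }
  idx <- which(upper.tri(state$adjacency), arr.ind = TRUE)
  keys <- pair_key(state$genes[idx[, 1L]], state$genes[idx[, 2L]])
  pred_keys <- keys[state$adjacency[upper.tri(state$adjacency)]]
  cnt <- confusion(pred_keys, gold)
  scores <- state$weights[upper.tri(state$weights)]
  curves <- roc_pr_curves(scores, keys %in% gold$positive_pairs)
  list(counts = cnt, metrics = classification_metrics(cnt),
       auroc = curves$auroc, aupr = curves$aupr, curves = curves)
}

#' Threshold offset in percent of the grid range
#'
#' `|true - predicted| / (grid_max - grid_min) * 100`. Offsets below 5, 10
#' and 20 percent satisfy the stringent, standard and moderate criteria
#' respectively.
#'
#' @param true_threshold,predicted_threshold Cutoffs to compare.
#' @param grid_min,grid_max Range of the scan grid (`grid_max > grid_min`).
#' @return Offset in percent.
#' @examples
#' threshold_offset(0.4, 0.5, 0, 1)  # 10
#' @export
threshold_offset <- function(true_threshold, predicted_threshold,
                             grid_min = 0, grid_max = 1) {
  if (grid_max <= grid_min) stop("grid_max must exceed grid_min", call. = FALSE)
  abs(true_threshold - predicted_threshold) / (grid_max - grid_min) * 100
}

#' Accuracy-maximizing cutoff over a grid (the "true threshold")
#'
#' Runs inference once per grid cutoff at the given order and returns the
#' cutoff whose resulting network maximizes classification accuracy against
#' the gold standard. Ties break toward the smallest cutoff.
#'
#' @param expr Expression matrix (genes x conditions).
#' @param gold A `gold_standard`.
#' @param order Conditioning order used for each inference run.
#' @param grid Ascending cutoff grid to search.
#' @param workers Worker chunks forwarded to inference.
#' @return List with `cutoff`, `accuracy` and the per-grid `accuracies`.
#' @export
true_threshold <- function(expr, gold, order = 1L, grid = default_grid(),
                           workers = 1L) {
  expr <- as_expression_matrix(expr)
  accs <- vapply(grid, function(cut) {
    st <- infer_network(expr, inference_config(max_order = order,
                                               threshold = cut,
                                               workers = workers))
    unname(evaluate_network(st, gold)$metrics[["ACC"]])
  }, numeric(1))
  best <- which.max(accs)  # which.max returns the first (smallest) maximizer
  list(cutoff = grid[best], accuracy = accs[best], accuracies = accs,
       grid = grid)
}
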