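#' Inference configuration
#'
#' Bundles the tunable parameters of the order-stepping inference loop.
#'
#' @param max_order Largest conditioning-set size to test (order 0 is plain
#'   mutual information). Default 1, the recommended accuracy/complexity
#'   trade-off; values above 3 are accepted with a warning because the
#'   number of conditioning subsets grows combinatorially.
#' @param threshold Either `"auto"` (cutoff recomputed at every order from
#'   the current weight distribution by [auto_threshold()]), a single
#'   non-negative number applied at every order, or a numeric vector of
#'   length `max_order + 1` giving one cutoff per order.
#' @param workers Number of worker chunks the pair list is partitioned into
#'   (>= 1). Results are independent of this value; it only controls
#'   chunking.
#' @param grid Optional ascending cutoff grid forwarded to the automatic
#'   threshold scan. `NULL` uses the default 51-point grid (see
#'   [default_grid()]).
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(max_order = 1L, threshold = "auto",
                             workers = 1L, grid = NULL) {
  max_order <- as.integer(max_order)
  if (is.na(max_order) || max_order < 0L) {
    stop("max_order must be a non-negative integer", call. = FALSE)
  }
  if (max_order > 3L) {
    warning("orders above 3 are combinatorially expensive; proceed with care",
            call. = FALSE)
  }
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) {
    stop("workers must be >= 1", call. = FALSE)
  }
  if (is.numeric(threshold)) {
    if (any(threshold < 0)) stop("fixed thresholds must be >= 0", call. = FALSE)
    if (!length(threshold) %in% c(1L, max_order + 1L)) {
      stop("threshold vector must have length 1 or max_order + 1", call. = FALSE)
    }
  } else if (!identical(threshold, "auto")) {
    stop('threshold must be "auto" or numeric', call. = FALSE)
  }
  if (!is.null(grid)) {
    grid <- as.numeric(grid)
    if (is.unsorted(grid, strictly = TRUE)) {
      stop("grid must be strictly ascending", call. = FALSE)
    }
  }
  structure(list(max_order = max_order, threshold = threshold,
                 workers = workers, grid = grid),
            class = "inference_config")
}

new_network_state <- function(genes, weights, adjacency, order_completed,
                              cutoffs_used) {
  dimnames(weights) <- list(genes, genes)
  dimnames(adjacency) <- list(genes, genes)
  structure(list(genes = genes, weights = weights, adjacency = adjacency,
                 order_completed = order_completed,
                 cutoffs_used = cutoffs_used),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("network_state: %d genes, %d edges, completed order %d\n",
              length(x$genes), network_edge_count(x), x$order_completed))
  cat("cutoffs used:", paste(signif(x$cutoffs_used, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Number of retained edges in a network state
#' @param state A `network_state`.
#' @return Integer edge count (unordered pairs).
#' @export
network_edge_count <- function(state) {
  sum(state$adjacency[upper.tri(state$adjacency)])
}

#' Pairwise weights of a network state as a vector
#' @param state A `network_state`.
#' @return Numeric vector of the upper-triangle pair weights.
#' @export
network_pair_weights <- function(state) {
  state$weights[upper.tri(state$weights)]
}

#' Order-0 relevance network from pairwise mutual information
#'
#' Scores every unordered gene pair with Gaussian mutual information and
#' keeps pairs whose score is strictly above the cutoff.
#'
#' @param expr Expression matrix, genes in rows, conditions in columns;
#'   rownames are the gene identifiers.
#' @param cutoff Interaction cutoff; an edge requires weight > cutoff.
#' @return A `network_state` with `order_completed = 0`.
#' @export
initial_network <- function(expr, cutoff) {
  expr <- as_expression_matrix(expr)
  genes <- rownames(expr)
  g <- length(genes)
  cv <- sample_covariance(expr)
  v <- diag(cv)
  zero_var <- v <= 0
  if (any(zero_var)) {
    warning("zero-variance gene(s): ", paste(genes[zero_var], collapse = ", "),
            "; their MI is set to 0", call. = FALSE)
  }
  # MI(i, j) = 0.5 * log(v_i * v_j / max(v_i v_j - c_ij^2, floor)), vectorised
  vv <- tcrossprod(v)
  det2 <- pmax(vv - cv^2, DET_FLOOR)
  w <- 0.5 * log(pmax(vv, DET_FLOOR) / det2)
  w[w < 0] <- 0
  w[zero_var, ] <- 0
  w[, zero_var] <- 0
  diag(w) <- 0
  adj <- w > cutoff
  diag(adj) <- FALSE
  new_network_state(genes, w, adj, 0L, cutoff)
}

#' Common neighbors of an edge
#'
#' A gene is a common neighbor of genes `i` and `j` when it currently has an
#' edge to both. Conditioning sets at order `k` are drawn from this pool.
#'
#' @param state A `network_state`.
#' @param i,j Gene indices or names (must differ).
#' @return Integer vector of neighbor indices in ascending order.
#' @export
common_neighbors <- function(state, i, j) {
  i <- resolve_gene(state, i)
  j <- resolve_gene(state, j)
  if (i == j) stop("i and j must differ", call. = FALSE)
  unname(which(state$adjacency[i, ] & state$adjacency[j, ] &
                 seq_along(state$genes) != i & seq_along(state$genes) != j))
}

resolve_gene <- function(state, g) {
  if (is.character(g)) {
    idx <- match(g, state$genes)
    if (is.na(idx)) stop("unknown gene: ", g, call. = FALSE)
    return(idx)
  }
  as.integer(g)
}

#' Partition a pair index range into near-equal contiguous chunks
#'
#' @param n_pairs Number of work items.
#' @param n_workers Number of chunks (>= 1); chunk sizes differ by at most 1,
#'   with the remainder going to the leading chunks.
#' @return List of integer vectors (possibly empty) covering
#'   `seq_len(n_pairs)` disjointly.
#' @export
partition_pairs <- function(n_pairs, n_workers) {
  if (n_workers < 1L) stop("n_workers must be >= 1", call. = FALSE)
  base <- n_pairs %/% n_workers
  extra <- n_pairs %% n_workers
  sizes <- rep(base, n_workers) + c(rep(1L, extra), rep(0L, n_workers - extra))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_len(n_workers), function(w) {
    if (sizes[w] == 0L) integer(0) else starts[w]:ends[w]
  })
}

#' One order of path-consistency pruning
#'
#' For every edge of the entry snapshot whose common-neighbor pool has at
#' least `k` members, evaluates the conditional mutual information over all
#' size-`k` conditioning subsets drawn from that pool, records the maximum
#' as the new edge weight, and retains the edge only if that maximum is
#' strictly above the cutoff. Edges with fewer than `k` common neighbors are
#' passed through unchanged. All decisions use the adjacency snapshot taken
#' at entry, so the result does not depend on edge processing order or on
#' how the pair list is chunked across workers.
#'
#' With `cutoff = "auto"` the cutoff is determined by [auto_threshold()]
#' from the updated weights of the order's candidate edges, after the CMI
#' update and before retention. The conditional mutual information of a
#' true edge is generally smaller than its marginal mutual information, so
#' reusing an MI-scale cutoff on CMI-scale weights would over-prune;
#' rescanning the updated distribution keeps the cutoff on the right scale
#' at every order.
#'
#' @param state A `network_state` with `order_completed == k - 1`.
#' @param k Conditioning-set size (order), >= 1.
#' @param cutoff Interaction cutoff applied to the updated weights, or
#'   `"auto"`.
#' @param expr The expression matrix the state was built from.
#' @param workers Number of chunks for the edge list (result-invariant).
#' @param grid Optional cutoff grid for the automatic threshold scan.
#' @return The pruned `network_state` with `order_completed = k`.
#' @export
prune_step <- function(state, k, cutoff, expr, workers = 1L, grid = NULL) {
  k <- as.integer(k)
  if (k < 1L) stop("order k must be >= 1", call. = FALSE)
  if (state$order_completed != k - 1L) {
    stop("state has completed order ", state$order_completed,
         "; expected ", k - 1L, call. = FALSE)
  }
  expr <- as_expression_matrix(expr)
  cv <- sample_covariance(expr)
  adj <- state$adjacency   # snapshot: all CMI queries use entry adjacency
  w <- state$weights
  ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  n_edges <- nrow(ut)
  updates <- list()
  if (n_edges > 0L) {
    chunks <- partition_pairs(n_edges, workers)
    results <- lapply(chunks, function(idx) {
      out <- vector("list", length(idx))
      for (m in seq_along(idx)) {
        i <- ut[idx[m], 1L]; j <- ut[idx[m], 2L]
        nb <- which(adj[i, ] & adj[j, ])
        nb <- nb[nb != i & nb != j]
        if (length(nb) < k) {
          out[[m]] <- NULL
          next
        }
        # combn(x, k) misreads a scalar x as seq_len(x); guard the
        # single-subset case explicitly
        subsets <- if (length(nb) == k) list(nb)
                   else utils::combn(nb, k, simplify = FALSE)
        best <- -Inf
        for (z in subsets) {
          val <- as.numeric(gauss_cmi_cov(cv, i, j, z))
          if (val > best) best <- val
        }
        out[[m]] <- c(i, j, best)
      }
      out
    })
    updates <- unlist(results, recursive = FALSE)
    updates <- updates[!vapply(updates, is.null, logical(1))]
    for (rec in updates) {
      w[rec[1L], rec[2L]] <- w[rec[2L], rec[1L]] <- rec[3L]
    }
  }
  if (identical(cutoff, "auto")) {
    # rescan this order's candidate edges with their updated weights
    cutoff <- if (n_edges > 0L) auto_threshold(w[ut], grid = grid) else 0
  }
  for (rec in updates) {
    keep <- rec[3L] > cutoff
    adj[rec[1L], rec[2L]] <- adj[rec[2L], rec[1L]] <- keep
  }
  new_network_state(state$genes, w, adj, k,
                    c(state$cutoffs_used, cutoff))
}

#' Infer a gene regulatory network by order-stepping CMI pruning
#'
#' Runs the full inference loop: an order-0 mutual-information relevance
#' network, then one pruning pass per order up to `config$max_order`,
#' conditioning each surviving edge on size-`k` subsets of its common
#' neighbors. The loop stops early when no edge has enough common neighbors
#' for the next order. With `threshold = "auto"` the cutoff is recomputed at
#' each order from the current pair-weight distribution.
#'
#' @param expr Expression matrix (genes x conditions) or an object accepted
#'   by [as_expression_matrix()].
#' @param config An [inference_config()].
#' @return A `network_state`.
#' @examples
#' set.seed(1)
#' fx <- chain_fixture(n_samples = 300, seed = 7)
#' net <- infer_network(fx$expression, inference_config(max_order = 1,
#'                                                      threshold = 0.05))
#' network_edge_count(net)
#' @export
infer_network <- function(expr, config = inference_config()) {
  expr <- as_expression_matrix(expr)
  if (!inherits(config, "inference_config")) {
    stop("config must be an inference_config", call. = FALSE)
  }
  resolve_cutoff <- function(order) {
    th <- config$threshold
    if (identical(th, "auto")) "auto"
    else if (length(th) == 1L) th
    else th[order + 1L]
  }
  # order 0: MI weights first, then the order-0 cutoff from their distribution
  cut0 <- resolve_cutoff(0L)
  if (identical(cut0, "auto")) {
    state0 <- initial_network(expr, cutoff = -Inf)
    cut0 <- auto_threshold(network_pair_weights(state0), grid = config$grid)
  }
  state <- initial_network(expr, cutoff = cut0)
  if (config$max_order >= 1L) {
    for (k in seq_len(config$max_order)) {
      eligible <- any_edge_with_neighbors(state, k)
      if (!eligible) {
        message("no edge has >= ", k, " common neighbors; stopping at order ",
                state$order_completed)
        break
      }
      state <- prune_step(state, k, resolve_cutoff(k), expr,
                          workers = config$workers, grid = config$grid)
    }
  }
  state
}

any_edge_with_neighbors <- function(state, k) {
  adj <- state$adjacency
  ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  if (nrow(ut) == 0L) return(FALSE)
  storage.mode(adj) <- "integer"
  # common-neighbor counts for all pairs at once
  cn <- adj %*% adj
  any(cn[ut] >= k)
}
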