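#' Configuration for the linear-Gaussian network simulator
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of simulated conditions (>= 3).
#' @param avg_degree Expected number of neighbors per gene (undirected
#'   sense); must be below `n_genes`.
#' @param weight_range Magnitude range for regulatory edge weights; signs
#'   are drawn at random. Kept away from 0 so every true edge has a
#'   recoverable effect.
#' @param noise_sd Standard deviation of the additive Gaussian noise driving
#'   every gene (> 0); root genes are pure noise.
#' @param seed Integer seed; every generator output is a pure function of
#'   seed plus config.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_genes, n_samples, avg_degree = 2,
                         weight_range = c(0.5, 1.5), noise_sd = 0.5,
                         seed = 1L) {
  if (n_samples < 3L) stop("n_samples must be >= 3", call. = FALSE)
  if (avg_degree < 0 || avg_degree >= n_genes) {
    stop("avg_degree must be in [0, n_genes)", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (weight_range[1L] <= 0 || weight_range[2L] < weight_range[1L]) {
    stop("weight_range must be a positive interval", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 avg_degree = avg_degree,
                 weight_range = as.numeric(weight_range),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Random ground-truth DAG
#'
#' Draws a random topological order over `G1..Gn` and includes each
#' earlier-to-later gene pair as a directed edge independently with
#' probability `avg_degree / (n_genes - 1)`, so the expected edge count is
#' `n_genes * avg_degree / 2`. Edge weights have magnitudes uniform in
#' `weight_range` with random sign.
#'
#' @param config A [synth_config()].
#' @return A `synth_network`: fields `n_genes`, `genes`, `edges` (data frame
#'   `from`, `to`, `weight`), `topo_order`.
#' @export
random_dag <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_genes
  genes <- paste0("G", seq_len(n))
  set.seed(config$seed)
  topo <- sample.int(n)
  p <- if (n > 1L) config$avg_degree / (n - 1) else 0
  from <- integer(0); to <- integer(0)
  if (n > 1L && p > 0) {
    idx <- utils::combn(n, 2L)           # positions in topological order
    take <- stats::runif(ncol(idx)) < p
    from <- topo[idx[1L, take]]
    to <- topo[idx[2L, take]]
  }
  wmag <- stats::runif(length(from), config$weight_range[1L],
                       config$weight_range[2L])
  wsgn <- sample(c(-1, 1), length(from), replace = TRUE)
  edges <- data.frame(from = genes[from], to = genes[to],
                      weight = wmag * wsgn, stringsAsFactors = FALSE)
  structure(list(n_genes = n, genes = genes, edges = edges,
                 topo_order = genes[topo]),
            class = "synth_network")
}

#' Simulate expression from a linear-Gaussian structural model
#'
#' Generates samples in topological order: each gene is the weighted sum of
#' its parents plus independent Gaussian noise with standard deviation
#' `noise_sd`; roots are pure noise. This matches the Gaussian assumption of
#' the covariance-determinant entropy estimator exactly, so population MI
#' and CMI values are available in closed form for test oracles.
#'
#' @param network A `synth_network`.
#' @param config The [synth_config()] used to build it (supplies sample
#'   count, noise level and seed).
#' @return Expression matrix, genes in rows (`G1..Gn`), samples in columns.
#' @export
simulate_expression <- function(network, config) {
  stopifnot(inherits(network, "synth_network"),
            inherits(config, "synth_config"))
  n <- network$n_genes
  m <- config$n_samples
  set.seed(config$seed + 1L)  # distinct stream from topology sampling
  expr <- matrix(stats::rnorm(n * m, sd = config$noise_sd), nrow = n,
                 dimnames = list(network$genes,
                                 paste0("S", seq_len(m))))
  e <- network$edges
  for (g in network$topo_order) {
    parents <- e[e$to == g, , drop = FALSE]
    if (nrow(parents) == 0L) next
    contrib <- crossprod(
      expr[parents$from, , drop = FALSE], parents$weight)
    expr[g, ] <- expr[g, ] + as.numeric(contrib)
  }
  expr
}

#' Gold standard of a synthetic network
#'
#' Symmetrizes the directed ground-truth edges into unordered positive
#' pairs over the full gene universe.
#'
#' @param network A `synth_network`.
#' @return A [gold_standard()].
#' @export
synth_gold <- function(network) {
  stopifnot(inherits(network, "synth_network"))
  if (nrow(network$edges) == 0L) {
    gold_standard(character(0), network$genes)
  } else {
    gold_standard(network$edges[, c("from", "to")], network$genes)
  }
}

#' Three-gene chain fixture with one hidden-common-cause pair
#'
#' The canonical testbed for indirect-edge removal: `Z` drives both `X` and
#' `Y` (true edges Z-X and Z-Y only), with unit-variance `Z` and noise
#' standard deviation 0.5. `X` and `Y` are marginally correlated
#' (population correlation 0.8, MI 0.5108 nats) but conditionally
#' independent given `Z` (population CMI 0), so order-1 pruning should
#' delete the X-Y edge.
#'
#' @param n_samples Number of samples (>= 100).
#' @param seed Integer seed.
#' @return List with `network` (a `synth_network`), `expression`
#'   (3 x n_samples matrix, rows Z, X, Y) and `gold` (a `gold_standard`).
#' @export
chain_fixture <- function(n_samples, seed = 1L) {
  if (n_samples < 100L) stop("n_samples must be >= 100", call. = FALSE)
  set.seed(seed)
  z <- stats::rnorm(n_samples)               # unit-variance driver
  x <- z + stats::rnorm(n_samples, sd = 0.5)
  y <- z + stats::rnorm(n_samples, sd = 0.5)
  expr <- rbind(Z = z, X = x, Y = y)
  colnames(expr) <- paste0("S", seq_len(n_samples))
  genes <- c("Z", "X", "Y")
  edges <- data.frame(from = c("Z", "Z"), to = c("X", "Y"),
                      weight = c(1, 1), stringsAsFactors = FALSE)
  network <- structure(list(n_genes = 3L, genes = genes, edges = edges,
                            topo_order = genes),
                       class = "synth_network")
  list(network = network, expression = expr,
       gold = gold_standard(edges[, c("from", "to")], genes))
}
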