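# Shared fixture builders; everything is generated in code under fixed
# seeds so the suite carries no data files.

# Random symmetric positive-definite covariance matrix of dimension d.
random_pd_cov <- function(d) {
  a <- matrix(stats::rnorm(d * d), d)
  crossprod(a) + diag(d) * 0.1
}

# Population covariance of the hidden-common-cause chain X <- Z -> Y with
# unit-variance Z and noise sd 0.5, variable order (X, Z, Y).
chain_population_cov <- function() {
  matrix(c(1.25, 1.00, 1.00,
           1.00, 1.00, 1.00,
           1.00, 1.00, 1.25), 3, byrow = TRUE,
         dimnames = list(c("X", "Z", "Y"), c("X", "Z", "Y")))
}

# First-order partial correlation of variables 1 and 2 given 3, from a
# 3x3 covariance; the independent closed-form oracle for single-condition
# CMI.
partial_correlation <- function(cv) {
  r <- stats::cov2cor(cv)
  (r[1, 2] - r[1, 3] * r[2, 3]) /
    sqrt((1 - r[1, 3]^2) * (1 - r[2, 3]^2))
}

# A network of disjoint hidden-common-cause triples (chain motifs):
# G(3t+1) drives G(3t+2) and G(3t+3) for t = 0..n_triples-1.
chain_rich_network <- function(n_triples) {
  n <- 3L * n_triples
  genes <- paste0("G", seq_len(n))
  hub <- 3L * (seq_len(n_triples) - 1L) + 1L
  edges <- data.frame(
    from = genes[rep(hub, each = 2L)],
    to = genes[as.vector(rbind(hub + 1L, hub + 2L))],
    weight = 1, stringsAsFactors = FALSE)
  structure(list(n_genes = n, genes = genes, edges = edges,
                 topo_order = genes),
            class = "synth_network")
}

# Mann-Whitney rank-statistic AUROC: independent oracle for the
# trapezoidal ROC integration, tie-aware via midranks.
mann_whitney_auroc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
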