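test_that("initial network thresholds pairwise MI as specified", {
  set.seed(11)
  a <- rnorm(500)
  b <- a + rnorm(500, sd = 0.1)
  cc <- rnorm(500)
  expr <- rbind(A = a, B = b, C = cc)
  net <- initial_network(expr, cutoff = 0.1)
  expect_equal(net$order_completed, 0L)
  expect_true(net$adjacency["A", "B"])
  expect_false(net$adjacency["A", "C"])
  expect_false(net$adjacency["B", "C"])
  # vacuous and all-pass cutoffs
  hi <- initial_network(expr, cutoff = max(network_pair_weights(net)) + 1)
  expect_equal(network_edge_count(hi), 0)
  lo <- initial_network(expr, cutoff = -1)
  expect_equal(network_edge_count(lo), choose(3, 2))
  expect_error(initial_network(rbind(A = a, A = b), 0), "duplicate")
})

test_that("initial network weights match pairwise CMI estimator values", {
  set.seed(12)
  expr <- matrix(rnorm(6 * 40), 6, dimnames = list(paste0("G", 1:6), NULL))
  net <- initial_network(expr, 0)
  cv <- sample_covariance(expr)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(net$weights[i, j], as.numeric(mutual_information(cv, i, j)),
                 tolerance = 1e-10)
  }
  expect_identical(net$weights, t(net$weights))
})

test_that("common neighbors follow the shared-edge definition", {
  set.seed(13)
  expr <- matrix(rnorm(5 * 20), 5, dimnames = list(LETTERS[1:5], NULL))
  net <- initial_network(expr, cutoff = Inf)
  adj <- function(pairs) {
    for (p in pairs) {
      net$adjacency[p[1], p[2]] <<- net$adjacency[p[2], p[1]] <<- TRUE
    }
  }
  # triangle A-B, B-C, A-C
  adj(list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(common_neighbors(net, 1, 2), 3L)
  expect_equal(common_neighbors(net, "A", "B"), 3L)
  # star: D is connected to everything else
  net$adjacency[] <- FALSE
  adj(list(c(4, 1), c(4, 2), c(4, 3), c(4, 5)))
  expect_equal(common_neighbors(net, 1, 2), 4L)
  net$adjacency[] <- FALSE
  expect_length(common_neighbors(net, 1, 2), 0)
  expect_error(common_neighbors(net, 2, 2), "differ")
})

test_that("pruning removes the indirect edge of a chain and keeps direct ones", {
  fx <- chain_fixture(1000, seed = 5)
  net0 <- initial_network(fx$expression, 0.05)
  expect_true(net0$adjacency["X", "Y"])  # indirect pair present at order 0
  net1 <- prune_step(net0, 1, 0.05, fx$expression)
  expect_equal(net1$order_completed, 1L)
  expect_false(net1$adjacency["X", "Y"])
  expect_true(net1$adjacency["Z", "X"])
  expect_true(net1$adjacency["Z", "Y"])
  # the updated X-Y weight is the (near-zero) conditional value
  expect_lt(net1$weights["X", "Y"], 0.01)
})

test_that("prune_step leaves edges without enough common neighbors untouched", {
  set.seed(21)
  expr <- matrix(rnorm(4 * 50), 4, dimnames = list(paste0("G", 1:4), NULL))
  net <- initial_network(expr, cutoff = Inf)
  net$adjacency["G1", "G2"] <- net$adjacency["G2", "G1"] <- TRUE
  out <- prune_step(net, 1, 0.5, expr)
  expect_identical(out$adjacency, net$adjacency)
  expect_identical(out$weights, net$weights)
  expect_equal(out$order_completed, 1L)
})

test_that("pair partitioning is balanced, disjoint and covering", {
  expect_equal(lengths(partition_pairs(10, 2)), c(5, 5))
  expect_equal(lengths(partition_pairs(10, 3)), c(4, 3, 3))
  expect_equal(lengths(partition_pairs(2, 5)), c(1, 1, 0, 0, 0))
  expect_error(partition_pairs(5, 0), ">= 1")
  for (n in c(0, 1, 17, 100)) for (w in c(1, 3, 8)) {
    pp <- partition_pairs(n, w)
    expect_equal(sort(unlist(pp)), seq_len(n))
    expect_lte(diff(range(lengths(pp))), 1)
  }
})

test_that("worker count never changes the inferred network", {
  cfg <- synth_config(30, 300, avg_degree = 2.5, seed = 17)
  expr <- simulate_expression(random_dag(cfg), cfg)
  runs <- lapply(c(1, 4, 8), function(wk) {
    suppressMessages(infer_network(
      expr, inference_config(max_order = 2, threshold = "auto", workers = wk)))
  })
  expect_identical(runs[[1]]$weights, runs[[2]]$weights)
  expect_identical(runs[[1]]$weights, runs[[3]]$weights)
  expect_identical(runs[[1]]$adjacency, runs[[2]]$adjacency)
  expect_identical(runs[[1]]$adjacency, runs[[3]]$adjacency)
  expect_identical(runs[[1]]$cutoffs_used, runs[[3]]$cutoffs_used)
})

test_that("edge sets are nested across orders and runs are deterministic", {
  cfg <- synth_config(15, 400, avg_degree = 2, seed = 23)
  expr <- simulate_expression(random_dag(cfg), cfg)
  prev <- NULL
  for (k in 0:2) {
    st <- suppressMessages(infer_network(
      expr, inference_config(max_order = k, threshold = 0.02)))
    if (!is.null(prev)) {
      expect_true(all(!st$adjacency | prev))  # subset of previous order
    }
    prev <- st$adjacency
  }
  a <- suppressMessages(infer_network(expr, inference_config(max_order = 1)))
  b <- suppressMessages(infer_network(expr, inference_config(max_order = 1)))
  expect_identical(a, b)
})

test_that("every retained edge exceeds the cutoff applied at its last evaluation", {
  cfg <- synth_config(12, 300, avg_degree = 2, seed = 31)
  expr <- simulate_expression(random_dag(cfg), cfg)
  st <- suppressMessages(infer_network(
    expr, inference_config(max_order = 1, threshold = "auto")))
  last_cut <- st$cutoffs_used[length(st$cutoffs_used)]
  kept <- st$weights[upper.tri(st$weights)][st$adjacency[upper.tri(st$adjacency)]]
  # edges evaluated at the final order carry weights above its cutoff;
  # edges last judged at order 0 exceed the order-0 cutoff
  expect_true(all(kept > min(st$cutoffs_used)))
})

test_that("inference config validates its inputs", {
  expect_error(inference_config(max_order = -1), "non-negative")
  expect_error(inference_config(threshold = -0.5), ">= 0")
  expect_error(inference_config(workers = 0), ">= 1")
  expect_error(inference_config(threshold = c(0.1, 0.2, 0.3)), "length")
  expect_warning(inference_config(max_order = 4), "expensive")
  cfg <- inference_config(max_order = 2, threshold = c(0.1, 0.2, 0.3))
  expect_equal(cfg$threshold, c(0.1, 0.2, 0.3))
})
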