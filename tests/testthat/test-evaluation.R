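test_that("confusion counts enumerate the unordered pair universe", {
  genes <- LETTERS[1:5]
  gold <- gold_standard(rbind(c("A", "B"), c("B", "C")), genes)
  cnt <- confusion(rbind(c("A", "B"), c("C", "D")), gold)
  expect_equal(unclass(cnt)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 7L))
  # identity and empty predictions
  ident <- confusion(rbind(c("A", "B"), c("B", "C")), gold)
  expect_equal(ident$FP, 0L)
  expect_equal(ident$FN, 0L)
  none <- confusion(character(0), gold)
  expect_equal(none$TP, 0L)
  expect_equal(none$FN, 2L)
  expect_error(confusion(rbind(c("A", "Q")), gold), "unknown gene")
})

test_that("gold standards symmetrize and reject self-pairs", {
  g <- gold_standard(rbind(c("G1", "G2"), c("G2", "G1")), c("G1", "G2", "G3"))
  expect_equal(g$positive_pairs, "G1|G2")
  expect_error(gold_standard(rbind(c("G1", "G1")), c("G1", "G2")), "self")
})

test_that("classification metrics reproduce the defining ratios", {
  m <- classification_metrics(list(TP = 8, FN = 2, FP = 4, TN = 86))
  expect_equal(unname(m["TPR"]), 0.8)
  expect_equal(unname(m["FPR"]), 0.04444, tolerance = 1e-3)
  expect_equal(unname(m["PPV"]), 0.66667, tolerance = 1e-4)
  expect_equal(unname(m["ACC"]), 0.94)
  expect_true(is.na(classification_metrics(
    list(TP = 0, FP = 0, TN = 5, FN = 2))["PPV"]))
  perfect <- classification_metrics(list(TP = 3, FP = 0, TN = 7, FN = 0))
  expect_equal(unname(perfect["ACC"]), 1)
  # property: hand-computed integer ratios on random tables
  set.seed(71)
  for (rep in 1:25) {
    v <- as.list(sample(1:50, 4)); names(v) <- c("TP", "FP", "TN", "FN")
    m <- classification_metrics(v)
    expect_equal(unname(m["TPR"]), v$TP / (v$TP + v$FN))
    expect_equal(unname(m["ACC"]), (v$TP + v$TN) / Reduce(`+`, v))
  }
})

test_that("ranking metrics behave at the extremes and under ties", {
  scores <- c(5, 4, 3, 2, 1)
  labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  out <- roc_pr_curves(scores, labels)
  expect_equal(out$auroc, 1)
  expect_equal(out$aupr, 1)
  rev <- roc_pr_curves(-scores, labels)
  expect_equal(rev$auroc, 0)
  # all scores tied: a single threshold step, AUROC 1/2
  tied <- roc_pr_curves(rep(1, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(tied$auroc, 0.5)
  expect_error(roc_pr_curves(1:3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("AUROC is invariant under strictly increasing score transforms", {
  set.seed(72)
  scores <- rnorm(300)
  labels <- runif(300) < 0.3
  base <- roc_pr_curves(scores, labels)$auroc
  expect_equal(roc_pr_curves(exp(scores), labels)$auroc, base,
               tolerance = 1e-12)
  expect_equal(roc_pr_curves(scores^3 + 2 * scores, labels)$auroc, base,
               tolerance = 1e-12)
})

test_that("AUROC agrees with the Mann-Whitney rank statistic", {
  set.seed(73)
  for (rep in 1:20) {
    n <- sample(50:400, 1)
    scores <- sample(rnorm(n))  # some exact ties via rounding below
    scores <- round(scores, 1)
    labels <- runif(n) < 0.25
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_pr_curves(scores, labels)$auroc,
                 mann_whitney_auroc(scores, labels), tolerance = 1e-9)
  }
})

test_that("random scores give null AUROC near one half", {
  set.seed(74)
  med <- median(replicate(20, {
    scores <- runif(10000)
    labels <- seq_len(10000) <= 1000
    roc_pr_curves(scores, labels)$auroc
  }))
  expect_lt(abs(med - 0.5), 0.02)
})

test_that("threshold offset is the range-normalized percent difference", {
  expect_equal(threshold_offset(0.4, 0.5, 0, 1), 10)
  expect_equal(threshold_offset(0.3, 0.3, 0, 1), 0)
  expect_equal(threshold_offset(0.2, 0.6, 0, 1), 40)
  expect_equal(threshold_offset(0.2, 0.3, 0, 2), 5)
  expect_error(threshold_offset(0.1, 0.2, 1, 1), "exceed")
  # offsets of 4, 9, 19 percent meet the stringent/standard/moderate bands
  expect_lt(threshold_offset(0.4, 0.44, 0, 1), 5)
  expect_lt(threshold_offset(0.4, 0.49, 0, 1), 10)
  expect_lt(threshold_offset(0.4, 0.59, 0, 1), 20)
})

test_that("the true threshold is the accuracy argmax over the grid", {
  cfg <- synth_config(10, 300, avg_degree = 2, seed = 75)
  net <- random_dag(cfg)
  expr <- simulate_expression(net, cfg)
  gold <- synth_gold(net)
  grid <- seq(0, 1, by = 0.1)
  tt <- suppressMessages(true_threshold(expr, gold, order = 0, grid = grid))
  expect_equal(tt$accuracy, max(tt$accuracies))
  expect_equal(tt$cutoff, grid[which.max(tt$accuracies)])
  # re-evaluating at the returned cutoff reproduces the maximum
  st <- suppressMessages(infer_network(
    expr, inference_config(max_order = 0, threshold = tt$cutoff)))
  expect_equal(unname(evaluate_network(st, gold)$metrics[["ACC"]]),
               tt$accuracy)
  # single-point grid returns that point
  one <- suppressMessages(true_threshold(expr, gold, order = 0, grid = 0.3))
  expect_equal(one$cutoff, 0.3)
})
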