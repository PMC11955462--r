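# Bag aggregation strategies and the metric suite.

test_that("aggregate_bag reproduces the worked pooling examples", {
  expect_equal(as.numeric(aggregate_bag(c(0.2, 0.4, 0.6), "mean")), 0.4)
  a <- aggregate_bag(c(0.9, 0.1, 0.5), "topk", k = 2)
  expect_equal(as.numeric(a), 0.7)
  expect_equal(attr(a, "k_used"), 2L)
  # k larger than the bag falls back to all instances
  a2 <- aggregate_bag(c(0.4, 0.8), "top10")
  expect_equal(as.numeric(a2), 0.6)
  expect_equal(attr(a2, "k_used"), 2L)
  expect_equal(as.numeric(aggregate_bag(c(0.2, 0.9, 0.3), "max")), 0.9)
  expect_error(aggregate_bag(numeric(0), "mean"),
               class = "hemil_invalid_argument")
})

test_that("all strategies match the sort-and-slice oracle on random bags", {
  set.seed(101)
  for (rep in 1:100) {
    probs <- runif(sample(1:200, 1))
    for (s in c("mean", "top10", "top100", "max")) {
      expect_equal(as.numeric(aggregate_bag(probs, s)),
                   oracle_aggregate(probs, s), tolerance = 1e-12)
    }
    k <- sample(1:50, 1)
    expect_equal(as.numeric(aggregate_bag(probs, "topk", k = k)),
                 oracle_aggregate(probs, "topk", k = k), tolerance = 1e-12)
  }
})

test_that("pooling identities and orderings hold", {
  set.seed(7)
  for (rep in 1:50) {
    probs <- runif(sample(1:40, 1))
    n <- length(probs)
    agg <- function(s, k = NULL) as.numeric(aggregate_bag(probs, s, k))
    # top-1 == max; top-k with k >= n == mean
    expect_identical(agg("topk", 1), agg("max"))
    expect_identical(agg("topk", n + 5), agg("mean"))
    # max >= top-k >= mean, and non-increasing in k
    ks <- seq_len(n)
    vals <- vapply(ks, function(k) agg("topk", k), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
    expect_gte(agg("max") + 1e-12, max(vals))
    expect_lte(agg("mean") - 1e-12, min(vals))
    # permutation invariance
    expect_equal(agg("topk", 3),
                 as.numeric(aggregate_bag(sample(probs), "topk", 3)))
  }
  # equality when all instances agree
  same <- rep(0.37, 12)
  expect_equal(as.numeric(aggregate_bag(same, "mean")),
               as.numeric(aggregate_bag(same, "max")))
})

test_that("bag thresholding uses an inclusive 0.5 boundary", {
  df <- data.frame(bag_prob = c(0.5, 0.4999, 0.7, 0))
  out <- classify_bags(df)
  expect_equal(out$predicted_label, c("high", "low", "high", "low"))
  out2 <- classify_bags(df, threshold = 1.1)
  expect_true(all(out2$predicted_label == "low"))
})

test_that("F1 reproduces the published per-strategy values", {
  # exact confusion fractions implied by the printed metrics on the
  # 13-patient validation set (5 high, 8 low): P = 5/13 is printed as its
  # rounding 0.3846
  expect_equal(round(f1_from_pr(5 / 13, 1), 4), 0.5556)      # top-10, max
  expect_equal(round(f1_from_pr(0.4000, 0.8000), 4), 0.5333) # top-100
  expect_equal(f1_from_pr(0.600, 0.600), 0.600)              # mean
  # recomputing from the rounded printed precision stays within one unit
  # of the fourth decimal
  expect_lt(abs(f1_from_pr(0.3846, 1.000) - 0.5556), 1e-4)
  expect_error(f1_from_pr(0, 0), class = "hemil_invalid_argument")
})

test_that("compute_metrics matches hand confusion arithmetic", {
  # truth: 5 high, 8 low; predictions giving tp=3 fp=2 fn=2 tn=6
  truth <- c(rep("high", 5), rep("low", 8))
  pred <- c(rep("high", 3), rep("low", 2),  # of the 5 high
            rep("high", 2), rep("low", 6))  # of the 8 low
  set.seed(1)
  m <- compute_metrics(truth, pred, runif(13))
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(3, 2, 2, 6))
  expect_equal(m$precision, 0.600)
  expect_equal(m$recall, 0.600)
  expect_equal(m$f1, 0.600)
  expect_equal(m$accuracy, 9 / 13)
})

test_that("rank AUC equals all-pairs counting and is monotone-invariant", {
  expect_equal(auc_roc(c("high", "high", "low"), c(0.9, 0.8, 0.1)), 1)
  expect_equal(auc_roc(c("high", "low", "high", "low"), rep(0.4, 4)), 0.5)
  set.seed(202)
  for (rep in 1:200) {
    n <- sample(4:40, 1)
    labels <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("high", "low")
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    a <- auc_roc(labels, scores)
    expect_equal(a, oracle_auc(labels, scores), tolerance = 1e-12)
    # strictly monotone transform leaves AUC unchanged
    expect_equal(auc_roc(labels, exp(3 * scores)), a, tolerance = 1e-12)
  }
  expect_warning(auc_roc(rep("high", 4), runif(4)), "one class")
})

test_that("predict_bags aggregates per patient across strategies", {
  preds <- data.frame(
    patient_id = rep(c("A", "B"), c(3, 2)),
    prob_high = c(0.2, 0.4, 0.9, 0.1, 0.3))
  bp <- predict_bags(preds, strategies = c("mean", "max"))
  expect_equal(nrow(bp), 4L)
  expect_equal(bp$bag_prob[bp$patient_id == "A" & bp$strategy == "mean"], 0.5)
  expect_equal(bp$bag_prob[bp$patient_id == "A" & bp$strategy == "max"], 0.9)
  expect_equal(bp$predicted_label[bp$patient_id == "B" & bp$strategy == "mean"],
               "low")
})
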