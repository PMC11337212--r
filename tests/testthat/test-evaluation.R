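test_that("binary_report equals the naive confusion-count oracle", {
  set.seed(101)
  for (trial in 1:1000) {
    n <- sample(4:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    calls <- rbinom(n, 1, 0.5)
    r <- binary_report(labels, calls)
    o <- naive_report(labels, calls)
    expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(o$tp, o$fp, o$tn, o$fn))
    expect_equal(r$sensitivity, o$sens)
    expect_equal(r$specificity, o$spec)
    expect_equal(r$balanced_accuracy, o$ba)
    expect_identical(r$balanced_accuracy,
                     (r$sensitivity + r$specificity) / 2)
    if (o$tp + o$fp > 0) expect_equal(r$ppv, o$ppv)
    if (is.finite(o$mcc)) expect_equal(r$mcc, o$mcc)
    expect_equal(r$f1, o$f1)
    if (is.finite(o$lr)) expect_equal(r$lr_plus, o$lr)
  }
})

test_that("AUC equals the Mann-Whitney U identity", {
  set.seed(202)
  for (trial in 1:200) {
    n <- sample(5:40, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    probs <- round(runif(n), 2) # force some ties
    # brute-force U with 0.5 credit for ties
    pos <- probs[labels == 1]; neg <- probs[labels == 0]
    u <- 0
    for (a in pos) for (b in neg) u <- u + (a > b) + 0.5 * (a == b)
    expect_equal(auc_roc(probs, labels), u / (length(pos) * length(neg)))
  }
})

test_that("average precision matches the reference implementation", {
  # frozen oracle values (scikit-learn average_precision_score)
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
                                 c(1, 0, 1, 1, 0, 1)), 0.7708333,
               tolerance = 1e-6)
  expect_equal(average_precision(c(0.9, 0.5, 0.5, 0.1), c(1, 1, 0, 0)),
               0.8333333, tolerance = 1e-6)
  expect_equal(auc_roc(c(0.9, 0.5, 0.5, 0.1), c(1, 1, 0, 0)), 0.875)
})

test_that("kappa agrees with the brute-force formula", {
  expect_equal(kappa_agreement(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(kappa_agreement(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_equal(kappa_agreement(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
  set.seed(303)
  for (trial in 1:200) {
    n <- sample(4:50, 1)
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    po <- mean(a == b)
    pe <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
    if (pe >= 1) {
      expect_true(is.na(kappa_agreement(a, b)))
    } else {
      expect_equal(kappa_agreement(a, b), (po - pe) / (1 - pe))
    }
  }
  expect_error(kappa_agreement(c(1, 0), c(1, 0, 1)), "length")
})

test_that("jaccard similarity counts mutual presence only", {
  expect_equal(jaccard_calls(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(jaccard_calls(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_equal(jaccard_calls(c(1, 0, 0), c(0, 1, 1)), 0)
  both0 <- jaccard_calls(c(0, 0), c(0, 0))
  expect_equal(as.numeric(both0), 1)
  expect_identical(attr(both0, "flag"), "both_empty")
  expect_error(jaccard_calls(c(1), c(1, 0)), "length")
})

test_that("top-k detection metrics reduce to binary_report at k = n", {
  probs <- c(0.9, 0.8, 0.7, 0.6); labels <- c(1, 0, 1, 0)
  at2 <- lr_plus_at_topk(probs, labels, 2)
  expect_identical(c(at2$tp, at2$fp), c(1L, 1L))
  expect_equal(at2$ppv, 0.5)
  atn <- lr_plus_at_topk(probs, labels, 4)
  allpos <- binary_report(labels, rep(1, 4), probs)
  expect_identical(atn$report[c("tp", "fp", "tn", "fn")],
                   allpos[c("tp", "fp", "tn", "fn")])
  # constant-positive closed form: spec = 0, LR+ = 1, PPV = prevalence
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$lr_plus, 1)
  expect_equal(allpos$ppv, mean(labels))
  # perfectly ranked at k = n_pos: infinite LR+ flag, PPV = 1
  perf <- lr_plus_at_topk(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 2)
  expect_identical(perf$lr_plus, Inf)
  expect_equal(perf$ppv, 1)
  expect_true("lr_plus_infinite" %in% perf$report$flags)
  expect_error(lr_plus_at_topk(probs, labels, 0), "k must be")
  # curve consistency
  curve <- topk_curve(probs, labels)
  expect_equal(curve$tp[2], 1)
  expect_identical(nrow(curve), 4L)
})

test_that("undefined metrics are flagged, never silently zeroed", {
  r <- binary_report(c(1, 1, 1), c(1, 1, 0)) # single-class labels
  expect_true(is.na(r$specificity))
  expect_true(all(c("specificity", "mcc") %in% r$flags))
  expect_equal(r$sensitivity, 2 / 3)
  lst <- report_as_list(r)
  expect_null(lst$specificity)
  perfect <- binary_report(c(1, 0), c(1, 0), c(0.9, 0.1))
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_identical(perfect$lr_plus, Inf)
  expect_true("lr_plus_infinite" %in% perfect$flags)
})

test_that("LR+ and PPV rank models identically at fixed prevalence", {
  set.seed(404)
  labels <- rbinom(80, 1, 0.4)
  reports <- lapply(1:10, function(i) {
    binary_report(labels, rbinom(80, 1, 0.5))
  })
  lr <- vapply(reports, function(r) r$lr_plus, 1)
  ppv <- vapply(reports, function(r) r$ppv, 1)
  keep <- is.finite(lr) & is.finite(ppv)
  expect_identical(order(lr[keep]), order(ppv[keep]))
})
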