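test_that("youden_threshold equals the exhaustive scan on spec examples", {
  thr <- youden_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(thr), 0.5)
  expect_equal(attr(thr, "j"), 1)
  # anti-ranked: no cutoff helps, flag raised
  anti <- youden_threshold(c(0.9, 0.6, 0.4, 0.1), c(0, 0, 1, 1))
  expect_identical(attr(anti, "flag"), "no_benefit")
  # degenerate: all probabilities equal
  expect_warning(deg <- youden_threshold(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)),
                 "equal")
  expect_equal(as.numeric(deg), 0.5)
  expect_error(youden_threshold(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("youden_threshold achieves the oracle J on random inputs", {
  set.seed(77)
  for (trial in 1:1000) {
    n <- sample(4:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    probs <- round(runif(n), 2)
    thr <- suppressWarnings(youden_threshold(probs, labels))
    j_pkg <- attr(thr, "j")
    expect_equal(j_pkg, youden_oracle_j(probs, labels), tolerance = 1e-12)
    # achieved J really is J at the returned threshold
    calls <- probs >= as.numeric(thr)
    j_chk <- mean(calls[labels == 1]) + mean(!calls[labels == 0]) - 1
    expect_equal(j_pkg, j_chk, tolerance = 1e-12)
  }
})

test_that("endpoint classifier training finds planted signal", {
  set.seed(21)
  n <- 150
  X <- matrix(rbinom(n * 20, 1, 0.3), n, 20,
              dimnames = list(NULL, paste0("b", 1:20)))
  y <- X[, 1] # linearly separable: label equals one feature
  keys <- sprintf("K%03d", seq_len(n))
  ds <- endpoint_dataset("toy", data.frame(key14 = keys, label = y),
                         "binary")
  em <- train_endpoint_classifier(ds, X, space = small_search_space(),
                                  seed = 1, n_configs = 4)
  expect_gte(em$cv_score, 0.95)
  expect_identical(em$training_digest, key_digest(keys))
  # determinism: retraining with the same seed reproduces predictions
  em2 <- train_endpoint_classifier(ds, X, space = small_search_space(),
                                   seed = 1, n_configs = 4)
  expect_identical(predict(em$model, X), predict(em2$model, X))
  # class smaller than fold count errors
  y2 <- c(rep(1, 3), rep(0, n - 3))
  ds2 <- endpoint_dataset("toy2", data.frame(key14 = keys, label = y2),
                          "binary")
  expect_error(train_endpoint_classifier(ds2, X), "fewer members")
})

test_that("null labels give chance-level inner-CV AUC", {
  set.seed(33)
  n <- 500
  X <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, paste0("x", 1:15)))
  y <- sample(rep(c(0, 1), each = n / 2))
  ds <- endpoint_dataset("null", data.frame(key14 = sprintf("N%03d", 1:n),
                                            label = y), "binary")
  em <- train_endpoint_classifier(ds, X, space = small_search_space(),
                                  seed = 5, n_configs = 2)
  expect_gte(em$cv_score, 0.4)
  expect_lte(em$cv_score, 0.6)
})

test_that("Cmax regressor recovers a linear target and rejects tiny data", {
  set.seed(44)
  n <- 160
  X <- matrix(runif(n * 10), n, 10, dimnames = list(NULL, paste0("d", 1:10)))
  y <- 3 * X[, 1] + 1 # exact function of a 'logP-like' column
  keys <- sprintf("C%03d", 1:n)
  ds <- endpoint_dataset("cmax", data.frame(key14 = keys[1:120],
                                            label = y[1:120]), "numeric")
  em <- train_cmax_regressor(ds, X[1:120, ], space = small_search_space(),
                             seed = 2, n_configs = 4)
  pred <- predict_endpoint(em, X[121:160, ])$pred
  r2 <- 1 - sum((y[121:160] - pred)^2) /
    sum((y[121:160] - mean(y[121:160]))^2)
  expect_gte(r2, 0.8)
  # permuted labels carry no signal
  ds_null <- endpoint_dataset("cmaxnull",
                              data.frame(key14 = keys[1:120],
                                         label = sample(y[1:120])),
                              "numeric")
  em_null <- train_cmax_regressor(ds_null, X[1:120, ],
                                  space = small_search_space(), seed = 3,
                                  n_configs = 2)
  expect_lte(em_null$cv_score, 0.1)
  # fewer than 20 rows errors
  tiny <- endpoint_dataset("t", data.frame(key14 = keys[1:10],
                                           label = y[1:10]), "numeric")
  expect_error(train_cmax_regressor(tiny, X[1:10, ]), "at least 20")
  # constant labels warn
  cst <- endpoint_dataset("c", data.frame(key14 = keys[1:30],
                                          label = rep(2, 30)), "numeric")
  expect_warning(train_cmax_regressor(cst, X[1:30, ],
                                      space = small_search_space(),
                                      n_configs = 2), "constant")
})

test_that("threshold calibration and prediction conventions", {
  set.seed(55)
  n <- 120
  X <- matrix(rbinom(n * 10, 1, 0.4), n, 10,
              dimnames = list(NULL, paste0("b", 1:10)))
  y <- as.integer(xor(X[, 1] == 1, rbinom(n, 1, 0.1) == 1))
  ds <- endpoint_dataset("cal", data.frame(key14 = sprintf("T%03d", 1:n),
                                           label = y), "binary")
  em <- train_endpoint_classifier(ds, X, space = small_search_space(),
                                  seed = 4, n_configs = 2)
  em <- calibrate_threshold(em, X, y)
  expect_true(em$threshold > 0 && em$threshold < 1)
  out <- predict_endpoint(em, X)
  expect_identical(out$calls, as.integer(out$probs >= em$threshold))
  # probability exactly at the threshold is a positive call
  em$threshold <- out$probs[1]
  expect_identical(predict_endpoint(em, X)$calls[1], 1L)
  # empty input gives empty output
  empty <- predict_endpoint(em, X[0, , drop = FALSE])
  expect_length(empty$probs, 0)
})

test_that("endpoint seeds fan out deterministically within integer range", {
  s1 <- endpoint_seed(7, "BSEP")
  expect_identical(s1, endpoint_seed(7, "BSEP"))
  expect_false(s1 == endpoint_seed(7, "Mitotox"))
  expect_true(s1 >= 0 && s1 < 2^31)
})

test_that("cross_predict_matrix has the contract shape", {
  set.seed(66)
  n <- 90
  X <- matrix(rbinom(n * 12, 1, 0.3), n, 12,
              dimnames = list(NULL, paste0("b", 1:12)))
  mk <- function(name, col) {
    y <- as.integer(xor(X[, col] == 1, rbinom(n, 1, 0.15) == 1))
    endpoint_dataset(name, data.frame(key14 = sprintf("%s%03d", name, 1:n),
                                      label = y), "binary")
  }
  datasets <- list(e1 = mk("e1", 1), e2 = mk("e2", 1), e3 = mk("e3", 7))
  models <- lapply(datasets, function(d) {
    train_endpoint_classifier(d, X, space = small_search_space(),
                              seed = endpoint_seed(1, d$name),
                              n_configs = 2)
  })
  feats <- list(e1 = X, e2 = X, e3 = X)
  cp <- cross_predict_matrix(models, datasets, feats)
  expect_identical(dim(cp$auc), c(3L, 3L))
  expect_true(all(is.finite(cp$auc)))
  expect_true(all(cp$auc >= 0 & cp$auc <= 1))
  # endpoints sharing the planted signal predict each other better than
  # independent ones
  expect_gt(cp$auc["e1", "e2"], cp$auc["e1", "e3"])
})
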