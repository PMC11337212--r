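test_that("stacked width identities hold for every combo", {
  w <- featurenet_world()
  keys <- w$gold$data$key14
  all_blk <- build_stacked(keys, w$chem_gold, w$models, combo = "all")
  n_struct <- ncol(w$chem_gold$structural)
  n_desc <- ncol(w$chem_gold$descriptors)
  expect_identical(ncol(all_blk$matrix), n_struct + n_desc + 11L)
  proxy_blk <- build_stacked(keys, w$chem_gold, w$models, combo = "proxy")
  expect_identical(ncol(proxy_blk$matrix), 11L)
  # proxy columns are probabilities in [0,1]; PK columns finite
  probs <- proxy_blk$matrix[, 1:9]
  expect_true(all(probs >= 0 & probs <= 1))
  expect_true(all(is.finite(proxy_blk$matrix)))
  # provenance aligns with columns
  expect_identical(length(attr(all_blk, "provenance")),
                   ncol(all_blk$matrix))
  # empty compound list keeps the full header
  empty_chem <- lapply(w$chem_gold, function(x) {
    if (is.matrix(x)) x[0, , drop = FALSE] else x
  })
  empty_chem$structural <- w$chem_gold$structural[0, , drop = FALSE]
  empty_chem$descriptors <- w$chem_gold$descriptors[0, , drop = FALSE]
  eb <- build_stacked(character(), empty_chem, w$models, combo = "all")
  expect_identical(nrow(eb$matrix), 0L)
  expect_identical(colnames(eb$matrix), colnames(all_blk$matrix))
})

test_that("the leak guard rejects compounds inside a proxy training set", {
  w <- featurenet_world()
  em <- w$models$human_hepatotoxicity
  bad_key <- em$training_keys[1]
  chem <- w$fx$chem_for(bad_key)
  expect_error(build_stacked(bad_key, chem, w$models, combo = "all"),
               "leak guard")
  # the guard is asserted on every call with gold keys: passes clean
  expect_silent(build_stacked(w$gold$data$key14[1:3],
                              w$fx$chem_for(w$gold$data$key14[1:3]),
                              w$models, combo = "all"))
})

test_that("nested_cv evaluates folds x repeats and respects stratification", {
  w <- featurenet_world()
  keys <- w$gold$data$key14
  stacked <- build_stacked(keys, w$chem_gold, w$models, combo = "proxy")
  y <- w$gold$data$label
  cv <- nested_cv(stacked$matrix, y, outer_folds = 5L, repeats = 2L,
                  inner_folds = 4L, seed = 1, tune = FALSE, config = w$cfg)
  expect_identical(nrow(cv), 10L) # 5 folds x 2 repeats
  expect_true(all(cv$threshold > 0 & cv$threshold < 1))
  s <- summary(cv)
  expect_identical(nrow(s$per_repeat), 2L)
  expect_error(nested_cv(stacked$matrix, rep(c(0, 1), c(178, 2)),
                         outer_folds = 5L, repeats = 1L),
               "stratification")
})

test_that("final model threshold is a pure function of training data", {
  w <- featurenet_world()
  keys <- w$gold$data$key14
  stacked <- build_stacked(keys, w$chem_gold, w$models, combo = "all")
  y <- w$gold$data$label
  final <- fit_final(stacked, y, w$cfg,
                     context = list(fitted_masks = w$fx$masks,
                                    endpoint_models = w$models),
                     seed = 3, train_keys = keys)
  expect_true(final$threshold > 0 && final$threshold < 1)
  # recomputing from the persisted out-of-fold probabilities reproduces it
  expect_identical(final$threshold,
                   as.numeric(youden_threshold(final$oof_probs, y)))
  # same seed -> identical model
  final2 <- fit_final(stacked, y, w$cfg, seed = 3, train_keys = keys)
  expect_identical(predict(final$model, stacked$matrix),
                   predict(final2$model, stacked$matrix))
  assign("featurenet_final", final, .fixture_cache)
})

test_that("predict_dili runs the full pipeline from raw SMILES", {
  w <- featurenet_world()
  final <- get("featurenet_final", .fixture_cache)
  # resubmitting a training compound reproduces its training-time score
  i <- match(final$train_keys[5], w$fx$std$key14)
  smi <- w$fx$std$smiles_in[i]
  out <- predict_dili(final, c(smi, "C1CC", "[Fe+2]"))
  expect_false(out$results$rejected[1])
  expect_true(all(out$results$rejected[2:3]))
  expect_identical(out$results$reject_reason[2], "parse_failure")
  stacked_train <- build_stacked(final$train_keys,
                                 w$fx$chem_for(final$train_keys),
                                 w$models, combo = "all")
  expected <- predict(final$model, stacked_train$matrix)[5]
  expect_equal(out$results$probability[1], expected, tolerance = 1e-12)
  expect_identical(out$results$call[1],
                   as.integer(out$results$probability[1] >=
                                final$threshold))
  # all compounds rejected -> structured empty result
  allbad <- predict_dili(final, c("C1CC", "xx"))
  expect_true(attr(allbad, "empty"))
  expect_true(all(allbad$results$rejected))
})

test_that("attribution is additive and honest about highlights", {
  w <- featurenet_world()
  final <- get("featurenet_final", .fixture_cache)
  # gold compounds: clean of every proxy training set by construction,
  # so the leak guard stays silent
  test_keys <- w$gold$data$key14[1:10]
  stacked <- build_stacked(test_keys, w$fx$chem_for(test_keys), w$models,
                           combo = "all")
  for (row in 1:3) {
    att <- attribute_prediction(final, stacked, row = row,
                                smiles = w$fx$std$smiles_std[
                                  match(test_keys[row], w$fx$std$key14)])
    pred <- predict(final$model, stacked$matrix[row, , drop = FALSE])
    expect_equal(att$prediction, pred, tolerance = 1e-6)
    expect_lte(length(att$top_pos_proxy), 3L)
    expect_lte(length(att$top_neg_proxy), 3L)
    if (!is.null(att$highlight)) {
      expect_true(att$highlight$maccs_key >= 1 &&
                    att$highlight$maccs_key <= 166)
    } else {
      expect_match(att$note, "MACCS")
    }
  }
})

test_that("best_nested_config picks from the top repeat", {
  w <- featurenet_world()
  keys <- w$gold$data$key14
  stacked <- build_stacked(keys, w$chem_gold, w$models, combo = "proxy")
  cv <- nested_cv(stacked$matrix, w$gold$data$label, outer_folds = 5L,
                  repeats = 2L, seed = 2, tune = FALSE, config = w$cfg)
  cfg <- best_nested_config(cv)
  expect_identical(cfg, w$cfg)
})
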