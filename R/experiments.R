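# End-to-end recovery experiments on the synthetic world: these drive the
# package's acceptance checks (stacking dominance, attribution recovery,
# permuted-label nulls, Cmax coefficient-sign recovery). Model budgets are
# deliberately desk-scale (fixed mid-grid configuration, 2 nested-CV
# repeats) so a multi-seed study completes in minutes; the protocol shape
# (Butina split, leak-guarded stacking, out-of-fold thresholds) is the
# production one.

fixed_config <- function() {
  list(n_trees = 100L, max_depth = 0L, min_leaf = 3L, mtry_frac = "sqrt",
       class_weight = "balanced")
}

singleton_space <- function(config) {
  lapply(config, function(v) if (is.list(v)) v else list(v))
}

#' Structural columns that track each planted toxicophore
#'
#' A masked structural column "matches" toxicophore k when it fires only
#' on carriers of that toxicophore (its 0/1 pattern over the whole library
#' is a non-empty subset of the planted indicator) -- i.e. the bit is
#' specific to the planted substructure, possibly in a scaffold-dependent
#' environment.
#'
#' @param fixture result of [prepare_fixture()]
#' @return named list: toxicophore -> character vector of column names
#' @export
toxicophore_feature_columns <- function(fixture) {
  chem <- fixture$chem_for(fixture$std$key14)
  struct <- chem$structural
  tox <- attr(fixture$lib, "tox")
  out <- list()
  for (k in colnames(tox)) {
    sub <- vapply(seq_len(ncol(struct)), function(j) {
      any(struct[, j] > 0) && all(struct[, j] <= tox[, k])
    }, logical(1))
    out[[k]] <- colnames(struct)[sub]
  }
  out
}

#' One seed of the signal-recovery experiment
#'
#' Generates the synthetic panel (salts/stereo/conflicts disabled so the
#' library -- and its standardization -- is seed-invariant and can be
#' cached), trains the nine proxy classifiers and two Cmax regressors with
#' a fixed mid-grid configuration, Butina-splits the gold set, runs nested
#' CV for the all-features and structure-only variants, fits the final
#' all-features model, and measures attribution recovery of the planted
#' toxicophores plus a permuted-label null.
#'
#' @param seed integer seed for this replicate
#' @param cache optional list(std, feats) reused across seeds
#' @param repeats nested-CV repeats (default 2, desk scale)
#' @return list of per-seed results (see source for fields)
#' @export
signal_recovery_run <- function(seed, cache = NULL, repeats = 2L) {
  spec <- generative_spec(seed = seed, salt_rate = 0, stereo_rate = 0,
                          conflict_rate = 0)
  fixture <- prepare_fixture(spec, std = cache$std, feats = cache$feats)
  panel <- fixture$panel
  cfg <- fixed_config()
  space1 <- singleton_space(cfg)

  models <- list()
  for (e in names(panel$proxies)) {
    d <- panel$proxies[[e]]
    chem <- fixture$chem_for(d$data$key14)
    models[[e]] <- train_endpoint_classifier(
      d, cbind(chem$structural, chem$descriptors), space = space1,
      seed = endpoint_seed(seed, e), n_configs = 1L, folds = 5L)
  }
  for (e in names(panel$pk)) {
    d <- panel$pk[[e]]
    chem <- fixture$chem_for(d$data$key14)
    models[[e]] <- train_cmax_regressor(
      d, cbind(chem$structural, chem$descriptors), space = space1,
      seed = endpoint_seed(seed, e), n_configs = 1L, folds = 5L)
  }

  gold <- panel$gold
  gold_idx <- match(gold$data$key14, fixture$std$key14)
  fp <- fixture$feats$blocks$morgan$matrix[gold_idx, , drop = FALSE]
  cl <- butina_cluster(fp, cutoff = 0.70)
  split <- cluster_split(cl, test_fraction = 0.2, keys = gold$data$key14)

  train_keys <- split$train_keys
  y_train <- gold$data$label[split$train_idx]
  chem_train <- fixture$chem_for(train_keys)
  stacked <- list(
    all = build_stacked(train_keys, chem_train, models, combo = "all"),
    structural = build_stacked(train_keys, chem_train, models,
                               combo = "structural")
  )
  cv <- lapply(stacked, function(s) {
    nested_cv(s$matrix, y_train, outer_folds = 5L, repeats = repeats,
              inner_folds = 4L, seed = seed, tune = FALSE, config = cfg)
  })
  auc_all <- mean(cv$all$auc_roc, na.rm = TRUE)
  auc_struct <- mean(cv$structural$auc_roc, na.rm = TRUE)

  final <- fit_final(stacked$all, y_train, cfg,
                     context = list(fitted_masks = fixture$masks,
                                    endpoint_models = models),
                     seed = seed, train_keys = train_keys)

  # attribution recovery on toxicophore-bearing held-out compounds
  tox_cols <- toxicophore_feature_columns(fixture)
  test_keys <- split$test_keys
  lib_idx <- match(test_keys, fixture$std$key14)
  tox_test <- attr(fixture$lib, "tox")[lib_idx, , drop = FALSE]
  carriers <- which(rowSums(tox_test) > 0)
  recovered <- logical(0)
  if (length(carriers)) {
    chem_test <- fixture$chem_for(test_keys)
    stacked_test <- build_stacked(test_keys, chem_test, models,
                                  combo = "all")
    for (i in utils::head(carriers, 20)) {
      att <- attribute_prediction(final, stacked_test, row = i)
      top3 <- names(utils::head(att$structural[att$structural > 0], 3))
      carried <- colnames(tox_test)[tox_test[i, ] == 1]
      hit <- any(unlist(tox_cols[carried]) %in% top3)
      recovered <- c(recovered, hit)
    }
  }

  # permuted-label null
  y_null <- with_seed(seed + 909L, sample(y_train))
  cv_null <- nested_cv(stacked$all$matrix, y_null, outer_folds = 5L,
                       repeats = 1L, inner_folds = 4L, seed = seed,
                       tune = FALSE, config = cfg)

  # Cmax coefficient-sign recovery on compounds outside the PK training set
  pk_model <- models$cmax_unbound
  held <- setdiff(fixture$std$key14, pk_model$training_keys)
  chem_held <- fixture$chem_for(held)
  pred <- predict(pk_model$model,
                  cbind(chem_held$structural, chem_held$descriptors))
  pc <- fixture$feats$blocks$physchem15$matrix[
    match(held, fixture$std$key14), , drop = FALSE]
  fit <- stats::lm(pred ~ pc[, "MolLogP"] + I(pc[, "TPSA"] / 100))
  cmax_signs <- sign(stats::coef(fit)[2:3])

  list(seed = seed, auc_all = auc_all, auc_structural = auc_struct,
       null_ba = mean(cv_null$balanced_accuracy, na.rm = TRUE),
       attribution_recovered = recovered,
       attribution_rate = if (length(recovered)) mean(recovered) else NA,
       cmax_signs_ok = all(cmax_signs == c(sign(spec$cmax_rule$logp),
                                           sign(spec$cmax_rule$tpsa_per100))),
       split = split, final = final, models = models, fixture = fixture)
}

#' Multi-seed signal-recovery study
#'
#' @param seeds integer vector of replicate seeds
#' @param repeats nested-CV repeats per seed
#' @param keep_fits keep the per-seed model objects (default FALSE)
#' @return list(results = per-seed summaries data.frame, runs = optional
#'   full run objects, cache = shared standardization cache)
#' @export
signal_recovery_study <- function(seeds, repeats = 2L, keep_fits = FALSE) {
  spec0 <- generative_spec(seed = seeds[1], salt_rate = 0, stereo_rate = 0,
                           conflict_rate = 0)
  lib0 <- generate_library(spec0)
  std0 <- standardize_compounds(lib0$smiles)
  feats0 <- featurize_compounds(std0$smiles_ph7)
  cache <- list(std = std0, feats = feats0)
  runs <- lapply(seeds, signal_recovery_run, cache = cache,
                 repeats = repeats)
  results <- do.call(rbind, lapply(runs, function(r) {
    data.frame(seed = r$seed, auc_all = r$auc_all,
               auc_structural = r$auc_structural, null_ba = r$null_ba,
               attribution_rate = r$attribution_rate,
               cmax_signs_ok = r$cmax_signs_ok)
  }))
  list(results = results, runs = if (keep_fits) runs, cache = cache)
}
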