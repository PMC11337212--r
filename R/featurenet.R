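# The level-2 "FeatureNet" stack: proxy-endpoint and Cmax predictions as
# features alongside masked chemical blocks, repeated nested
# cross-validation over the five feature-combination variants, final-model
# fitting with an out-of-fold Youden threshold, end-to-end prediction from
# raw SMILES, and per-compound tree-path attribution.

COMBOS <- c("structural", "descriptors", "chem-all", "proxy", "all")

#' Build the stacked feature matrix for a compound set
#'
#' Proxy columns are the nine classifiers' predicted probabilities and the
#' PK columns the two Cmax regressors' predictions, all computed from the
#' compounds' chemical features; chemical columns are the masked structural
#' and descriptor blocks. A leak guard errors if any input compound's key14
#' appears in any endpoint model's training set.
#'
#' @param keys key14 vector of the compounds (leak guard input)
#' @param chem list from [apply_feature_masks()] for these compounds
#' @param endpoint_models named list of fitted EndpointModels (classifiers
#'   and regressors); their feature layout must be
#'   cbind(chem$structural, chem$descriptors)
#' @param combo one of "structural", "descriptors", "chem-all", "proxy",
#'   "all"
#' @param check_leak set FALSE only when scoring compounds deliberately
#'   inside an endpoint's training set (e.g. resubmission diagnostics)
#' @return FeatureBlock "stacked" with a per-column \code{provenance}
#'   attribute naming each column's source block
#' @export
build_stacked <- function(keys, chem, endpoint_models,
                          combo = c("all", "structural", "descriptors",
                                    "chem-all", "proxy"),
                          check_leak = TRUE) {
  combo <- match.arg(combo)
  chem_all <- cbind(chem$structural, chem$descriptors)
  need_proxy <- combo %in% c("proxy", "all")
  if (need_proxy) {
    if (check_leak) {
      # PK/Cmax regressors are exempt: overlap with gold is only removed
      # for the nine binary proxy labels, so the guard covers classifiers
      for (em in endpoint_models) {
        if (em$type != "classification") next
        hit <- keys %in% em$training_keys
        if (any(hit)) {
          stop("leak guard: compound ", keys[which(hit)[1]],
               " is in the training set of endpoint model '", em$endpoint,
               "'")
        }
      }
    }
    pred_cols <- lapply(endpoint_models, function(em) {
      if (em$type == "classification") {
        predict_endpoint(em, chem_all)$probs
      } else {
        predict_endpoint(em, chem_all)$pred
      }
    })
    proxy <- do.call(cbind, pred_cols)
    colnames(proxy) <- paste0("pred_", names(endpoint_models))
    if (nrow(chem_all) == 0) { # keep header on empty input
      proxy <- matrix(numeric(0), 0, length(endpoint_models),
                      dimnames = list(NULL,
                                      paste0("pred_",
                                             names(endpoint_models))))
    }
  }
  parts <- switch(combo,
    "structural" = list(structural = chem$structural),
    "descriptors" = list(descriptors = chem$descriptors),
    "chem-all" = list(structural = chem$structural,
                      descriptors = chem$descriptors),
    "proxy" = list(proxy = proxy),
    "all" = list(structural = chem$structural,
                 descriptors = chem$descriptors, proxy = proxy)
  )
  mat <- do.call(cbind, parts)
  colnames(mat) <- unlist(lapply(parts, colnames), use.names = FALSE)
  provenance <- rep(names(parts), vapply(parts, ncol, 1L))
  block <- feature_block("stacked", mat)
  attr(block, "provenance") <- provenance
  attr(block, "combo") <- combo
  block
}

#' Repeated nested cross-validation for a level-2 DILI model
#'
#' Within each repeat the training set is split into \code{outer_folds}
#' stratified folds. For each outer fold the remaining folds are tuned by
#' successive-halving random search with \code{inner_folds}-fold CV, the
#' Youden threshold is derived from inner out-of-fold probabilities on the
#' tuning data only, and the refit model is evaluated on the outer
#' validation fold. All folds x repeats evaluations are returned.
#'
#' @param X stacked feature matrix for the gold training compounds
#' @param y binary DILI labels
#' @param space hyperparameter space
#' @param outer_folds,repeats,inner_folds protocol configuration
#'   (defaults 5, 10, 4)
#' @param n_configs halving-search budget
#' @param seed master seed
#' @param tune set FALSE to skip the inner search and use \code{config}
#' @param config fixed configuration when tune = FALSE
#' @return NestedCVReport: data.frame with one row per fold x repeat
#'   (metrics, threshold, repeat, fold) plus a \code{configs} attribute of
#'   selected hyperparameters per repeat
#' @export
nested_cv <- function(X, y, space = default_search_space(),
                      outer_folds = 5L, repeats = 10L, inner_folds = 4L,
                      n_configs = 8L, seed = 1L, tune = TRUE,
                      config = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (min(table(factor(y, levels = c(0, 1)))) < outer_folds) {
    stop("stratification impossible: a class has fewer members than folds")
  }
  rows <- list()
  configs <- list()
  for (r in seq_len(repeats)) {
    rseed <- as.integer((seed + 7919 * r) %% 2147483647)
    fids <- stratified_folds(y, outer_folds, rseed)
    fold_cfgs <- list()
    for (f in sort(unique(fids))) {
      tr <- fids != f
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      cfg <- if (tune) {
        halving_search(Xtr, ytr, space, "classification", n_configs,
                       inner_folds, rseed + f)$best_config
      } else {
        config
      }
      oof <- oof_predictions(Xtr, ytr, cfg, "classification", inner_folds,
                             rseed + f)
      thr <- as.numeric(youden_threshold(oof, ytr))
      model <- fit_config(Xtr, ytr, cfg, "classification", rseed + f)
      probs <- predict(model, X[!tr, , drop = FALSE])
      rep_ <- binary_report(y[!tr], as.integer(probs >= thr), probs)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, threshold = thr,
        auc_roc = rep_$auc_roc, balanced_accuracy = rep_$balanced_accuracy,
        mcc = rep_$mcc, f1 = rep_$f1, sensitivity = rep_$sensitivity,
        specificity = rep_$specificity, ppv = rep_$ppv,
        lr_plus = rep_$lr_plus, average_precision = rep_$average_precision
      )
      fold_cfgs[[f]] <- cfg
    }
    configs[[r]] <- fold_cfgs
  }
  out <- do.call(rbind, rows)
  attr(out, "configs") <- configs
  class(out) <- c("NestedCVReport", class(out))
  out
}

#' Summarize a nested-CV report
#' @param object NestedCVReport
#' @param ... unused
#' @return list(mean = overall means, per_repeat = per-repeat means)
#' @export
summary.NestedCVReport <- function(object, ...) {
  metrics <- c("auc_roc", "balanced_accuracy", "mcc", "f1", "sensitivity",
               "specificity", "ppv", "lr_plus", "average_precision")
  df <- as.data.frame(object)
  list(
    mean = colMeans(df[metrics], na.rm = TRUE),
    per_repeat = stats::aggregate(df[metrics], by = list(repeat_ =
                                                           df$repeat_),
                                  FUN = mean, na.rm = TRUE)
  )
}

#' Select the best repeat's modal configuration from a nested-CV report
#'
#' The repeat with the highest mean outer-fold AUC is chosen; among that
#' repeat's per-fold selections the most frequent configuration wins (ties
#' resolve to the earliest fold).
#'
#' @param report NestedCVReport
#' @return hyperparameter configuration list
#' @export
best_nested_config <- function(report) {
  s <- summary(report)$per_repeat
  best_rep <- s$repeat_[which.max(s$auc_roc)]
  cfgs <- attr(report, "configs")[[best_rep]]
  keys <- vapply(cfgs, function(cf) paste(deparse(cf), collapse = ""), "")
  cfgs[[which.max(ave(seq_along(keys), keys, FUN = length))]]
}

#' Fit the final DILI model
#'
#' Refits the chosen configuration on all training rows and derives the
#' decision threshold from fresh 4-fold out-of-fold probabilities on the
#' full training set (never from test data). The out-of-fold probabilities
#' are stored so the threshold is reproducible from persisted state.
#'
#' @param stacked stacked FeatureBlock for the gold training set
#' @param y binary DILI labels
#' @param config hyperparameter configuration (e.g. from
#'   [best_nested_config()])
#' @param context list with the state needed to predict from raw SMILES:
#'   fitted_masks ([fit_feature_masks()] result) and endpoint_models
#' @param seed integer seed
#' @param train_keys key14 of the training compounds
#' @return object of class FinalModel
#' @export
fit_final <- function(stacked, y, config, context = NULL, seed = 1L,
                      train_keys = NULL) {
  X <- stacked$matrix
  oof <- oof_predictions(X, y, config, "classification", 4L, seed)
  thr <- as.numeric(youden_threshold(oof, y))
  model <- fit_config(X, y, config, "classification", seed)
  model$feature_names <- colnames(X)
  structure(
    list(model = model, threshold = thr, config = config,
         combo = attr(stacked, "combo"),
         provenance = attr(stacked, "provenance"),
         feature_names = colnames(X), oof_probs = oof,
         training_digest = key_digest(if (is.null(train_keys)) character()
                                      else train_keys),
         train_keys = train_keys, context = context, seed = seed),
    class = "FinalModel"
  )
}

#' @export
print.FinalModel <- function(x, ...) {
  cat(sprintf("<FinalModel combo='%s'> %d features, threshold %.3f\n",
              x$combo, length(x$feature_names), x$threshold))
  invisible(x)
}

#' Predict DILI from raw SMILES
#'
#' Runs the full pipeline internally: standardization and pH-7 protonation,
#' featurization, the fitted selection masks, endpoint-model stacking, and
#' the final classifier with its calibrated threshold. Rejected compounds
#' are reported with their reasons rather than dropped silently.
#'
#' @param final FinalModel fitted with a \code{context} (fitted_masks and
#'   endpoint_models)
#' @param smiles character vector of raw SMILES
#' @param check_leak passed to [build_stacked()]; default FALSE because
#'   prediction-time compounds may legitimately revisit training chemistry
#' @return list(results = data.frame(smiles_in, smiles_std, key14,
#'   probability, call, rejected, reject_reason), stacked = FeatureBlock
#'   for the accepted compounds)
#' @export
predict_dili <- function(final, smiles, check_leak = FALSE) {
  stopifnot(inherits(final, "FinalModel"))
  if (is.null(final$context)) {
    stop("FinalModel was fitted without context; cannot predict from SMILES")
  }
  std <- standardize_compounds(smiles)
  ok <- !std$rejected
  results <- data.frame(
    smiles_in = std$smiles_in, smiles_std = std$smiles_std,
    key14 = std$key14, probability = NA_real_, call = NA_integer_,
    rejected = std$rejected, reject_reason = std$reject_reason,
    stringsAsFactors = FALSE
  )
  if (!any(ok)) {
    return(structure(list(results = results, stacked = NULL),
                     class = "dili_predictions", empty = TRUE))
  }
  feats <- featurize_compounds(std$smiles_ph7[ok])
  chem <- apply_feature_masks(feats$blocks, final$context$fitted_masks)
  stacked <- build_stacked(std$key14[ok], chem,
                           final$context$endpoint_models,
                           combo = final$combo, check_leak = check_leak)
  probs <- predict(final$model, stacked$matrix)
  results$probability[ok] <- probs
  results$call[ok] <- as.integer(probs >= final$threshold)
  structure(list(results = results, stacked = stacked),
            class = "dili_predictions", empty = FALSE)
}

#' Per-compound feature attribution with substructure highlight
#'
#' Tree-path attribution of the final model's predicted probability:
#' additive per-feature contributions (summing to prediction minus base
#' value), the top-3 positively and negatively contributing proxy/PK
#' columns, the ranked structural contributions, and the MACCS key with the
#' largest positive contribution mapped back to matching atoms via its
#' structural pattern.
#'
#' @param final FinalModel
#' @param stacked stacked FeatureBlock (e.g. from [predict_dili()])
#' @param row which compound (row index) to attribute
#' @param smiles optional standardized SMILES of that compound, needed for
#'   the atom-level MACCS highlight
#' @return list(prediction, base, contributions, top_pos_proxy,
#'   top_neg_proxy, structural, highlight)
#' @export
attribute_prediction <- function(final, stacked, row = 1L, smiles = NULL) {
  stopifnot(inherits(final, "FinalModel"))
  X <- stacked$matrix[row, , drop = FALSE]
  att <- rf_attribute(final$model, X)
  contrib <- att$contributions[1, ]
  prov <- final$provenance
  top_k <- function(v, k, decreasing) {
    v <- sort(v[v != 0], decreasing = decreasing)
    utils::head(v, k)
  }
  proxy_contrib <- contrib[prov == "proxy"]
  structural_contrib <- contrib[prov == "structural"]
  highlight <- NULL
  note <- NULL
  maccs_idx <- grep("^maccs_", names(structural_contrib))
  pos_maccs <- structural_contrib[maccs_idx]
  pos_maccs <- pos_maccs[pos_maccs > 0 & X[1, names(pos_maccs)] == 1]
  if (length(pos_maccs) && !is.null(smiles)) {
    key <- as.integer(sub("maccs_", "", names(which.max(pos_maccs)))) + 1L
    res <- backend_call("maccs_highlight", smiles, list(keys = list(key)))
    h <- res$highlights[[1]][[1]]
    highlight <- list(maccs_key = key, smarts = h$smarts,
                      atoms = unlist(h$atoms))
  } else if (!length(pos_maccs)) {
    note <- "no set MACCS key among selected keys contributes positively"
  }
  list(
    prediction = att$base + sum(contrib), base = att$base,
    contributions = contrib,
    top_pos_proxy = top_k(proxy_contrib[proxy_contrib > 0], 3, TRUE),
    top_neg_proxy = top_k(proxy_contrib[proxy_contrib < 0], 3, FALSE),
    structural = sort(structural_contrib[structural_contrib != 0],
                      decreasing = TRUE),
    highlight = highlight, note = note
  )
}
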