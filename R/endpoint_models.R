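# Level-1 models: one random-forest classifier per binary proxy endpoint
# and one regressor per Cmax target, tuned by successive-halving random
# search with stratified cross-validation, refit on all rows, and
# calibrated with a Youden-J decision threshold.

#' Default hyperparameter search space
#'
#' The reference grid is unpublished; this stand-in grid is recorded in
#' every model's cv_config so results tied to it are identifiable.
#'
#' @return named list of candidate values per hyperparameter
#' @export
default_search_space <- function() {
  list(
    n_trees = c(100L, 300L, 500L, 1000L),
    max_depth = c(0L, 8L, 16L, 32L), # 0 = unlimited
    min_leaf = c(1L, 3L, 5L, 10L),
    mtry_frac = list("sqrt", 0.3, 0.5),
    class_weight = c("none", "balanced")
  )
}

#' A reduced search space for tests and desk-scale simulations
#' @return named list
#' @export
small_search_space <- function() {
  list(
    n_trees = c(60L, 120L),
    max_depth = c(0L, 12L),
    min_leaf = c(1L, 3L),
    mtry_frac = list("sqrt", 0.3),
    class_weight = c("none", "balanced")
  )
}

validate_search_space <- function(space) {
  if (any(vapply(space, length, 1L) == 0)) stop("empty hyperparameter range")
  space
}

sample_config <- function(space) {
  lapply(space, function(v) v[[sample.int(length(v), 1L)]])
}

fit_config <- function(X, y, config, type, seed) {
  rf_fit(X, y, type = type,
         n_trees = config$n_trees, max_depth = config$max_depth,
         min_leaf = config$min_leaf, mtry_frac = config$mtry_frac,
         class_weight = if (type == "classification") config$class_weight
                        else "none",
         seed = seed)
}

#' Stratified fold assignment
#'
#' Binary labels are stratified by class; numeric targets by quantile bins.
#'
#' @param y labels
#' @param k number of folds
#' @param seed RNG seed (local, does not disturb the session RNG)
#' @return integer fold id per observation
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  n <- length(y)
  strata <- if (all(y %in% c(0, 1))) {
    as.integer(y)
  } else {
    bins <- unique(stats::quantile(y, probs = seq(0, 1, length.out =
                                                    min(k, 4) + 1)))
    as.integer(cut(y, breaks = bins, include.lowest = TRUE))
  }
  folds <- integer(n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(seed)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  folds
}

r_squared <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

cv_score <- function(X, y, config, type, folds, seed) {
  scores <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    model <- fit_config(X[tr, , drop = FALSE], y[tr], config, type, seed)
    pred <- predict(model, X[!tr, , drop = FALSE])
    if (type == "classification") {
      auc_roc(pred, y[!tr])
    } else {
      r_squared(y[!tr], pred)
    }
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Successive-halving random hyperparameter search
#'
#' Samples \code{n_configs} configurations, scores them by stratified
#' k-fold cross-validation (AUC-ROC for classification, R-squared for
#' regression) on a stratified subsample that starts at 1/8 of the rows and
#' doubles per rung while the candidate set is halved; survivors are scored
#' on the full data in the final rung.
#'
#' @param X feature matrix
#' @param y labels
#' @param space search space (see [default_search_space()])
#' @param type "classification" or "regression"
#' @param n_configs initial number of sampled configurations
#' @param folds number of CV folds (default 5)
#' @param seed integer seed controlling sampling, subsampling and fitting
#' @return list(best_config, history)
#' @export
halving_search <- function(X, y, space, type, n_configs = 8L, folds = 5L,
                           seed = 1L) {
  validate_search_space(space)
  n <- nrow(X)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(seed)
  configs <- replicate(n_configs, sample_config(space), simplify = FALSE)
  budget <- max(ceiling(n / 8), 8 * folds)
  history <- list()
  while (length(configs) > 1L && budget < n) {
    sub <- sort(sample.int(n, min(budget, n)))
    fids <- stratified_folds(y[sub], folds, seed + length(configs))
    scores <- vapply(configs, function(cfg) {
      cv_score(X[sub, , drop = FALSE], y[sub], cfg, type, fids, seed)
    }, numeric(1))
    history[[length(history) + 1L]] <-
      list(budget = length(sub), scores = scores)
    keep <- order(-scores)[seq_len(ceiling(length(configs) / 2))]
    configs <- configs[keep]
    budget <- budget * 2L
  }
  fids <- stratified_folds(y, folds, seed)
  scores <- vapply(configs, function(cfg) {
    cv_score(X, y, cfg, type, fids, seed)
  }, numeric(1))
  history[[length(history) + 1L]] <- list(budget = n, scores = scores)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  # degenerate targets (e.g. constant labels) score NA everywhere; fall
  # back to the first sampled configuration
  best <- if (all(is.na(scores))) 1L else which.max(scores)
  list(best_config = configs[[best]], best_score = suppressWarnings(
    max(scores, na.rm = TRUE)), history = history)
}

#' Youden-J optimal decision threshold
#'
#' Scans every distinct operating point: candidate thresholds are the
#' midpoints between consecutive sorted unique probabilities plus 0 and 1,
#' calls are \code{prob >= threshold}, and the threshold maximizing
#' J = sensitivity + specificity - 1 is returned (ties resolve to the
#' smallest threshold). Degenerate inputs (all probabilities equal) return
#' 0.5 with a warning; if no threshold achieves J > 0 the result carries a
#' \code{no_benefit} flag attribute.
#'
#' @param probs probabilities in [0,1]
#' @param labels binary labels with both classes present
#' @return threshold in [0,1]; attributes: j (achieved J), possibly flag
#' @export
youden_threshold <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) {
    stop("youden_threshold() requires both classes")
  }
  u <- sort(unique(probs))
  if (length(u) == 1L) {
    warning("all probabilities are equal; returning threshold 0.5 (J = 0)")
    return(structure(0.5, j = 0, flag = "degenerate"))
  }
  cand <- sort(unique(c(0, (u[-1] + u[-length(u)]) / 2, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  j <- vapply(cand, function(t) {
    calls <- probs >= t
    sum(calls & labels == 1) / n_pos + sum(!calls & labels == 0) / n_neg - 1
  }, numeric(1))
  best <- which.max(j) # which.max returns the first (smallest) maximizer
  out <- structure(cand[best], j = j[best])
  if (j[best] <= 0) attr(out, "flag") <- "no_benefit"
  out
}

#' Derive a per-endpoint seed from the master seed
#'
#' Fans the master seed out via a fixed hash of the endpoint name, keeping
#' the result inside the 31-bit integer range.
#'
#' @param master integer master seed
#' @param endpoint endpoint name
#' @return integer seed
#' @export
endpoint_seed <- function(master, endpoint) {
  h <- strtoi(substr(fnv1a_hash_cpp(endpoint), 1, 7), base = 16L)
  as.integer((as.numeric(master) + h) %% 2147483647)
}

new_endpoint_model <- function(endpoint, model, type, search, cv_config,
                               keys, seed) {
  structure(
    list(endpoint = endpoint, model = model, type = type,
         threshold = NULL, best_config = search$best_config,
         cv_score = search$best_score, cv_config = cv_config,
         training_keys = keys, training_digest = key_digest(keys),
         seed = seed),
    class = "EndpointModel"
  )
}

#' @export
print.EndpointModel <- function(x, ...) {
  cat(sprintf("<EndpointModel '%s'> %s, inner-CV score %.3f%s\n",
              x$endpoint, x$type, x$cv_score,
              if (!is.null(x$threshold)) {
                sprintf(", threshold %.3f", x$threshold)
              } else ""))
  invisible(x)
}

#' Train a proxy-endpoint classifier
#'
#' Successive-halving random search scored by inner-CV AUC-ROC; the best
#' configuration is refit on the entire dataset. The decision threshold is
#' not set here; see [calibrate_threshold()].
#'
#' @param dataset binary EndpointDataset
#' @param features feature matrix row-aligned to dataset$data
#' @param space search space
#' @param seed integer seed
#' @param n_configs,folds search budget
#' @return EndpointModel (threshold unset)
#' @export
train_endpoint_classifier <- function(dataset, features,
                                      space = default_search_space(),
                                      seed = 1L, n_configs = 8L,
                                      folds = 5L) {
  stopifnot(inherits(dataset, "EndpointDataset"), dataset$kind == "binary")
  X <- as.matrix(features)
  y <- dataset$data$label
  if (nrow(X) != length(y)) stop("features not row-aligned to dataset")
  if (min(table(factor(y, levels = c(0, 1)))) < folds) {
    stop("a class has fewer members than folds")
  }
  search <- halving_search(X, y, space, "classification", n_configs, folds,
                           seed)
  model <- fit_config(X, y, search$best_config, "classification", seed)
  model$feature_names <- colnames(X)
  new_endpoint_model(dataset$name, model, "classification", search,
                     list(folds = folds, n_configs = n_configs,
                          space = space, seed = seed),
                     dataset$data$key14, seed)
}

#' Train a Cmax regressor
#'
#' Same search protocol as the classifiers but scored by R-squared;
#' predictions are continuous pMolar values.
#'
#' @inheritParams train_endpoint_classifier
#' @param dataset numeric EndpointDataset (pMolar Cmax values)
#' @return EndpointModel
#' @export
train_cmax_regressor <- function(dataset, features,
                                 space = default_search_space(),
                                 seed = 1L, n_configs = 8L, folds = 5L) {
  stopifnot(inherits(dataset, "EndpointDataset"), dataset$kind == "numeric")
  X <- as.matrix(features)
  y <- dataset$data$label
  if (nrow(X) != length(y)) stop("features not row-aligned to dataset")
  if (length(y) < 20) stop("need at least 20 training rows")
  if (stats::var(y) == 0) {
    warning("constant labels; regressor will predict a constant and ",
            "R-squared is undefined")
  }
  search <- halving_search(X, y, space, "regression", n_configs, folds, seed)
  model <- fit_config(X, y, search$best_config, "regression", seed)
  model$feature_names <- colnames(X)
  new_endpoint_model(dataset$name, model, "regression", search,
                     list(folds = folds, n_configs = n_configs,
                          space = space, seed = seed),
                     dataset$data$key14, seed)
}

#' Out-of-fold predictions with a fixed configuration
#'
#' @param X feature matrix
#' @param y labels
#' @param config hyperparameter configuration
#' @param type model type
#' @param folds number of folds
#' @param seed seed
#' @return numeric vector of out-of-fold predictions, one per row
#' @export
oof_predictions <- function(X, y, config, type, folds = 5L, seed = 1L) {
  fids <- stratified_folds(y, folds, seed)
  out <- numeric(length(y))
  for (f in sort(unique(fids))) {
    tr <- fids != f
    model <- fit_config(X[tr, , drop = FALSE], y[tr], config, type, seed)
    out[!tr] <- predict(model, X[!tr, , drop = FALSE])
  }
  out
}

#' Calibrate an endpoint classifier's decision threshold
#'
#' Computes out-of-fold probabilities on the training data with the model's
#' tuned configuration and sets the Youden-J threshold derived from them.
#'
#' @param em EndpointModel (classifier)
#' @param features training feature matrix (row-aligned as at training)
#' @param labels training labels
#' @param folds folds for the out-of-fold probabilities
#' @return EndpointModel with threshold set
#' @export
calibrate_threshold <- function(em, features, labels, folds = 5L) {
  stopifnot(inherits(em, "EndpointModel"), em$type == "classification")
  probs <- oof_predictions(as.matrix(features), labels, em$best_config,
                           "classification", folds, em$seed)
  em$threshold <- as.numeric(youden_threshold(probs, labels))
  em$oof_probs <- probs
  em
}

#' Predict with an endpoint model
#'
#' @param em fitted EndpointModel
#' @param features feature matrix with the training layout
#' @return for classifiers list(probs, calls) where calls use
#'   \code{prob >= threshold} (NULL calls when no threshold is set); for
#'   regressors list(pred)
#' @export
predict_endpoint <- function(em, features) {
  stopifnot(inherits(em, "EndpointModel"))
  pred <- predict(em$model, as.matrix(features))
  if (em$type == "classification") {
    calls <- if (!is.null(em$threshold)) {
      as.integer(pred >= em$threshold)
    }
    list(probs = pred, calls = calls)
  } else {
    list(pred = pred)
  }
}

#' Cross-endpoint predictivity matrix
#'
#' Model i predicts dataset j for every ordered pair of binary endpoints.
#' Off-diagonal cells use the best-case protocol: model i's threshold is
#' re-derived against dataset j's labels by Youden J before computing the
#' thresholded metrics. Diagonal cells report the model's own stratified
#' out-of-fold cross-validation on its training endpoint.
#'
#' @param models named list of EndpointModel classifiers
#' @param datasets named list of binary EndpointDatasets (same names)
#' @param features named list of feature matrices, one per dataset,
#'   row-aligned and in the models' training feature layout
#' @return list of three matrices: auc, f1, lr_plus
#' @export
cross_predict_matrix <- function(models, datasets, features) {
  nms <- names(models)
  stopifnot(!is.null(nms), identical(sort(nms), sort(names(datasets))))
  m <- length(nms)
  auc <- f1 <- lrp <- matrix(NA_real_, m, m, dimnames = list(nms, nms))
  for (i in nms) {
    for (j in nms) {
      yj <- datasets[[j]]$data$label
      if (i == j) {
        probs <- oof_predictions(as.matrix(features[[j]]), yj,
                                 models[[i]]$best_config, "classification",
                                 folds = 5L, seed = models[[i]]$seed)
      } else {
        probs <- predict(models[[i]]$model, as.matrix(features[[j]]))
      }
      thr <- as.numeric(youden_threshold(probs, yj))
      rep <- binary_report(yj, as.integer(probs >= thr), probs)
      auc[i, j] <- rep$auc_roc
      f1[i, j] <- rep$f1
      lrp[i, j] <- rep$lr_plus
    }
  }
  list(auc = auc, f1 = f1, lr_plus = lrp)
}
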