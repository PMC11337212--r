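#' Fit a random forest (classification or regression)
#'
#' Bootstrap-bagged CART trees with per-node feature subsampling, built on
#' the package's own C++ tree learner. Classification targets are 0/1 and
#' predictions are averaged leaf class fractions (vote fractions in [0,1]);
#' regression predictions are averaged leaf means.
#'
#' @param X numeric matrix (rows = compounds, columns = features)
#' @param y numeric vector; for classification must be in {0,1}
#' @param type "classification" or "regression"
#' @param n_trees number of trees
#' @param max_depth maximum tree depth; 0 means unlimited
#' @param min_leaf minimum samples per leaf
#' @param mtry_frac "sqrt" or a fraction of features tried per split
#' @param class_weight "none" or "balanced" (inverse class-frequency case
#'   weights; classification only)
#' @param seed integer seed; fitting is fully deterministic given the seed
#' @return object of class dili_forest
#' @export
rf_fit <- function(X, y, type = c("classification", "regression"),
                   n_trees = 300L, max_depth = 0L, min_leaf = 1L,
                   mtry_frac = "sqrt", class_weight = c("none", "balanced"),
                   seed = 1L) {
  type <- match.arg(type)
  class_weight <- match.arg(class_weight)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (any(!is.finite(X))) stop("X contains non-finite values")
  if (type == "classification" && !all(y %in% c(0, 1))) {
    stop("classification labels must be in {0,1}")
  }
  p <- ncol(X)
  mtry <- if (identical(mtry_frac, "sqrt")) {
    max(1L, as.integer(ceiling(sqrt(p))))
  } else {
    max(1L, as.integer(ceiling(as.numeric(mtry_frac) * p)))
  }
  w <- rep(1, length(y))
  if (type == "classification" && class_weight == "balanced") {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 > 0 && n0 > 0) {
      w <- ifelse(y == 1, length(y) / (2 * n1), length(y) / (2 * n0))
    }
  }
  trees <- forest_fit_cpp(X, as.numeric(y), as.integer(n_trees),
                          as.integer(max_depth), as.integer(min_leaf),
                          mtry, w, as.integer(seed))
  structure(
    list(trees = trees, type = type, feature_names = colnames(X),
         p = p, n_trees = as.integer(n_trees),
         params = list(max_depth = max_depth, min_leaf = min_leaf,
                       mtry_frac = mtry_frac, class_weight = class_weight),
         seed = as.integer(seed)),
    class = "dili_forest"
  )
}

check_rf_features <- function(model, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != model$p) {
    stop("feature width mismatch: model expects ", model$p, ", got ", ncol(X))
  }
  if (!is.null(model$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$feature_names)) {
    bad <- which(colnames(X) != model$feature_names)[1]
    stop("feature name mismatch at column ", bad, ": '", colnames(X)[bad],
         "' vs '", model$feature_names[bad], "'")
  }
  X
}

#' Predict with a fitted forest
#' @param object dili_forest model
#' @param X feature matrix with the training column layout
#' @param ... unused
#' @return numeric vector (probabilities for classification)
#' @export
predict.dili_forest <- function(object, X, ...) {
  X <- check_rf_features(object, X)
  if (nrow(X) == 0) return(numeric(0))
  forest_predict_cpp(object$trees, X)
}

#' Per-feature path attribution for forest predictions
#'
#' Saabas-style tree-path attribution: walking each tree from root to leaf,
#' each split's change in node value is credited to the split feature.
#' Contributions are additive: base + rowSums(contributions) equals the
#' forest prediction exactly (to floating-point tolerance).
#'
#' @param model dili_forest
#' @param X feature matrix
#' @return list(base = scalar, contributions = n x p matrix)
#' @export
rf_attribute <- function(model, X) {
  X <- check_rf_features(model, X)
  out <- forest_attribute_cpp(model$trees, X)
  colnames(out$contributions) <- model$feature_names
  out
}

#' Digest of a set of strings (order-invariant FNV-1a hash)
#' @param keys character vector (e.g. training key14 set)
#' @return 16-hex-character digest
#' @export
key_digest <- function(keys) {
  fnv1a_hash_cpp(as.character(keys))
}
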