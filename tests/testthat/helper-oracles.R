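# Independent oracles shared across test files.

# naive O(n) confusion-count oracle, written from the definitions
naive_report <- function(labels, calls) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && calls[i] == 1) tp <- tp + 1
    if (labels[i] == 0 && calls[i] == 1) fp <- fp + 1
    if (labels[i] == 0 && calls[i] == 0) tn <- tn + 1
    if (labels[i] == 1 && calls[i] == 0) fn <- fn + 1
  }
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn, sens = sens, spec = spec,
       ba = (sens + spec) / 2, ppv = tp / (tp + fp),
       mcc = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
       f1 = 2 * tp / (2 * tp + fp + fn),
       lr = if (spec < 1) sens / (1 - spec) else Inf)
}

# exhaustive-scan oracle for the Youden threshold: evaluate J at every
# reachable operating point (top-i ranked observations called positive)
youden_oracle_j <- function(probs, labels) {
  ord <- order(-probs)
  best <- -Inf
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  for (i in 0:length(probs)) {
    calls <- integer(length(probs))
    if (i > 0) calls[ord[seq_len(i)]] <- 1L
    # ties in probs make some prefixes unreachable by a threshold rule
    if (i > 0 && i < length(probs) &&
        probs[ord[i]] == probs[ord[i + 1]]) next
    # with prob >= threshold calls, all-negative is unreachable when the
    # maximum probability is 1
    if (i == 0 && max(probs) >= 1) next
    j <- sum(calls & labels == 1) / n_pos +
      sum(!calls & labels == 0) / n_neg - 1
    best <- max(best, j)
  }
  best
}

# a small trained world shared by the featurenet and acceptance tests:
# endpoint models on the default fixture, fixed configuration (no search)
featurenet_world <- function() {
  cached("featurenet_world", function() {
    fx <- default_fixture()
    cfg <- list(n_trees = 60L, max_depth = 0L, min_leaf = 3L,
                mtry_frac = "sqrt", class_weight = "balanced")
    space1 <- lapply(cfg, function(v) list(v))
    models <- list()
    for (e in names(fx$panel$proxies)) {
      d <- fx$panel$proxies[[e]]
      chem <- fx$chem_for(d$data$key14)
      models[[e]] <- train_endpoint_classifier(
        d, cbind(chem$structural, chem$descriptors), space = space1,
        seed = endpoint_seed(42, e), n_configs = 1)
    }
    for (e in names(fx$panel$pk)) {
      d <- fx$panel$pk[[e]]
      chem <- fx$chem_for(d$data$key14)
      models[[e]] <- train_cmax_regressor(
        d, cbind(chem$structural, chem$descriptors), space = space1,
        seed = endpoint_seed(42, e), n_configs = 1)
    }
    gold <- fx$panel$gold
    chem_gold <- fx$chem_for(gold$data$key14)
    list(fx = fx, models = models, cfg = cfg, gold = gold,
         chem_gold = chem_gold)
  })
}
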