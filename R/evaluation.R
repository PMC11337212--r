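# Full metric panel used across the package. Undefined metrics are NA (or
# Inf for a zero-denominator LR+) with an explicit flag, never a silent 0;
# reports serialize NA/Inf-flagged values as null.

#' AUC-ROC from a probability ranking
#'
#' Computed as the normalized Mann-Whitney U statistic with midrank tie
#' handling.
#'
#' @param probs numeric scores
#' @param labels binary labels
#' @return AUC in [0,1], or NA if only one class is present
#' @export
auc_roc <- function(probs, labels) {
  stopifnot(length(probs) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Computed over the distinct score thresholds:
#' \eqn{AP = \sum_k (R_k - R_{k-1}) P_k}.
#'
#' @inheritParams auc_roc
#' @return AP in [0,1], or NA if no positives
#' @export
average_precision <- function(probs, labels) {
  stopifnot(length(probs) == length(labels))
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) return(NA_real_)
  thr <- sort(unique(probs), decreasing = TRUE)
  ap <- 0; r_prev <- 0
  for (t in thr) {
    call <- probs >= t
    tp <- sum(call & labels == 1)
    prec <- tp / sum(call)
    rec <- tp / n1
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

#' Full binary evaluation report
#'
#' Computes sensitivity, specificity, balanced accuracy, MCC, F1, PPV, LR+,
#' average precision and AUC-ROC from labels, thresholded calls and (for the
#' ranking metrics) predicted probabilities.
#'
#' @param labels binary truth vector
#' @param calls binary predicted calls
#' @param probs optional probabilities for AUC/AP (NULL to skip)
#' @return object of class EvaluationReport: a list of metrics, confusion
#'   counts (tp, fp, tn, fn, n_pos, n_neg) and a character vector of flags
#'   naming any undefined quantities
#' @export
binary_report <- function(labels, calls, probs = NULL) {
  stopifnot(length(labels) == length(calls))
  if (!all(labels %in% c(0, 1)) || !all(calls %in% c(0, 1))) {
    stop("labels and calls must be binary")
  }
  tp <- sum(labels == 1 & calls == 1)
  fn <- sum(labels == 1 & calls == 0)
  tn <- sum(labels == 0 & calls == 0)
  fp <- sum(labels == 0 & calls == 1)
  n_pos <- tp + fn; n_neg <- tn + fp
  flags <- character()
  flag <- function(what) flags <<- c(flags, what)

  sens <- if (n_pos > 0) tp / n_pos else { flag("sensitivity"); NA_real_ }
  spec <- if (n_neg > 0) tn / n_neg else { flag("specificity"); NA_real_ }
  ba <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  ppv <- if (tp + fp > 0) tp / (tp + fp) else { flag("ppv"); NA_real_ }
  f1 <- if (2 * tp + fp + fn > 0) {
    2 * tp / (2 * tp + fp + fn)
  } else { flag("f1"); NA_real_ }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) {
    (tp * tn - fp * fn) / sqrt(denom)
  } else { flag("mcc"); NA_real_ }
  lr_plus <- if (is.na(sens) || is.na(spec)) {
    flag("lr_plus"); NA_real_
  } else if (spec < 1) {
    sens / (1 - spec)
  } else { flag("lr_plus_infinite"); Inf }

  auc <- ap <- NA_real_
  if (!is.null(probs)) {
    auc <- auc_roc(probs, labels)
    ap <- average_precision(probs, labels)
    if (is.na(auc)) flag("auc_roc")
    if (is.na(ap)) flag("average_precision")
  }
  structure(
    list(sensitivity = sens, specificity = spec, balanced_accuracy = ba,
         mcc = mcc, f1 = f1, ppv = ppv, lr_plus = lr_plus,
         average_precision = ap, auc_roc = auc,
         tp = tp, fp = fp, tn = tn, fn = fn, n_pos = n_pos, n_neg = n_neg,
         flags = unique(flags)),
    class = "EvaluationReport"
  )
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf(
    "<EvaluationReport> n=%d (%d+/%d-)  BA=%.3f MCC=%.3f F1=%.3f\n",
    x$n_pos + x$n_neg, x$n_pos, x$n_neg, x$balanced_accuracy, x$mcc, x$f1))
  cat(sprintf("  sens=%.3f spec=%.3f PPV=%.3f LR+=%.3g AUC=%.3f AP=%.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$lr_plus, x$auc_roc,
              x$average_precision))
  if (length(x$flags)) cat("  flagged:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an EvaluationReport to a JSON-ready list
#'
#' Flagged undefined / infinite metrics become NULL so they serialize as
#' JSON null rather than a misleading 0.
#' @param report EvaluationReport
#' @return plain list
#' @export
report_as_list <- function(report) {
  metrics <- c("sensitivity", "specificity", "balanced_accuracy", "mcc",
               "f1", "ppv", "lr_plus", "average_precision", "auc_roc")
  out <- lapply(report[metrics], function(v) {
    if (is.null(v) || is.na(v) || is.infinite(v)) NULL else v
  })
  c(out, report[c("tp", "fp", "tn", "fn", "n_pos", "n_neg")],
    list(flags = report$flags))
}

#' Detection metrics treating the top-k ranked compounds as positive calls
#'
#' Ranks compounds by decreasing probability (ties broken by stable input
#' order), calls the top k positive, and reports TP, FP, LR+ and PPV at
#' that operating point.
#'
#' @param probs probabilities
#' @param labels binary truth
#' @param k number of top-ranked compounds to call positive (1..n)
#' @return list(tp, fp, lr_plus, ppv, k, report = full EvaluationReport)
#' @export
lr_plus_at_topk <- function(probs, labels, k) {
  n <- length(probs)
  stopifnot(length(labels) == n)
  if (k <= 0 || k > n) stop("k must be in 1..n")
  ord <- order(-probs, seq_len(n))
  calls <- integer(n)
  calls[ord[seq_len(k)]] <- 1L
  rep <- binary_report(labels, calls, probs)
  list(tp = rep$tp, fp = rep$fp, lr_plus = rep$lr_plus, ppv = rep$ppv,
       k = k, report = rep)
}

#' Full top-k detection curve over k = 1..n
#' @inheritParams lr_plus_at_topk
#' @return data.frame with columns k, tp, fp, ppv, lr_plus
#' @export
topk_curve <- function(probs, labels) {
  n <- length(probs)
  ord <- order(-probs, seq_len(n))
  lab <- labels[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  sens <- tp / n_pos
  fpr <- fp / n_neg
  data.frame(k = seq_len(n), tp = tp, fp = fp, ppv = tp / seq_len(n),
             lr_plus = ifelse(fpr > 0, sens / fpr, Inf))
}

#' Jaccard similarity of two binary call vectors
#'
#' Counts mutual presence (positives) as matches: |a AND b| / |a OR b|.
#' Two all-zero vectors are defined as similarity 1 with an attribute flag.
#'
#' @param calls_a,calls_b equal-length binary vectors
#' @return similarity in [0,1]
#' @export
jaccard_calls <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) stop("length mismatch")
  stopifnot(all(calls_a %in% c(0, 1)), all(calls_b %in% c(0, 1)))
  union <- sum(calls_a == 1 | calls_b == 1)
  if (union == 0) {
    return(structure(1, flag = "both_empty"))
  }
  sum(calls_a == 1 & calls_b == 1) / union
}

#' Cohen's kappa between two categorical label vectors
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with the expected agreement from
#' marginal products. Perfect expected agreement (p_e = 1) is undefined and
#' returns NA with a flag attribute.
#'
#' @param labels_a,labels_b equal-length vectors
#' @return kappa in [-1, 1], or flagged NA
#' @export
kappa_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  n <- length(labels_a)
  if (n == 0) return(structure(NA_real_, flag = "empty"))
  cats <- union(unique(labels_a), unique(labels_b))
  po <- mean(labels_a == labels_b)
  pe <- sum(vapply(cats, function(cc) {
    mean(labels_a == cc) * mean(labels_b == cc)
  }, numeric(1)))
  if (pe >= 1) return(structure(NA_real_, flag = "degenerate_expected"))
  (po - pe) / (1 - pe)
}
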