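#' Filter, standardize, protonate and key raw SMILES records
#'
#' Applies the preprocessing pipeline used throughout the package:
#' parse-level filters (unparseable, metal-only, carbon-free structures),
#' then an iterated standardization sequence (metal disconnection,
#' normalization, reionization, principal-fragment selection, uncharging,
#' most-common-isotope form, stereochemistry removal, tautomer
#' canonicalization) applied up to five times or until the canonical SMILES
#' reaches a fixpoint, then post-standardization filters (no carbon left,
#' molecular weight of the principal fragment strictly above 1500 Da, or an
#' ambiguous multi-fragment structure), then rule-based protonation to the
#' dominant microstate at pH 7.0, and finally the 14-character InChIKey
#' connectivity ("hash") layer computed on the protonated form.
#'
#' Rejected inputs never raise an error: they come back as rows with
#' \code{rejected = TRUE} and a \code{reject_reason} in
#' \code{c("no_carbon", "disconnected", "metals_only", "mw_over_1500",
#' "parse_failure")}.
#'
#' @param smiles character vector of raw SMILES
#' @param protonate apply the pH-7 protonation rules (default TRUE). When
#'   disabled a warning is emitted and \code{smiles_ph7 == smiles_std}.
#' @return data.frame with columns smiles_in, smiles_std, smiles_ph7,
#'   key14, mw, rejected, reject_reason
#' @export
#' @examples
#' \dontrun{
#' standardize_compounds(c("CCO", "[Na+].CC(=O)[O-]", "[Fe+2]"))
#' }
standardize_compounds <- function(smiles, protonate = TRUE) {
  stopifnot(is.character(smiles))
  if (!protonate) {
    warning("pH-7 protonation disabled; smiles_ph7 will equal smiles_std")
  }
  if (length(smiles) == 0) {
    return(data.frame(
      smiles_in = character(), smiles_std = character(),
      smiles_ph7 = character(), key14 = character(), mw = numeric(),
      rejected = logical(), reject_reason = character(),
      stringsAsFactors = FALSE
    ))
  }
  rules <- if (protonate) rules_as_list(pka_rules()) else list()
  res <- backend_call("standardize", smiles,
                      list(protonate = protonate, pka_rules = rules))
  recs <- res$records
  out <- data.frame(
    smiles_in = smiles,
    smiles_std = vapply(recs, function(r) chr_or_na(r$smiles_std), ""),
    smiles_ph7 = vapply(recs, function(r) chr_or_na(r$smiles_ph7), ""),
    key14 = vapply(recs, function(r) chr_or_na(r$key14), ""),
    mw = vapply(recs, function(r) num_or_na(r$mw), 0),
    rejected = vapply(recs, function(r) isTRUE(r$rejected), TRUE),
    reject_reason = vapply(recs, function(r) chr_or_na(r$reject_reason), ""),
    stringsAsFactors = FALSE
  )
  bad <- !out$rejected & nchar(out$key14) != 14L
  if (any(bad)) { # key generation failure -> rejected record
    out$rejected[bad] <- TRUE
    out$reject_reason[bad] <- "parse_failure"
  }
  out
}

#' Construct an endpoint dataset
#'
#' @param name endpoint identifier
#' @param data data.frame with at least key14 and label columns (smiles_std
#'   and smiles_ph7 carried along when present)
#' @param kind "binary" or "numeric"
#' @param n_conflicts number of label conflicts resolved during deduplication
#' @return object of class EndpointDataset
#' @export
endpoint_dataset <- function(name, data, kind = c("binary", "numeric"),
                             n_conflicts = 0L) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(data), all(c("key14", "label") %in% names(data)))
  if (anyDuplicated(data$key14)) {
    stop("EndpointDataset '", name, "' has duplicate key14 values")
  }
  if (kind == "binary") {
    if (!all(data$label %in% c(0, 1))) {
      stop("binary endpoint '", name, "' has labels outside {0,1}")
    }
  } else if (!all(is.finite(data$label))) {
    stop("numeric endpoint '", name, "' has non-finite labels")
  }
  structure(
    list(name = name, kind = kind, data = data,
         n_conflicts = as.integer(n_conflicts)),
    class = "EndpointDataset"
  )
}

#' @export
print.EndpointDataset <- function(x, ...) {
  cat(sprintf("<EndpointDataset '%s'> %s, %d compounds", x$name, x$kind,
              nrow(x$data)))
  if (x$kind == "binary") {
    cat(sprintf(" (%d active)", sum(x$data$label == 1)))
  }
  cat(sprintf(", %d conflicts resolved\n", x$n_conflicts))
  invisible(x)
}

#' Deduplicate standardized records into an endpoint dataset
#'
#' Groups records by the key14 connectivity key. Conflicting binary labels
#' resolve to 1 (the toxic/active annotation wins); duplicated numeric
#' labels resolve to their median. The number of groups whose labels
#' actually disagreed is recorded as \code{n_conflicts}.
#'
#' @param records data.frame of unrejected standardized compounds with a
#'   label column (binary or numeric, not mixed)
#' @param policy "prefer_active" for binary labels, "median_numeric" for
#'   numeric labels
#' @param name endpoint name for the resulting dataset
#' @return EndpointDataset with unique key14 values
#' @export
deduplicate <- function(records, policy = c("prefer_active", "median_numeric"),
                        name = "endpoint") {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(records),
            all(c("key14", "label") %in% names(records)))
  if (any(is.na(records$key14)) ||
      (("rejected" %in% names(records)) && any(records$rejected))) {
    stop("deduplicate() requires unrejected records only")
  }
  binary <- all(records$label %in% c(0, 1))
  if (policy == "prefer_active" && !binary) {
    stop("prefer_active policy requires binary labels in {0,1}")
  }
  if (policy == "median_numeric" && binary && nrow(records) > 0 &&
      !all(records$label %in% c(0, 1))) {
    stop("mixed binary/numeric labels") # nocov
  }
  # deterministic, order-invariant: sort groups by key
  keys <- sort(unique(records$key14))
  idx_first <- match(keys, records$key14)
  label <- vapply(keys, function(k) {
    v <- records$label[records$key14 == k]
    if (policy == "prefer_active") max(v) else stats::median(v)
  }, numeric(1))
  conflicts <- sum(vapply(keys, function(k) {
    length(unique(records$label[records$key14 == k])) > 1L
  }, logical(1)))
  keep_cols <- intersect(c("smiles_std", "smiles_ph7", "source"),
                         names(records))
  out <- cbind(
    data.frame(key14 = keys, label = unname(label),
               stringsAsFactors = FALSE),
    records[idx_first, keep_cols, drop = FALSE]
  )
  rownames(out) <- NULL
  endpoint_dataset(name, out,
                   kind = if (policy == "prefer_active") "binary"
                          else "numeric",
                   n_conflicts = conflicts)
}

#' Read a raw compound CSV (columns: smiles, label[, id, source])
#' @param path CSV file path
#' @return data.frame
#' @export
read_raw_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df)) stop("CSV must have a 'smiles' column")
  df
}

#' Write a standardized dataset CSV
#' @param std data.frame from [standardize_compounds()] (label/source columns
#'   carried through when present)
#' @param path output path
#' @export
write_standardized_csv <- function(std, path) {
  utils::write.csv(std, path, row.names = FALSE)
  invisible(path)
}
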