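# Assembly of the gold-standard DILI dataset and the proxy-endpoint panel
# with leak-proof overlap removal and concordance analysis.

#' Assemble the gold-standard DILI dataset from two label sources
#'
#' DILIrank-style categorical labels are mapped vMost/vLess -> 1 (DILI
#' positive), vNo -> 0, and Ambiguous compounds are dropped; DILIst-style
#' records are already binary. The two sources are merged by key14 and
#' cross-source conflicts resolve to 1 (the toxic annotation is retained).
#'
#' @param dilist_records data.frame with key14 and binary label columns
#'   (smiles columns carried through)
#' @param dilirank_records data.frame with key14 and a categorical label
#'   column with values in c("vMost", "vLess", "vNo", "Ambiguous")
#' @return EndpointDataset named "DILI"
#' @export
assemble_gold <- function(dilist_records, dilirank_records) {
  stopifnot(all(c("key14", "label") %in% names(dilist_records)),
            all(c("key14", "label") %in% names(dilirank_records)))
  known <- c("vMost", "vLess", "vNo", "Ambiguous")
  bad <- setdiff(unique(dilirank_records$label), known)
  if (length(bad)) {
    stop("unknown DILIrank category: ", paste(bad, collapse = ", "))
  }
  rank <- dilirank_records[dilirank_records$label != "Ambiguous", ,
                           drop = FALSE]
  rank$label <- ifelse(rank$label %in% c("vMost", "vLess"), 1, 0)
  if (!all(dilist_records$label %in% c(0, 1))) {
    stop("DILIst labels must be binary")
  }
  merged <- rbind(
    dilist_records[, intersect(names(dilist_records),
                               c("key14", "label", "smiles_std",
                                 "smiles_ph7")), drop = FALSE],
    rank[, intersect(names(rank), c("key14", "label", "smiles_std",
                                    "smiles_ph7")), drop = FALSE]
  )
  deduplicate(merged, policy = "prefer_active", name = "DILI")
}

#' Remove gold-standard compounds from a proxy endpoint dataset
#'
#' Drops every proxy compound whose key14 connectivity key appears in the
#' gold dataset, preventing information leaks from level-1 training into
#' the level-2 DILI evaluation.
#'
#' @param proxy EndpointDataset
#' @param gold EndpointDataset (the DILI gold standard)
#' @return proxy EndpointDataset minus overlapping compounds; the number of
#'   removed compounds is recorded in the \code{n_removed} attribute
#' @export
remove_overlap <- function(proxy, gold) {
  stopifnot(inherits(proxy, "EndpointDataset"),
            inherits(gold, "EndpointDataset"))
  drop <- proxy$data$key14 %in% gold$data$key14
  out <- proxy
  out$data <- proxy$data[!drop, , drop = FALSE]
  rownames(out$data) <- NULL
  if (nrow(out$data) == 0) {
    warning("proxy dataset '", proxy$name,
            "' is empty after overlap removal")
  }
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Pairwise Cohen's kappa concordance across binary endpoint datasets
#'
#' For every dataset pair, labels are compared on the compounds (key14)
#' shared by both; the table reports kappa and the overlap count. Pairs
#' with zero shared compounds, or where a dataset is constant on the
#' shared subset with perfect expected agreement, are reported as missing
#' (NA) with a reason code, never as 0.
#'
#' @param datasets list of binary EndpointDatasets
#' @return list(kappa = symmetric matrix with unit diagonal,
#'   n_overlap = integer matrix, reason = character matrix of NA-reasons)
#' @export
concordance_matrix <- function(datasets) {
  if (length(datasets) < 2) {
    stop("concordance_matrix() requires at least two datasets")
  }
  for (d in datasets) {
    if (!inherits(d, "EndpointDataset") || d$kind != "binary") {
      stop("concordance_matrix() requires binary EndpointDatasets")
    }
  }
  nms <- vapply(datasets, function(d) d$name, "")
  m <- length(datasets)
  kap <- matrix(NA_real_, m, m, dimnames = list(nms, nms))
  nov <- matrix(0L, m, m, dimnames = list(nms, nms))
  reason <- matrix(NA_character_, m, m, dimnames = list(nms, nms))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j < i) next
      a <- datasets[[i]]$data; b <- datasets[[j]]$data
      shared <- intersect(a$key14, b$key14)
      nov[i, j] <- nov[j, i] <- length(shared)
      if (length(shared) == 0) {
        reason[i, j] <- reason[j, i] <- "no_overlap"
        next
      }
      la <- a$label[match(shared, a$key14)]
      lb <- b$label[match(shared, b$key14)]
      k <- kappa_agreement(la, lb)
      if (is.na(k)) {
        reason[i, j] <- reason[j, i] <- attr(k, "flag")
      }
      kap[i, j] <- kap[j, i] <- as.numeric(k)
    }
  }
  list(kappa = kap, n_overlap = nov, reason = reason)
}

#' Build a leak-checked panel of gold + proxy + PK datasets
#'
#' Applies [remove_overlap()] to every binary proxy endpoint (PK/Cmax
#' datasets are exempt, matching the level-1 protocol) and asserts the
#' leak-guard invariant that no proxy key14 remains in the gold set.
#'
#' @param gold EndpointDataset (binary, the DILI gold standard)
#' @param proxies named list of binary EndpointDatasets
#' @param pk named list of numeric (Cmax) EndpointDatasets
#' @return object of class Panel
#' @export
build_panel <- function(gold, proxies, pk = list()) {
  stopifnot(inherits(gold, "EndpointDataset"), gold$kind == "binary")
  proxies <- lapply(proxies, remove_overlap, gold = gold)
  for (d in proxies) {
    if (any(d$data$key14 %in% gold$data$key14)) {
      stop("leak guard violated for proxy '", d$name, "'") # nocov
    }
  }
  structure(list(gold = gold, proxies = proxies, pk = pk), class = "Panel")
}

#' @export
print.Panel <- function(x, ...) {
  cat(sprintf("<Panel> gold: %d compounds; %d proxies; %d PK targets\n",
              nrow(x$gold$data), length(x$proxies), length(x$pk)))
  invisible(x)
}

#' Persist a panel as per-endpoint CSVs plus a manifest
#' @param panel Panel
#' @param dir output directory (created if needed)
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all <- c(list(gold = panel$gold), panel$proxies, panel$pk)
  manifest <- list()
  for (nm in names(all)) {
    d <- all[[nm]]
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(d$data, f, row.names = FALSE)
    manifest[[nm]] <- list(name = d$name, kind = d$kind,
                           n = nrow(d$data),
                           n_removed = attr(d, "n_removed"))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
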