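#' Construct a FeatureBlock
#'
#' A named, ordered feature matrix (structural bits, descriptors, or
#' stacked predictions) with optional selection metadata.
#'
#' @param name block name ("morgan", "maccs", "descriptors", "physchem15",
#'   "stacked")
#' @param matrix numeric matrix, compounds x features
#' @param feature_names ordered feature names (defaults to colnames)
#' @param catalogue_version descriptor catalogue version string, if relevant
#' @return object of class FeatureBlock
#' @export
feature_block <- function(name, matrix, feature_names = colnames(matrix),
                          catalogue_version = NULL) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != length(feature_names)) {
    stop("matrix column count must equal length of feature_names")
  }
  colnames(matrix) <- feature_names
  structure(list(name = name, matrix = matrix,
                 feature_names = feature_names,
                 catalogue_version = catalogue_version),
            class = "FeatureBlock")
}

#' @export
print.FeatureBlock <- function(x, ...) {
  cat(sprintf("<FeatureBlock '%s'> %d x %d\n", x$name, nrow(x$matrix),
              ncol(x$matrix)))
  invisible(x)
}

bits_to_matrix <- function(bit_lists, width, prefix) {
  n <- length(bit_lists)
  m <- matrix(0, n, width,
              dimnames = list(NULL, sprintf("%s_%04d", prefix,
                                            seq_len(width) - 1L)))
  for (i in seq_len(n)) {
    bits <- unlist(bit_lists[[i]])
    if (length(bits)) m[i, bits + 1L] <- 1
  }
  m
}

#' Compute the chemical feature blocks for standardized compounds
#'
#' Produces four blocks: 2048-bit radius-2 Morgan fingerprints, 166-bit
#' MACCS keys, the full 2D descriptor catalogue of the bundled RDKit
#' backend (version recorded; columns may contain NA before descriptor
#' selection), and the fixed panel of 15 physicochemical parameters
#' (TPSA, H-bond acceptors/donors, fraction sp3 carbons, logP, rotatable
#' bonds, rings, assembled ring systems, aromatic rings, heteroatoms,
#' stereocenters, positively/negatively charged atoms, NHOH and NO counts).
#'
#' Compounds the backend cannot featurize are excluded from every block and
#' reported in the \code{excluded} element with a warning.
#'
#' @param smiles character vector of standardized (pH-7) SMILES, or a
#'   data.frame from [standardize_compounds()] (its smiles_ph7 is used)
#' @param which subset of blocks to compute
#' @return list(blocks = named list of FeatureBlocks, ok = logical vector,
#'   excluded = integer indices)
#' @export
featurize_compounds <- function(smiles,
                                which = c("morgan", "maccs", "descriptors",
                                          "physchem15")) {
  if (is.data.frame(smiles)) {
    if ("rejected" %in% names(smiles) && any(smiles$rejected)) {
      stop("featurize_compounds() requires unrejected compounds only")
    }
    smiles <- smiles$smiles_ph7
  }
  which <- match.arg(which, several.ok = TRUE)
  res <- backend_call("features", smiles, list(which = as.list(which)))
  ok <- vapply(res$ok, isTRUE, logical(1))
  excluded <- base::which(!ok)
  if (length(excluded)) {
    warning(length(excluded), " compound(s) failed featurization and were ",
            "excluded: indices ", paste(excluded, collapse = ", "))
  }
  blocks <- list()
  if ("morgan" %in% which) {
    blocks$morgan <- feature_block("morgan",
                                   bits_to_matrix(res$morgan[ok], 2048L,
                                                  "morgan"))
  }
  if ("maccs" %in% which) {
    blocks$maccs <- feature_block("maccs",
                                  bits_to_matrix(res$maccs[ok], 166L,
                                                 "maccs"))
  }
  if ("descriptors" %in% which) {
    nms <- unlist(res$descriptor_names)
    rows <- lapply(res$descriptors[ok], function(r) {
      vapply(r, num_or_na, numeric(1))
    })
    m <- do.call(rbind, c(rows, list(matrix(numeric(0), 0, length(nms)))))
    colnames(m) <- nms
    blocks$descriptors <- feature_block("descriptors", m,
                                        catalogue_version =
                                          res$catalogue_version)
  }
  if ("physchem15" %in% which) {
    nms <- unlist(res$physchem15_names)
    rows <- lapply(res$physchem15[ok], function(r) {
      vapply(r, num_or_na, numeric(1))
    })
    m <- do.call(rbind, c(rows, list(matrix(numeric(0), 0, length(nms)))))
    colnames(m) <- nms
    blocks$physchem15 <- feature_block("physchem15", m)
  }
  list(blocks = blocks, ok = ok, excluded = excluded)
}

#' Fit the descriptor drop-missing selection on a reference set
#'
#' Any descriptor with a missing or non-finite value for any compound in
#' the reference set is dropped for all compounds; reference-set medians of
#' the surviving descriptors are stored for imputing new compounds.
#'
#' @param block descriptors FeatureBlock computed on the reference set
#' @return list(block_name, keep_names, medians, catalogue_version)
#' @export
fit_descriptor_selection <- function(block) {
  stopifnot(inherits(block, "FeatureBlock"))
  if (nrow(block$matrix) == 0) stop("empty reference set")
  finite <- apply(block$matrix, 2, function(x) all(is.finite(x)))
  keep <- block$feature_names[finite]
  med <- apply(block$matrix[, keep, drop = FALSE], 2, stats::median)
  list(block_name = block$name, keep_names = keep, medians = med,
       catalogue_version = block$catalogue_version)
}

#' Apply a fitted descriptor selection to a block
#'
#' Subsets to the surviving descriptors; non-finite values in surviving
#' columns (possible for compounds outside the reference set) are imputed
#' with the reference-set median and counted in the \code{n_imputed}
#' attribute.
#'
#' @param block descriptors FeatureBlock
#' @param sel result of [fit_descriptor_selection()]
#' @return reduced FeatureBlock with no non-finite values
#' @export
apply_descriptor_selection <- function(block, sel) {
  stopifnot(inherits(block, "FeatureBlock"))
  if (!identical(block$name, sel$block_name)) {
    stop("selection was fitted on block '", sel$block_name, "', not '",
         block$name, "'")
  }
  missing_cols <- setdiff(sel$keep_names, block$feature_names)
  if (length(missing_cols)) {
    stop("block lacks descriptor '", missing_cols[1], "'")
  }
  m <- block$matrix[, sel$keep_names, drop = FALSE]
  n_imputed <- 0L
  for (j in seq_along(sel$keep_names)) {
    bad <- !is.finite(m[, j])
    if (any(bad)) {
      m[bad, j] <- sel$medians[[j]]
      n_imputed <- n_imputed + sum(bad)
    }
  }
  out <- feature_block(block$name, m, catalogue_version =
                         block$catalogue_version)
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Fit a low-variance selection mask on a reference feature block
#'
#' Keeps feature j iff its population (divide-by-n) variance over the
#' reference rows is strictly greater than the threshold. Masks must be
#' fitted on the proxy-endpoint reference panel, never on the gold-standard
#' set, to avoid information leaks.
#'
#' @param block FeatureBlock computed on the reference set
#' @param threshold variance threshold (default 0.05 for morgan, 0.10 for
#'   maccs and descriptors per [default_mask_thresholds()])
#' @return mask object: list(block_name, threshold, keep = named logical)
#' @export
fit_variance_mask <- function(block, threshold) {
  stopifnot(inherits(block, "FeatureBlock"))
  n <- nrow(block$matrix)
  if (n == 0) stop("empty reference set")
  mu <- colMeans(block$matrix)
  v <- colMeans(block$matrix^2) - mu^2 # population variance
  keep <- v > threshold
  names(keep) <- block$feature_names
  list(block_name = block$name, threshold = threshold, keep = keep,
       feature_names = block$feature_names)
}

#' Default variance thresholds per block
#' @return named numeric vector
#' @export
default_mask_thresholds <- function() {
  c(morgan = 0.05, maccs = 0.10, descriptors = 0.10)
}

#' Apply a fitted selection mask to a feature block
#'
#' @param block FeatureBlock whose feature_names equal those the mask was
#'   fitted on
#' @param mask result of [fit_variance_mask()]
#' @return column-subset FeatureBlock in original order
#' @export
apply_mask <- function(block, mask) {
  stopifnot(inherits(block, "FeatureBlock"))
  if (!identical(block$name, mask$block_name)) {
    stop("mask was fitted on block '", mask$block_name, "', not '",
         block$name, "'")
  }
  if (!identical(block$feature_names, mask$feature_names)) {
    bad <- which(block$feature_names != mask$feature_names)[1]
    if (is.na(bad)) bad <- min(length(block$feature_names),
                               length(mask$feature_names)) + 1L
    stop("feature name mismatch at position ", bad, ": '",
         block$feature_names[bad], "'")
  }
  out <- feature_block(block$name,
                       block$matrix[, mask$keep, drop = FALSE],
                       catalogue_version = block$catalogue_version)
  attr(out, "mask_threshold") <- mask$threshold
  out
}

#' Fit all selection state (descriptor drop-missing + variance masks) on a
#' reference panel
#'
#' @param blocks named list of FeatureBlocks from [featurize_compounds()]
#'   computed on the proxy-endpoint reference compounds
#' @param thresholds named thresholds (see [default_mask_thresholds()]);
#'   physchem15 is never masked
#' @return list(desc_sel, masks) reusable on any other compound set
#' @export
fit_feature_masks <- function(blocks, thresholds = default_mask_thresholds()) {
  desc_sel <- NULL
  masks <- list()
  if (!is.null(blocks$descriptors)) {
    desc_sel <- fit_descriptor_selection(blocks$descriptors)
    reduced <- apply_descriptor_selection(blocks$descriptors, desc_sel)
    masks$descriptors <- fit_variance_mask(reduced,
                                           thresholds[["descriptors"]])
  }
  for (b in c("morgan", "maccs")) {
    if (!is.null(blocks[[b]])) {
      masks[[b]] <- fit_variance_mask(blocks[[b]], thresholds[[b]])
    }
  }
  list(desc_sel = desc_sel, masks = masks, thresholds = thresholds)
}

#' Apply fitted selection state to a compound set's feature blocks
#'
#' @param blocks named list of FeatureBlocks
#' @param fitted result of [fit_feature_masks()]
#' @return list with elements structural (masked morgan + maccs, one
#'   matrix), descriptors (masked descriptors + physchem15, one matrix) and
#'   the individual reduced blocks
#' @export
apply_feature_masks <- function(blocks, fitted) {
  morgan <- apply_mask(blocks$morgan, fitted$masks$morgan)
  maccs <- apply_mask(blocks$maccs, fitted$masks$maccs)
  desc <- apply_descriptor_selection(blocks$descriptors, fitted$desc_sel)
  desc <- apply_mask(desc, fitted$masks$descriptors)
  structural <- cbind(morgan$matrix, maccs$matrix)
  descriptors <- cbind(desc$matrix, blocks$physchem15$matrix)
  list(structural = structural, descriptors = descriptors,
       morgan = morgan, maccs = maccs, descriptors_block = desc,
       physchem15 = blocks$physchem15)
}

#' Persist a FeatureBlock (CSV matrix + JSON sidecar)
#' @param block FeatureBlock
#' @param path output path without extension; writes path.csv and path.json
#' @param mask optional fitted mask to record
#' @export
write_feature_block <- function(block, path, mask = NULL) {
  utils::write.csv(as.data.frame(block$matrix), paste0(path, ".csv"),
                   row.names = FALSE)
  meta <- list(name = block$name, feature_names = block$feature_names,
               catalogue_version = block$catalogue_version)
  if (!is.null(mask)) {
    meta$mask <- list(threshold = mask$threshold,
                      keep = unname(mask$keep),
                      feature_names = mask$feature_names)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a persisted FeatureBlock
#' @param path path stem used in [write_feature_block()]
#' @return list(block, mask or NULL)
#' @export
read_feature_block <- function(path) {
  m <- as.matrix(utils::read.csv(paste0(path, ".csv"),
                                 check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  block <- feature_block(meta$name, m, meta$feature_names,
                         meta$catalogue_version)
  mask <- NULL
  if (!is.null(meta$mask)) {
    keep <- as.logical(meta$mask$keep)
    names(keep) <- meta$mask$feature_names
    mask <- list(block_name = meta$name, threshold = meta$mask$threshold,
                 keep = keep, feature_names = meta$mask$feature_names)
  }
  list(block = block, mask = mask)
}
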