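#' @useDynLib dilinet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Bridge to the bundled RDKit batch backend (inst/python/chem_backend.py).
# One system2() call per batch; requests and responses travel as JSON files.

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "dilinet")
  if (!nzchar(path) || !file.exists(path)) {
    stop("chem_backend.py not found; is the package installed correctly?")
  }
  path
}

backend_python <- function() {
  python <- Sys.getenv("DILINET_PYTHON", "")
  if (!nzchar(python)) python <- Sys.which("python")
  if (!nzchar(python)) stop("no 'python' interpreter found on PATH")
  python
}

#' Run one batch operation in the chemistry backend
#'
#' @param op one of "standardize", "features", "match", "validate"
#' @param smiles character vector of SMILES
#' @param options named list of op-specific options
#' @return parsed JSON response as a list
#' @keywords internal
backend_call <- function(op, smiles, options = list()) {
  req <- tempfile(fileext = ".json")
  res <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, res)), add = TRUE)
  jsonlite::write_json(
    list(op = op, smiles = as.list(as.character(smiles)), options = options),
    req, auto_unbox = TRUE, digits = NA, null = "null"
  )
  status <- suppressWarnings(system2(
    backend_python(), c(shQuote(backend_script()), shQuote(req), shQuote(res)),
    stdout = FALSE, stderr = FALSE
  ))
  if (!identical(status, 0L) || !file.exists(res)) {
    stop("chemistry backend failed (op = ", op, ", exit status ", status, ")")
  }
  jsonlite::read_json(res, simplifyVector = FALSE)
}

#' Load the bundled pH-7 pKa rule table
#'
#' A versioned substructure/pKa table used to place ionizable groups in
#' their dominant microstate at pH 7.0 (acids with pKa < 7 deprotonated,
#' bases with pKa > 7 protonated).
#'
#' @return data.frame with columns name, type, smarts, pka, atom, max_sites
#' @export
pka_rules <- function() {
  path <- system.file("extdata", "pka_rules.csv", package = "dilinet")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

rules_as_list <- function(rules) {
  lapply(seq_len(nrow(rules)), function(i) as.list(rules[i, ]))
}

num_or_na <- function(x) {
  if (is.null(x)) NA_real_ else as.numeric(x)
}

chr_or_na <- function(x) {
  if (is.null(x)) NA_character_ else as.character(x)
}
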