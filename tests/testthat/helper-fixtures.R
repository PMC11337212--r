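# Shared fixtures, built once per test run and cached. Everything is
# generated in code; nothing is downloaded or stored as binary.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .fixture_cache)) {
    assign(name, builder(), .fixture_cache)
  }
  get(name, .fixture_cache)
}

# a handful of standardized small molecules used across files
tiny_std <- function() {
  cached("tiny_std", function() {
    standardize_compounds(c(
      ethanol = "CCO", methanol = "CO", benzene = "c1ccccc1",
      cyclohexane = "C1CCCCC1", acetic = "CC(=O)O", decane = "CCCCCCCCCC"
    ))
  })
}

tiny_features <- function() {
  cached("tiny_features", function() featurize_compounds(tiny_std()))
}

# the default synthetic world (seed 42) with the full fixture pipeline
default_fixture <- function() {
  cached("default_fixture", function() {
    prepare_fixture(generative_spec(seed = 42))
  })
}

# small deterministic 0/1 fingerprint matrices for splitting tests
random_fp <- function(n, bits, seed, p = 0.3) {
  set.seed(seed)
  matrix(rbinom(n * bits, 1, p), n, bits)
}

# independent sphere-exclusion oracle used to check butina_cluster():
# naive per-pair Tanimoto (explicit set counting, no matrix algebra) and a
# literal reading of the clustering rule
tanimoto_pair_oracle <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) 0 else inter / uni
}

butina_oracle <- function(fp, cutoff) {
  n <- nrow(fp)
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sim[i, j] <- tanimoto_pair_oracle(fp[i, ], fp[j, ])
    }
  }
  within <- (1 - sim) <= cutoff
  diag(within) <- TRUE
  diag(within) <- TRUE
  counts <- rowSums(within)
  order_idx <- order(-counts, seq_len(n))
  assign <- rep(NA_integer_, n)
  cl <- 0L
  for (i in order_idx) {
    if (!is.na(assign[i])) next
    cl <- cl + 1L
    for (j in seq_len(n)) {
      if (is.na(assign[j]) && within[i, j]) assign[j] <- cl
    }
  }
  assign
}
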