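test_that("library generation is deterministic and grammar-valid", {
  spec <- generative_spec(seed = 9)
  lib1 <- generate_library(spec)
  lib2 <- generate_library(spec)
  expect_identical(lib1, lib2)
  # different seed changes only the decoration, not the base enumeration
  lib3 <- generate_library(generative_spec(seed = 10))
  expect_identical(lib1$base_smiles, lib3$base_smiles)
  # salt_rate 0 -> all single-fragment SMILES
  lib0 <- generate_library(generative_spec(seed = 9, salt_rate = 0))
  expect_false(any(grepl(".", lib0$smiles, fixed = TRUE)))
  # the whole default library standardizes without rejections (checked
  # end-to-end by the cached fixture)
  fx <- default_fixture()
  expect_false(any(fx$std$rejected))
})

test_that("planted conflicts are exact and collapse to one key14", {
  fx <- default_fixture()
  conf <- fx$manifest$conflicts
  spec <- fx$spec
  per_ep <- table(conf$endpoint)
  expect_true(all(per_ep == floor(spec$conflict_rate * spec$n_per_endpoint)))
  # dedup resolved exactly the planted conflicts and nothing else
  for (e in names(fx$panel$proxies)) {
    expect_identical(fx$panel$proxies[[e]]$n_conflicts,
                     as.integer(per_ep[[e]]))
  }
  # both records of a conflict pair share a key14 after standardization
  some <- conf[seq_len(min(5, nrow(conf))), ]
  std_a <- standardize_compounds(some$smiles_a)
  std_b <- standardize_compounds(some$smiles_b)
  expect_identical(std_a$key14, std_b$key14)
})

test_that("noiseless endpoint labels equal the SMARTS-matcher indicator", {
  spec <- generative_spec(seed = 5, noise_rate = 0, conflict_rate = 0,
                          salt_rate = 0, stereo_rate = 0)
  lib <- generate_library(spec)
  std <- standardize_compounds(lib$smiles)
  feats <- featurize_compounds(std$smiles_ph7, which = "physchem15")
  labels <- assign_endpoint_labels(lib, spec,
                                   feats$blocks$physchem15$matrix)
  tox <- spec$toxicophores
  res <- backend_call("match", std$smiles_ph7,
                      list(patterns = as.list(tox$smarts)))
  hits <- do.call(rbind, lapply(res$hits, function(r) {
    vapply(r, function(x) as.integer(x), 1L)
  }))
  colnames(hits) <- tox$name
  for (e in spec$endpoints[c(1, 4, 7)]) { # spot-check three endpoints
    df <- labels$proxies_raw[[e]]
    want <- as.integer(
      rowSums(hits[df$lib_id, spec$signal_map[[e]], drop = FALSE]) > 0)
    expect_identical(df$label, want)
  }
  # the matcher also reproduces the generator's own indicator matrix
  expect_identical(unname(hits), unname(attr(lib, "tox")))
})

test_that("label noise shifts agreement by the expected binomial amount", {
  spec <- generative_spec(seed = 6, noise_rate = 0.2, conflict_rate = 0,
                          salt_rate = 0, stereo_rate = 0)
  lib <- generate_library(spec)
  pc <- matrix(1, nrow(lib), 15,
               dimnames = list(NULL, c("TPSA", "NumHAcceptors",
                                       "NumHDonors", "FractionCSP3",
                                       "MolLogP", "NumRotatableBonds",
                                       "RingCount", "NumRingSystems",
                                       "NumAromaticRings",
                                       "NumHeteroatoms",
                                       "NumStereocenters", "NumPosCharged",
                                       "NumNegCharged", "NHOHCount",
                                       "NOCount")))
  labels <- assign_endpoint_labels(lib, spec, pc)
  agree <- unlist(lapply(spec$endpoints, function(e) {
    df <- labels$proxies_raw[[e]]
    ind <- labels$latent$ep_indicator[df$lib_id, e]
    mean(df$label == ind)
  }))
  # pooled agreement ~ Binomial(9 * 140, 0.8)
  expect_gt(mean(agree), 0.8 - 3 * sqrt(0.2 * 0.8 / (9 * 140)))
  expect_lt(mean(agree), 0.8 + 3 * sqrt(0.2 * 0.8 / (9 * 140)))
})

test_that("endpoints sharing a toxicophore are more concordant", {
  fx <- default_fixture()
  cc <- concordance_matrix(fx$panel$proxies)
  # BSEP and Mitotox share toxicophore 4; BSEP and human share none
  expect_gt(cc$kappa["BSEP", "Mitotox"],
            cc$kappa["BSEP", "human_hepatotoxicity"])
})

test_that("the manifest is a faithful answer key", {
  fx <- default_fixture()
  expect_identical(fx$manifest$toxicophores, fx$spec$toxicophores)
  expect_identical(ncol(fx$manifest$tox_indicators),
                   nrow(fx$spec$toxicophores))
  expect_identical(colnames(fx$manifest$ep_indicator), fx$spec$endpoints)
  expect_true(all(c("intercept", "logp", "tpsa_per100", "sigma") %in%
                    names(fx$manifest$cmax_rule)))
})
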