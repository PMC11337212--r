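test_that("fingerprint blocks have the canonical widths", {
  f <- tiny_features()
  expect_identical(ncol(f$blocks$morgan$matrix), 2048L)
  expect_identical(ncol(f$blocks$maccs$matrix), 166L)
  # concatenated structural fingerprint width
  expect_identical(ncol(f$blocks$morgan$matrix) +
                     ncol(f$blocks$maccs$matrix), 2214L)
  expect_true(all(f$blocks$morgan$matrix %in% c(0, 1)))
  expect_true(all(f$blocks$maccs$matrix %in% c(0, 1)))
})

test_that("fingerprints are deterministic and discriminate structures", {
  f <- featurize_compounds(c("C", "C", "CCCCCCCCCC"))
  expect_identical(f$blocks$morgan$matrix[1, ], f$blocks$morgan$matrix[2, ])
  expect_false(all(f$blocks$morgan$matrix[1, ] ==
                     f$blocks$morgan$matrix[3, ]))
})

test_that("descriptor catalogue and physchem15 values are sane", {
  f <- tiny_features()
  std <- tiny_std()
  i_eth <- which(std$smiles_in == "CCO")
  # MW of ethanol from atomic-mass summation: 2*12.011+6*1.008+15.999
  expect_equal(unname(f$blocks$descriptors$matrix[i_eth, "MolWt"]), 46.069,
               tolerance = 1e-3)
  pc <- f$blocks$physchem15$matrix
  expect_identical(ncol(pc), 15L)
  i_cyh <- which(std$smiles_in == "C1CCCCC1")
  expect_equal(unname(pc[i_cyh, c("NumRotatableBonds", "RingCount",
                                  "NumAromaticRings", "NumHeteroatoms")]),
               c(0, 1, 0, 0))
  i_benz <- which(std$smiles_in == "c1ccccc1")
  expect_equal(unname(pc[i_benz, c("NumAromaticRings", "FractionCSP3")]),
               c(1, 0))
  expect_equal(unname(pc[i_eth, c("NumHDonors", "NumHAcceptors",
                                  "NumHeteroatoms")]), c(1, 1, 1))
  # count-valued entries are non-negative integers
  counts <- pc[, c("NumHAcceptors", "NumHDonors", "NumRotatableBonds",
                   "RingCount", "NumRingSystems", "NumAromaticRings",
                   "NumHeteroatoms", "NumStereocenters", "NumPosCharged",
                   "NumNegCharged", "NHOHCount", "NOCount")]
  expect_true(all(counts >= 0 & counts == round(counts)))
})

test_that("variance mask uses strict population-variance thresholding", {
  m <- cbind(const = rep(1, 10),
             rare = c(1, rep(0, 9)),      # p = 0.1 -> var = 0.09
             half = rep(c(0, 1), 5))      # p = 0.5 -> var = 0.25
  b <- feature_block("test", m)
  expect_identical(unname(fit_variance_mask(b, 0.05)$keep),
                   c(FALSE, TRUE, TRUE))
  expect_identical(unname(fit_variance_mask(b, 0.10)$keep),
                   c(FALSE, FALSE, TRUE))
  # strictly-greater at the boundary: var == threshold is dropped
  expect_false(fit_variance_mask(b, 0.25)$keep[["half"]])
  expect_error(fit_variance_mask(feature_block("e", m[0, , drop = FALSE]),
                                 0.05), "empty")
})

test_that("apply_mask subsets deterministically and checks provenance", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  b <- feature_block("blk", m)
  mask <- fit_variance_mask(b, -1) # keep all (variance > -1)
  expect_identical(apply_mask(b, mask)$matrix, b$matrix) # all-true identity
  # refit on shuffled rows yields the same mask
  b2 <- feature_block("blk", m[sample(10), ])
  expect_identical(fit_variance_mask(b2, 0.5)$keep,
                   fit_variance_mask(b, 0.5)$keep)
  # idempotence of an applied mask
  reduced <- apply_mask(b, fit_variance_mask(b, 0.5))
  mask2 <- fit_variance_mask(reduced, -1)
  expect_identical(apply_mask(reduced, mask2)$matrix, reduced$matrix)
  # wrong block name errors
  other <- feature_block("other", m)
  expect_error(apply_mask(other, mask), "fitted on block")
  # feature mismatch names the offending feature
  b3 <- feature_block("blk", m[, c(2, 1, 3, 4)])
  expect_error(apply_mask(b3, mask), "f2")
})

test_that("descriptor selection drops NA columns and imputes new rows", {
  ref <- matrix(c(1, 2, 3, 4,
                  5, NA, 6, 7,
                  8, 9, 10, 11), 3, 4, byrow = FALSE,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  ref[2, "b"] <- NA # column b has a missing value -> dropped for all
  blk <- feature_block("descriptors", ref)
  sel <- fit_descriptor_selection(blk)
  expect_false("b" %in% sel$keep_names)
  red <- apply_descriptor_selection(blk, sel)
  expect_true(all(is.finite(red$matrix)))
  # a new compound with NA in a surviving column gets the reference median
  new <- feature_block("descriptors",
                       matrix(c(NA, 1, 2, 3), 1, 4,
                              dimnames = list(NULL, c("a", "b", "c", "d"))))
  imp <- apply_descriptor_selection(new, sel)
  expect_identical(unname(imp$matrix[1, "a"]), unname(sel$medians[["a"]]))
  expect_identical(attr(imp, "n_imputed"), 1L)
})

test_that("structural width identity holds on the synthetic reference", {
  fx <- default_fixture()
  chem <- fx$chem_for(fx$panel$gold$data$key14)
  expect_identical(ncol(chem$structural),
                   ncol(chem$morgan$matrix) + ncol(chem$maccs$matrix))
  expect_false(any(!is.finite(chem$descriptors)))
})
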