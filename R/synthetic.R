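# Self-contained synthetic multi-endpoint panel with planted
# structure-activity signal. A fragment grammar (scaffold templates x
# substituents) guarantees valid SMILES and controllable Tanimoto
# structure; six planted toxicophore substituents drive the endpoint
# labels; a logistic gold rule routes label signal through the endpoint
# latents plus one direct structural alert. All randomness flows from the
# spec seed through named substreams.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  set.seed(as.integer(seed %% 2147483647))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  expr
}

#' The planted toxicophore catalogue
#'
#' Each toxicophore is a substituent SMILES planted by the grammar and a
#' SMARTS pattern that detects it on standardized structures.
#' @return data.frame(name, substituent, smarts)
#' @export
toxicophores <- function() {
  data.frame(
    name = c("nitro", "sulfonamide", "hydrazine", "furan", "thiourea",
             "epoxide"),
    substituent = c("[N+](=O)[O-]", "S(N)(=O)=O", "NN", "c3ccoc3",
                    "NC(=S)N", "CC3CO3"),
    smarts = c("[N+](=O)[O-]", "S(=O)(=O)[NX3]", "[NX3][NX3H2]",
               "c1ccoc1", "[NX3]C(=S)[NX3]", "C1CO1"),
    stringsAsFactors = FALSE
  )
}

grammar_templates <- function() {
  c("c1ccc(%s)cc1%s",      # benzene
    "c1ccc2cc(%s)ccc2c1%s", # naphthalene
    "C1CCN(%s)CC1%s",       # piperidine
    "c1cc(%s)ncc1%s",       # pyridine
    "C1CCC(%s)CC1%s",       # cyclohexane
    "c1csc(%s)c1%s")        # thiophene
}

grammar_substituents_a <- function() {
  c("C", "CC", "CCO", "OC", "C#N", "C(C)O")
}

# disjoint from slot A so that substituent swaps on symmetry-equivalent
# ring positions can never collide into the same molecule
grammar_substituents_b <- function() {
  c("", "F", "Cl", "C(C)C", "CC(C)C", "OCCC", "CCCCC", "C(F)(F)F",
    "OCCO", "CCl")
}

#' Construct a generative specification for the synthetic panel
#'
#' Defaults define the package's stated synthetic world: a 9-endpoint
#' binary panel plus two Cmax regression targets over an enumerated
#' fragment-grammar library, 10 percent label-flip noise, 5 percent planted
#' label conflicts, 10 percent salt forms and 15 percent injected
#' stereocenters.
#'
#' @param seed master seed
#' @param n_per_endpoint compounds sampled per proxy endpoint
#' @param gold_n compounds in the gold DILI set
#' @param pk_n compounds per Cmax target
#' @param noise_rate per-endpoint label flip probability (in [0, 0.5))
#' @param conflict_rate fraction of endpoint records duplicated with a
#'   conflicting label
#' @param salt_rate fraction of library records decorated with a counterion
#' @param stereo_rate fraction of eligible records written with an
#'   explicit stereocenter
#' @return object of class GenerativeSpec
#' @export
generative_spec <- function(seed = 1L, n_per_endpoint = 140L, gold_n = 180L,
                            pk_n = 140L, noise_rate = 0.10,
                            conflict_rate = 0.05, salt_rate = 0.10,
                            stereo_rate = 0.15) {
  stopifnot(noise_rate >= 0, noise_rate < 0.5, conflict_rate >= 0,
            conflict_rate <= 1, salt_rate >= 0, salt_rate <= 1)
  endpoints <- c("human_hepatotoxicity", "animal_hepatotoxicity_A",
                 "animal_hepatotoxicity_B", "preclinical_hepatotoxicity",
                 "diverse_dili_A", "diverse_dili_C", "BSEP", "Mitotox",
                 "reactive_metabolite")
  signal_map <- list(
    human_hepatotoxicity = 1L, animal_hepatotoxicity_A = 2L,
    animal_hepatotoxicity_B = c(2L, 3L),
    preclinical_hepatotoxicity = c(1L, 2L),
    diverse_dili_A = c(1L, 3L), diverse_dili_C = c(1L, 4L),
    BSEP = 4L, Mitotox = c(4L, 5L), reactive_metabolite = 5L
  )
  gold_rule <- list(
    intercept = -1.5,
    endpoint_weights = c(human_hepatotoxicity = 1.0,
                         preclinical_hepatotoxicity = 0.7,
                         diverse_dili_A = 0.7, diverse_dili_C = 0.7,
                         animal_hepatotoxicity_A = 0.7,
                         animal_hepatotoxicity_B = 0.7, BSEP = 0.8,
                         Mitotox = 0.7, reactive_metabolite = 0.9),
    alert_toxicophore = 6L, # epoxide enters the rule directly
    alert_weight = 2.0,
    cmax_weight = -0.7 # risk falls with pMolar (lower exposure)
  )
  cmax_rule <- list(intercept = 5.0, logp = -0.45, tpsa_per100 = -0.8,
                    sigma = 0.35)
  structure(
    list(seed = as.integer(seed), n_per_endpoint = as.integer(n_per_endpoint),
         gold_n = as.integer(gold_n), pk_n = as.integer(pk_n),
         noise_rate = noise_rate, conflict_rate = conflict_rate,
         salt_rate = salt_rate, stereo_rate = stereo_rate,
         endpoints = endpoints, signal_map = signal_map,
         gold_rule = gold_rule, cmax_rule = cmax_rule,
         toxicophores = toxicophores()),
    class = "GenerativeSpec"
  )
}

#' Generate the compound library from the fragment grammar
#'
#' Enumerates every scaffold-template x substituent combination (slot A
#' holds the plain substituents and the six toxicophores, slot B the
#' decorators; the slots use disjoint lists so no two combinations collide
#' into the same molecule), then applies seeded decoration: counterions at
#' \code{salt_rate} and explicit stereocenters at \code{stereo_rate} on the
#' eligible substituent. Deterministic under the spec seed.
#'
#' @param spec GenerativeSpec
#' @return data.frame(lib_id, smiles, base_smiles, salted, stereo) with a
#'   \code{tox} attribute: library x toxicophore indicator matrix
#' @export
generate_library <- function(spec) {
  tox <- spec$toxicophores
  slot_a <- c(grammar_substituents_a(), tox$substituent)
  slot_b <- grammar_substituents_b()
  combos <- expand.grid(tpl = grammar_templates(), a = slot_a, b = slot_b,
                        stringsAsFactors = FALSE)
  smiles <- sprintf(combos$tpl, combos$a, combos$b)
  n <- length(smiles)
  tox_mat <- matrix(0L, n, nrow(tox),
                    dimnames = list(NULL, tox$name))
  for (k in seq_len(nrow(tox))) {
    tox_mat[combos$a == tox$substituent[k], k] <- 1L
  }
  lib <- with_seed(spec$seed + 101L, {
    salted <- stats::runif(n) < spec$salt_rate
    ion <- sample(c(".Cl", ".[Na+]"), n, replace = TRUE)
    stereo_ok <- combos$a == "C(C)O"
    stereo <- stereo_ok & stats::runif(n) < spec$stereo_rate
    flavor <- sample(c("[C@H](C)O", "[C@@H](C)O"), n, replace = TRUE)
    out <- smiles
    out[stereo] <- sprintf(combos$tpl[stereo], flavor[stereo],
                           combos$b[stereo])
    out[salted] <- paste0(out[salted], ion[salted])
    data.frame(lib_id = seq_len(n), smiles = out, base_smiles = smiles,
               salted = salted, stereo = stereo, stringsAsFactors = FALSE)
  })
  attr(lib, "tox") <- tox_mat
  lib
}

#' Assign endpoint, gold and Cmax labels over the library
#'
#' Each proxy endpoint samples its member compounds (creating realistic
#' partial overlap between endpoints), labels them
#' indicator(any mapped toxicophore) XOR Bernoulli(noise_rate), and then
#' duplicates \code{floor(conflict_rate * n)} members as variant records
#' with the opposite label (the planted conflicts). The gold label is
#' Bernoulli(logistic(intercept + sum of endpoint-latent weights + direct
#' alert)); gold records are emitted in DILIst/DILIrank form. Cmax values
#' are a linear function of logP and TPSA plus Gaussian noise, in pMolar.
#'
#' @param lib library from [generate_library()]
#' @param spec GenerativeSpec
#' @param physchem physchem15 matrix row-aligned with \code{lib} (columns
#'   TPSA and MolLogP are used for the Cmax rule)
#' @return list(proxies_raw, gold_raw = list(dilist, dilirank), pk_raw,
#'   conflicts, latent)
#' @export
assign_endpoint_labels <- function(lib, spec, physchem) {
  tox_mat <- attr(lib, "tox")
  n <- nrow(lib)
  stopifnot(nrow(physchem) == n)
  ep_indicator <- sapply(spec$endpoints, function(e) {
    as.integer(rowSums(tox_mat[, spec$signal_map[[e]], drop = FALSE]) > 0)
  })
  proxies_raw <- list()
  conflicts <- list()
  with_seed(spec$seed + 202L, {
    for (e in spec$endpoints) {
      members <- sort(sample.int(n, spec$n_per_endpoint))
      flips <- stats::rbinom(length(members), 1, spec$noise_rate)
      label <- as.integer(xor(ep_indicator[members, e] == 1, flips == 1))
      df <- data.frame(lib_id = members, smiles = lib$smiles[members],
                       label = label, stringsAsFactors = FALSE)
      n_conf <- floor(spec$conflict_rate * nrow(df))
      if (n_conf > 0) {
        pick <- sort(sample.int(nrow(df), n_conf))
        dup <- df[pick, , drop = FALSE]
        dup$smiles <- paste0(lib$base_smiles[dup$lib_id], ".Cl")
        dup$label <- 1L - dup$label
        conflicts[[e]] <- data.frame(endpoint = e, lib_id = dup$lib_id,
                                     smiles_a = df$smiles[pick],
                                     smiles_b = dup$smiles,
                                     stringsAsFactors = FALSE)
        df <- rbind(df, dup)
      }
      proxies_raw[[e]] <- df
    }
  })
  # gold rule on the endpoint latents, one direct structural alert, and
  # the (standardized) Cmax latent -- the physicochemical signal axis
  gr <- spec$gold_rule
  cm <- spec$cmax_rule
  cmax_latent <- cm$intercept + cm$logp * physchem[, "MolLogP"] +
    cm$tpsa_per100 * physchem[, "TPSA"] / 100
  cmax_std <- (cmax_latent - mean(cmax_latent)) /
    max(stats::sd(cmax_latent), 1e-8)
  eta <- gr$intercept +
    as.vector(ep_indicator[, names(gr$endpoint_weights)] %*%
                gr$endpoint_weights) +
    gr$alert_weight * tox_mat[, gr$alert_toxicophore] +
    gr$cmax_weight * cmax_std
  gold <- with_seed(spec$seed + 303L, {
    members <- sort(sample.int(n, spec$gold_n))
    p <- stats::plogis(eta[members])
    label <- stats::rbinom(length(members), 1, p)
    split <- stats::runif(length(members)) < 0.7
    dilist <- data.frame(lib_id = members[split],
                         smiles = lib$smiles[members[split]],
                         label = label[split], stringsAsFactors = FALSE)
    rank_members <- members[!split]
    rank_label <- label[!split]
    cat_label <- ifelse(rank_label == 1,
                        sample(c("vMost", "vLess"), length(rank_label),
                               replace = TRUE), "vNo")
    # a few Ambiguous rows that assemble_gold must drop
    amb <- sample.int(n, max(3L, round(0.03 * spec$gold_n)))
    dilirank <- data.frame(
      lib_id = c(rank_members, amb),
      smiles = lib$smiles[c(rank_members, amb)],
      label = c(cat_label, rep("Ambiguous", length(amb))),
      stringsAsFactors = FALSE)
    list(dilist = dilist, dilirank = dilirank, members = members,
         label = label)
  })
  base_val <- cmax_latent
  pk_raw <- with_seed(spec$seed + 404L, {
    lapply(c(cmax_unbound = 1L, cmax_total = 2L), function(i) {
      members <- sort(sample.int(n, spec$pk_n))
      data.frame(lib_id = members, smiles = lib$smiles[members],
                 label = base_val[members] +
                   stats::rnorm(length(members), 0, cm$sigma),
                 stringsAsFactors = FALSE)
    })
  })
  list(proxies_raw = proxies_raw, gold_raw = gold, pk_raw = pk_raw,
       conflicts = do.call(rbind, c(conflicts, list(NULL))),
       latent = list(ep_indicator = ep_indicator, gold_eta = eta))
}

#' Machine-readable answer key for a generated panel
#'
#' @param spec GenerativeSpec
#' @param lib library from [generate_library()]
#' @param labels result of [assign_endpoint_labels()]
#' @return list with the planted toxicophores, per-compound latent
#'   indicators, true Cmax coefficients, gold rule, and conflict pairs
#' @export
ground_truth_manifest <- function(spec, lib, labels) {
  list(
    toxicophores = spec$toxicophores,
    tox_indicators = attr(lib, "tox"),
    ep_indicator = labels$latent$ep_indicator,
    gold_rule = spec$gold_rule,
    cmax_rule = spec$cmax_rule,
    conflicts = labels$conflicts,
    signal_map = spec$signal_map
  )
}

#' Generate, standardize, label and assemble a complete fixture panel
#'
#' Runs the whole upstream pipeline on the synthetic world: grammar
#' library, standardization, featurization, label assignment, per-endpoint
#' deduplication, gold assembly from the DILIst/DILIrank-form records,
#' leak-checked panel construction, and feature-mask fitting on the union
#' of proxy compounds (the reference set).
#'
#' @param spec GenerativeSpec
#' @param std optional pre-computed result of
#'   \code{standardize_compounds(generate_library(spec)$smiles)} to reuse
#'   across seeds when the library is seed-invariant
#' @param feats optional pre-computed featurization of \code{std}
#' @return list(spec, lib, std, feats, manifest, panel, masks, chem_for)
#'   where chem_for(keys) returns the masked chemical blocks for any key14
#'   subset
#' @export
prepare_fixture <- function(spec, std = NULL, feats = NULL) {
  lib <- generate_library(spec)
  if (is.null(std)) std <- standardize_compounds(lib$smiles)
  if (any(std$rejected)) {
    stop("synthetic grammar produced ", sum(std$rejected),
         " rejected SMILES; spec invalid")
  }
  if (is.null(feats)) feats <- featurize_compounds(std$smiles_ph7)
  labels <- assign_endpoint_labels(lib, spec,
                                   feats$blocks$physchem15$matrix)
  manifest <- ground_truth_manifest(spec, lib, labels)

  key_of <- std$key14
  as_std_records <- function(df) {
    data.frame(key14 = key_of[df$lib_id],
               smiles_std = std$smiles_std[df$lib_id],
               smiles_ph7 = std$smiles_ph7[df$lib_id],
               label = df$label, stringsAsFactors = FALSE)
  }
  proxies <- lapply(names(labels$proxies_raw), function(e) {
    deduplicate(as_std_records(labels$proxies_raw[[e]]),
                policy = "prefer_active", name = e)
  })
  names(proxies) <- names(labels$proxies_raw)
  gold <- assemble_gold(as_std_records(labels$gold_raw$dilist),
                        as_std_records(labels$gold_raw$dilirank))
  pk <- lapply(names(labels$pk_raw), function(e) {
    deduplicate(as_std_records(labels$pk_raw[[e]]),
                policy = "median_numeric", name = e)
  })
  names(pk) <- names(labels$pk_raw)
  panel <- build_panel(gold, proxies, pk)

  # reference set for all selection state: union of post-removal proxy
  # compounds (never the gold set)
  ref_keys <- sort(unique(unlist(lapply(panel$proxies,
                                        function(d) d$data$key14))))
  ref_idx <- match(ref_keys, key_of)
  subset_blocks <- function(idx) {
    list(
      morgan = feature_block("morgan",
                             feats$blocks$morgan$matrix[idx, , drop = FALSE]),
      maccs = feature_block("maccs",
                            feats$blocks$maccs$matrix[idx, , drop = FALSE]),
      descriptors = feature_block(
        "descriptors",
        feats$blocks$descriptors$matrix[idx, , drop = FALSE],
        catalogue_version = feats$blocks$descriptors$catalogue_version),
      physchem15 = feature_block(
        "physchem15", feats$blocks$physchem15$matrix[idx, , drop = FALSE])
    )
  }
  masks <- fit_feature_masks(subset_blocks(ref_idx))
  chem_for <- function(keys) {
    idx <- match(keys, key_of)
    if (any(is.na(idx))) stop("unknown key14 in chem_for()")
    apply_feature_masks(subset_blocks(idx), masks)
  }
  list(spec = spec, lib = lib, std = std, feats = feats,
       manifest = manifest, labels = labels, panel = panel, masks = masks,
       chem_for = chem_for)
}
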