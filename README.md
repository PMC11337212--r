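# dilinet

Stacked proxy-endpoint models for predicting drug-induced liver injury
(DILI) from chemical structure.

## The problem

DILI is a leading cause of acute liver failure and of late-stage drug
attrition, and it is hard to predict from structure alone: the human
outcome aggregates several mechanisms (bile salt export pump inhibition,
mitochondrial dysfunction, reactive metabolite formation), species
differences, and exposure. In vitro and preclinical in vivo assays each
capture a slice of this risk — but for a new compound none of that data
exists yet.

`dilinet` implements a two-level stacked ("FeatureNet") pipeline that
needs only SMILES as input:

- **Level 1** — random-forest classifiers for nine binary *proxy-DILI*
  endpoints (human / animal / preclinical hepatotoxicity, two diverse
  DILI collections, BSEP inhibition, mitochondrial toxicity, reactive
  metabolite formation) and random-forest regressors for plasma Cmax
  (total and unbound, pMolar), all trained on chemical features.
- **Level 2** — a DILI classifier over the eleven level-1 predictions
  plus masked structural fingerprints (Morgan 2048 bits radius 2 +
  166 MACCS keys = 2,214 bits before selection), the masked 2D
  descriptor catalogue, and 15 physicochemical parameters.

The level-2 decision threshold maximizes Youden's J
(J = sensitivity + specificity − 1) on out-of-fold probabilities only.
Evaluation is scaffold-aware (Butina sphere-exclusion clustering on
Tanimoto distance, cutoff 0.70, whole clusters assigned to one side) and
reports the full panel — BA, MCC, F1, PPV, LR+ = sens/(1 − spec), AP,
AUC-ROC — plus top-k detection curves for the low-false-positive-rate
regime. Per-compound tree-path attribution explains each prediction as
additive feature contributions and maps the top MACCS key back to atoms.

Chemistry primitives (standardization, pH-7 protonation, InChIKey hash
layer, fingerprints, descriptors) run through a bundled RDKit batch
backend (`inst/python/chem_backend.py`); the tree ensemble is the
package's own Rcpp CART learner.

## Worked example

Train the full pipeline on the package's self-contained synthetic world
(planted toxicophores, label noise, salts, conflicts), then predict and
explain a compound:

```r
library(dilinet)

run <- signal_recovery_run(seed = 7)   # generates panel, trains 9+2
                                       # level-1 models, Butina-splits the
                                       # gold set, nested-CV + final model
run$auc_all; run$auc_structural
#> [1] 0.7370707
#> [1] 0.6882828

final <- run$final
out <- predict_dili(final, c("c1ccc([N+](=O)[O-])cc1CCl", "C1CC"))
out$results[, c("smiles_std", "probability", "call", "reject_reason")]
#>                  smiles_std probability call reject_reason
#> 1 O=[N+]([O-])c1cccc(CCl)c1   0.4751879    1          none
#> 2                      <NA>          NA   NA parse_failure
```

The first compound carries the planted nitro toxicophore and is called
toxic (probability 0.475, above this run's Youden-calibrated threshold —
the synthetic gold set is one-third positive, so the calibrated cutoff
sits well below 0.5); the second is
an unparseable SMILES and is rejected with a reason instead of crashing.
Attribution (`attribute_prediction()`) then reports the top
positively/negatively contributing proxy endpoints and highlights the
MACCS substructure with the largest positive contribution.

A quick metric check on the worked detection example (25 true and 4
false positives among the top 29 calls on a 156/67 test set):

```r
labels <- rep(c(1, 0), c(156, 67))
probs <- c(rep(.99, 25), rep(.01, 131), rep(.99, 4), rep(.01, 63))
r <- lr_plus_at_topk(probs, labels, 29)
c(lr_plus = r$lr_plus, ppv = r$ppv)
#>  lr_plus      ppv
#> 2.684295 0.862069
```

## Layout

- `R/` — chemprep, featurization, data model/panel, Butina splitting,
  Rcpp forest wrapper, level-1 endpoint models, level-2 FeatureNet,
  evaluation, synthetic fixtures, recovery experiments.
- `src/forest.cpp` — CART forest (fit / predict / path attribution).
- `inst/python/chem_backend.py` — RDKit batch backend.
- `inst/extdata/pka_rules.csv` — versioned pH-7 protonation rule table.
- `inst/cli/dilinet` — command-line interface (`standardize`,
  `featurize`, `split`, `make-fixtures`, `train`, `predict`, `explain`,
  `evaluate`).
- `vignettes/dilinet-methods.Rmd` — model, assumptions, parameter and
  design rationale, synthetic-world notes, limitations.
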