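---
title: "dilinet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dilinet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Drug-induced liver injury (DILI) is a leading cause of clinical-trial
failure and post-market withdrawal, and it is poorly predicted from
chemical structure alone: the label is an organ-level human outcome
influenced by multiple mechanisms (bile salt export pump inhibition,
mitochondrial dysfunction, reactive metabolite formation), species
differences, and exposure. `dilinet` implements a two-level stacked
("FeatureNet") strategy:

1. **Level 1.** Nine random-forest classifiers are trained on binary
   *proxy* endpoints — in vivo hepatotoxicity readouts (human, two animal
   panels, preclinical), two heterogeneous DILI collections, and three
   mechanism assays (BSEP inhibition, mitochondrial toxicity, reactive
   metabolite formation) — and two random-forest regressors on plasma
   Cmax (total and unbound, pMolar scale). All level-1 models see only
   chemical features.
2. **Level 2.** A DILI classifier is trained on the gold-standard DILI
   set (DILIst plus DILIrank) using the eleven level-1 predictions as
   features, alongside the masked structural fingerprints (Morgan 2048
   bits, radius 2, plus 166 MACCS keys), the masked bulk 2D descriptor
   catalogue, and 15 physicochemical parameters.

The rationale is sample efficiency: each proxy endpoint distils its own
(larger) training corpus into a single calibrated probability, so the
small gold set only needs to learn how to weigh eleven informative
columns instead of re-estimating every substructure effect from scratch.

All models are bagged CART ensembles implemented in the package's own
C++ learner (the runtime environment ships no R tree package).
Classification probabilities are averaged leaf class fractions;
attribution uses tree-path (Saabas) contributions, which are additive by
construction — `base + sum(contributions) == prediction` to floating
point — and are the tree-path analogue of the SHAP-style per-compound
explanations used for this class of model.

## Preprocessing

Raw SMILES pass a two-stage filter — filtering runs twice because salt
stripping changes the molecular weight: parse-level rejection of
unparseable, metal-only, and carbon-free records, then an iterated
standardization sequence — metal disconnection, normalization,
reionization, principal-fragment selection, uncharging, most-common
isotope, stereochemistry removal, tautomer canonicalization — applied up
to five times or until the canonical SMILES is a fixpoint (no fixpoint:
most frequent iterate, ties lexicographically smallest). After
standardization, structures whose principal fragment exceeds 1500 Da
(strictly greater) are rejected, as are multi-fragment records whose
largest organic fragment is ambiguous (a heavy-atom tie between two
*distinct* fragments; identical tied fragments are kept, as a doubled
record is not ambiguous).

Protonation at liver pH (7.0) is a rule-based pKa-substructure table
bundled at `inst/extdata/pka_rules.csv` (acids with pKa < 7
deprotonated, bases with pKa > 7 protonated; the table also records
groups deliberately left untouched, such as phenols and anilines). The
stage is on by default and can be disabled, in which case a warning is
emitted and downstream steps use the neutral form.

Compound identity is the 14-character InChIKey connectivity ("hash")
layer, computed on the protonated form; it is insensitive to
stereochemistry, isotopes and (for the chemistry exercised here)
protonation state, which the tests assert. Duplicates are grouped by
this key: conflicting binary labels resolve to toxic/active (the field's
usual preference for positive evidence), numeric duplicates to their
median.

## Features and selection

Four blocks per compound: Morgan (2048 bits, radius 2), MACCS (166
keys), the full 2D descriptor catalogue of the bundled RDKit backend
(about 210 descriptors; the catalogue version is recorded in every
persisted block — descriptor counts are version-dependent and treated as
report values, not invariants), and a fixed panel of 15 physicochemical
parameters. "Assembled rings" is implemented as the number of fused ring
systems.

Selection state is fitted **only** on the proxy-endpoint reference panel
(never the gold set, to avoid leaking test-set statistics): descriptors
with any non-finite value on the reference set are dropped for all
compounds (new compounds with a non-finite value in a surviving
descriptor get the reference median, counted and flagged); variance
masks use population (divide-by-n) variance with a strictly-greater
comparison at thresholds 0.05 (Morgan), 0.10 (MACCS), 0.10
(descriptors). The physchem15 block is never masked. Tree ensembles are
scale-invariant, so no feature scaling is applied anywhere.

## Splitting and evaluation

The gold set is split scaffold-aware: Butina sphere-exclusion clustering
on Tanimoto **distance** (1 − similarity) over the 2048-bit fingerprints
at cutoff 0.70 — distance, not similarity, being the convention of the
reference scaffold splitter and the most common reproduction mistake —
then whole clusters are assigned to the training side largest-first
(ties by lower cluster id) until it holds 1 − `test_fraction` of the
compounds. Structural novelty of a held-out compound is summarized as
the mean Tanimoto similarity to its three nearest training neighbours.

The metric panel is sensitivity, specificity, balanced accuracy, MCC,
F1, PPV, LR+ (sensitivity / (1 − specificity)), average precision, and
AUC-ROC (computed as the normalized Mann–Whitney statistic with midrank
ties). Undefined quantities are flagged and serialize as JSON `null`,
never silently 0, because silent zeros corrupt model rankings. Top-k
detection metrics call the k highest-probability compounds positive,
with ties broken by stable input order (documented because it changes
TP/FP at small k).

## Training protocol

Level-1 models use successive-halving random search (the published grid
is unavailable; the stand-in space is `default_search_space()` — trees
{100, 300, 500, 1000}, depth {unlimited, 8, 16, 32}, min leaf {1, 3, 5,
10}, feature fraction {sqrt, 0.3, 0.5}, class weight {none, balanced} —
and is recorded in every model's metadata), scored by stratified 5-fold
CV AUC (classifiers) or R² (regressors), starting at 1/8 of the rows and
doubling while halving the candidate set; the winner is refit on all
rows. Decision thresholds maximize Youden's J over the midpoints of
consecutive sorted unique out-of-fold probabilities (plus 0 and 1), ties
to the smallest threshold; a probability exactly at the threshold is a
positive call (stated because it changes confusion counts). Seeds fan
out from one master seed through a fixed hash of the endpoint name.

The level-2 protocol is repeated nested cross-validation: 5 stratified
outer folds, inner 4-fold halving search, threshold from inner
out-of-fold probabilities only, evaluation on the outer fold; the whole
setup repeated (10 repeats in the production configuration, i.e. 50
evaluations — the source material variously implies 50 or 55; 5 × 10 =
50 is the arithmetic this package follows). The final model takes the
configuration from the repeat with the highest mean outer AUC, refits on
all training rows, and derives its threshold from fresh 4-fold
out-of-fold probabilities, never from test data; those probabilities are
persisted so the threshold is reproducible from stored state.

Proxy features are continuous probabilities rather than thresholded
calls: probabilities carry strictly more information, and the
released-tool behaviour this package mirrors uses them. A leak guard at
stacking time errors if any input compound's key appears in a *binary*
proxy model's training set; the Cmax regressors are exempt because
overlap with gold is only removed for the nine binary labels.

## The synthetic world

Everything is testable offline through a generative specification
(`generative_spec()`): a fragment grammar of 6 scaffold templates × 18
slot-A substituents (12 of them the planted toxicophores: nitro,
sulfonamide, hydrazine, furan, thiourea, epoxide, plus 6 plain) × 10
slot-B decorators, enumerating 1080 valid molecules. The two slots use
disjoint substituent lists so symmetric ring positions can never make
two combinations collide into one molecule, which keeps the planted
conflict list exact. Decoration adds counterions (10%), explicit
stereocenters (15% of the eligible substituent), and per-endpoint
conflicting duplicate records (5%), all under named seed substreams.

Endpoint labels are `indicator(mapped toxicophore) XOR
Bernoulli(noise)`, with XOR noise (rate 0.10, a typical assay error
scale) chosen over class-imbalance noise so the noiseless limit is
exactly testable against a SMARTS matcher. The gold label is Bernoulli
of a logistic rule over the endpoint latents (weights 0.3–1.0 spread so
each toxicophore contributes a comparable effective weight of roughly
1.4–3.1), one direct structural alert (epoxide, weight 2.0), and the
standardized Cmax latent (weight −0.7): the Cmax axis routes part of the
label signal through physicochemistry (logP, TPSA), which fingerprints
cannot express — this is what makes the all-features variant genuinely
better informed than the structure-only variant, mirroring the
mechanism the stacked design exploits on real data. Cmax values are
`5.0 − 0.45·logP − 0.8·TPSA/100 + N(0, 0.35)` pMolar.

Default sizes (140 per proxy endpoint, 180 gold, 140 per Cmax target)
are desk-scale stand-ins for the real corpus (317–5,239 per endpoint,
1,111 gold): large enough for stratified 5-fold work, small enough that
the multi-seed recovery study runs in minutes. What a green test
establishes is therefore *mechanism recovery under the stated world* —
pipeline correctness, leak-freedom, stacking dominance when signal is
split across chemistry and endpoints, attribution pointing at planted
substructures — not the numerical performance of the published model,
which depends on its supplementary datasets and unpublished grid.
Features of real data the generator does not emulate: medicinal-chemistry
scale scaffold diversity, correlated assay batch effects, and
class-balance drift between sources.

The recovery experiments (`signal_recovery_study()`) disable salts,
stereo and conflicts so the library (and its standardization) is
seed-invariant and cacheable across seeds; those decorations are
exercised separately by the chemprep tests, and standardization
collapses them to the same keys anyway. Experiments use a fixed
mid-grid configuration (100 trees, balanced weights) and 2 nested-CV
repeats: the criterion under test is an ordering of variants, not a
tuned score, and the reduced budget keeps ten seeds inside the test-time
budget.

## Numerical and degenerate-input choices

- Fixpoint detection in standardization is exact string equality of
  canonical SMILES.
- Variance threshold comparison is strict (`>`); a variance exactly at
  the threshold drops the feature.
- `youden_threshold` on all-equal probabilities returns 0.5 with a
  warning; an anti-ranked input returns its best (zero-benefit)
  threshold with a `no_benefit` flag.
- Cohen's kappa with perfect expected agreement, and pairwise
  concordance with zero shared compounds, are reported as missing with a
  reason code, never 0.
- Two all-zero call vectors have Jaccard similarity defined as 1 with a
  flag.
- Tanimoto similarity between two all-zero fingerprints is defined as 0.
- `cluster_split` with a single cluster errors and advises a smaller
  cutoff; `nn_similarity_to_train` with k larger than the training set
  warns and uses all of it.

## Known limitations

- The descriptor catalogue is the bundled RDKit 2D list, not the larger
  catalogue used for the published counts; counts like "1,016 surviving
  descriptors" are catalogue-version-dependent by design.
- The pKa rule table is deliberately small and rule-based; it places the
  common ionizable groups but is not a microstate enumerator.
- No bootstrap confidence intervals or DeLong tests on the metric panel.
- Multitask learning, dose/time modelling, and the web interface are out
  of scope.
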