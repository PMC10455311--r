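---
title: "Predicting folding-rate effects of amino acid substitutions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting folding-rate effects of amino acid substitutions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the quantity modelled

Two-state folding proteins convert between the unfolded and native states
in a single cooperative step with rate constant $k_f$ (s$^{-1}$). A single
amino acid substitution perturbs this rate; the package models the log
rate change

$$\Delta \ln k_f \;=\; \ln k_f^{\mathrm{var}} - \ln k_f^{\mathrm{wt}},$$

both as a continuous regression target and as a three-class label
(*decrease* / *no effect* / *increase*) defined by a symmetric band of
half-width 0.15 around zero. Experimental $\Delta \ln k_f$ values span
roughly $-5$ to $+3$; the band width is a property of the curated
benchmark this methodology was developed on, and is configurable
(`threshold` argument throughout).

**Boundary convention.** The band is *closed*: $|\Delta \ln k_f| = 0.15$
exactly is labelled *no effect*. The literature leaves the boundary
unspecified; a closed band is the only choice under which the label is a
total, deterministic function of the delta, and it is applied identically
everywhere (loader, generator, tests).

# Feature representation (1161 features, six families)

| family | size | content |
|---|---|---|
| amino_acid | 688 | 553 per-residue index scales, encoded as value(var) − value(wt); 135 residue-pair potentials, encoded as the (wt, var) matrix entry |
| conservation | 3 | per-position conservation score + two coevolution summaries (max coupling, number of strong partners) |
| variation_type | 436 | one-hot (wt, var) cell of the 20×20 substitution matrix + one-hot cell of a 6×6 physicochemical-group matrix |
| neighborhood | 25 | proportions of the 20 residue types and of 5 residue classes in a 25-position window |
| protein_type | 1 | relative position, position/length ∈ (0, 1] |
| structural | 8 | 7-state secondary-structure one-hot + RSA = ASA/maxASA |

Decisions worth recording:

* **Single-index encoding.** How one value per index is derived from a
  residue pair is not standardised; the difference value(var) − value(wt)
  is used. It is zero only for wt = var (excluded by the data model), is
  antisymmetric under swapping the residues, and yields exactly one
  feature per scale, which is what the 688-feature arithmetic
  (553 + 135) requires.
* **Window of 25, proportions.** Published descriptions of this feature
  family conflict between a 23- and 25-position window and between counts
  and proportions; the selected-feature names ("window of 25 positions",
  "proportion of …") pin both down, so a 25-position window (half-width
  12, configurable) with proportions normalised by the *actual* window
  size is used. Normalising by actual size handles truncation at sequence
  ends without special cases.
* **Relative position.** Defined as position/length. The inverted ratio
  (length/position) appears in some descriptions but produces unbounded
  values ≥ 1 and contradicts the name; the conventional reading is taken
  deliberately.
* **Six-group partition.** The 6×6 matrix needs a 20-residue partition
  into six groups. Two cells are pinned by published feature names: g2
  must be {D, E} and g6 must contain {A, T}. The bundled partition is
  {I,L,M,V}, {D,E}, {F,W,Y}, {N,Q,S,C}, {H,K,R}, {A,G,P,T} — a standard
  physicochemical grouping consistent with those constraints. It is a
  configuration file (`inst/extdata/aa_groups6.tsv`), not code.
* **Conservation features.** The exact composition of the three
  conservation features in the original methodology is not published.
  The package consumes a per-position table (c_score, coev_max, coev_np)
  produced by external conservation/coevolution tools, and offers a
  clearly-labelled entropy fallback (`entropy_conservation()`). This is a
  stand-in by construction and is documented as such.
* **Index table.** The real amino-acid index database cannot be bundled;
  the default table is a seeded synthetic one (553 + 135 indices,
  symmetric pair matrices, `synthetic = TRUE` flag) whose identifiers
  include every index named in the published selected-feature lists, so
  those subsets resolve by name. Real flat files load via
  `read_aaindex()`.

## Accessible surface area

`compute_asa()` is a reference Shrake–Rupley implementation: each atom's
sphere (van der Waals radius + 1.4 Å probe) is sampled at a fixed number
of deterministic golden-spiral points and the unoccluded fraction scaled
to the expanded-sphere area. Before sampling, coordinates are
*canonicalised* — centred at the centroid and rotated onto the principal
axes of the coordinate covariance, with axis signs fixed by the third
moment (falling back to the largest-magnitude coordinate). Pairwise
geometry is unchanged, but the sphere-point orientation becomes a
function of the structure alone, so computed areas are **exactly
invariant to rigid-body motion** of the input (verified to 1e-6 in the
tests). The point count (default 240) trades accuracy for speed; the
two-atom analytic-cap oracle in the test suite bounds the discretisation
error at about 2%.

RSA divides by residue-type maxima from the bundled theoretical maxASA
table (Tien et al. 2013 values — the field-standard normalisation).
RSA can slightly exceed 1 for highly exposed conformations; it is not
clipped.

# Models

## Boosted-tree engine

No tree learner is available in the target environment, so the package
carries a minimal Newton-boosting GBDT (Rcpp): squared-error regression
and softmax multiclass objectives, exact greedy split search, L2
leaf regularisation ($\lambda = 1$), depth limit 5, minimum leaf size 5,
learning rate 0.1, and **no stochastic subsampling** — models are pure
functions of their inputs. Split ties are broken toward the lowest
feature index and first threshold scanned; voting and ranking ties are
likewise broken by fixed orders (class order *decrease, no_effect,
increase*; lexicographic feature names). Hyperparameters were fixed once
at these conventional defaults (they are unreported in the source
methodology) and are all exposed via `gbdt_params()`; no early stopping,
to keep training deterministic.

## The voting ensemble

Folding-rate datasets are heavily imbalanced (roughly 69% decrease / 18%
no effect / 13% increase). `train_classifier()` draws `n_models = 10`
independent balanced under-samples of `per_class = 80` variants per class
(sub-seeds derived from one master seed) and trains one sub-classifier on
each. Prediction uses *soft voting* — the normalised sum of sub-model
class probabilities — with majority voting available as an option. Soft
voting is the package's reading of "voting" in the source methodology,
chosen because it uses the calibrated information in the probabilities
and is deterministic without a tie-break in the generic case.

## Feature selection

`select_features()` implements performance-weighted importance ranking:
over $10 \times 5$ grouped cross-divisions (50 partitions), each
partition's model importances (total split gain by default; split counts
optional) are multiplied by that partition's test accuracy (Pearson
correlation for regression) and summed. For classification the training
side of each partition is balanced by under-sampling before fitting.
Nested subsets of increasing size along the ranking are then scored by
repeated grouped CV, and the size maximising the metric is chosen
(smaller size on ties). The source methodology describes both forward
("highest score selected") and backward ("dropping one feature at a
time") procedures; forward ranking matches its selection flowchart and is
the default, with backward elimination provided as `mode = "backward"`.
The magnitudes of published selection scores depend on the importance
units of the underlying library and are not comparable across
implementations; no attempt is made to match them.

# Evaluation

All partitioning — train/test splits, CV folds, selection partitions — is
**group-disjoint on (protein, position)**: all variants at the same site
stay together, preventing leakage through near-duplicate records.
`run_cv()` runs the 10×5 protocol and reports both per-fold metrics and a
pooled report (summed confusion counts for classification, concatenated
predictions for regression); pooling is the headline because it matches
the count-style presentation of published confusion summaries, and the
tests verify pooled metrics equal metrics on the concatenated
predictions.

Metrics follow the folding-prediction literature's naming: SPEC is
TP/(TP+FP) — mathematically *precision* — and SENS is TP/(TP+FN)
(*recall*); the report carries precision/recall aliases rather than
silently renaming published quantities. Accuracy for $K>2$ is read as
$\sum_i z_{ii}/N$ (the only multi-class reading consistent with the
published values, e.g. $(65+11+8)/190 = 0.442$ on the bundled blind-test
counts). GC2 is $\sum_{ij}(z_{ij}-e_{ij})^2/e_{ij}\,/\,N(K-1)$ with
$e_{ij} = x_i y_j/N$; it is 1 on a perfect diagonal, 0 when observed
equals expected, and reduces to the squared $\phi$ coefficient for
$K = 2$ (all verified in tests). Metrics with zero denominators are
reported as `NA` with an `undefined` flag, never coerced to 0; a
confusion summary reconstructed from per-class counts
(`confusion_from_perclass()`) has under-determined off-diagonals for
$K = 3$, so GC2 is flagged undefined there. The normalised
"imbalance-mitigated" companion values printed alongside some published
confusion tables have no stated formula and are out of scope.

# The synthetic world

`generate_dataset()` emulates the benchmark the methodology was built on:
by default 952 variants in 25 proteins (lengths 60–120), class
proportions 653:175:124, band ±0.15, and noise $\sigma = 0.1$. Sequences
are uniform-random over the 20 residues (an alanine-enriched option
mirrors the alanine-scanning bias of real folding data); secondary
structure is drawn in runs; ASA is uniform under each residue's maximum
(so RSA is uniform on [0, 1]); conservation and coevolution annotations
are random. The planted signal is linear in a small set of named features
(default weights on rsa, C-score, rp and window_NonPolarAA), standardised
over the generated variants, plus Gaussian noise.

The mapping to $\Delta \ln k_f$ is calibrated affinely so that the
empirical $p_{\mathrm{dec}}$ and $1-p_{\mathrm{inc}}$ quantiles of the
signal-plus-noise sum land exactly on the band edges — realised class
proportions then match the stated ones up to order statistics, which is
the generator's contract (the tests check a 3-standard-deviation
multinomial bound). Wild-type rates are drawn log-uniform over
$10^{-3}$–$10^{5}$ s$^{-1}$ and variant rates set to
$k_f^{\mathrm{wt}} e^{\Delta}$, so labels regenerate identically from
either the stored deltas or the rate pairs.

**What a green test does and does not establish.** The generator plants
*statistical* structure, not folding physics: features are mutually
independent apart from the planted linear combination, annotations carry
no real evolutionary or structural correlations, and the signal is
noiseless linear where real folding effects are epistatic and noisy.
Green recovery tests therefore establish that the pipeline *can* extract
a signal it is pointed at and that nothing leaks across the grouped
partitions — not that the trained models are biophysically accurate.
Headline benchmark figures (CV PCC ≈ 0.52, blind-test PCC ≈ 0.33 on the
real data) require the external benchmark download and unreported seeds
and are deliberately not asserted; the acceptance layer replaces them
with planted-signal recovery, permutation null controls, and metric-layer
exactness against the bundled published confusion counts.

**Scaling.** The acceptance checks run the selection-recovery experiment
with 2×5 ranking partitions and 1×5 subset CV rather than the full
10×5/10×5 protocol, and 400-variant datasets rather than 952 — a
deliberate desk-hardware scaling, stated here once; thresholds are
unchanged.

# Known limitations

* The bundled index table is synthetic; predictions with it are only as
  meaningful as the planted benchmark. Real applications must supply the
  genuine index database, conservation and structure annotations.
* The published lists of selected features for the two tasks share ten
  names as printed, while the accompanying prose says nine; the package
  transcribes the tables and computes ten.
* The GBDT engine is exact-greedy and single-threaded; it is sized for
  benchmark-scale data (~10³ variants × ~10³ features), not for
  large-scale screens.
* `confusion_from_perclass()` cannot recover off-diagonal confusion cells
  for three classes; GC2 from per-class counts is undefined by
  construction.
* The no-effect class sits in a narrow band between the other two; under
  label noise near the boundaries its per-class metrics are intrinsically
  unstable, on synthetic and real data alike.
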