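# foldvar

Machine-learning prediction of how single amino acid substitutions change
the **folding rate of two-state folding proteins**.

Most small single-domain proteins fold in a single cooperative step with a
rate constant k<sub>f</sub> (s⁻¹). A point substitution can speed folding
up, slow it down, or leave it untouched, and the effect is summarised by
the log rate change

```
Δln kf = ln kf(variant) − ln kf(wild type)
```

`foldvar` provides two predictors over this quantity, for protein
scientists and variant-effect tool builders:

* a **three-class classifier** — *decrease* / *no effect* / *increase*,
  defined by a closed band of ±0.15 on Δln k<sub>f</sub> — built as a
  voting ensemble of ten gradient-boosted tree sub-models, each trained on
  a class-balanced under-sample (80 variants per class by default) to cope
  with the strong imbalance of experimental folding datasets;
* a **regression predictor** of Δln k<sub>f</sub> itself.

Variants are represented by **1161 features in six families**: 688
amino-acid index features (553 per-residue scales as variant−wild-type
differences plus 135 residue-pair potentials), 3 conservation features
(conservation score and two coevolution summaries), 436 substitution-type
one-hot indicators (20×20 residue matrix plus a 6×6 physicochemical-group
matrix), 25 sequence-window composition proportions (20 residue types + 5
classes, 25-position window), 1 relative sequence position, and 8
structural features (7-state secondary structure one-hot plus relative
solvent accessibility RSA = ASA/maxASA). A reference Shrake–Rupley ASA
routine is included for when only PDB coordinates are available.

Around the predictors the package implements the full supporting
methodology:

* leakage-safe data handling: variants sharing a (protein, position) group
  are never split across train and test sides;
* **weighted-importance feature selection**: feature importances from
  models trained on repeated grouped cross-divisions are weighted by each
  division's test accuracy (classification) or Pearson correlation
  (regression), summed into one ranking, and nested subsets are scored by
  repeated cross-validation; the published 31-feature (classification) and
  21-feature (regression) subsets are bundled and resolvable by name;
* the evaluation metric suite: per-class SPEC/SENS/F1 (precision/recall
  aliases included), accuracy, macro-F1, the generalized squared
  correlation GC2 ∈ [0,1], and PCC/MAE/MSE/R² for regression;
* a **synthetic benchmark generator** that plants a known linear
  feature→Δln k<sub>f</sub> signal in fully synthetic proteins,
  annotations and rates, so the entire pipeline is testable offline;
* a command-line interface (`exec/foldvar`) with `train`, `predict`,
  `evaluate`, `select-features`, `simulate` and `summarize` subcommands.

Because no gradient-boosting library is assumed, the package ships its own
small deterministic Newton-boosting tree engine (Rcpp): exact greedy
splits, L2-regularised leaves, softmax multiclass, gain/split-count
importances. Identical inputs always produce identical models.

## Worked example

Generate a synthetic benchmark, train the voting ensemble on the published
31-feature subset, and evaluate on a group-disjoint held-out split:

```r
library(foldvar)

bench <- generate_dataset(synthetic_spec(n_variants = 400,
                                         n_proteins = 12, seed = 11))
bench$dataset
#> <variant_dataset: 400 variants in 12 proteins>
#>   decrease 274 | no_effect 74 | increase 52 (|delta| band 0.15)

x  <- select_named_subset(bench$features, selected_features("classification"))
sp <- grouped_split(bench$dataset, test_fraction = 0.3, seed = 2)

ens <- train_classifier(x[sp$train_indices, ],
                        bench$dataset$records$label[sp$train_indices],
                        per_class = 25, seed = 4,
                        params = gbdt_params(n_rounds = 40))
pred <- predict(ens, x[sp$test_indices, ], type = "class")
classification_metrics(bench$dataset$records$label[sp$test_indices], pred)
#> <metric_report: classification>
#>      class TP TN FP FN  SPEC  SENS    F1
#>   decrease 71 36  6  7 0.922 0.910 0.916
#>  no_effect  5 87 13 15 0.278 0.250 0.263
#>   increase 16 89  9  6 0.640 0.727 0.681
#>      ACC macro_F1      GC2
#>    0.767    0.620    0.343
```

Reading the report: SPEC is TP/(TP+FP) (precision) and SENS is TP/(TP+FN)
(recall) per class; ACC is the fraction of correct labels; GC2 is a
χ²-normalised association measure (0 = independence, 1 = perfect
association). The synthetic signal is planted mostly in solvent
accessibility, conservation and sequence position, so the majority
*decrease* class is recovered well while the narrow *no effect* band —
exactly as with real folding data — is hardest.

The same pipeline runs from the shell:

```sh
foldvar simulate --n-variants 400 --n-proteins 12 --seed 11 --out-dir fix/
foldvar train    --variants fix/variants.tsv --fasta fix/proteins.fasta \
                 --structural fix/structural.tsv --conservation fix/conservation.tsv \
                 --task classify --subset table2_31 --per-class 25 \
                 --seed 4 --out-dir run/
foldvar predict  --model run/model --variants fix/variants.tsv \
                 --fasta fix/proteins.fasta --structural fix/structural.tsv \
                 --conservation fix/conservation.tsv --out run/pred.tsv
```

## Notes

* The bundled amino-acid index table is a deterministic **synthetic
  stand-in** (flagged as such): the real index database is not
  redistributable here. `read_aaindex()` ingests the standard H/I/M
  flat-file format if you have it.
* Conservation/coevolution and secondary-structure annotations are
  consumed from TSV tables produced by external tools; a Shannon-entropy
  fallback (`entropy_conservation()`) and an internal ASA computation
  (`compute_asa()`) are provided.
* See `vignettes/methods.Rmd` for the model, its assumptions, parameter
  choices and known limitations.
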