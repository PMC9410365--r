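# finclass

Classifying fish species in unconstrained underwater imagery runs into
two walls at once: the available labeled datasets are small and heavily
imbalanced (majority species outnumber minority species by up to three
orders of magnitude), and many species are congeners that share coarse
appearance, so the discriminative signal is fine-grained. `finclass` is
an R toolkit for two complementary strategies against those walls:

1. **Flat classification with targeted data augmentation.** One N-way
   softmax head over all species, trained by transfer learning on a
   pluggable feature trunk. During training the package tracks the
   train and validation loss curves *per class*; a class whose
   validation curve sits persistently above its train curve (windowed
   mean of max(0, ℓ_val − ℓ_train) above a threshold) is overfitting
   for lack of representative data, and only those flagged classes get
   their training data enlarged — by horizontal flips, rescaling
   (tinier/larger), central crops and ±10°/±20° rotations, one variant
   per transform.

2. **Hierarchical, taxonomy-driven classification.** A tree of
   classifiers over a shared trunk: a root node assigns the family
   (softmax over families, cross-entropy loss), then the feature maps
   are routed to that family's leaf node, which assigns the species.
   Training is staged — root first (after which the trunk is frozen),
   then each leaf independently — and confusable families carry an
   extra leaf class `Others` that absorbs samples routed in by root
   mistakes; a leaf answering `Others` yields the reserved `REJECT`
   label.

Evaluation uses the field's two standard summaries: per-class precision
P_i = TP_i/(TP_i+FP_i), their unweighted mean **AP** (macro), and the
micro accuracy **AC** = ΣTP_i / Σ(TP_i+FP_i).

Everything is testable at desk scale: a bundled generator builds
taxonomy-structured synthetic image datasets (family = silhouette shape
and hue band; species = saturation/brightness, stripes, texture) with
underwater-style nuisance, mirroring the 6-family / 15-species
structure of a public benchmark, so the whole pipeline trains in about
a minute on one CPU.

## A worked example

```r
library(finclass)

# a small taxonomy-structured synthetic dataset: 6 families, 15 species
gen <- generate_synthetic(synth_spec(seed = 1))
records <- standardize(gen$records)
print(gen$tree)
#> <taxonomy_tree> 15 species in 6 families
#>   fam01: fam01_sp01, fam01_sp02
#>   fam02: fam02_sp01, fam02_sp02, fam02_sp03
#>   fam03: fam03_sp01
#>   fam04: fam04_sp01
#>   fam05: fam05_sp01
#>   fam06: fam06_sp01, fam06_sp02, ..., fam06_sp07

split <- stratified_kfold(records, k = 7, seed = 0)[[1]]
print(split)
#> <dataset_split> fold 1: 300 train / 75 validation / 75 test

# hierarchical model: root (family) stage, then leaf (species) stage
model <- build_tree_model("tiny", gen$tree, seed = 0)
fit  <- train_root(model, records, split, training_config(epochs = 30, seed = 0))
fit2 <- train_leaves(fit$model, records, split, training_config(epochs = 30, seed = 0))

routed <- route_predict(fit2$model, records[split$test])
report <- metrics_report(record_species(records)[split$test],
                         routed$predictions$species,
                         gen$tree$species_labels)
print(report)
#> <metrics_report> n = 75, AC = 100.00%, AP = 100.00%
head(routed$predictions, 3)
#>   family    species root_confidence leaf_confidence
#> 1  fam01 fam01_sp01       0.9986013       0.9635335
#> 2  fam01 fam01_sp01       0.9981270       0.9802045
#> 3  fam01 fam01_sp01       0.9879461       0.9509545
```

On this fixture the hierarchical model routes every test image to the
right family and species; a flat model trained under the same budget
reaches ~93–99% species accuracy depending on the seed, so the
hierarchy matches or beats it — the coarse-to-fine decomposition pays
off exactly when species within a family are the hard distinctions.

The targeted-augmentation loop is the other half of the package:

```r
fit <- train_flat(build_flat_model("tiny", classes, freeze = "conv_only"),
                  records, split, training_config(epochs = 30))
flags <- flag_classes(fit$history)        # divergence-scored classes
plan <- augmentation_plan(flagged_classes = flags$flagged)
bigger <- enlarge_training_set(records[split$train], plan)
# ... retrain on `bigger`, evaluate both rounds
```

`run_pipeline(config, mode = c("flat", "flat+augment", "hier"))` wires
these stages end to end from a YAML config, writing split manifests,
loss histories, divergence reports, per-class metrics and a hashed file
manifest. A thin command-line wrapper lives at `inst/cli/finclass.R`
(subcommands `generate`, `train-flat`, `train-hier`, `predict`,
`predict-hier`, `evaluate`).

## Package layout

| Area | Functions |
| --- | --- |
| Taxonomy | `load_taxonomy`, `family_of`, `leaf_label_space`, `auto_confusable_pairs` |
| Data | `read_annotations`, `standardize`, `stratified_kfold`, `holdout_split`, `dataset_summary` |
| Augmentation | `augmentation_plan`, `augment_image`, `enlarge_training_set` |
| Loss monitor | `loss_history`, `record_epoch`, `divergence_score`, `flag_classes`, `plot_curves` |
| Flat model | `softmax`, `cross_entropy`, `build_flat_model`, `train_flat`, `predict_flat` |
| Tree model | `build_tree_model`, `train_root`, `assemble_leaf_training_set`, `train_leaves`, `route_predict` |
| Metrics | `confusion`, `precision_per_class`, `average_precision`, `average_count`, `relative_improvement`, `metrics_report` |
| Synthetic data | `synth_spec`, `generate_synthetic`, `imbalance_profile`, `make_difficult_class` |
| Pipeline | `run_config`, `run_pipeline` |

See `vignettes/finclass-methods.Rmd` for the full account of the
models, the divergence criterion, the staged training budgets, and what
the synthetic fixture does and does not demonstrate.
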