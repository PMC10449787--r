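# arcvir

Random-forest classification of archaeal viruses among metagenomic viral
contigs.

Viruses infecting Archaea are rare finds in metagenomes and are routinely
misfiled as bacteriophages. `arcvir` assigns every pre-identified dsDNA
viral contig (recommended >10 kb) a probability of being an **archaeal
virus** rather than a **phage**, together with the machinery to build and
audit such a classifier offline:

* a 27-column per-contig feature table from gene calls (external
  metagenome gene caller or built-in six-frame scanner) and three layers
  of filtered homology evidence — protein-vs-protein (e-value < 1e-5),
  profile-HMM (full-sequence e-value < 1e-10), and iterative-profile
  searches against a curated archaeal-virus reference set (e-value
  < 1e-5);
* correlation pruning (|Pearson r| > 0.95), a stratified 70:30
  train/test split, five-fold cross-validated recursive feature
  elimination by Gini importance (floor of 5 features), and a seeded
  random forest whose prediction probability is the fraction of trees
  voting archaeal — call archaeal at probability ≥ 0.80 for confident
  results;
* the legacy homology-rule classifier it supersedes (category 1/2 calls
  at >2/3 and >1/2 archaeal-affiliated genes with bitscore gates);
* a from-scratch metric engine — TPR, specificity (SPEC), accuracy
  (ACC), Matthews correlation (MCC), false discovery rate (FDR), F1,
  ROC/PR curves with trapezoid AUROC/AUPRC:

  TPR = TP/(TP+FN)  SPEC = TN/(TN+FP)  ACC = (TP+TN)/n  FDR = FP/(FP+TP)

  MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))

* dataset-perturbation benchmarking: 5'-anchored size fractionation
  (1–10 kb windows plus the >10 kb pass-through), microbial contamination
  spiking (10–95% of the final dataset, 10–200 kb fragments, half archaea
  half bacteria), and seeded subsampling;
* a synthetic-data generator that plants the class-conditional homology
  structure the classifier exploits (archaeal viruses: ~27% of ORFs
  annotated of which ~71% archaeal-affiliated, iterative-profile hits
  with mean 18; phages: ~70% annotated, ~2% archaeal, near-zero profile
  hits), so everything above is testable with no downloads.

All user-facing functions take and return tibbles and chain with the
pipe; fitted objects support `tidy()`, `glance()`, `augment()` and
`autoplot()`.

## Worked example

Simulate labeled contigs, build features, train and evaluate:

```r
library(arcvir)

ds    <- simulate_dataset(sim_config(n_per_class = 100, seed = 42))
ft    <- dataset_features(ds)              # 200 x 27 feature table
parts <- split_train_test(ft, seed = 1)    # stratified 70:30
model <- train_forest(parts$train, n_trees = 500, seed = 1)
model
#> Random-forest archaeal-virus classifier
#>   trees: 500  seed: 1
#>   features: 27
#>   OOB error: 0
#>   training class counts: archaeal_virus=70, phage=70

pred <- predict_contigs(model, parts$test, threshold = 0.80)
head(pred, 4)
#> # A tibble: 4 x 5
#>   contig_id p_archaeal p_phage predicted_class threshold_used
#>   <chr>          <dbl>   <dbl> <chr>                    <dbl>
#> 1 av_0003        1       0     archaeal_virus             0.8
#> 2 av_0004        0.998   0.002 archaeal_virus             0.8
#> 3 av_0005        1       0     archaeal_virus             0.8
#> 4 av_0008        1       0     archaeal_virus             0.8
```

`p_archaeal` is the fraction of the 500 trees voting archaeal; at the
0.80 threshold only high-confidence contigs are called archaeal. The
planted class structure is fully separable, so held-out metrics are
perfect and the iterative-profile features dominate the importances:

```r
compute_metrics(confusion_counts(parts$test$label, pred$predicted_class))
#> # A tibble: 1 x 6
#>     TPR  SPEC   ACC   MCC   FDR    F1
#> 1     1     1     1     1     0     1

glance(roc_pr(pred$p_archaeal, parts$test$label))
#> # A tibble: 1 x 4
#>   auroc auprc n_pos n_neg
#> 1     1     1    30    30

head(tidy(model), 5)
#> # A tibble: 5 x 2
#>   feature                              gini_importance
#> 1 ocav_profile_n_best_archaeal                   0.176
#> 2 ocav_hit_count                                 0.163
#> 3 ocav_profile_n_orfs_with_hit                   0.145
#> 4 ocav_profile_fraction_orfs_annotated           0.137
#> 5 archaeal_fraction_annotated                    0.135
```

For real data, replace the simulation with `read_fasta()` +
`call_genes()` (external gene-caller backend), `run_search()` /
`read_hit_table()` against your own reference databases with their
`target_id -> target_class` metadata maps, then `filter_hits()` and
`build_feature_table()`. Robustness is probed with `run_benchmark()`
(size fractions, contamination proportions, subsampling). A thin
command-line wrapper over the same functions is installed as
`exec/arcvir` with subcommands `simulate`, `features`, `train`,
`predict`, `benchmark` and `v1-classify`.

The methods vignette
(`vignettes/archaeal-virus-classification.Rmd`) documents the model,
every tunable constant, the generator's assumptions, and known
limitations.

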