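# kinmode

Multi-class prediction of kinase inhibitor binding modes — type I (active
"DFG in / αC-helix in"), type I½ (intermediate "DFG in / αC-helix out"), and
type II (inactive "DFG out") — from two fundamentally different molecular
representations, and tooling to compare how much binding-mode information
each representation carries:

* **Interaction fingerprints (IFPs)**: presence/absence of protein–ligand
  contacts over the 85 standardized kinase binding-site residue positions,
  as one bit per position (`IFP_85`) or expanded into seven interaction
  categories per position (`IFP_595`, 85 × 7 bits, position-major), with the
  per-bit majority-vote consensus rule (ties set "on") for inhibitors
  crystallized in several complexes.
* **Atom environment fingerprints** (ECFP4-like): hashed integer feature
  sets of the ligand's 2D structure, variable-size (`ECFP4_unfolded`) or
  folded to 1024 bits by modulo mapping (`ECFP4_folded`).

Around these the package implements the full comparison pipeline for
cheminformatics / machine-learning practitioners:

* 100-tree random forest classification with balanced class weights;
  stratified 90/10 benchmark trials (20 by default, 70/30 as control);
* evaluation by multi-class Matthews correlation coefficient
  (Gorodkin's R_K; binary
  `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))` one-vs-rest per
  class) and balanced accuracy (macro recall;
  `BA = ½(TP/(TP+FN) + TN/(TN+FP))` in the binary case);
* label-permutation significance tests (`p = max(c, 1)/n_perm`, smallest
  achievable p of 1/1000 at the default 1000 permutations);
* pool-based active learning: start from one instance per class, add the
  N = 10 pool compounds with the largest Shannon entropy
  `H = −Σ pᵢ log₂ pᵢ` of their predicted class distribution (or random
  draws as control), retrain to pool exhaustion; 6 trials = 2 splits × 3
  executions; entropy-minus-random difference curves with peak detection
  diagnose how redundantly a representation encodes its information;
* Gini feature-importance tracking across iterations with
  median-importance filtering;
* Tanimoto-distance t-SNE embeddings (perplexity 30) with silhouette
  scoring, plus figure and summary-report generation.

A seeded synthetic cohort generator reproduces the statistical structure of
the real KLIFS-derived compound set (exact 1424/394/190 class composition,
2008 inhibitors; class-conditional signature interactions with controllable
redundancy; multiple noisy structures per inhibitor; sparse weak-signal
hashed features), so the entire pipeline runs and is testable with no
external data. Adapters read KLIFS-style 595-bit interaction TSVs for
real-data use.

## Worked example

```r
library(kinmode)

cohort <- generate_dataset(default_config(), seed = 7)
cohort
#> Labeled synthetic kinase inhibitor cohort
#>   inhibitors: 2008
#>   class composition: I=1424, I1/2=394, II=190
#>   structures per inhibitor: 3

ifp  <- build_ifp_datasets(cohort)   # consensus IFP_85 + IFP_595
ecfp <- build_ecfp_datasets(cohort)  # ECFP4_folded + ECFP4_unfolded
ifp$ifp85
#> <fingerprint_dataset IFP_85: 2008 inhibitors x 85 features>

bench <- benchmark_trials(ifp$ifp85, n_trials = 5, base_seed = 1)
subset(summary(bench), class == "all")
#>   representation metric class    median        q1        q3 whisker_low whisker_high
#> 1         IFP_85     ba   all 0.8272605 0.8082689 0.8281601   0.8020693    0.8579971
#> 2         IFP_85    mcc   all 0.7956276 0.7704496 0.8162396   0.7691233    0.8634160

split <- stratified_split(ifp$ifp85$labels, test_fraction = 0.1, seed = 1)
model <- train_rf(ifp$ifp85$matrix[split$pool_indices, ],
                  ifp$ifp85$labels[split$pool_indices], seed = 1)
pred  <- predict_class(model, ifp$ifp85$matrix[split$test_indices, ])
evaluate_predictions(ifp$ifp85$labels[split$test_indices], pred)
#> MCC 0.816 | BA 0.827 | n = 200
#>   I     MCC 0.867 BA 0.905
#>   I1/2  MCC 0.731 BA 0.834
#>   II    MCC 0.847 BA 0.892
```

The numbers mean: across 5 stratified 90/10 trials the 85-bit interaction
fingerprint reaches a median multi-class MCC of about 0.80 and balanced
accuracy of about 0.83 on held-out inhibitors; on one split, the
intermediate type I½ class is the hardest to recover (one-vs-rest MCC 0.73)
while type I and the distinctive type II are easier — the per-class ordering
expected for this prediction task. Running the same benchmark on
`ecfp$folded` lands around MCC 0.5: interaction information clearly
outperforms ligand structure alone, which is the package's central
comparison.

Active learning in two lines:

```r
ex <- run_al_experiment(ifp$ifp595, base_seed = 3)          # entropy + random, 6 trials each
difference_curve(aggregate_trials(ex$entropy), aggregate_trials(ex$random))
```

## Vignette

`vignettes/binding-mode-classification.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, numerical conventions
(degenerate-input rules, tie-breaking, seeding), and known limitations.
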