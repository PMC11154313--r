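# vitalnet

Multi-omics recurrent neural classification of cancer patient vital
status, with survival-oriented evaluation and ratio-based marker
discovery.

Pancreatic cancer patients differ sharply in how long they survive, and
part of that difference is molecular: copy-number dosage, transcript
levels and protein abundance all carry signal about who dies early.
`vitalnet` is an R implementation of a dead-vs-alive analysis for such
cohorts, aimed at computational biologists who want the whole chain —
from feature-by-sample matrices to a ranked shortlist of candidate drug
targets — as tested, seeded, reproducible code.

The pipeline:

1. **Synthetic cohort generation** (`cohort_spec()`, `generate_cohort()`) —
   seeded multi-omics cohorts with the statistical structure the
   analysis assumes (planted ~4× copy-number amplification in the dead
   group, planted 8.5–26× expression fold changes, a signal-free
   protein layer, exponential survival with 20% censoring, injected
   missingness), so every downstream stage is testable without any
   download.
2. **Preprocessing** (`preprocess_matrix()`, `assemble_model_inputs()`) —
   three-stage missing-value handling: drop features whose stored zeros
   exceed 20% of present entries (strict), drop samples missing more
   than 20% of features, impute the rest by a 10-nearest-sample mean,
   drop all-null features; then zero-pad each subset to a common width.
   Values are never rescaled.
3. **Classification** (`vitalnet()`) — one LSTM branch per omics subset
   feeding a switching layer, dropout (0.5), a sigmoid feed-forward
   stack (96/76) and a two-way softmax; trained by backpropagation
   through time with Adam, 5-fold cross-validation, and a
   *sensitivity-restart* rule: training is reseeded until every
   structurally connected weight has mean \|∂(dead logit)/∂w\| above
   ε = 0.01, or a restart cap is reached (flagged). Subset ablation
   (`ablate_subsets()`) and progressive hidden-unit adaptation
   (`adapt_hidden_units()`) quantify each layer's contribution.
4. **Evaluation** (`evaluate_predictions()`) — accuracy, sensitivity,
   specificity (dead = positive), Harrell's C-index over comparable
   pairs with censoring, Brier score, ROC/AUC, and the two-group
   log-rank test.
5. **Marker discovery and triage** (`relative_amplification_table()`,
   `fold_change_table()`, `protein_group_tests()`,
   `triage_drug_targets()`) — dead/alive group-mean ratios with strict
   thresholds (> 4 for copy number, > 8.5 for expression), Welch t and
   variance-ratio F tests for protein, and a deterministic rule engine
   that excludes CNV-only, protein-informative and already-known genes
   before ranking candidates by fold change.

`run_pipeline()` drives all stages end to end and writes every artifact
(TSV tables, JSON reports, a manifest with seeds and stage timings).

## Worked example

```r
library(vitalnet)

spec <- cohort_spec(n_alive = 120, n_dead = 80, seed = 42)
co   <- generate_cohort(spec)
co
#> <omics_cohort> 200 samples (120 alive, 80 dead)
#>   DNA-seq       120 features x  200 samples
#>   RNA-seq       200 features x  200 samples
#>   Methylation   150 features x  200 samples
#>   miRNA-seq      80 features x  200 samples
#>   Protein        40 features x   50 samples

cfg <- classifier_config(lstm_hidden_units = 16, block_length = 64,
                         epochs = 30, learning_rate = 0.01, patience = 8,
                         max_restarts = 2, seed = 1)
fit <- vitalnet(co, config = cfg, subsets = c("DNA-seq", "RNA-seq", "Methylation"))
fit
#> Multi-omics recurrent vital-status classifier
#> <vitalnet_model> 3 LSTM branches (16 hidden units, block 64), 96-76-2 head
#>   branches: DNA-seq[on] RNA-seq[on] Methylation[on]
#>   23513 parameters
#> Restart rule: 2 run(s), cap reached (flagged) (min active sensitivity 0, epsilon 0.01)
#> Training accuracy 1.000 (sensitivity 1.000, specificity 1.000)
```

The planted signal is fully separable, so training accuracy reaches
1.000; the restart flag records that some weight derivatives underflow
once the gates saturate (see the methods vignette). The marker tables
recover the planted effects from the simulated groups:

```r
g   <- split_by_vital_status(co, "DNA-seq")
amp <- relative_amplification_table(g$dead, g$alive, threshold = 4)
subset(amp, amplified, select = c(gene_id, dead_mean, alive_mean, ratio_2dp))
#>     gene_id dead_mean alive_mean ratio_2dp
#>       EWSR1  5.322584   1.310529      4.06
#>        FLT3  5.341156   1.309898      4.08
#>        GPC3  5.460754   1.237819      4.41
#>       HIF1A  5.675408   1.303684      4.35
#>         HLF  5.240354   1.309509      4.00
#>        MEN1  5.530681   1.339182      4.13

e <- split_by_vital_status(co, "RNA-seq")
fold_change_table(e$dead, e$alive, threshold = 8.5)[, c("gene_id", "fold_change")]
#>       gene_id fold_change
#> 1       RPL30   25.999971
#> 2     RPS28P7   16.239225
#> 3 Metazoa_SRP   10.226332
#> ...
```

Each estimated ratio sits within sampling error of its planted value
(e.g. RPL30 was planted at 26.06 and is estimated at 26.00 from 80 vs
120 samples). `triage_drug_targets()` then turns the tables plus a
user-supplied known-marker list into a flagged candidate shortlist.

## Layout

```
R/                  implementation (cohort, preprocess, nnet core,
                    classifier + vitalnet S3 methods, metrics, markers,
                    io, pipeline)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R  headline-number reproduction script
vignettes/          methods vignette (model, assumptions, choices)
```
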