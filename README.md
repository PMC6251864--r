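# m5cpred

Tissue-aware prediction of RNA 5-methylcytosine (m5C) sites from sequence
context.

m5C is a post-transcriptional modification of cytosines that is distributed
unevenly across tissues and species. Experimental maps (e.g. from bisulfite
sequencing) are expensive and incomplete, so a common strategy is to learn a
sequence model from known sites and use it to score every other cytosine.
`m5cpred` implements that protocol end to end:

- **Windows.** Each candidate site is represented by the 21 nucleotides
  centred on the cytosine (flank `w = 10`); windows running past a
  transcript end are `N`-padded.
- **Encodings.** Windows are turned into numeric features by one-hot
  encoding (`A→1000`, `G→0100`, `C→0010`, `T→0001`; `N→0000`) or by a
  physicochemical scheme that maps each base to a purine/amino/weak-bond
  triple plus its accumulated occurrence frequency along the window. Both
  yield 84 features for a 21-nt window.
- **Datasets.** Negative candidates (unmodified C's) vastly outnumber
  positives, so training sets are subsampled to a 1:30 positive:negative
  ratio, while test sets keep *all* candidate C's on the held-out
  transcripts (a quarter of the positives) to reflect deployment
  conditions. Per-tissue datasets additionally exclude every other
  tissue's training samples from their test sets, so the cross-tissue
  benchmark is leak-free.
- **Models.** A random forest (300-tree probability forest) is the
  production learner; logistic regression, naive Bayes and a decision tree
  are included as baselines. All emit a probability-like score in [0, 1].
- **Stringency thresholds.** Score cutoffs are calibrated on held-out
  negatives so that "high", "medium" and "low" stringency correspond to
  1%, 5% and 10% false positive rates.
- **Evaluation.** ROC curves and AUC are computed from first principles
  (tie-aware trapezoid / Mann–Whitney), plus an intra- vs inter-tissue
  AUC matrix.
- **Synthetic benchmark.** A motif-implantation generator produces
  transcripts with tissue-specific positive sites, so the whole pipeline
  runs and can be validated without any external data.

Everything is tibble-in / tibble-out and composes with dplyr; `roc_curve()`
and `cross_tissue_benchmark()` results have `autoplot()`, `tidy()` and
`glance()` methods.

## Quick start

Simulate a benchmark, build the comprehensive dataset, train and calibrate
a forest, and evaluate on the untouched test split:

```r
library(m5cpred)

sim <- simulate_m5c(synthetic_spec())   # 60 transcripts, 3 tissues
dplyr::count(sim$sites, tissue, label)
#> # A tibble: 6 × 3
#>   tissue      label        n
#>   <chr>       <chr>    <int>
#> 1 human_Hela  negative 13280
#> 2 human_Hela  positive   127
#> 3 mouse_Brain negative 13270
#> 4 mouse_Brain positive   137
#> 5 mouse_Heart negative 13292
#> 6 mouse_Heart positive   115

ds <- build_comprehensive_dataset(sim$sites, sim$transcripts,
                                  ratio = 30, seed = 1)
p <- train_predictor(ds$train, "random_forest", seed = 1)
p
#> <m5c_predictor>
#>   algorithm: random_forest
#>   encoding:  one_hot (w = 10)
#>   tissue:    comprehensive
#>   trained on 8804 windows (284 positives)

# calibrate stringency thresholds on negatives unseen during training
pos  <- sim$sites[sim$sites$label == "positive",
                  c("transcript_id", "position")]
used <- rbind(ds$train[, c("transcript_id", "position")], pos)
neg  <- sample_negative_windows(sim$transcripts, 2000,
                                exclude = used, seed = 99, w = 10)
p <- calibrate_thresholds(p, neg)
unlist(p$thresholds$levels)
#>        high      medium         low
#> 0.034761905 0.009523810 0.003333333

glance(roc_curve(predict_scores(p, ds$test), ds$test$label))
#> # A tibble: 1 × 4
#>     auc n_pos n_neg n_points
#>   <dbl> <int> <int>    <int>
#> 1     1    95  3384      344
```

Score every cytosine in a transcript and rank the calls:

```r
calls <- scan_transcripts(p, sim$transcripts[1, ])
head(calls[order(-calls$score), ], 5)
#> # A tibble: 5 × 6
#>   transcript_id position score call_high call_medium call_low
#>   <chr>            <int> <dbl> <lgl>     <lgl>       <lgl>
#> 1 synth_0001         315 0.987 TRUE      TRUE        TRUE
#> 2 synth_0001          56 0.977 TRUE      TRUE        TRUE
#> 3 synth_0001         338 0.975 TRUE      TRUE        TRUE
#> 4 synth_0001         304 0.973 TRUE      TRUE        TRUE
#> 5 synth_0001         979 0.973 TRUE      TRUE        TRUE
```

All five top-ranked positions are true implanted sites on that transcript.

The same workflow is available from the shell via the bundled CLI
(`system.file("cli", "m5cpred.R", package = "m5cpred")`), with subcommands
`simulate`, `build-datasets`, `train`, `calibrate`, `predict`, `evaluate`,
`benchmark` and `pipeline`; `run_pipeline()` is the in-R equivalent of the
last one.

## Testing

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "m5cpred",
                               load_package = "installed")'
```

The suite covers unit oracles (brute-force AUC concordance, hand-computed
encodings, order-statistic thresholds, an external ROC implementation as a
cross-check) and whole-protocol acceptance tests in
`tests/testthat/test-acceptance.R` (dataset invariants, FPR calibration
accuracy, end-to-end signal recovery, bit-reproducibility).

## License

MIT (see `LICENSE`).
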