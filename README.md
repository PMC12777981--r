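# poremae

Self-supervised masked-autoencoder learning for single-molecule nanopore
event classification, in R.

A nanopore records an analyte — a DNA barcode carrier, a carrier with a bound
protein, a denatured peptide — as a transient dip in ionic current. Labeled
single-molecule events are expensive, so supervised classifiers operate in a
chronically data-scarce regime. `poremae` implements a generative
self-supervised route around the scarcity:

1. **Tokenize** each fixed-length event into `L = ceiling(F/w)` windows of
   `w = 12` points (~one amino acid per token for peptide reads).
2. **Pretrain** an asymmetric attention autoencoder on unlabeled events:
   a random 60 % of token positions is hidden; the encoder sees visible and
   masked tokens as separate sequences; the decoder must predict the
   encoder's own (gradient-isolated) latent representation of the hidden
   content at every masked slot, under a mean-squared latent loss.
3. **Fine-tune**: load the pretrained projection/positions/encoder, pool the
   full-event token representations by global averaging, and train a
   two-layer softmax head with AdamW under a cosine learning-rate schedule.

The package is a complete, dependency-light implementation: the transformer
forward and backward passes (multi-head attention, LayerNorm, GELU feedforward,
and a drop-in 1-D CNN ablation backbone) are written in base R matrices with
small C++ kernels via Rcpp/RcppArmadillo, and every analytic gradient is pinned
by finite-difference tests. A seeded simulator generates nanopore-like
benchmark datasets (barcode carriers, protein binding, residue-volume-driven
peptide reads), so the whole method runs end to end with no external data.

## Worked example

Three-class peptide benchmark: a 42-residue reference sequence vs its E22G and
G37R point mutants. Residue `i` of a read dwells at a depth proportional to its
amino-acid volume, so a single substitution shifts a ~12-point window of the
trace by a fraction of the noise scale.

```r
library(poremae)

events <- generate_dataset("peptide", n_per_class = 60,
                           params = peptide_sim_params(noise_sd = 0.08),
                           seed = 42)
events
#> <event_set> 180 events, 3 classes, fixed length 500

prepped <- preprocess_events(events, 500, mode = "interpolate",
                             standardize = "none")

folds <- kfold(prepped, k = 3, seed = 1)
train <- subset_events(prepped, which(folds != 1))
test  <- subset_events(prepped, which(folds == 1))

mcfg <- model_config(d = 32, d_k = 32, d_v = 32, n_layers = 2, h = 2, w = 12)
tcfg <- train_config(epochs_pretrain = 30, epochs_finetune = 30,
                     batch_size = 8, seed = 1)

ckpt <- pretrain(train, mcfg, tcfg)   # self-supervised: labels are stripped
tail(ckpt$log, 3)
#> # A tibble: 3 × 4
#>   epoch    loss    lr seconds
#>   <int>   <dbl> <dbl>   <dbl>
#> 1    28 0.00251 0.001   0.607
#> 2    29 0.00247 0.001   0.589
#> 3    30 0.00246 0.001   0.511

fit <- finetune(train, mcfg, tcfg, init = ckpt)
preds <- predict_events(test, fit)
head(preds, 3)
#>                    id true_label pred_label  p_native    p_E22G      p_G37R
#> 1 peptide_native_0004     native     native 0.7831428 0.2123622 0.004494979
#> 2 peptide_native_0005     native     native 0.8462561 0.1472098 0.006534134
#> 3 peptide_native_0007     native       E22G 0.4642547 0.5331029 0.002642418

compute_metrics(preds$pred_label, preds$true_label)
#> <metric_report> n = 60 (macro): accuracy 0.8333, precision 0.8290, recall 0.8333, F1 0.8311
```

Against the supervised-only baseline (identical recipe from random
initialization) and the simulator's independent nearest-template oracle:

```r
scratch <- finetune(train, mcfg, tcfg)
ps <- predict_events(test, scratch)
cat(sprintf("pretrained %.3f | scratch %.3f | nearest-template %.3f\n",
            mean(preds$pred_label == preds$true_label),
            mean(ps$pred_label == ps$true_label),
            mean(nearest_template(events, "peptide",
                                  params = peptide_sim_params(noise_sd = 0.08)) ==
                 event_labels(events))))
#> pretrained 0.833 | scratch 0.967 | nearest-template 1.000
```

At this scale — 120 training events with full labels and moderate noise — the
supervised-only baseline is competitive and single splits vary by seed; the
pretrained route earns its keep when labels are scarce relative to unlabeled
events (see `scarcity_experiment()`) and in cross-validated protocols rather
than one split. The hardest confusion is native vs E22G (a
glutamate-to-glycine substitution, the smallest volume contrast of the three
classes), visible in the class probabilities above.

## Experiment runners

* `run_cv()` — stratified k-fold cross-validation of the pretrained or
  scratch variant, with macro precision/recall/F1 reports.
* `scarcity_experiment()` — accuracy as a function of the labeled fraction
  (pretraining always uses the full unlabeled training split; only the
  fine-tuning labels are subsampled), on a fixed stratified holdout.
* `mask_ratio_sweep()` — full pretrain + fine-tune per mask ratio.
* `model_config(backbone = "cnn")` — swaps each attention sublayer for a
  same-width kernel-3 convolution, isolating the contribution of attention.
* `export_embeddings()` — pooled per-event embeddings at any training stage,
  as TSV for downstream projection (t-SNE/UMAP).

## Command-line interface

A thin Rscript CLI wraps the exported functions:

```sh
inst/cli/poremae simulate   --task peptide --n-per-class 60 --noise 0.08 \
                            --seed 42 --out events.ndjson
inst/cli/poremae preprocess --in events.ndjson --out fixed.ndjson \
                            --mode interp --length 500
inst/cli/poremae pretrain   --data fixed.ndjson --out enc.rds [--config cfg.yaml]
inst/cli/poremae finetune   --data fixed.ndjson --init enc.rds --out clf.rds
inst/cli/poremae predict    --data fixed.ndjson --model clf.rds --out preds.tsv
```

Events travel as NDJSON (one JSON object per line: `id`, `trace`, `label`,
`source`, `duration_points`) or as a rectangular TSV for fixed-length sets;
checkpoints are RDS with a JSON sidecar describing architecture and
preprocessing, so compatibility is checked before weights are loaded.

## Testing and reproduction

```r
testthat::test_dir("tests/testthat", package = "poremae",
                   load_package = "installed")
```

`tests/testthat/test-acceptance.R` holds the package's acceptance protocol:
exact formula/structure/contract checks plus scaled-down end-to-end trainings
on checked-in fixture recipes. The same protocol is runnable as a standalone
report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

which regenerates the benchmark from the seed, runs cross-validation, the
scarcity grid, the mask-ratio sweep and the CNN ablation, and writes each
headline quantity as a JSON number with its sample size.

The methods vignette (`vignettes/poremae-methods.Rmd`) documents the model,
the simulator's calibration and its deliberate realism gaps, the scaled-down
evaluation protocol, and known limitations.
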