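# helixlite

Base-wise structural gene annotation of eukaryotic genome sequence with a
pooled-timestep stacked bidirectional LSTM — a desk-scale, fully
self-contained R implementation of the deep-learning annotation loop:

- **data pipeline** — FASTA + GFF3 → per-base one-hot labels over
  {intergenic, UTR, CDS, intron}, annotation-error masking via per-base
  sample weights, 20 kb chunking of both strands (minus strand
  reverse-complemented), N90-stratified train/validation split, an
  on-disk chunk store;
- **network** — a stacked bidirectional LSTM that reads 10 bases per
  recurrent timestep (40 inputs → 40 outputs per step) with layer
  normalization between layers and an independent softmax over the four
  classes at every base; class-weighted, mask-aware cross-entropy;
  per-epoch Genic-F1 validation, checkpointing, early stopping; the
  reference 4×256 configuration has ≈5.4 million parameters. Training
  (BPTT) and inference are implemented in RcppArmadillo — no external
  deep-learning framework;
- **inference** — overlapping sliding windows with core cropping and
  probability-space averaging, extended input lengths (the architecture
  is length-free), and 8-member ensembles built from 4 training runs ×
  2 checkpoints (best precision + best recall epochs represented);
- **metrics** — pooled (micro-averaged) confusion-matrix metrics:
  per-class precision/recall/F1, **Genic F1** (UTR+CDS+intron),
  **Subgenic F1** (CDS+intron), base-wise accuracy; masked bases never
  count;
- **rnaseq_support** — per-base coverage (CIGAR `=`/`M`/`X`) and spliced
  coverage (`N`/`D`) from SAM alignment records, and the breakdown of
  read support over the confusion cells of two annotations;
- **mutagenesis** — N-masking of motifs (`[0.25 ×4]` rows) and
  frame-preserving codon scrambling, with before/after prediction deltas;
- **synthetic_genome** — a seeded gene-grammar generator (canonical
  GT..AG introns, ATG/stop codons, codon-positional bias, AT-rich
  intergenic background, injectable annotation errors) so the whole loop
  runs end-to-end with no downloads.

The model emits per-base class probabilities; assembling them into
finished transcript models is out of scope.

## The metric

All headline numbers are micro-averaged F1 over a pooled 4×4 confusion
matrix of unmasked bases. For a class subset C:

    TP = Σ_{c∈C} TP_c,  FP = Σ_{c∈C} FP_c,  FN = Σ_{c∈C} FN_c
    Precision = TP/(TP+FP),  Recall = TP/(TP+FN),  F1 = 2PR/(P+R)

A true intron base predicted CDS is one FP for CDS *and* one FN for
intron. Genic F1 uses C = {UTR, CDS, intron}; Subgenic F1 uses
C = {CDS, intron}; correct intergenic calls are never credited.

## Worked example

```r
library(helixlite)

res <- run_end_to_end(run_config(out_dir = "smoke_run", seed = 1))
#> simulate: generating synthetic genome
#> preprocess: encoding, masking, chunking
#> train: 8 training / 2 validation chunks
#> epoch 1: loss 1.2948, val Genic F1 0.0018
#> ...
#> epoch 5: loss 0.9284, val Genic F1 0.4480
#> predict + evaluate: scoring versus truth
#> done: Genic F1 vs truth = 0.5059
round(unlist(res$summary[c("best_epoch", "val_genic_f1", "eval_genic_f1",
                           "eval_subgenic_f1", "eval_accuracy")]), 4)
#>       best_epoch     val_genic_f1    eval_genic_f1 eval_subgenic_f1
#>           5.0000           0.4480           0.5059           0.5629
#>    eval_accuracy
#>           0.6690
```

This smoke run simulates one 100 kb genome, trains a 2-layer 32-unit
model for 5 epochs (about a minute) and scores the overlap-averaged
predictions against the simulated truth: after roughly 40 gradient steps
on 0.2 Mb of (two-stranded) training signal the model already recovers
half of the pooled genic bases (Genic F1 0.51) at 67% base-wise
accuracy — mostly from the compositional contrast between genic and
intergenic sequence. Training on the full default 1 Mb grammar for 20
epochs (about 3 minutes on one CPU; the test suite does exactly this)
takes the same tiny architecture to a validation Genic F1 of 0.80 under
overlap-averaged inference.

Individual stages are exposed both as functions (`generate_genome()`,
`preprocess_annotation()`, `train_network()`, `predict_windows()`,
`ensemble_predict()`, `confusion()` / `genic_f1()`, `quantify()`,
`prediction_delta()`, ...) and as a thin CLI (`exec/helixlite`) with
subcommands `simulate`, `preprocess`, `train`, `predict`, `evaluate`,
`rnaseq-support`, `mutate` and `smoke`.

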