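---
title: "Base-wise gene annotation with helixlite: models, data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-wise gene annotation with helixlite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structural gene annotation assigns every base of a genome assembly one of
four classes: **intergenic**, **UTR**, **CDS** or **intron**. helixlite
frames this as dense sequence labeling: a recurrent network reads the DNA
alone (no expression data, no homology) and emits a softmax over the four
classes at every base. The output is a probability track, not a finished
transcript model — post-processing probabilities into coherent gene models
is deliberately out of scope.

This package implements the full loop at desk scale: data encoding and
error masking, a trainable pooled-timestep stacked bidirectional LSTM,
overlapping sliding-window and ensemble inference, mask-aware pooled
confusion-matrix metrics (Genic/Subgenic F1), per-base RNA-seq
coverage/spliced-coverage quantification, and in-silico mutagenesis. A
synthetic-genome generator with a known gene grammar provides the training
substrate, so everything can be exercised end-to-end on one CPU.

## Data model and encoding

Sequences are encoded base-wise over columns (A, C, G, T): unambiguous
bases one-hot, IUPAC ambiguity codes as uniform mass over their base set
(`N` = `[0.25, 0.25, 0.25, 0.25]`), so every input row sums to 1. Labels
are one-hot over the four classes, derived from a GFF3 annotation reduced
to the transcript with the longest protein per gene (CDS-length maximum,
ties broken by ascending transcript id for determinism). A base inside an
exon is CDS if covered by a CDS segment, otherwise UTR; a base inside the
transcript span but outside every exon is intron — the encoding does not
distinguish introns in coding versus non-coding regions; everything
outside transcript spans is intergenic. All coordinates are handled
internally as 0-based half-open intervals to keep intron gaps exact.

### Error masking

Reference annotations contain systematic errors, by far the most common
being missing UTRs. Rather than learning from such regions, a per-base
sample weight in {0, 1} removes them from the loss and the metrics. The
rules implemented: CDS segment outside every exon, CDS length not
divisible by 3, missing ATG at the (spliced) CDS start, missing stop codon
at its end, missing 5′ or 3′ UTR, and overlapping same-strand genes
(overlap region masked). Any failing transcript has its whole footprint
masked; a missing UTR additionally masks the flanking intergenic stretch
up to the neighboring same-strand gene or the sequence end — the true
transcript boundary could lie anywhere in that stretch, so none of it is
trustworthy. The extension is deliberately unbounded (a design choice; the
error could extend arbitrarily far).

Masking touches only weights, never labels, and a chunk whose weights are
all zero is excluded from the data entirely, as are sequences with no
annotated gene (an unannotated sequence is ambiguous between "no genes"
and "not annotated").

### Chunking and strands

Each retained sequence is cut into consecutive 20 000 bp windows per
strand (zero-padded at the end, padded bases weight 0). The minus strand
is emitted reverse-complemented so the network always reads 5′→3′; its
labels and weights are reversed accordingly, and minus-strand chunk
offsets are in the reverse-complemented coordinate system. This makes the
two strands exactly symmetric: chunking the reverse complement of a
sequence reproduces the other strand's chunks, which the test suite
verifies.

### Train/validation split

The validation set takes 20% of sequences above and 20% below the
assembly's N90, sampled at whole-sequence level, so both long and short
sequences appear in both sets. A length exactly equal to the N90 counts as
"above" (a determinism choice). A stratum with a single sequence goes to
training with a warning.

## The classifier

The architecture is a stack of bidirectional LSTM layers with layer
normalization on the concatenated (2×units) output between consecutive
layers and a per-timestep dense head. Ten consecutive bases form one
recurrent timestep: the input is reshaped from L×4 to (L/10)×40, and the
head emits 40 values per timestep (10 bases × 4 classes) that are reshaped
back and softmaxed per base. Pooling lengthens the effective context a
recurrent layer can integrate, at the cost of the head having to resolve
where within the 10-base block a transition falls. Because no layer is
length-fixed, the same weights accept any input length divisible by the
pool size — the property that extended-length inference exploits.

The reference configuration (4 layers × 256 units/direction) has 5 356 584
trainable parameters (≈5.4 M): 608 256 in the first layer
(2 × 4·256·(40+256+1)), 1 574 912 in each of the three deeper layers,
3 072 in the three layer norms and 20 520 in the output head.

The implementation (forward pass, backpropagation through time, layer-norm
backward, Adam) is self-contained C++ via RcppArmadillo, with parameters
stored in a single flat vector so checkpoints are trivially serializable
and the graph can be rebuilt at any input length.

### Loss, class weights and training protocol

The loss is class-weighted cross-entropy with the per-base sample weight
multiplied in, normalized by the total weight in the batch, so masked and
padded bases contribute exactly zero and all-ones weights recover plain
mean cross-entropy. Class weights default to inverse class frequency
normalized so the frequency-weighted mean weight is 1
(`sum(f * w) = 1`) — with four balanced classes this is all-ones. The
weight scheme is exposed in the config because full inverse-frequency
weighting is aggressive when the intergenic class dominates: in our
desk-scale experiments it traded intergenic precision for rare-class
recall and lowered the Genic F1 (the metric weighs classes by frequency),
so the end-to-end defaults temper it.

After every epoch the validation Genic F1 (with pooled genic precision and
recall) is computed and a checkpoint kept. Training stops at the epoch cap
or when the epoch-to-epoch Genic F1 improvement is at most 0.0001 for 2
consecutive epochs; the reported model is the epoch with the highest
validation Genic F1. Optimizer (Adam), learning rate and batch size are
exposed in the config; at desk scale the dominant factor is simply the
number of gradient steps, so the defaults favor small batches.

### Ensembles

Four independent training runs contribute two checkpoints each: the
best-Genic-F1 epoch, plus a complement chosen so the best-precision and
best-recall epochs are both represented. Eight members' probability tracks
are averaged per base. Member diversity comes from seeds and checkpoint
selection, not architecture.

## Inference

Prediction uses overlapping sliding windows: starts at 0, step, 2·step
(default step = window/2), last window right-aligned; each window is
cropped to a core (default margin = window/4 off each end) wherever
another window still covers the base, and the final probability is the
arithmetic mean — in probability space — of all windows retaining the
base. Bases that every window cropped (the sequence ends, or any geometry
with step = window) fall back to the uncropped window average, so
step = window degenerates exactly to plain chunked prediction. Extended
inference multiplies the window length (the architecture accepts it
natively); it helps when genes are long relative to the training window.

The `edge_effect_profile()` diagnostic bins non-overlapped predictions by
their position within the input window (200 bp bins; 100 bins for a 20 kb
window) and scores each bin, making the characteristic performance drop at
window edges — and its suppression by overlap — measurable.

Hard class calls use an argmax with a documented deterministic tie-break:
probabilities are rounded to 1e-9 and the lowest class index among the
maxima wins. No class-priority scheme is applied.

## Metrics

All metrics derive from a single pooled 4×4 confusion matrix over
unmasked, unpadded bases. Per-class TP/FP/FN are summed over the
considered subset (micro-averaging) and combined into precision, recall
and F1; a base whose true and predicted classes both lie in the subset but
disagree counts as one FP and one FN. **Genic F1** pools {UTR, CDS,
intron}; **Subgenic F1** pools {CDS, intron} (for comparability with
UTR-less predictors); neither credits correct intergenic calls. Accuracy
is trace/total over all four classes. The degenerate case TP+FP = 0 and
TP+FN = 0 is defined as 0 with a warning (a convention; the quantity is
otherwise undefined).

## The synthetic genome generator

The generator emits genomes from an explicit grammar: every gene is
5′UTR — CDS exons interleaved with introns — 3′UTR, with ATG start,
TAA/TAG/TGA stop, no in-frame internal stop, GT..AG introns, genes placed
on both strands between intergenic spacers. Defaults (chosen once, to
emulate a compact plant-like genome): 8 sequences × 125 kb (1 Mb total),
UTRs 100–300 bp, total CDS 600–1500 bp (forced to a multiple of 3), 1–4
introns of 60–200 bp per gene, intergenic spacers 500–1500 bp. Counting
both strands separately this realizes class fractions of about
[IG 0.68, UTR 0.07, CDS 0.19, intron 0.06].

Two composition signals make the grammar learnable by a small network,
mirroring the signals real classifiers exploit: intergenic background at
GC 0.30 and AT-rich intron bodies (GC 0.35) versus genic GC 0.50, and a
codon-positional bias (strength 0.75 by default; 0 gives uniform usage of
the 61 sense codons) that creates the period-3 signature of coding
sequence. Splice motifs and start/stop codons provide the motif-level
signal.

`error_injection_rate` corrupts the *emitted* annotation of a fraction of
genes (sequence stays truthful) in one of three ways matched to the
masking rules under test: delete the UTRs, truncate the CDS by 1–2 bases,
or shift an exon boundary by 1–5 non-multiple-of-3 bases. With rate 0 the
truth passes `flag_errors()` with zero masked bases; with rate r the
flagged genes are exactly the corrupted ones.

What the generator does **not** emulate: repeats and transposons,
alternative splicing, non-canonical splice sites, ncRNA genes, overlapping
genes, GC isochores, sequencing error. Passing tests on this substrate
demonstrate that the machinery (encoding, training, inference, metrics)
is correct and that the model can exploit compositional and motif signals
— they say nothing about performance on real genomes, where those ignored
features dominate the difficulty.

The RNA-seq simulator places exonic reads (Poisson read counts at a target
mean depth) along each transcript, maps them back through the exon
structure to genomic M/N CIGAR runs, and with probability
1 − `splice_fidelity` lets a junction-spanning read read through the
intron instead. Intergenic reads are optional and default to zero.

## Numerical choices and degenerate inputs

- LSTM gates use the standard [i, f, g, o] layout; Glorot-uniform
  initialization with unit forget-gate bias; layer-norm epsilon 1e-5;
  softmax is max-shifted; log-probabilities are clamped at 1e-12.
- Seeds are explicit everywhere (weight init, shuffling, generator,
  splits, scrambling); library code saves and restores the caller's RNG
  state.
- A training batch whose total weight is zero is skipped (no update, zero
  loss). A validation set with no unmasked genic bases aborts training
  with a diagnostic, since Genic F1 would be undefined every epoch.
- The chunk store is a plain directory container (flat binary arrays +
  TSV metadata + JSON attributes) with lossless, order-preserving round
  trips.

## Desk-scale study sizes

The test suite and examples train a 2-layer, 32-unit/direction model on
the default 1 Mb synthetic genome for at most 20 epochs (about three
minutes on one CPU). The training settings were selected on validation
Genic F1, the same model-selection principle the full-scale protocol
uses: batch size 1 (at ~75 chunks per epoch the number of gradient
steps, not the data volume, limits desk-scale convergence), Adam at
2e-3 with a 0.95 per-epoch decay, global gradient-norm clipping at 5
(LSTM gradients spike late in training), inverse-frequency class
weights tempered by an exponent of 0.5 (full inverse-frequency
weighting under-penalizes intergenic errors and floods the genic
classes with false positives; no weighting collapses training to the
all-intergenic solution), and an early-stopping patience of 5 epochs
(the per-epoch validation F1 of a small model on a small validation
set is noisy, and the strict 2-epoch rule regularly kills runs on a
transient dip). At this scale the selected checkpoint reaches a Genic
F1 of 0.80 on held-out validation sequences under the package's
standard overlap-averaged inference; per-epoch chunked validation peaks
slightly lower (~0.79) because window edges are included unaveraged.
The 4×256 reference configuration is instantiated (for its parameter
count and output contract) but not trained in the tests.

A desk-scale peculiarity worth knowing: with this little capacity the
forward reading direction ends up carrying most of the signal, so the
characteristic window-edge degradation is one-sided — severe at window
starts (first-bin Genic F1 roughly half the interior value) and absent
at window ends. Overlap averaging repairs the degraded edge; it cannot
improve the edge that never degrades.

## Known limitations

- No post-processing from probabilities to transcript models.
- CDS labels carry no reading-frame phase classes.
- Alternative transcripts are reduced to the longest protein.
- The masking catalogue is a pragmatic approximation of full structural
  validation; it is the package's own enumeration, chosen to be testable.
- Coverage bins in the support breakdown default to {0}, [1,10),
  [10,100), [100,∞) on raw counts; strand-aware coverage is pooled unless
  alignment flags are usable.
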