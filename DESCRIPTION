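Package: helixlite
Title: Base-Wise Structural Gene Annotation with Pooled-Timestep
    Bidirectional Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale framework for base-wise structural annotation of
    eukaryotic genome sequence. Converts FASTA assemblies and GFF3 gene
    annotations into masked, chunked, numerically encoded training arrays;
    trains a pooled-timestep stacked bidirectional LSTM classifier that
    labels every base as intergenic, UTR, CDS or intron; performs
    overlapping sliding-window and ensemble inference; scores predictions
    with mask-aware pooled confusion-matrix metrics (Genic and Subgenic F1);
    quantifies per-base RNA-seq coverage and spliced coverage from
    alignment records; and probes trained models by in-silico mutagenesis.
    A parameterized synthetic-genome generator with a known gene grammar
    (canonical splice motifs, codon-positional composition bias, injectable
    annotation errors) makes the full pipeline exercisable end-to-end on a
    single CPU without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
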