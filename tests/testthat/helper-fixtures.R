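# Shared fixtures, built in code. Expensive objects (the trained model)
# are memoised for the session.

.fixtures <- new.env(parent = emptyenv())

# A hand-built single-gene genome: 5'UTR 20, exon1 CDS 30, intron 20,
# exon2 CDS 30, 3'UTR 20, flanked by 40 bp intergenic on each side.
toy_gene_genome <- function() {
  set.seed(421)
  ig <- function(n) paste(sample(c("A", "T"), n, TRUE, prob = c(.7, .3)),
                          collapse = "")
  utr <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  cds1 <- paste0("ATG", paste(rep("GCT", 9), collapse = ""))   # 30 bp
  cds2 <- paste0(paste(rep("GAA", 9), collapse = ""), "TAA")   # 30 bp
  intron <- paste0("GT", paste(rep("TA", 8), collapse = ""), "AG")  # 20 bp
  seqs <- paste0(ig(40), utr(20), cds1, intron, cds2, utr(20), ig(40))
  rec <- genome_record("toy", seqs)
  # coordinates (0-based half-open)
  tx <- transcript("t1",
                   exons = rbind(c(40, 90), c(110, 160)),
                   cds_segments = rbind(c(60, 90), c(110, 140)))
  gene <- gene_model("g1", "toy", "+", list(tx))
  list(record = rec, gene = gene)
}

# Small synthetic genome shared by several structural tests.
small_genome <- function(seed = 11, n_sequences = 1, seq_len = 60000, ...) {
  key <- paste0("genome_", seed, "_", n_sequences, "_", seq_len)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_genome(
      grammar_config(seed = seed, n_sequences = n_sequences,
                     seq_len = seq_len, ...))
  .fixtures[[key]]
}

# Study-scale training fixture: tiny 2x32 network trained on the default
# 1 Mb synthetic grammar with fixed seeds. Memoised; several tests reuse
# it. Also scores the best checkpoint on the held-out validation
# sequences with the package's standard inference mode (overlap on).
trained_fixture <- function() {
  if (!is.null(.fixtures$trained)) return(.fixtures$trained)
  g <- generate_genome(grammar_config(seed = 101))
  prep <- preprocess_annotation(g$records, g$truth)
  split <- split_train_val(g$records, 0.2, seed = 202)
  in_val <- vapply(prep$chunks, function(ch) ch$seq_id %in% split$val_ids,
                   TRUE)
  fr <- realized_class_fractions(g$records, g$truth)
  ncfg <- network_config(n_layers = 2, units = 32, chunk_len = 20000,
                         class_weights = compute_class_weights(fr,
                                                               temper = 0.5),
                         batch_size = 1, learning_rate = 2e-3,
                         lr_decay = 0.95, grad_clip = 5,
                         early_stop_patience = 5L, max_epochs = 20,
                         seed = 7)
  t0 <- Sys.time()
  history <- train_network(build_model(ncfg), prep$chunks[!in_val],
                           prep$chunks[in_val])
  train_minutes <- as.numeric(difftime(Sys.time(), t0, units = "mins"))
  best <- history$models[[history$best_epoch]]
  # overlap-averaged validation score of the selected checkpoint
  genes <- helixlite:::reduce_to_longest(g$truth)
  cm <- matrix(0L, 4, 4)
  for (rec in Filter(function(r) r$seq_id %in% split$val_ids, g$records)) {
    gs <- Filter(function(x) x$seq_id == rec$seq_id, genes)
    for (strand in c("+", "-")) {
      sq <- if (strand == "+") rec$sequence else helixlite:::revcomp(rec$sequence)
      lt <- encode_labels(gs, rec$length, strand)
      cls <- if (strand == "+") lt$classes else rev(lt$classes)
      tr <- predict_windows(best, sq,
                            overlap_config(ncfg$chunk_len,
                                           pool = ncfg$pool))
      cm <- cm + confusion(tr$probs, cls)
    }
  }
  .fixtures$trained <- list(genome = g, prep = prep, split = split,
                            fractions = fr, config = ncfg,
                            history = history, best = best,
                            train_minutes = train_minutes,
                            val_overlap_genic_f1 =
                              suppressWarnings(genic_f1(cm)))
  .fixtures$trained
}

# A tiny randomly initialized model (fast forward passes).
tiny_model <- function(units = 8, n_layers = 1, chunk_len = 2000,
                       seed = 5) {
  build_model(network_config(n_layers = n_layers, units = units,
                             chunk_len = chunk_len, seed = seed))
}

# Mirror a gene to the reverse-complemented coordinate system.
mirror_gene <- function(gene, len) {
  flip <- function(iv) cbind(len - iv[, 2], len - iv[, 1])[rev(seq_len(nrow(iv))), , drop = FALSE]
  txs <- lapply(gene$transcripts, function(t)
    transcript(t$transcript_id, flip(t$exons), flip(t$cds_segments)))
  gene_model(gene$gene_id, gene$seq_id,
             if (gene$strand == "+") "-" else "+", txs)
}

# Extract intron sequences of a transcript in sense orientation.
intron_seqs <- function(tx, sequence, strand) {
  ex <- tx$exons
  if (nrow(ex) < 2) return(character())
  ivs <- cbind(ex[-nrow(ex), 2], ex[-1, 1])
  out <- vapply(seq_len(nrow(ivs)), function(i)
    substr(sequence, ivs[i, 1] + 1, ivs[i, 2]), "")
  if (strand == "-") out <- rev(vapply(out, revcomp_chr, ""))
  out
}

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Brute-force per-base metric oracle, independent of the confusion-matrix
# implementation: walks bases and counts TP/FP/FN per class directly.
oracle_pooled <- function(pred, truth, weights, classes) {
  tp <- fp <- fn <- 0
  for (i in seq_along(truth)) {
    if (weights[i] == 0) next
    t <- truth[i]; p <- pred[i]
    for (c in classes) {
      if (t == c && p == c) tp <- tp + 1
      if (p == c && t != c) fp <- fp + 1
      if (t == c && p != c) fn <- fn + 1
    }
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

oracle_accuracy <- function(pred, truth, weights) {
  keep <- weights > 0
  sum(pred[keep] == truth[keep]) / sum(keep)
}
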