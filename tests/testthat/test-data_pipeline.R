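# FASTA/GFF3 parsing, encoding, masking, chunking, split and store.

test_that("read_fasta parses records, upper-cases, and rejects duplicates", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">s1 some description", "acgt", "ACGT", ">s2", "NNNN"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$seq_id, "s1")
  expect_equal(recs[[1]]$sequence, "ACGTACGT")
  expect_equal(recs[[1]]$length, 8)

  writeLines(character(), f)
  expect_length(read_fasta(f), 0)

  writeLines(c(">s1", "ACGT", ">s1", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")
})

test_that("read_gff3 converts coordinates and builds the hierarchy", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=e1;Parent=m1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tID=e2;Parent=m1",
    "chr1\tsrc\tCDS\t51\t100\t.\t+\t.\tID=c1;Parent=m1",
    "chr1\tsrc\tCDS\t201\t250\t.\t+\t.\tID=c2;Parent=m1"), f)
  genes <- read_gff3(f)
  expect_length(genes, 1)
  tx <- genes[[1]]$transcripts[[1]]
  expect_equal(unname(tx$exons), rbind(c(0L, 100L), c(200L, 300L)))
  expect_equal(unname(tx$cds_segments), rbind(c(50L, 100L), c(200L, 250L)))
  expect_equal(unname(tx$span), c(0L, 300L))
})

test_that("read_gff3 keeps multiple transcripts, skips orphans, flags bad lines", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\tmRNA\t1\t200\t.\t+\t.\tID=m2;Parent=g1",
    "chr1\tsrc\texon\t1\t300\t.\t+\t.\tParent=m1",
    "chr1\tsrc\texon\t1\t200\t.\t+\t.\tParent=m2",
    "chr1\tsrc\texon\t50\t80\t.\t+\t.\tID=orphan_exon"), f)
  expect_message(genes <- read_gff3(f), "without a parent")
  expect_length(genes[[1]]$transcripts, 2)

  writeLines(c("chr1\tsrc\tgene\tnotanumber\t5\t.\t+\t.\tID=g1"), f)
  expect_error(read_gff3(f), "line 1")
  writeLines("only three\tfields", f)
  expect_error(read_gff3(f), "columns")
  writeLines(character(), f)
  expect_length(read_gff3(f), 0)
})

test_that("longest-protein transcript selection maximizes CDS with id tie-break", {
  mk <- function(id, cds_len) transcript(id, rbind(c(0L, 2000L)),
                                         rbind(c(0L, cds_len)))
  g <- gene_model("g", "s", "+", list(mk("tX", 300L), mk("tY", 450L)))
  expect_equal(select_longest_protein_transcript(g)$transcript_id, "tY")
  g2 <- gene_model("g", "s", "+", list(mk("tB", 300L), mk("tA", 300L)))
  expect_equal(select_longest_protein_transcript(g2)$transcript_id, "tA")
  g3 <- gene_model("g", "s", "+", list(mk("only", 30L)))
  expect_equal(select_longest_protein_transcript(g3)$transcript_id, "only")
  # no CDS anywhere: longest exonic length, flagged non-coding
  nc <- gene_model("g", "s", "+", list(
    transcript("a", rbind(c(0L, 100L))), transcript("b", rbind(c(0L, 500L)))))
  pick <- select_longest_protein_transcript(nc)
  expect_equal(pick$transcript_id, "b")
  expect_true(attr(pick, "noncoding"))
})

test_that("sequence encoding is one-hot with uniform mass on ambiguity codes", {
  enc <- encode_sequence("ANRGc")
  expect_equal(enc[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(enc[2, ], c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(enc[3, ], c(A = .5, C = 0, G = .5, T = 0))
  expect_equal(enc[4, ], c(A = 0, C = 0, G = 1, T = 0))
  expect_equal(enc[5, ], c(A = 0, C = 1, G = 0, T = 0))
  expect_true(all(abs(rowSums(encode_sequence("ACGTRYSWKMBDHVN")) - 1) < 1e-12))
  expect_error(encode_sequence("ACQT"), "position 3")
})

test_that("label encoding follows the four-region rules", {
  toy <- toy_gene_genome()
  lt <- encode_labels(list(toy$gene), toy$record$length, "+")
  cls <- lt$classes
  expect_equal(unique(cls[1:40]), 1L)          # upstream intergenic
  expect_equal(unique(cls[41:60]), 2L)         # 5' UTR
  expect_equal(unique(cls[61:90]), 3L)         # CDS exon 1
  expect_equal(unique(cls[91:110]), 4L)        # intron
  expect_equal(unique(cls[111:140]), 3L)       # CDS exon 2
  expect_equal(unique(cls[141:160]), 2L)       # 3' UTR
  expect_equal(unique(cls[161:200]), 1L)       # downstream intergenic
  # the other strand sees only intergenic
  expect_equal(unique(encode_labels(list(toy$gene), 200, "-")$classes), 1L)
})

test_that("an intron between pure-UTR exons is still labeled intron", {
  tx <- transcript("t", rbind(c(10L, 30L), c(50L, 120L)),
                   rbind(c(60L, 120L)))
  g <- gene_model("g", "s", "+", list(tx))
  cls <- encode_labels(list(g), 150L, "+")$classes
  expect_equal(unique(cls[31:50]), 4L)   # gap between UTR-only exon and next
  expect_equal(unique(cls[11:30]), 2L)
})

test_that("flag_errors masks broken transcripts and UTR-less flanks", {
  toy <- toy_gene_genome()
  # clean gene: no mask at all
  fe <- flag_errors(list(toy$gene), toy$record$length, toy$record$sequence, "+")
  expect_equal(sum(fe$weights == 0), 0)
  expect_equal(nrow(fe$flags), 0)

  # CDS length 31 (not divisible by 3): whole footprint masked
  tx <- toy$gene$transcripts[[1]]
  bad <- transcript("t1", tx$exons, rbind(c(60L, 90L), c(110L, 141L)))
  g_bad <- gene_model("g1", "toy", "+", list(bad))
  fe2 <- flag_errors(list(g_bad), toy$record$length, toy$record$sequence, "+")
  expect_true(all(fe2$weights[41:160] == 0))
  expect_true("cds_not_multiple_of_3" %in% fe2$flags$reason)

  # UTR-less transcript: adjacent intergenic masked to the sequence ends
  noutr <- transcript("t1", rbind(c(60L, 90L), c(110L, 140L)),
                      rbind(c(60L, 90L), c(110L, 140L)))
  g3 <- gene_model("g1", "toy", "+", list(noutr))
  fe3 <- flag_errors(list(g3), toy$record$length, toy$record$sequence, "+")
  expect_true(all(fe3$weights == 0))
  expect_true(all(c("missing_5p_utr", "missing_3p_utr") %in% fe3$flags$reason))
})

test_that("masking changes weights but never labels", {
  toy <- toy_gene_genome()
  tx <- toy$gene$transcripts[[1]]
  bad <- transcript("t1", tx$exons, rbind(c(60L, 90L), c(110L, 141L)))
  clean <- preprocess_annotation(list(toy$record), list(toy$gene),
                                 chunk_len = 200L, pool = 10L)
  broken <- preprocess_annotation(list(toy$record),
                                  list(gene_model("g1", "toy", "+", list(bad))),
                                  chunk_len = 200L, pool = 10L)
  expect_lt(sum(broken$tracks$toy$plus$weights),
            sum(clean$tracks$toy$plus$weights))
})

test_that("chunking arithmetic, padding and exclusions are exact", {
  set.seed(91)
  n <- 50000
  seqs <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  rec <- genome_record("s", seqs)
  mk_track <- function(n) list(classes = rep(c(1L, 3L), length.out = n),
                               weights = rep(1L, n))
  tracks <- list(s = list(plus = mk_track(n), minus = mk_track(n),
                          n_genes = 1L))
  chunks <- chunk_genome(list(rec), tracks, chunk_len = 20000L)
  plus <- Filter(function(ch) ch$strand == "+", chunks)
  expect_length(plus, 3)
  expect_equal(vapply(plus, `[[`, 0L, "pad_len"), c(0L, 0L, 10000L))
  # per-strand unpadded bases reconstruct the sequence length
  expect_equal(sum(vapply(plus, function(ch) 20000L - ch$pad_len, 0L)), n)
  # padded rows are all-zero with weight 0
  last <- plus[[3]]
  expect_true(all(last$input[10001:20000, ] == 0))
  expect_true(all(last$sample_weights[10001:20000] == 0))
  expect_true(all(rowSums(last$labels) == 1))

  # a fully masked chunk is dropped
  tracks$s$plus$weights[1:20000] <- 0L
  chunks2 <- chunk_genome(list(rec), tracks, chunk_len = 20000L)
  plus2 <- Filter(function(ch) ch$strand == "+", chunks2)
  expect_length(plus2, 2)
  expect_false(0L %in% vapply(plus2, `[[`, 0L, "start"))

  # a geneless sequence contributes nothing
  tracks$s$n_genes <- 0L
  expect_length(chunk_genome(list(rec), tracks, chunk_len = 20000L), 0)

  expect_error(chunk_genome(list(rec), tracks, chunk_len = 10007L),
               "multiple")
})

test_that("minus-strand chunks equal plus-strand chunks of the mirrored genome", {
  g <- small_genome(seed = 21, n_sequences = 1, seq_len = 50000)
  prep <- preprocess_annotation(g$records, g$truth)
  rec <- g$records[[1]]
  mirrored_rec <- genome_record(rec$seq_id, revcomp(rec$sequence))
  mirrored_genes <- lapply(g$truth, mirror_gene, len = rec$length)
  prep_m <- preprocess_annotation(list(mirrored_rec), mirrored_genes)
  minus <- Filter(function(ch) ch$strand == "-", prep$chunks)
  plus_m <- Filter(function(ch) ch$strand == "+", prep_m$chunks)
  expect_equal(length(minus), length(plus_m))
  for (i in seq_along(minus)) {
    expect_equal(minus[[i]]$start, plus_m[[i]]$start)
    expect_equal(minus[[i]]$input, plus_m[[i]]$input)
    expect_equal(minus[[i]]$labels, plus_m[[i]]$labels)
    expect_equal(minus[[i]]$sample_weights, plus_m[[i]]$sample_weights)
  }
})

test_that("N90-stratified split is deterministic and stratum-exact", {
  recs <- c(
    lapply(1:5, function(i) genome_record(paste0("big", i),
                                          strrep("A", 100))),
    lapply(1:5, function(i) genome_record(paste0("small", i),
                                          strrep("A", 10))))
  sp <- split_train_val(recs, fraction = 0.2, seed = 3)
  expect_equal(length(sp$val_ids), 2)
  expect_equal(sum(grepl("big", sp$val_ids)), 1)
  expect_equal(sum(grepl("small", sp$val_ids)), 1)
  expect_setequal(c(sp$train_ids, sp$val_ids),
                  vapply(recs, `[[`, "", "seq_id"))
  sp2 <- split_train_val(recs, fraction = 0.2, seed = 3)
  expect_identical(sp, sp2)
  sp0 <- split_train_val(recs, fraction = 0, seed = 3)
  expect_length(sp0$val_ids, 0)
  # single-sequence stratum goes to training with a warning
  recs2 <- c(list(genome_record("huge", strrep("A", 1000))), recs[6:9])
  expect_warning(sp3 <- split_train_val(recs2, 0.25, seed = 1),
                 "single sequence")
  expect_false("huge" %in% sp3$val_ids)
})

test_that("chunk store round trips losslessly and exposes metadata", {
  toy <- toy_gene_genome()
  prep <- preprocess_annotation(list(toy$record), list(toy$gene),
                                chunk_len = 100L, pool = 10L)
  expect_gt(length(prep$chunks), 0)
  store <- tempfile("store_")
  write_chunk_store(prep$chunks, store)
  back <- read_chunk_store(store)
  expect_equal(attr(back, "chunk_len"), 100L)
  expect_length(back, length(prep$chunks))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$input, prep$chunks[[i]]$input)
    expect_equal(back[[i]]$labels, prep$chunks[[i]]$labels)
    expect_equal(back[[i]]$sample_weights, prep$chunks[[i]]$sample_weights)
    expect_equal(back[[i]]$seq_id, prep$chunks[[i]]$seq_id)
    expect_equal(back[[i]]$start, prep$chunks[[i]]$start)
    expect_equal(back[[i]]$strand, prep$chunks[[i]]$strand)
    expect_equal(back[[i]]$pad_len, prep$chunks[[i]]$pad_len)
  }
  # empty store is valid
  empty <- tempfile("store_")
  write_chunk_store(list(), empty)
  expect_length(read_chunk_store(empty), 0)
  # corruption is detected
  unlink(file.path(store, "y.bin"))
  expect_error(read_chunk_store(store), "corrupt")
})
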