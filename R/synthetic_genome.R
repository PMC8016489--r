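# Desk-scale synthetic genomes from a parameterized gene grammar.
#
# Every gene is 5'UTR — CDS exons interleaved with introns — 3'UTR, with a
# canonical ATG start, TAA/TAG/TGA stop, GT..AG splice dinucleotides and a
# tunable codon-positional composition bias in the CDS. The intergenic
# background (and intron bodies) are AT-richer than genic sequence, which
# is what gives a small network a learnable compositional signal alongside
# the motif-level one. Genes are placed on both strands, separated by
# intergenic spacers; the emitted annotation is exact truth except for
# genes selected by `error_injection_rate`, whose records are deliberately
# corrupted (UTRs deleted, CDS truncated, or an exon boundary shifted).

BASES <- c("A", "C", "G", "T")

all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
}

sense_codons <- function() setdiff(sort(all_codons()), STOP_CODONS)

# Fixed, deterministic codon preference: favors G/C in the wobble position
# and G starts, creating a period-3 composition signal when bias > 0.
codon_pref_probs <- function() {
  cods <- sense_codons()
  third <- substr(cods, 3, 3)
  first <- substr(cods, 1, 1)
  w <- exp(1.5 * (third %in% c("G", "C")) + 0.5 * (first == "G"))
  w / sum(w)
}

sample_range <- function(r) if (r[1] >= r[2]) as.integer(r[1]) else
  sample(r[1]:r[2], 1)

random_seq <- function(n, gc) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Gene-grammar configuration for the synthetic genome generator
#'
#' Defaults emulate a compact, plant-like genome: short UTRs, CDS of
#' 0.6–1.5 kb with 1–4 AT-rich GT..AG introns, intergenic spacers at GC
#' 0.30 versus genic GC 0.50, and a codon bias of 0.75. Counting both
#' strands separately, these settings realize class fractions of roughly
#' intergenic 0.68, UTR 0.07, CDS 0.19, intron 0.06.
#'
#' @param seed RNG seed; the full output is a deterministic function of it.
#' @param n_sequences,seq_len number and length (bases) of sequences.
#' @param target_class_fractions expected 4-vector of class fractions
#'   (intergenic, UTR, CDS, intron), both strands counted.
#' @param utr_len,cds_len,intron_len,intergenic_len integer min/max length
#'   ranges; realized CDS lengths are forced to multiples of 3.
#' @param introns_per_gene min/max introns per gene.
#' @param codon_bias_strength 0–1; 0 means uniform usage of the 61 sense
#'   codons, 1 means fully preferred usage.
#' @param gc_intergenic,gc_genic,gc_intron base compositions.
#' @param error_injection_rate fraction of genes whose emitted annotation is
#'   corrupted (the sequence stays truthful).
#' @return object of class `"grammar_config"`.
#' @export
grammar_config <- function(seed = 1L, n_sequences = 8L, seq_len = 125000L,
                           target_class_fractions =
                             c(intergenic = 0.68, utr = 0.07,
                               cds = 0.19, intron = 0.06),
                           utr_len = c(100L, 300L),
                           cds_len = c(600L, 1500L),
                           intron_len = c(60L, 200L),
                           intergenic_len = c(500L, 1500L),
                           introns_per_gene = c(1L, 4L),
                           codon_bias_strength = 0.75,
                           gc_intergenic = 0.30, gc_genic = 0.50,
                           gc_intron = 0.35,
                           error_injection_rate = 0) {
  cfg <- list(seed = seed, n_sequences = n_sequences, seq_len = seq_len,
              target_class_fractions = target_class_fractions,
              utr_len = utr_len, cds_len = cds_len, intron_len = intron_len,
              intergenic_len = intergenic_len,
              introns_per_gene = introns_per_gene,
              codon_bias_strength = codon_bias_strength,
              gc_intergenic = gc_intergenic, gc_genic = gc_genic,
              gc_intron = gc_intron,
              error_injection_rate = error_injection_rate)
  stopifnot(abs(sum(cfg$target_class_fractions) - 1) < 1e-8,
            codon_bias_strength >= 0, codon_bias_strength <= 1,
            error_injection_rate >= 0, error_injection_rate <= 1,
            cds_len[1] >= 9, intron_len[1] >= 10, utr_len[1] >= 1)
  max_gene <- 2 * utr_len[2] + cds_len[2] +
    introns_per_gene[2] * intron_len[2]
  if (max_gene > seq_len)
    stopf("infeasible grammar: maximal gene (%d bp) exceeds seq_len (%d)",
          max_gene, seq_len)
  structure(cfg, class = "grammar_config")
}

# Build one gene in sense orientation: sequence plus gene-relative exon and
# CDS intervals (0-based half-open).
build_gene_parts <- function(cfg) {
  u5 <- sample_range(cfg$utr_len)
  u3 <- sample_range(cfg$utr_len)
  clen <- sample_range(cfg$cds_len)
  clen <- clen - clen %% 3L
  n_internal <- clen / 3L - 2L
  cods <- sense_codons()
  probs <- (1 - cfg$codon_bias_strength) / length(cods) +
    cfg$codon_bias_strength * codon_pref_probs()
  body <- if (n_internal > 0)
    paste(sample(cods, n_internal, replace = TRUE, prob = probs),
          collapse = "") else ""
  cds_seq <- paste0("ATG", body, sample(STOP_CODONS, 1))
  k <- sample_range(cfg$introns_per_gene)
  k <- min(k, clen - 1L)
  bp <- if (k > 0) sort(sample(seq_len(clen - 1L), k)) else integer()
  il <- if (k > 0) vapply(seq_len(k), function(i)
    sample_range(cfg$intron_len), 0L) else integer()
  introns <- vapply(il, function(n)
    paste0("GT", random_seq(n - 4L, cfg$gc_intron), "AG"), "")
  piece_len <- diff(c(0L, bp, clen))
  pieces <- character(k + 1)
  off <- 0L
  for (i in seq_len(k + 1)) {
    pieces[i] <- substr(cds_seq, off + 1L, off + piece_len[i])
    off <- off + piece_len[i]
  }
  seq <- paste0(random_seq(u5, cfg$gc_genic),
                paste(rbind(pieces, c(introns, "")), collapse = ""),
                random_seq(u3, cfg$gc_genic))
  # gene-relative CDS segment starts (introns accumulate before segment i)
  cds_start <- u5 + c(0L, cumsum(piece_len))[seq_len(k + 1)] +
    c(0L, cumsum(il))[seq_len(k + 1)]
  cds_iv <- cbind(cds_start, cds_start + piece_len)
  glen <- u5 + clen + sum(il) + u3
  if (k == 0) {
    exons <- cbind(0L, glen)
  } else {
    ex_start <- c(0L, cds_iv[-1, 1])
    ex_end <- c(cds_iv[-(k + 1), 2], glen)
    exons <- cbind(ex_start, ex_end)
  }
  list(seq = seq, len = glen, exons = exons, cds = cds_iv)
}

mirror_iv <- function(iv, g0, glen) {
  cbind(g0 + glen - iv[, 2], g0 + glen - iv[, 1])[rev(seq_len(nrow(iv))), ,
                                                  drop = FALSE]
}

place_gene <- function(parts, g0, strand, seq_id, gid) {
  if (strand == "+") {
    ex <- parts$exons + g0
    cd <- parts$cds + g0
    gseq <- parts$seq
  } else {
    ex <- mirror_iv(parts$exons, g0, parts$len)
    cd <- mirror_iv(parts$cds, g0, parts$len)
    gseq <- revcomp(parts$seq)
  }
  list(seq = gseq,
       gene = gene_model(gid, seq_id, strand,
                         list(transcript(paste0(gid, ".t1"), ex, cd))))
}

corrupt_gene <- function(gene, mode, delta) {
  tx <- gene$transcripts[[1]]
  if (mode == "drop_utrs" || nrow(tx$exons) < 2 && mode == "shift_boundary") {
    lo <- min(tx$cds_segments[, 1]); hi <- max(tx$cds_segments[, 2])
    ex <- tx$exons
    ex[, 1] <- pmax(ex[, 1], lo); ex[, 2] <- pmin(ex[, 2], hi)
    ex <- ex[ex[, 2] > ex[, 1], , drop = FALSE]
    tx <- transcript(tx$transcript_id, ex, tx$cds_segments)
  } else if (mode == "truncate_cds") {
    d <- 1L + (delta %% 2L)  # 1 or 2 bases off the genomic right end
    seg <- tx$cds_segments
    i <- nrow(seg)
    seg[i, 2] <- seg[i, 2] - d
    tx <- transcript(tx$transcript_id, tx$exons, seg)
  } else {  # shift an internal exon boundary into the intron
    d <- c(1L, 2L, 4L, 5L)[1L + (delta %% 4L)]
    seg <- tx$cds_segments
    ex <- tx$exons
    i <- min(nrow(ex) - 1L, which.max(ex[, 2]))  # an internal exon end
    i <- max(1L, i)
    hit <- which(seg[, 2] == ex[i, 2])
    ex[i, 2] <- ex[i, 2] + d
    if (length(hit) == 1) seg[hit, 2] <- seg[hit, 2] + d
    tx <- transcript(tx$transcript_id, ex, seg)
  }
  gene$transcripts <- list(tx)
  gene
}

#' Generate a synthetic genome with known gene structure
#'
#' @param config a [grammar_config()].
#' @return list with `records` (genome records), `genes` (the emitted —
#'   possibly corrupted — annotation), `truth` (the exact annotation) and
#'   `corrupted_ids`. Identical seeds give byte-identical output.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "grammar_config"))
  with_seed(config$seed, {
    records <- list()
    truth <- list()
    emitted <- list()
    corrupted <- character()
    gid_n <- 0L
    for (s in seq_len(config$n_sequences)) {
      seq_id <- sprintf("synth_%02d", s)
      parts_acc <- character()
      pos <- 0L
      repeat {
        ig <- sample_range(config$intergenic_len)
        gp <- build_gene_parts(config)
        if (pos + ig + gp$len > config$seq_len) {
          parts_acc <- c(parts_acc,
                         random_seq(config$seq_len - pos,
                                    config$gc_intergenic))
          break
        }
        gid_n <- gid_n + 1L
        gid <- sprintf("g%04d", gid_n)
        strand <- sample(c("+", "-"), 1)
        placed <- place_gene(gp, pos + ig, strand, seq_id, gid)
        parts_acc <- c(parts_acc, random_seq(ig, config$gc_intergenic),
                       placed$seq)
        truth <- c(truth, list(placed$gene))
        g_emit <- placed$gene
        if (config$error_injection_rate > 0 &&
            stats::runif(1) < config$error_injection_rate) {
          mode <- sample(c("drop_utrs", "truncate_cds", "shift_boundary"), 1)
          g_emit <- corrupt_gene(g_emit, mode, sample.int(1000L, 1))
          corrupted <- c(corrupted, gid)
        }
        emitted <- c(emitted, list(g_emit))
        pos <- pos + ig + gp$len
      }
      records <- c(records,
                   list(genome_record(seq_id, paste(parts_acc, collapse = ""))))
    }
    list(records = records, genes = emitted, truth = truth,
         corrupted_ids = corrupted)
  })
}

#' Realized per-class base fractions of an annotated genome
#'
#' Fractions of the four classes over all unmasked bases, both strands
#' counted separately; sums to 1.
#'
#' @param records list of [genome_record()].
#' @param genes list of [gene_model()] (the truth annotation).
#' @return named numeric 4-vector.
#' @export
realized_class_fractions <- function(records, genes) {
  if (length(genes) == 0)
    stopf("no genes annotated: class fractions are undefined")
  genes <- reduce_to_longest(genes)
  counts <- stats::setNames(numeric(4), CLASS_NAMES)
  for (rec in records) {
    gs <- Filter(function(g) g$seq_id == rec$seq_id, genes)
    if (length(gs) == 0) next
    for (strand in c("+", "-")) {
      lt <- encode_labels(gs, rec$length, strand)
      fe <- flag_errors(gs, rec$length, rec$sequence, strand)
      keep <- fe$weights > 0
      tab <- tabulate(lt$classes[keep], nbins = 4)
      counts <- counts + tab
    }
  }
  counts / sum(counts)
}

# ---- RNA-seq coverage simulation -------------------------------------------

#' RNA-seq coverage simulation settings
#'
#' @param read_len read length in bases.
#' @param depth_exonic,depth_intergenic mean per-base depths.
#' @param splice_fidelity probability that a junction-spanning read reports
#'   the true intron (as an N gap) rather than reading through it.
#' @return object of class `"coverage_sim"`.
#' @export
coverage_sim <- function(read_len = 100L, depth_exonic = 30,
                         depth_intergenic = 0, splice_fidelity = 0.9) {
  stopifnot(read_len > 0, depth_exonic >= 0, depth_intergenic >= 0,
            splice_fidelity >= 0, splice_fidelity <= 1)
  structure(list(read_len = read_len, depth_exonic = depth_exonic,
                 depth_intergenic = depth_intergenic,
                 splice_fidelity = splice_fidelity),
            class = "coverage_sim")
}

# Map a transcript-coordinate interval [s, s+n) (over the ascending exon
# concatenation) to genomic segments; returns matrix of (start, end).
map_to_genome <- function(exons, s, n) {
  segs <- matrix(integer(), 0, 2)
  ex_len <- exons[, 2] - exons[, 1]
  offs <- c(0L, cumsum(ex_len))
  for (i in seq_len(nrow(exons))) {
    a <- max(s, offs[i]); b <- min(s + n, offs[i + 1])
    if (b > a)
      segs <- rbind(segs, c(exons[i, 1] + (a - offs[i]),
                            exons[i, 1] + (b - offs[i])))
  }
  segs
}

#' Simulate RNA-seq alignment records over a synthetic genome
#'
#' Emits SAM-style alignment records: exonic reads (M runs, with N gaps
#' spanning true introns for junction reads) at `depth_exonic`, and sparse
#' intergenic reads at `depth_intergenic`. With probability
#' `1 - splice_fidelity` a junction-spanning read reads through the intron
#' as a contiguous M run instead.
#'
#' @param records list of [genome_record()].
#' @param genes truth annotation ([gene_model()] list).
#' @param sim a [coverage_sim()].
#' @param seed RNG seed.
#' @return data.frame of alignment records (qname, flag, rname, pos
#'   (1-based), mapq, cigar, seq) suitable for [write_sam()].
#' @export
simulate_coverage <- function(records, genes, sim = coverage_sim(),
                              seed = 1L) {
  genes <- reduce_to_longest(genes)
  rl <- sim$read_len
  rows <- list()
  with_seed(seed, {
    n_read <- 0L
    for (rec in records) {
      gs <- Filter(function(g) g$seq_id == rec$seq_id, genes)
      for (g in gs) {
        tx <- g$transcripts[[1]]
        ex <- tx$exons
        SL <- sum(ex[, 2] - ex[, 1])
        if (SL < rl) next
        n <- stats::rpois(1, sim$depth_exonic * SL / rl)
        if (n == 0) next
        starts <- sample.int(SL - rl + 1L, n, replace = TRUE) - 1L
        for (s in starts) {
          segs <- map_to_genome(ex, s, rl)
          spliced <- nrow(segs) > 1
          if (spliced && stats::runif(1) >= sim$splice_fidelity) {
            g_start <- segs[1, 1]
            if (g_start + rl > rec$length) next
            cigar <- sprintf("%dM", rl)
            segs <- cbind(g_start, g_start + rl)
          } else {
            ops <- sprintf("%dM", segs[, 2] - segs[, 1])
            if (spliced) {
              gaps <- sprintf("%dN", segs[-1, 1] - segs[-nrow(segs), 2])
              cigar <- paste0(paste0(ops[-length(ops)], gaps, collapse = ""),
                              ops[length(ops)])
            } else cigar <- ops
          }
          n_read <- n_read + 1L
          sq <- paste(vapply(seq_len(nrow(segs)), function(i)
            substr(rec$sequence, segs[i, 1] + 1L, segs[i, 2]), ""),
            collapse = "")
          rows[[n_read]] <- data.frame(
            qname = sprintf("read%07d", n_read),
            flag = if (g$strand == "+") 0L else 16L,
            rname = rec$seq_id, pos = segs[1, 1] + 1L, mapq = 60L,
            cigar = cigar, seq = sq, stringsAsFactors = FALSE)
        }
      }
      if (sim$depth_intergenic > 0) {
        spans <- if (length(gs))
          t(vapply(gs, gene_span, c(0L, 0L))) else matrix(integer(), 0, 2)
        ig <- complement_intervals(spans, rec$length)
        ig <- ig[ig[, 2] - ig[, 1] >= rl, , drop = FALSE]
        if (nrow(ig) > 0) {
          total <- sum(ig[, 2] - ig[, 1])
          n <- stats::rpois(1, sim$depth_intergenic * total / rl)
          if (n > 0) {
            pick <- sample.int(nrow(ig), n, replace = TRUE,
                               prob = ig[, 2] - ig[, 1] - rl + 1)
            for (i in pick) {
              s <- ig[i, 1] +
                sample.int(ig[i, 2] - ig[i, 1] - rl + 1L, 1) - 1L
              n_read <- n_read + 1L
              rows[[n_read]] <- data.frame(
                qname = sprintf("read%07d", n_read), flag = 0L,
                rname = rec$seq_id, pos = s + 1L, mapq = 60L,
                cigar = sprintf("%dM", rl),
                seq = substr(rec$sequence, s + 1L, s + rl),
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  })
  if (length(rows) == 0)
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

complement_intervals <- function(iv, len) {
  if (nrow(iv) == 0) return(matrix(c(0L, len), 1, 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- matrix(integer(), 0, 2)
  pos <- 0L
  for (i in seq_len(nrow(iv))) {
    if (iv[i, 1] > pos) out <- rbind(out, c(pos, iv[i, 1]))
    pos <- max(pos, iv[i, 2])
  }
  if (pos < len) out <- rbind(out, c(pos, len))
  out
}

#' Write alignment records as a SAM file
#'
#' @param alignments data.frame from [simulate_coverage()].
#' @param records list of [genome_record()] (for the header).
#' @param path output file.
#' @export
write_sam <- function(alignments, records, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(records, function(r)
             sprintf("@SQ\tSN:%s\tLN:%d", r$seq_id, r$length), ""))
  body <- if (nrow(alignments) == 0) character() else
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            alignments$qname, alignments$flag, alignments$rname,
            alignments$pos, alignments$mapq, alignments$cigar,
            alignments$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}
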