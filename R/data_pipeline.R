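# FASTA + GFF3 -> masked, chunked, numerically encoded training arrays.
#
# Internal coordinate convention: 0-based half-open throughout ([start, end)),
# converted from GFF3's 1-based inclusive on read. Intervals are integer
# matrices with columns start, end. Labels use class indices 1..4 =
# intergenic, UTR, CDS, intron.

# ---- domain constructors ----------------------------------------------------

#' Genome record
#'
#' One assembly sequence with identifier and (upper-case) IUPAC bases.
#'
#' @param seq_id sequence identifier.
#' @param sequence IUPAC nucleotide string.
#' @return object of class `"genome_record"`.
#' @export
genome_record <- function(seq_id, sequence) {
  sequence <- toupper(sequence)
  structure(list(seq_id = seq_id, sequence = sequence,
                 length = nchar(sequence)),
            class = "genome_record")
}

#' Transcript
#'
#' Exon and CDS intervals in internal 0-based half-open coordinates. Exons
#' are sorted and must not overlap; introns are the gaps between consecutive
#' exons.
#'
#' @param transcript_id identifier.
#' @param exons integer matrix (start, end), 0-based half-open.
#' @param cds_segments integer matrix (start, end); may have zero rows.
#' @return object of class `"transcript"`.
#' @export
transcript <- function(transcript_id, exons, cds_segments = NULL) {
  exons <- as_intervals(exons)
  cds_segments <- as_intervals(cds_segments)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds_segments <- cds_segments[order(cds_segments[, 1]), , drop = FALSE]
  if (nrow(exons) == 0) stopf("transcript '%s' has no exons", transcript_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stopf("transcript '%s' has overlapping exons", transcript_id)
  span <- c(min(exons[, 1]), max(exons[, 2]))
  structure(list(transcript_id = transcript_id, exons = exons,
                 cds_segments = cds_segments, span = span),
            class = "transcript")
}

#' Gene model
#'
#' Hierarchical annotation: gene -> transcripts -> exon/CDS segments, all on
#' one strand of one sequence.
#'
#' @param gene_id identifier.
#' @param seq_id sequence the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param transcripts list of [transcript()] objects (at least one).
#' @return object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, seq_id, strand, transcripts) {
  if (!strand %in% c("+", "-")) stopf("gene '%s': strand must be + or -", gene_id)
  if (length(transcripts) < 1) stopf("gene '%s' has no transcripts", gene_id)
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

as_intervals <- function(x) {
  if (is.null(x)) return(matrix(integer(), 0, 2,
                                dimnames = list(NULL, c("start", "end"))))
  x <- matrix(as.integer(x), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (any(x[, 2] <= x[, 1])) stopf("empty or inverted interval")
  x
}

gene_span <- function(gene) {
  sp <- sapply(gene$transcripts, function(t) t$span)
  c(min(sp[1, ]), max(sp[2, ]))
}

# ---- FASTA ------------------------------------------------------------------

#' Read a FASTA file into genome records
#'
#' Sequences are upper-cased; the identifier is the first whitespace-limited
#' token of the header. Duplicate identifiers are a parse error.
#'
#' @param path FASTA file.
#' @return list of [genome_record()] objects (empty list for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  if (file.size(path) == 0) return(list())
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stopf("FASTA parse error in %s: %s",
                                           path, conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stopf("duplicate FASTA identifier(s): %s", paste(unique(dup), collapse = ", "))
  lapply(seq_along(ss), function(i)
    genome_record(ids[i], as.character(ss[[i]])))
}

#' Write genome records as FASTA
#'
#' @param records list of [genome_record()].
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(ss) <- vapply(records, `[[`, "", "seq_id")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# ---- GFF3 -------------------------------------------------------------------

parse_gff3_attrs <- function(s) {
  out <- list()
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (!nzchar(kv)) next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    out[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  out
}

#' Read a GFF3 annotation into gene models
#'
#' Parses gene / mRNA (or transcript) / exon / CDS features with ID/Parent
#' attributes. GFF3 1-based inclusive coordinates become internal 0-based
#' half-open. Features that cannot be tied to a gene are reported via a
#' message and skipped. Transcripts whose CDS extends outside their exons
#' are kept but flagged (the masking step picks this up).
#'
#' @param path GFF3 file.
#' @return list of [gene_model()] objects.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  genes <- list()      # id -> list(seq_id, strand)
  mrnas <- list()      # id -> parent gene id
  mrna_meta <- list()
  exons <- list()      # mrna id -> list of c(start, end)
  cds <- list()
  orphans <- character()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stopf("GFF3 parse error at line %d of %s: expected 9 columns, got %d",
            i, path, length(f))
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 1 || end < start)
      stopf("GFF3 parse error at line %d of %s: bad coordinates", i, path)
    type <- f[3]
    attrs <- parse_gff3_attrs(f[9])
    iv <- c(start - 1L, end)  # to 0-based half-open
    if (type == "gene") {
      id <- attrs$ID %||% sprintf("gene_line%d", i)
      genes[[id]] <- list(seq_id = f[1], strand = f[7])
    } else if (type %in% c("mRNA", "transcript")) {
      id <- attrs$ID %||% sprintf("mrna_line%d", i)
      parent <- attrs$Parent
      if (is.null(parent)) { orphans <- c(orphans, id); next }
      mrnas[[id]] <- parent
      mrna_meta[[id]] <- list(seq_id = f[1], strand = f[7])
    } else if (type %in% c("exon", "CDS")) {
      parents <- strsplit(attrs$Parent %||% "", ",", fixed = TRUE)[[1]]
      if (length(parents) == 0) {
        orphans <- c(orphans, sprintf("%s@line%d", type, i))
        next
      }
      for (p in parents) {
        if (type == "exon") exons[[p]] <- c(exons[[p]], list(iv))
        else cds[[p]] <- c(cds[[p]], list(iv))
      }
    }
    # other feature types are ignored
  }
  if (length(orphans) > 0)
    message(sprintf("read_gff3: skipped %d feature(s) without a parent gene: %s",
                    length(orphans), paste(utils::head(orphans, 5), collapse = ", ")))
  # assemble
  by_gene <- if (length(mrnas) == 0) list()
  else split(names(mrnas), unlist(mrnas))
  out <- list()
  for (gid in names(by_gene)) {
    if (is.null(genes[[gid]])) {
      message(sprintf("read_gff3: mRNA(s) of unknown gene '%s' skipped", gid))
      next
    }
    txs <- list()
    for (tid in sort(by_gene[[gid]])) {
      ex <- exons[[tid]]
      cd <- cds[[tid]]
      if (is.null(ex) && is.null(cd)) next
      ex_m <- if (is.null(ex)) do.call(rbind, cd) else do.call(rbind, ex)
      cd_m <- if (is.null(cd)) NULL else do.call(rbind, cd)
      txs <- c(txs, list(transcript(tid, ex_m, cd_m)))
    }
    if (length(txs) == 0) next
    g <- genes[[gid]]
    out <- c(out, list(gene_model(gid, g$seq_id, g$strand, txs)))
  }
  out[order(vapply(out, `[[`, "", "gene_id"))]
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA / exon / CDS records with ID/Parent attributes,
#' converting internal 0-based half-open coordinates back to GFF3's
#' 1-based inclusive. Deterministic ordering (by sequence, then start).
#'
#' @param genes list of [gene_model()].
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  ord <- order(vapply(genes, `[[`, "", "seq_id"),
               vapply(genes, function(g) gene_span(g)[1], 0L))
  for (g in genes[ord]) {
    sp <- gene_span(g)
    fmt <- function(type, iv, id, parent = NULL) {
      attrs <- paste0("ID=", id)
      if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
      sprintf("%s\thelixlite\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$seq_id, type, iv[1] + 1L, iv[2], g$strand, attrs)
    }
    lines <- c(lines, fmt("gene", sp, g$gene_id))
    for (t in g$transcripts) {
      lines <- c(lines, fmt("mRNA", t$span, t$transcript_id, g$gene_id))
      for (i in seq_len(nrow(t$exons)))
        lines <- c(lines, fmt("exon", t$exons[i, ],
                              sprintf("%s.exon%d", t$transcript_id, i),
                              t$transcript_id))
      for (i in seq_len(nrow(t$cds_segments)))
        lines <- c(lines, fmt("CDS", t$cds_segments[i, ],
                              sprintf("%s.cds%d", t$transcript_id, i),
                              t$transcript_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- transcript selection ---------------------------------------------------

cds_length <- function(tx) if (nrow(tx$cds_segments) == 0) 0L else
  sum(tx$cds_segments[, 2] - tx$cds_segments[, 1])

exonic_length <- function(tx) sum(tx$exons[, 2] - tx$exons[, 1])

#' Select the transcript with the longest protein
#'
#' Returns the transcript maximizing total CDS length; ties are broken by
#' ascending transcript id. If no transcript has any CDS, the transcript
#' with the longest exonic length is returned with attribute
#' `noncoding = TRUE`.
#'
#' @param gene a [gene_model()].
#' @return a [transcript()].
#' @export
select_longest_protein_transcript <- function(gene) {
  lens <- vapply(gene$transcripts, cds_length, 0L)
  ids <- vapply(gene$transcripts, `[[`, "", "transcript_id")
  if (all(lens == 0)) {
    ex <- vapply(gene$transcripts, exonic_length, 0L)
    pick <- order(-ex, ids)[1]
    tx <- gene$transcripts[[pick]]
    attr(tx, "noncoding") <- TRUE
    return(tx)
  }
  pick <- order(-lens, ids)[1]
  gene$transcripts[[pick]]
}

# Reduce each gene to its longest-protein transcript.
reduce_to_longest <- function(genes) {
  lapply(genes, function(g) {
    g$transcripts <- list(select_longest_protein_transcript(g))
    g
  })
}

# ---- sequence encoding ------------------------------------------------------

iupac_encoding_table <- function() {
  sets <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  tab <- matrix(0, length(sets), 4,
                dimnames = list(names(sets), c("A", "C", "G", "T")))
  for (nm in names(sets))
    tab[nm, sets[[nm]]] <- 1 / length(sets[[nm]])
  tab
}

#' Encode an IUPAC nucleotide string as an L x 4 matrix
#'
#' Column order A, C, G, T. Unambiguous bases are one-hot; an ambiguity code
#' spreads uniform mass over its base set, so `N` becomes
#' `[0.25, 0.25, 0.25, 0.25]` and every row sums to 1.
#'
#' @param sequence IUPAC nucleotide string (case-insensitive).
#' @return numeric matrix, one row per base.
#' @export
encode_sequence <- function(sequence) {
  tab <- iupac_encoding_table()
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(tab))
  if (anyNA(idx))
    stopf("non-IUPAC character '%s' at position %d",
          chars[which(is.na(idx))[1]], which(is.na(idx))[1])
  out <- tab[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- label encoding ---------------------------------------------------------

fill_iv <- function(v, iv, value) {
  s <- max(iv[1], 0L); e <- min(iv[2], length(v))
  if (e > s) v[(s + 1L):e] <- value
  v
}

#' Encode per-base structural labels for one strand
#'
#' A base outside all transcript spans is intergenic; within a span it is
#' CDS if inside a CDS segment, UTR if inside an exon but outside the CDS,
#' and intron otherwise (introns between pure-UTR exons are intron too —
#' the encoding does not distinguish coding from non-coding introns).
#' Overlapping same-strand genes are resolved in favor of the
#' earlier-starting gene; the overlap interval is returned for masking.
#'
#' @param genes list of [gene_model()] (already reduced to one transcript
#'   each, see [select_longest_protein_transcript()]).
#' @param seq_len sequence length in bases.
#' @param strand `"+"` or `"-"`; only genes on this strand contribute.
#' @return a `"label_track"`: list with `classes` (integer vector, 1..4),
#'   `weights` (all 1; see [flag_errors()]), and `overlaps` (interval matrix
#'   of same-strand overlap regions).
#' @export
encode_labels <- function(genes, seq_len, strand) {
  genes <- Filter(function(g) g$strand == strand, genes)
  cls <- rep(1L, seq_len)
  spans <- t(vapply(genes, gene_span, c(0L, 0L)))
  ord <- if (length(genes)) order(spans[, 1]) else integer()
  overlaps <- matrix(integer(), 0, 2)
  covered_to <- -1L
  for (k in ord) {
    g <- genes[[k]]
    tx <- g$transcripts[[1]]
    sp <- tx$span
    if (sp[1] < covered_to)  # same-strand overlap with an earlier gene
      overlaps <- rbind(overlaps, c(sp[1], min(sp[2], covered_to)))
    paint_from <- max(sp[1], covered_to)
    if (sp[2] > paint_from) {
      cls <- fill_iv(cls, c(paint_from, sp[2]), 4L)  # intron by default
      for (i in seq_len(nrow(tx$exons))) {
        iv <- c(max(tx$exons[i, 1], paint_from), tx$exons[i, 2])
        if (iv[2] > iv[1]) cls <- fill_iv(cls, iv, 2L)
      }
      for (i in seq_len(nrow(tx$cds_segments))) {
        iv <- c(max(tx$cds_segments[i, 1], paint_from), tx$cds_segments[i, 2])
        if (iv[2] > iv[1]) cls <- fill_iv(cls, iv, 3L)
      }
    }
    covered_to <- max(covered_to, sp[2])
  }
  structure(list(classes = cls, weights = rep(1L, seq_len),
                 overlaps = overlaps),
            class = "label_track")
}

# ---- error flagging / masking ----------------------------------------------

spliced_cds_seq <- function(tx, sequence, strand) {
  segs <- tx$cds_segments
  if (nrow(segs) == 0) return("")
  parts <- vapply(seq_len(nrow(segs)), function(i)
    substr(sequence, segs[i, 1] + 1L, segs[i, 2]), "")
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

utr_lengths <- function(tx, strand) {
  # exonic bases 5' of the first CDS base and 3' of the last, in transcript
  # orientation
  if (nrow(tx$cds_segments) == 0) return(c(five = 0L, three = 0L))
  cds_lo <- min(tx$cds_segments[, 1])
  cds_hi <- max(tx$cds_segments[, 2])
  left <- sum(pmax(0L, pmin(tx$exons[, 2], cds_lo) - tx$exons[, 1]))
  right <- sum(pmax(0L, tx$exons[, 2] - pmax(tx$exons[, 1], cds_hi)))
  if (strand == "+") c(five = left, three = right)
  else c(five = right, three = left)
}

cds_in_exons <- function(tx) {
  if (nrow(tx$cds_segments) == 0) return(TRUE)
  all(vapply(seq_len(nrow(tx$cds_segments)), function(i) {
    s <- tx$cds_segments[i, ]
    any(tx$exons[, 1] <= s[1] & tx$exons[, 2] >= s[2])
  }, TRUE))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Flag annotation errors and build the per-base sample-weight mask
#'
#' Applies the sanity rules: CDS segment outside exons, CDS length not
#' divisible by 3, missing ATG start codon, missing stop codon, missing
#' 5'/3' UTR, and same-strand gene overlap. Any failing transcript has its
#' footprint weighted 0; a missing UTR additionally masks the adjacent
#' intergenic region up to the neighboring same-strand gene (or the
#' sequence end), mirroring the behavior of annotation-error marking where
#' a missing UTR taints a potentially large flanking region.
#'
#' @param genes list of [gene_model()], one transcript each, on one strand.
#' @param seq_len sequence length.
#' @param sequence the genomic sequence (needed for start/stop checks).
#' @param strand `"+"` or `"-"`.
#' @return list with `weights` (integer vector in `{0,1}` of length
#'   `seq_len`) and `flags` (data.frame gene_id x reason).
#' @export
flag_errors <- function(genes, seq_len, sequence, strand) {
  genes <- Filter(function(g) g$strand == strand, genes)
  w <- rep(1L, seq_len)
  flags <- list()
  if (length(genes) == 0)
    return(list(weights = w,
                flags = data.frame(gene_id = character(), reason = character())))
  spans <- t(vapply(genes, gene_span, c(0L, 0L)))
  ord <- order(spans[, 1])
  genes <- genes[ord]; spans <- spans[ord, , drop = FALSE]
  n <- length(genes)
  for (k in seq_len(n)) {
    g <- genes[[k]]
    tx <- g$transcripts[[1]]
    reasons <- character()
    if (!cds_in_exons(tx)) reasons <- c(reasons, "cds_outside_exon")
    clen <- cds_length(tx)
    if (clen == 0) reasons <- c(reasons, "no_cds")
    if (clen > 0 && clen %% 3 != 0) reasons <- c(reasons, "cds_not_multiple_of_3")
    if (clen >= 3) {
      cseq <- spliced_cds_seq(tx, sequence, g$strand)
      if (substr(cseq, 1, 3) != "ATG") reasons <- c(reasons, "missing_start_codon")
      if (!substr(cseq, nchar(cseq) - 2, nchar(cseq)) %in% STOP_CODONS)
        reasons <- c(reasons, "missing_stop_codon")
    }
    ut <- utr_lengths(tx, g$strand)
    miss5 <- clen > 0 && ut["five"] == 0
    miss3 <- clen > 0 && ut["three"] == 0
    if (miss5) reasons <- c(reasons, "missing_5p_utr")
    if (miss3) reasons <- c(reasons, "missing_3p_utr")
    # same-strand overlap with neighbors
    ovl <- k > 1 && spans[k, 1] < spans[k - 1, 2] ||
           k < n && spans[k, 2] > spans[k + 1, 1]
    if (ovl) reasons <- c(reasons, "same_strand_overlap")
    if (length(reasons) > 0) {
      w <- fill_iv(w, spans[k, ], 0L)
      flags[[g$gene_id]] <- reasons
      # mask the adjacent intergenic stretch for missing UTRs; genomic left
      # is the 5' side for "+" genes and the 3' side for "-" genes
      mask_left <- (miss5 && g$strand == "+") || (miss3 && g$strand == "-")
      mask_right <- (miss3 && g$strand == "+") || (miss5 && g$strand == "-")
      if (mask_left) {
        from <- if (k > 1) spans[k - 1, 2] else 0L
        w <- fill_iv(w, c(min(from, spans[k, 1]), spans[k, 1]), 0L)
      }
      if (mask_right) {
        to <- if (k < n) spans[k + 1, 1] else seq_len
        w <- fill_iv(w, c(spans[k, 2], max(to, spans[k, 2])), 0L)
      }
      if (ovl) {
        if (k > 1 && spans[k, 1] < spans[k - 1, 2])
          w <- fill_iv(w, c(spans[k, 1], min(spans[k, 2], spans[k - 1, 2])), 0L)
        if (k < n && spans[k, 2] > spans[k + 1, 1])
          w <- fill_iv(w, c(max(spans[k, 1], spans[k + 1, 1]), spans[k, 2]), 0L)
      }
    }
  }
  fdf <- if (length(flags) == 0)
    data.frame(gene_id = character(), reason = character())
  else data.frame(gene_id = rep(names(flags), lengths(flags)),
                  reason = unlist(flags, use.names = FALSE))
  list(weights = w, flags = fdf)
}

# ---- chunking ---------------------------------------------------------------

new_chunk <- function(input, labels, sample_weights, seq_id, start, strand,
                      pad_len) {
  structure(list(input = input, labels = labels,
                 sample_weights = sample_weights, seq_id = seq_id,
                 start = start, strand = strand, pad_len = pad_len),
            class = "genome_chunk")
}

one_hot_labels <- function(classes, n_classes = 4L) {
  m <- matrix(0L, length(classes), n_classes)
  m[cbind(seq_along(classes), classes)] <- 1L
  m
}

chunk_one_strand <- function(sequence, classes, weights, seq_id, strand,
                             chunk_len, offset = 0L, enc = NULL) {
  L <- nchar(sequence)
  if (is.null(enc)) enc <- encode_sequence(sequence)
  if (offset >= L) return(list())
  starts <- seq(offset, L - 1L, by = chunk_len)
  out <- list()
  for (s in starts) {
    e <- min(s + chunk_len, L)
    n <- e - s
    pad <- chunk_len - n
    wts <- c(weights[(s + 1):e], rep(0L, pad))
    if (all(wts == 0)) next  # fully erroneous chunk: excluded
    inp <- matrix(0, chunk_len, 4)
    inp[seq_len(n), ] <- enc[(s + 1):e, , drop = FALSE]
    cls <- c(classes[(s + 1):e], rep(1L, pad))
    out <- c(out, list(new_chunk(inp, one_hot_labels(cls), wts, seq_id, s,
                                 strand, pad)))
  }
  out
}

#' Divide label-encoded genomes into fixed-length training chunks
#'
#' Each retained sequence is cut into consecutive non-overlapping windows of
#' `chunk_len` bases per strand. The minus strand is emitted
#' reverse-complemented (the network always reads 5'->3') with labels and
#' weights reversed accordingly; chunk `start` offsets on the minus strand
#' are in the reverse-complemented coordinate system. The final chunk is
#' zero-padded (padded bases have weight 0). Chunks whose weights are all 0
#' are dropped, and sequences with no annotated gene contribute nothing.
#'
#' @param records list of [genome_record()].
#' @param label_tracks named list (by seq_id) of
#'   `list(plus = , minus = , n_genes = )` where the strand entries are
#'   label tracks whose `weights` already include the error mask.
#' @param chunk_len chunk length in bases (default 20000).
#' @param pool network pool size; `chunk_len` must be a positive multiple.
#' @param offsets window-start offsets. The default `0` gives the plain
#'   consecutive tiling; adding a second pass offset by half a window
#'   (e.g. `c(0, chunk_len / 2)`) is a training-time augmentation that
#'   presents every locus in two window contexts (the leading partial
#'   window of an offset pass is dropped).
#' @return list of `"genome_chunk"` objects.
#' @export
chunk_genome <- function(records, label_tracks, chunk_len = 20000L,
                         pool = 10L, offsets = 0L) {
  if (chunk_len <= 0 || chunk_len %% pool != 0)
    stopf("chunk_len must be a positive multiple of the pool size (%d)", pool)
  if (any(offsets < 0 | offsets >= chunk_len))
    stopf("offsets must lie in [0, chunk_len)")
  out <- list()
  for (rec in records) {
    lt <- label_tracks[[rec$seq_id]]
    if (is.null(lt) || (lt$n_genes %||% 0) == 0) next
    rc <- revcomp(rec$sequence)
    enc_p <- encode_sequence(rec$sequence)
    enc_m <- encode_sequence(rc)
    for (off in as.integer(offsets)) {
      out <- c(out,
               chunk_one_strand(rec$sequence, lt$plus$classes,
                                lt$plus$weights, rec$seq_id, "+", chunk_len,
                                off, enc_p))
      out <- c(out,
               chunk_one_strand(rc, rev(lt$minus$classes),
                                rev(lt$minus$weights), rec$seq_id, "-",
                                chunk_len, off, enc_m))
    }
  }
  out
}

#' Full preprocessing: gene models to masked label tracks and chunks
#'
#' Reduces each gene to its longest-protein transcript, encodes per-base
#' labels for both strands, applies the error mask from [flag_errors()]
#' (plus same-strand overlap masking), and chunks the result.
#'
#' @param records list of [genome_record()].
#' @param genes list of [gene_model()].
#' @param chunk_len,pool,offsets see [chunk_genome()].
#' @return list with `chunks`, `tracks` (per-seq strand label tracks with
#'   masked weights) and `flags` (combined flag table).
#' @export
preprocess_annotation <- function(records, genes, chunk_len = 20000L,
                                  pool = 10L, offsets = 0L) {
  genes <- reduce_to_longest(genes)
  tracks <- list()
  flags <- list()
  for (rec in records) {
    gs <- Filter(function(g) g$seq_id == rec$seq_id, genes)
    entry <- list(n_genes = length(gs))
    for (strand in c("+", "-")) {
      lt <- encode_labels(gs, rec$length, strand)
      fe <- flag_errors(gs, rec$length, rec$sequence, strand)
      lt$weights <- pmin(lt$weights, fe$weights)
      if (nrow(lt$overlaps) > 0)
        for (i in seq_len(nrow(lt$overlaps)))
          lt$weights <- fill_iv(lt$weights, lt$overlaps[i, ], 0L)
      entry[[if (strand == "+") "plus" else "minus"]] <- lt
      if (nrow(fe$flags) > 0) flags <- c(flags, list(fe$flags))
    }
    tracks[[rec$seq_id]] <- entry
  }
  flags <- if (length(flags)) unique(do.call(rbind, flags))
  else data.frame(gene_id = character(), reason = character())
  list(chunks = chunk_genome(records, tracks, chunk_len, pool, offsets),
       tracks = tracks, flags = flags)
}

# ---- train/validation split -------------------------------------------------

#' N90 of a set of sequence lengths
#'
#' The length such that sequences of at least that length jointly contain
#' 90% of the total bases.
#'
#' @param lengths integer vector of sequence lengths.
#' @return the N90 length.
#' @export
n90 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= 0.9 * sum(s))[1]]
}

#' N90-stratified train/validation split
#'
#' Sequences are stratified into above-N90 (length >= N90) and below-N90
#' groups; within each stratum, `round(fraction * n)` sequences are chosen
#' uniformly at random (with the given seed) as the validation set. The
#' split is at whole-sequence level. A stratum with a single sequence goes
#' entirely to training, with a warning.
#'
#' @param records list of [genome_record()] (the retained sequences).
#' @param fraction validation fraction per stratum (default 0.2).
#' @param seed RNG seed.
#' @return a `"dataset_split"`: list with `train_ids`, `val_ids`, `n90`.
#' @export
split_train_val <- function(records, fraction = 0.2, seed = 1L) {
  if (length(records) < 1) stopf("need at least one retained sequence")
  ids <- vapply(records, `[[`, "", "seq_id")
  lens <- vapply(records, `[[`, 0L, "length")
  cut <- n90(lens)
  val <- character()
  with_seed(seed, {
    for (above in c(TRUE, FALSE)) {
      stratum <- ids[if (above) lens >= cut else lens < cut]
      if (length(stratum) == 0) next
      if (length(stratum) == 1) {
        warnf("stratum with a single sequence ('%s') assigned to training",
              stratum)
        next
      }
      k <- round(fraction * length(stratum))
      if (k > 0) val <- c(val, sample(stratum, k))
    }
  })
  structure(list(train_ids = setdiff(ids, val), val_ids = val, n90 = cut),
            class = "dataset_split")
}

# ---- chunk store ------------------------------------------------------------

#' Write chunks to an on-disk store
#'
#' A lightweight directory container with one flat binary array per data
#' type — `X` (input, double), `y` (one-hot labels, integer),
#' `sample_weights` (integer) — plus `meta.tsv` (seq_id, start, strand,
#' pad_len) and `attrs.json` (n_chunks, chunk_len). Round trips are
#' lossless and order-preserving.
#'
#' @param chunks list of `"genome_chunk"` objects (may be empty).
#' @param path store directory (created, overwritten if present).
#' @export
write_chunk_store <- function(chunks, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  chunk_len <- if (length(chunks)) nrow(chunks[[1]]$input) else NA_integer_
  con <- file(file.path(path, "X.bin"), "wb")
  for (ch in chunks) writeBin(as.vector(ch$input), con)
  close(con)
  con <- file(file.path(path, "y.bin"), "wb")
  for (ch in chunks) writeBin(as.integer(ch$labels), con)
  close(con)
  con <- file(file.path(path, "sample_weights.bin"), "wb")
  for (ch in chunks) writeBin(as.integer(ch$sample_weights), con)
  close(con)
  meta <- data.frame(
    seq_id = vapply(chunks, `[[`, "", "seq_id"),
    start = vapply(chunks, `[[`, 0L, "start"),
    strand = vapply(chunks, `[[`, "", "strand"),
    pad_len = vapply(chunks, `[[`, 0L, "pad_len"))
  utils::write.table(meta, file.path(path, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_chunks = length(chunks), chunk_len = chunk_len,
                            n_classes = 4L, format_version = 1L),
                       file.path(path, "attrs.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_chunk_store
#' @param path store directory written by [write_chunk_store()].
#' @return list of `"genome_chunk"` objects with attribute `chunk_len`.
#' @export
read_chunk_store <- function(path) {
  attrs_f <- file.path(path, "attrs.json")
  if (!file.exists(attrs_f)) stopf("not a chunk store (missing attrs.json): %s", path)
  attrs <- jsonlite::read_json(attrs_f)
  n <- attrs$n_chunks
  cl <- attrs$chunk_len
  if (n == 0) {
    out <- list()
    attr(out, "chunk_len") <- NA_integer_
    return(out)
  }
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stopf("corrupt chunk store: missing %s", f)
    fp
  }
  X <- readBin(need("X.bin"), "double", n * cl * 4)
  y <- readBin(need("y.bin"), "integer", n * cl * 4)
  w <- readBin(need("sample_weights.bin"), "integer", n * cl)
  if (length(X) != n * cl * 4 || length(y) != n * cl * 4 ||
      length(w) != n * cl)
    stopf("corrupt chunk store: array sizes do not match metadata")
  meta <- utils::read.table(need("meta.tsv"), header = TRUE, sep = "\t",
                            colClasses = c("character", "integer",
                                           "character", "integer"))
  if (nrow(meta) != n) stopf("corrupt chunk store: metadata row count mismatch")
  out <- lapply(seq_len(n), function(i) {
    off <- (i - 1) * cl * 4
    new_chunk(matrix(X[(off + 1):(off + cl * 4)], cl, 4),
              matrix(y[(off + 1):(off + cl * 4)], cl, 4),
              w[((i - 1) * cl + 1):(i * cl)],
              meta$seq_id[i], meta$start[i], meta$strand[i], meta$pad_len[i])
  })
  attr(out, "chunk_len") <- cl
  out
}
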