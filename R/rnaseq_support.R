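# Per-base RNA-seq coverage and spliced coverage from alignment records,
# and the breakdown of read support by the confusion cells of two
# annotations. Coverage counts reads whose CIGAR =, M or X operation
# covers a base; spliced coverage counts reads whose N or D operation
# spans it (evidence of an intron). Insertions and clips advance only the
# read. Each aligned segment is counted independently.

#' Read SAM-format alignment records
#'
#' Minimal reader for the fields the coverage quantification needs.
#'
#' @param path SAM file.
#' @return data.frame with qname, flag, rname, pos (1-based), mapq, cigar,
#'   seq.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stopf("SAM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0)
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      seq = character(), stringsAsFactors = FALSE))
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 11)
  if (length(bad) > 0)
    stopf("SAM parse error: alignment line %d has fewer than 11 fields", bad[1])
  data.frame(qname = vapply(f, `[[`, "", 1),
             flag = as.integer(vapply(f, `[[`, "", 2)),
             rname = vapply(f, `[[`, "", 3),
             pos = as.integer(vapply(f, `[[`, "", 4)),
             mapq = as.integer(vapply(f, `[[`, "", 5)),
             cigar = vapply(f, `[[`, "", 6),
             seq = vapply(f, `[[`, "", 10),
             stringsAsFactors = FALSE)
}

parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1) return(NULL)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) return(NULL)
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

#' Quantify per-base coverage and spliced coverage
#'
#' For each alignment record, bases under `=`, `M` or `X` operations
#' increment `coverage`; bases spanned by `N` or `D` operations increment
#' `spliced_coverage` (only — D bases do not also count as coverage).
#' Records whose CIGAR is unparseable, inconsistent with the stored read
#' length, or runs past the sequence end are skipped and counted.
#'
#' @param alignments data.frame as from [read_sam()] (or
#'   [simulate_coverage()]).
#' @param seq_len target sequence length.
#' @param seq_id restrict to this reference name (default: all records).
#' @return a `"coverage_track"`: list with `coverage` and
#'   `spliced_coverage` (integer vectors of length `seq_len`) and
#'   `skipped` (record count).
#' @export
quantify <- function(alignments, seq_len, seq_id = NULL) {
  if (!is.null(seq_id)) alignments <- alignments[alignments$rname == seq_id, ]
  cov_s <- integer(); cov_e <- integer()
  spl_s <- integer(); spl_e <- integer()
  skipped <- 0L
  for (i in seq_len(nrow(alignments))) {
    ops <- parse_cigar(alignments$cigar[i])
    if (is.null(ops)) { skipped <- skipped + 1L; next }
    sq <- alignments$seq[i]
    if (!is.na(sq) && sq != "*") {
      read_span <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
      if (read_span != nchar(sq)) { skipped <- skipped + 1L; next }
    }
    ref_span <- sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
    pos <- alignments$pos[i]  # 1-based
    if (pos < 1 || pos + ref_span - 1L > seq_len) { skipped <- skipped + 1L; next }
    for (j in seq_along(ops$op)) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("M", "=", "X")) {
        cov_s <- c(cov_s, pos); cov_e <- c(cov_e, pos + len - 1L)
        pos <- pos + len
      } else if (op %in% c("N", "D")) {
        spl_s <- c(spl_s, pos); spl_e <- c(spl_e, pos + len - 1L)
        pos <- pos + len
      }
      # I, S, H, P advance only the read
    }
  }
  sum_intervals <- function(s, e) {
    d <- integer(seq_len + 1L)
    if (length(s) > 0) {
      ts <- tabulate(s, nbins = seq_len + 1L)
      te <- tabulate(pmin(e + 1L, seq_len + 1L), nbins = seq_len + 1L)
      d <- ts - te
    }
    cumsum(d)[seq_len(seq_len)]
  }
  structure(list(coverage = sum_intervals(cov_s, cov_e),
                 spliced_coverage = sum_intervals(spl_s, spl_e),
                 skipped = skipped),
            class = "coverage_track")
}

#' Break down read support by the confusion cells of two annotations
#'
#' Every base is assigned to one (annotation A class, annotation B class)
#' cell; per cell, the fraction of bases falling into each coverage bin is
#' reported. Default bins are `{0}`, `[1,10)`, `[10,100)`, `[100,Inf)`.
#' Exonic cells (either class UTR or CDS) are the meaningful comparison
#' for coverage, intron cells for spliced coverage; the `displayed` column
#' marks them, but raw counts for all cells are always included.
#'
#' @param classesA,classesB integer class vectors (1..4) of equal length.
#' @param cov a `"coverage_track"` from [quantify()].
#' @param bins ascending nonzero bin thresholds (default `c(1, 10, 100)`).
#' @param use `"coverage"` or `"spliced_coverage"`.
#' @return data.frame with class_a, class_b, bin, n_cell, n, frac,
#'   displayed.
#' @export
support_breakdown <- function(classesA, classesB, cov,
                              bins = c(1, 10, 100), use = "coverage") {
  use <- match.arg(use, c("coverage", "spliced_coverage"))
  x <- cov[[use]]
  if (length(classesA) != length(classesB) ||
      length(classesA) != length(x))
    stopf("class tracks and coverage must have equal length")
  stopifnot(all(diff(bins) > 0), all(bins > 0))
  bin_idx <- findInterval(x, bins)  # 0 = zero bin
  bin_labels <- c("0", paste0("[", bins, ",", c(bins[-1], Inf), ")"))
  out <- list()
  for (a in 1:4) for (b in 1:4) {
    sel <- classesA == a & classesB == b
    n_cell <- sum(sel)
    tab <- tabulate(bin_idx[sel] + 1L, nbins = length(bins) + 1L)
    displayed <- if (use == "coverage") a %in% c(2, 3) || b %in% c(2, 3)
    else a == 4 || b == 4
    out <- c(out, list(data.frame(
      class_a = CLASS_NAMES[a], class_b = CLASS_NAMES[b],
      bin = bin_labels, n_cell = n_cell, n = tab,
      frac = if (n_cell > 0) tab / n_cell else
        c(1, rep(0, length(bins))),  # empty coverage => all mass in zero bin
      displayed = displayed, stringsAsFactors = FALSE)))
  }
  do.call(rbind, out)
}
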