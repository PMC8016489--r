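#' @useDynLib helixlite, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Class labels used everywhere, in fixed order. Index 1..4.
CLASS_NAMES <- c("intergenic", "utr", "cds", "intron")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never disturbs user-level reproducibility.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Reverse complement of an IUPAC nucleotide string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
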