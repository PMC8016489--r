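# In-silico mutagenesis: N-masking of motifs (rows become
# [0.25, 0.25, 0.25, 0.25]) and frame-preserving codon scrambling
# (3-bp blocks permuted, base composition untouched), with before/after
# prediction deltas under overlap inference.

#' Define a sequence perturbation
#'
#' @param region length-2 integer vector, 0-based half-open interval.
#' @param kind `"n_mask"` or `"codon_scramble"`.
#' @param seed RNG seed (codon_scramble only; the permutation is a
#'   deterministic function of it).
#' @return object of class `"perturbation"`.
#' @export
perturbation <- function(region, kind = c("n_mask", "codon_scramble"),
                         seed = 1L) {
  kind <- match.arg(kind)
  region <- as.integer(region)
  stopifnot(length(region) == 2, region[2] >= region[1], region[1] >= 0)
  if (kind == "codon_scramble" && (region[2] - region[1]) %% 3 != 0)
    stopf("codon_scramble region length must be divisible by 3")
  structure(list(region = region, kind = kind, seed = as.integer(seed)),
            class = "perturbation")
}

#' Apply a perturbation to an encoded sequence
#'
#' `n_mask` replaces every row in the region with the ambiguous-base
#' encoding `[0.25, 0.25, 0.25, 0.25]`. `codon_scramble` permutes the
#' region's 3-base blocks uniformly at random (block-internal order kept),
#' leaving the overall base composition identical. Bases outside the
#' region are untouched.
#'
#' @param encoded L x 4 encoded sequence (see [encode_sequence()]).
#' @param p a [perturbation()].
#' @return the perturbed L x 4 matrix.
#' @export
apply_perturbation <- function(encoded, p) {
  stopifnot(inherits(p, "perturbation"), is.matrix(encoded))
  r <- p$region
  if (r[2] > nrow(encoded)) stopf("perturbation region exceeds the sequence")
  if (r[1] == r[2]) return(encoded)
  idx <- (r[1] + 1L):r[2]
  if (p$kind == "n_mask") {
    encoded[idx, ] <- matrix(0.25, length(idx), 4)
  } else {
    n_blocks <- length(idx) / 3L
    perm <- with_seed(p$seed, sample.int(n_blocks))
    src <- rep((perm - 1L) * 3L, each = 3L) + rep(1:3, n_blocks)
    encoded[idx, ] <- encoded[idx[src], , drop = FALSE]
  }
  encoded
}

#' Prediction delta under a perturbation
#'
#' Runs overlap inference on the original and the perturbed sequence and
#' returns the per-base, per-class probability difference
#' (perturbed - original).
#'
#' @param model a `"helix_model"` (or prediction function).
#' @param record a [genome_record()], sequence string, or encoded matrix.
#' @param p a [perturbation()].
#' @param cfg an [overlap_config()].
#' @return L x 4 matrix of probability differences.
#' @export
prediction_delta <- function(model, record, p, cfg = overlap_config()) {
  rec <- as_encoded(record)
  orig <- predict_windows(model, rec$enc, cfg)
  pert <- predict_windows(model, apply_perturbation(rec$enc, p), cfg)
  pert$probs - orig$probs
}
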