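# Sliding-window overlap inference, extended input lengths and ensemble
# averaging. Windows start at 0, step, 2*step, ... with the last window
# right-aligned to the sequence end; each window is cropped to a core
# (min_core_margin trimmed from both ends) wherever other windows still
# cover the base, and the per-base probability is the arithmetic mean of
# the softmax outputs of all windows that retain that base. Averaging is
# done in probability space.

#' Overlap-inference configuration
#'
#' @param window_len window length in bases (divisible by the pool size).
#' @param step distance between window starts; default `window_len / 2`.
#' @param min_core_margin bases cropped from each window end when interior
#'   windows are available; default `window_len / 4`.
#' @param pool network pool size (window_len must be a multiple).
#' @return object of class `"overlap_config"`.
#' @export
overlap_config <- function(window_len = 20000L, step = window_len / 2,
                           min_core_margin = window_len / 4, pool = 10L) {
  window_len <- as.integer(window_len)
  step <- as.integer(step)
  min_core_margin <- as.integer(min_core_margin)
  if (step <= 0 || step > window_len)
    stopf("need 0 < step <= window_len")
  if (window_len < 2 * min_core_margin)
    stopf("window_len must be at least 2 * min_core_margin")
  if (window_len %% pool != 0)
    stopf("window_len must be divisible by the pool size")
  structure(list(window_len = window_len, step = step,
                 min_core_margin = min_core_margin, pool = as.integer(pool)),
            class = "overlap_config")
}

# Run the model on a list of encoded windows. `model` may be a
# "helix_model" or, for algebraic testing, a plain function mapping an
# L x 4 input matrix to an L x 4 probability matrix.
run_model <- function(model, X_list) {
  if (is.function(model)) lapply(X_list, model)
  else nn_forward_cpp(model$params, model$config, X_list)
}

as_encoded <- function(record) {
  if (is.matrix(record)) return(list(seq_id = "seq", enc = record))
  if (inherits(record, "genome_record"))
    return(list(seq_id = record$seq_id, enc = encode_sequence(record$sequence)))
  if (is.character(record) && length(record) == 1)
    return(list(seq_id = "seq", enc = encode_sequence(record)))
  stopf("record must be a genome_record, a sequence string or an encoded matrix")
}

#' Overlapping sliding-window prediction
#'
#' @param model a `"helix_model"` (or a function of the encoded input, for
#'   constructed tests).
#' @param record a [genome_record()], sequence string, or pre-encoded
#'   L x 4 matrix.
#' @param cfg an [overlap_config()].
#' @return a `"probability_track"`: list with `seq_id` and `probs`
#'   (L x 4, rows sum to 1, padding removed).
#' @export
predict_windows <- function(model, record, cfg = overlap_config()) {
  rec <- as_encoded(record)
  enc <- rec$enc
  L <- nrow(enc)
  wlen <- cfg$window_len
  starts <- if (L <= wlen) 0L else {
    s <- seq(0L, L - wlen, by = cfg$step)
    if (s[length(s)] < L - wlen) s <- c(s, L - wlen)
    s
  }
  nw <- length(starts)
  X_list <- lapply(starts, function(s) {
    e <- min(s + wlen, L)
    X <- matrix(0, wlen, 4)
    X[seq_len(e - s), ] <- enc[(s + 1):e, , drop = FALSE]
    X
  })
  probs_list <- run_model(model, X_list)
  acc <- matrix(0, L, 4); cnt <- numeric(L)       # cropped pass
  acc_all <- matrix(0, L, 4); cnt_all <- numeric(L)  # uncropped fallback
  for (i in seq_len(nw)) {
    s <- starts[i]
    n_real <- min(s + wlen, L) - s
    p <- probs_list[[i]][seq_len(n_real), , drop = FALSE]
    idx <- (s + 1):(s + n_real)
    keep <- rep(TRUE, n_real)
    if (nw > 1 && cfg$min_core_margin > 0) {
      if (i > 1) keep[seq_len(min(cfg$min_core_margin, n_real))] <- FALSE
      if (i < nw && n_real > cfg$min_core_margin)
        keep[(n_real - cfg$min_core_margin + 1):n_real] <- FALSE
    }
    acc[idx[keep], ] <- acc[idx[keep], ] + p[keep, , drop = FALSE]
    cnt[idx[keep]] <- cnt[idx[keep]] + 1
    acc_all[idx, ] <- acc_all[idx, ] + p
    cnt_all[idx] <- cnt_all[idx] + 1
  }
  hole <- cnt == 0  # bases every window cropped away: fall back to uncropped
  acc[hole, ] <- acc_all[hole, , drop = FALSE]
  cnt[hole] <- cnt_all[hole]
  structure(list(seq_id = rec$seq_id, probs = acc / cnt),
            class = "probability_track")
}

#' Prediction with extended input length
#'
#' Same contract as [predict_windows()] with
#' `window_len = length_multiplier * chunk_len` (the model's training
#' length), reproducing inference on sequences far longer than anything
#' seen in training.
#'
#' @param model a `"helix_model"`.
#' @param record see [predict_windows()].
#' @param length_multiplier integer >= 1.
#' @return a `"probability_track"`.
#' @export
predict_extended <- function(model, record, length_multiplier = 1L) {
  if (length_multiplier < 1) stopf("length_multiplier must be >= 1")
  if (is.function(model)) stopf("predict_extended needs a trained model")
  wlen <- as.integer(length_multiplier * model$config$chunk_len)
  if (wlen %% model$config$pool != 0)
    stopf("resulting window length is not divisible by the pool size")
  predict_windows(model, record,
                  overlap_config(wlen, pool = model$config$pool))
}

#' Ensemble prediction
#'
#' Each member is overlap-averaged individually, then the member tracks
#' are averaged per base.
#'
#' @param models non-empty list of models.
#' @param record see [predict_windows()].
#' @param cfg an [overlap_config()].
#' @return a `"probability_track"`.
#' @export
ensemble_predict <- function(models, record, cfg = overlap_config()) {
  if (length(models) < 1) stopf("need at least one ensemble member")
  tracks <- lapply(models, predict_windows, record = record, cfg = cfg)
  lens <- vapply(tracks, function(t) nrow(t$probs), 0L)
  if (length(unique(lens)) != 1)
    stopf("ensemble members disagree on sequence length")
  probs <- Reduce(`+`, lapply(tracks, `[[`, "probs")) / length(tracks)
  structure(list(seq_id = tracks[[1]]$seq_id, probs = probs),
            class = "probability_track")
}

#' Accuracy and Genic F1 by position within the input window
#'
#' Diagnoses the window-edge effect: predictions made without overlap are
#' binned by their position inside the fixed-length input window (200 bp
#' bins by default) and scored per bin, so a 20 kb window yields 100 bins.
#'
#' @param probs probability matrix (or list of matrices) predicted with
#'   non-overlapping windows tiling from position 0.
#' @param truth integer class vector (or list) aligned with `probs`.
#' @param weights per-base weights (or list); 0 excludes a base.
#' @param window_len the window length the predictor used.
#' @param bin_size bin width in bases.
#' @return data.frame with bin, from, to, n, accuracy, genic_f1.
#' @export
edge_effect_profile <- function(probs, truth, weights = NULL,
                                window_len = 20000L, bin_size = 200L) {
  if (!is.list(probs)) probs <- list(probs)
  if (!is.list(truth)) truth <- list(truth)
  if (is.null(weights)) weights <- lapply(truth, function(t) rep(1L, length(t)))
  if (!is.list(weights)) weights <- list(weights)
  n_bins <- as.integer(ceiling(window_len / bin_size))
  cms <- lapply(seq_len(n_bins), function(i) matrix(0L, 4, 4))
  for (k in seq_along(probs)) {
    pred <- argmax_classes(probs[[k]])
    tr <- truth[[k]]
    w <- weights[[k]]
    pos <- (seq_along(tr) - 1L) %% window_len
    bin <- pos %/% bin_size + 1L
    keep <- w > 0
    for (b in unique(bin[keep])) {
      sel <- keep & bin == b
      cms[[b]] <- cms[[b]] + table(factor(tr[sel], levels = 1:4),
                                   factor(pred[sel], levels = 1:4))
    }
  }
  do.call(rbind, lapply(seq_len(n_bins), function(b) {
    cm <- cms[[b]]
    n <- sum(cm)
    data.frame(bin = b, from = (b - 1L) * bin_size, to = b * bin_size,
               n = n,
               accuracy = if (n > 0) sum(diag(cm)) / n else NA_real_,
               genic_f1 = if (n > 0)
                 suppressWarnings(genic_f1(cm)) else NA_real_)
  }))
}
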