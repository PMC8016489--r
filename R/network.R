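# Pooled-timestep stacked BLSTM classifier: configuration, training with
# class-weighted masked cross-entropy, per-epoch Genic-F1 validation,
# checkpointing, early stopping, and ensemble checkpoint selection.

#' Network configuration
#'
#' The reference architecture is 4 stacked bidirectional LSTM layers with
#' 256 units per direction, layer normalization between consecutive layers,
#' 10 bases of sequence per recurrent timestep and an independent softmax
#' over the 4 structural classes at every base (circa 5.4 million
#' parameters). Smaller settings are used for desk-scale training.
#'
#' @param n_layers number of stacked bidirectional layers.
#' @param units LSTM units per direction.
#' @param pool bases per recurrent timestep.
#' @param n_classes number of output classes.
#' @param chunk_len training sequence length (must be divisible by `pool`).
#' @param class_weights positive per-class loss weights; see
#'   [compute_class_weights()].
#' @param batch_size chunks per gradient step.
#' @param learning_rate Adam learning rate.
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param lr_decay multiplicative per-epoch learning-rate decay factor.
#' @param dropout inverted-dropout rate on the normalized between-layer
#'   activations during training (0 disables; inference never drops).
#' @param input_mask_rate training-time augmentation: each input base is
#'   independently replaced by the ambiguous encoding `[0.25 x4]` with
#'   this probability.
#' @param weight_decay decoupled (AdamW-style) weight decay coefficient.
#' @param recurrent_dropout variational recurrent dropout rate: the same
#'   hidden units are dropped from the recurrent path at every timestep
#'   of a batch (training only).
#' @param max_epochs training epoch cap.
#' @param early_stop_delta,early_stop_patience stop when the epoch-to-epoch
#'   improvement in validation Genic F1 is at most `early_stop_delta` for
#'   `early_stop_patience` consecutive epochs.
#' @param seed seed for weight initialization and shuffling.
#' @return object of class `"network_config"`.
#' @export
network_config <- function(n_layers = 4L, units = 256L, pool = 10L,
                           n_classes = 4L, chunk_len = 20000L,
                           class_weights = rep(1, 4), batch_size = 32L,
                           learning_rate = 1e-3, max_epochs = 20L,
                           early_stop_delta = 1e-4,
                           early_stop_patience = 2L, grad_clip = 5,
                           lr_decay = 1, dropout = 0,
                           input_mask_rate = 0, weight_decay = 0,
                           recurrent_dropout = 0, seed = 42L) {
  if (chunk_len %% pool != 0)
    stopf("chunk_len (%d) must be divisible by pool (%d)", chunk_len, pool)
  if (any(class_weights <= 0)) stopf("class weights must be positive")
  if (length(class_weights) != n_classes)
    stopf("need %d class weights", n_classes)
  structure(list(n_layers = as.integer(n_layers), units = as.integer(units),
                 pool = as.integer(pool), n_classes = as.integer(n_classes),
                 chunk_len = as.integer(chunk_len),
                 class_weights = class_weights,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_delta = early_stop_delta,
                 early_stop_patience = as.integer(early_stop_patience),
                 grad_clip = grad_clip, lr_decay = lr_decay,
                 dropout = dropout, input_mask_rate = input_mask_rate,
                 weight_decay = weight_decay,
                 recurrent_dropout = recurrent_dropout,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Build (initialize) a model
#'
#' Weight initialization is Glorot-uniform with unit forget-gate bias,
#' seeded by `config$seed`.
#'
#' @param config a [network_config()].
#' @return object of class `"helix_model"`: the flat parameter vector plus
#'   its configuration; accepts any input length divisible by `pool`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "network_config"))
  params <- with_seed(config$seed, nn_init_params_cpp(config))
  structure(list(params = params, config = config), class = "helix_model")
}

#' Number of trainable parameters
#'
#' @param x a `"helix_model"` or [network_config()].
#' @return parameter count.
#' @export
n_params <- function(x) {
  cfg <- if (inherits(x, "helix_model")) x$config else x
  nn_param_count_cpp(cfg)
}

#' @export
print.helix_model <- function(x, ...) {
  cat(sprintf(
    "<helix_model> %d x BLSTM(%d/direction), pool %d, %s parameters\n",
    x$config$n_layers, x$config$units, x$config$pool,
    format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' Weight of class c is proportional to `(1/fraction_c)^temper`,
#' normalized so that the fraction-weighted mean weight is 1
#' (i.e. `sum(f * w) == 1`). The default `temper = 1` is plain inverse
#' frequency; values below 1 soften the re-balancing (at desk scale,
#' `temper = 0.5` trades a little rare-class recall for much better
#' intergenic precision). A zero fraction gets the configured cap with a
#' warning.
#'
#' @param class_fractions positive 4-vector summing to 1.
#' @param max_weight cap applied to the raw inverse of a zero fraction.
#' @param temper exponent on the inverse frequency, in `[0, 1]`.
#' @return numeric weight vector.
#' @export
compute_class_weights <- function(class_fractions, max_weight = 1e4,
                                  temper = 1) {
  f <- class_fractions
  stopifnot(all(f >= 0), abs(sum(f) - 1) < 1e-6, temper >= 0, temper <= 1)
  inv <- ifelse(f > 0, 1 / f, NA)
  if (anyNA(inv)) {
    warnf("zero class fraction: weight capped at %g", max_weight)
    inv[is.na(inv)] <- max_weight
  }
  inv <- pmin(inv, max_weight)^temper
  inv / sum(f * inv)
}

# ---- training ---------------------------------------------------------------

chunk_class_ids <- function(chunk) max.col(chunk$labels, ties.method = "first")

chunks_to_arrays <- function(chunks) {
  list(X = lapply(chunks, `[[`, "input"),
       y0 = lapply(chunks, function(ch) chunk_class_ids(ch) - 1L),
       w = lapply(chunks, function(ch) as.numeric(ch$sample_weights)))
}

validation_metrics <- function(params, config, val) {
  preds <- nn_forward_cpp(params, config, val$X)
  cm <- matrix(0L, 4, 4)
  for (i in seq_along(preds))
    cm <- cm + confusion(preds[[i]], val$y0[[i]] + 1L, val$w[[i]])
  cm <- structure(cm, dimnames = list(truth = CLASS_NAMES,
                                      pred = CLASS_NAMES),
                  class = c("confusion_matrix4", "matrix", "array"))
  pf <- suppressWarnings(pooled_f1(cm, c("utr", "cds", "intron")))
  list(genic_f1 = pf$f1, precision = pf$precision, recall = pf$recall,
       cm = cm)
}

#' Has validation Genic F1 stopped improving?
#'
#' TRUE when the last `patience` epoch-to-epoch improvements are all at
#' most `delta`.
#'
#' @param f1_history per-epoch validation Genic F1 values so far.
#' @param delta minimal improvement that counts.
#' @param patience number of consecutive non-improvements required.
#' @return logical.
#' @export
early_stop_triggered <- function(f1_history, delta = 1e-4, patience = 2L) {
  if (length(f1_history) < patience + 1) return(FALSE)
  imp <- diff(f1_history)
  all(utils::tail(imp, patience) <= delta)
}

#' Train the classifier
#'
#' Loss is class-weighted cross-entropy with the per-base sample weights
#' multiplied in, so masked and padded bases contribute exactly zero.
#' After each epoch the validation Genic F1 (and pooled genic
#' precision/recall) is computed; a checkpoint is kept per epoch. Training
#' stops at `max_epochs` or when the Genic F1 improvement is at most
#' `early_stop_delta` for `early_stop_patience` consecutive epochs. The
#' best checkpoint is the epoch with the highest validation Genic F1
#' (earliest on ties).
#'
#' @param model a [build_model()] result.
#' @param train_chunks,val_chunks non-empty lists of genome chunks.
#' @param config overrides the model's config if supplied.
#' @param checkpoint_dir optional directory; per-epoch checkpoints are also
#'   serialized there as `epoch_###.rds`.
#' @param verbose print per-epoch progress.
#' @return a `"training_history"`: `table` (data.frame epoch, loss,
#'   val_genic_f1, val_precision, val_recall, checkpoint), `models`
#'   (per-epoch `"helix_model"` objects), `best_epoch`.
#' @export
train_network <- function(model, train_chunks, val_chunks,
                          config = model$config, checkpoint_dir = NULL,
                          verbose = FALSE) {
  if (length(train_chunks) == 0 || length(val_chunks) == 0)
    stopf("training and validation chunk sets must be non-empty")
  tr <- chunks_to_arrays(train_chunks)
  va <- chunks_to_arrays(val_chunks)
  genic_bases <- sum(vapply(seq_along(va$y0), function(i)
    sum(va$w[[i]] > 0 & va$y0[[i]] > 0), 0))
  if (genic_bases == 0)
    stopf("validation Genic F1 not computable: no unmasked genic bases in the validation set")
  params <- model$params
  m <- numeric(length(params)); v <- numeric(length(params)); step <- 0L
  n <- length(tr$X)
  hist_rows <- list()
  models <- list()
  f1s <- numeric()
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      lr_epoch <- config$learning_rate * config$lr_decay^(epoch - 1)
      res <- nn_train_epoch_cpp(params, m, v, step, config, tr$X, tr$y0,
                                tr$w, config$class_weights,
                                lr_epoch, ord, config$batch_size,
                                config$grad_clip, config$dropout,
                                config$input_mask_rate, config$weight_decay,
                                config$recurrent_dropout)
      params <- res$params; m <- res$adam_m; v <- res$adam_v
      step <- res$adam_step
      vm <- validation_metrics(params, config, va)
      ckpt <- NA_character_
      mod <- structure(list(params = params, config = config),
                       class = "helix_model")
      if (!is.null(checkpoint_dir)) {
        ckpt <- file.path(checkpoint_dir, sprintf("epoch_%03d.rds", epoch))
        saveRDS(mod, ckpt)
      }
      models[[epoch]] <- mod
      f1s <- c(f1s, vm$genic_f1)
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, loss = res$loss, val_genic_f1 = vm$genic_f1,
        val_precision = vm$precision, val_recall = vm$recall,
        checkpoint = ckpt, stringsAsFactors = FALSE)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val Genic F1 %.4f",
                        epoch, res$loss, vm$genic_f1))
      if (early_stop_triggered(f1s, config$early_stop_delta,
                               config$early_stop_patience)) break
    }
  })
  tab <- do.call(rbind, hist_rows)
  structure(list(table = tab, models = models,
                 best_epoch = which.max(tab$val_genic_f1)),
            class = "training_history")
}

#' @export
print.training_history <- function(x, ...) {
  print(x$table[, c("epoch", "loss", "val_genic_f1", "val_precision",
                    "val_recall")])
  cat(sprintf("best epoch: %d (Genic F1 %.4f)\n", x$best_epoch,
              x$table$val_genic_f1[x$best_epoch]))
  invisible(x)
}

#' Select ensemble checkpoints from independent training runs
#'
#' Per run, picks the epoch with the best validation Genic F1 plus a
#' complementary epoch so that both the best-precision and the best-recall
#' epochs are represented: if the best-F1 epoch attains the best precision,
#' the complement is the best-recall epoch (and vice versa); if it attains
#' neither, the complement is whichever of the best-precision/best-recall
#' epochs has the higher Genic F1. Ties always resolve to the earliest
#' epoch. Four runs thus yield the 8-member ensemble.
#'
#' @param histories list of `"training_history"` objects.
#' @return list of selections: each `list(run, epoch, model)` (model is
#'   `NULL` when the history carries none).
#' @export
select_ensemble_checkpoints <- function(histories) {
  out <- list()
  for (r in seq_along(histories)) {
    h <- histories[[r]]
    tab <- h$table
    if (is.null(tab$val_precision) || is.null(tab$val_recall))
      stopf("history %d lacks precision/recall records", r)
    bf <- which.max(tab$val_genic_f1)
    bp <- which.max(tab$val_precision)
    br <- which.max(tab$val_recall)
    second <- if (bf == bp) br
    else if (bf == br) bp
    else if (tab$val_genic_f1[bp] >= tab$val_genic_f1[br]) bp else br
    if (nrow(tab) == 1) {
      warnf("run %d has a single epoch; the same checkpoint is used twice", r)
      second <- bf
    }
    for (e in c(bf, second))
      out <- c(out, list(list(run = r, epoch = e,
                              model = if (length(h$models) >= e)
                                h$models[[e]] else NULL)))
  }
  out
}
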