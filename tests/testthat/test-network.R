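# Architecture constants, loss semantics, early stopping and ensemble
# checkpoint selection.

test_that("the reference configuration has the documented parameter count", {
  cfg <- network_config()  # 4 x 256/direction, pool 10, 4 classes
  # layer-shape arithmetic: first layer 2 x 4U(D+U+1) with D = 40,
  # three more with D = 512, three layer norms of 2x512, head 512x40+40
  by_hand <- 2 * (4 * 256 * (40 + 256 + 1)) +
    3 * 2 * (4 * 256 * (512 + 256 + 1)) +
    3 * (2 * (2 * 256)) +
    (2 * 256) * 40 + 40
  expect_equal(n_params(cfg), by_hand)
  expect_equal(n_params(cfg), 5356584)
  expect_equal(signif(n_params(cfg) / 1e6, 2), 5.4)
})

test_that("forward pass emits one softmax row per base at any pooled length", {
  m <- tiny_model(units = 8, n_layers = 2, chunk_len = 2000)
  # per-timestep head emits pool x n_classes = 40 values
  expect_equal(m$config$pool * m$config$n_classes, 40)
  set.seed(2)
  for (L in c(10, 200, 2000, 4000)) {  # any multiple of the pool size works
    X <- encode_sequence(paste(sample(c("A", "C", "G", "T"), L, TRUE),
                               collapse = ""))
    P <- helixlite:::nn_forward_cpp(m$params, m$config, list(X))[[1]]
    expect_equal(dim(P), c(L, 4))
    expect_true(all(abs(rowSums(P) - 1) < 1e-5))
  }
  X <- matrix(0.25, 17, 4)
  expect_error(helixlite:::nn_forward_cpp(m$params, m$config, list(X)),
               "divisible")
})

test_that("inverse-frequency class weights are normalized to unit weighted mean", {
  expect_equal(compute_class_weights(c(.25, .25, .25, .25)), rep(1, 4))
  expect_equal(compute_class_weights(c(.8, .05, .1, .05)),
               c(0.3125, 5, 2.5, 5))
  w <- compute_class_weights(c(.7, .1, .15, .05))
  expect_equal(sum(c(.7, .1, .15, .05) * w), 1)
  expect_warning(wz <- compute_class_weights(c(.5, .5, 0, 0)), "capped")
  expect_true(all(wz > 0))
})

make_random_chunk <- function(L = 200, seed = 1, w = NULL) {
  set.seed(seed)
  X <- encode_sequence(paste(sample(c("A", "C", "G", "T"), L, TRUE),
                             collapse = ""))
  y0 <- sample(0:3, L, TRUE)
  list(X = X, y0 = y0, w = w %||% rep(1, L))
}

test_that("the training loss with unit weights is plain mean cross-entropy", {
  m <- tiny_model(units = 6, n_layers = 1, chunk_len = 200)
  ch <- make_random_chunk(200, seed = 3)
  res <- helixlite:::nn_train_epoch_cpp(
    m$params, numeric(length(m$params)), numeric(length(m$params)), 0L,
    m$config, list(ch$X), list(ch$y0), list(ch$w), rep(1, 4),
    lr = 0, batch_order = 1L, batch_size = 1L, grad_clip = 0, dropout = 0, input_mask_rate = 0, weight_decay = 0, recurrent_dropout = 0)
  P <- helixlite:::nn_forward_cpp(m$params, m$config, list(ch$X))[[1]]
  manual <- -mean(log(P[cbind(1:200, ch$y0 + 1)]))
  expect_equal(res$loss, manual, tolerance = 1e-10)
  # lr = 0 leaves parameters untouched
  expect_equal(res$params, m$params)
})

test_that("fully masked chunks contribute zero loss and no update", {
  m <- tiny_model(units = 6, n_layers = 1, chunk_len = 200)
  ch <- make_random_chunk(200, seed = 4, w = rep(0, 200))
  res <- helixlite:::nn_train_epoch_cpp(
    m$params, numeric(length(m$params)), numeric(length(m$params)), 0L,
    m$config, list(ch$X), list(ch$y0), list(ch$w), rep(1, 4),
    lr = 0.01, batch_order = 1L, batch_size = 1L, grad_clip = 0, dropout = 0, input_mask_rate = 0, weight_decay = 0, recurrent_dropout = 0)
  expect_equal(res$loss, 0)
  expect_equal(res$params, m$params)
  expect_equal(res$adam_step, 0L)
})

test_that("rescaling all class weights leaves the update direction unchanged", {
  m <- tiny_model(units = 6, n_layers = 2, chunk_len = 200)
  ch <- make_random_chunk(200, seed = 5)
  run <- function(cw) helixlite:::nn_train_epoch_cpp(
    m$params, numeric(length(m$params)), numeric(length(m$params)), 0L,
    m$config, list(ch$X), list(ch$y0), list(ch$w), cw,
    lr = 1e-3, batch_order = 1L, batch_size = 1L, grad_clip = 0, dropout = 0, input_mask_rate = 0, weight_decay = 0, recurrent_dropout = 0)
  r1 <- run(c(1, 2, 1, 2))
  r2 <- run(2 * c(1, 2, 1, 2))
  # the weighted-mean loss is scale-free, and so is the adaptive update
  expect_equal(r1$loss, r2$loss, tolerance = 1e-12)
  expect_equal(r1$params, r2$params, tolerance = 1e-6)
})

test_that("batch loss is invariant to chunk order within one batch", {
  m <- tiny_model(units = 6, n_layers = 1, chunk_len = 200)
  c1 <- make_random_chunk(200, seed = 6)
  c2 <- make_random_chunk(200, seed = 7)
  run <- function(ord) helixlite:::nn_train_epoch_cpp(
    m$params, numeric(length(m$params)), numeric(length(m$params)), 0L,
    m$config, list(c1$X, c2$X), list(c1$y0, c2$y0), list(c1$w, c2$w),
    rep(1, 4), lr = 0, batch_order = ord, batch_size = 2L, grad_clip = 0, dropout = 0, input_mask_rate = 0, weight_decay = 0, recurrent_dropout = 0)
  expect_equal(run(c(1L, 2L))$loss, run(c(2L, 1L))$loss, tolerance = 1e-12)
})

test_that("a few gradient steps reduce the loss on a learnable toy problem", {
  m <- tiny_model(units = 8, n_layers = 1, chunk_len = 200)
  set.seed(8)
  # labels deterministically follow the base identity: learnable quickly
  X <- encode_sequence(paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                             collapse = ""))
  y0 <- max.col(X) - 1L
  params <- m$params
  mm <- numeric(length(params)); vv <- numeric(length(params)); st <- 0L
  losses <- numeric(60)
  for (i in 1:60) {
    res <- helixlite:::nn_train_epoch_cpp(
      params, mm, vv, st, m$config, list(X), list(y0), list(rep(1, 200)),
      rep(1, 4), lr = 1e-2, batch_order = 1L, batch_size = 1L, grad_clip = 0, dropout = 0, input_mask_rate = 0, weight_decay = 0, recurrent_dropout = 0)
    params <- res$params; mm <- res$adam_m; vv <- res$adam_v
    st <- res$adam_step
    losses[i] <- res$loss
  }
  expect_lt(losses[60], losses[1] * 0.3)
})

test_that("distant sequence context barely moves central predictions", {
  m <- tiny_model(units = 8, n_layers = 2, chunk_len = 2000)
  set.seed(9)
  base <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  suffix <- paste(sample(c("A", "T"), 4000, TRUE, prob = c(.7, .3)),
                  collapse = "")
  P1 <- helixlite:::nn_forward_cpp(m$params, m$config,
                                   list(encode_sequence(base)))[[1]]
  P2 <- helixlite:::nn_forward_cpp(m$params, m$config,
                                   list(encode_sequence(paste0(base, suffix))))[[1]]
  central <- 1000:2000
  expect_lt(max(abs(P1[central, ] - P2[central, ])), 0.05)
})

test_that("the early-stopping rule follows the improvement-threshold protocol", {
  # two consecutive improvements <= 1e-4 stop training after epoch 4
  expect_false(early_stop_triggered(c(0.50, 0.60, 0.60005)))
  expect_true(early_stop_triggered(c(0.50, 0.60, 0.60005, 0.60009)))
  # a real improvement resets the patience
  expect_false(early_stop_triggered(c(0.50, 0.50001, 0.60)))
  # a drop counts as a non-improvement
  expect_true(early_stop_triggered(c(0.50, 0.60, 0.59, 0.58)))
  expect_false(early_stop_triggered(c(0.60), patience = 2))
  expect_true(early_stop_triggered(c(.1, .2, .2, .2, .3, .3, .3)[1:4]))
})

fake_history <- function(f1, prec, rec) {
  structure(list(table = data.frame(
    epoch = seq_along(f1), loss = rev(seq_along(f1)),
    val_genic_f1 = f1, val_precision = prec, val_recall = rec,
    checkpoint = NA_character_), models = list(),
    best_epoch = which.max(f1)), class = "training_history")
}

test_that("ensemble checkpoint selection represents best precision and recall", {
  # best-F1 epoch (2) also has best precision: complement is best recall (3)
  h1 <- fake_history(c(.5, .8, .7), c(.6, .9, .7), c(.5, .7, .9))
  picks <- select_ensemble_checkpoints(list(h1))
  expect_equal(vapply(picks, `[[`, 0L, "epoch"), c(2L, 3L))
  # best-F1 epoch has best recall: complement is best precision
  h2 <- fake_history(c(.5, .8, .7), c(.9, .7, .6), c(.5, .9, .7))
  expect_equal(vapply(select_ensemble_checkpoints(list(h2)), `[[`, 0L,
                      "epoch"), c(2L, 1L))
  # identical metrics everywhere: earliest epoch for each criterion
  h3 <- fake_history(rep(.7, 4), rep(.8, 4), rep(.6, 4))
  expect_equal(vapply(select_ensemble_checkpoints(list(h3)), `[[`, 0L,
                      "epoch"), c(1L, 1L))
  # four runs yield the 8-member ensemble
  picks8 <- select_ensemble_checkpoints(list(h1, h2, h1, h2))
  expect_length(picks8, 8)
  # single-epoch run: same checkpoint twice, with a warning
  h4 <- fake_history(.6, .6, .6)
  expect_warning(p4 <- select_ensemble_checkpoints(list(h4)), "single epoch")
  expect_equal(vapply(p4, `[[`, 0L, "epoch"), c(1L, 1L))
})

test_that("train_network validates inputs and records one row per epoch", {
  toy <- toy_gene_genome()
  prep <- preprocess_annotation(list(toy$record), list(toy$gene),
                                chunk_len = 200L, pool = 10L)
  cfg <- network_config(n_layers = 1, units = 4, chunk_len = 200L,
                        max_epochs = 2, batch_size = 2, seed = 3)
  m <- build_model(cfg)
  h <- train_network(m, prep$chunks, prep$chunks)
  expect_equal(nrow(h$table), 2)
  expect_equal(h$best_epoch, which.max(h$table$val_genic_f1))
  expect_error(train_network(m, list(), prep$chunks), "non-empty")
  # validation set without genic bases is refused
  masked <- lapply(prep$chunks, function(ch) {
    ch$sample_weights[chunk_class_ids <- max.col(ch$labels) > 1] <- 0
    ch
  })
  expect_error(train_network(m, prep$chunks, masked), "no unmasked genic")
})

test_that("model building is seed-deterministic", {
  cfg <- network_config(n_layers = 1, units = 4, chunk_len = 200L, seed = 11)
  expect_identical(build_model(cfg)$params, build_model(cfg)$params)
  cfg2 <- network_config(n_layers = 1, units = 4, chunk_len = 200L, seed = 12)
  expect_false(identical(build_model(cfg)$params, build_model(cfg2)$params))
})
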