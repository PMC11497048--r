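test_that("warmup/decay schedule is piecewise linear and exact at the knots", {
  s <- lr_schedule(peak_lr = 4e-4, warmup_steps = 10000L,
                   total_steps = 200000L)
  expect_equal(lr_at(s, 0L), 0)
  expect_equal(lr_at(s, 10000L), 4e-4)
  expect_equal(lr_at(s, 200000L), 0)
  expect_equal(lr_at(s, 5000L), 2e-4)
  expect_equal(lr_at(s, 105000L), 4e-4 * 95000 / 190000)
  expect_error(lr_schedule(1e-3, 10L, 10L), "warmup")
})

test_that("pretraining reduces the MLM loss and recovers masked tokens above chance", {
  v <- tiny_vocab()
  cfg <- tiny_config(v, d = 16L, max_positions = 64L, dropout = 0.1)
  cp <- make_pretrain_corpus(n_sequences = 40L, length = 60L,
                             window_nt = 60L, vocab = v,
                             max_positions = 64L, seed = 3L)
  fit <- pretrain(cp$tokenized, v, cfg, steps = 60L, batch_size = 8L,
                  seed = 3L, schedule = lr_schedule(2e-3, 6L, 60L))
  h <- fit$history
  expect_equal(nrow(h), 60L)
  expect_true(all(is.finite(h$loss)))
  expect_lt(mean(tail(h$loss, 10L)), mean(head(h$loss, 10L)))
  # masked-token recovery accuracy well above 1/|vocab| chance,
  # aggregated over the corpus
  accs <- vapply(seq_along(cp$tokenized), function(i) {
    w <- cp$tokenized[[i]]
    plan <- plan_masking(w, v, seed = 1000L + i)
    ap <- apply_masking(w, plan, v)
    res <- mlm_loss(fit$params, w, ap$corrupted, ap$targets, ap$loss_mask)
    mean(res$pred_ids == ap$targets[ap$loss_mask])
  }, 0)
  expect_gt(mean(accs), 2 / v$size)
})

test_that("zero pretraining steps leave the parameters untouched", {
  v <- tiny_vocab()
  cfg <- tiny_config(v)
  p0 <- init_model(cfg, seed = 8L)
  cp <- make_pretrain_corpus(n_sequences = 5L, length = 40L,
                             window_nt = 40L, vocab = v,
                             max_positions = 64L, seed = 1L)
  fit <- pretrain(cp$tokenized, v, cfg, steps = 0L, batch_size = 2L,
                  params = p0, seed = 8L)
  expect_identical(unclass(fit$params), unclass(p0))
  expect_error(pretrain(cp$tokenized, v, cfg, steps = 1L,
                        batch_size = 100L), "batch size")
})

test_that("training is bit-reproducible given identical seeds", {
  v <- tiny_vocab()
  cfg <- tiny_config(v, d = 8L, layers = 1L, heads = 1L)
  cp <- make_pretrain_corpus(n_sequences = 10L, length = 40L,
                             window_nt = 40L, vocab = v,
                             max_positions = 64L, seed = 2L)
  f1 <- pretrain(cp$tokenized, v, cfg, steps = 10L, batch_size = 4L,
                 seed = 21L)
  f2 <- pretrain(cp$tokenized, v, cfg, steps = 10L, batch_size = 4L,
                 seed = 21L)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(unclass(f1$params), unclass(f2$params))
})

test_that("fine-tuning separates an easily separable synthetic task", {
  v <- tiny_vocab()
  cfg <- tiny_config(v, d = 16L, max_positions = 64L, dropout = 0.1)
  # positives all-start with a strong fixed element, negatives background
  rbp <- make_rbp_dataset(n_pos = 30L, motif = "UGUAUAU", plant_rate = 1.0,
                          window_nt = 50L, seed = 5L)
  p0 <- init_model(cfg, seed = 5L)
  fit <- finetune(p0, rbp$dataset, v, task = "binary", epochs = 6L,
                  batch_size = 8L, peak_lr = 2e-3, seed = 5L)
  train <- rbp$dataset[rbp$dataset$split == "train", ]
  sc <- predict_binary(fit$params, train$sequence, v)
  m <- compute_metrics(sc, as.numeric(train$label))
  expect_gt(m$auroc, 0.8)
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("zero-epoch fine-tuning leaves predictions unchanged", {
  v <- tiny_vocab()
  cfg <- tiny_config(v)
  rbp <- make_rbp_dataset(n_pos = 6L, window_nt = 40L, seed = 6L)
  p0 <- init_model(cfg, seed = 6L)
  before <- predict_binary(p0, rbp$dataset$sequence[1:4], v)
  fit <- finetune(p0, rbp$dataset, v, task = "binary", epochs = 0L,
                  seed = 6L)
  after <- predict_binary(fit$params, rbp$dataset$sequence[1:4], v)
  expect_identical(before, after)
  expect_error(finetune(p0, data.frame(sequence = "AUGACA", label = 2,
                                       split = "train"),
                        v, task = "binary", epochs = 1L), "0/1")
})

test_that("frozen-encoder multi-label fine-tuning recovers planted structure", {
  v <- tiny_vocab()
  cfg <- tiny_config(v, d = 16L, max_positions = 200L)
  loc <- make_localization_dataset(n = 100L, length_range = c(120L, 180L),
                                   prevalence = 0.4, n_instances = 8L,
                                   flank = 4000L, seed = 9L)
  p0 <- init_model(cfg, seed = 9L)
  fit <- finetune(p0, loc$dataset, v, task = "multilabel",
                  window_nt = 198L, seed = 9L)
  test_idx <- which(loc$dataset$split == "test")
  out <- multilabel_head(fit$head, fit$embeddings[test_idx, , drop = FALSE])
  aucs <- vapply(1:6, function(j) {
    y <- loc$labels[test_idx, j]
    if (length(unique(y)) < 2L) return(NA_real_)
    compute_metrics(out$prob[, j], y)$auroc
  }, 0)
  expect_gt(mean(aucs, na.rm = TRUE), 0.85)
  expect_gt(min(aucs, na.rm = TRUE), 0.7)
})
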