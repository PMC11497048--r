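test_that("initialization is deterministic given the seed and shape-correct", {
  v <- tiny_vocab()
  cfg <- tiny_config(v, d = 16L, layers = 2L, heads = 2L)
  p1 <- init_model(cfg, seed = 4L)
  p2 <- init_model(cfg, seed = 4L)
  p3 <- init_model(cfg, seed = 5L)
  expect_identical(unclass(p1), unclass(p2))
  expect_false(identical(p1$tok_emb, p3$tok_emb))
  expect_equal(dim(p1$tok_emb), c(v$size, 16L))
  expect_equal(dim(p1$pos_emb), c(64L, 16L))
  expect_equal(dim(p1$l01_Wq), c(16L, 16L))
  expect_equal(dim(p1$l02_W1), c(16L, 32L))
  expect_equal(dim(p1$cls_W), c(16L, 2L))
  expect_error(model_config(n_heads = 5L, d_model = 16L), "divisible")
})

test_that("attention rows are stochastic over real tokens and PAD gets zero", {
  v <- tiny_vocab()
  cfg <- tiny_config(v)
  p <- init_model(cfg, seed = 1L)
  w <- tiny_window(random_rna(30, 1), v)
  st <- encode_sequence(p, w)
  P <- st$n_active
  for (layer in seq_along(st$attention)) {
    for (A in st$attention[[layer]]) {
      expect_equal(rowSums(A[seq_len(P), , drop = FALSE]),
                   rep(1, P), tolerance = 1e-5)
      # PAD keys (columns after the active prefix) receive zero attention
      expect_true(all(A[, (P + 1L):ncol(A)] == 0))
      expect_true(all(A[(P + 1L):nrow(A), ] == 0))
    }
  }
})

test_that("a hand-computed single-head attention matches the encoder's", {
  # 2 real tokens, d = 2, one head: attention = softmax(q k^T / sqrt(2))
  v <- tiny_vocab()
  cfg <- model_config(n_layers = 1L, n_heads = 1L, d_model = 2L, d_ffn = 4L,
                      max_positions = 8L, vocab_size = v$size, dropout = 0,
                      pos_init = "random")
  p <- init_model(cfg, seed = 2L)
  w <- tiny_window("AUGA", v, max_positions = 8L)  # 2 real tokens
  ids <- w$ids[1:4]
  X <- p$tok_emb[ids + 1L, ] + p$pos_emb[1:4, ]
  Q <- X %*% p$l01_Wq + rep(p$l01_bq, each = 4L)
  K <- X %*% p$l01_Wk + rep(p$l01_bk, each = 4L)
  S <- (Q %*% t(K)) / sqrt(2)
  A_hand <- t(apply(S, 1L, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  st <- encode_sequence(p, w)
  expect_equal(st$attention[[1L]][[1L]][1:4, 1:4], A_hand, tolerance = 1e-10)
})

test_that("uniform logits give MLM loss ln(vocab) and perfect logits near 0", {
  v <- tiny_vocab()
  cfg <- tiny_config(v, tie_mlm = FALSE)
  p <- init_model(cfg, seed = 1L)
  w <- tiny_window(random_rna(20, 2), v)
  plan <- plan_masking(w, v, mask_rate = 0.3, seed = 1L)
  ap <- apply_masking(w, plan, v)
  # uniform logits: zero out the MLM projection entirely
  p$mlm_W[] <- 0
  p$mlm_b[] <- 0
  res <- mlm_loss(p, w, ap$corrupted, ap$targets, ap$loss_mask)
  expect_equal(res$loss, log(69), tolerance = 1e-12)
  # near-one-hot correct logits drive the loss to ~0
  p$mlm_b[] <- 0
  p$mlm_b[ap$targets[ap$loss_mask][1L] + 1L] <- 50
  one <- mlm_loss(p, w, ap$corrupted, ap$targets,
                  ap$loss_mask & seq_along(ap$loss_mask) ==
                    which(ap$loss_mask)[1L])
  expect_lt(one$loss, 1e-6)
})

test_that("4-class toy cross-entropy matches the closed form", {
  # softmax of logits (1,0,0,0) puts e/(e+3) on class 1
  expected <- -log(exp(1) / (exp(1) + 3))
  logits <- c(1, 0, 0, 0)
  p <- exp(logits) / sum(exp(logits))
  expect_equal(-log(p[1L]), expected, tolerance = 1e-12)
  expect_equal(expected, 0.7437, tolerance = 1e-4)
})

test_that("analytic gradients match numerical gradients on a d=4 toy", {
  v <- tiny_vocab()
  cfg <- model_config(n_layers = 2L, n_heads = 2L, d_model = 4L, d_ffn = 8L,
                      max_positions = 16L, vocab_size = v$size, dropout = 0)
  p <- init_model(cfg, seed = 7L)
  w <- tiny_window("AUGACAUGGACA", v, max_positions = 16L)
  plan <- plan_masking(w, v, mask_rate = 0.3, seed = 3L)
  ap <- apply_masking(w, plan, v)
  res <- mlm_loss(p, w, ap$corrupted, ap$targets, ap$loss_mask,
                  with_grads = TRUE)
  h <- 1e-4
  set.seed(1)
  for (nm in names(res$grads)) {
    for (i in sample(length(res$grads[[nm]]),
                     min(3L, length(res$grads[[nm]])))) {
      p2 <- p
      p2[[nm]][i] <- p2[[nm]][i] + h
      lp <- mlm_loss(p2, w, ap$corrupted, ap$targets, ap$loss_mask)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h
      lm <- mlm_loss(p2, w, ap$corrupted, ap$targets, ap$loss_mask)$loss
      gnum <- (lp - lm) / (2 * h)
      gana <- res$grads[[nm]][i]
      expect_lt(abs(gnum - gana) / max(1e-6, abs(gnum) + abs(gana)), 1e-4)
    }
  }
})

test_that("empty loss mask warns and returns zero loss", {
  v <- tiny_vocab()
  cfg <- tiny_config(v)
  p <- init_model(cfg, seed = 1L)
  w <- tiny_window(random_rna(20, 3), v)
  expect_warning(res <- mlm_loss(p, w, w$ids, w$ids,
                                 rep(FALSE, length(w$ids))), "empty")
  expect_equal(res$loss, 0)
})

test_that("encoding is sensitive to token order (positions are active)", {
  v <- tiny_vocab()
  cfg <- tiny_config(v)
  p <- init_model(cfg, seed = 2L)
  s <- random_rna(30, 4)
  rev_s <- paste(rev(strsplit(s, "")[[1L]]), collapse = "")
  h1 <- encode_sequence(p, tiny_window(s, v))$hidden
  h2 <- encode_sequence(p, tiny_window(rev_s, v))$hidden
  expect_gt(max(abs(h1 - h2)), 1e-6)
})

test_that("classification probabilities are a proper 2-class softmax", {
  v <- tiny_vocab()
  cfg <- tiny_config(v)
  p <- init_model(cfg, seed = 3L)
  w <- tiny_window(random_rna(40, 5), v)
  prob <- classify_window(p, w)
  expect_gt(prob, 0)
  expect_lt(prob, 1)
  full <- classify_window(p, w, with_grads = TRUE, label = 1)
  expect_equal(full$prob, prob)
  expect_equal(full$loss, -log(prob), tolerance = 1e-12)
})

test_that("mean-pooled long-sequence embeddings behave like means", {
  v <- tiny_vocab()
  cfg <- tiny_config(v)
  p <- init_model(cfg, seed = 6L)
  w1 <- tiny_window(random_rna(30, 6), v)
  w2 <- tiny_window(random_rna(30, 7), v)
  e1 <- embed_long_sequence(p, list(w1))
  e12 <- embed_long_sequence(p, list(w1, w2))
  e21 <- embed_long_sequence(p, list(w2, w1))
  expect_length(e1, cfg$d_model)
  expect_equal(e12, e21)  # window order cannot matter
  # single window equals its own pool
  fwd_pool <- colMeans(encode_sequence(p, w1)$hidden[2:(1 + w1$n_real_tokens), ])
  expect_equal(e1, fwd_pool, tolerance = 1e-12)
})

test_that("multi-label head emits independent probabilities in (0,1)", {
  set.seed(11)
  emb <- matrix(rnorm(60 * 8), 60, 8)
  labels <- matrix(rbinom(60 * 6, 1L, 0.4), 60, 6)
  head_fit <- fit_multilabel_head(emb, labels)
  out <- multilabel_head(head_fit, emb[1:5, ])
  expect_equal(dim(out$prob), c(5L, 6L))
  expect_true(all(out$prob > 0 & out$prob < 1))
  # no sum-to-one constraint across compartments
  expect_false(all(abs(rowSums(out$prob) - 1) < 0.01))
  expect_true(all(out$call %in% c(0L, 1L)))
})
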