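#' Encoder configuration
#'
#' Defaults follow the full-scale reference configuration (12 layers, 12
#' heads, model width 768, feed-forward width 3072, 512 positions); every
#' dimension is configurable, and the test suite and worked examples use
#' desk-scale models such as 2 layers / 2 heads / width 32.
#'
#' @param n_layers Number of stacked encoder layers.
#' @param n_heads Number of attention heads; must divide `d_model`.
#' @param d_model Embedding / hidden width.
#' @param d_ffn Feed-forward inner width.
#' @param max_positions Maximum window length in tokens (incl. specials).
#' @param vocab_size Vocabulary size (`4^k + 5`).
#' @param dropout Dropout fraction applied after the attention and
#'   feed-forward sublayers during training.
#' @param n_labels Number of compartments for the multi-label head.
#' @param tie_mlm If `TRUE` (default) the MLM output projection shares
#'   its weights with the token embedding matrix (standard weight
#'   tying), which speeds up masked-token learning considerably at
#'   small scale.
#' @param pos_init Initialization of the learned absolute positional
#'   embeddings: `"sinusoidal"` (default; fixed-frequency sine/cosine
#'   start, which makes relative-offset attention patterns linearly
#'   accessible from the first step) or `"random"` (Gaussian).
#' @param pos_scale Amplitude of the sinusoidal initialization.
#' @return A list of class `utr_config`.
#' @export
model_config <- function(n_layers = 12L, n_heads = 12L, d_model = 768L,
                         d_ffn = 3072L, max_positions = 512L,
                         vocab_size = 69L, dropout = 0.1, n_labels = 6L,
                         tie_mlm = TRUE,
                         pos_init = c("sinusoidal", "random"),
                         pos_scale = 0.15) {
  pos_init <- match.arg(pos_init)
  if (d_model %% n_heads != 0L) {
    stop("d_model must be divisible by n_heads", call. = FALSE)
  }
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model),
                 d_ffn = as.integer(d_ffn),
                 max_positions = as.integer(max_positions),
                 vocab_size = as.integer(vocab_size),
                 dropout = dropout,
                 d_head = as.integer(d_model / n_heads),
                 n_labels = as.integer(n_labels),
                 tie_mlm = isTRUE(tie_mlm),
                 pos_init = pos_init, pos_scale = pos_scale),
            class = "utr_config")
}

LN_EPS <- 1e-5

#' Initialize model parameters
#'
#' All weight matrices are drawn N(0, 0.02^2); biases and layer-norm
#' shifts start at 0, layer-norm gains at 1.  Deterministic given the
#' seed.
#'
#' @param config A `utr_config`.
#' @param seed Integer seed.
#' @return Named list of parameter arrays (class `utr_params`), carrying
#'   the config as attribute `config`.
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "utr_config"))
  d <- config$d_model
  with_seed(seed, {
    mat <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
    p <- list(tok_emb = mat(config$vocab_size, d),
              pos_emb = if (config$pos_init == "sinusoidal") {
                sinusoidal_embedding(config$max_positions, d,
                                     config$pos_scale)
              } else mat(config$max_positions, d))
    for (l in seq_len(config$n_layers)) {
      pre <- sprintf("l%02d_", l)
      p[[paste0(pre, "Wq")]] <- mat(d, d)
      p[[paste0(pre, "bq")]] <- numeric(d)
      p[[paste0(pre, "Wk")]] <- mat(d, d)
      p[[paste0(pre, "bk")]] <- numeric(d)
      p[[paste0(pre, "Wv")]] <- mat(d, d)
      p[[paste0(pre, "bv")]] <- numeric(d)
      p[[paste0(pre, "Wo")]] <- mat(d, d)
      p[[paste0(pre, "bo")]] <- numeric(d)
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- mat(d, config$d_ffn)
      p[[paste0(pre, "b1")]] <- numeric(config$d_ffn)
      p[[paste0(pre, "W2")]] <- mat(config$d_ffn, d)
      p[[paste0(pre, "b2")]] <- numeric(d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- numeric(d)
    }
    if (!config$tie_mlm) p$mlm_W <- mat(d, config$vocab_size)
    p$mlm_b <- numeric(config$vocab_size)
    p$cls_W <- mat(d, 2L)
    p$cls_b <- numeric(2L)
    structure(p, config = config, class = "utr_params")
  })
}

#' @export
print.utr_params <- function(x, ...) {
  cfg <- attr(x, "config")
  n <- sum(vapply(x, length, 0L))
  cat(sprintf("encoder parameters: %d layers, %d heads, d = %d (%s values)\n",
              cfg$n_layers, cfg$n_heads, cfg$d_model, format(n, big.mark = ",")))
  invisible(x)
}

# Fixed-frequency sine/cosine position code (used as the starting value
# of the learned positional embeddings).
sinusoidal_embedding <- function(P, d, scale) {
  pe <- matrix(0, P, d)
  pos <- seq_len(P) - 1L
  for (i in 0:(d %/% 2L - 1L)) {
    f <- 1 / 10000^(2 * i / d)
    pe[, 2L * i + 1L] <- sin(pos * f)
    pe[, 2L * i + 2L] <- cos(pos * f)
  }
  pe * scale
}

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

row_softmax <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}

layer_norm_fwd <- function(s, g, b) {
  mu <- rowMeans(s)
  ctr <- s - mu
  v <- rowMeans(ctr * ctr)
  sig <- sqrt(v + LN_EPS)
  xhat <- ctr / sig
  list(out = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(s)),
       xhat = xhat, sig = sig)
}

layer_norm_bwd <- function(dout, cache, g) {
  dxhat <- sweep(dout, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  ds <- (dxhat - m1 - cache$xhat * m2) / cache$sig
  list(ds = ds,
       dg = colSums(dout * cache$xhat),
       db = colSums(dout))
}

# Forward pass over the active (non-PAD) prefix of a window.
#
# Returns final hidden states, per-layer caches for backprop, and the
# per-layer per-head attention matrices over the active positions.
# PAD positions are never computed: they receive zero attention and
# contribute nothing, which realizes the attention-masking contract
# exactly.
tf_forward <- function(params, window, train = FALSE, dropout_seed = NULL) {
  cfg <- attr(params, "config")
  P <- window$n_real_tokens + 2L
  if (P > cfg$max_positions) stop("window exceeds max_positions", call. = FALSE)
  ids <- window$ids[seq_len(P)]
  H <- cfg$n_heads
  dh <- cfg$d_head
  scale <- 1 / sqrt(dh)
  keep <- 1 - cfg$dropout
  use_drop <- train && cfg$dropout > 0

  drop_masks <- NULL
  if (use_drop) {
    drop_masks <- with_seed(dropout_seed, {
      lapply(seq_len(cfg$n_layers), function(l) {
        list(attn = matrix(rbinom(P * cfg$d_model, 1L, keep) / keep,
                           P, cfg$d_model),
             ffn = matrix(rbinom(P * cfg$d_model, 1L, keep) / keep,
                          P, cfg$d_model))
      })
    })
  }

  X <- params$tok_emb[ids + 1L, , drop = FALSE] +
       params$pos_emb[seq_len(P), , drop = FALSE]
  X0 <- X
  layers <- vector("list", cfg$n_layers)
  attn <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("l%02d_", l)
    Xin <- X
    Q <- Xin %*% params[[paste0(pre, "Wq")]] +
      rep(params[[paste0(pre, "bq")]], each = P)
    K <- Xin %*% params[[paste0(pre, "Wk")]] +
      rep(params[[paste0(pre, "bk")]], each = P)
    V <- Xin %*% params[[paste0(pre, "Wv")]] +
      rep(params[[paste0(pre, "bv")]], each = P)
    A <- vector("list", H)
    O_pre <- matrix(0, P, cfg$d_model)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) * scale
      A[[h]] <- row_softmax(S)
      O_pre[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
    }
    attn_out <- O_pre %*% params[[paste0(pre, "Wo")]] +
      rep(params[[paste0(pre, "bo")]], each = P)
    if (use_drop) attn_out <- attn_out * drop_masks[[l]]$attn
    ln1 <- layer_norm_fwd(Xin + attn_out,
                          params[[paste0(pre, "ln1_g")]],
                          params[[paste0(pre, "ln1_b")]])
    F_pre <- ln1$out %*% params[[paste0(pre, "W1")]] +
      rep(params[[paste0(pre, "b1")]], each = P)
    G <- gelu(F_pre)
    ffn_out <- G %*% params[[paste0(pre, "W2")]] +
      rep(params[[paste0(pre, "b2")]], each = P)
    if (use_drop) ffn_out <- ffn_out * drop_masks[[l]]$ffn
    ln2 <- layer_norm_fwd(ln1$out + ffn_out,
                          params[[paste0(pre, "ln2_g")]],
                          params[[paste0(pre, "ln2_b")]])
    layers[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V, A = A, O_pre = O_pre,
                        ln1 = ln1, F_pre = F_pre, G = G)
    attn[[l]] <- A
    X <- ln2$out
    layers[[l]]$out <- X
    layers[[l]]$ln2 <- ln2
  }
  list(h = X, layers = layers, attn = attn, ids = ids, P = P, X0 = X0,
       drop_masks = drop_masks)
}

# Backward pass through the encoder given dH = dLoss/d(final hidden).
# Returns the gradient list (same shapes as params, missing head params).
tf_backward <- function(params, fwd, dH) {
  cfg <- attr(params, "config")
  P <- fwd$P
  H <- cfg$n_heads
  dh <- cfg$d_head
  scale <- 1 / sqrt(dh)
  grads <- list()
  dX <- dH
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("l%02d_", l)
    cache <- fwd$layers[[l]]
    drop <- if (!is.null(fwd$drop_masks)) fwd$drop_masks[[l]] else NULL

    lb2 <- layer_norm_bwd(dX, cache$ln2, params[[paste0(pre, "ln2_g")]])
    grads[[paste0(pre, "ln2_g")]] <- lb2$dg
    grads[[paste0(pre, "ln2_b")]] <- lb2$db
    ds2 <- lb2$ds
    dffn <- if (is.null(drop)) ds2 else ds2 * drop$ffn
    dG <- dffn %*% t(params[[paste0(pre, "W2")]])
    grads[[paste0(pre, "W2")]] <- t(cache$G) %*% dffn
    grads[[paste0(pre, "b2")]] <- colSums(dffn)
    dF <- dG * gelu_grad(cache$F_pre)
    dln1out <- ds2 + dF %*% t(params[[paste0(pre, "W1")]])
    grads[[paste0(pre, "W1")]] <- t(cache$ln1$out) %*% dF
    grads[[paste0(pre, "b1")]] <- colSums(dF)

    lb1 <- layer_norm_bwd(dln1out, cache$ln1, params[[paste0(pre, "ln1_g")]])
    grads[[paste0(pre, "ln1_g")]] <- lb1$dg
    grads[[paste0(pre, "ln1_b")]] <- lb1$db
    ds1 <- lb1$ds
    dXin <- ds1
    dattn <- if (is.null(drop)) ds1 else ds1 * drop$attn
    dO_pre <- dattn %*% t(params[[paste0(pre, "Wo")]])
    grads[[paste0(pre, "Wo")]] <- t(cache$O_pre) %*% dattn
    grads[[paste0(pre, "bo")]] <- colSums(dattn)

    dQ <- matrix(0, P, cfg$d_model)
    dK <- matrix(0, P, cfg$d_model)
    dV <- matrix(0, P, cfg$d_model)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Ah <- cache$A[[h]]
      dOh <- dO_pre[, cols, drop = FALSE]
      Vh <- cache$V[, cols, drop = FALSE]
      dAh <- dOh %*% t(Vh)
      dV[, cols] <- t(Ah) %*% dOh
      dS <- Ah * (dAh - rowSums(dAh * Ah))
      dQ[, cols] <- (dS %*% cache$K[, cols, drop = FALSE]) * scale
      dK[, cols] <- (t(dS) %*% cache$Q[, cols, drop = FALSE]) * scale
    }
    grads[[paste0(pre, "Wq")]] <- t(cache$Xin) %*% dQ
    grads[[paste0(pre, "bq")]] <- colSums(dQ)
    grads[[paste0(pre, "Wk")]] <- t(cache$Xin) %*% dK
    grads[[paste0(pre, "bk")]] <- colSums(dK)
    grads[[paste0(pre, "Wv")]] <- t(cache$Xin) %*% dV
    grads[[paste0(pre, "bv")]] <- colSums(dV)
    dXin <- dXin + dQ %*% t(params[[paste0(pre, "Wq")]]) +
      dK %*% t(params[[paste0(pre, "Wk")]]) +
      dV %*% t(params[[paste0(pre, "Wv")]])
    dX <- dXin
  }
  dtok <- matrix(0, cfg$vocab_size, cfg$d_model)
  agg <- rowsum(dX, fwd$ids)
  dtok[as.integer(rownames(agg)) + 1L, ] <- agg
  grads$tok_emb <- dtok
  dpos <- matrix(0, cfg$max_positions, cfg$d_model)
  dpos[seq_len(P), ] <- dX
  grads$pos_emb <- dpos
  grads
}

#' Run the encoder over one tokenized window
#'
#' Applies the token + positional embedding and the stack of post-norm
#' encoder layers (multi-head scaled dot-product attention with residual
#' and layer normalization, then a GeLU feed-forward sublayer with
#' residual and layer normalization).  Attention maps for every layer
#' and head are retained for analysis.  `[PAD]` positions after `[SEP]`
#' are excluded from computation entirely, so they receive exactly zero
#' attention and every attention row is a distribution over the real
#' positions.
#'
#' @param params A `utr_params`.
#' @param window A `utr_window`.
#' @return An object of class `utr_encoder_state`: list with `hidden`
#'   (final hidden states, `max_positions x d`, zero at PAD rows),
#'   `attention` (per layer, per head, full `max_positions^2` matrices
#'   with zeros at PAD rows/columns), `n_active`, `n_real_tokens`.
#' @export
encode_sequence <- function(params, window) {
  cfg <- attr(params, "config")
  fwd <- tf_forward(params, window)
  P <- fwd$P
  M <- cfg$max_positions
  hidden <- matrix(0, M, cfg$d_model)
  hidden[seq_len(P), ] <- fwd$h
  attention <- lapply(fwd$attn, function(heads) {
    lapply(heads, function(A) {
      full <- matrix(0, M, M)
      full[seq_len(P), seq_len(P)] <- A
      full
    })
  })
  structure(list(hidden = hidden, attention = attention,
                 n_active = P, n_real_tokens = window$n_real_tokens,
                 k = window$k),
            class = "utr_encoder_state")
}

#' Masked-language-model loss
#'
#' Mean negative log-probability of the original token at the masked
#' positions, computed from a softmax over the vocabulary on the final
#' hidden states of the corrupted window.
#'
#' @param params A `utr_params`.
#' @param window A `utr_window` (provides geometry; its ids are ignored).
#' @param corrupted Integer ids after masking (full window length).
#' @param targets Original integer ids.
#' @param loss_mask Logical vector, `TRUE` at positions contributing to
#'   the loss.
#' @param with_grads If `TRUE`, also return analytic gradients for every
#'   parameter.
#' @param train,dropout_seed Enable dropout (training mode).
#' @return List with `loss` (scalar; 0 with a warning if the mask is
#'   empty), `n_masked`, optionally `grads` and `pred_ids` (argmax
#'   prediction at masked positions).
#' @export
mlm_loss <- function(params, window, corrupted, targets, loss_mask,
                     with_grads = FALSE, train = FALSE, dropout_seed = NULL) {
  cfg <- attr(params, "config")
  w <- window
  w$ids <- as.integer(corrupted)
  fwd <- tf_forward(params, w, train = train, dropout_seed = dropout_seed)
  P <- fwd$P
  mask_idx <- which(loss_mask[seq_len(P)])
  if (length(mask_idx) == 0L) {
    warning("empty loss mask: MLM loss defined as 0")
    out <- list(loss = 0, n_masked = 0L)
    if (with_grads) out$grads <- NULL
    return(out)
  }
  Hm <- fwd$h[mask_idx, , drop = FALSE]
  Wout <- if (cfg$tie_mlm) t(params$tok_emb) else params$mlm_W
  logits <- Hm %*% Wout + rep(params$mlm_b, each = length(mask_idx))
  probs <- row_softmax(logits)
  tgt <- targets[mask_idx] + 1L
  nm <- length(mask_idx)
  loss <- -mean(log(probs[cbind(seq_len(nm), tgt)]))
  out <- list(loss = loss, n_masked = nm,
              pred_ids = max.col(probs, ties.method = "first") - 1L)
  if (with_grads) {
    dlogits <- probs
    dlogits[cbind(seq_len(nm), tgt)] <- dlogits[cbind(seq_len(nm), tgt)] - 1
    dlogits <- dlogits / nm
    grads <- list(mlm_b = colSums(dlogits))
    if (!cfg$tie_mlm) grads$mlm_W <- t(Hm) %*% dlogits
    dH <- matrix(0, P, cfg$d_model)
    dH[mask_idx, ] <- dlogits %*% t(Wout)
    enc_grads <- tf_backward(params, fwd, dH)
    if (cfg$tie_mlm) {
      # tied output projection: add the softmax-layer contribution to the
      # embedding gradient
      enc_grads$tok_emb <- enc_grads$tok_emb + t(dlogits) %*% Hm
    }
    out$grads <- c(grads, enc_grads)
  }
  out
}

#' Binary classification from the `[CLS]` token
#'
#' A single feed-forward layer with a 2-class softmax applied to the
#' final-layer `[CLS]` hidden vector.
#'
#' @param params A `utr_params` (after fine-tuning, for meaningful
#'   scores).
#' @param window A `utr_window`.
#' @param with_grads If `TRUE` (training), also return gradients of the
#'   cross-entropy loss against `label`.
#' @param label Binary label (0/1), required with `with_grads`.
#' @param train,dropout_seed Enable dropout.
#' @return With `with_grads = FALSE`, the positive-class probability (a
#'   scalar in (0, 1)).  Otherwise a list with `prob`, `loss`, `grads`.
#' @export
classify_window <- function(params, window, with_grads = FALSE, label = NULL,
                            train = FALSE, dropout_seed = NULL) {
  cfg <- attr(params, "config")
  fwd <- tf_forward(params, window, train = train, dropout_seed = dropout_seed)
  cls <- fwd$h[1L, ]
  logits <- drop(cls %*% params$cls_W) + params$cls_b
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  if (!with_grads) return(unname(p[2L]))
  stopifnot(label %in% c(0, 1))
  tgt <- label + 1L
  loss <- -log(p[tgt])
  dlogits <- p
  dlogits[tgt] <- dlogits[tgt] - 1
  grads <- list(cls_W = outer(cls, dlogits), cls_b = dlogits)
  dH <- matrix(0, fwd$P, cfg$d_model)
  dH[1L, ] <- drop(params$cls_W %*% dlogits)
  grads <- c(grads, tf_backward(params, fwd, dH))
  list(prob = unname(p[2L]), loss = loss, grads = grads)
}

#' Frozen mean-pooled embedding of a long sequence
#'
#' Final-layer hidden states are mean-pooled across the real token
#' positions of each window (specials and padding excluded) and the
#' per-window vectors are averaged, yielding one d-vector per sequence.
#' No gradients flow; the encoder stays frozen.
#'
#' @param params A `utr_params`.
#' @param windows A list of `utr_window` objects covering the sequence.
#' @return Numeric vector of length `d_model`.
#' @export
embed_long_sequence <- function(params, windows) {
  stopifnot(length(windows) >= 1L)
  pooled <- vapply(windows, function(w) {
    fwd <- tf_forward(params, w)
    real <- seq.int(2L, 1L + w$n_real_tokens)
    colMeans(fwd$h[real, , drop = FALSE])
  }, numeric(attr(params, "config")$d_model))
  rowMeans(matrix(pooled, nrow = attr(params, "config")$d_model))
}

#' Multi-label localization probabilities
#'
#' Applies a fitted multi-label head (independent per-compartment
#' logistic units, see [fit_multilabel_head()]) to a frozen mean-pooled
#' embedding.  There is no sum-to-one constraint across compartments: a
#' transcript can localize to several.
#'
#' @param head A `utr_multilabel_head` from [fit_multilabel_head()].
#' @param embedding Numeric d-vector from [embed_long_sequence()], or a
#'   matrix with one row per sequence.
#' @param threshold Probability cutoff for the binary calls.
#' @return List with `prob` (matrix, sequences x labels) and `call`
#'   (0/1 matrix at the threshold).
#' @export
multilabel_head <- function(head, embedding, threshold = 0.5) {
  stopifnot(inherits(head, "utr_multilabel_head"))
  X <- if (is.matrix(embedding)) embedding else matrix(embedding, nrow = 1L)
  z <- X %*% head$W + rep(head$b, each = nrow(X))
  p <- 1 / (1 + exp(-z))
  colnames(p) <- head$labels
  list(prob = p, call = (p >= threshold) * 1L)
}

#' Fit the frozen-encoder multi-label head
#'
#' One ridge-regularized logistic regression per compartment on the
#' mean-pooled embeddings (encoder frozen).  Ridge keeps the head well
#' conditioned when embeddings are low-rank or classes are separable.
#'
#' @param embeddings Matrix, sequences x d.
#' @param labels 0/1 matrix, sequences x compartments.
#' @param lambda Ridge penalty (fixed; no data-driven tuning so fits are
#'   deterministic).
#' @param label_names Optional compartment names.
#' @return A `utr_multilabel_head` with weight matrix `W` (d x labels)
#'   and intercepts `b`.
#' @export
fit_multilabel_head <- function(embeddings, labels, lambda = 0.05,
                                label_names = NULL) {
  stopifnot(is.matrix(embeddings), nrow(embeddings) == nrow(labels))
  nl <- ncol(labels)
  W <- matrix(0, ncol(embeddings), nl)
  b <- numeric(nl)
  for (j in seq_len(nl)) {
    y <- labels[, j]
    if (length(unique(y)) < 2L) {
      # degenerate compartment: constant label; intercept-only unit
      pj <- max(min(mean(y), 1 - 1e-6), 1e-6)
      b[j] <- log(pj / (1 - pj))
      next
    }
    fit <- glmnet::glmnet(embeddings, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = TRUE)
    cf <- as.numeric(coef(fit, s = lambda))
    b[j] <- cf[1L]
    W[, j] <- cf[-1L]
  }
  if (is.null(label_names)) {
    label_names <- if (nl == 6L) {
      c("nucleus", "exosome", "cytosol", "ribosome", "membrane", "ER")
    } else paste0("label", seq_len(nl))
  }
  structure(list(W = W, b = b, labels = label_names),
            class = "utr_multilabel_head")
}

#' @importFrom stats coef
NULL
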