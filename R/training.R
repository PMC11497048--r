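#' Warmup / linear-decay learning-rate schedule
#'
#' The learning rate rises linearly from 0 to `peak_lr` over the first
#' `warmup_steps` steps, then decays linearly back to 0 at `total_steps`
#' (the full-scale reference run warmed up to 4e-4 over 10k of 200k
#' steps; desk-scale runs shrink all three numbers together).
#'
#' @param peak_lr Peak learning rate.
#' @param warmup_steps Steps of linear warmup.
#' @param total_steps Total steps; `lr_at(schedule, total_steps) == 0`.
#' @return A list of class `utr_schedule`.
#' @export
lr_schedule <- function(peak_lr = 4e-4, warmup_steps = 10000L,
                        total_steps = 200000L) {
  if (!(warmup_steps > 0L && warmup_steps < total_steps)) {
    stop("need 0 < warmup_steps < total_steps", call. = FALSE)
  }
  structure(list(peak_lr = peak_lr, warmup_steps = as.integer(warmup_steps),
                 total_steps = as.integer(total_steps)),
            class = "utr_schedule")
}

#' @rdname lr_schedule
#' @param schedule A `utr_schedule`.
#' @param step Step number (0-based).
#' @return `lr_at()` returns the learning rate at `step`.
#' @export
lr_at <- function(schedule, step) {
  w <- schedule$warmup_steps
  t <- schedule$total_steps
  ifelse(step <= w,
         schedule$peak_lr * step / w,
         pmax(0, schedule$peak_lr * (t - step) / (t - w)))
}

#' AdamW optimizer specification
#'
#' Decoupled-weight-decay adaptive-moment optimizer with the defaults
#' used throughout: beta1 = 0.9, beta2 = 0.98, eps = 1e-6, weight decay
#' 0.01, global gradient-norm clipping at 1.
#'
#' @param beta1,beta2 Moment decay rates.
#' @param eps Numerical stabilizer.
#' @param weight_decay Decoupled weight decay.
#' @param clip_norm Global gradient-norm clip (`Inf` disables).
#' @return A list of class `utr_optim`.
#' @export
optim_spec <- function(beta1 = 0.9, beta2 = 0.98, eps = 1e-6,
                       weight_decay = 0.01, clip_norm = 1.0) {
  stopifnot(beta1 > 0, beta2 > 0, eps > 0, weight_decay >= 0)
  structure(list(beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay, clip_norm = clip_norm),
            class = "utr_optim")
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One AdamW update over the named gradient list (only the names present
# in `grads` are touched; no weight decay on biases, gains or shifts).
adamw_step <- function(params, grads, state, optim, lr) {
  if (is.finite(optim$clip_norm)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
    if (gn > optim$clip_norm) {
      grads <- lapply(grads, function(g) g * (optim$clip_norm / gn))
    }
  }
  state$t <- state$t + 1L
  bc1 <- 1 - optim$beta1^state$t
  bc2 <- 1 - optim$beta2^state$t
  decay_exempt <- grepl("(_b[a-z0-9]?$)|(_g$)|(ln[12]_[gb]$)|(_bq$)|(_bk$)|(_bv$)|(_bo$)|(b[12]$)",
                        names(grads))
  for (i in seq_along(grads)) {
    nm <- names(grads)[i]
    g <- grads[[i]]
    state$m[[nm]] <- optim$beta1 * state$m[[nm]] + (1 - optim$beta1) * g
    state$v[[nm]] <- optim$beta2 * state$v[[nm]] + (1 - optim$beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + optim$eps)
    wd <- if (decay_exempt[i]) 0 else optim$weight_decay
    params[[nm]] <- params[[nm]] - lr * (upd + wd * params[[nm]])
  }
  list(params = params, state = state)
}

sum_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}

#' Pre-train the encoder with the span-masked MLM objective
#'
#' Each step samples a batch of windows, draws a fresh masking plan per
#' window (masks are re-sampled dynamically every time a window is
#' visited), computes the masked cross-entropy loss and takes one AdamW
#' step under the warmup/decay schedule.  Deterministic given the seed.
#'
#' @param corpus List of `utr_window` objects.
#' @param vocab The `utr_vocab`.
#' @param config A `utr_config`; a fresh model is initialized from
#'   `seed` unless `params` is supplied.
#' @param steps Number of optimization steps.
#' @param batch_size Windows per step.
#' @param schedule A `utr_schedule` (defaults to warmup over the first
#'   10% of `steps`).
#' @param optim A `utr_optim`.
#' @param mask_rate MLM masking rate.
#' @param params Optional starting parameters (continue training).
#' @param seed Integer seed controlling initialization, batching,
#'   masking and dropout.
#' @return List with `params` (trained `utr_params`) and `history`
#'   (data frame step / loss / lr).
#' @export
pretrain <- function(corpus, vocab, config, steps = 300L, batch_size = 16L,
                     schedule = NULL, optim = optim_spec(),
                     mask_rate = 0.15, params = NULL, seed = 1L) {
  stopifnot(length(corpus) >= 1L)
  if (batch_size > length(corpus)) {
    stop("batch size exceeds corpus size", call. = FALSE)
  }
  if (is.null(schedule)) {
    schedule <- lr_schedule(peak_lr = 1e-3,
                            warmup_steps = max(1L, round(steps * 0.1)),
                            total_steps = max(2L, steps))
  }
  if (is.null(params)) params <- init_model(config, seed = seed)
  state <- adamw_init(params)
  history <- data.frame(step = integer(0), loss = numeric(0), lr = numeric(0))
  if (steps == 0L) return(list(params = params, history = history))
  for (step in seq_len(steps)) {
    sstep <- derive_seed(seed, step)
    batch_idx <- with_seed(sstep, sample.int(length(corpus), batch_size))
    acc <- NULL
    total_loss <- 0
    for (b in seq_along(batch_idx)) {
      w <- corpus[[batch_idx[b]]]
      mseed <- derive_seed(sstep, b)
      plan <- plan_masking(w, vocab, mask_rate = mask_rate, seed = mseed)
      ap <- apply_masking(w, plan, vocab)
      res <- mlm_loss(params, w, ap$corrupted, ap$targets, ap$loss_mask,
                      with_grads = TRUE, train = TRUE,
                      dropout_seed = derive_seed(mseed, 1L))
      if (!is.finite(res$loss)) stop("non-finite MLM loss at step ", step)
      total_loss <- total_loss + res$loss
      acc <- sum_grads(acc, res$grads)
    }
    acc <- lapply(acc, function(g) g / batch_size)
    lr <- lr_at(schedule, step)
    upd <- adamw_step(params, acc, state, optim, lr)
    params <- upd$params
    state <- upd$state
    history <- rbind(history,
                     data.frame(step = step, loss = total_loss / batch_size,
                                lr = lr))
  }
  attr(params, "config") <- config
  class(params) <- "utr_params"
  list(params = params, history = history)
}

#' Fine-tune on a labeled dataset
#'
#' For the binary task the whole encoder plus the `[CLS]` head is
#' updated end-to-end from the given initialization.  For the
#' multi-label task the encoder is frozen: mean-pooled embeddings are
#' computed once and an independent logistic head per compartment is
#' fitted ([fit_multilabel_head()]).
#'
#' The full-scale reference peak learning rate for fine-tuning is 5e-5;
#' desk-scale models train from much less data, so the default here is
#' larger (2e-3) and both are plain arguments.
#'
#' @param params Starting `utr_params` (pre-trained or random).
#' @param dataset Data frame with columns `sequence`, `label` and
#'   optionally `split` (`"train"` / `"val"` rows are used; others
#'   ignored).  For the multilabel task `label` holds comma-separated
#'   bits.
#' @param vocab The vocabulary.
#' @param task `"binary"` or `"multilabel"`.
#' @param epochs Passes over the training split.
#' @param batch_size Windows per step.
#' @param peak_lr Peak learning rate of the warmup/decay schedule.
#' @param optim A `utr_optim`.
#' @param window_nt Window width for tokenizing multilabel sequences.
#' @param seed Integer seed.
#' @return For binary: list with `params` (fine-tuned), `history`, and
#'   `val_loss`.  For multilabel: list with `params` (unchanged),
#'   `head` (a `utr_multilabel_head`).
#' @export
finetune <- function(params, dataset, vocab, task = c("binary", "multilabel"),
                     epochs = 6L, batch_size = 16L, peak_lr = 2e-3,
                     optim = optim_spec(), window_nt = 510L, seed = 1L) {
  task <- match.arg(task)
  cfg <- attr(params, "config")
  if (!"split" %in% names(dataset)) dataset$split <- "train"
  train <- dataset[dataset$split == "train", , drop = FALSE]
  val <- dataset[dataset$split == "val", , drop = FALSE]
  stopifnot(nrow(train) >= 1L)

  if (task == "multilabel") {
    lab <- do.call(rbind, lapply(strsplit(dataset$label, ","), as.integer))
    if (any(is.na(lab)) || any(!lab %in% c(0L, 1L))) {
      stop("multilabel labels must be comma-separated 0/1 bits", call. = FALSE)
    }
    emb <- t(vapply(dataset$sequence, function(s) {
      wins <- window_sequence(s, window = window_nt)
      tw <- lapply(wins$sequence, function(x)
        encode_window(tokenize(x, vocab$k), vocab,
                      max_positions = cfg$max_positions))
      embed_long_sequence(params, tw)
    }, numeric(cfg$d_model)))
    rownames(emb) <- NULL
    idx <- dataset$split == "train"
    head_fit <- fit_multilabel_head(emb[idx, , drop = FALSE],
                                    lab[idx, , drop = FALSE])
    return(list(params = params, head = head_fit, embeddings = emb,
                labels = lab))
  }

  labv <- as.numeric(train$label)
  if (any(!labv %in% c(0, 1))) {
    stop("binary labels must be 0/1", call. = FALSE)
  }
  windows <- lapply(train$sequence, function(s)
    encode_window(tokenize(s, vocab$k), vocab,
                  max_positions = cfg$max_positions))
  val_windows <- lapply(val$sequence, function(s)
    encode_window(tokenize(s, vocab$k), vocab,
                  max_positions = cfg$max_positions))
  val_labels <- as.numeric(val$label)

  n <- length(windows)
  steps_per_epoch <- ceiling(n / batch_size)
  total_steps <- max(2L, epochs * steps_per_epoch)
  schedule <- lr_schedule(peak_lr = peak_lr,
                          warmup_steps = max(1L, round(total_steps * 0.1)),
                          total_steps = total_steps)
  state <- adamw_init(params)
  history <- data.frame(step = integer(0), loss = numeric(0), lr = numeric(0))
  if (epochs == 0L) {
    return(list(params = params, history = history, val_loss = NA_real_))
  }
  step <- 0L
  best <- list(loss = Inf, params = params)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 1000L + ep), sample.int(n))
    for (start in seq.int(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      acc <- NULL
      total_loss <- 0
      for (b in seq_along(idx)) {
        res <- classify_window(params, windows[[idx[b]]], with_grads = TRUE,
                               label = labv[idx[b]], train = TRUE,
                               dropout_seed = derive_seed(seed, step * 131L + b))
        if (!is.finite(res$loss)) stop("non-finite loss during fine-tuning")
        total_loss <- total_loss + res$loss
        acc <- sum_grads(acc, res$grads)
      }
      acc <- lapply(acc, function(g) g / length(idx))
      step <- step + 1L
      lr <- lr_at(schedule, step)
      upd <- adamw_step(params, acc, state, optim, lr)
      params <- upd$params
      state <- upd$state
      history <- rbind(history, data.frame(step = step,
                                           loss = total_loss / length(idx),
                                           lr = lr))
    }
    if (length(val_windows)) {
      vl <- mean(vapply(seq_along(val_windows), function(i) {
        p <- classify_window(params, val_windows[[i]])
        -log(max(1e-12, if (val_labels[i] == 1) p else 1 - p))
      }, 0))
      if (vl < best$loss) best <- list(loss = vl, params = params)
    }
  }
  final <- if (length(val_windows)) best$params else params
  attr(final, "config") <- cfg
  class(final) <- "utr_params"
  list(params = final, history = history,
       val_loss = if (length(val_windows)) best$loss else NA_real_)
}

#' Score sequences with a fine-tuned binary model
#'
#' @param params Fine-tuned `utr_params`.
#' @param sequences Character vector of windows.
#' @param vocab The vocabulary.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_binary <- function(params, sequences, vocab) {
  cfg <- attr(params, "config")
  vapply(sequences, function(s) {
    w <- encode_window(tokenize(s, vocab$k), vocab,
                       max_positions = cfg$max_positions)
    classify_window(params, w)
  }, 0, USE.NAMES = FALSE)
}
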