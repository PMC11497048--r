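#' Plan span-contiguous MLM masking for one window
#'
#' Because stride-1 k-mers overlap, masking single tokens independently
#' would let the model read a masked k-mer off its unmasked neighbours.
#' Masking therefore proceeds by spans: an anchor token is drawn and the
#' k contiguous tokens starting at the anchor are masked together, so at
#' least one nucleotide inside a full-length span is covered by no
#' unmasked token.  Anchors are drawn uniformly without replacement until
#' the token budget `round(mask_rate * n_real_tokens)` is met; the final
#' span is truncated to the remaining budget and spans are clipped at the
#' window end.  Each masked token independently receives one of three
#' replacement actions: `[MASK]` with probability 0.8, a random k-mer
#' from the vocabulary with probability 0.1, or kept unchanged with
#' probability 0.1 (it still contributes to the loss).
#'
#' Special tokens and `[UNK]` tokens are never masked.
#'
#' @param window A `utr_window` from [encode_window()].
#' @param vocab The `utr_vocab` the window was encoded with.
#' @param mask_rate Fraction of real tokens to mask (default 0.15).
#' @param seed Integer seed; the plan is deterministic given it.
#' @param anchors Optional explicit anchor positions (1-based indices
#'   into `window$ids`) for reproducing worked examples; overrides the
#'   random draw.
#' @param force_action Optional single action (`"MASK"`, `"RANDOM"`,
#'   `"KEEP"`) applied to every masked token instead of the 80/10/10
#'   draw.
#' @return An object of class `utr_masking_plan`: list with
#'   `masked_positions` (1-based indices into `window$ids`), `spans`
#'   (two-column matrix of first/last masked position per anchor span,
#'   each span at most k tokens), `actions` (character vector parallel to
#'   `masked_positions`), `random_ids` (replacement ids where the action
#'   is RANDOM, NA elsewhere) and `seed`.
#' @export
plan_masking <- function(window, vocab, mask_rate = 0.15, seed = 1L,
                         anchors = NULL, force_action = NULL) {
  stopifnot(inherits(window, "utr_window"))
  if (mask_rate < 0 || mask_rate >= 1) {
    stop("mask_rate must be in [0, 1)", call. = FALSE)
  }
  k <- window$k
  n <- window$n_real_tokens
  if (n < k) stop("window has fewer than k real tokens", call. = FALSE)
  first_real <- 2L
  last_real <- 1L + n
  real_pos <- first_real:last_real
  maskable <- window$ids[real_pos] != vocab$unk_id
  budget <- round(mask_rate * n)

  masked <- logical(length(window$ids))
  spans <- list()
  positions <- integer(0)

  with_seed(seed, {
    anchor_order <- if (is.null(anchors)) {
      sample(real_pos[maskable])
    } else {
      as.integer(anchors)
    }
    for (a in anchor_order) {
      if (budget <= 0L) break
      if (masked[a]) next
      cand <- a:min(a + k - 1L, last_real)
      ok <- !masked[cand] & maskable[cand - first_real + 1L]
      # keep the contiguous run that starts at the anchor
      run_len <- if (all(ok)) length(ok) else which(!ok)[1L] - 1L
      if (run_len == 0L) next
      seg <- cand[seq_len(min(run_len, budget))]
      masked[seg] <- TRUE
      positions <- c(positions, seg)
      spans[[length(spans) + 1L]] <- c(seg[1L], seg[length(seg)])
      budget <- budget - length(seg)
    }
    positions <- sort(positions)
    if (is.null(force_action)) {
      u <- runif(length(positions))
      actions <- ifelse(u < 0.8, "MASK", ifelse(u < 0.9, "RANDOM", "KEEP"))
    } else {
      actions <- rep(force_action, length(positions))
    }
    random_ids <- rep(NA_integer_, length(positions))
    is_rand <- actions == "RANDOM"
    if (any(is_rand)) {
      # random replacements come from the k-mer part of the vocabulary,
      # never from the specials
      random_ids[is_rand] <- vocab$n_special - 1L +
        sample.int(vocab$size - vocab$n_special, sum(is_rand), replace = TRUE)
    }
    structure(list(masked_positions = positions,
                   spans = if (length(spans)) do.call(rbind, spans)
                           else matrix(integer(0), ncol = 2L),
                   actions = actions, random_ids = random_ids,
                   seed = seed),
              class = "utr_masking_plan")
  })
}

#' Apply a masking plan to a window
#'
#' @param window A `utr_window`.
#' @param plan The `utr_masking_plan` built for it.
#' @param vocab The vocabulary.
#' @return List with `corrupted` (ids after replacement), `targets` (the
#'   original ids) and `loss_mask` (logical; `TRUE` exactly at masked
#'   positions, including KEEP positions).
#' @export
apply_masking <- function(window, plan, vocab) {
  stopifnot(inherits(window, "utr_window"), inherits(plan, "utr_masking_plan"))
  if (length(plan$masked_positions) &&
      max(plan$masked_positions) > 1L + window$n_real_tokens) {
    stop("masking plan does not match window", call. = FALSE)
  }
  corrupted <- window$ids
  for (i in seq_along(plan$masked_positions)) {
    p <- plan$masked_positions[i]
    corrupted[p] <- switch(plan$actions[i],
                           MASK = vocab$mask_id,
                           RANDOM = plan$random_ids[i],
                           KEEP = corrupted[p])
  }
  loss_mask <- logical(length(window$ids))
  loss_mask[plan$masked_positions] <- TRUE
  list(corrupted = as.integer(corrupted), targets = window$ids,
       loss_mask = loss_mask)
}

#' Write a masking plan as a text sidecar
#'
#' One masked position per line (`position`, `action`, `random_id`),
#' preceded by `# seed:` — a reproducibility audit trail for
#' pre-training runs.
#'
#' @param plan A `utr_masking_plan`.
#' @param path Output path.
#' @export
write_masking_plan <- function(plan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", plan$seed), con)
  writeLines(paste(plan$masked_positions, plan$actions,
                   ifelse(is.na(plan$random_ids), ".", plan$random_ids),
                   sep = "\t"), con)
  invisible(path)
}
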