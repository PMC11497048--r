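#' Per-token attention scores from the `[CLS]` query
#'
#' For the chosen layer, the attention each head pays from the `[CLS]`
#' token to every real k-mer token is collected, renormalized within
#' each head over the real tokens (special-token mass excluded so the
#' score track reflects sequence positions only) and summed over heads.
#' The scores therefore sum to the number of heads H; with uniform
#' attention every token scores H/J.
#'
#' @param state A `utr_encoder_state` from [encode_sequence()].
#' @param layer Encoder layer to read (default: the final layer).
#' @return Numeric vector of length `n_real_tokens` (the token scores
#'   alpha_j).
#' @export
cls_attention <- function(state, layer = NULL) {
  stopifnot(inherits(state, "utr_encoder_state"))
  nl <- length(state$attention)
  if (is.null(layer)) layer <- nl
  if (layer < 1L || layer > nl) stop("layer out of range", call. = FALSE)
  J <- state$n_real_tokens
  real_cols <- seq.int(2L, 1L + J)
  heads <- state$attention[[layer]]
  alpha <- numeric(J)
  for (A in heads) {
    a <- A[1L, real_cols]
    alpha <- alpha + a / sum(a)
  }
  alpha
}

#' Convert token scores to a per-nucleotide track
#'
#' The score of nucleotide i is the mean of the scores of all k-mer
#' tokens whose window covers i (fewer than k tokens at the two edges).
#'
#' @param token_scores Numeric vector of per-token scores (length
#'   `L - k + 1`).
#' @param k k-mer size.
#' @param L Sequence length in nucleotides.
#' @return Numeric vector of length `L`.
#' @export
token_to_nucleotide <- function(token_scores, k, L) {
  J <- length(token_scores)
  stopifnot(J == L - k + 1L)
  vapply(seq_len(L) - 1L, function(i) {
    j <- max(0L, i - k + 1L):min(J - 1L, i)
    mean(token_scores[j + 1L])
  }, 0)
}

#' Attention profile of one sequence window
#'
#' Convenience wrapper: encode, read the `[CLS]` attention of the chosen
#' layer, and convert to the nucleotide track.
#'
#' @param params A `utr_params`.
#' @param sequence Sequence string.
#' @param vocab The vocabulary.
#' @param layer Encoder layer (default final).
#' @return An object of class `utr_attention_profile`: list with
#'   `token_scores`, `nucleotide_scores`, `layer`, `n_heads`, `n_tokens`,
#'   `sequence`.
#' @export
attention_profile <- function(params, sequence, vocab, layer = NULL) {
  cfg <- attr(params, "config")
  w <- encode_window(tokenize(sequence, vocab$k), vocab,
                     max_positions = cfg$max_positions)
  st <- encode_sequence(params, w)
  if (is.null(layer)) layer <- length(st$attention)
  ts <- cls_attention(st, layer)
  structure(list(token_scores = ts,
                 nucleotide_scores = token_to_nucleotide(ts, vocab$k,
                                                         nchar(sequence)),
                 layer = layer, n_heads = cfg$n_heads, n_tokens = length(ts),
                 sequence = sequence),
            class = "utr_attention_profile")
}

#' Mean attention landscape around labeled windows
#'
#' Column-wise mean of the per-nucleotide attention tracks across each
#' label class, aligned on window coordinates.  All windows must have
#' equal length (as the fixed-width RBP / m6A window sets do).
#'
#' @param params A `utr_params`.
#' @param dataset Data frame with `sequence` and binary `label` columns.
#' @param vocab The vocabulary.
#' @param layer Encoder layer.
#' @return Data frame with columns `position` (1-based),
#'   `positive_mean`, `negative_mean`.
#' @export
attention_landscape <- function(params, dataset, vocab, layer = NULL) {
  L <- unique(nchar(dataset$sequence))
  if (length(L) != 1L) {
    stop("attention_landscape needs equal-length windows", call. = FALSE)
  }
  tracks <- t(vapply(dataset$sequence, function(s)
    attention_profile(params, s, vocab, layer)$nucleotide_scores,
    numeric(L)))
  lab <- as.numeric(dataset$label)
  data.frame(position = seq_len(L),
             positive_mean = colMeans(tracks[lab == 1, , drop = FALSE]),
             negative_mean = colMeans(tracks[lab == 0, , drop = FALSE]))
}

#' In-silico saturation mutagenesis map
#'
#' Every position of the sequence is substituted by each of the three
#' alternative bases and re-scored with the fine-tuned binary head; the
#' map records `classify(mutant) - classify(wildtype)`, so negative
#' values mark disruptive substitutions.  Cells at the reference base
#' are 0 by definition.
#'
#' @param params Fine-tuned `utr_params`.
#' @param sequence Window sequence (no `N`).
#' @param vocab The vocabulary.
#' @return An object of class `utr_mutation_map`: list with `delta`
#'   (L x 4 matrix, columns A, C, G, U), `wildtype_score`, `sequence`.
#' @export
mutation_map <- function(params, sequence, vocab) {
  if (grepl("N", sequence, fixed = TRUE)) {
    stop("cannot mutate a sequence containing N", call. = FALSE)
  }
  L <- nchar(sequence)
  wt <- predict_binary(params, sequence, vocab)
  delta <- matrix(0, L, 4L, dimnames = list(NULL, RNA_BASES))
  chars <- strsplit(sequence, "")[[1L]]
  for (p in seq_len(L)) {
    for (b in RNA_BASES) {
      if (b == chars[p]) next
      mut <- chars
      mut[p] <- b
      delta[p, b] <- predict_binary(params, paste(mut, collapse = ""),
                                    vocab) - wt
    }
  }
  structure(list(delta = delta, wildtype_score = wt, sequence = sequence),
            class = "utr_mutation_map")
}

#' Write a nucleotide score track / mutation map as TSV
#'
#' Tracks use a bedGraph-style layout (`seq_id`, `start`, `end`,
#' `score`, one row per nucleotide); mutation maps are L x 4 with base
#' order A, C, G, U.
#'
#' @param profile A `utr_attention_profile`.
#' @param seq_id Identifier written in the first column.
#' @param path Output path.
#' @export
write_attention_track <- function(profile, seq_id, path) {
  L <- length(profile$nucleotide_scores)
  write.table(data.frame(seq_id, seq_len(L) - 1L, seq_len(L),
                         profile$nucleotide_scores),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_attention_track
#' @param state A `utr_encoder_state`.
#' @param layer,head Which attention map to export.
#' @export
write_attention_matrix <- function(state, layer, head, path) {
  stopifnot(inherits(state, "utr_encoder_state"))
  A <- state$attention[[layer]][[head]]
  write.table(A[seq_len(state$n_active), seq_len(state$n_active)],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_attention_track
#' @param map A `utr_mutation_map`.
#' @export
write_mutation_map <- function(map, path) {
  df <- data.frame(position = seq_len(nrow(map$delta)),
                   ref = strsplit(map$sequence, "")[[1L]], map$delta)
  names(df)[3:6] <- RNA_BASES
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
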