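#' Special token names, in id order
#'
#' Ids 0--4 are reserved for, in order, `[PAD]`, `[UNK]`, `[CLS]`,
#' `[SEP]`, `[MASK]`; the `4^k` k-mers follow in lexicographic order
#' (A < C < G < U).  Placing `[PAD]` at id 0 keeps attention masking and
#' zero-padding aligned.
#' @keywords internal
SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

RNA_BASES <- c("A", "C", "G", "U")

#' Build the k-mer vocabulary
#'
#' The vocabulary contains all `4^k` k-mers over the RNA alphabet plus
#' the five special tokens, for `4^k + 5` tokens in total.  Token order
#' (and therefore every id) is deterministic: specials first at ids 0--4,
#' then k-mers sorted lexicographically with A < C < G < U.
#'
#' @param k k-mer size, an integer in 3..6.
#' @return An object of class `utr_vocab`: a list with `k`, `tokens`
#'   (character vector, index i holds the token with id i-1), `size`, and
#'   the ids of the special tokens (`pad_id`, `unk_id`, `cls_id`,
#'   `sep_id`, `mask_id`).
#' @export
build_vocabulary <- function(k) {
  if (length(k) != 1L || k < 3L || k > 6L || k != as.integer(k)) {
    stop("k must be an integer in [3, 6]", call. = FALSE)
  }
  k <- as.integer(k)
  grid <- do.call(expand.grid,
                  c(rev(rep(list(RNA_BASES), k)), stringsAsFactors = FALSE))
  kmers <- do.call(paste0, rev(grid))  # first position most significant
  tokens <- c(SPECIAL_TOKENS, sort(kmers))
  structure(
    list(k = k, tokens = tokens, size = length(tokens),
         pad_id = 0L, unk_id = 1L, cls_id = 2L, sep_id = 3L, mask_id = 4L,
         n_special = length(SPECIAL_TOKENS)),
    class = "utr_vocab"
  )
}

#' @export
print.utr_vocab <- function(x, ...) {
  cat(sprintf("k-mer vocabulary: k = %d, %d tokens (%d k-mers + %d specials)\n",
              x$k, x$size, x$size - x$n_special, x$n_special))
  invisible(x)
}

#' Map token strings to ids and back
#'
#' @param vocab A `utr_vocab`.
#' @param tokens Character vector of token strings.
#' @param ids Integer vector of token ids (0-based).
#' @return `token_to_id()` gives 0-based integer ids (unknown strings map
#'   to the `[UNK]` id); `id_to_token()` gives token strings.
#' @export
token_to_id <- function(vocab, tokens) {
  ids <- match(tokens, vocab$tokens) - 1L
  ids[is.na(ids)] <- vocab$unk_id
  ids
}

#' @rdname token_to_id
#' @export
id_to_token <- function(vocab, ids) {
  vocab$tokens[ids + 1L]
}

#' Tokenize a sequence into overlapping k-mers
#'
#' Windows of width `k` are taken left to right at the given stride
#' (stride 1 everywhere in this package; the parameter exists for
#' experimentation).  Any k-mer containing `N` becomes the `[UNK]`
#' token.
#'
#' @param sequence A single RNA sequence string.
#' @param k k-mer size.
#' @param stride Step between successive k-mer starts.
#' @return Character vector of token strings; for stride 1 a sequence of
#'   length L yields `L - k + 1` tokens.
#' @export
tokenize <- function(sequence, k, stride = 1L) {
  stopifnot(length(sequence) == 1L, k >= 1L, stride >= 1L)
  L <- nchar(sequence)
  if (L < k) {
    stop(sprintf("sequence of length %d is shorter than k = %d", L, k),
         call. = FALSE)
  }
  starts <- seq.int(1L, L - k + 1L, by = stride)
  kmers <- substring(sequence, starts, starts + k - 1L)
  kmers[grepl("N", kmers, fixed = TRUE)] <- "[UNK]"
  kmers
}

#' Reassemble a sequence from its stride-1 k-mer tokens
#'
#' Inverse of [tokenize()] on N-free sequences: overlapping k-mers are
#' collapsed back to the original string.
#' @param tokens Character vector of k-mer tokens (no specials).
#' @param k k-mer size.
#' @return The reconstructed sequence string.
#' @export
reconstruct <- function(tokens, k) {
  stopifnot(length(tokens) >= 1L)
  paste0(tokens[1L], paste(substring(tokens[-1L], k, k), collapse = ""))
}

#' Encode tokens into a fixed-length model window
#'
#' The id sequence is framed as `[CLS] tokens... [SEP]` and right-padded
#' with `[PAD]` to `max_positions`.
#'
#' @param tokens Character vector of token strings (from [tokenize()]).
#' @param vocab A `utr_vocab`.
#' @param max_positions Model length (default 512).
#' @param source Optional interval (one-row data frame from
#'   [window_sequence()]) recording where the window came from.
#' @return An object of class `utr_window`: list with `ids` (0-based
#'   integer vector of length `max_positions`), `n_real_tokens`, `k`,
#'   `source`.
#' @export
encode_window <- function(tokens, vocab, max_positions = 512L, source = NULL) {
  n <- length(tokens)
  if (n == 0L) stop("cannot encode an empty token list", call. = FALSE)
  if (n + 2L > max_positions) {
    stop(sprintf(paste0("window of %d tokens does not fit in %d positions ",
                        "(with [CLS]/[SEP]); split the sequence with ",
                        "window_sequence() first"), n, max_positions),
         call. = FALSE)
  }
  ids <- c(vocab$cls_id, token_to_id(vocab, tokens), vocab$sep_id,
           rep.int(vocab$pad_id, max_positions - n - 2L))
  structure(list(ids = as.integer(ids), n_real_tokens = n, k = vocab$k,
                 source = source),
            class = "utr_window")
}

#' @rdname encode_window
#' @param window A `utr_window`.
#' @return `decode_window()` returns the real token strings (no
#'   specials).
#' @export
decode_window <- function(window, vocab) {
  real <- window$ids[seq.int(2L, 1L + window$n_real_tokens)]
  id_to_token(vocab, real)
}

#' Nucleotide span covered by a k-mer token
#'
#' With stride-1 tokenization, real token `j` (0-based) covers
#' nucleotides `[j, j + k)` in 0-based half-open coordinates.
#'
#' @param token_index 0-based index among the real tokens.
#' @param k k-mer size.
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
detokenize_positions <- function(token_index, k) {
  stopifnot(token_index >= 0L)
  c(start = as.integer(token_index), end = as.integer(token_index + k))
}

#' Serialize / load a vocabulary as one token per line
#'
#' Line `i` of the file holds the token with id `i - 1`.
#' @param vocab A `utr_vocab`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path)
  if (!identical(tokens[1:5], SPECIAL_TOKENS)) {
    stop("vocabulary file does not start with the five special tokens",
         call. = FALSE)
  }
  k <- as.integer(round(log(length(tokens) - 5L, base = 4)))
  v <- build_vocabulary(k)
  if (!identical(v$tokens, tokens)) {
    stop("vocabulary file does not match the canonical token order",
         call. = FALSE)
  }
  v
}
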