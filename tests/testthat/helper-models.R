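# Shared desk-scale fixtures, built in code at test time.

tiny_vocab <- function(k = 3L) build_vocabulary(k)

tiny_config <- function(vocab, d = 16L, layers = 2L, heads = 2L,
                        max_positions = 64L, dropout = 0, ...) {
  model_config(n_layers = layers, n_heads = heads, d_model = d,
               d_ffn = 2L * d, max_positions = max_positions,
               vocab_size = vocab$size, dropout = dropout, ...)
}

tiny_window <- function(sequence, vocab, max_positions = 64L) {
  encode_window(tokenize(sequence, vocab$k), vocab,
                max_positions = max_positions)
}

random_rna <- function(L, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

# Shift-tolerant Hamming distance between a planted consensus and a
# cluster consensus: minimum over relative offsets (|offset| <= 2, the
# same tolerance the cluster merger uses) of mismatches in the overlap
# plus the planted positions left unaligned.
hamming_min <- function(needle, hay) {
  nc <- strsplit(needle, "")[[1L]]
  hc <- strsplit(hay, "")[[1L]]
  n <- length(nc)
  h <- length(hc)
  best <- n
  for (off in -2:(h - n + 2L)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= h
    if (sum(ok) < n - 2L) next
    d <- sum(nc[ok] != hc[j[ok]]) + (n - sum(ok))
    best <- min(best, d)
  }
  best
}
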