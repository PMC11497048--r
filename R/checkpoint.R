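#' Save / load a model checkpoint
#'
#' A checkpoint bundles the configuration, the parameter arrays, the
#' vocabulary size/k and optionally a fitted multi-label head.
#'
#' @param params A `utr_params`.
#' @param path File path (`.rds`).
#' @param vocab Optional `utr_vocab` to record `k`.
#' @param head Optional `utr_multilabel_head`.
#' @export
save_checkpoint <- function(params, path, vocab = NULL, head = NULL) {
  saveRDS(list(config = attr(params, "config"),
               params = unclass(params),
               k = if (!is.null(vocab)) vocab$k else NULL,
               head = head),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a list with `params` (a
#'   `utr_params`), `config`, `k`, `head`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  params <- x$params
  attr(params, "config") <- x$config
  class(params) <- "utr_params"
  list(params = params, config = x$config, k = x$k, head = x$head)
}
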