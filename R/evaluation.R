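#' Binary classification metrics
#'
#' AUROC is computed with the rank (Mann-Whitney) statistic, giving ties
#' half credit; AUPRC by step-wise precision-recall integration (no
#' interpolation); F1, MCC and accuracy from the confusion matrix at the
#' threshold.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels (same length).
#' @param threshold Decision threshold for the confusion-matrix metrics.
#' @return A list of class `utr_metrics` with `auroc`, `auprc`, `f1`,
#'   `mcc`, `acc`, `n_pos`, `n_neg`, `threshold`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC/AUPRC need at least one positive and one negative",
         call. = FALSE)
  }
  r <- rank(scores)
  auroc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / n_pos
  # evaluate at the last index of each tied score group
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  prec_g <- precision[grp_end]
  rec_g <- recall[grp_end]
  auprc <- sum(diff(c(0, rec_g)) * prec_g)

  pred <- as.numeric(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1)
  TN <- sum(pred == 0 & labels == 0)
  FP <- sum(pred == 1 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  acc <- (TP + TN) / length(labels)
  f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  denom <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  mcc <- if (denom == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / denom
  structure(list(auroc = auroc, auprc = auprc, f1 = f1, mcc = mcc,
                 acc = acc, n_pos = n_pos, n_neg = n_neg,
                 threshold = threshold),
            class = "utr_metrics")
}

#' @export
print.utr_metrics <- function(x, ...) {
  cat(sprintf(paste0("AUROC %.3f  AUPRC %.3f  F1 %.3f  MCC %.3f  ACC %.3f",
                     "  (%d pos / %d neg, threshold %.2f)\n"),
              x$auroc, x$auprc, x$f1, x$mcc, x$acc, x$n_pos, x$n_neg,
              x$threshold))
  invisible(x)
}

#' Positional enrichment of sites along scaled 3'UTRs
#'
#' Site positions are rescaled to relative distances in (0, 1] (a site
#' at 1-based position 10 on a 50-nt sequence sits at 10/50 = 0.2),
#' binned, and within each bin the fraction of sites whose attention
#' score exceeds the threshold (default 0.3) is computed.  The Pearson
#' correlation between bin midpoints and fractions summarizes whether
#' high-attention sites concentrate near the 5' end (negative r) or the
#' 3' end (positive r).  If the fractions are constant the correlation
#' is undefined and reported as 0 with `constant = TRUE`.
#'
#' @param sites Data frame with `seq_id` and `start` (0-based site
#'   position).
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param attention Named list of per-sequence nucleotide score tracks.
#' @param threshold High-attention cutoff on the score at the site.
#' @param n_bins Number of relative-position bins.
#' @return A list of class `utr_positional_enrichment` with
#'   `relative_positions`, `bins` (data frame: midpoint, n_sites,
#'   n_high, fraction), `pearson_r`, `constant`, `threshold`.
#' @export
positional_enrichment <- function(sites, seq_lengths, attention,
                                  threshold = 0.3, n_bins = 10L) {
  lens <- seq_lengths[sites$seq_id]
  if (any(is.na(lens))) stop("site on unknown sequence", call. = FALSE)
  pos1 <- sites$start + 1L
  if (any(pos1 > lens)) stop("site beyond sequence length", call. = FALSE)
  rel <- unname(pos1 / lens)
  high <- vapply(seq_len(nrow(sites)), function(i)
    attention[[sites$seq_id[i]]][pos1[i]] > threshold, FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(n_bins, pmax(1L, ceiling(rel * n_bins)))
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  n_sites <- tabulate(bin, nbins = n_bins)
  n_high <- vapply(seq_len(n_bins), function(b) sum(high[bin == b]), 0L)
  fraction <- ifelse(n_sites > 0, n_high / n_sites, NA_real_)
  use <- !is.na(fraction)
  constant <- sum(use) < 2L || sd(fraction[use]) == 0
  r <- if (constant) 0 else cor(mids[use], fraction[use])
  structure(list(relative_positions = rel,
                 bins = data.frame(midpoint = mids, n_sites = n_sites,
                                   n_high = n_high, fraction = fraction),
                 pearson_r = r, constant = constant, threshold = threshold),
            class = "utr_positional_enrichment")
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class (per-fold class counts within one of
#' the global ratio); each fold is scored by a user-supplied trainer.
#'
#' @param dataset Data frame with `sequence` and binary `label`.
#' @param k_folds Number of folds.
#' @param trainer Function `(train_df, seed)` returning a function that
#'   maps a test data frame to numeric scores.
#' @param seed Integer seed for the fold assignment and the trainers.
#' @return List with `folds` (per-fold `utr_metrics`), `assignments`
#'   (fold id per row), `mean` and `sd` (named vectors over the five
#'   metrics).
#' @export
cross_validate <- function(dataset, k_folds = 5L, trainer, seed = 1L) {
  stopifnot(k_folds >= 2L, nrow(dataset) >= k_folds)
  lab <- as.numeric(dataset$label)
  fold <- integer(nrow(dataset))
  with_seed(seed, {
    for (cl in unique(lab)) {
      idx <- which(lab == cl)
      fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  reports <- lapply(seq_len(k_folds), function(f) {
    train <- dataset[fold != f, , drop = FALSE]
    test <- dataset[fold == f, , drop = FALSE]
    predict_fun <- trainer(train, derive_seed(seed, f))
    compute_metrics(predict_fun(test), as.numeric(test$label))
  })
  vals <- vapply(reports, function(r)
    c(auroc = r$auroc, auprc = r$auprc, f1 = r$f1, mcc = r$mcc, acc = r$acc),
    numeric(5))
  list(folds = reports, assignments = fold,
       mean = rowMeans(vals), sd = apply(vals, 1L, sd))
}

#' Write a metric report as a key-value TSV
#' @param metrics A `utr_metrics`.
#' @param path Output path.
#' @export
write_metrics <- function(metrics, path) {
  keys <- c("auroc", "auprc", "f1", "mcc", "acc", "n_pos", "n_neg",
            "threshold")
  write.table(data.frame(metric = keys,
                         value = unlist(metrics[keys], use.names = FALSE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
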