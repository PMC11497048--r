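#' Select high-attention regions from a nucleotide track
#'
#' Maximal runs of nucleotides whose score reaches the cutoff.  The
#' default policy sets the cutoff at the per-sequence mean plus one
#' standard deviation; a quantile policy is available.  Degenerate
#' (constant) tracks yield no regions under the adaptive policies, since
#' no position stands out.  Runs shorter than `min_width` are extended
#' symmetrically to `min_width` (shifted inward at sequence edges), and
#' regions that touch after extension are merged.
#'
#' @param scores Numeric nucleotide score track, or a
#'   `utr_attention_profile`.
#' @param cutoff Explicit cutoff (overrides the policy); positions with
#'   `score >= cutoff` are selected.
#' @param policy `"mean_sd"` (mean + 1 SD) or `"quantile"`.
#' @param q Quantile for the quantile policy.
#' @param min_width Minimum region width in nucleotides (default 7, the
#'   motif candidate width).
#' @param seq_id Identifier for the output intervals.
#' @return Data frame of intervals (`seq_id`, `start`, `end`, `name`,
#'   `score` = peak score in the region), 0-based half-open.
#' @export
high_attention_regions <- function(scores, cutoff = NULL,
                                   policy = c("mean_sd", "quantile"),
                                   q = 0.9, min_width = 7L, seq_id = "seq") {
  if (inherits(scores, "utr_attention_profile")) {
    scores <- scores$nucleotide_scores
  }
  policy <- match.arg(policy)
  L <- length(scores)
  if (L == 0L) stop("empty attention profile", call. = FALSE)
  if (is.null(cutoff)) {
    s <- sd(scores)
    if (is.na(s) || s == 0) {
      # flat track: nothing is "high"
      return(data.frame(seq_id = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        score = numeric(0)))
    }
    cutoff <- switch(policy,
                     mean_sd = mean(scores) + s,
                     quantile = unname(quantile(scores, q)))
  }
  hit <- scores >= cutoff
  if (!any(hit)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0)))
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])  # 1-based inclusive
  # extend short runs symmetrically to min_width, clipped to the sequence
  out <- t(apply(runs, 1L, function(rr) {
    w <- rr[2L] - rr[1L] + 1L
    if (w < min_width && L >= min_width) {
      pad <- min_width - w
      left <- rr[1L] - ceiling(pad / 2)
      right <- rr[2L] + floor(pad / 2)
      if (left < 1L) { right <- right + (1L - left); left <- 1L }
      if (right > L) { left <- left - (right - L); right <- L }
      left <- max(1L, left)
      rr <- c(left, right)
    }
    rr
  }))
  # merge overlapping/adjacent extended regions
  ord <- order(out[, 1L])
  out <- out[ord, , drop = FALSE]
  merged <- list(out[1L, ])
  for (i in seq_len(nrow(out))[-1L]) {
    last <- merged[[length(merged)]]
    if (out[i, 1L] <= last[2L] + 1L) {
      merged[[length(merged)]] <- c(last[1L], max(last[2L], out[i, 2L]))
    } else {
      merged[[length(merged) + 1L]] <- out[i, ]
    }
  }
  m <- do.call(rbind, merged)
  data.frame(seq_id = seq_id, start = m[, 1L] - 1L, end = m[, 2L],
             name = paste0("region", seq_len(nrow(m))),
             score = vapply(seq_len(nrow(m)),
                            function(i) max(scores[m[i, 1L]:m[i, 2L]]), 0),
             stringsAsFactors = FALSE)
}

kmer_set <- function(sequence, width) {
  L <- nchar(sequence)
  if (L < width) return(character(0))
  unique(substring(sequence, seq_len(L - width + 1L),
                   seq.int(width, L)))
}

#' Count motif candidates in high-attention regions
#'
#' Foreground counts are presence/absence per positive sequence of each
#' `width`-mer found inside that sequence's high-attention regions;
#' background counts are presence/absence over the full sequences of the
#' whole comparison universe (positives plus negatives).  Presence (not
#' multiplicity) keeps the sequences exchangeable for the hypergeometric
#' sampling model.
#'
#' @param positive_sequences Character vector of positive windows.
#' @param regions_per_sequence List (parallel to `positive_sequences`) of
#'   interval data frames from [high_attention_regions()].
#' @param universe_sequences Character vector: the full comparison set
#'   used as the background population.
#' @param width Candidate width (default 7).
#' @return Data frame with `kmer`, `fg_count`, `bg_count` for every
#'   candidate seen in at least one foreground region.
#' @export
count_candidates <- function(positive_sequences, regions_per_sequence,
                             universe_sequences, width = 7L) {
  stopifnot(length(positive_sequences) == length(regions_per_sequence))
  fg <- new.env(parent = emptyenv())
  for (i in seq_along(positive_sequences)) {
    reg <- regions_per_sequence[[i]]
    if (is.null(reg) || nrow(reg) == 0L) next
    kms <- unique(unlist(lapply(seq_len(nrow(reg)), function(r)
      kmer_set(substr(positive_sequences[i], reg$start[r] + 1L, reg$end[r]),
               width))))
    for (km in kms) {
      assign(km, (if (exists(km, fg, inherits = FALSE))
        get(km, fg) else 0L) + 1L, fg)
    }
  }
  kmers <- ls(fg)
  if (length(kmers) == 0L) {
    return(data.frame(kmer = character(0), fg_count = integer(0),
                      bg_count = integer(0)))
  }
  bg_sets <- lapply(universe_sequences, kmer_set, width = width)
  bg_count <- vapply(kmers, function(km)
    sum(vapply(bg_sets, function(s) km %in% s, FALSE)), 0L)
  data.frame(kmer = kmers,
             fg_count = vapply(kmers, get, 0L, envir = fg),
             bg_count = unname(bg_count),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sided hypergeometric over-representation p-value
#'
#' Probability of observing at least `x` candidate-bearing sequences in
#' a draw of `n_fg` from a population of `N_total` sequences of which
#' `K` bear the candidate: `P(X >= x)` under the hypergeometric.
#'
#' @param x Foreground sequences containing the candidate.
#' @param n_fg Foreground set size (number of draws).
#' @param K Universe sequences containing the candidate.
#' @param N_total Universe size.
#' @return The upper-tail p-value.
#' @export
hypergeom_enrich <- function(x, n_fg, K, N_total) {
  if (any(c(x, n_fg, K, N_total) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (x > min(K, n_fg)) {
    stop("x cannot exceed min(K, n_fg)", call. = FALSE)
  }
  phyper(x - 1, K, N_total - K, n_fg, lower.tail = FALSE)
}

#' Benjamini-Hochberg correction with significance calls
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) with significance
#' called at adjusted p < `alpha` (default 0.005).
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha Significance level on the adjusted scale.
#' @return Data frame with `p`, `q`, `significant`.
#' @export
bh_correct <- function(p_values, alpha = 0.005) {
  q <- p.adjust(p_values, method = "BH")
  data.frame(p = p_values, q = q, significant = q < alpha)
}

align_offset <- function(a, b, max_offset = 2L, max_mismatch = 1L) {
  # best ungapped alignment of b against a with |offset| <= max_offset and
  # at most max_mismatch mismatches in the overlap; NA if none qualifies
  wa <- nchar(a); wb <- nchar(b)
  best <- NULL
  for (off in -max_offset:max_offset) {
    sa <- max(1L, 1L + off); ea <- min(wa, wb + off)
    if (ea - sa + 1L < 4L) next  # require a meaningful overlap
    ca <- substr(a, sa, ea)
    cb <- substr(b, sa - off, ea - off)
    mm <- sum(strsplit(ca, "")[[1L]] != strsplit(cb, "")[[1L]])
    if (mm <= max_mismatch && (is.null(best) || mm < best$mm)) {
      best <- list(offset = off, mm = mm)
    }
  }
  best
}

#' Merge similar motif candidates into clusters
#'
#' Greedy clustering of significant candidates: the most frequent
#' remaining candidate (ties broken lexicographically) seeds a cluster,
#' which absorbs every candidate alignable to the seed with an offset of
#' at most 2 and at most 1 mismatch in the overlap; the process repeats
#' on the remainder.
#'
#' @param candidates Data frame with `kmer` and `fg_count` (typically
#'   the significant rows of the candidate table).
#' @param max_offset,max_mismatch Alignment tolerances.
#' @return List of clusters; each is a data frame with `kmer`,
#'   `fg_count`, `offset` (relative to the seed, first row).
#' @export
merge_candidates <- function(candidates, max_offset = 2L, max_mismatch = 1L) {
  if (nrow(candidates) == 0L) return(list())
  remaining <- candidates[order(-candidates$fg_count, candidates$kmer), ,
                          drop = FALSE]
  clusters <- list()
  while (nrow(remaining) > 0L) {
    seed <- remaining[1L, ]
    members <- data.frame(kmer = seed$kmer, fg_count = seed$fg_count,
                          offset = 0L, stringsAsFactors = FALSE)
    keep <- logical(nrow(remaining))
    for (i in seq_len(nrow(remaining))[-1L]) {
      al <- align_offset(seed$kmer, remaining$kmer[i], max_offset,
                         max_mismatch)
      if (!is.null(al)) {
        members <- rbind(members,
                         data.frame(kmer = remaining$kmer[i],
                                    fg_count = remaining$fg_count[i],
                                    offset = al$offset))
      } else {
        keep[i] <- TRUE
      }
    }
    clusters[[length(clusters) + 1L]] <- members
    remaining <- remaining[keep, , drop = FALSE]
  }
  clusters
}

#' Build a position weight matrix from aligned instances
#'
#' Column base frequencies of the aligned instances (one instance, one
#' vote; optional weights).  The consensus is the per-column argmax with
#' lexicographic tie-breaking (A < C < G < U).
#'
#' @param instances Character vector of instance strings.
#' @param offsets Integer offsets aligning each instance to a common
#'   frame (0 = no shift); defaults to all 0.
#' @param weights Optional per-instance weights (default 1 each).
#' @return An object of class `utr_pwm`: list with `matrix` (4 x w, rows
#'   A, C, G, U, every covered column sums to 1), `consensus`,
#'   `n_instances`.
#' @export
build_pwm <- function(instances, offsets = NULL, weights = NULL) {
  stopifnot(length(instances) >= 1L)
  if (is.null(offsets)) offsets <- rep(0L, length(instances))
  if (is.null(weights)) weights <- rep(1, length(instances))
  starts <- offsets
  ends <- offsets + nchar(instances) - 1L
  left <- min(starts)
  w <- max(ends) - left + 1L
  counts <- matrix(0, 4L, w, dimnames = list(RNA_BASES, NULL))
  for (i in seq_along(instances)) {
    chars <- strsplit(instances[i], "")[[1L]]
    cols <- (starts[i] - left + 1L):(ends[i] - left + 1L)
    for (j in seq_along(cols)) {
      counts[chars[j], cols[j]] <- counts[chars[j], cols[j]] + weights[i]
    }
  }
  cs <- colSums(counts)
  mat <- sweep(counts, 2L, ifelse(cs == 0, 1, cs), `/`)
  consensus <- paste(RNA_BASES[apply(mat, 2L, which.max)], collapse = "")
  structure(list(matrix = mat, consensus = consensus,
                 n_instances = length(instances)),
            class = "utr_pwm")
}

#' @export
print.utr_pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%d instances, width %d)\n", x$consensus,
              x$n_instances, ncol(x$matrix)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Full motif discovery pipeline
#'
#' From a fine-tuned binary model and its dataset to significant motif
#' PWMs: per-positive attention profiles, high-attention regions, 7-mer
#' candidate counting against the positive-plus-negative universe,
#' hypergeometric enrichment, BH correction at adjusted p < `alpha`,
#' greedy merging and PWM construction.
#'
#' @param params Fine-tuned `utr_params`.
#' @param dataset Data frame with `sequence` and binary `label`.
#' @param vocab The vocabulary.
#' @param width Candidate width (default 7).
#' @param alpha BH significance level (default 0.005).
#' @param cutoff,policy Passed to [high_attention_regions()].
#' @return List with `candidates` (full table with p, q, significant),
#'   `clusters`, `pwms` (one `utr_pwm` per cluster, ordered by total
#'   foreground support).
#' @export
discover_motifs <- function(params, dataset, vocab, width = 7L,
                            alpha = 0.005, cutoff = NULL,
                            policy = "mean_sd") {
  pos <- dataset$sequence[dataset$label == 1]
  universe <- dataset$sequence
  regions <- lapply(pos, function(s) {
    prof <- attention_profile(params, s, vocab)
    high_attention_regions(prof, cutoff = cutoff, policy = policy,
                           min_width = width)
  })
  cand <- count_candidates(pos, regions, universe, width = width)
  if (nrow(cand) == 0L) {
    return(list(candidates = cand, clusters = list(), pwms = list()))
  }
  cand$p <- vapply(seq_len(nrow(cand)), function(i)
    hypergeom_enrich(cand$fg_count[i], length(pos), cand$bg_count[i],
                     length(universe)), 0)
  bh <- bh_correct(cand$p, alpha = alpha)
  cand$q <- bh$q
  cand$significant <- bh$significant
  sig <- cand[cand$significant, , drop = FALSE]
  clusters <- merge_candidates(sig)
  ord <- order(-vapply(clusters, function(cl) sum(cl$fg_count), 0))
  clusters <- clusters[ord]
  pwms <- lapply(clusters, function(cl)
    build_pwm(cl$kmer, offsets = cl$offset, weights = cl$fg_count))
  list(candidates = cand[order(cand$q, -cand$fg_count), ],
       clusters = clusters, pwms = pwms)
}

#' Write / read PWMs in MEME minimal motif format
#'
#' The MEME minimal text format with an ACGU alphabet, one
#' letter-probability matrix per motif, suitable for downstream motif
#' comparison tools.
#'
#' @param pwms List of `utr_pwm` objects (possibly empty).
#' @param path Output path.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 U 0.25", ""), con)
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    writeLines(sprintf("MOTIF %s motif_%d", p$consensus, i), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(p$matrix), p$n_instances), con)
    for (j in seq_len(ncol(p$matrix))) {
      writeLines(paste(sprintf("%.6f", p$matrix[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  lapply(starts, function(s) {
    hdr <- strsplit(lines[s], " +")[[1L]]
    ml <- grep("^letter-probability matrix:", lines)
    ml <- ml[ml > s][1L]
    w <- as.integer(sub(".* w= *([0-9]+).*", "\\1", lines[ml]))
    n <- as.integer(sub(".* nsites= *([0-9]+).*", "\\1", lines[ml]))
    rows <- lines[(ml + 1L):(ml + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), " +")[[1L]]), numeric(4)))
    mat <- t(mat)
    dimnames(mat) <- list(RNA_BASES, NULL)
    structure(list(matrix = mat, consensus = hdr[2L], n_instances = n),
              class = "utr_pwm")
  })
}

#' Write the candidate table as TSV
#' @param candidates Candidate data frame from [discover_motifs()].
#' @param path Output path.
#' @export
write_candidates <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
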