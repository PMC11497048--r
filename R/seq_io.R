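#' Read a FASTA file of RNA or DNA sequences
#'
#' Sequences are normalized to the RNA alphabet: lowercase letters are
#' uppercased and `T` is rewritten to `U`.  Ambiguous `N` bases are kept
#' (they become `[UNK]` tokens downstream); any other character is an
#' error that names the offending record and 1-based position.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `sequence` (RNA alphabet) and
#'   `source_alphabet` (`"RNA"` or `"DNA"`, by presence of `T`/`U` in the
#'   raw record).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file is empty: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  raw <- toupper(as.character(set))
  alphabet <- ifelse(grepl("T", raw, fixed = TRUE), "DNA", "RNA")
  seqs <- chartr("T", "U", raw)
  bad <- regexpr("[^ACGUN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]),
         call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence in record '", ids[which(nchar(seqs) == 0L)[1L]], "'",
         call. = FALSE)
  }
  data.frame(id = ids, sequence = unname(seqs), source_alphabet = alphabet,
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA (60-column wrap)
#'
#' @param records Data frame with `id` and `sequence` columns, as returned
#'   by [read_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Split a sequence into non-overlapping model windows
#'
#' A sequence is cut left-to-right into non-overlapping windows of
#' `window` nucleotides.  The final fragment is emitted at its natural
#' (shorter) length: padding of short windows happens at the token level
#' with `[PAD]` ids when the window is encoded for the model, so the
#' sequence text itself is never altered.  Coordinates are 0-based,
#' half-open.
#'
#' @param sequence A single sequence string.
#' @param seq_id Identifier recorded in the output intervals.
#' @param window Window width in nucleotides (default 510, leaving room
#'   for the two special tokens within a 512-position model).
#' @return Data frame with columns `seq_id`, `start`, `end`, `sequence`;
#'   the concatenation of the `sequence` column equals the input.
#' @export
window_sequence <- function(sequence, seq_id = "seq", window = 510L) {
  stopifnot(length(sequence) == 1L, window >= 1L)
  L <- nchar(sequence)
  if (L == 0L) stop("cannot window an empty sequence", call. = FALSE)
  starts <- seq.int(0L, L - 1L, by = window)
  ends <- pmin(starts + window, L)
  data.frame(seq_id = seq_id, start = starts, end = ends,
             sequence = substring(sequence, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Greedy redundancy filter on sequence identity
#'
#' A deterministic keep-first filter: records are scanned in input order
#' and a record is dropped iff its ungapped end-to-end identity to an
#' already-kept record is at least `identity_cutoff`.  Identity between
#' two sequences is the fraction of matching positions over the shorter
#' of the two lengths.  This is the in-package replacement for external
#' clustering tools when preparing non-redundant window sets.
#'
#' @param records Data frame with a `sequence` column.
#' @param identity_cutoff Fraction in (0, 1].
#' @return The kept subset of `records`, original order preserved.
#' @export
redundancy_filter <- function(records, identity_cutoff = 0.8) {
  stopifnot(is.data.frame(records))
  if (identity_cutoff <= 0 || identity_cutoff > 1) {
    stop("identity_cutoff must be in (0, 1]", call. = FALSE)
  }
  seqs <- records$sequence
  keep <- logical(length(seqs))
  kept_split <- list()
  for (i in seq_along(seqs)) {
    si <- strsplit(seqs[[i]], "")[[1L]]
    dup <- FALSE
    for (sj in kept_split) {
      n <- min(length(si), length(sj))
      ident <- sum(si[seq_len(n)] == sj[seq_len(n)]) / n
      if (ident >= identity_cutoff) { dup <- TRUE; break }
    }
    if (!dup) {
      keep[i] <- TRUE
      kept_split[[length(kept_split) + 1L]] <- si
    }
  }
  records[keep, , drop = FALSE]
}

#' Read / write BED6 interval files
#'
#' Intervals are 0-based, half-open, matching BED conventions.  Strand is
#' written as `"."`; malformed lines are reported with their line number.
#'
#' @param intervals Data frame with columns `seq_id`, `start`, `end` and
#'   optionally `name`, `score`.
#' @param path File path.
#' @return `read_bed()` returns a data frame with columns `seq_id`,
#'   `start`, `end`, `name`, `score`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(is.data.frame(intervals),
            all(c("seq_id", "start", "end") %in% names(intervals)))
  if (any(intervals$start < 0L) || any(intervals$start >= intervals$end)) {
    stop("intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  score <- if ("score" %in% names(intervals)) intervals$score else 0
  out <- data.frame(intervals$seq_id, intervals$start, intervals$end,
                    name, score, ".")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop("malformed BED line ", which(n < 3L)[1L], ": fewer than 3 fields",
         call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], ": need 0 <= start < end",
         call. = FALSE)
  }
  data.frame(
    seq_id = vapply(fields, `[`, "", 1L),
    start = start,
    end = end,
    name = vapply(fields, function(f) if (length(f) >= 4L) f[4L] else ".", ""),
    score = vapply(fields, function(f)
      if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Read / write labeled sequence datasets as TSV
#'
#' The on-disk format is `sequence<TAB>label`, one window per line, with
#' multi-labels comma-separated (e.g. `"1,0,0,1,0,0"` for a six-
#' compartment localization label).  An optional third column carries the
#' train/val/test split.
#'
#' @param dataset Data frame with columns `sequence`, `label` and
#'   optionally `split`.
#' @param path File path.
#' @return `read_labeled_tsv()` returns the data frame back.
#' @export
write_labeled_tsv <- function(dataset, path) {
  stopifnot(all(c("sequence", "label") %in% names(dataset)))
  cols <- c("sequence", "label", intersect("split", names(dataset)))
  write.table(dataset[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_labeled_tsv
#' @export
read_labeled_tsv <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character", quote = "")
  names(df)[1:2] <- c("sequence", "label")
  if (ncol(df) >= 3L) names(df)[3L] <- "split"
  df
}
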