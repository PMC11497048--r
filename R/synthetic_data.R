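#' IUPAC nucleotide codes over the RNA alphabet
#' @keywords internal
IUPAC_RNA <- list(A = "A", C = "C", G = "G", U = "U",
                  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"),
                  W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
                  B = c("C", "G", "U"), D = c("A", "G", "U"),
                  H = c("A", "C", "U"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "U"))

#' Generate i.i.d. background sequences
#'
#' Bases are drawn independently from the given composition; the
#' default is the uniform composition.  Deterministic given the seed.
#'
#' @param n Number of sequences.
#' @param length Sequence length (scalar or vector of length `n`).
#' @param composition Named probabilities for A, C, G, U summing to 1.
#' @param seed Integer seed.
#' @param prefix Id prefix.
#' @return Data frame of sequence records (`id`, `sequence`,
#'   `source_alphabet`).
#' @export
generate_background <- function(n, length,
                                composition = c(A = 0.25, C = 0.25,
                                                G = 0.25, U = 0.25),
                                seed = 1L, prefix = "bg") {
  stopifnot(n >= 1L, all(length >= 1L))
  if (abs(sum(composition) - 1) > 1e-9 || any(composition < 0)) {
    stop("composition must be non-negative and sum to 1", call. = FALSE)
  }
  lens <- rep_len(as.integer(length), n)
  with_seed(seed, {
    seqs <- vapply(lens, function(L)
      paste(sample(RNA_BASES, L, replace = TRUE, prob = composition),
            collapse = ""), "")
    data.frame(id = sprintf("%s%04d", prefix, seq_len(n)), sequence = seqs,
               source_alphabet = "RNA", stringsAsFactors = FALSE)
  })
}

sample_motif_instance <- function(motif) {
  if (inherits(motif, "utr_pwm")) {
    paste(apply(motif$matrix, 2L, function(col)
      sample(RNA_BASES, 1L, prob = col)), collapse = "")
  } else {
    # IUPAC consensus string: each code drawn uniformly over its bases
    paste(vapply(strsplit(motif, "")[[1L]], function(ch)
      sample(IUPAC_RNA[[ch]], 1L), ""), collapse = "")
  }
}

#' Plant motif instances into sequence records
#'
#' In a `plant_rate` fraction of records (chosen at random) one instance
#' sampled from the motif (a `utr_pwm` or an IUPAC consensus string) is
#' written at a position drawn by the policy, and the planted interval
#' is recorded as ground truth.
#'
#' @param records Data frame of sequence records.
#' @param motif A `utr_pwm` or IUPAC consensus string.
#' @param plant_rate Fraction of records that receive an instance.
#' @param position_policy `"uniform"` (anywhere), `"fixed"` (at
#'   `fixed_start`), or `"near_end"` (uniform within the final quarter).
#' @param fixed_start 0-based start for the fixed policy.
#' @param seed Integer seed.
#' @return List with `records` (modified) and `truth` (BED-style data
#'   frame of planted intervals: `seq_id`, `start`, `end`, `name` = the
#'   instance).
#' @export
plant_motif <- function(records, motif, plant_rate = 1.0,
                        position_policy = c("uniform", "fixed", "near_end"),
                        fixed_start = 0L, seed = 1L) {
  position_policy <- match.arg(position_policy)
  stopifnot(plant_rate >= 0, plant_rate <= 1)
  w <- if (inherits(motif, "utr_pwm")) ncol(motif$matrix) else nchar(motif)
  with_seed(seed, {
    n <- nrow(records)
    planted <- which(runif(n) < plant_rate)
    truth <- data.frame(seq_id = character(0), start = integer(0),
                        end = integer(0), name = character(0))
    for (i in planted) {
      L <- nchar(records$sequence[i])
      if (L < w) next
      start <- switch(position_policy,
                      uniform = sample.int(L - w + 1L, 1L) - 1L,
                      fixed = fixed_start,
                      near_end = L - w - sample.int(max(1L, L %/% 4L), 1L) + 1L)
      start <- max(0L, min(start, L - w))
      inst <- sample_motif_instance(motif)
      substr(records$sequence[i], start + 1L, start + w) <- inst
      truth <- rbind(truth, data.frame(seq_id = records$id[i], start = start,
                                       end = start + w, name = inst))
    }
    list(records = records, truth = truth)
  })
}

assign_splits <- function(n, seed, test_frac = 0.2, val_frac_of_train = 0.2) {
  # 80/20 train-test, then 4:1 train:validation inside the 80%
  with_seed(seed, {
    split <- rep("train", n)
    test_n <- round(n * test_frac)
    idx <- sample.int(n)
    split[idx[seq_len(test_n)]] <- "test"
    rest <- idx[-seq_len(test_n)]
    val_n <- round(length(rest) * val_frac_of_train)
    split[rest[seq_len(val_n)]] <- "val"
    split
  })
}

#' Synthetic RBP binding-site dataset
#'
#' Fixed 100-nt windows at a 1:2 positive:negative ratio.  Positives
#' carry one instance of the motif planted at a `plant_rate` fraction;
#' negatives are pure background (optionally a 1-mismatch decoy can be
#' planted into negatives to emulate confusable binding patterns).
#' Rows are split 80/20 into train+validation/test with a 4:1
#' train:validation ratio, stratified per class.
#'
#' @param n_pos Number of positive windows (negatives are `2 * n_pos`).
#' @param motif IUPAC consensus or `utr_pwm` (default `"UGUAUAU"`, a
#'   UG-rich single-stranded binding element).
#' @param plant_rate Fraction of positives that actually carry the
#'   motif (default 0.9; real CLIP positives are not all true sites).
#' @param window_nt Window width (default 100).
#' @param composition Background base composition.
#' @param decoy_rate Fraction of negatives receiving a 1-mismatch decoy
#'   (default 0: clean negatives).
#' @param seed Integer seed.
#' @return List with `dataset` (data frame `id`, `sequence`, `label`,
#'   `split`) and `truth` (planted intervals).
#' @export
make_rbp_dataset <- function(n_pos = 150L, motif = "UGUAUAU",
                             plant_rate = 0.9, window_nt = 100L,
                             composition = c(A = 0.25, C = 0.25,
                                             G = 0.25, U = 0.25),
                             decoy_rate = 0, seed = 1L) {
  n_neg <- 2L * n_pos
  pos <- generate_background(n_pos, window_nt, composition,
                             seed = derive_seed(seed, 1L), prefix = "pos")
  neg <- generate_background(n_neg, window_nt, composition,
                             seed = derive_seed(seed, 2L), prefix = "neg")
  pl <- plant_motif(pos, motif, plant_rate = plant_rate,
                    seed = derive_seed(seed, 3L))
  pos <- pl$records
  truth <- pl$truth
  if (decoy_rate > 0 && is.character(motif)) {
    decoy <- make_decoy(motif, seed = derive_seed(seed, 5L))
    neg <- plant_motif(neg, decoy, plant_rate = decoy_rate,
                       seed = derive_seed(seed, 6L))$records
  }
  dataset <- rbind(
    data.frame(id = pos$id, sequence = pos$sequence, label = 1L,
               split = assign_splits(n_pos, derive_seed(seed, 7L))),
    data.frame(id = neg$id, sequence = neg$sequence, label = 0L,
               split = assign_splits(n_neg, derive_seed(seed, 8L)))
  )
  list(dataset = dataset, truth = truth)
}

make_decoy <- function(consensus, seed) {
  with_seed(seed, {
    chars <- strsplit(consensus, "")[[1L]]
    p <- sample.int(length(chars), 1L)
    alt <- setdiff(RNA_BASES, IUPAC_RNA[[chars[p]]])
    if (length(alt) == 0L) alt <- RNA_BASES
    chars[p] <- sample(alt, 1L)
    paste(chars, collapse = "")
  })
}

#' Synthetic m6A modification dataset
#'
#' 41-nt windows centered on an adenosine (position 21, 1-based).
#' Positives carry an RRACH-compatible context planted so that its A is
#' the central base; negatives are background windows with an A forced
#' at the center.  Positive:negative ratio is 1:1.
#'
#' @param n_pos Number of positive windows.
#' @param window_nt Window width (odd; default 41).
#' @param composition Background base composition.
#' @param seed Integer seed.
#' @return List with `dataset` and `truth` as in [make_rbp_dataset()].
#' @export
make_m6a_dataset <- function(n_pos = 150L, window_nt = 41L,
                             composition = c(A = 0.25, C = 0.25,
                                             G = 0.25, U = 0.25),
                             seed = 1L) {
  if (window_nt %% 2L != 1L) {
    stop("window_nt must be odd so a single adenosine sits at the center",
         call. = FALSE)
  }
  center <- (window_nt + 1L) %/% 2L  # 1-based
  force_center_A <- function(records) {
    substr(records$sequence, center, center) <- "A"
    records
  }
  pos <- force_center_A(generate_background(n_pos, window_nt, composition,
                                            seed = derive_seed(seed, 1L),
                                            prefix = "m6a_pos"))
  neg <- force_center_A(generate_background(n_pos, window_nt, composition,
                                            seed = derive_seed(seed, 2L),
                                            prefix = "m6a_neg"))
  # RRACH: plant so the consensus A (3rd position) is the window center
  start0 <- center - 3L  # 0-based start of the 5-mer
  pl <- plant_motif(pos, "RRACH", plant_rate = 1.0,
                    position_policy = "fixed", fixed_start = start0,
                    seed = derive_seed(seed, 3L))
  pos <- pl$records
  dataset <- rbind(
    data.frame(id = pos$id, sequence = pos$sequence, label = 1L,
               split = assign_splits(n_pos, derive_seed(seed, 7L))),
    data.frame(id = neg$id, sequence = neg$sequence, label = 0L,
               split = assign_splits(n_pos, derive_seed(seed, 8L)))
  )
  list(dataset = dataset, truth = pl$truth)
}

#' Concatenate a transcript to its first-4000 + last-4000 form
#'
#' Long localization inputs keep the first 4000 nt (5' side) and the
#' last 4000 nt (3' side) of the transcript, concatenated; transcripts
#' of 8000 nt or less pass through unchanged (padding to the model
#' length happens at the token level).
#'
#' @param sequence Transcript sequence.
#' @param flank Number of nucleotides kept per side (default 4000).
#' @return The concatenated sequence, never longer than `2 * flank`.
#' @export
concat_ends <- function(sequence, flank = 4000L) {
  L <- nchar(sequence)
  if (L <= 2L * flank) return(sequence)
  paste0(substr(sequence, 1L, flank), substr(sequence, L - flank + 1L, L))
}

#' Synthetic multi-label mRNA localization dataset
#'
#' Each transcript receives an independent Bernoulli label per
#' compartment (nucleus, exosome, cytosol, ribosome, membrane, ER); a
#' transcript can carry several labels or none.  Every active
#' compartment plants `n_instances` copies of its own distinct 7-mer
#' zipcode-like element at uniform positions.  Transcripts longer than
#' `2 * flank` are reduced to their first-`flank` + last-`flank`
#' concatenation.
#'
#' @param n Number of transcripts.
#' @param length_range Transcript length range (sampled uniformly).
#' @param prevalence Per-compartment label probability.
#' @param n_instances Planted copies per active compartment.
#' @param flank Nucleotides kept per transcript end (default 4000).
#' @param composition Background base composition.
#' @param seed Integer seed.
#' @return List with `dataset` (data frame `id`, `sequence`, `label`
#'   with comma-separated bits, `split`), `labels` (0/1 matrix),
#'   `motifs` (the six compartment consensus elements).
#' @export
make_localization_dataset <- function(n = 100L,
                                      length_range = c(1000L, 9000L),
                                      prevalence = 0.3, n_instances = 5L,
                                      flank = 4000L,
                                      composition = c(A = 0.25, C = 0.25,
                                                      G = 0.25, U = 0.25),
                                      seed = 1L) {
  compartments <- c("nucleus", "exosome", "cytosol", "ribosome",
                    "membrane", "ER")
  motifs <- c(nucleus = "ACGCGCA", exosome = "UUCGAAU", cytosol = "GAUAUCG",
              ribosome = "CCAUGGC", membrane = "AGGCCUA", ER = "UGCAUGU")
  lens <- with_seed(derive_seed(seed, 1L),
                    sample.int(length_range[2L] - length_range[1L] + 1L, n,
                               replace = TRUE) + length_range[1L] - 1L)
  records <- generate_background(n, lens, composition,
                                 seed = derive_seed(seed, 2L), prefix = "tx")
  labels <- with_seed(derive_seed(seed, 3L),
                      matrix(rbinom(n * 6L, 1L, prevalence), n, 6L,
                             dimnames = list(NULL, compartments)))
  for (j in seq_len(6L)) {
    active <- which(labels[, j] == 1L)
    if (length(active) == 0L) next
    for (rep_i in seq_len(n_instances)) {
      sub <- records[active, , drop = FALSE]
      pl <- plant_motif(sub, unname(motifs[j]), plant_rate = 1.0,
                        seed = derive_seed(seed, 100L + j * 10L + rep_i))
      records$sequence[active] <- pl$records$sequence
    }
  }
  records$sequence <- vapply(records$sequence, concat_ends, "",
                             flank = flank, USE.NAMES = FALSE)
  dataset <- data.frame(
    id = records$id, sequence = records$sequence,
    label = apply(labels, 1L, paste, collapse = ","),
    split = assign_splits(n, derive_seed(seed, 4L)),
    stringsAsFactors = FALSE)
  list(dataset = dataset, labels = labels, motifs = motifs)
}

#' Synthetic pre-training corpus
#'
#' Background sequences with recurring motifs sprinkled in at a given
#' per-sequence rate, so the masked-language-model objective has
#' learnable structure; sequences are then cut into model windows and
#' tokenized.
#'
#' @param n_sequences Corpus size.
#' @param length Sequence length.
#' @param motifs Character vector of recurring elements.
#' @param motif_rate Expected planted motifs per sequence (each motif
#'   planted independently with probability `motif_rate /
#'   length(motifs)`).
#' @param window_nt Model window width in nucleotides.
#' @param vocab A `utr_vocab` used for tokenization.
#' @param max_positions Model length for the tokenized windows.
#' @param composition Background base composition.
#' @param seed Integer seed.
#' @return List with `records`, `windows` (data frame from
#'   [window_sequence()]) and `tokenized` (list of `utr_window`).
#' @export
make_pretrain_corpus <- function(n_sequences = 200L, length = 100L,
                                 motifs = c("UGUAUAU", "AAUAAA", "UUUUUUU"),
                                 motif_rate = 1.5, window_nt = 510L,
                                 vocab = build_vocabulary(3L),
                                 max_positions = 512L,
                                 composition = c(A = 0.25, C = 0.25,
                                                 G = 0.25, U = 0.25),
                                 seed = 1L) {
  records <- generate_background(n_sequences, length, composition,
                                 seed = derive_seed(seed, 1L), prefix = "utr")
  per_motif_rate <- min(1, motif_rate / max(1L, base::length(motifs)))
  for (j in seq_along(motifs)) {
    records <- plant_motif(records, motifs[j], plant_rate = per_motif_rate,
                           seed = derive_seed(seed, 10L + j))$records
  }
  windows <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
    window_sequence(records$sequence[i], records$id[i], window = window_nt)))
  keep <- nchar(windows$sequence) >= vocab$k
  windows <- windows[keep, , drop = FALSE]
  tokenized <- lapply(seq_len(nrow(windows)), function(i)
    encode_window(tokenize(windows$sequence[i], vocab$k), vocab,
                  max_positions = max_positions,
                  source = windows[i, c("seq_id", "start", "end")]))
  list(records = records, windows = windows, tokenized = tokenized)
}
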