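test_that("background generation respects composition and seed", {
  allA <- generate_background(3L, 30L, c(A = 1, C = 0, G = 0, U = 0),
                              seed = 1L)
  expect_true(all(allA$sequence == strrep("A", 30L)))
  b1 <- generate_background(5L, 40L, seed = 2L)
  b2 <- generate_background(5L, 40L, seed = 2L)
  expect_identical(b1, b2)
  # empirical base frequencies close to spec at n*L = 1e5
  big <- generate_background(100L, 1000L,
                             c(A = 0.4, C = 0.2, G = 0.2, U = 0.2),
                             seed = 3L)
  chars <- strsplit(paste(big$sequence, collapse = ""), "")[[1L]]
  freq <- table(chars) / length(chars)
  expect_equal(unname(freq[c("A", "C", "G", "U")]),
               c(0.4, 0.2, 0.2, 0.2), tolerance = 0.02,
               ignore_attr = TRUE)
  expect_error(generate_background(2L, 10L, c(A = 0.5, C = 0.5, G = 0.5,
                                              U = 0.5)), "sum to 1")
})

test_that("motif planting honors the rate and records exact ground truth", {
  recs <- generate_background(40L, 60L, seed = 4L)
  all_planted <- plant_motif(recs, "UGUAUAU", plant_rate = 1.0, seed = 4L)
  expect_equal(nrow(all_planted$truth), 40L)
  for (i in seq_len(40L)) {
    tr <- all_planted$truth[i, ]
    seq_i <- all_planted$records$sequence[
      all_planted$records$id == tr$seq_id]
    expect_equal(substr(seq_i, tr$start + 1L, tr$end), tr$name)
    expect_equal(tr$name, "UGUAUAU")
  }
  none <- plant_motif(recs, "UGUAUAU", plant_rate = 0, seed = 4L)
  expect_identical(none$records, recs)
  expect_equal(nrow(none$truth), 0L)
  # IUPAC consensus instances stay within the supported set
  rr <- plant_motif(recs, "RRACH", plant_rate = 1.0, seed = 5L)
  expect_true(all(grepl("^[AG][AG]AC[ACU]$", rr$truth$name)))
})

test_that("PWM-sampled instances are PWM-supported", {
  pwm <- build_pwm(c("AAAAAAA", "AAAAAAC"))
  recs <- generate_background(20L, 30L, seed = 6L)
  pl <- plant_motif(recs, pwm, plant_rate = 1.0, seed = 6L)
  expect_true(all(grepl("^AAAAAA[AC]$", pl$truth$name)))
})

test_that("RBP datasets have the 1:2 ratio, 100-nt windows and clean splits", {
  rbp <- make_rbp_dataset(n_pos = 50L, seed = 7L)
  ds <- rbp$dataset
  expect_equal(sum(ds$label == 1), 50L)
  expect_equal(sum(ds$label == 0), 100L)
  expect_true(all(nchar(ds$sequence) == 100L))
  # 80/20 train+val/test per class, 4:1 train:val
  for (cl in c(0, 1)) {
    tab <- table(ds$split[ds$label == cl])
    n <- sum(tab)
    expect_equal(unname(tab["test"]), round(0.2 * n))
    expect_equal(unname(tab["val"]), round(0.2 * (n - round(0.2 * n))))
  }
  expect_equal(length(intersect(ds$sequence[ds$split == "test"],
                                ds$sequence[ds$split == "train"])), 0L)
  # ground truth intervals point at real motif instances
  expect_true(all(vapply(seq_len(nrow(rbp$truth)), function(i) {
    tr <- rbp$truth[i, ]
    s <- ds$sequence[ds$id == tr$seq_id]
    substr(s, tr$start + 1L, tr$end) == tr$name
  }, FALSE)))
})

test_that("m6A datasets are 41-nt, A-centered and balanced 1:1", {
  m6a <- make_m6a_dataset(n_pos = 40L, seed = 8L)
  ds <- m6a$dataset
  expect_true(all(nchar(ds$sequence) == 41L))
  expect_true(all(substr(ds$sequence, 21L, 21L) == "A"))
  expect_equal(sum(ds$label == 1), sum(ds$label == 0))
  # positives carry an RRACH context with its A at the center
  pos <- ds$sequence[ds$label == 1]
  expect_true(all(grepl("^[AG][AG]AC[ACU]$", substr(pos, 19L, 23L))))
  expect_error(make_m6a_dataset(n_pos = 5L, window_nt = 40L), "odd|%% 2")
})

test_that("localization sequences follow the first/last-4000 rule", {
  expect_equal(concat_ends(strrep("A", 3000L)), strrep("A", 3000L))
  long <- paste0(strrep("A", 4000L), strrep("C", 1000L), strrep("G", 4000L))
  cc <- concat_ends(long)
  expect_equal(nchar(cc), 8000L)
  expect_equal(cc, paste0(strrep("A", 4000L), strrep("G", 4000L)))
  loc <- make_localization_dataset(n = 30L, length_range = c(500L, 9000L),
                                   seed = 9L)
  expect_true(all(nchar(loc$dataset$sequence) <= 8000L))
  expect_equal(dim(loc$labels), c(30L, 6L))
  # multi-label: some transcripts have two or more active compartments
  expect_true(any(rowSums(loc$labels) >= 2L))
  lab_str <- strsplit(loc$dataset$label, ",")
  expect_true(all(lengths(lab_str) == 6L))
})

test_that("pretraining corpora are reproducible and carry recurring motifs", {
  v <- tiny_vocab()
  c1 <- make_pretrain_corpus(n_sequences = 30L, length = 80L,
                             window_nt = 80L, vocab = v,
                             max_positions = 96L, seed = 10L)
  c2 <- make_pretrain_corpus(n_sequences = 30L, length = 80L,
                             window_nt = 80L, vocab = v,
                             max_positions = 96L, seed = 10L)
  expect_identical(c1$records, c2$records)
  expect_length(c1$tokenized, 30L)
  expect_true(all(vapply(c1$tokenized, function(w)
    length(w$ids) == 96L, FALSE)))
  # the default recurring motifs appear at a substantial rate
  hits <- mean(grepl("UGUAUAU|AAUAAA|UUUUUUU", c1$records$sequence))
  expect_gt(hits, 0.5)
})
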