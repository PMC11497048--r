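test_that("high-attention region selection follows the cutoff policy", {
  # constant track: nothing stands out under the adaptive policy
  expect_equal(nrow(high_attention_regions(rep(1, 50))), 0L)
  # a single spike becomes one 7-nt region centered on it
  sp <- rep(0, 50); sp[25] <- 10
  reg <- high_attention_regions(sp)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$end - reg$start, 7L)
  expect_true(reg$start <= 24L && reg$end >= 25L)
  # explicit cutoff 0 on a non-negative track covers the sequence
  set.seed(1)
  tr <- runif(40)
  reg0 <- high_attention_regions(tr, cutoff = 0)
  expect_equal(nrow(reg0), 1L)
  expect_equal(c(reg0$start, reg0$end), c(0L, 40L))
  expect_error(high_attention_regions(numeric(0)), "empty")
})

test_that("candidate counting is presence/absence per sequence", {
  pos <- c("AAAAAAA", "CCAAAAAAACC", "GGGGGGGGGGG")
  regions <- list(
    data.frame(seq_id = "s1", start = 0L, end = 7L),
    data.frame(seq_id = "s2", start = 2L, end = 9L),
    data.frame(seq_id = "s3", start = 0L, end = 0L)[0, ]  # no regions
  )
  cand <- count_candidates(pos, regions, c(pos, "UUUUUUUUU"))
  a7 <- cand[cand$kmer == "AAAAAAA", ]
  expect_equal(a7$fg_count, 2L)  # shared planted 7-mer counts once per seq
  expect_equal(a7$bg_count, 2L)
  expect_false("GGGGGGG" %in% cand$kmer)  # no high-attention region there
  expect_false("UUUUUUU" %in% cand$kmer)  # absent from foreground regions
})

test_that("hypergeometric tail matches exact enumeration", {
  # printed worked example: N=10, K=4, n=5, x=4 -> 6/252
  expect_equal(hypergeom_enrich(4, 5, 4, 10), 6 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_enrich(0, 5, 4, 10), 1)
  expect_equal(hypergeom_enrich(3, 3, 10, 10), 1)  # K = N
  expect_error(hypergeom_enrich(5, 5, 4, 10), "exceed")
  expect_error(hypergeom_enrich(-1, 5, 4, 10), "non-negative")

  # brute force over all C(N, n) draws for small N
  brute_tail <- function(x, n, K, N) {
    draws <- combn(N, n)
    mean(colSums(draws <= K) >= x)  # elements 1..K are the "successes"
  }
  set.seed(4)
  for (rep_i in 1:20) {
    N <- sample(5:12, 1L)
    K <- sample.int(N, 1L)
    n <- sample.int(N, 1L)
    x <- sample(0:min(K, n), 1L)
    expect_equal(hypergeom_enrich(x, n, K, N), brute_tail(x, n, K, N),
                 tolerance = 1e-10)
  }
})

test_that("BH correction matches an independent step-up implementation", {
  # worked example: (0.01..0.05) all adjust to 0.05
  bh <- bh_correct(c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_equal(bh$q, rep(0.05, 5L), tolerance = 1e-12)
  expect_equal(bh_correct(0.03)$q, 0.03)
  expect_equal(bh_correct(c(0.001, 0.8))$q, c(0.002, 0.8))

  step_up <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    i <- m:1L
    q <- pmin(1, cummin(m / i * p[o]))
    q[ro]
  }
  set.seed(7)
  for (rep_i in 1:1000) {
    p <- runif(sample(1:30, 1L))
    expect_equal(bh_correct(p)$q, step_up(p), tolerance = 1e-12)
  }
  expect_true(all(bh_correct(c(1e-6, 0.5))$significant ==
                    c(TRUE, FALSE)))
})

test_that("greedy merging clusters near-identical 7-mers", {
  cand <- data.frame(kmer = c("AAAAAAA", "AAAAAAC", "CCCCCCC"),
                     fg_count = c(10L, 5L, 4L))
  cl <- merge_candidates(cand)
  expect_length(cl, 2L)
  expect_equal(sort(cl[[1L]]$kmer), c("AAAAAAA", "AAAAAAC"))
  expect_equal(cl[[2L]]$kmer, "CCCCCCC")
  # identical k-mers always merge
  same <- merge_candidates(data.frame(kmer = c("AUGCAUG", "AUGCAUG"),
                                      fg_count = c(2L, 1L)))
  expect_length(same, 1L)
  # offset alignment: shifted copies merge with the seed
  sh <- merge_candidates(data.frame(kmer = c("GUGUAUA", "UGUAUAU"),
                                    fg_count = c(5L, 4L)))
  expect_length(sh, 1L)
  expect_length(merge_candidates(cand[0, ]), 0L)
})

test_that("PWMs are column-stochastic with lexicographic-tie consensus", {
  single <- build_pwm("AUGCAUG")
  expect_equal(dim(single$matrix), c(4L, 7L))
  expect_true(all(colSums(single$matrix) == 1))
  expect_true(all(single$matrix %in% c(0, 1)))
  expect_equal(single$consensus, "AUGCAUG")

  two <- build_pwm(c("AAAAAAA", "AAAAAAC"))
  expect_equal(unname(two$matrix["A", 7L]), 0.5)
  expect_equal(unname(two$matrix["C", 7L]), 0.5)
  expect_equal(substr(two$consensus, 7L, 7L), "A")  # tie -> A first
  expect_equal(colSums(two$matrix), rep(1, 7L), tolerance = 1e-9)

  off <- build_pwm(c("GUGUAUA", "UGUAUAU"), offsets = c(0L, 1L))
  expect_equal(ncol(off$matrix), 8L)
  expect_equal(off$consensus, "GUGUAUAU")
})

test_that("MEME minimal format round-trips", {
  pwms <- list(build_pwm(c("AAAAAAA", "AAAAAAC")), build_pwm("UGCAUGU"))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, f)
  lines <- readLines(f)
  expect_equal(length(grep("^MOTIF ", lines)), 2L)
  expect_equal(lines[1L], "MEME version 4")
  back <- read_meme(f)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(unname(back[[i]]$matrix), unname(pwms[[i]]$matrix),
                 tolerance = 1e-6)
    expect_equal(back[[i]]$n_instances, pwms[[i]]$n_instances)
  }
  # empty motif list still yields a valid header-only file
  write_meme(list(), f)
  expect_equal(readLines(f)[1L], "MEME version 4")
  expect_length(read_meme(f), 0L)
})
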