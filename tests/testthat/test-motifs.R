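test_that("PWM estimation applies the pseudocount formula", {
  p0 <- build_pwm(c("CACGTG", "CACGTG"), pseudocount = 0)
  expect_equal(unname(p0$probs["C", 1]), 1)
  p <- build_pwm(c("AA", "CC"), pseudocount = 0.5)
  expect_equal(unname(p$probs["A", 1]), (1 + 0.5) / (2 + 4 * 0.5))  # 0.375
  expect_true(all(p$probs > 0))
  expect_error(build_pwm(c("AA", "AN")), "non-ACGT")
  expect_error(build_pwm(c("AA", "AAA")), "unequal")
  expect_error(build_pwm("AA"), ">= 2")
})

test_that("log-odds scanning scores in bits with both strands", {
  # uniform PWM equal to background: every window scores 0
  unif <- new_pwm(matrix(0.25, 4, 5))
  hits <- scan_pwm(unif, random_seq(50), min_score = 0.1)
  expect_equal(nrow(hits), 0)

  # consensus score equals the hand-summed column maxima
  pwm <- example_pwm("ACGT", p_consensus = 0.97)
  expect_equal(pwm_max_score(pwm), 4 * log2(0.97 / 0.25), tolerance = 1e-12)
  h <- scan_pwm(pwm, "ACGT", min_score = -Inf)
  expect_equal(h$score[h$strand == "+" & h$start == 0], 4 * log2(0.97 / 0.25))

  # N contributes background odds (0 bits)
  hN <- scan_pwm(pwm, "ANGT", min_score = -Inf)
  expect_equal(hN$score[hN$strand == "+" & hN$start == 0],
               3 * log2(0.97 / 0.25))
})

test_that("palindromic hits collapse to the plus strand", {
  pwm <- example_pwm("CACGTG")
  h <- scan_pwm(pwm, "TTCACGTGTT", min_score = 0.9 * pwm_max_score(pwm))
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "+")
  expect_equal(h$start, 2)
})

test_that("scan scores are strand-symmetric on random sequences", {
  set.seed(41)
  pwm <- pwm_second()
  for (i in 1:20) {
    s <- random_seq(60)
    a <- scan_pwm(pwm, s, min_score = -Inf)
    b <- scan_pwm(revcomp_pwm(pwm), revcomp(s), min_score = -Inf)
    expect_equal(sort(a$score), sort(b$score), tolerance = 1e-9)
  }
})

test_that("hit sets are nested under nested score thresholds", {
  set.seed(42)
  pwm <- pwm_gbox()
  s <- splice_seq(random_seq(200), "CACGTG", 90)
  key <- function(h) paste(h$start, h$strand)
  prev <- NULL
  for (ms in c(2, 5, 8, 10)) {
    h <- scan_pwm(pwm, s, min_score = ms)
    if (!is.null(prev)) expect_true(all(key(h) %in% prev))
    prev <- key(h)
  }
})

test_that("best hit near center recovers planted sites within the window", {
  set.seed(43)
  pwm <- pwm_gbox()
  len <- 300L; summit <- 150L
  seq0 <- random_seq(len)
  # planted consensus with midpoint at the summit
  s1 <- splice_seq(seq0, "CACGTG", summit - 3)
  genome <- c(pk = s1)
  pk <- peak_table("pk", 0L, len, name = "pk", summit_offset = summit)
  h <- best_hit_near_center(pwm, pk, genome)
  expect_equal(h$offset, 0)
  expect_equal(h$score, pwm_max_score(pwm))

  # planted site with midpoint 60 bp from the summit, window 50 -> none
  far <- c(pk = splice_seq(random_seq(len), "CACGTG", summit + 60 - 3))
  expect_null(best_hit_near_center(pwm, pk, far, window = 50,
                                   min_score = 0.8 * pwm_max_score(pwm)))

  # two equal-score hits: smaller |offset| wins
  two <- c(pk = splice_seq(splice_seq(seq0, "CACGTG", summit - 10 - 3),
                           "CACGTG", summit + 20 - 3))
  h2 <- best_hit_near_center(pwm, pk, two)
  expect_equal(h2$offset, -10)
})

test_that("best hit is invariant to peak padding beyond the window", {
  set.seed(44)
  pwm <- pwm_gbox()
  s <- splice_seq(random_seq(600), "CACGTG", 300 - 3)
  genome <- c(pk = s)
  narrow <- peak_table("pk", 250L, 350L, name = "pk", summit_offset = 50L)
  wide <- peak_table("pk", 100L, 500L, name = "pk", summit_offset = 200L)
  h1 <- best_hit_near_center(pwm, narrow, genome)
  h2 <- best_hit_near_center(pwm, wide, genome)
  expect_equal(h1$start, h2$start)
  expect_equal(h1$score, h2$score)
})

test_that("motif presence separates planted from background subsets", {
  set.seed(45)
  pwm <- pwm_gbox()
  len <- 200L; summit <- 100L
  mk <- function(n, insert) {
    vapply(seq_len(n), function(i) {
      s <- random_seq(len)
      if (!is.null(insert)) s <- splice_seq(s, insert, summit - 3)
      s
    }, character(1))
  }
  n <- 40
  genome <- c(mk(n, "CACGTG"), mk(n, NULL))
  names(genome) <- sprintf("pk_%02d", seq_len(2 * n))
  pk <- peak_table(names(genome), 0L, len, name = names(genome),
                   summit_offset = summit)
  subsets <- list(planted = pk[1:n, ], background = pk[(n + 1):(2 * n), ])
  res <- motif_presence(subsets, pwm, genome, window = 50)
  expect_equal(res$fraction[res$label == "planted"], 1.0)
  expect_lt(res$fraction[res$label == "background"], 0.2)
  expect_error(motif_presence(list(a = pk[1:2, ], b = pk[2:3, ]), pwm, genome),
               "disjoint")
})

test_that("null motif-presence matches exhaustive 4-mer enumeration", {
  # single scan position per strand: exact per-peak hit probability is the
  # fraction of the 256 4-mers scoring >= threshold on either strand
  pwm <- example_pwm("ACGT", p_consensus = 0.9, name = "m4")
  thr <- 0.8 * pwm_max_score(pwm)
  kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1, paste,
                 collapse = "")
  hit <- vapply(kmers, function(k) {
    h <- scan_pwm(pwm, k, min_score = thr)
    nrow(h) > 0
  }, logical(1))
  q <- mean(hit)
  set.seed(46)
  n <- 3000
  emp <- mean(vapply(seq_len(n), function(i) {
    nrow(scan_pwm(pwm, random_seq(4), min_score = thr)) > 0
  }, logical(1)))
  expect_lt(abs(emp - q), 4 * sqrt(q * (1 - q) / n))
})

test_that("degenerate planted sites score lower than perfect sites", {
  set.seed(47)
  pwm <- pwm_gbox()
  len <- 160L; summit <- 80L
  mutate1 <- function(s) {
    i <- sample(nchar(s), 1)
    bases <- setdiff(c("A", "C", "G", "T"), substr(s, i, i))
    substr(s, i, i) <- sample(bases, 1)
    s
  }
  n <- 50
  perfect <- vapply(seq_len(n), function(i)
    splice_seq(random_seq(len), "CACGTG", summit - 3), character(1))
  degen <- vapply(seq_len(n), function(i)
    splice_seq(random_seq(len), mutate1("CACGTG"), summit - 3), character(1))
  genome <- c(perfect, degen)
  names(genome) <- sprintf("pk_%03d", seq_len(2 * n))
  pk <- peak_table(names(genome), 0L, len, name = names(genome),
                   summit_offset = summit)
  res <- motif_presence(list(B = pk[1:n, ], A = pk[(n + 1):(2 * n), ]),
                        pwm, genome, window = 50,
                        min_score = 0.4 * pwm_max_score(pwm))
  a <- res[res$label == "A", ]; b <- res[res$label == "B", ]
  expect_lt(a$mean_best_score, b$mean_best_score)
  expect_lte(a$fraction, b$fraction)
})

test_that("PWMs round-trip through PFM text", {
  pwm <- build_pwm(c("ACGT", "ACGG", "TCGT"), pseudocount = 0.5, name = "rt")
  f <- withr::local_tempfile(fileext = ".pfm")
  write_pwm(pwm, f)
  back <- read_pwm(f)
  expect_equal(back$probs, pwm$probs, tolerance = 1e-12)
  expect_equal(back$name, "rt")
})
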