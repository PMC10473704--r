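test_that("concentration generator puts the stated mass in the top block", {
  cm <- sim_counts(n_genes = 10, n_cells = 1, total_counts = 1e6,
                   top_fraction = 0.1, mass_in_top = 0.5, seed = 5)
  top_share <- as.numeric(cm$counts[1, 1]) / 1e6
  # binomial tolerance: 4 SE of a Binomial(1e6, 0.5) proportion
  expect_lt(abs(top_share - 0.5), 4 * sqrt(0.25 / 1e6))
  expect_error(sim_counts(10, 1, 100, top_fraction = 0.2, mass_in_top = 0.1),
               "invert")
})

test_that("generators are pure functions of parameters and seed", {
  a <- sim_counts(50, 10, 1000, mass_in_top = 0.4, seed = 9)
  b <- sim_counts(50, 10, 1000, mass_in_top = 0.4, seed = 9)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))

  pa <- pwm_gbox(); pb <- pwm_second()
  g1 <- sim_peak_genome(20, 260, pa, pb, "constrained", offset = 8,
                        jitter_sd = 1, seed = 3)
  g2 <- sim_peak_genome(20, 260, pa, pb, "constrained", offset = 8,
                        jitter_sd = 1, seed = 3)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$sites, g2$sites)

  d <- data.frame(sample = paste0("s", 1:4), group = rep(c("x", "y"), each = 2))
  l1 <- sim_lfq(120, d, enriched = 1:5, missing_rate = 0.2, seed = 4)
  l2 <- sim_lfq(120, d, enriched = 1:5, missing_rate = 0.2, seed = 4)
  expect_identical(l1$log2, l2$log2)
})

test_that("constrained spacing truth has tight planted distances", {
  g <- sim_peak_genome(200, 260, pwm_gbox(), pwm_second(), "constrained",
                       offset = 8, jitter_sd = 1, seed = 7)
  expect_lte(sd(g$distances), 2)
  expect_equal(length(g$distances), 200)
  # planted sites really are in the emitted sequence at the recorded spot
  s <- g$sites[g$sites$factor == "b" & g$sites$strand == "+", ][1, ]
  frag <- substr(g$genome[[s$peak]], s$start + 1, s$start + 6)
  sc <- scan_pwm(pwm_second(), frag, min_score = -Inf)
  expect_gte(max(sc$score[sc$strand == "+"]), 0.5 * pwm_max_score(pwm_second()))
})

test_that("random spacing truth is uniform over the scan window", {
  g <- sim_peak_genome(500, 260, pwm_gbox(), pwm_second(), "random",
                       window = 50, seed = 8)
  expect_gte(min(g$distances), -50 - 1)
  expect_lte(max(g$distances), 50 + 1)
  p <- stats::ks.test(g$distances + runif(500, -0.5, 0.5), "punif",
                      -50.5, 50.5)$p.value
  expect_gt(p, 0.01)
})

test_that("spacing generator validates its geometry", {
  expect_error(sim_peak_genome(5, 40, pwm_gbox(), pwm_second(), "constrained",
                               offset = 8, jitter_sd = 1), "peak_len")
  expect_error(sim_peak_genome(5, 400, pwm_gbox(), pwm_second(), "constrained",
                               offset = 49, jitter_sd = 1), "scan window")
  expect_error(sim_peak_genome(5, 400, pwm_gbox(), pwm_second(), "relaxed",
                               offset = 8, jitter_sd = 1), "relaxed")
})

test_that("occupancy generator separates nucleosomal from free peaks", {
  pk <- peak_table(c("p1", "p2"), 0L, 400L, name = c("p1", "p2"))
  trk <- sim_occupancy(pk, nucleosomal_ids = "p1", amp = 10, seed = 6)
  win <- function(ch) {
    s <- 200
    mean(trk[[ch]][(s - 73):(s + 73) + 1])
  }
  expect_gte(win("p1"), 5 * win("p2"))
  expect_error(sim_occupancy(pk, nucleosomal_ids = "p1", amp = 0), "amp")
})

test_that("noise-only occupancy matches the folded-normal mean", {
  pk <- peak_table("p1", 0L, 50000L, name = "p1")
  trk <- sim_occupancy(pk, nucleosomal_ids = character(), amp = 10, seed = 6)
  sig <- trk$p1
  expected <- (10 / 10) * sqrt(2 / pi)  # sigma * sqrt(2/pi)
  se <- sd(sig) / sqrt(length(sig))
  expect_lt(abs(mean(sig) - expected), 4 * se)
})

test_that("LFQ generator plants the effect and low-abundance missingness", {
  d <- data.frame(sample = paste0("s", 1:6), group = rep(c("bait", "wt"), each = 3))
  lf <- sim_lfq(400, d, enriched = 1:40, effect = 3, missing_rate = 0,
                bait_group = "bait", seed = 10)
  diffs <- rowMeans(lf$log2[1:40, 1:3]) - rowMeans(lf$log2[1:40, 4:6])
  expect_equal(mean(diffs), 3, tolerance = 4 * sd(diffs) / sqrt(40))

  lf2 <- sim_lfq(400, d, enriched = integer(), missing_rate = 0.3, seed = 11)
  frac <- mean(is.na(lf2$log2))
  expect_lt(abs(frac - 0.3 * 0.25), 4 * sqrt(0.075 * 0.925 / 2400))
  # missingness is biased to low abundance: missing rows sit below the median
  expect_error(sim_lfq(10, data.frame(sample = "s1", group = "g")), "replicates")
})

test_that("planted-target counts make the TF exclusive to the positive cells", {
  tg <- sim_target_counts(n_genes = 100, n_cells_in = 20, n_cells_out = 20,
                          n_planted = 10, seed = 12)
  pos <- tf_positive_cells(tg$counts, tg$tf_gene)
  expect_true(all(grepl("cell_00(0[1-9]|1[0-9]|20)$", pos)))
  expect_equal(length(tg$planted), 10)
})
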