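test_that("peak annotation honours the inclusive 3 kb TSS cutoff", {
  gn <- gene_table("g1", "c1", 10000L, 12000L, "+")  # TSS at 10000
  near <- peak_table("c1", 7000L, 7002L, summit_offset = 1L)  # summit 7001
  ann <- annotate_peaks(near, gn)
  expect_equal(ann$gene_id, "g1")
  expect_equal(ann$distance_to_tss, -2999)
  expect_equal(ann$category, "upstream")

  boundary <- peak_table("c1", 6999L, 7001L, summit_offset = 1L)  # summit 7000
  expect_equal(annotate_peaks(boundary, gn)$distance_to_tss, -3000)
  expect_equal(annotate_peaks(boundary, gn)$category, "upstream")

  far <- peak_table("c1", 6998L, 7000L, summit_offset = 1L)  # summit 6999
  expect_equal(annotate_peaks(far, gn)$category, "unassigned")
  expect_true(is.na(annotate_peaks(far, gn)$gene_id))
})

test_that("gene-body overlap wins and distances are strand-signed", {
  gn <- gene_table(c("g1", "g2"), "c1", c(1000L, 8000L), c(2000L, 9000L),
                   c("+", "-"))
  inside <- peak_table("c1", 1500L, 1600L, summit_offset = 50L)
  ann <- annotate_peaks(inside, gn)
  expect_equal(ann$category, "overlapping")
  expect_equal(ann$distance_to_tss, 1550 - 1000)
  # minus-strand gene: TSS at end-1, upstream = larger coordinates
  up_minus <- peak_table("c1", 9500L, 9502L, summit_offset = 1L)  # summit 9501
  ann2 <- annotate_peaks(up_minus, gn)
  expect_equal(ann2$gene_id, "g2")
  expect_equal(ann2$distance_to_tss, -(9501 - 8999))
  expect_equal(ann2$category, "upstream")
})

test_that("annotation is invariant to peak input order and ties are stable", {
  gn <- gene_table(c("gB", "gA"), "c1", c(5000L, 5000L), c(5100L, 5100L), "+")
  pk <- peak_table("c1", c(4000L, 4500L), c(4004L, 4504L))
  a1 <- annotate_peaks(pk, gn)
  a2 <- annotate_peaks(pk[2:1, ], gn)
  expect_equal(a1[order(a1$peak_id), ], a2[order(a2$peak_id), ],
               ignore_attr = TRUE)
  expect_equal(unique(a1$gene_id), "gA")  # lexicographic tie-break
})

test_that("self-overlap gives the maximal observed count and minimal p", {
  a <- peak_table(rep("c1", 20), seq(0, 19000, 1000), seq(200, 19200, 1000))
  ot <- overlap_permutation_test(a, a, c(c1 = 50000L), n_perm = 200, seed = 1)
  expect_equal(ot$observed, 20)
  expect_lte(ot$p_empirical, 2 / 201)
})

test_that("null overlap frequency matches the exact placement probability", {
  # 1 bp peak re-placed on a 100 bp chromosome vs a fixed 1 bp interval:
  # exact hit probability 1/100
  a <- peak_table("c1", 10L, 11L)
  b <- peak_table("c1", 42L, 43L)
  ot <- overlap_permutation_test(a, b, c(c1 = 100L), n_perm = 4000, seed = 2)
  se <- sqrt(0.01 * 0.99 / 4000)
  expect_lt(abs(ot$null_mean - 0.01), 3 * se)
})

test_that("overlap z grows along a monotone spike-in series", {
  set.seed(33)
  bs <- sample(0:49000, 100) * 2
  b <- peak_table(rep("c1", 100), bs, bs + 100)
  zs <- vapply(c(0, 10, 20), function(k) {
    starts <- sort(c(b$start[seq_len(k)], sample(0:99900, 20 - k)))
    a <- peak_table(rep("c1", 20), starts, starts + 80)
    overlap_permutation_test(a, b, c(c1 = 100000L), n_perm = 300, seed = 4)$z
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("peaks longer than their chromosome are rejected", {
  a <- peak_table("c1", 0L, 500L)
  expect_error(overlap_permutation_test(a, a, c(c1 = 400L), n_perm = 100),
               "longer than its chromosome")
  expect_error(overlap_permutation_test(a, a, c(c1 = 1000L), n_perm = 10),
               "n_perm")
})

test_that("nucleosome classification thresholds summit-window occupancy", {
  pk <- peak_table(c("p1", "p2"), 0L, 400L, name = c("p1", "p2"))
  zero <- list(p1 = numeric(400), p2 = numeric(400))
  nc <- classify_nucleosomal(pk, zero, threshold = 1)
  expect_true(all(nc$label == "non_nucleosomal"))

  # exact plateau, no noise: planted labels recovered exactly
  plat <- list(p1 = numeric(400), p2 = numeric(400))
  plat$p1[(200 - 73):(200 + 73) + 1] <- 10
  nc2 <- classify_nucleosomal(pk, plat, threshold = 5)
  expect_equal(nc2$label, c("nucleosomal", "non_nucleosomal"))
  expect_equal(nc2$mean_occupancy[1], 10)

  # boundary: mean exactly equal to the threshold is nucleosomal
  const <- list(p1 = rep(5, 400), p2 = rep(4.999, 400))
  nc3 <- classify_nucleosomal(pk, const, threshold = 5)
  expect_equal(nc3$label, c("nucleosomal", "non_nucleosomal"))
})

test_that("classification warns and truncates at chromosome ends", {
  pk <- peak_table("p1", 0L, 60L, name = "p1", summit_offset = 10L)
  trk <- list(p1 = rep(2, 60))
  expect_warning(nc <- classify_nucleosomal(pk, trk, threshold = 1), "truncated")
  expect_equal(nc$mean_occupancy, 2)
})

test_that("metaprofiles bin bodies, flanks and log ratios correctly", {
  trk <- list(c1 = rep(3, 500))
  anch <- data.frame(chrom = "c1", start = c(100, 300), end = c(200, 400))
  mp <- metaprofile(trk, NULL, anch, flank = 50, n_bins = 5)
  expect_true(all(mp$value == 3))
  expect_equal(table(mp$region)[["body"]], 5)

  # numerator == denominator -> all-zero log ratio
  mp2 <- metaprofile(trk, trk, anch, flank = 50, n_bins = 5)
  expect_true(all(mp2$value == 0))

  # unit impulse at the anchor midpoint lands in the central body bin
  imp <- list(c1 = numeric(500)); imp$c1[150] <- 100  # midpoint of [100,200)
  mp3 <- metaprofile(imp, NULL, data.frame(chrom = "c1", start = 100, end = 200),
                     flank = 0, n_bins = 11)
  expect_equal(which.max(mp3$value), 6)

  # minus-strand anchors are reversed before averaging
  ramp <- list(c1 = seq_len(500))
  a_plus <- data.frame(chrom = "c1", start = 100, end = 200, strand = "+")
  a_minus <- data.frame(chrom = "c1", start = 100, end = 200, strand = "-")
  expect_equal(metaprofile(ramp, NULL, a_minus, n_bins = 4)$value,
               rev(metaprofile(ramp, NULL, a_plus, n_bins = 4)$value))
})

test_that("anchors shorter than the bin count are interpolated", {
  trk <- list(c1 = c(1, 2, 3, 4, 5))
  mp <- metaprofile(trk, NULL, data.frame(chrom = "c1", start = 0, end = 3),
                    n_bins = 6)
  expect_equal(length(mp$value), 6)
  expect_equal(mp$value[1], 1)
  expect_equal(mp$value[6], 3)
})
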