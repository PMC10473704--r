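test_that("imputation draws from the downshifted normal and is deterministic", {
  set.seed(81)
  mat <- matrix(rnorm(600 * 6, 25, 2), 600, 6,
                dimnames = list(sprintf("p%03d", 1:600), sprintf("s%d", 1:6)))
  complete <- impute_missing(mat)
  expect_identical(complete, mat)  # nothing missing -> unchanged

  miss <- mat
  miss[sample(length(miss), 800)] <- NA
  mu <- mean(miss, na.rm = TRUE); sg <- sd(miss, na.rm = TRUE)
  i1 <- impute_missing(miss, seed = 5)
  i2 <- impute_missing(miss, seed = 5)
  expect_identical(i1, i2)
  expect_identical(i1[!is.na(miss)], miss[!is.na(miss)])
  imputed <- i1[is.na(miss)]
  expect_lt(abs(mean(imputed) - (mu - 1.8 * sg)), 3 * 0.3 * sg / sqrt(800))
  expect_equal(sd(imputed), 0.3 * sg, tolerance = 0.1)
  # with the nominal model these are ~ 25 - 3.6 and 0.6
  expect_equal(mean(imputed), 25 - 3.6, tolerance = 0.2)

  allna <- matrix(NA_real_, 10, 10)
  expect_error(impute_missing(allna), "all-missing")
})

test_that("bait normalization zeroes the bait and cancels column shifts", {
  mat <- matrix(c(10, 12, 20, 21, 30, 33), 3, 2, byrow = TRUE,
                dimnames = list(c("bait", "p1", "p2"), c("s1", "s2")))
  norm <- normalize_to_bait(mat, "bait")
  expect_equal(unname(norm["bait", ]), c(0, 0))
  # hand-computed entrywise subtraction
  expect_equal(unname(norm["p1", ]), c(20 - 10, 21 - 12))
  expect_equal(unname(norm["p2", ]), c(30 - 10, 33 - 12))
  # adding a constant to one sample's column is cancelled
  shifted <- mat; shifted[, 2] <- shifted[, 2] + 5
  expect_equal(normalize_to_bait(shifted, "bait"), norm)
  mat["bait", 2] <- NA
  expect_error(normalize_to_bait(mat, "bait"), "s2")
})

test_that("moderated t collapses to Student's t at s0 = 0", {
  r <- moderated_t(c(3, 4, 5), c(1, 2, 3), s0 = 0)
  expect_equal(r$t_mod, brute_pooled_t(c(3, 4, 5), c(1, 2, 3)), tolerance = 1e-12)
  expect_equal(r$t_mod, 2.449489743, tolerance = 1e-9)  # frozen textbook value
  expect_equal(r$diff, 2)
  # identical groups
  z <- moderated_t(c(1, 2, 3), c(1, 2, 3), s0 = 0.5)
  expect_equal(z$diff, 0); expect_equal(z$t_mod, 0)
  # s0 strictly shrinks |t|
  r5 <- moderated_t(c(3, 4, 5), c(1, 2, 3), s0 = 0.5)
  expect_lt(abs(r5$t_mod), abs(r$t_mod))
  expect_error(moderated_t(c(1, 1), c(1, 1), s0 = 0), "zero variance")
  expect_error(moderated_t(1, c(1, 2)), ">= 2")
})

test_that("permutation FDR matches the explicit-enumeration oracle", {
  set.seed(82)
  mat <- matrix(rnorm(20 * 6, 25, 1), 20, 6,
                dimnames = list(sprintf("p%02d", 1:20), sprintf("s%d", 1:6)))
  mat[1:4, 1:3] <- mat[1:4, 1:3] + 4
  got <- permutation_fdr(mat, 1:3, 4:6, s0 = 0.5, fdr = 0.05, n_perm = 250)
  oracle <- brute_perm_fdr(mat, 1:3, 4:6, s0 = 0.5, fdr = 0.05)
  expect_true(attr(got, "exhaustive"))
  expect_equal(abs(got$t_mod), unname(oracle$abs_t), tolerance = 1e-12)
  expect_equal(got$fdr_est, unname(oracle$q), tolerance = 1e-9)
  expect_equal(got$significant, unname(oracle$significant))
})

test_that("exhaustive permutations are seed-free", {
  set.seed(83)
  mat <- matrix(rnorm(50 * 6, 25, 1), 50, 6)
  mat[1:5, 1:3] <- mat[1:5, 1:3] + 3
  a <- permutation_fdr(mat, 1:3, 4:6, n_perm = 250, seed = 1)
  b <- permutation_fdr(mat, 1:3, 4:6, n_perm = 250, seed = 999)
  expect_identical(a$significant, b$significant)
  expect_identical(a$fdr_est, b$fdr_est)
})

test_that("significant sets shrink as s0 rises or the FDR target falls", {
  set.seed(84)
  d <- data.frame(sample = sprintf("s%d", 1:6), group = rep(c("b", "w"), each = 3))
  lf <- sim_lfq(300, d, enriched = 1:30, effect = 2, seed = 85)
  sig <- function(s0, fdr) {
    r <- permutation_fdr(lf$log2, 1:3, 4:6, s0 = s0, fdr = fdr)
    r$protein[r$significant]
  }
  base <- sig(0.5, 0.05)
  expect_true(all(sig(1.5, 0.05) %in% base))
  expect_true(all(sig(0.5, 0.01) %in% base))
})

test_that("the candidate filter applies every gate", {
  res <- list(
    vs_wt = data.frame(protein = c("a", "b", "c", "d"),
                       diff = c(3, 3, 3, -2),
                       significant = c(TRUE, TRUE, TRUE, TRUE)),
    vs_untreated = data.frame(protein = c("a", "b", "c", "d"),
                              diff = c(2, 2, 2, 2),
                              significant = c(TRUE, FALSE, TRUE, TRUE))
  )
  detected <- matrix(TRUE, 4, 3, dimnames = list(c("a", "b", "c", "d"),
                                                 c("s1", "s2", "s3")))
  detected["c", ] <- c(TRUE, FALSE, FALSE)  # only 1 bait replicate
  cand <- candidate_filter(res, detected, c("s1", "s2", "s3"),
                           min_reps = 2, msms = c("a", "b", "c"))
  expect_equal(cand, "a")
  # b fails the untreated-control contrast, c the replicate gate,
  # d the enrichment direction
  expect_error(candidate_filter(list(), detected, "s1"), "no contrasts")
  expect_error(candidate_filter(list(x = data.frame(protein = "a")),
                                detected, "s1"), "missing contrast result")
})
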