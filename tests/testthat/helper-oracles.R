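# Independent oracles used across test files. These deliberately use naive,
# direct formulations (double loops, explicit enumeration) so they share no
# code path with the package implementations they check.

# brute-force two-sample KS statistic: ECDF difference at every pooled point
brute_ks_D <- function(x, y) {
  pool <- sort(unique(c(x, y)))
  max(abs(vapply(pool, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# textbook pooled two-sample t statistic
brute_pooled_t <- function(a, b) {
  s2p <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(s2p * (1 / length(a) + 1 / length(b)))
}

# explicit-enumeration permutation FDR oracle for a two-group design:
# every distinct assignment of columns to group A (minus the observed one
# and its mirror), naive per-protein counting, direct monotonisation
brute_perm_fdr <- function(mat, ia, ib, s0, fdr) {
  n <- length(ia) + length(ib)
  pool <- c(ia, ib)
  tmod <- function(cols_a) {
    cols_b <- setdiff(pool, cols_a)
    apply(mat, 1, function(r) {
      a <- r[cols_a]; b <- r[cols_b]
      s2p <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
        (length(a) + length(b) - 2)
      (mean(a) - mean(b)) / (sqrt(s2p * (1 / length(a) + 1 / length(b))) + s0)
    })
  }
  obs <- abs(tmod(ia))
  splits <- combn(pool, length(ia), simplify = FALSE)
  splits <- Filter(function(s) !setequal(s, ia) && !setequal(s, ib), splits)
  null_pool <- unlist(lapply(splits, function(s) abs(tmod(s))))
  raw <- vapply(obs, function(ti) {
    min(1, ((1 + sum(null_pool >= ti)) / length(splits)) / sum(obs >= ti))
  }, numeric(1))
  q <- vapply(obs, function(ti) min(raw[obs <= ti]), numeric(1))
  list(abs_t = obs, q = q, significant = q <= fdr)
}

# shared PWM fixtures
pwm_gbox <- function() example_pwm("CACGTG", name = "gbox")
pwm_second <- function() example_pwm("TTGACC", name = "second")

# insert a subsequence into a string at a 0-based start
splice_seq <- function(seq, site, start0) {
  paste0(substr(seq, 1, start0), site,
         substr(seq, start0 + nchar(site) + 1, nchar(seq)))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
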