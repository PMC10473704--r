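#' Impute missing log2 LFQ values from a downshifted normal
#'
#' Missing values are drawn from `Normal(mu - downshift * sigma,
#' (width * sigma)^2)` where `mu` and `sigma` are the mean and SD of all
#' observed values of the whole matrix (total-matrix mode). This mimics the
#' conventional proteomics treatment of missing-not-at-random dropout at low
#' abundance: imputed values land in the lower tail of the observed
#' distribution. Observed entries are untouched.
#'
#' @param mat Proteins x samples matrix of log2 intensities, NA = missing.
#' @param width Imputation SD as a fraction of the matrix SD (default 0.3).
#' @param downshift Shift below the matrix mean in SDs (default 1.8).
#' @param seed Integer seed.
#' @return The matrix with missing entries imputed.
#' @export
impute_missing <- function(mat, width = 0.3, downshift = 1.8, seed = 1) {
  miss <- is.na(mat)
  if (!any(miss)) return(mat)
  obs <- mat[!miss]
  if (!length(obs)) stop("all-missing matrix: cannot estimate moments")
  if (length(obs) < 100) stop("need >= 100 observed values to estimate matrix moments")
  mu <- mean(obs); sigma <- stats::sd(obs)
  mat[miss] <- with_seed(seed, stats::rnorm(sum(miss), mu - downshift * sigma,
                                            width * sigma))
  mat
}

#' Normalize each sample to the bait protein
#'
#' Subtracts the bait's log2 value from every protein in the same sample
#' (the bait row becomes 0 everywhere). Used to compensate for unequal bait
#' expression between lines before cross-line comparisons.
#'
#' @param mat Proteins x samples log2 matrix with the bait as a row.
#' @param bait_protein Row name of the bait; must be observed in every
#'   sample.
#' @return The bait-normalised matrix.
#' @export
normalize_to_bait <- function(mat, bait_protein) {
  if (!bait_protein %in% rownames(mat)) stop("bait not in matrix: ", bait_protein)
  bait <- mat[bait_protein, ]
  missing <- colnames(mat)[is.na(bait)]
  if (length(missing)) stop("bait missing in sample(s): ", paste(missing, collapse = ", "))
  sweep(mat, 2, bait, "-")
}

#' S0-moderated two-sample t statistic
#'
#' `t_mod = (mean_a - mean_b) / (se_pooled + s0)` where `se_pooled` is the
#' pooled-variance two-sample standard error. The fudge factor `s0` inflates
#' the denominator so that large fold changes with tiny variances do not
#' dominate the ranking (the SAM formulation); `s0 = 0` recovers Student's
#' pooled t exactly.
#'
#' @param group_a,group_b Numeric vectors, each >= 2 values.
#' @param s0 Denominator fudge factor in log2 units (default 0.5).
#' @return List: `diff` (mean_a - mean_b), `t_mod`, `se`.
#' @export
moderated_t <- function(group_a, group_b, s0 = 0.5) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values")
  diff <- mean(group_a) - mean(group_b)
  s2p <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  se <- sqrt(s2p * (1 / na + 1 / nb))
  if (se + s0 == 0) stop("zero variance in both groups with s0 = 0: t undefined")
  list(diff = diff, t_mod = diff / (se + s0), se = se)
}

# row-wise moderated t over a complete matrix
mod_t_matrix <- function(mat, ia, ib, s0) {
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(mat[, ia, drop = FALSE])
  mb <- rowMeans(mat[, ib, drop = FALSE])
  va <- rowSums((mat[, ia, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((mat[, ib, drop = FALSE] - mb)^2) / (nb - 1)
  s2p <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(s2p * (1 / na + 1 / nb))
  d <- ma - mb
  list(diff = d, t_mod = d / (se + s0))
}

# distinct group-A index sets over pooled columns, excluding the observed
# assignment and its mirror (both reproduce the observed |t| exactly)
null_assignments <- function(n_pool, ia_pos, ib_pos, n_perm, seed) {
  na <- length(ia_pos)
  total <- choose(n_pool, na)
  all_sets <- utils::combn(n_pool, na, simplify = FALSE)
  is_obs <- vapply(all_sets, function(s) setequal(s, ia_pos) || setequal(s, ib_pos),
                   logical(1))
  null_sets <- all_sets[!is_obs]
  if (length(null_sets) <= n_perm) {
    list(sets = null_sets, exhaustive = TRUE)
  } else {
    idx <- with_seed(seed, sample.int(length(null_sets), n_perm))
    list(sets = null_sets[idx], exhaustive = FALSE)
  }
}

#' Permutation-based FDR for a two-group contrast
#'
#' Computes the observed moderated |t| per protein, builds a matrix-wide
#' null from random group-label permutations (all distinct assignments when
#' the design admits no more than `n_perm`, otherwise a seeded sample;
#' the observed assignment and its mirror are excluded from the null), and
#' estimates for each |t| threshold the plug-in FDR
#' `(1 + total null count of |t| >= c) / n_perm` / `observed count of
#' |t| >= c`. The add-one numerator is the standard guard against
#' zero-null-count anti-conservatism in permutation estimates. Estimates are
#' monotonised (running minimum over decreasing |t|, q-value style) so the
#' significant set is a |t|-threshold set.
#'
#' @param mat Complete (imputed) proteins x samples log2 matrix.
#' @param cols_a,cols_b Column names or indices of the two groups (>= 2
#'   each).
#' @param s0 Moderation constant (default 0.5).
#' @param fdr Target FDR (default 0.05).
#' @param n_perm Maximum number of permutations (default 250).
#' @param seed Integer seed (unused when permutations are exhaustive).
#' @return data.frame: `protein`, `diff`, `t_mod`, `fdr_est`, `significant`;
#'   attribute `n_perm_used` and `exhaustive`.
#' @export
permutation_fdr <- function(mat, cols_a, cols_b, s0 = 0.5, fdr = 0.05,
                            n_perm = 250, seed = 1) {
  if (anyNA(mat)) stop("matrix contains missing values; impute first")
  ia <- if (is.character(cols_a)) match(cols_a, colnames(mat)) else cols_a
  ib <- if (is.character(cols_b)) match(cols_b, colnames(mat)) else cols_b
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample column")
  if (length(ia) < 2 || length(ib) < 2) stop("each group needs >= 2 samples")
  pool <- c(ia, ib)
  obs <- mod_t_matrix(mat, ia, ib, s0)
  abs_t <- abs(obs$t_mod)

  perms <- null_assignments(length(pool), seq_along(ia),
                            length(ia) + seq_along(ib), n_perm, seed)
  null_abs <- unlist(lapply(perms$sets, function(s) {
    abs(mod_t_matrix(mat, pool[s], pool[-s], s0)$t_mod)
  }))
  n_used <- length(perms$sets)

  null_sorted <- sort(null_abs)
  ord <- order(abs_t, decreasing = TRUE)
  thr <- abs_t[ord]
  # count of observed |t| >= threshold, tie-aware
  n_obs_ge <- vapply(thr, function(c) sum(abs_t >= c - 1e-12), numeric(1))
  n_null_ge <- length(null_sorted) -
    findInterval(thr - 1e-12, null_sorted)
  raw <- pmin(1, ((1 + n_null_ge) / n_used) / pmax(1, n_obs_ge))
  q_sorted <- rev(cummin(rev(raw)))
  fdr_est <- numeric(length(abs_t))
  fdr_est[ord] <- q_sorted

  out <- data.frame(
    protein = rownames(mat) %||% sprintf("prot_%d", seq_along(abs_t)),
    diff = obs$diff, t_mod = obs$t_mod, fdr_est = fdr_est,
    significant = fdr_est <= fdr, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_perm_used") <- n_used
  attr(out, "exhaustive") <- perms$exhaustive
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-control high-confidence candidate filter
#'
#' A protein is a high-confidence candidate when it is significantly
#' enriched in every configured contrast (consecutive pairwise comparisons
#' against all controls), was detected (pre-imputation) in at least
#' `min_reps` replicates of the bait + biotin condition, and was identified
#' by MS/MS.
#'
#' @param results_by_contrast Named list of [permutation_fdr()] outputs.
#' @param detected Logical proteins x samples matrix of pre-imputation
#'   detection.
#' @param bait_samples Column names of the bait + biotin replicates.
#' @param min_reps Minimum detected replicates among `bait_samples`
#'   (default 2).
#' @param msms Character vector of MS/MS-identified proteins (NULL = no
#'   MS/MS gate).
#' @return Character vector of candidate protein ids.
#' @export
candidate_filter <- function(results_by_contrast, detected, bait_samples,
                             min_reps = 2L, msms = NULL) {
  if (!length(results_by_contrast)) stop("no contrasts configured")
  ok <- vapply(results_by_contrast, function(r) {
    all(c("protein", "significant", "diff") %in% names(r))
  }, logical(1))
  if (!all(ok)) stop("missing contrast result columns in: ",
                     paste(names(results_by_contrast)[!ok], collapse = ", "))
  sig_sets <- lapply(results_by_contrast, function(r) {
    r$protein[r$significant & r$diff > 0]
  })
  cand <- Reduce(intersect, sig_sets)
  miss_cols <- setdiff(bait_samples, colnames(detected))
  if (length(miss_cols)) stop("unknown bait samples: ", paste(miss_cols, collapse = ", "))
  n_det <- rowSums(detected[, bait_samples, drop = FALSE])
  cand <- intersect(cand, rownames(detected)[n_det >= min_reps])
  if (!is.null(msms)) cand <- intersect(cand, msms)
  sort(cand)
}
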