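#' Per-cell Shannon transcriptional entropy
#'
#' Computes \eqn{S = -\sum_i p_i \ln p_i} with \eqn{p_i = c_i / \sum_j c_j},
#' the probability of expressing gene i in the cell, summing over genes with
#' positive counts (the 0 log 0 terms vanish). Natural logarithm; use
#' `log_base` to convert for display. No pseudocount and no normalisation are
#' applied: raw counts define the probabilities. Under strong regulatory
#' constraint expression concentrates on few genes and S drops; a uniform
#' profile maximises S at ln(genes expressed).
#'
#' @param x Non-negative integer count vector for one cell.
#' @param log_base Base of the logarithm for the returned value (default e,
#'   i.e. nats).
#' @return Entropy of the cell's expression distribution.
#' @export
#' @examples
#' cell_entropy(c(1, 1, 1, 1))  # ln 4
#' cell_entropy(c(7, 0, 0))     # 0
cell_entropy <- function(x, log_base = exp(1)) {
  if (any(x < 0)) stop("negative counts")
  tot <- sum(x)
  if (tot == 0) stop("all-zero count vector: entropy undefined")
  p <- x[x > 0] / tot
  -sum(p * log(p)) / log(log_base)
}

#' Number of genes expressed in a cell
#'
#' @param x Count vector.
#' @param min_count Minimum raw count for a gene to be called expressed
#'   (>= 1).
#' @return Integer count of genes with `x >= min_count`.
#' @export
genes_expressed <- function(x, min_count = 1L) {
  if (min_count < 1) stop("min_count must be >= 1")
  sum(x >= min_count)
}

#' Per-cell entropy and expressed-gene statistics, grouped by cluster
#'
#' @param m An `sc_counts` object (see [sc_counts()]); every cell must carry a
#'   cluster label. All-zero cells are not admitted.
#' @return List with `cells` (one row per cell: `cell_id`, `cluster`,
#'   `entropy_nats`, `n_expressed`, `total_counts`) and `summary` (per
#'   cluster: n, median and quartiles of both statistics).
#' @export
entropy_by_cluster <- function(m) {
  counts <- m$counts
  tot <- Matrix::rowSums(counts)
  if (any(tot == 0)) stop("all-zero cell(s) in matrix: entropy undefined")
  # column-compressed over genes: iterate cells via the transpose
  tc <- Matrix::t(counts)  # genes x cells, dgCMatrix
  S <- numeric(ncol(tc)); nexp <- integer(ncol(tc))
  ptr <- tc@p
  for (j in seq_len(ncol(tc))) {
    idx <- if (ptr[j + 1] > ptr[j]) (ptr[j] + 1L):ptr[j + 1] else integer()
    v <- tc@x[idx]
    v <- v[v > 0]
    p <- v / tot[j]
    S[j] <- -sum(p * log(p))
    nexp[j] <- length(v)
  }
  cells <- data.frame(
    cell_id = m$cell_ids,
    cluster = unname(m$cluster[m$cell_ids]),
    entropy_nats = S, n_expressed = nexp,
    total_counts = as.integer(tot),
    stringsAsFactors = FALSE
  )
  present <- unique(cells$cluster)
  empties <- setdiff(unique(m$cluster), present)
  if (length(empties)) warning("empty cluster(s) omitted: ", paste(empties, collapse = ", "))
  qs <- function(v) stats::quantile(v, c(.25, .5, .75), names = FALSE)
  summary <- do.call(rbind, lapply(split(cells, cells$cluster), function(d) {
    e <- qs(d$entropy_nats); g <- qs(d$n_expressed)
    data.frame(cluster = d$cluster[1], n = nrow(d),
               entropy_q1 = e[1], entropy_median = e[2], entropy_q3 = e[3],
               n_expressed_q1 = g[1], n_expressed_median = g[2],
               n_expressed_q3 = g[3], stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(cells = cells, summary = summary)
}

#' Closed-form entropy of a two-level expression model
#'
#' For G genes of which k = ceiling(top_fraction * G) share a fraction m of
#' the transcript mass uniformly and the remaining G - k genes share 1 - m
#' uniformly, the population entropy is
#' \deqn{S^* = -[m \ln(m/k) + (1-m) \ln((1-m)/(G-k))].}
#' With `mass_in_top = NULL` (homogeneous model) this is ln G. This is the
#' infinite-depth limit; see [expected_plugin_entropy()] for the expectation
#' of the plug-in estimator at finite sequencing depth.
#'
#' @param n_genes G.
#' @param top_fraction Fraction of genes in the concentrated block.
#' @param mass_in_top Fraction m of transcripts carried by the block, or NULL
#'   for the homogeneous model.
#' @return Entropy in nats.
#' @export
two_level_entropy <- function(n_genes, top_fraction = 0.1, mass_in_top = NULL) {
  if (is.null(mass_in_top)) return(log(n_genes))
  k <- ceiling(top_fraction * n_genes)
  m <- mass_in_top
  if (k >= n_genes) stop("top block covers all genes")
  -(m * log(m / k) + (1 - m) * log((1 - m) / (n_genes - k)))
}

# probability vector of the two-level model
two_level_probs <- function(n_genes, top_fraction = 0.1, mass_in_top = NULL) {
  if (is.null(mass_in_top)) return(rep(1 / n_genes, n_genes))
  k <- ceiling(top_fraction * n_genes)
  if (mass_in_top < top_fraction) {
    stop("mass_in_top < top_fraction would invert the concentration")
  }
  c(rep(mass_in_top / k, k), rep((1 - mass_in_top) / (n_genes - k), n_genes - k))
}

#' Exact expectation of the plug-in entropy at finite depth
#'
#' The plug-in (maximum-likelihood) entropy of a multinomial sample of N
#' counts is biased below the population entropy. Its expectation has the
#' exact form \eqn{E[\hat S] = \ln N - (1/N) \sum_i E[c_i \log c_i]} with
#' \eqn{c_i \sim Binomial(N, p_i)} (multinomial marginals), which this
#' function evaluates by truncated binomial sums over the distinct
#' probability values. Used as the analytic oracle for simulated mean
#' entropies.
#'
#' @param p Probability vector (or the distinct values via `p`/`mult`).
#' @param n_counts Total counts N per cell.
#' @return Expected plug-in entropy in nats.
#' @export
expected_plugin_entropy <- function(p, n_counts) {
  stopifnot(abs(sum(p) - 1) < 1e-8, n_counts >= 1)
  vals <- unique(p)
  N <- as.integer(n_counts)
  total <- 0
  for (pv in vals) {
    mult <- sum(p == pv)
    lo <- max(1L, stats::qbinom(1e-14, N, pv))
    hi <- stats::qbinom(1e-14, N, pv, lower.tail = FALSE)
    cc <- lo:hi
    e_clogc <- sum(stats::dbinom(cc, N, pv) * cc * log(cc))
    total <- total + mult * e_clogc
  }
  log(N) - total / N
}

#' Mean simulated entropy over a concentration-model grid
#'
#' Simulates cell populations from the two-level concentration model (see
#' [sim_counts()]) for every combination of gene number and concentration
#' setting, and reports the mean and standard error of per-cell plug-in
#' entropy. Reproduces the illustration that entropy rises with the number of
#' expressed genes and falls as expression concentrates into the top genes.
#'
#' @param n_genes_grid Integer vector of gene numbers.
#' @param mass_grid List of `mass_in_top` settings (NULL = homogeneous).
#' @param n_cells Cells per grid point.
#' @param total_counts Counts per cell.
#' @param top_fraction Fraction of genes in the concentrated block.
#' @param seed Integer seed.
#' @return data.frame with columns `n_genes`, `mass_in_top` (NA for
#'   homogeneous), `mean_entropy`, `se_entropy`, `expected_entropy` (exact
#'   finite-depth expectation), `limit_entropy` (infinite-depth closed form).
#' @export
entropy_curve <- function(n_genes_grid, mass_grid = list(NULL, 0.4, 0.5),
                          n_cells = 200, total_counts = 10000,
                          top_fraction = 0.1, seed = 1) {
  grid <- expand.grid(gi = seq_along(n_genes_grid), mi = seq_along(mass_grid))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    G <- n_genes_grid[grid$gi[r]]
    m <- mass_grid[[grid$mi[r]]]
    cm <- sim_counts(n_genes = G, n_cells = n_cells,
                     total_counts = total_counts, top_fraction = top_fraction,
                     mass_in_top = m, seed = seed + r)
    S <- entropy_by_cluster(cm)$cells$entropy_nats
    data.frame(
      n_genes = G, mass_in_top = if (is.null(m)) NA_real_ else m,
      mean_entropy = mean(S), se_entropy = stats::sd(S) / sqrt(length(S)),
      expected_entropy = expected_plugin_entropy(
        two_level_probs(G, top_fraction, m), total_counts),
      limit_entropy = two_level_entropy(G, top_fraction, m)
    )
  })
  do.call(rbind, rows)
}
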