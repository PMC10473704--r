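#' Target-calling rule parameters
#'
#' A gene is a TF target when it is expressed in at least
#' `min_expr_fraction` of the TF-expressing cells, up-regulated by at least
#' `min_log2fc` log2 units relative to the out-group, and carries at least
#' one binding site of the TF within `max_peak_gene_dist` bp. All thresholds
#' are inclusive ("at least"). The default fold-change floor 0.223
#' corresponds to a modest ~1.17-fold enrichment.
#'
#' @param min_expr_fraction Minimum expressed fraction among TF-positive
#'   cells (default 0.25).
#' @param min_log2fc Minimum log2 fold change (default 0.223).
#' @param require_bound Require a binding site (default TRUE).
#' @param max_peak_gene_dist Peak-to-gene distance cutoff fed to
#'   [annotate_peaks()] (default 3000).
#' @return List of class `target_rule`.
#' @export
target_rule <- function(min_expr_fraction = 0.25, min_log2fc = 0.223,
                        require_bound = TRUE, max_peak_gene_dist = 3000) {
  stopifnot(min_expr_fraction > 0, min_expr_fraction <= 1, min_log2fc >= 0)
  structure(list(min_expr_fraction = min_expr_fraction,
                 min_log2fc = min_log2fc, require_bound = require_bound,
                 max_peak_gene_dist = max_peak_gene_dist),
            class = "target_rule")
}

#' Cells expressing a transcription factor
#'
#' @param m `sc_counts` object.
#' @param tf_gene Gene id of the TF (must be present).
#' @param min_count Minimum raw count to call a cell TF-positive (default 1).
#' @return Character vector of cell ids.
#' @export
tf_positive_cells <- function(m, tf_gene, min_count = 1L) {
  if (!tf_gene %in% m$gene_ids) stop("tf_gene not in matrix: ", tf_gene)
  v <- m$counts[, tf_gene]
  m$cell_ids[as.numeric(v) >= min_count]
}

#' Per-gene expression fraction and fold change between cell groups
#'
#' `expr_fraction_in` is the fraction of in-group cells with a raw count of
#' at least 1. Fold changes are computed on depth-normalised means
#' (counts per 10k per cell) with a pseudocount:
#' `log2((mean_cpm_in + pc) / (mean_cpm_out + pc))`.
#'
#' @param m `sc_counts` object.
#' @param cells_in,cells_out Disjoint, non-empty cell id sets.
#' @param pseudocount Pseudocount on the normalised means (default 1).
#' @return data.frame: `gene_id`, `expr_fraction_in`, `mean_cpm_in`,
#'   `mean_cpm_out`, `log2fc`.
#' @export
expression_stats <- function(m, cells_in, cells_out, pseudocount = 1) {
  if (!length(cells_in) || !length(cells_out)) stop("empty cell group")
  if (length(intersect(cells_in, cells_out))) stop("cell groups must be disjoint")
  sub <- function(cells) m$counts[match(cells, m$cell_ids), , drop = FALSE]
  ci <- sub(cells_in); co <- sub(cells_out)
  cpm_mean <- function(x) {
    tot <- Matrix::rowSums(x)
    if (any(tot == 0)) stop("all-zero cell in group")
    Matrix::colMeans(x * (1e4 / tot))
  }
  mi <- cpm_mean(ci); mo <- cpm_mean(co)
  data.frame(
    gene_id = m$gene_ids,
    expr_fraction_in = Matrix::colMeans(ci >= 1),
    mean_cpm_in = as.numeric(mi), mean_cpm_out = as.numeric(mo),
    log2fc = log2((as.numeric(mi) + pseudocount) / (as.numeric(mo) + pseudocount)),
    stringsAsFactors = FALSE
  )
}

#' Call TF targets from expression statistics and binding
#'
#' @param stats Output of [expression_stats()].
#' @param bound_genes Gene ids with at least one binding site of the TF
#'   (e.g. assigned genes from [annotate_peaks()]).
#' @param rule A [target_rule()].
#' @param tf_name TF label carried into the output.
#' @return data.frame: `gene_id`, `tf_name`, `expr_fraction`, `log2fc`,
#'   `bound`, `is_target`.
#' @export
call_targets <- function(stats, bound_genes, rule = target_rule(),
                         tf_name = "TF") {
  bound <- stats$gene_id %in% bound_genes
  is_target <- stats$expr_fraction_in >= rule$min_expr_fraction &
    stats$log2fc >= rule$min_log2fc &
    (!rule$require_bound | bound)
  data.frame(gene_id = stats$gene_id, tf_name = tf_name,
             expr_fraction = stats$expr_fraction_in, log2fc = stats$log2fc,
             bound = bound, is_target = is_target, stringsAsFactors = FALSE)
}
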