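# Generators with planted ground truth. Each is a pure function of its
# parameters and seed; the global RNG state is restored on exit.

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Simulate counts from the two-level concentration model
#'
#' Each cell draws `total_counts` transcripts multinomially from a two-level
#' probability vector: the top `ceiling(top_fraction * n_genes)` genes share
#' `mass_in_top` of the transcript mass uniformly, the rest share the
#' remainder uniformly. `mass_in_top = NULL` gives the homogeneous model
#' (all genes equal). This is the minimal model in which a tunable fraction
#' of transcripts concentrates in the top 10% of genes, the regime where
#' rising concentration depresses per-cell entropy.
#'
#' @param n_genes,n_cells Dimensions.
#' @param total_counts Transcripts per cell.
#' @param top_fraction Fraction of genes in the concentrated block
#'   (default 0.10).
#' @param mass_in_top Transcript mass in the block (e.g. 0.40, 0.50), or NULL
#'   for homogeneous expression. Must be >= `top_fraction`.
#' @param seed Integer seed.
#' @param cluster_label Cluster label applied to all cells.
#' @return An `sc_counts` object.
#' @export
sim_counts <- function(n_genes, n_cells, total_counts = 10000,
                       top_fraction = 0.1, mass_in_top = NULL, seed = 1,
                       cluster_label = "sim") {
  stopifnot(n_cells >= 1, n_genes >= 2)
  p <- two_level_probs(n_genes, top_fraction, mass_in_top)
  m <- with_seed(seed, stats::rmultinom(n_cells, size = total_counts, prob = p))
  counts <- t(m)  # cells x genes
  rownames(counts) <- sprintf("cell_%04d", seq_len(n_cells))
  colnames(counts) <- sprintf("gene_%05d", seq_len(n_genes))
  sc_counts(counts, cluster = stats::setNames(rep(cluster_label, n_cells),
                                              rownames(counts)))
}

# sample one site from a PWM's column distributions
sample_site <- function(pwm) {
  paste(apply(pwm$probs, 2, function(col) sample(c("A", "C", "G", "T"), 1, prob = col)),
        collapse = "")
}

#' Simulate a peak genome with planted co-binding motif sites
#'
#' Emits one contig per peak (uniform i.i.d. ACGT background), plants one
#' site sampled from `pwm_a` with its midpoint at the peak summit, and one
#' site from `pwm_b` whose midpoint sits at `offset + Normal(0, jitter_sd)`
#' bp from the summit (modes `constrained`/`relaxed`) or uniformly within
#' +/- `window` bp (mode `random`). Site strands are random; minus-strand
#' sites are inserted as reverse complements. The emitted site table carries
#' the planted positions, strands and center-to-center distances, and is
#' sufficient to score downstream spacing calls without re-deriving
#' generation internals.
#'
#' @param n_peaks Number of peaks/contigs.
#' @param peak_len Contig length; must be at least
#'   `2 * (width_a + width_b + |offset| + 6 * jitter_sd)`.
#' @param pwm_a,pwm_b PWMs (see [build_pwm()]).
#' @param mode `constrained`, `relaxed` or `random`.
#' @param offset Planted center-to-center spacing (ignored for `random`).
#' @param jitter_sd Spacing jitter SD in bp; `constrained` requires
#'   `jitter_sd <= 3`, `relaxed` requires `3 < jitter_sd <= 30`.
#' @param window Scan half-window the spacing analysis will use (bp).
#' @param seed Integer seed.
#' @return List: `genome` (named character vector), `peaks` (peak table),
#'   `sites` (data.frame: `peak`, `factor`, `start`, `strand`,
#'   `center_offset`), `distances` (planted center-to-center distances,
#'   b minus a).
#' @export
sim_peak_genome <- function(n_peaks, peak_len = 300, pwm_a, pwm_b,
                            mode = c("constrained", "relaxed", "random"),
                            offset = 8, jitter_sd = 1, window = 50, seed = 1) {
  mode <- match.arg(mode)
  la <- ncol(pwm_a$probs); lb <- ncol(pwm_b$probs)
  if (mode == "constrained" && jitter_sd > 3) stop("constrained mode requires jitter_sd <= 3")
  if (mode == "relaxed" && (jitter_sd <= 3 || jitter_sd > 30)) {
    stop("relaxed mode requires jitter_sd in (3, 30]")
  }
  if (mode != "random") {
    if (peak_len < 2 * (la + lb + abs(offset) + 6 * jitter_sd)) {
      stop("peak_len too small for the requested spacing model")
    }
    if (mode == "constrained" && abs(offset) + 6 * jitter_sd + lb / 2 > window) {
      stop("planted site would fall outside the +/-", window, " bp scan window")
    }
  } else {
    if (peak_len < 2 * (la + lb + window)) stop("peak_len too small for random placement")
  }
  with_seed(seed, {
    summit <- peak_len %/% 2L
    genome <- character(n_peaks)
    sites <- vector("list", n_peaks)
    names <- sprintf("peak_%04d", seq_len(n_peaks))
    for (i in seq_len(n_peaks)) {
      seq_i <- sample(c("A", "C", "G", "T"), peak_len, replace = TRUE)
      # factor A: midpoint at the summit
      start_a <- as.integer(round(summit - la / 2))
      strand_a <- sample(c("+", "-"), 1)
      site_a <- sample_site(pwm_a)
      ins_a <- if (strand_a == "-") revcomp(site_a) else site_a
      seq_i[(start_a + 1L):(start_a + la)] <- strsplit(ins_a, "")[[1]]
      # factor B: midpoint at summit + d
      d <- if (mode == "random") {
        sample(seq(-window, window), 1)
      } else {
        round(offset + stats::rnorm(1, 0, jitter_sd))
      }
      start_b <- as.integer(round(summit + d - lb / 2))
      start_b <- max(0L, min(peak_len - lb, start_b))
      strand_b <- sample(c("+", "-"), 1)
      site_b <- sample_site(pwm_b)
      ins_b <- if (strand_b == "-") revcomp(site_b) else site_b
      seq_i[(start_b + 1L):(start_b + lb)] <- strsplit(ins_b, "")[[1]]
      genome[i] <- paste(seq_i, collapse = "")
      sites[[i]] <- data.frame(
        peak = names[i], factor = c("a", "b"),
        start = c(start_a, start_b), strand = c(strand_a, strand_b),
        center_offset = c(start_a + la / 2 - summit, start_b + lb / 2 - summit),
        stringsAsFactors = FALSE
      )
    }
    names(genome) <- names
    sites <- do.call(rbind, sites)
    peaks <- peak_table(names, 0L, peak_len, name = names,
                        summit_offset = summit)
    dist <- sites$center_offset[sites$factor == "b"] -
      sites$center_offset[sites$factor == "a"]
    list(genome = genome, peaks = peaks, sites = sites, distances = dist)
  })
}

#' Simulate nucleosome occupancy over a peak set
#'
#' Peaks in `nucleosomal_ids` receive a 147 bp plateau of height `amp`
#' centred on the summit (the canonical nucleosome core-particle footprint);
#' all positions additionally carry half-normal noise |Normal(0, amp/10)|,
#' i.e. Normal noise truncated at zero.
#'
#' @param peaks Peak table.
#' @param chrom_sizes Named integer vector of contig lengths; defaults to the
#'   largest peak end per contig.
#' @param nucleosomal_ids Peak names to receive the plateau.
#' @param amp Plateau height (> 0).
#' @param footprint Plateau width in bp (default 147).
#' @param seed Integer seed.
#' @return Occupancy track (named list of per-base numeric vectors).
#' @export
sim_occupancy <- function(peaks, chrom_sizes = NULL, nucleosomal_ids = character(),
                          amp, footprint = 147L, seed = 1) {
  if (amp <= 0) stop("amp must be > 0")
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(split(peaks$end, peaks$chrom), max, integer(1))
  }
  with_seed(seed, {
    track <- lapply(chrom_sizes, function(len) abs(stats::rnorm(len, 0, amp / 10)))
    names(track) <- names(chrom_sizes)
    half <- footprint %/% 2L
    for (i in which(peaks$name %in% nucleosomal_ids)) {
      ch <- peaks$chrom[i]
      s <- peak_center(peaks)[i]
      lo <- max(0L, s - half)
      hi <- min(length(track[[ch]]) - 1L, s + half)
      track[[ch]][(lo + 1L):(hi + 1L)] <- track[[ch]][(lo + 1L):(hi + 1L)] + amp
    }
    track
  })
}

#' Simulate a log2 LFQ proteomics table with planted enrichment
#'
#' Protein baselines are Normal(`baseline_mean`, `baseline_sd`) in log2
#' units; replicate values add Normal(0, `rep_sd`) scatter. Proteins in
#' `enriched` are shifted by `+effect` in `bait_group` samples. Values below
#' the matrix-wide `miss_quantile` quantile go missing with probability
#' `missing_rate` (missing-not-at-random at low abundance, the regime
#' downshifted imputation presumes). An optional always-observed bait row is
#' appended.
#'
#' @param n_proteins Number of (non-bait) proteins.
#' @param design data.frame with columns `sample`, `group`; every group needs
#'   >= 2 replicates.
#' @param enriched Protein ids (or indices) planted as enriched.
#' @param effect Planted log2 shift (> 0).
#' @param missing_rate Missingness probability below the quantile.
#' @param bait_protein Optional name for an appended bait row.
#' @param bait_group Group receiving the effect (default: first group).
#' @param baseline_mean,baseline_sd,rep_sd,miss_quantile Model parameters.
#' @param seed Integer seed.
#' @return List: `log2` (proteins x samples, NA = missing), `design`,
#'   `detected` (logical matrix, pre-imputation), `truth` (enriched ids,
#'   effect, missing_rate, bait).
#' @export
sim_lfq <- function(n_proteins, design, enriched = integer(), effect = 3,
                    missing_rate = 0, bait_protein = NULL,
                    bait_group = NULL, baseline_mean = 25, baseline_sd = 2,
                    rep_sd = 0.3, miss_quantile = 0.25, seed = 1) {
  stopifnot(is.data.frame(design), all(c("sample", "group") %in% names(design)))
  if (effect <= 0) stop("effect must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  reps <- table(design$group)
  if (any(reps < 2)) {
    stop("group(s) with < 2 replicates: ",
         paste(names(reps)[reps < 2], collapse = ", "))
  }
  if (is.null(bait_group)) bait_group <- design$group[1]
  ids <- sprintf("prot_%04d", seq_len(n_proteins))
  if (is.numeric(enriched)) enriched <- ids[enriched]
  with_seed(seed, {
    ns <- nrow(design)
    base <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
    mat <- matrix(stats::rnorm(n_proteins * ns, 0, rep_sd), n_proteins, ns) + base
    shift <- outer(ids %in% enriched, design$group == bait_group) * effect
    mat <- mat + shift
    dimnames(mat) <- list(ids, design$sample)
    if (missing_rate > 0) {
      thr <- stats::quantile(mat, miss_quantile)
      drop <- mat < thr & matrix(stats::runif(length(mat)) < missing_rate,
                                 nrow(mat), ncol(mat))
      mat[drop] <- NA_real_
    }
    if (!is.null(bait_protein)) {
      bait_row <- matrix(stats::rnorm(ns, baseline_mean + 5, rep_sd), 1, ns,
                         dimnames = list(bait_protein, design$sample))
      mat <- rbind(mat, bait_row)
    }
    list(log2 = mat, design = design, detected = !is.na(mat),
         truth = list(enriched = enriched, effect = effect,
                      missing_rate = missing_rate, bait = bait_protein))
  })
}

#' Simulate counts with planted TF-dependent target genes
#'
#' Builds a two-population count matrix for exercising the target-calling
#' rule: gene 1 acts as the TF (expressed only in the positive population),
#' planted target genes are up-weighted `fold`-fold in TF-positive cells, and
#' all other genes are uniform in both populations.
#'
#' @param n_genes Total genes (including the TF gene).
#' @param n_cells_in,n_cells_out TF-positive / negative population sizes.
#' @param n_planted Number of planted target genes.
#' @param fold Probability up-weighting of planted genes in positive cells.
#' @param total_counts Counts per cell.
#' @param seed Integer seed.
#' @return List: `counts` (`sc_counts`, clusters `tf_pos`/`tf_neg`),
#'   `tf_gene`, `planted` (target gene ids).
#' @export
sim_target_counts <- function(n_genes = 500, n_cells_in = 100,
                              n_cells_out = 100, n_planted = 50, fold = 4,
                              total_counts = 10000, seed = 1) {
  stopifnot(n_planted + 1 < n_genes)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  tf <- genes[1]
  planted <- genes[1 + seq_len(n_planted)]
  w_in <- rep(1, n_genes); w_in[genes %in% c(tf, planted)] <- fold
  w_out <- rep(1, n_genes); w_out[1] <- 0
  with_seed(seed, {
    m_in <- stats::rmultinom(n_cells_in, total_counts, w_in / sum(w_in))
    m_out <- stats::rmultinom(n_cells_out, total_counts, w_out / sum(w_out))
    counts <- t(cbind(m_in, m_out))
    rownames(counts) <- sprintf("cell_%04d", seq_len(nrow(counts)))
    colnames(counts) <- genes
    cl <- stats::setNames(rep(c("tf_pos", "tf_neg"), c(n_cells_in, n_cells_out)),
                          rownames(counts))
    list(counts = sc_counts(counts, cluster = cl), tf_gene = tf,
         planted = planted)
  })
}
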