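# Pipeline orchestration: a single config drives all stages with
# deterministic per-stage seeds and auditable output headers.

PIPELINE_STAGES <- c("entropy", "annotate", "nucleosome", "motifs_spacing",
                     "targets", "plms")

CONFIG_KEYS <- c(
  "seed", "outdir",
  "counts_matrix", "counts_cells", "counts_genes", "counts_clusters",
  "genome", "peaks_a", "peaks_b", "genes", "occupancy", "pwm_a", "pwm_b",
  "lfq_table", "lfq_design", "lfq_msms",
  "tf_gene", "bait_protein", "bait_group",
  "control_group_primary", "control_group_secondary",
  "window", "min_score_frac", "nuc_window", "nuc_threshold", "max_dist",
  "min_expr_fraction", "min_log2fc", "s0", "fdr_primary", "fdr_secondary",
  "n_perm", "impute_width", "impute_downshift", "min_reps_detected"
)

CONFIG_PATH_KEYS <- c("counts_matrix", "counts_cells", "counts_genes",
                      "counts_clusters", "genome", "peaks_a", "peaks_b",
                      "genes", "occupancy", "pwm_a", "pwm_b", "lfq_table",
                      "lfq_design", "lfq_msms")

config_defaults <- function() {
  list(window = 50, min_score_frac = 0.8, nuc_window = 147,
       nuc_threshold = NULL, max_dist = 3000, min_expr_fraction = 0.25,
       min_log2fc = 0.223, s0 = 0.5, fdr_primary = 0.05, fdr_secondary = 0.1,
       n_perm = 250, impute_width = 0.3, impute_downshift = 1.8,
       min_reps_detected = 2)
}

#' Validate a pipeline run configuration
#'
#' Unknown keys are errors (no silent typo tolerance); all referenced input
#' paths must exist at validation time. Defaults are filled for unset
#' parameters.
#'
#' @param config A named list or a YAML file path.
#' @return The validated, default-filled config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  req <- c("seed", "outdir")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("missing config key(s): ", paste(miss, collapse = ", "))
  for (k in intersect(CONFIG_PATH_KEYS, names(config))) {
    if (!file.exists(config[[k]])) stop("config path does not exist: ", k, " = ", config[[k]])
  }
  defaults <- config_defaults()
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config
}

stage_seed <- function(seed, stage) {
  i <- match(stage, PIPELINE_STAGES)
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483647)
}

# TSV with '#key=value' metadata header lines; numbers formatted stably so
# repeated runs are byte-identical
write_stage_table <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s=%s", names(meta), vapply(meta, as.character, character(1))), con)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- num_chr(df[[j]])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline from a config
#'
#' Executes the configured stages in dependency order (entropy; annotate ->
#' nucleosome -> motif presence + spacing; targets; plms), writing each
#' stage's tables under `outdir` with parameter/seed metadata headers and a
#' machine-readable JSON run report. Stages whose inputs are not configured
#' are skipped; a stage failure marks downstream dependents skipped.
#' Repeated runs with the same config and seed are byte-identical.
#'
#' @param config Named list or YAML path (see [validate_config()]).
#' @return The run report list, invisibly. `report$ok` is FALSE if any stage
#'   failed.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, stages = list(), ok = TRUE)
  state <- new.env(parent = emptyenv())
  failed <- character()

  run_stage <- function(name, deps, fn) {
    if (length(intersect(deps, failed))) {
      report$stages[[name]] <<- list(status = "skipped",
                                     reason = paste("failed dependency:",
                                                    paste(intersect(deps, failed), collapse = ",")))
      failed <<- c(failed, name)
      return(invisible(NULL))
    }
    res <- tryCatch(
      list(status = "ok", outputs = basename(fn(stage_seed(cfg$seed, name)))),
      error = function(e) list(status = "failed", error = conditionMessage(e))
    )
    if (res$status == "failed") {
      failed <<- c(failed, name)
      report$ok <<- FALSE
    }
    report$stages[[name]] <<- res
    invisible(NULL)
  }

  meta_base <- list(seed = cfg$seed, package = "stomatalchrom")

  if (!is.null(cfg$counts_matrix)) {
    run_stage("entropy", character(), function(sd) {
      m <- read_counts(cfg$counts_matrix, cfg$counts_cells, cfg$counts_genes,
                       cfg$counts_clusters)
      state$counts <- m
      ent <- entropy_by_cluster(m)
      p1 <- file.path(cfg$outdir, "entropy_cells.tsv")
      p2 <- file.path(cfg$outdir, "entropy_summary.tsv")
      write_stage_table(ent$cells, p1, c(meta_base, stage = "entropy"))
      write_stage_table(ent$summary, p2, c(meta_base, stage = "entropy"))
      c(p1, p2)
    })
  }

  if (!is.null(cfg$peaks_a) && !is.null(cfg$genes)) {
    run_stage("annotate", character(), function(sd) {
      pk <- read_bed(cfg$peaks_a)
      gn <- read_gene_table(cfg$genes)
      state$peaks_a <- pk
      state$annotation <- annotate_peaks(pk, gn, max_dist = cfg$max_dist)
      p <- file.path(cfg$outdir, "peak_annotation.tsv")
      write_stage_table(state$annotation, p,
                        c(meta_base, stage = "annotate", max_dist = cfg$max_dist))
      p
    })
  }

  if (!is.null(cfg$occupancy) && !is.null(cfg$peaks_a)) {
    run_stage("nucleosome", "annotate", function(sd) {
      trk <- read_track(cfg$occupancy)
      state$nuc <- classify_nucleosomal(state$peaks_a, trk,
                                        window = cfg$nuc_window,
                                        threshold = cfg$nuc_threshold)
      p <- file.path(cfg$outdir, "nucleosome_classes.tsv")
      write_stage_table(state$nuc, p,
                        c(meta_base, stage = "nucleosome", window = cfg$nuc_window))
      p
    })
  }

  if (!is.null(cfg$genome) && !is.null(cfg$pwm_a)) {
    run_stage("motifs_spacing", c("annotate", "nucleosome"), function(sd) {
      genome <- read_genome(cfg$genome)
      pwm_a <- read_pwm(cfg$pwm_a)
      min_a <- cfg$min_score_frac * pwm_max_score(pwm_a)
      subsets <- split(state$peaks_a, state$nuc$label[match(state$peaks_a$name,
                                                            state$nuc$peak_id)])
      pres <- motif_presence(subsets, pwm_a, genome, window = cfg$window,
                             min_score = min_a)
      outs <- file.path(cfg$outdir, "motif_presence.tsv")
      write_stage_table(pres, outs, c(meta_base, stage = "motifs_spacing",
                                      window = cfg$window,
                                      min_score_frac = cfg$min_score_frac))
      if (!is.null(cfg$pwm_b) && !is.null(cfg$peaks_b)) {
        pwm_b <- read_pwm(cfg$pwm_b)
        pk_b <- read_bed(cfg$peaks_b)
        ha <- best_hits(pwm_a, state$peaks_a, genome, window = cfg$window,
                        min_score = min_a)
        hb <- best_hits(pwm_b, pk_b, genome, window = cfg$window,
                        min_score = cfg$min_score_frac * pwm_max_score(pwm_b))
        sp <- shared_peak_distances(ha, hb)
        call <- classify_spacing(sp, window = cfg$window)
        pd <- file.path(cfg$outdir, "spacing_distances.tsv")
        write_stage_table(data.frame(peak_id = sp$peak_ids,
                                     distance = sp$distances), pd,
                          c(meta_base, stage = "motifs_spacing",
                            convention = "signed_center_to_center_b_minus_a"))
        pj <- file.path(cfg$outdir, "spacing_call.json")
        jsonlite::write_json(list(call = call$call, spread = call$spread,
                                  uniformity_p = call$uniformity_p, n = call$n,
                                  seed = cfg$seed),
                             pj, auto_unbox = TRUE, digits = NA)
        outs <- c(outs, pd, pj)
      }
      outs
    })
  }

  if (!is.null(cfg$tf_gene) && !is.null(cfg$counts_matrix)) {
    run_stage("targets", c("entropy", "annotate"), function(sd) {
      m <- state$counts
      pos <- tf_positive_cells(m, cfg$tf_gene)
      neg <- setdiff(m$cell_ids, pos)
      st <- expression_stats(m, pos, neg)
      bound <- unique(stats::na.omit(state$annotation$gene_id))
      rule <- target_rule(min_expr_fraction = cfg$min_expr_fraction,
                          min_log2fc = cfg$min_log2fc,
                          max_peak_gene_dist = cfg$max_dist)
      calls <- call_targets(st, bound, rule, tf_name = cfg$tf_gene)
      p <- file.path(cfg$outdir, "target_calls.tsv")
      write_stage_table(calls, p, c(meta_base, stage = "targets",
                                    min_expr_fraction = cfg$min_expr_fraction,
                                    min_log2fc = cfg$min_log2fc))
      p
    })
  }

  if (!is.null(cfg$lfq_table)) {
    run_stage("plms", character(), function(sd) {
      raw <- as.matrix(utils::read.delim(cfg$lfq_table, row.names = 1,
                                         check.names = FALSE))
      design <- utils::read.delim(cfg$lfq_design, stringsAsFactors = FALSE)
      msms <- if (!is.null(cfg$lfq_msms)) readLines(cfg$lfq_msms) else NULL
      detected <- !is.na(raw)
      imp <- impute_missing(raw, width = cfg$impute_width,
                            downshift = cfg$impute_downshift, seed = sd)
      grp <- function(g) design$sample[design$group == g]
      bait_cols <- grp(cfg$bait_group)
      res <- list()
      res$vs_primary <- permutation_fdr(imp, bait_cols,
                                        grp(cfg$control_group_primary),
                                        s0 = cfg$s0, fdr = cfg$fdr_primary,
                                        n_perm = cfg$n_perm, seed = sd)
      norm <- if (!is.null(cfg$bait_protein)) {
        normalize_to_bait(imp, cfg$bait_protein)
      } else imp
      res$vs_secondary <- permutation_fdr(norm, bait_cols,
                                          grp(cfg$control_group_secondary),
                                          s0 = cfg$s0, fdr = cfg$fdr_secondary,
                                          n_perm = cfg$n_perm, seed = sd + 1)
      cand <- candidate_filter(res, detected, bait_cols,
                               min_reps = cfg$min_reps_detected, msms = msms)
      outs <- character()
      for (nm in names(res)) {
        p <- file.path(cfg$outdir, sprintf("plms_%s.tsv", nm))
        write_stage_table(res[[nm]], p, c(meta_base, stage = "plms", s0 = cfg$s0,
                                          contrast = nm))
        outs <- c(outs, p)
      }
      pc <- file.path(cfg$outdir, "plms_candidates.txt")
      writeLines(cand, pc)
      c(outs, pc)
    })
  }

  report$n_stages <- length(report$stages)
  jsonlite::write_json(report, file.path(cfg$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!report$ok) warning("pipeline finished with failed stage(s): ",
                          paste(failed, collapse = ", "))
  invisible(report)
}

#' Write a complete synthetic demo dataset
#'
#' Generates a small, fully synthetic input set — counts with clusters, a
#' peak genome with planted co-binding sites for two factors, nucleosome
#' occupancy with planted nucleosomal peaks, gene models near the peaks, a
#' proteomics LFQ table with planted enrichment — plus the truth tables for
#' every planted signal and a ready-to-run `config.yaml`. Sized to run the
#' full pipeline in well under two minutes.
#'
#' @param outdir Output directory (created).
#' @param seed Integer seed; fixed seed gives byte-identical fixtures.
#' @return The config file path, invisibly.
#' @export
demo_dataset <- function(outdir, seed = 7) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outdir, ...)

  # counts with a planted TF and targets (also used for entropy)
  tg <- sim_target_counts(n_genes = 300, n_cells_in = 80, n_cells_out = 80,
                          n_planted = 30, fold = 4, total_counts = 2000,
                          seed = seed)
  write_counts(tg$counts, pth("counts"))
  writeLines(tg$planted, pth("truth_target_genes.txt"))

  # peak genome with constrained co-binding of two factors
  pwm_a <- example_pwm("CACGTG", name = "factor_a")
  pwm_b <- example_pwm("TTGACC", name = "factor_b")
  gen <- sim_peak_genome(n_peaks = 150, peak_len = 260, pwm_a = pwm_a,
                         pwm_b = pwm_b, mode = "constrained", offset = 8,
                         jitter_sd = 1, seed = seed + 1)
  write_genome(gen$genome, pth("genome.fa"))
  write_bed(gen$peaks, pth("peaks_a.narrowPeak"))
  write_bed(gen$peaks, pth("peaks_b.narrowPeak"))
  write_pwm(pwm_a, pth("pwm_a.pfm"))
  write_pwm(pwm_b, pth("pwm_b.pfm"))
  utils::write.table(gen$sites, pth("truth_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # nucleosome occupancy: half the peaks nucleosomal
  nuc_ids <- gen$peaks$name[seq_len(nrow(gen$peaks)) %% 2 == 1]
  trk <- sim_occupancy(gen$peaks, nucleosomal_ids = nuc_ids, amp = 10,
                       seed = seed + 2)
  write_track(trk, pth("occupancy.bedGraph"))
  writeLines(nuc_ids, pth("truth_nucleosomal_peaks.txt"))

  # genes on the peak contigs; ids line up with the count matrix so target
  # calling can intersect binding with expression (gene 1 is the TF itself)
  n_bound <- 100
  genes <- gene_table(
    gene_id = sprintf("gene_%05d", 1 + seq_len(n_bound)),
    chrom = gen$peaks$chrom[seq_len(n_bound)],
    start = 150, end = 250, strand = rep(c("+", "-"), length.out = n_bound)
  )
  utils::write.table(genes[, c("gene_id", "chrom", "start", "end", "strand")],
                     pth("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # proteomics with planted enrichment and a bait row
  design <- data.frame(
    sample = sprintf("s%02d", 1:9),
    group = rep(c("bait_biotin", "wt", "untreated"), each = 3),
    stringsAsFactors = FALSE
  )
  lfq <- sim_lfq(n_proteins = 300, design = design, enriched = 1:20,
                 effect = 3, missing_rate = 0.2, bait_protein = "TbID",
                 bait_group = "bait_biotin", seed = seed + 3)
  df <- data.frame(protein = rownames(lfq$log2), lfq$log2, check.names = FALSE)
  utils::write.table(df, pth("lfq.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(design, pth("lfq_design.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(setdiff(rownames(lfq$log2), "TbID"), pth("lfq_msms.txt"))
  writeLines(lfq$truth$enriched, pth("truth_enriched_proteins.txt"))

  cfg <- list(
    seed = seed, outdir = pth("results"),
    counts_matrix = pth("counts.mtx"), counts_cells = pth("counts.cells.txt"),
    counts_genes = pth("counts.genes.txt"),
    counts_clusters = pth("counts.clusters.tsv"),
    genome = pth("genome.fa"), peaks_a = pth("peaks_a.narrowPeak"),
    peaks_b = pth("peaks_b.narrowPeak"), genes = pth("genes.tsv"),
    occupancy = pth("occupancy.bedGraph"), pwm_a = pth("pwm_a.pfm"),
    pwm_b = pth("pwm_b.pfm"), lfq_table = pth("lfq.tsv"),
    lfq_design = pth("lfq_design.tsv"), lfq_msms = pth("lfq_msms.txt"),
    tf_gene = tg$tf_gene, bait_protein = "TbID", bait_group = "bait_biotin",
    control_group_primary = "wt", control_group_secondary = "untreated",
    n_perm = 250
  )
  yaml::write_yaml(cfg, pth("config.yaml"))
  invisible(pth("config.yaml"))
}
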