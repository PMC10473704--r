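#' Annotate peaks to genes by body overlap or nearest TSS
#'
#' A peak overlapping at least one gene body is assigned to that gene
#' (category `overlapping`); otherwise it is assigned to the gene with the
#' smallest |summit - TSS| when that distance is within `max_dist` bp
#' (inclusive, default 3 kb), else left `unassigned`. Distances are
#' summit-based and signed on the gene's strand: negative upstream of the
#' TSS. Ties break to the gene with the smaller start, then lexicographic
#' `gene_id`.
#'
#' @param peaks Peak table.
#' @param genes Gene table (see [gene_table()]), non-empty.
#' @param max_dist TSS distance cutoff in bp (inclusive).
#' @return data.frame: `peak_id`, `gene_id` (NA if unassigned),
#'   `distance_to_tss`, `category` (`overlapping`, `upstream`, `downstream`,
#'   `unassigned`).
#' @export
annotate_peaks <- function(peaks, genes, max_dist = 3000) {
  if (!nrow(genes)) stop("gene table is empty")
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  pk_gr <- GenomicRanges::GRanges(peaks$chrom,
                                  IRanges::IRanges(peaks$start + 1L, peaks$end))
  gn_gr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(pk_gr, gn_gr)
  first_ov <- tapply(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov), min)
  summit <- peak_center(peaks)
  signed_dist <- function(gi, pi) {
    d <- summit[pi] - genes$tss[gi]
    if (genes$strand[gi] == "-") -d else d
  }
  out <- data.frame(peak_id = peaks$name, gene_id = NA_character_,
                    distance_to_tss = NA_real_, category = "unassigned",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    key <- as.character(i)
    if (key %in% names(first_ov)) {
      gi <- first_ov[[key]]
      out$gene_id[i] <- genes$gene_id[gi]
      out$distance_to_tss[i] <- signed_dist(gi, i)
      out$category[i] <- "overlapping"
      next
    }
    same <- which(genes$chrom == peaks$chrom[i])
    if (!length(same)) next
    d_abs <- abs(summit[i] - genes$tss[same])
    best <- same[order(d_abs, genes$start[same], genes$gene_id[same])][1]
    if (min(d_abs) <= max_dist) {
      d <- signed_dist(best, i)
      out$gene_id[i] <- genes$gene_id[best]
      out$distance_to_tss[i] <- d
      out$category[i] <- if (d < 0) "upstream" else "downstream"
    }
  }
  out
}

# count of query intervals [s, e) overlapping any interval in a prepared
# index (per-chromosome sorted starts + running max of ends)
overlap_index <- function(pk) {
  lapply(split(seq_len(nrow(pk)), pk$chrom), function(idx) {
    o <- idx[order(pk$start[idx])]
    list(starts = pk$start[o], maxend = cummax(pk$end[o]))
  })
}

count_overlaps_idx <- function(chrom, start, end, index) {
  hit <- logical(length(start))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    bi <- index[[ch]]
    if (is.null(bi)) next
    k <- findInterval(end[sel] - 0.5, bi$starts)  # b starts strictly < end
    ok <- k >= 1
    ok[ok] <- bi$maxend[k[ok]] > start[sel][ok]
    hit[sel] <- ok
  }
  sum(hit)
}

#' Interval-overlap permutation test between two peak sets
#'
#' Observed statistic: the number of peaks in `a` whose interval intersects
#' any interval in `b`. Null model: each peak of `a` is independently
#' re-placed uniformly on its own chromosome, preserving its length (a
#' simple exchangeable null, conservative in that it ignores accessibility
#' structure). The empirical p-value for enrichment is
#' `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param a,b Peak tables.
#' @param chrom_sizes Named integer vector of chromosome lengths covering all
#'   chromosomes of `a`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List of class `overlap_test`: `observed`, `null_mean`, `null_sd`,
#'   `z`, `p_empirical`, `n_perm`.
#' @export
overlap_permutation_test <- function(a, b, chrom_sizes, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  check_chrom_names(a$chrom, names(chrom_sizes), "chrom_sizes")
  len <- a$end - a$start
  maxlen <- tapply(len, a$chrom, max)
  over <- names(maxlen)[maxlen > chrom_sizes[names(maxlen)]]
  if (length(over)) stop("peak longer than its chromosome on: ", paste(over, collapse = ", "))
  idx <- overlap_index(b)
  observed <- count_overlaps_idx(a$chrom, a$start, a$end, idx)
  space <- chrom_sizes[a$chrom] - len  # start drawn from 0..space
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      s <- floor(stats::runif(nrow(a)) * (space + 1))
      count_overlaps_idx(a$chrom, s, s + len, idx)
    }, numeric(1))
  })
  sdn <- stats::sd(null)
  structure(list(
    observed = observed, null_mean = mean(null), null_sd = sdn,
    z = if (sdn > 0) (observed - mean(null)) / sdn else NA_real_,
    p_empirical = (1 + sum(null >= observed)) / (1 + n_perm),
    n_perm = n_perm
  ), class = "overlap_test")
}

#' Classify peaks as nucleosomal by summit-window occupancy
#'
#' The mean occupancy over a `window` bp interval centred on each summit
#' (147 bp by default, the nucleosome core footprint) is compared against an
#' explicit threshold; the label is `nucleosomal` when the mean is greater
#' than or equal to the threshold (boundary inclusive). The default
#' threshold is the track-wide mean plus one SD — a transparent stand-in for
#' dedicated nucleosome-region callers, adequate because the question is
#' relative occupancy at binding sites.
#'
#' @param peaks Peak table.
#' @param track Occupancy track (named list of per-base vectors) covering all
#'   peak chromosomes.
#' @param window Window width in bp centred on the summit.
#' @param threshold Occupancy threshold (> 0); default track mean + 1 SD.
#' @return data.frame: `peak_id`, `mean_occupancy`, `label`.
#' @export
classify_nucleosomal <- function(peaks, track, window = 147L, threshold = NULL) {
  check_chrom_names(peaks$chrom, names(track), "track")
  if (is.null(threshold)) {
    all_sig <- unlist(track, use.names = FALSE)
    threshold <- mean(all_sig) + stats::sd(all_sig)
  }
  if (threshold <= 0) stop("threshold must be > 0")
  half <- window %/% 2L
  summit <- peak_center(peaks)
  mean_occ <- vapply(seq_len(nrow(peaks)), function(i) {
    sig <- track[[peaks$chrom[i]]]
    lo <- summit[i] - half
    hi <- summit[i] + (window - half - 1L)
    if (lo < 0L || hi >= length(sig)) {
      warning("window truncated at chromosome end for peak ", peaks$name[i])
      lo <- max(0L, lo); hi <- min(length(sig) - 1L, hi)
    }
    mean(sig[(lo + 1L):(hi + 1L)])
  }, numeric(1))
  data.frame(peak_id = peaks$name, mean_occupancy = mean_occ,
             label = ifelse(mean_occ >= threshold, "nucleosomal", "non_nucleosomal"),
             threshold = threshold, stringsAsFactors = FALSE)
}

# mean signal of one anchor region in n_bins bins; anchors shorter than
# n_bins fall back to per-bin linear interpolation
bin_region <- function(sig, start, end, n_bins) {
  vals <- sig[(start + 1L):end]
  len <- length(vals)
  if (len >= n_bins) {
    edges <- floor(seq(0, len, length.out = n_bins + 1))
    vapply(seq_len(n_bins), function(b) {
      mean(vals[(edges[b] + 1L):edges[b + 1L]])
    }, numeric(1))
  } else {
    stats::approx(seq_len(len), vals, xout = seq(1, len, length.out = n_bins))$y
  }
}

#' Metaprofile of (relative) signal over anchor regions
#'
#' Each anchor body is scaled to `n_bins` bins, flanked on both sides by
#' fixed-width bins covering `flank` bp. Minus-strand anchors are reversed
#' before averaging. With a denominator track the per-bin value is
#' `log2((num + eps) / (den + eps))` of the across-anchor mean signals, with
#' a pseudo-signal `eps = 1` to keep ratios finite — the standard
#' log2(ChIP/Input) relative-enrichment metaplot.
#'
#' @param track_num Numerator occupancy track.
#' @param track_den Optional denominator (input) track.
#' @param anchors data.frame with `chrom`, `start`, `end` and optionally
#'   `strand` (0-based half-open).
#' @param flank Flank width in bp on each side.
#' @param n_bins Number of body bins (>= 1).
#' @param flank_bin_width Width of flank bins in bp (default: `flank /
#'   n_bins`, rounded up, so flanks get about `n_bins` bins).
#' @param eps Pseudo-signal for the log ratio.
#' @return data.frame: `bin` (1..total), `region` (`upstream`, `body`,
#'   `downstream`), `value`.
#' @export
metaprofile <- function(track_num, track_den = NULL, anchors, flank = 0,
                        n_bins = 10L, flank_bin_width = NULL, eps = 1) {
  stopifnot(n_bins >= 1, nrow(anchors) >= 1)
  check_chrom_names(anchors$chrom, names(track_num), "numerator track")
  if (!is.null(track_den)) check_chrom_names(anchors$chrom, names(track_den), "denominator track")
  if (is.null(flank_bin_width)) flank_bin_width <- max(1L, ceiling(flank / n_bins))
  nf <- if (flank > 0) as.integer(ceiling(flank / flank_bin_width)) else 0L
  strand <- if ("strand" %in% names(anchors)) anchors$strand else rep("+", nrow(anchors))

  profile_one <- function(track, i) {
    sig <- track[[anchors$chrom[i]]]
    pad <- function(lo, hi) {  # clipped region, zero-padded to length
      n <- hi - lo
      lo2 <- max(0L, lo); hi2 <- min(length(sig), hi)
      out <- numeric(n)
      if (hi2 > lo2) out[(lo2 - lo + 1L):(hi2 - lo)] <- sig[(lo2 + 1L):hi2]
      out
    }
    body <- bin_region(sig, max(0L, anchors$start[i]),
                       min(length(sig), anchors$end[i]), n_bins)
    if (nf > 0) {
      up <- pad(anchors$start[i] - nf * flank_bin_width, anchors$start[i])
      dn <- pad(anchors$end[i], anchors$end[i] + nf * flank_bin_width)
      grp <- rep(seq_len(nf), each = flank_bin_width)
      up <- tapply(up, grp, mean)
      dn <- tapply(dn, grp, mean)
      v <- c(up, body, dn)
    } else {
      v <- body
    }
    if (strand[i] == "-") rev(v) else v
  }

  n_total <- n_bins + 2L * nf
  num <- rowMeans(vapply(seq_len(nrow(anchors)), function(i) profile_one(track_num, i),
                         numeric(n_total)))
  value <- if (is.null(track_den)) {
    num
  } else {
    den <- rowMeans(vapply(seq_len(nrow(anchors)), function(i) profile_one(track_den, i),
                           numeric(n_total)))
    log2((num + eps) / (den + eps))
  }
  region <- rep(c("upstream", "body", "downstream"), c(nf, n_bins, nf))
  data.frame(bin = seq_len(n_total), region = region, value = value,
             stringsAsFactors = FALSE)
}
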