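BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param s A character string over the DNA alphabet.
#' @return The reverse complement (delegates to Biostrings).
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are `(count + pseudocount) / (N + 4 * pseudocount)`.
#' Scores produced from the PWM are log2-odds against the background (bits).
#'
#' @param sites Character vector of >= 2 equal-length ACGT sequences.
#' @param pseudocount Added to every cell (default 0.5).
#' @param background Length-4 background probabilities (A, C, G, T), default
#'   uniform. A genome-derived background may be supplied explicitly; it is
#'   never inferred silently.
#' @param name Motif name.
#' @return A `pwm` object: list with `probs` (4 x L matrix, rows A/C/G/T),
#'   `background`, `pseudocount`, `name`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5, background = rep(0.25, 4),
                      name = "motif") {
  if (length(sites) < 2) stop("need >= 2 aligned sites")
  sites <- toupper(sites)
  L <- unique(nchar(sites))
  if (length(L) != 1) stop("unequal site lengths")
  chars <- do.call(rbind, strsplit(sites, ""))
  bad <- which(!chars %in% BASES)
  if (length(bad)) {
    pos <- arrayInd(bad[1], dim(chars))
    stop(sprintf("non-ACGT character '%s' in site %d position %d",
                 chars[bad[1]], pos[1], pos[2]))
  }
  counts <- apply(chars, 2, function(col) table(factor(col, levels = BASES)))
  probs <- (counts + pseudocount) / (length(sites) + 4 * pseudocount)
  rownames(probs) <- BASES
  stopifnot(all(abs(colSums(probs) - 1) < 1e-9))
  new_pwm(probs, background = background, pseudocount = pseudocount, name = name)
}

#' Construct a PWM from a probability matrix
#'
#' @param probs 4 x L matrix (rows A, C, G, T), columns summing to 1.
#' @param background,pseudocount,name See [build_pwm()].
#' @return A `pwm` object.
#' @export
new_pwm <- function(probs, background = rep(0.25, 4), pseudocount = 0,
                    name = "motif") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  rownames(probs) <- BASES
  if (any(abs(colSums(probs) - 1) > 1e-9)) stop("PWM columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  structure(list(probs = probs, background = as.numeric(background),
                 pseudocount = pseudocount, name = name),
            class = "pwm")
}

#' Reverse-complement a PWM
#'
#' @param pwm A `pwm` object.
#' @return The PWM matching sites on the opposite strand (columns reversed,
#'   rows complement-swapped; background likewise).
#' @export
revcomp_pwm <- function(pwm) {
  rc <- pwm$probs[4:1, rev(seq_len(ncol(pwm$probs))), drop = FALSE]
  rownames(rc) <- BASES
  new_pwm(rc, background = pwm$background[4:1], pseudocount = pwm$pseudocount,
          name = paste0(pwm$name, "_rc"))
}

# 4 x L log2-odds score matrix
pwm_score_matrix <- function(pwm) log2(pwm$probs / pwm$background)

#' Consensus sequence and score of a PWM
#'
#' @param pwm A `pwm` object.
#' @return `pwm_consensus`: the per-column argmax base string.
#'   `pwm_max_score`: the consensus log2-odds score in bits (sum of column
#'   maxima).
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' @rdname pwm_consensus
#' @export
pwm_max_score <- function(pwm) {
  sum(apply(pwm_score_matrix(pwm), 2, max))
}

# per-start-position scores of one strand; codes are ints 1..4 (NA for N),
# ambiguity codes contribute 0 (background odds)
scan_scores_one <- function(S, codes) {
  L <- ncol(S)
  n <- length(codes)
  if (n < L) return(numeric(0))
  starts <- seq_len(n - L + 1L)
  total <- numeric(length(starts))
  for (j in seq_len(L)) {
    sc <- S[cbind(codes[starts + j - 1L], j)]
    sc[is.na(sc)] <- 0
    total <- total + sc
  }
  total
}

#' Scan a sequence with a PWM on both strands
#'
#' Windows are scored as summed log2-odds (bits) against the PWM background;
#' `N` positions contribute 0. The minus strand is scored by scanning with
#' the reverse-complement PWM, so hit coordinates stay on the forward strand.
#' Palindromic duplicate hits (same start, equal score on both strands)
#' collapse to the `+` record. Hits are sorted by score (desc), then start
#' (asc), then `+` before `-`.
#'
#' @param pwm A `pwm` object.
#' @param seq A character sequence (ACGTN).
#' @param min_score Minimum score in bits; defaults to 0.8 x the consensus
#'   score.
#' @return data.frame with columns `start` (0-based), `strand`, `score`,
#'   `center` (start + L/2).
#' @export
scan_pwm <- function(pwm, seq, min_score = NULL) {
  if (is.null(min_score)) min_score <- 0.8 * pwm_max_score(pwm)
  seq <- toupper(seq)
  L <- ncol(pwm$probs)
  if (nchar(seq) < L) stop("sequence shorter than the PWM")
  codes <- match(strsplit(seq, "")[[1]], BASES)
  fwd <- scan_scores_one(pwm_score_matrix(pwm), codes)
  rev <- scan_scores_one(pwm_score_matrix(revcomp_pwm(pwm)), codes)
  starts <- seq_along(fwd) - 1L
  hits <- rbind(
    data.frame(start = starts, strand = "+", score = fwd),
    data.frame(start = starts, strand = "-", score = rev)
  )
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  if (nrow(hits)) {
    # collapse palindromic duplicates to the + record
    dup <- hits$strand == "-" &
      hits$start %in% hits$start[hits$strand == "+"]
    if (any(dup)) {
      plus_score <- hits$score[hits$strand == "+"]
      names(plus_score) <- hits$start[hits$strand == "+"]
      dup <- dup & abs(hits$score - plus_score[as.character(hits$start)]) < 1e-9
      hits <- hits[!dup, , drop = FALSE]
    }
    hits <- hits[order(-hits$score, hits$start, hits$strand), , drop = FALSE]
  }
  hits$center <- hits$start + L / 2
  rownames(hits) <- NULL
  hits
}

#' Best motif hit near a peak center
#'
#' Scans the region around the peak summit and returns the best-scoring hit
#' whose midpoint lies within +/- `window` bp of the summit (the region a
#' PWM fitted within 50 bp of peak centers describes). Ties are broken by
#' smaller |offset|, then leftmost start. The hit `offset` is
#' center-to-center: hit midpoint minus summit, signed.
#'
#' @param pwm A `pwm` object.
#' @param peak One-row peak table (or a row index into `peaks`).
#' @param genome Named character vector of sequences.
#' @param window Half-window in bp around the summit (default 50).
#' @param min_score Minimum score in bits (default 0.8 x consensus score).
#' @return One-row data.frame (`peak_id`, `offset`, `start`, `strand`,
#'   `score`) or NULL when no hit passes.
#' @export
best_hit_near_center <- function(pwm, peak, genome, window = 50,
                                 min_score = NULL) {
  if (is.null(min_score)) min_score <- 0.8 * pwm_max_score(pwm)
  check_chrom_names(peak$chrom, names(genome), "genome")
  L <- ncol(pwm$probs)
  chrom_seq <- genome[[peak$chrom]]
  summit <- peak$start + peak$summit_offset
  lo <- summit - window - L  # 0-based scan region start
  hi <- summit + window + L
  if (lo < 0 || hi > nchar(chrom_seq)) {
    warning("scan window truncated at chromosome boundary for peak ", peak$name)
    lo <- max(0, lo); hi <- min(nchar(chrom_seq), hi)
  }
  if (hi - lo < L) return(NULL)
  sub <- substr(chrom_seq, lo + 1, hi)
  hits <- scan_pwm(pwm, sub, min_score = min_score)
  if (!nrow(hits)) return(NULL)
  hits$start <- hits$start + lo
  hits$center <- hits$center + lo
  hits$offset <- hits$center - summit
  hits <- hits[abs(hits$offset) <= window, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  hits <- hits[order(-hits$score, abs(hits$offset), hits$start, hits$strand), , drop = FALSE]
  data.frame(peak_id = peak$name, offset = hits$offset[1], start = hits$start[1],
             strand = hits$strand[1], score = hits$score[1],
             stringsAsFactors = FALSE)
}

#' Best hits near center for a whole peak set
#'
#' @param pwm A `pwm` object.
#' @param peaks Peak table.
#' @param genome Named character vector.
#' @param window,min_score See [best_hit_near_center()].
#' @return data.frame of best hits, one row per peak with a passing hit.
#' @export
best_hits <- function(pwm, peaks, genome, window = 50, min_score = NULL) {
  if (is.null(min_score)) min_score <- 0.8 * pwm_max_score(pwm)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    best_hit_near_center(pwm, peaks[i, , drop = FALSE], genome,
                         window = window, min_score = min_score)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(peak_id = character(), offset = numeric(),
                      start = numeric(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif presence and stringency across peak subsets
#'
#' For each labeled, disjoint peak subset, reports the fraction of peaks
#' carrying a motif hit within `window` bp of the summit and the mean
#' best-hit score — the two readouts used to compare motif stringency
#' between, e.g., nucleosomal and non-nucleosomal binding sites.
#'
#' @param peak_subsets Named list of peak tables (disjoint peak names).
#' @param pwm A `pwm` object.
#' @param genome Named character vector.
#' @param window,min_score See [best_hit_near_center()].
#' @return data.frame: `label`, `n`, `n_with_motif`, `fraction`,
#'   `mean_best_score`, `min_score`.
#' @export
motif_presence <- function(peak_subsets, pwm, genome, window = 50,
                           min_score = NULL) {
  if (is.null(min_score)) min_score <- 0.8 * pwm_max_score(pwm)
  all_names <- unlist(lapply(peak_subsets, `[[`, "name"))
  if (anyDuplicated(all_names)) stop("peak subsets must be disjoint")
  rows <- lapply(names(peak_subsets), function(lab) {
    pk <- peak_subsets[[lab]]
    if (!nrow(pk)) {
      return(data.frame(label = lab, n = 0L, n_with_motif = NA_integer_,
                        fraction = NA_real_, mean_best_score = NA_real_,
                        min_score = min_score))
    }
    h <- best_hits(pwm, pk, genome, window = window, min_score = min_score)
    data.frame(label = lab, n = nrow(pk), n_with_motif = nrow(h),
               fraction = nrow(h) / nrow(pk),
               mean_best_score = if (nrow(h)) mean(h$score) else NA_real_,
               min_score = min_score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a PWM in JASPAR-style PFM text
#'
#' Four `BASE [ counts... ]` lines after a `>name` header; probabilities are
#' written scaled by 1000.
#'
#' @param pwm A `pwm` object.
#' @param path File path.
#' @return `write_pwm`: `path` invisibly. `read_pwm`: a `pwm` object.
#' @export
write_pwm <- function(pwm, path) {
  lines <- c(paste0(">", pwm$name),
             vapply(BASES, function(b) {
               sprintf("%s  [ %s ]", b,
                       paste(num_chr(pwm$probs[b, ] * 1000), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  name <- sub("^>", "", lines[1])
  vals <- lapply(lines[2:5], function(ln) {
    body <- gsub(".*\\[|\\].*", "", ln)
    as.numeric(strsplit(trimws(body), "[ \t]+")[[1]])
  })
  m <- do.call(rbind, vals)
  m <- sweep(m, 2, colSums(m), "/")
  new_pwm(m, name = name)
}

#' Example G-box position weight matrix
#'
#' A sharp PWM centred on the palindromic G-box CACGTG bound by the stomatal
#' bHLH heterodimers, with `p_consensus` on the consensus base and the
#' remainder spread evenly — convenient for simulations and demos. The
#' default 0.97 reflects the near-invariant core of G-box-family ChIP
#' motifs.
#'
#' @param consensus Consensus string (default `CACGTG`).
#' @param p_consensus Probability of the consensus base per column.
#' @param name Motif name.
#' @return A `pwm` object.
#' @export
example_pwm <- function(consensus = "CACGTG", p_consensus = 0.97,
                        name = "Gbox") {
  bases <- strsplit(toupper(consensus), "")[[1]]
  probs <- vapply(bases, function(b) {
    p <- rep((1 - p_consensus) / 3, 4)
    p[match(b, BASES)] <- p_consensus
    p
  }, numeric(4))
  new_pwm(probs, name = name)
}
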