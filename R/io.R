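#' Read peaks from BED3/BED6/narrowPeak
#'
#' Coordinates are taken as 0-based half-open (the BED convention); no
#' convention auto-detection is attempted. Set `one_based = TRUE` to shift
#' 1-based inclusive input on read. narrowPeak column 10 (summit offset from
#' start) populates `summit_offset`; plain BED records fall back to the
#' floored interval midpoint.
#'
#' @param path Path to a BED3, BED6 or ENCODE 10-column narrowPeak file.
#' @param one_based Shift input coordinates from 1-based inclusive to 0-based
#'   half-open on read.
#' @return A peak table (see [peak_table()]), sorted by (chrom, start).
#' @export
read_bed <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(peak_table(character(), integer(), integer())[0, , drop = FALSE])
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (!all(nf %in% c(3L, 6L, 10L)) || length(unique(nf)) != 1L) {
    bad <- which(!nf %in% c(3L, 6L, 10L) | nf != nf[1])[1]
    stop(sprintf("malformed BED line %d: expected 3, 6 or 10 uniform columns", lineno[bad]))
  }
  nf <- nf[1]
  m <- matrix(unlist(fields), ncol = nf, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop(sprintf("malformed BED line %d: non-integer coordinates", lineno[bad[1]]))
  if (one_based) start <- start - 1L
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    stop(sprintf("validation error at line %d: start=%d end=%d (need 0 <= start < end)",
                 lineno[bad[1]], start[bad[1]], end[bad[1]]))
  }
  name <- if (nf >= 6L) m[, 4] else sprintf("peak_%d", seq_along(start))
  strand <- if (nf >= 6L) m[, 6] else "."
  enrichment <- if (nf == 10L) as.numeric(m[, 7]) else 0
  qvalue <- if (nf == 10L) as.numeric(m[, 9]) else NA_real_
  summit <- if (nf == 10L) {
    s <- suppressWarnings(as.integer(m[, 10]))
    ifelse(is.na(s) | s < 0L, (end - start) %/% 2L, s)
  } else {
    (end - start) %/% 2L
  }
  peak_table(m[, 1], start, end, name = name, summit_offset = summit,
             enrichment = enrichment, qvalue = qvalue, strand = strand)
}

#' Write peaks as narrowPeak or BED6
#'
#' @param pk Peak table.
#' @param path Output path.
#' @param format `"narrowPeak"` (10 columns, summit preserved) or `"bed6"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(pk, path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  pk <- validate_peaks(pk)
  strand <- ifelse(pk$strand %in% c("+", "-"), pk$strand, ".")
  lines <- if (format == "narrowPeak") {
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t-1\t%s\t%d",
            pk$chrom, pk$start, pk$end, pk$name, strand,
            num_chr(pk$enrichment), num_chr(ifelse(is.na(pk$qvalue), -1, pk$qvalue)),
            pk$summit_offset)
  } else {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", pk$chrom, pk$start, pk$end, pk$name, strand)
  }
  writeLines(lines, path)
  invisible(path)
}

# full-precision, locale-stable number formatting for text output round-trips
num_chr <- function(x) {
  out <- sprintf("%.17g", x)
  int <- is.finite(x) & x == round(x) & abs(x) < 1e15
  out[int] <- sprintf("%d", as.integer(x[int]))
  out
}

#' Read a per-base occupancy track
#'
#' Supports bedGraph (4 columns, 0-based half-open) and fixed-step WIG
#' (`fixedStep` declarations, 1-based starts converted on read). Positions not
#' covered by any record are 0. Overlapping bedGraph records and negative
#' values are errors.
#'
#' @param path Input file.
#' @param chrom_sizes Optional named integer vector of chromosome lengths; by
#'   default each chromosome's length is the largest end coordinate seen.
#' @return An occupancy track: a named list of per-base numeric vectors.
#' @export
read_track <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  recs <- if (any(grepl("^fixedStep", lines))) parse_wig_fixed(lines) else parse_bedgraph(lines)
  if (any(recs$value < 0)) stop("negative value in track")
  track_from_records(recs, chrom_sizes)
}

parse_bedgraph <- function(lines) {
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      value = numeric()))
  }
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) != 4L)) {
    stop(sprintf("malformed bedGraph line %d: expected 4 columns",
                 which(lengths(fields) != 4L)[1]))
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  data.frame(chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
             value = as.numeric(m[, 4]), stringsAsFactors = FALSE)
}

parse_wig_fixed <- function(lines) {
  chrom <- NULL; pos <- NA_integer_; step <- 1L; span <- 1L
  out <- vector("list", length(lines)); k <- 0L
  for (ln in lines) {
    if (startsWith(ln, "fixedStep")) {
      get <- function(key, default = NA) {
        m <- regmatches(ln, regexec(paste0(key, "=([^ \t]+)"), ln))[[1]]
        if (length(m) == 2) m[2] else default
      }
      chrom <- get("chrom")
      if (is.na(chrom)) stop("fixedStep declaration missing chrom=")
      pos <- as.integer(get("start")) - 1L  # WIG is 1-based
      step <- as.integer(get("step", "1"))
      span <- as.integer(get("span", "1"))
    } else {
      if (is.null(chrom)) stop("WIG data line before any fixedStep declaration")
      k <- k + 1L
      out[[k]] <- data.frame(chrom = chrom, start = pos, end = pos + span,
                             value = as.numeric(ln), stringsAsFactors = FALSE)
      pos <- pos + step
    }
  }
  do.call(rbind, out[seq_len(k)])
}

track_from_records <- function(recs, chrom_sizes = NULL) {
  chroms <- if (is.null(chrom_sizes)) unique(recs$chrom) else names(chrom_sizes)
  if (!is.null(chrom_sizes)) check_chrom_names(recs$chrom, chroms, "chrom_sizes")
  track <- list()
  for (ch in chroms) {
    r <- recs[recs$chrom == ch, , drop = FALSE]
    len <- if (is.null(chrom_sizes)) max(r$end, 0L) else as.integer(chrom_sizes[[ch]])
    sig <- numeric(len)
    if (nrow(r)) {
      r <- r[order(r$start), , drop = FALSE]
      if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)])) {
        stop("overlapping records in track for chromosome ", ch)
      }
      if (any(r$end > len)) stop("track record beyond chromosome end on ", ch)
      for (i in seq_len(nrow(r))) {
        sig[(r$start[i] + 1L):r$end[i]] <- r$value[i]
      }
    }
    track[[ch]] <- sig
  }
  track
}

#' Write an occupancy track as bedGraph
#'
#' Runs of equal signal are collapsed to single records; zero runs are
#' omitted (uncovered positions read back as 0), so
#' `read_track(write_track(x))` reproduces the signal exactly.
#'
#' @param track Named list of per-base numeric vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    sig <- track[[ch]]
    if (!length(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         num_chr(r$values[keep])), con)
    }
  }
  invisible(path)
}

#' Read a single-cell count matrix
#'
#' MatrixMarket input follows the 10x convention (rows = genes, columns =
#' cells) with one-name-per-line sidecar files; dense TSV input has genes in
#' rows and cells in columns with names embedded. Counts are returned
#' cells x genes. Every cell must appear in the cluster file when one is
#' given.
#'
#' @param matrix_path `.mtx` file or dense TSV.
#' @param cells_path,genes_path Name files (required for MTX input).
#' @param clusters_path Optional two-column TSV (`cell`, `cluster`) mapping
#'   every cell to one label.
#' @return A list of class `sc_counts`: `counts` (cells x genes, sparse),
#'   `cell_ids`, `gene_ids`, `cluster` (named character vector).
#' @export
read_counts <- function(matrix_path, cells_path = NULL, genes_path = NULL,
                        clusters_path = NULL) {
  if (grepl("\\.mtx$", matrix_path)) {
    if (is.null(cells_path) || is.null(genes_path)) {
      stop("MTX input requires cells_path and genes_path")
    }
    m <- Matrix::readMM(matrix_path)
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop(sprintf("dimension mismatch: matrix is %d x %d but %d genes / %d cells named",
                   nrow(m), ncol(m), length(genes), length(cells)))
    }
    counts <- Matrix::t(m)
    dimnames(counts) <- list(cells, genes)
  } else {
    df <- utils::read.delim(matrix_path, row.names = 1, check.names = FALSE)
    counts <- Matrix::Matrix(t(as.matrix(df)), sparse = TRUE)
  }
  if (any(counts@x < 0)) stop("negative count in matrix")
  if (any(counts@x != round(counts@x))) stop("non-integer count in matrix")
  cluster <- NULL
  if (!is.null(clusters_path)) {
    cl <- utils::read.delim(clusters_path, header = TRUE,
                            colClasses = "character")
    cluster <- stats::setNames(cl[[2]], cl[[1]])
    missing <- setdiff(rownames(counts), names(cluster))
    if (length(missing)) {
      stop("cells missing from cluster file: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    unknown <- setdiff(names(cluster), rownames(counts))
    if (length(unknown)) {
      stop("unknown cells in cluster file: ", paste(utils::head(unknown, 5), collapse = ", "))
    }
    cluster <- cluster[rownames(counts)]
  }
  sc_counts(counts, cluster = cluster)
}

#' Construct a single-cell counts object
#'
#' @param counts cells x genes matrix (coerced to sparse) of non-negative
#'   integer counts with dimnames.
#' @param cluster Optional named vector mapping every cell to a cluster label.
#' @return An `sc_counts` list.
#' @export
sc_counts <- function(counts, cluster = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("cell_%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("gene_%d", seq_len(ncol(counts)))
  if (is.null(cluster)) {
    cluster <- stats::setNames(rep("all", nrow(counts)), rownames(counts))
  }
  structure(list(counts = counts, cell_ids = rownames(counts),
                 gene_ids = colnames(counts), cluster = cluster),
            class = "sc_counts")
}

#' Write a single-cell count matrix (MTX + sidecars)
#'
#' @param x `sc_counts` object.
#' @param prefix Output path prefix; writes `<prefix>.mtx`,
#'   `<prefix>.cells.txt`, `<prefix>.genes.txt`, `<prefix>.clusters.tsv`.
#' @return The matrix path, invisibly.
#' @export
write_counts <- function(x, prefix) {
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(Matrix::t(x$counts), mtx)
  writeLines(x$cell_ids, paste0(prefix, ".cells.txt"))
  writeLines(x$gene_ids, paste0(prefix, ".genes.txt"))
  utils::write.table(
    data.frame(cell = x$cell_ids, cluster = unname(x$cluster[x$cell_ids])),
    paste0(prefix, ".clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mtx)
}

#' Read a minimal gene table TSV
#'
#' Expects columns `gene_id`, `chrom`, `start`, `end`, `strand` (0-based
#' half-open). The strand-aware TSS is computed on read.
#'
#' @param path TSV path.
#' @return Gene table (see [gene_table()]).
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("gene table missing columns: ", paste(miss, collapse = ", "))
  gene_table(df$gene_id, df$chrom, df$start, df$end, df$strand)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write a genome (named character vector) as FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}
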