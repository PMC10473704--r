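#' Construct a validated peak table
#'
#' Peaks are stored as a plain data.frame with 0-based, half-open coordinates
#' (BED convention). `summit_offset` is the distance in bp from `start` to the
#' peak summit; wherever the package needs a single "center" position it uses
#' `start + summit_offset` (the summit, or the interval midpoint when no
#' summit was provided).
#'
#' @param chrom Character vector of chromosome/contig names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param name Peak identifiers (defaults to `peak_<i>`).
#' @param summit_offset Offset of the summit from `start`; defaults to the
#'   floored midpoint `(end - start) %/% 2`.
#' @param enrichment Fold enrichment (>= 0).
#' @param qvalue Significance value carried through from peak calling.
#' @param strand One of `+`, `-`, `.`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `summit_offset`, `enrichment`, `qvalue`, `strand`, sorted by
#'   (chrom, start).
#' @export
peak_table <- function(chrom, start, end, name = NULL, summit_offset = NULL,
                       enrichment = 0, qvalue = NA_real_, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  chrom <- rep_len(as.character(chrom), n)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  if (is.null(summit_offset)) summit_offset <- (end - start) %/% 2L
  pk <- data.frame(
    chrom = chrom, start = start, end = end,
    name = as.character(name),
    summit_offset = as.integer(summit_offset),
    enrichment = rep_len(as.numeric(enrichment), n),
    qvalue = rep_len(as.numeric(qvalue), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_peaks(pk)
}

#' Validate a peak table
#'
#' Checks the interval invariants (0 <= start < end, non-empty chrom,
#' summit inside the interval, enrichment >= 0) and returns the table sorted
#' by (chrom, start).
#'
#' @param pk A peak `data.frame` as produced by [peak_table()] or [read_bed()].
#' @return The validated, sorted peak table.
#' @export
validate_peaks <- function(pk) {
  stopifnot(is.data.frame(pk))
  req <- c("chrom", "start", "end", "name", "summit_offset")
  miss <- setdiff(req, names(pk))
  if (length(miss)) stop("peak table missing columns: ", paste(miss, collapse = ", "))
  if (any(!nzchar(pk$chrom))) stop("empty chromosome name in peak table")
  bad <- which(!(pk$start >= 0L & pk$start < pk$end))
  if (length(bad)) {
    stop(sprintf("invalid interval at record %d: start=%d end=%d (need 0 <= start < end)",
                 bad[1], pk$start[bad[1]], pk$end[bad[1]]))
  }
  len <- pk$end - pk$start
  bad <- which(pk$summit_offset < 0L | pk$summit_offset >= len)
  if (length(bad)) stop(sprintf("summit_offset outside interval at record %d", bad[1]))
  if (!is.null(pk$enrichment) && any(pk$enrichment < 0, na.rm = TRUE)) {
    stop("negative enrichment in peak table")
  }
  pk <- pk[order(pk$chrom, pk$start, pk$end), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' Summit (center) positions of peaks
#'
#' @param pk Peak table.
#' @return Integer vector of absolute 0-based summit positions
#'   (`start + summit_offset`).
#' @export
peak_center <- function(pk) pk$start + pk$summit_offset

#' Construct a gene model table
#'
#' Gene models carry a strand-aware transcription start site: `tss = start`
#' for `+` (or unstranded) genes and `tss = end - 1` for `-` genes, in 0-based
#' coordinates.
#'
#' @param gene_id Gene identifiers (unique).
#' @param chrom,start,end 0-based half-open gene body coordinates.
#' @param strand `+`, `-` or `.`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(start >= end)) stop("invalid gene interval (need 0 <= start < end)")
  if (anyDuplicated(gene_id)) stop("duplicate gene_id in gene table")
  strand <- rep_len(as.character(strand), length(gene_id))
  data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = start, end = end, strand = strand,
    tss = ifelse(strand == "-", end - 1L, start),
    stringsAsFactors = FALSE
  )
}

# error if peak chromosomes are absent from a reference set (no name
# normalization anywhere: exact string match only)
check_chrom_names <- function(peak_chroms, ref_chroms, what = "reference") {
  missing <- setdiff(unique(peak_chroms), ref_chroms)
  if (length(missing)) {
    stop("chromosome names absent from ", what, ": ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
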