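#' @importFrom GenomicRanges GRanges findOverlaps pintersect
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All interval data.frames in this package are 0-based half-open:
# a row covers bases start .. end-1. GFF3 (1-based closed) and rMATS exonEnd
# (1-based) are converted on ingest; BED-style tables pass through unchanged.

#' Validate an interval data.frame
#'
#' Checks the package-internal interval convention (0-based half-open,
#' `start < end`, non-empty `chrom`).
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (and optionally
#'   `strand` in `+`, `-`, `.`).
#' @return `df`, invisibly; errors describe the first offending row.
#' @keywords internal
validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!(df$start < df$end))
  if (length(bad)) {
    stop("interval with start >= end at row ", bad[1L], ": ",
         df$chrom[bad[1L]], ":", df$start[bad[1L]], "-", df$end[bad[1L]])
  }
  if (any(is.na(df$chrom) | df$chrom == "")) stop("empty chrom in interval table")
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of +, -, .")
  }
  invisible(df)
}

# GRanges view of an internal interval data.frame (shifts to 1-based closed).
as_granges0 <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end),
                         strand = strand)
}

#' Overlapping pairs between two interval tables
#'
#' Strand-blind overlap (>= 1 bp intersection) between two 0-based half-open
#' interval data.frames, via [GenomicRanges::findOverlaps()].
#'
#' @param a,b interval data.frames (`chrom`, `start`, `end`).
#' @return data.frame with columns `a` (row index into `a`), `b` (row index
#'   into `b`) and `overlap_bp` (width of the intersection).
#' @export
overlap_pairs <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(a = integer(), b = integer(), overlap_bp = integer()))
  }
  ga <- as_granges0(a[, c("chrom", "start", "end")])
  gb <- as_granges0(b[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(ga, gb, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  data.frame(a = qi, b = si, overlap_bp = as.integer(ov))
}
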