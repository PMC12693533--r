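HISTONE_MARKS <- c("H3K27ac", "H3K27me3", "H3K36me3", "H3K9me3", "H3K4me3")

#' Read a MAnorm-style differential histone-mark peak table
#'
#' Expects a tab-separated table with header columns `chr`/`chrom`, `start`,
#' `end`, `M_value`, `P_value`, optionally `FDR`, and a `peak_group` (or
#' `peak_type`) column whose values contain `common` for peaks found in both
#' conditions. In the `manorm` dialect coordinates are 1-based closed (the
#' MAnorm output convention) and are shifted to the package-internal 0-based
#' half-open convention; the `bed` dialect is taken as already 0-based.
#' Common peaks and peaks at or above `fdr_max` are removed. If no FDR column
#' is present, Benjamini-Hochberg adjustment of `P_value` is applied across
#' the table.
#'
#' @param path path to the peak table.
#' @param mark histone-mark label; must be one of H3K27ac, H3K27me3,
#'   H3K36me3, H3K9me3, H3K4me3.
#' @param fdr_max FDR cutoff (default 0.05).
#' @param dialect `"manorm"` (1-based closed) or `"bed"` (0-based half-open).
#' @return data.frame `chrom`, `start`, `end`, `mark`, `m_value`, `p_value`,
#'   `fdr` (unique, significant peaks only).
#' @export
load_dhm_peaks <- function(path, mark, fdr_max = 0.05,
                           dialect = c("manorm", "bed")) {
  dialect <- match.arg(dialect)
  if (!mark %in% HISTONE_MARKS) {
    stop("unknown histone mark '", mark, "'; expected one of ",
         paste(HISTONE_MARKS, collapse = ", "))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) return(empty_dhm_df(mark))
  nm <- tolower(names(tab))
  col <- function(...) {
    for (cand in c(...)) {
      i <- match(cand, nm)
      if (!is.na(i)) return(tab[[i]])
    }
    stop("peak table ", path, " lacks a ", ..1, " column")
  }
  out <- data.frame(
    chrom = as.character(col("chr", "chrom")),
    start = as.integer(col("start")),
    end = as.integer(col("end")),
    mark = mark,
    m_value = as.numeric(col("m_value", "m")),
    p_value = as.numeric(col("p_value", "p")),
    stringsAsFactors = FALSE
  )
  if (dialect == "manorm") out$start <- out$start - 1L
  grp <- tolower(as.character(col("peak_group", "peak_type")))
  has_fdr <- any(nm %in% c("fdr", "p_fdr"))
  out$fdr <- if (has_fdr) as.numeric(col("fdr", "p_fdr")) else
    stats::p.adjust(out$p_value, method = "BH")
  out <- out[!grepl("common", grp) & out$fdr < fdr_max, , drop = FALSE]
  out <- out[!duplicated(out[, c("chrom", "start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  validate_intervals(out)
  out
}

empty_dhm_df <- function(mark = character()) {
  data.frame(chrom = character(), start = integer(), end = integer(),
             mark = if (length(mark)) character() else character(),
             m_value = numeric(), p_value = numeric(), fdr = numeric(),
             stringsAsFactors = FALSE)
}

#' Peak-leak filtering of differential peaks
#'
#' Two rules keep transcription-initiation chromatin signal and marginal peak
#' spill-over out of the flank annotation: (a) a peak overlapping any exon
#' that lies within `window` bp of a TSS is treated as
#' transcription-initiation-associated and removed globally; (b) a surviving
#' peak may annotate a candidate exon's flanks only when it covers at least
#' `min_cover_frac` of that exon's length (inclusive threshold).
#'
#' @param peaks peak data.frame from [load_dhm_peaks()].
#' @param exons the full exon universe *before* TSS-proximity exclusion
#'   (TSS-proximal exons are needed to detect rule (a) peaks).
#' @param tss TSS data.frame (`chrom`, `pos`).
#' @param window TSS proximity window in bp (default 200).
#' @param min_cover_frac minimum fraction of an exon a peak must cover to be
#'   annotated to the exon's flanks (default 0.5).
#' @return the globally retained peaks with a list-column `exon_ids` naming
#'   the candidate exons whose flanks each peak may annotate (possibly
#'   character(0)).
#' @export
peak_leak_filter <- function(peaks, exons, tss, window = 200,
                             min_cover_frac = 0.5) {
  if (nrow(peaks) == 0L) {
    peaks$exon_ids <- list()
    return(peaks)
  }
  tss_prox <- if (nrow(exons)) {
    retained <- exclude_tss_proximal(exons, tss, window)
    setdiff(exons$exon_id, retained$exon_id)
  } else character()
  hits <- overlap_pairs(peaks, exons)
  bad_peaks <- unique(hits$a[exons$exon_id[hits$b] %in% tss_prox])
  keep <- setdiff(seq_len(nrow(peaks)), bad_peaks)
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  # rule (b): per retained (peak, exon) pair, require coverage >= frac of exon
  hits <- hits[hits$a %in% keep & !(exons$exon_id[hits$b] %in% tss_prox), ,
               drop = FALSE]
  exon_len <- exons$end - exons$start
  ok <- hits$overlap_bp >= min_cover_frac * exon_len[hits$b]
  hits <- hits[ok, , drop = FALSE]
  new_idx <- match(hits$a, keep)
  ids <- rep(list(character(0)), nrow(out))
  if (nrow(hits)) {
    sp <- split(exons$exon_id[hits$b], new_idx)
    ids[as.integer(names(sp))] <- lapply(sp, unique)
  }
  out$exon_ids <- ids
  out
}

#' Annotate flanks with differential histone-mark scores
#'
#' Each flank receives the M-value of the overlapping eligible peak with the
#' largest |M| (ties broken by smaller FDR, then leftmost start), or 0 when no
#' eligible peak overlaps it (zero imputation). A peak is eligible for a flank
#' when it overlaps the flank by >= 1 bp and, if the peaks carry an
#' `exon_ids` column from [peak_leak_filter()], the flank's exon is listed.
#'
#' @param flanks flank data.frame from [extract_flanks()].
#' @param peaks peak data.frame, ideally after [peak_leak_filter()].
#' @param mark histone-mark label recorded on the output.
#' @return data.frame `flank_id`, `mark`, `dhm_score` (one row per flank).
#' @export
annotate_flanks_with_dhm <- function(flanks, peaks, mark) {
  score <- numeric(nrow(flanks))
  if (nrow(peaks) > 0L && nrow(flanks) > 0L) {
    hits <- overlap_pairs(flanks, peaks)
    if ("exon_ids" %in% names(peaks) && nrow(hits)) {
      ok <- mapply(function(f, p) flanks$exon_id[f] %in% peaks$exon_ids[[p]],
                   hits$a, hits$b)
      hits <- hits[ok, , drop = FALSE]
    }
    if (nrow(hits)) {
      o <- order(hits$a, -abs(peaks$m_value[hits$b]), peaks$fdr[hits$b],
                 peaks$start[hits$b])
      hits <- hits[o, , drop = FALSE]
      best <- hits[!duplicated(hits$a), , drop = FALSE]
      score[best$a] <- peaks$m_value[best$b]
    }
  }
  data.frame(flank_id = flanks$flank_id, mark = mark, dhm_score = score,
             stringsAsFactors = FALSE)
}
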