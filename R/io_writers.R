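# Writers for the external tool dialects the pipeline consumes. These exist
# so the synthetic generators can round-trip through the same readers that
# handle real tool output.

#' Write internal usage-event records as an rMATS-style skipped-exon table
#'
#' @param records internal event data.frame (see [load_deu_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmats_se <- function(records, path) {
  n <- nrow(records)
  psi1 <- pmin(1, pmax(0, 0.5 + records$delta_psi / 2))
  psi2 <- pmin(1, pmax(0, 0.5 - records$delta_psi / 2))
  tab <- data.frame(
    ID = seq_len(n),
    GeneID = sprintf('"%s"', records$gene_id),
    geneSymbol = sprintf('"%s"', records$gene_id),
    chr = records$chrom,
    strand = records$strand,
    exonStart_0base = records$start,
    exonEnd = records$end,
    upstreamES = records$start - 1000L,
    upstreamEE = records$start - 800L,
    downstreamES = records$end + 800L,
    downstreamEE = records$end + 1000L,
    ID.1 = seq_len(n),
    IJC_SAMPLE_1 = paste(ceiling(records$inc_reads / 2),
                         floor(records$inc_reads / 2), sep = ","),
    SJC_SAMPLE_1 = paste(ceiling(records$skip_reads / 2),
                         floor(records$skip_reads / 2), sep = ","),
    IJC_SAMPLE_2 = rep("0,0", n),
    SJC_SAMPLE_2 = rep("0,0", n),
    IncFormLen = rep(198L, n),
    SkipFormLen = rep(99L, n),
    PValue = records$p_value,
    FDR = records$fdr,
    IncLevel1 = sprintf("%.3f,%.3f", psi1, psi1),
    IncLevel2 = sprintf("%.3f,%.3f", psi2, psi2),
    IncLevelDifference = records$delta_psi,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write internal peak records as a MAnorm-style table
#'
#' Coordinates are emitted 1-based closed, matching MAnorm output; the
#' `common` flag becomes the `peak_group` classification.
#'
#' @param peaks internal peak data.frame with `chrom`, `start`, `end`,
#'   `m_value`, `p_value`, `fdr`, and logical `common`.
#' @param path output path.
#' @param sample_names labels for the two conditions (used in `peak_group`).
#' @return `path`, invisibly.
#' @export
write_manorm <- function(peaks, path, sample_names = c("cond1", "cond2")) {
  grp <- ifelse(peaks$common, "common",
                ifelse(peaks$m_value >= 0,
                       paste0(sample_names[1], "_unique"),
                       paste0(sample_names[2], "_unique")))
  tab <- data.frame(
    chr = peaks$chrom,
    start = peaks$start + 1L,
    end = peaks$end,
    summit = (peaks$start + peaks$end) %/% 2L + 1L,
    M_value = peaks$m_value,
    A_value = rep(5, nrow(peaks)),
    P_value = peaks$p_value,
    FDR = peaks$fdr,
    peak_group = grp,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write RBP binding events as RBPmap-style per-protein hit tables
#'
#' One tab-separated file per RBP (`<rbp>.tsv`: protein, flank id, Z-score)
#' in `dir`.
#'
#' @param events event data.frame (`rbp`, `flank_id`, `z_score`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_rbp_hits <- function(events, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rbp in unique(events$rbp)) {
    sub <- events[events$rbp == rbp, c("rbp", "flank_id", "z_score")]
    names(sub) <- c("Protein", "Sequence_name", "Z_score")
    utils::write.table(sub, file.path(dir, paste0(rbp, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read RBPmap-style hit tables from a directory
#'
#' @param dir directory of `*.tsv` files written in the
#'   [write_rbp_hits()] layout.
#' @return event data.frame (`rbp`, `flank_id`, `z_score`).
#' @export
load_rbp_hits <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no hit tables under ", dir)
  out <- do.call(rbind, lapply(files, function(f) {
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    data.frame(rbp = as.character(tab$Protein),
               flank_id = as.character(tab$Sequence_name),
               z_score = as.numeric(tab$Z_score), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write peaks or flanks as BED6
#'
#' @param df interval data.frame; `name` defaults to `flank_id` or
#'   `rbp_cellline` when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path) {
  name <- if ("flank_id" %in% names(df)) df$flank_id
  else if (all(c("rbp", "cell_line") %in% names(df)))
    paste(df$rbp, df$cell_line, sep = "_")
  else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  tab <- data.frame(df$chrom, df$start, df$end, name, score, strand)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Apply the common-peak and FDR filters to in-memory peak records
#'
#' The in-memory analogue of what [load_dhm_peaks()] applies on ingest.
#'
#' @param peaks internal peak data.frame with a logical `common` column.
#' @param fdr_max FDR cutoff (default 0.05).
#' @return filtered peaks without the `common` column.
#' @export
prefilter_dhm <- function(peaks, fdr_max = 0.05) {
  out <- peaks[!peaks$common & peaks$fdr < fdr_max, , drop = FALSE]
  out$common <- NULL
  rownames(out) <- NULL
  out
}
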