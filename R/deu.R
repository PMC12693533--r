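#' Read an rMATS-style differential exon usage table
#'
#' Accepts the skipped-exon (`SE.MATS.JC.txt`) and mutually-exclusive-exon
#' (`MXE.MATS.JC.txt`) column dialects (tab-separated, header row; exon starts
#' 0-based, ends 1-based as written by rMATS). MXE events are expanded to one
#' record per constituent exon; the reported inclusion-level difference refers
#' to the first exon, so the second exon receives the opposite sign. Rows with
#' no supporting junction reads are dropped with a warning.
#'
#' @param path path to the table.
#' @return data.frame with one row per exon-level event: `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `gene_id`, `event_type` (`SE`/`MXE`),
#'   `delta_psi`, `p_value`, `fdr`, `inc_reads`, `skip_reads`.
#' @export
load_deu_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) return(empty_deu_df())
  cn <- names(tab)
  count_sum <- function(x) {
    vapply(strsplit(as.character(x), ","),
           function(v) sum(as.numeric(v), na.rm = TRUE), numeric(1))
  }
  inc <- count_sum(tab$IJC_SAMPLE_1) + count_sum(tab$IJC_SAMPLE_2)
  skp <- count_sum(tab$SJC_SAMPLE_1) + count_sum(tab$SJC_SAMPLE_2)
  base <- data.frame(
    gene_id = gsub('"', "", tab$GeneID),
    chrom = tab$chr,
    strand = tab$strand,
    delta_psi = as.numeric(tab$IncLevelDifference),
    p_value = as.numeric(tab$PValue),
    fdr = as.numeric(tab$FDR),
    inc_reads = as.integer(round(inc)),
    skip_reads = as.integer(round(skp)),
    stringsAsFactors = FALSE
  )
  if ("exonStart_0base" %in% cn) {
    rec <- cbind(base,
                 start = as.integer(tab$exonStart_0base),
                 end = as.integer(tab$exonEnd),
                 event_type = "SE")
  } else if ("1stExonStart_0base" %in% cn) {
    first <- cbind(base,
                   start = as.integer(tab[["1stExonStart_0base"]]),
                   end = as.integer(tab[["1stExonEnd"]]),
                   event_type = "MXE")
    second <- cbind(base,
                    start = as.integer(tab[["2ndExonStart_0base"]]),
                    end = as.integer(tab[["2ndExonEnd"]]),
                    event_type = "MXE")
    second$delta_psi <- -second$delta_psi
    rec <- rbind(first, second)
  } else {
    stop("unrecognized differential-exon-usage table layout: ", path)
  }
  no_reads <- rec$inc_reads + rec$skip_reads == 0L
  if (any(no_reads)) {
    warning(sum(no_reads), " event record(s) without junction-read support dropped")
    rec <- rec[!no_reads, , drop = FALSE]
  }
  if (any(abs(rec$delta_psi) > 1 + 1e-9, na.rm = TRUE)) {
    stop("delta PSI outside [-1, 1] in ", path)
  }
  rec <- rec[, names(empty_deu_df())]
  rownames(rec) <- NULL
  validate_intervals(rec)
  rec
}

empty_deu_df <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(),
             event_type = character(), delta_psi = numeric(),
             p_value = numeric(), fdr = numeric(), inc_reads = integer(),
             skip_reads = integer(), stringsAsFactors = FALSE)
}

#' Keep events with sufficient junction-read support
#'
#' @param records data.frame from [load_deu_table()].
#' @param min_reads minimum total (inclusion + skipping) junction reads
#'   (default 10, the setting used for the eCLIP validation workflow; pass 0
#'   for the unfiltered embryonic-style analysis).
#' @return filtered records.
#' @export
min_read_filter <- function(records, min_reads = 10) {
  records[records$inc_reads + records$skip_reads >= min_reads, , drop = FALSE]
}

#' Assign differential-usage scores to candidate exons
#'
#' An exon that coincides exactly (chrom, start, end, strand, gene) with a
#' qualifying event (`|delta_psi| >= deu_threshold` and `fdr < fdr_max`)
#' receives the event's delta PSI and is flagged alternative. All remaining
#' candidate exons of genes holding at least one such qualifying exon score 0.
#' Genes without a qualifying event are absent from the result. When two
#' qualifying records hit the same exon, the larger |delta PSI| wins (ties
#' logged via message).
#'
#' @param candidates candidate exon data.frame (already TSS-filtered).
#' @param records event data.frame from [load_deu_table()].
#' @param deu_threshold minimum |delta PSI| to call an exon alternative
#'   (default 0.2).
#' @param fdr_max FDR cutoff for qualifying events (default 0.05).
#' @return data.frame `exon_id`, `gene_id`, `deu_score`, `is_alternative`.
#' @export
assign_deu_scores <- function(candidates, records, deu_threshold = 0.2,
                              fdr_max = 0.05) {
  qual <- records[abs(records$delta_psi) >= deu_threshold &
                    records$fdr < fdr_max, , drop = FALSE]
  out0 <- data.frame(exon_id = character(), gene_id = character(),
                     deu_score = numeric(), is_alternative = logical(),
                     stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L || nrow(qual) == 0L) return(out0)
  ckey <- paste(candidates$chrom, candidates$start, candidates$end,
                candidates$strand, candidates$gene_id, sep = "\r")
  rkey <- paste(qual$chrom, qual$start, qual$end, qual$strand, qual$gene_id,
                sep = "\r")
  qual <- qual[rkey %in% ckey, , drop = FALSE]
  rkey <- rkey[rkey %in% ckey]
  if (nrow(qual) == 0L) return(out0)
  # conflict resolution: max |delta_psi| per exon, order-invariant
  o <- order(rkey, -abs(qual$delta_psi), qual$delta_psi)
  qual <- qual[o, , drop = FALSE]; rkey <- rkey[o]
  dup <- duplicated(rkey)
  if (any(dup)) {
    message(sum(dup), " conflicting event record(s) on the same exon resolved ",
            "by max |delta PSI|")
  }
  qual <- qual[!dup, , drop = FALSE]; rkey <- rkey[!dup]
  score <- stats::setNames(qual$delta_psi, rkey)
  genes <- unique(qual$gene_id)
  keep <- candidates$gene_id %in% genes
  cand <- candidates[keep, , drop = FALSE]
  s <- unname(score[paste(cand$chrom, cand$start, cand$end, cand$strand,
                          cand$gene_id, sep = "\r")])
  s[is.na(s)] <- 0
  data.frame(exon_id = cand$exon_id, gene_id = cand$gene_id, deu_score = s,
             is_alternative = abs(s) >= deu_threshold,
             stringsAsFactors = FALSE)
}

#' Extrapolate exon usage scores onto flanks
#'
#' Both flanks of an exon inherit the exon's DEU score unchanged; flanks of
#' exons absent from the score map (genes without a qualifying event) are
#' omitted.
#'
#' @param flanks flank data.frame from [extract_flanks()].
#' @param score_map data.frame from [assign_deu_scores()].
#' @return data.frame `flank_id`, `exon_id`, `gene_id`, `side`, `deu_score`,
#'   `is_alternative`.
#' @export
annotate_flanks_with_deu <- function(flanks, score_map) {
  m <- merge(flanks[, c("flank_id", "exon_id", "side")],
             score_map, by = "exon_id")
  m <- m[, c("flank_id", "exon_id", "gene_id", "side", "deu_score",
             "is_alternative")]
  m <- m[order(m$flank_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}
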