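#' Load gene annotation and apply the transcript-support filter
#'
#' Reads a GFF3 file (Gencode-style attributes: `gene_id`, `transcript_id`,
#' `transcript_support_level`) and returns the candidate-exon universe plus the
#' transcription start sites (TSS) of all transcripts.
#'
#' Only exons belonging to at least one transcript with support level (TSL)
#' `<= tsl_max` become candidate exons; the TSS set is taken from every
#' transcript with a valid TSL 1-5 regardless of `tsl_max`, because
#' TSS-proximity filtering must see starts of poorly supported transcripts too.
#' Transcripts without a parseable TSL attribute are skipped with a warning.
#'
#' @param gff3_path path to a GFF3 file with gene/transcript/exon features.
#' @param tsl_max highest transcript support level admitted for candidate
#'   exons (default 3).
#' @return list with elements
#'   \describe{
#'     \item{exons}{data.frame, one row per distinct
#'       (chrom, start, end, strand, gene_id): `chrom`, `start`, `end`
#'       (0-based half-open), `strand`, `gene_id`, `exon_id`, `tsl`
#'       (minimum over supporting transcripts), `transcript_ids`
#'       (comma-separated).}
#'     \item{tss}{data.frame `chrom`, `pos` (0-based coordinate of the
#'       strand-aware first transcribed base), `transcript_id`, `tsl`.}
#'   }
#' @export
load_annotation <- function(gff3_path, tsl_max = 3) {
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  if (length(gff) == 0L) {
    return(list(exons = empty_exon_df(), tss = empty_tss_df()))
  }
  meta <- S4Vectors::mcols(gff)
  type <- as.character(meta$type)

  is_tx <- type %in% c("transcript", "mRNA")
  tx <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gff))[is_tx],
    start = GenomicRanges::start(gff)[is_tx] - 1L,
    end   = GenomicRanges::end(gff)[is_tx],
    strand = as.character(GenomicRanges::strand(gff))[is_tx],
    transcript_id = as.character(meta$transcript_id[is_tx]),
    tsl_raw = if ("transcript_support_level" %in% names(meta))
      as.character(meta$transcript_support_level[is_tx]) else NA_character_,
    stringsAsFactors = FALSE
  )
  tx$tsl <- suppressWarnings(as.integer(sub("^([0-9]+).*", "\\1", tx$tsl_raw)))
  bad_tsl <- is.na(tx$tsl) | tx$tsl < 1L | tx$tsl > 5L
  if (any(bad_tsl)) {
    warning(sum(bad_tsl), " transcript(s) without a valid TSL attribute skipped")
    tx <- tx[!bad_tsl, , drop = FALSE]
  }
  if (nrow(tx) == 0L) {
    return(list(exons = empty_exon_df(), tss = empty_tss_df()))
  }

  tss <- data.frame(
    chrom = tx$chrom,
    pos = ifelse(tx$strand == "-", tx$end - 1L, tx$start),
    transcript_id = tx$transcript_id,
    tsl = tx$tsl,
    stringsAsFactors = FALSE
  )

  is_exon <- type == "exon"
  if (!any(is_exon)) {
    return(list(exons = empty_exon_df(), tss = tss))
  }
  ex <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gff))[is_exon],
    start = GenomicRanges::start(gff)[is_exon] - 1L,
    end   = GenomicRanges::end(gff)[is_exon],
    strand = as.character(GenomicRanges::strand(gff))[is_exon],
    gene_id = as.character(meta$gene_id[is_exon]),
    transcript_id = as.character(meta$transcript_id[is_exon]),
    stringsAsFactors = FALSE
  )
  ex <- merge(ex, tx[, c("transcript_id", "tsl")], by = "transcript_id")
  keep <- ex$tsl <= tsl_max
  ex <- ex[keep, , drop = FALSE]
  if (nrow(ex) == 0L) {
    return(list(exons = empty_exon_df(), tss = tss))
  }

  key <- paste(ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, sep = "\r")
  agg_tsl <- tapply(ex$tsl, key, min)
  agg_tx <- tapply(ex$transcript_id, key,
                   function(x) paste(sort(unique(x)), collapse = ","))
  first <- ex[!duplicated(key), , drop = FALSE]
  fkey <- key[!duplicated(key)]
  exons <- data.frame(
    chrom = first$chrom, start = first$start, end = first$end,
    strand = first$strand, gene_id = first$gene_id,
    tsl = as.integer(agg_tsl[fkey]),
    transcript_ids = as.character(agg_tx[fkey]),
    stringsAsFactors = FALSE
  )
  exons$exon_id <- make_exon_id(exons$gene_id, exons$chrom, exons$start,
                                exons$end, exons$strand)
  o <- order(exons$chrom, exons$start, exons$end, exons$gene_id)
  exons <- exons[o, , drop = FALSE]
  rownames(exons) <- NULL
  validate_intervals(exons)
  list(exons = exons, tss = tss[order(tss$chrom, tss$pos), , drop = FALSE])
}

# canonical exon / flank identifiers shared by the loader and the generator
make_exon_id <- function(gene_id, chrom, start, end, strand) {
  sprintf("%s:%s:%d-%d:%s", gene_id, chrom, as.integer(start),
          as.integer(end), strand)
}

make_flank_id <- function(gene_id, exon_id, side) {
  paste(gene_id, exon_id, side, sep = "|")
}

empty_exon_df <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(), tsl = integer(),
             transcript_ids = character(), exon_id = character(),
             stringsAsFactors = FALSE)
}

empty_tss_df <- function() {
  data.frame(chrom = character(), pos = integer(),
             transcript_id = character(), tsl = integer(),
             stringsAsFactors = FALSE)
}

#' Exclude exons near transcription start sites
#'
#' Removes exons with any base within `window` bp (inclusive) of any TSS, so
#' that chromatin signal tied to transcription initiation does not enter the
#' splicing analysis. Distance is measured from the nearest exon base to the
#' TSS base; an exon overlapping a TSS has distance 0.
#'
#' @param exons exon data.frame as produced by [load_annotation()].
#' @param tss data.frame with columns `chrom`, `pos` (0-based).
#' @param window maximum distance (bp) that still excludes an exon
#'   (default 200).
#' @return the retained subset of `exons`.
#' @export
exclude_tss_proximal <- function(exons, tss, window = 200) {
  stopifnot(window >= 0)
  if (nrow(exons) == 0L || nrow(tss) == 0L) return(exons)
  win <- data.frame(chrom = tss$chrom,
                    start = tss$pos - as.integer(window),
                    end = tss$pos + as.integer(window) + 1L)
  hits <- overlap_pairs(exons, win)
  drop <- unique(hits$a)
  out <- if (length(drop)) exons[-drop, , drop = FALSE] else exons
  rownames(out) <- NULL
  out
}

#' Extract the two flanking intervals of each candidate exon
#'
#' Builds the upstream and downstream `flank_size` bp intervals of every exon
#' in genomic orientation. `side` is genomic (`left`/`right`); `side_tx`
#' relabels them as `5prime`/`3prime` according to strand. Flanks that would
#' extend past the start of the contig are clipped and, by default, dropped.
#'
#' @param exons exon data.frame ([load_annotation()] output, any subset).
#' @param flank_size flank length in bp (default 200).
#' @param drop_clipped drop flanks shorter than `flank_size` after clipping
#'   at coordinate 0 (default TRUE; set FALSE to keep them flagged).
#' @return data.frame with one row per flank: interval columns, `gene_id`,
#'   `exon_id`, `side`, `side_tx`, `flank_id` (`gene|exon|side`), `clipped`.
#' @export
extract_flanks <- function(exons, flank_size = 200, drop_clipped = TRUE) {
  stopifnot(flank_size > 0)
  if (nrow(exons) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character(),
                      exon_id = character(), side = character(),
                      side_tx = character(), flank_id = character(),
                      clipped = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  fs <- as.integer(flank_size)
  left <- data.frame(
    chrom = exons$chrom, start = exons$start - fs, end = exons$start,
    strand = exons$strand, gene_id = exons$gene_id, exon_id = exons$exon_id,
    side = "left", stringsAsFactors = FALSE)
  right <- data.frame(
    chrom = exons$chrom, start = exons$end, end = exons$end + fs,
    strand = exons$strand, gene_id = exons$gene_id, exon_id = exons$exon_id,
    side = "right", stringsAsFactors = FALSE)
  out <- rbind(left, right)
  out$clipped <- out$start < 0L
  out$start <- pmax(out$start, 0L)
  # transcript-relative side: on '+' (and '.') the left flank is 5'
  plus <- out$strand != "-"
  out$side_tx <- ifelse((out$side == "left") == plus, "5prime", "3prime")
  out$flank_id <- paste(out$gene_id, out$exon_id, out$side, sep = "|")
  if (drop_clipped && any(out$clipped)) {
    out <- out[!out$clipped, , drop = FALSE]
  }
  out <- out[out$start < out$end, , drop = FALSE]
  o <- order(out$chrom, out$start, out$end, out$side)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  validate_intervals(out)
  out
}
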