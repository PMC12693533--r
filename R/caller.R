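#' Gene-wise correlation of absolute usage and histone-mark scores
#'
#' Pearson correlation (two-sided test) between the absolute DEU and absolute
#' DHM scores over the flanks of one gene. Genes offering fewer than
#' `min_flanks` flanks, or a constant vector on either side (correlation
#' undefined), are excluded with a reason rather than propagating NaN.
#'
#' @param abs_deu,abs_dhm non-negative score vectors, one entry per flank.
#' @param min_flanks minimum number of flanks required (default 3).
#' @return list with `r`, `p` (numeric, NA when excluded), `n`, and `reason`
#'   (`"ok"`, `"too_few_flanks"`, or `"constant_vector"`).
#' @export
gene_correlation <- function(abs_deu, abs_dhm, min_flanks = 3) {
  stopifnot(length(abs_deu) == length(abs_dhm))
  n <- length(abs_deu)
  if (n < min_flanks) {
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "too_few_flanks"))
  }
  if (stats::sd(abs_deu) == 0 || stats::sd(abs_dhm) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "constant_vector"))
  }
  ct <- stats::cor.test(abs_deu, abs_dhm, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, reason = "ok")
}

#' Call epispliced and non-epispliced genes for one mark and comparison
#'
#' For every gene carrying a DEU annotation, the absolute DEU and DHM scores
#' of its flanks (zeros included) are correlated; Benjamini-Hochberg
#' adjustment is applied across all tested genes of the batch (one mark, one
#' pairwise comparison). A gene is labelled
#' \describe{
#'   \item{epispliced}{`r >= r_min`, `p_fdr < fdr_max`, and every flank with a
#'     non-zero DHM score for this mark belongs to an alternative exon
#'     (non-zero DEU).}
#'   \item{non_epispliced}{the gene has at least one alternative exon and all
#'     of its flank DHM scores are zero — across all five marks when
#'     `dhm_all` is supplied, else for this mark alone.}
#'   \item{unclassified}{anything else (including genes excluded from the
#'     correlation that still carry DHM signal).}
#' }
#'
#' @param flank_table data.frame with columns `flank_id`, `exon_id`,
#'   `gene_id`, `deu_score`, `is_alternative`, `dhm_score` (the mark under
#'   study).
#' @param mark histone-mark label for the output.
#' @param r_min correlation threshold (default 0.5).
#' @param fdr_max BH-FDR threshold (default 0.05).
#' @param min_flanks minimum flanks per gene (default 3).
#' @param dhm_all optional long data.frame `flank_id`, `mark`, `dhm_score`
#'   covering every mark, used for the non-epispliced rule.
#' @return data.frame with one row per gene: `gene_id`, `mark`, `n_flanks`,
#'   `pearson_r`, `p_raw`, `p_fdr`, `label`, `epispliced_exons`
#'   (comma-separated ids, empty unless epispliced), `reason`.
#' @export
call_epispliced <- function(flank_table, mark, r_min = 0.5, fdr_max = 0.05,
                            min_flanks = 3, dhm_all = NULL) {
  stopifnot(all(c("flank_id", "exon_id", "gene_id", "deu_score",
                  "is_alternative", "dhm_score") %in% names(flank_table)))
  genes <- unique(flank_table$gene_id)
  if (length(genes) == 0L) {
    return(data.frame(gene_id = character(), mark = character(),
                      n_flanks = integer(), pearson_r = numeric(),
                      p_raw = numeric(), p_fdr = numeric(),
                      label = character(), epispliced_exons = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  per_gene <- split(flank_table, flank_table$gene_id)[genes]
  cors <- lapply(per_gene, function(g) {
    gene_correlation(abs(g$deu_score), abs(g$dhm_score), min_flanks)
  })
  out <- data.frame(
    gene_id = genes,
    mark = mark,
    n_flanks = vapply(cors, function(x) x$n, integer(1)),
    pearson_r = vapply(cors, function(x) x$r, numeric(1)),
    p_raw = vapply(cors, function(x) x$p, numeric(1)),
    reason = vapply(cors, function(x) x$reason, character(1)),
    stringsAsFactors = FALSE
  )
  out$p_fdr <- NA_real_
  tested <- !is.na(out$p_raw)
  out$p_fdr[tested] <- stats::p.adjust(out$p_raw[tested], method = "BH")

  # all-marks DHM presence per gene, for the non-epispliced rule
  zero_dhm_all <- vapply(per_gene, function(g) {
    if (is.null(dhm_all)) return(all(g$dhm_score == 0))
    all(dhm_all$dhm_score[dhm_all$flank_id %in% g$flank_id] == 0) &&
      all(g$dhm_score == 0)
  }, logical(1))
  has_alt <- vapply(per_gene, function(g) any(g$is_alternative), logical(1))
  alt_only_dhm <- vapply(per_gene, function(g) {
    all(g$deu_score[g$dhm_score != 0] != 0)
  }, logical(1))

  pass <- tested & !is.na(out$p_fdr) & out$pearson_r >= r_min &
    out$p_fdr < fdr_max & alt_only_dhm
  out$label <- ifelse(pass, "epispliced",
                      ifelse(zero_dhm_all & has_alt, "non_epispliced",
                             "unclassified"))
  out$epispliced_exons <- vapply(seq_along(genes), function(i) {
    if (out$label[i] != "epispliced") return("")
    g <- per_gene[[i]]
    paste(sort(unique(g$exon_id[g$is_alternative])), collapse = ",")
  }, character(1))
  out <- out[, c("gene_id", "mark", "n_flanks", "pearson_r", "p_raw", "p_fdr",
                 "label", "epispliced_exons", "reason")]
  rownames(out) <- NULL
  out
}

#' Flank-level class labels derived from gene calls
#'
#' Flanks of the alternative exons of epispliced genes are labelled
#' `epispliced`; flanks of the alternative exons of non-epispliced genes are
#' labelled `non_epispliced`. Other flanks are omitted.
#'
#' @param calls gene-level data.frame from [call_epispliced()].
#' @param flank_table the flank table the calls were made from.
#' @return data.frame `flank_id`, `gene_id`, `class`.
#' @export
flank_classes <- function(calls, flank_table) {
  lab <- stats::setNames(calls$label, calls$gene_id)
  ft <- flank_table[flank_table$is_alternative, , drop = FALSE]
  cls <- unname(lab[ft$gene_id])
  keep <- !is.na(cls) & cls %in% c("epispliced", "non_epispliced")
  data.frame(flank_id = ft$flank_id[keep], gene_id = ft$gene_id[keep],
             class = cls[keep], stringsAsFactors = FALSE)
}

#' Consolidate flank sets across pairwise comparisons
#'
#' The epispliced flank set is the union over comparisons of flanks of
#' epispliced exons. The control set holds flanks labelled non-epispliced in
#' at least `ceiling(control_frac * n)` of the `n` comparisons in which the
#' flank's gene was testable (appeared in that comparison's table); flanks
#' ever labelled epispliced are removed from the control set so the classes
#' never overlap.
#'
#' @param class_list list of per-comparison data.frames from
#'   [flank_classes()].
#' @param control_frac fraction of testable comparisons in which a control
#'   flank must be reported non-epispliced (default 0.7).
#' @return list with character vectors `epispliced` and `control`.
#' @export
consolidate_flank_sets <- function(class_list, control_frac = 0.7) {
  stopifnot(length(class_list) >= 1)
  epi <- sort(unique(unlist(lapply(class_list, function(d) {
    d$flank_id[d$class == "epispliced"]
  }))))
  all_flanks <- unique(unlist(lapply(class_list, function(d) d$flank_id)))
  gene_of <- do.call(rbind, class_list)
  gene_of <- gene_of[!duplicated(gene_of$flank_id), c("flank_id", "gene_id")]
  gmap <- stats::setNames(gene_of$gene_id, gene_of$flank_id)
  nonepi_count <- vapply(all_flanks, function(f) {
    sum(vapply(class_list, function(d) {
      any(d$flank_id == f & d$class == "non_epispliced")
    }, logical(1)))
  }, integer(1))
  testable <- vapply(all_flanks, function(f) {
    g <- gmap[[f]]
    sum(vapply(class_list, function(d) g %in% d$gene_id, logical(1)))
  }, integer(1))
  need <- ceiling(control_frac * testable)
  control <- sort(setdiff(all_flanks[nonepi_count >= need & testable > 0], epi))
  list(epispliced = epi, control = control)
}
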