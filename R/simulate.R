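# Synthetic-data generators. Every upstream file class consumed by the
# pipeline (GFF3 annotation, rMATS-style event tables, MAnorm-style peak
# tables, RBPmap-style hit tables, eCLIP BED) is emitted with planted ground
# truth so every stage is testable without downloads. All generators are
# deterministic per seed.

#' Generate a synthetic gene annotation with known TSS and candidate exons
#'
#' Lays out non-overlapping genes on two synthetic contigs with intron gaps
#' wide enough (>= 600 bp) that 200 bp flanks never touch a neighbouring
#' exon and no exon other than a transcript's first transcribed exon lies
#' within 200 bp of a TSS. Each gene has a main transcript with a mixed TSL
#' (mostly 1-3, some 4-5); a fraction of genes gains a second, shorter
#' transcript whose TSS sits on an internal exon of the main transcript,
#' exercising the TSS-proximity filter beyond first exons.
#'
#' @param n_genes number of genes (default 300).
#' @param exons_per_gene integer range `c(min, max)` of exons per gene
#'   (default `c(4, 7)`).
#' @param seed RNG seed.
#' @param extra_tx_frac fraction of genes with a second transcript
#'   (default 0.15).
#' @return list with `gff_lines` (character vector, a complete GFF3 file),
#'   `exons` (all exons: interval columns, `gene_id`, `exon_id`, `tsl`,
#'   `transcript_ids`), `tss` (`chrom`, `pos`, `transcript_id`, `tsl`),
#'   `candidate_ids` (exon ids expected to survive the TSL and TSS filters,
#'   from construction knowledge), `genes` (per-gene bookkeeping).
#' @export
generate_annotation <- function(n_genes = 300, exons_per_gene = c(4, 7),
                                seed = 1, extra_tx_frac = 0.15) {
  stopifnot(n_genes >= 1, length(exons_per_gene) == 2,
            exons_per_gene[1] >= 2)
  set.seed(seed)
  cursor <- c(chrS1 = 5000L, chrS2 = 5000L)
  exon_rows <- list(); tx_rows <- list(); gene_rows <- list()
  for (i in seq_len(n_genes)) {
    gene_id <- sprintf("GENE%04d", i)
    chrom <- names(cursor)[(i %% 2L) + 1L]
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1L)
    lens <- sample(80:300, n_ex, replace = TRUE)
    gaps <- sample(600:1200, n_ex - 1L, replace = TRUE)
    starts <- cursor[[chrom]] + cumsum(c(0L, lens[-n_ex] + gaps))
    ends <- starts + lens
    cursor[[chrom]] <- ends[n_ex] + 2000L
    tsl_main <- sample(1:5, 1L, prob = c(.3, .3, .3, .05, .05))
    main_tx <- paste0(gene_id, ".T1")
    exon_tx <- rep(list(main_tx), n_ex)
    exon_tsl <- rep(tsl_main, n_ex)
    txs <- data.frame(transcript_id = main_tx, gene_id = gene_id,
                      chrom = chrom, start = starts[1L], end = ends[n_ex],
                      strand = strand, tsl = tsl_main,
                      stringsAsFactors = FALSE)
    has_extra <- stats::runif(1) < extra_tx_frac && n_ex >= 3
    if (has_extra) {
      # second TSS lands on an internal exon of the main transcript
      idx <- if (strand == "+") 2:n_ex else 1:(n_ex - 1L)
      tsl2 <- sample(1:5, 1L)
      tx2 <- paste0(gene_id, ".T2")
      txs <- rbind(txs, data.frame(
        transcript_id = tx2, gene_id = gene_id, chrom = chrom,
        start = starts[idx[1L]], end = ends[idx[length(idx)]],
        strand = strand, tsl = tsl2, stringsAsFactors = FALSE))
      for (k in idx) {
        exon_tx[[k]] <- c(exon_tx[[k]], tx2)
        exon_tsl[k] <- min(exon_tsl[k], tsl2)
      }
    }
    # first transcribed exon of each transcript is TSS-adjacent by layout
    tss_exon <- if (strand == "+") 1L else n_ex
    tss_adjacent <- rep(FALSE, n_ex)
    tss_adjacent[tss_exon] <- TRUE
    if (has_extra) {
      tss_adjacent[if (strand == "+") 2L else n_ex - 1L] <- TRUE
    }
    exon_rows[[i]] <- data.frame(
      chrom = chrom, start = starts, end = ends, strand = strand,
      gene_id = gene_id,
      tsl = exon_tsl,
      transcript_ids = vapply(exon_tx, paste, "", collapse = ","),
      tss_adjacent = tss_adjacent,
      exon_index = seq_len(n_ex),
      stringsAsFactors = FALSE)
    tx_rows[[i]] <- txs
    gene_rows[[i]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                 start = starts[1L], end = ends[n_ex],
                                 strand = strand, n_exons = n_ex,
                                 tsl_main = tsl_main,
                                 stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, exon_rows)
  txs <- do.call(rbind, tx_rows)
  genes <- do.call(rbind, gene_rows)
  exons$exon_id <- make_exon_id(exons$gene_id, exons$chrom, exons$start,
                                exons$end, exons$strand)
  tss <- data.frame(
    chrom = txs$chrom,
    pos = ifelse(txs$strand == "-", txs$end - 1L, txs$start),
    transcript_id = txs$transcript_id, tsl = txs$tsl,
    stringsAsFactors = FALSE)
  candidate_ids <- exons$exon_id[exons$tsl <= 3L & !exons$tss_adjacent]

  gff <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gff <- c(gff, sprintf(
      "%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s",
      g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$gene_id))
    gt <- txs[txs$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(gt))) {
      t_ <- gt[j, ]
      gff <- c(gff, sprintf(
        "%s\tsynth\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;gene_id=%s;transcript_id=%s;transcript_support_level=%d",
        t_$chrom, t_$start + 1L, t_$end, t_$strand, t_$transcript_id,
        t_$gene_id, t_$gene_id, t_$transcript_id, t_$tsl))
      ge <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
      in_tx <- vapply(strsplit(ge$transcript_ids, ","),
                      function(v) t_$transcript_id %in% v, logical(1))
      ge <- ge[in_tx, , drop = FALSE]
      for (k in seq_len(nrow(ge))) {
        gff <- c(gff, sprintf(
          "%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tID=%s.ex%d;Parent=%s;gene_id=%s;transcript_id=%s;transcript_support_level=%d",
          ge$chrom[k], ge$start[k] + 1L, ge$end[k], ge$strand[k],
          t_$transcript_id, ge$exon_index[k], t_$transcript_id, t_$gene_id,
          t_$transcript_id, t_$tsl))
      }
    }
  }
  list(gff_lines = gff, exons = exons, tss = tss,
       candidate_ids = candidate_ids, genes = genes, transcripts = txs)
}

#' Assign planted gene classes over a synthetic annotation
#'
#' Genes eligible for planting need a main transcript with TSL 1-3 and at
#' least three candidate exons (so the gene-wise correlation is defined).
#' Eligible genes are split into: `epispliced` (with an assigned mark, two
#' planted alternative exons), `non_epispliced` (alternative exons, no
#' peaks), `sub_threshold` (events below the usage or FDR threshold),
#' `common_only` (peaks present in both conditions only), `uncorrelated`
#' (peaks also on constitutive exons, breaking the alternative-only rule)
#' and `constitutive_marked` (no usage events, marked exons; the
#' `!DEU & DHM` class).
#'
#' @param ann output of [generate_annotation()].
#' @param seed RNG seed.
#' @param frac named fractions of eligible genes per planted class; the
#'   remainder is `constitutive_marked`.
#' @return data.frame per eligible gene: `gene_id`, `class`, `mark`
#'   (epispliced and constitutive_marked only), `alt_exons` (comma-separated
#'   exon ids of the planted alternative or marked exons).
#' @export
assign_gene_classes <- function(ann, seed = 1,
                                frac = c(epispliced = 0.25,
                                         non_epispliced = 0.25,
                                         sub_threshold = 0.12,
                                         common_only = 0.12,
                                         uncorrelated = 0.12)) {
  set.seed(seed)
  cand <- ann$exons[ann$exons$exon_id %in% ann$candidate_ids, , drop = FALSE]
  n_cand <- table(cand$gene_id)
  eligible <- sort(names(n_cand)[n_cand >= 3])
  eligible <- eligible[ann$genes$tsl_main[match(eligible, ann$genes$gene_id)] <= 3L]
  n <- length(eligible)
  counts <- floor(frac * n)
  cls <- rep("constitutive_marked", n)
  pool <- sample(n)
  at <- 1L
  for (cname in names(counts)) {
    take <- counts[[cname]]
    cls[pool[seq.int(at, length.out = take)]] <- cname
    at <- at + take
  }
  out <- data.frame(gene_id = eligible, class = cls, stringsAsFactors = FALSE)
  out$mark <- NA_character_
  epi <- which(out$class == "epispliced")
  out$mark[epi] <- rep_len(HISTONE_MARKS, length(epi))
  cm <- which(out$class == "constitutive_marked")
  out$mark[cm] <- rep_len(HISTONE_MARKS, length(cm))
  out$alt_exons <- vapply(seq_len(nrow(out)), function(i) {
    ids <- cand$exon_id[cand$gene_id == out$gene_id[i]]
    paste(sort(sample(ids, 2L)), collapse = ",")
  }, character(1))
  out
}

#' Generate one pairwise comparison's usage events and differential peaks
#'
#' Emits an rMATS-style skipped-exon record set and per-mark MAnorm-style
#' peak sets for one pairwise comparison of the planted scene. Epispliced
#' genes receive qualifying usage events at their two planted alternative
#' exons and mark-specific peaks whose |M| tracks |delta PSI|
#' (`|M| = m_per_dpsi * |dPSI| + N(0, m_noise_sd)`), placed to cover the
#' exon and both flanks. Non-epispliced genes receive events (with
#' probability `nonepi_present`) and no peaks; distractor classes receive
#' sub-threshold events, common-only peaks, or peaks leaking onto
#' constitutive exons; constitutive-marked genes receive peaks without
#' events. A handful of TSS-overlapping and under-covering peaks exercise
#' the peak-leak filter.
#'
#' @param ann annotation from [generate_annotation()].
#' @param classes gene-class table from [assign_gene_classes()].
#' @param seed RNG seed (vary per comparison).
#' @param m_per_dpsi slope tying |M| to |delta PSI| (default 3).
#' @param m_noise_sd Gaussian noise sd on |M| (default 0.35).
#' @param nonepi_present probability a non-epispliced gene reports its
#'   events in this comparison (default 0.85).
#' @return list with `deu` (internal event record data.frame, see
#'   [load_deu_table()]) and `dhm` (named list per mark of internal peak
#'   data.frames, see [load_dhm_peaks()]).
#' @export
generate_deu_dhm <- function(ann, classes, seed = 1, m_per_dpsi = 3,
                             m_noise_sd = 0.35, nonepi_present = 0.85) {
  set.seed(seed)
  exons <- ann$exons
  deu <- list(); peaks <- stats::setNames(
    rep(list(list()), length(HISTONE_MARKS)), HISTONE_MARKS)

  event_row <- function(ex, dpsi, p, fdr) {
    total <- 40L + stats::rpois(1, 20)
    psi1 <- stats::runif(1, 0.2, 0.8)
    inc <- as.integer(round(total * mean(c(psi1, min(1, max(0, psi1 - dpsi))))))
    data.frame(chrom = ex$chrom, start = ex$start, end = ex$end,
               strand = ex$strand, gene_id = ex$gene_id, event_type = "SE",
               delta_psi = dpsi, p_value = p, fdr = fdr,
               inc_reads = inc, skip_reads = total - inc,
               stringsAsFactors = FALSE)
  }
  peak_row <- function(ex, m, fdr = stats::runif(1, 1e-4, 0.04),
                       pad = 120L, common = FALSE) {
    data.frame(chrom = ex$chrom, start = ex$start - pad, end = ex$end + pad,
               m_value = m, p_value = fdr / 2, fdr = fdr,
               common = common, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(classes))) {
    g <- classes[i, ]
    alt <- exons[exons$exon_id %in% strsplit(g$alt_exons, ",")[[1]], ,
                 drop = FALSE]
    if (g$class == "epispliced") {
      for (k in seq_len(nrow(alt))) {
        dpsi <- sample(c(-1, 1), 1) * stats::runif(1, 0.25, 0.8)
        p <- stats::runif(1, 1e-6, 1e-3)
        deu[[length(deu) + 1L]] <- event_row(alt[k, ], dpsi, p, min(p * 20, 0.04))
        m_abs <- max(0.2, m_per_dpsi * abs(dpsi) + stats::rnorm(1, 0, m_noise_sd))
        m <- sample(c(-1, 1), 1) * m_abs
        peaks[[g$mark]][[length(peaks[[g$mark]]) + 1L]] <- peak_row(alt[k, ], m)
      }
    } else if (g$class == "non_epispliced") {
      if (stats::runif(1) < nonepi_present) {
        for (k in seq_len(nrow(alt))) {
          dpsi <- sample(c(-1, 1), 1) * stats::runif(1, 0.25, 0.8)
          p <- stats::runif(1, 1e-6, 1e-3)
          deu[[length(deu) + 1L]] <- event_row(alt[k, ], dpsi, p, min(p * 20, 0.04))
        }
      }
    } else if (g$class == "sub_threshold") {
      for (k in seq_len(nrow(alt))) {
        if (stats::runif(1) < 0.5) {
          dpsi <- sample(c(-1, 1), 1) * stats::runif(1, 0.03, 0.15)
          p <- stats::runif(1, 1e-4, 0.01)
          deu[[length(deu) + 1L]] <- event_row(alt[k, ], dpsi, p, p * 4)
        } else {
          dpsi <- sample(c(-1, 1), 1) * stats::runif(1, 0.25, 0.6)
          deu[[length(deu) + 1L]] <- event_row(alt[k, ], dpsi, 0.4, 0.7)
        }
      }
    } else if (g$class == "common_only") {
      mark <- sample(HISTONE_MARKS, 1L)
      for (k in seq_len(nrow(alt))) {
        dpsi <- sample(c(-1, 1), 1) * stats::runif(1, 0.25, 0.8)
        p <- stats::runif(1, 1e-6, 1e-3)
        deu[[length(deu) + 1L]] <- event_row(alt[k, ], dpsi, p, min(p * 20, 0.04))
        peaks[[mark]][[length(peaks[[mark]]) + 1L]] <-
          peak_row(alt[k, ], stats::rnorm(1, 0, 1.5), common = TRUE)
      }
    } else if (g$class == "uncorrelated") {
      mark <- sample(HISTONE_MARKS, 1L)
      gc <- exons[exons$gene_id == g$gene_id &
                    exons$exon_id %in% ann$candidate_ids, , drop = FALSE]
      zero_ex <- gc[!(gc$exon_id %in% alt$exon_id), , drop = FALSE][1L, ]
      for (k in seq_len(nrow(alt))) {
        dpsi <- sample(c(-1, 1), 1) * stats::runif(1, 0.25, 0.8)
        p <- stats::runif(1, 1e-6, 1e-3)
        deu[[length(deu) + 1L]] <- event_row(alt[k, ], dpsi, p, min(p * 20, 0.04))
        peaks[[mark]][[length(peaks[[mark]]) + 1L]] <-
          peak_row(alt[k, ], sample(c(-1, 1), 1) * stats::runif(1, 0.3, 3))
      }
      # the leak onto a zero-usage exon breaks the alternative-only rule
      peaks[[mark]][[length(peaks[[mark]]) + 1L]] <-
        peak_row(zero_ex, sample(c(-1, 1), 1) * stats::runif(1, 0.5, 3))
    } else if (g$class == "constitutive_marked") {
      gc <- exons[exons$gene_id == g$gene_id &
                    exons$exon_id %in% ann$candidate_ids, , drop = FALSE]
      pick <- gc[sample(nrow(gc), min(2L, nrow(gc))), , drop = FALSE]
      for (k in seq_len(nrow(pick))) {
        peaks[[g$mark]][[length(peaks[[g$mark]]) + 1L]] <-
          peak_row(pick[k, ], sample(c(-1, 1), 1) * stats::runif(1, 0.5, 3))
      }
    }
  }
  # peak-leak exercisers: TSS-exon-overlapping peaks and sub-half-coverage
  first_ex <- exons[exons$tss_adjacent, , drop = FALSE]
  leak <- first_ex[sample(nrow(first_ex), min(10L, nrow(first_ex))), ,
                   drop = FALSE]
  for (k in seq_len(nrow(leak))) {
    mark <- sample(HISTONE_MARKS, 1L)
    peaks[[mark]][[length(peaks[[mark]]) + 1L]] <-
      peak_row(leak[k, ], stats::rnorm(1, 0, 2))
  }
  cand <- exons[exons$exon_id %in% ann$candidate_ids, , drop = FALSE]
  thin <- cand[sample(nrow(cand), min(10L, nrow(cand))), , drop = FALSE]
  for (k in seq_len(nrow(thin))) {
    mark <- sample(HISTONE_MARKS, 1L)
    ex <- thin[k, ]
    width <- floor((ex$end - ex$start) * 0.3)     # covers < half the exon
    p <- data.frame(chrom = ex$chrom, start = ex$start - 50L,
                    end = ex$start + width, m_value = stats::rnorm(1, 0, 2),
                    p_value = 0.001, fdr = 0.002, common = FALSE,
                    stringsAsFactors = FALSE)
    peaks[[mark]][[length(peaks[[mark]]) + 1L]] <- p
  }
  dhm <- lapply(names(peaks), function(m) {
    if (!length(peaks[[m]])) return(cbind(empty_dhm_df(), common = logical()))
    d <- do.call(rbind, peaks[[m]])
    d$mark <- m
    d[, c("chrom", "start", "end", "mark", "m_value", "p_value", "fdr",
          "common")]
  })
  names(dhm) <- names(peaks)
  deu <- if (length(deu)) do.call(rbind, deu) else empty_deu_df()
  rownames(deu) <- NULL
  list(deu = deu, dhm = dhm)
}

#' Generate RBP binding events and eCLIP peaks with planted signal
#'
#' Background binding sites are drawn per (RBP, flank) with probability
#' `p_event` and Z ~ Normal(1.5, 0.8) truncated at 0, so only a minority
#' exceed the Z >= 2 binding threshold. Planted discriminative RBPs gain
#' `dz_plant` on flanks listed in `shifted_flanks` (and half that on
#' `half_shifted_flanks`, the constitutive-marked class). The last two
#' planted RBPs form a collinear pair: the final one has no independent
#' signal, its scores copy its partner's with small jitter, which is what
#' the correlation-expansion step is meant to recover. eCLIP peaks are
#' placed uniformly over the synthetic genome at `eclip_background` peaks
#' per contig plus one peak per validated flank.
#'
#' @param flank_ids character vector of all flank ids to emit events for.
#' @param shifted_flanks flank ids carrying the full planted shift.
#' @param n_rbps panel size (default 160).
#' @param n_planted number of discriminative RBPs (default 10).
#' @param dz_plant Z-score shift of planted RBPs on shifted flanks
#'   (default 2).
#' @param half_shifted_flanks flank ids receiving `dz_plant / 2`
#'   (default none).
#' @param p_event probability that a given (RBP, flank) reports a site
#'   (default 0.7).
#' @param seed RNG seed.
#' @return list with `events` (`rbp`, `flank_id`, `z_score`), `panel`
#'   (RBP names), `planted` (planted RBP names; the last entry is the
#'   collinear copy of the second-to-last).
#' @export
generate_binding <- function(flank_ids, shifted_flanks, n_rbps = 160,
                             n_planted = 10, dz_plant = 2.0,
                             half_shifted_flanks = character(),
                             p_event = 0.7, seed = 1) {
  stopifnot(n_rbps >= n_planted, n_planted >= 2)
  set.seed(seed)
  panel <- sprintf("RBP%03d", seq_len(n_rbps))
  planted <- panel[seq_len(n_planted)]
  nf <- length(flank_ids)
  shift <- numeric(nf)
  shift[flank_ids %in% shifted_flanks] <- dz_plant
  shift[flank_ids %in% half_shifted_flanks] <- dz_plant / 2
  ev <- list()
  for (j in seq_len(n_rbps)) {
    rbp <- panel[j]
    has <- stats::runif(nf) < p_event
    if (!any(has)) next
    z <- pmax(0, stats::rnorm(sum(has), 1.5, 0.8))
    if (rbp %in% planted[-n_planted]) {
      z <- z + shift[has] * (if (rbp == planted[n_planted - 1L]) 1 else
        stats::runif(1, 0.8, 1.2))
    }
    ev[[rbp]] <- data.frame(rbp = rbp, flank_id = flank_ids[has],
                            z_score = z, stringsAsFactors = FALSE)
  }
  # collinear partner: copies the second-to-last planted RBP's sites
  src <- ev[[planted[n_planted - 1L]]]
  ev[[planted[n_planted]]] <- data.frame(
    rbp = planted[n_planted], flank_id = src$flank_id,
    z_score = pmax(0, src$z_score + stats::rnorm(nrow(src), 0, 0.15)),
    stringsAsFactors = FALSE)
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  list(events = events, panel = panel, planted = planted)
}

#' Generate eCLIP peaks over the synthetic genome
#'
#' Places `n_background` peaks uniformly per contig and one planted peak in
#' each interval of `at_flanks`, with the given RBP and cell-line labels.
#'
#' @param contig_lengths named integer vector of contig lengths.
#' @param at_flanks interval data.frame of flanks to plant peaks in (may be
#'   empty); a `cell_line` column, if present, is carried through.
#' @param rbp RBP name for all peaks.
#' @param cell_line default cell-line label.
#' @param n_background uniform background peaks per contig (default 200).
#' @param peak_width width of generated peaks in bp (default 60).
#' @param seed RNG seed.
#' @return eCLIP peak data.frame (`chrom`, `start`, `end`, `rbp`,
#'   `cell_line`, `score`, `strand`).
#' @export
generate_eclip <- function(contig_lengths, at_flanks = NULL, rbp = "RBP001",
                           cell_line = "cellA", n_background = 200,
                           peak_width = 60, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (chrom in names(contig_lengths)) {
    s <- sort(sample.int(contig_lengths[[chrom]] - peak_width, n_background))
    rows[[chrom]] <- data.frame(chrom = chrom, start = s,
                                end = s + peak_width, rbp = rbp,
                                cell_line = cell_line, score = 1,
                                strand = ".", stringsAsFactors = FALSE)
  }
  if (!is.null(at_flanks) && nrow(at_flanks)) {
    mid <- (at_flanks$start + at_flanks$end) %/% 2L
    rows[["planted"]] <- data.frame(
      chrom = at_flanks$chrom,
      start = mid - peak_width %/% 2L,
      end = mid + peak_width %/% 2L,
      rbp = rbp,
      cell_line = if ("cell_line" %in% names(at_flanks))
        at_flanks$cell_line else cell_line,
      score = 2, strand = ".", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic scene
#'
#' Bundles annotation, gene classes and `n_comparisons` pairwise
#' usage/peak comparisons into one object. The default scene (300 genes,
#' 5 marks, 160 RBPs, 10 comparisons, ~2000 candidate flanks) is sized for
#' single-CPU runs of the full pipeline in a few minutes.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_genes,exons_per_gene passed to [generate_annotation()].
#' @param n_comparisons number of pairwise comparisons (default 10).
#' @param m_per_dpsi,m_noise_sd,nonepi_present passed to
#'   [generate_deu_dhm()].
#' @return list `ann`, `classes`, `comparisons` (list of
#'   [generate_deu_dhm()] outputs), `seed`.
#' @export
simulate_scene <- function(seed = 1, n_genes = 300, exons_per_gene = c(4, 7),
                           n_comparisons = 10, m_per_dpsi = 3,
                           m_noise_sd = 0.35, nonepi_present = 0.85) {
  ann <- generate_annotation(n_genes, exons_per_gene, seed = seed)
  classes <- assign_gene_classes(ann, seed = seed + 1L)
  comparisons <- lapply(seq_len(n_comparisons), function(c_) {
    generate_deu_dhm(ann, classes, seed = seed + 10L + c_,
                     m_per_dpsi = m_per_dpsi, m_noise_sd = m_noise_sd,
                     nonepi_present = nonepi_present)
  })
  list(ann = ann, classes = classes, comparisons = comparisons, seed = seed)
}
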