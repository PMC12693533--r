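# End-to-end orchestration: wiring the module functions over a synthetic
# scene (or equivalently over loaded tool tables) into per-comparison calls,
# consolidated flank sets, feature matrices, and performance measures.

#' Candidate exons and flanks from an exon universe
#'
#' Applies the TSL filter, the TSS-proximity exclusion and flank extraction
#' in one step.
#'
#' @param exons exon data.frame carrying a `tsl` column (from
#'   [load_annotation()] or [generate_annotation()]).
#' @param tss TSS data.frame (`chrom`, `pos`).
#' @param tsl_max,tss_window,flank_size filter parameters (defaults 3, 200,
#'   200).
#' @return list `candidates` (exon data.frame) and `flanks`
#'   ([extract_flanks()] output).
#' @export
candidate_flanks <- function(exons, tss, tsl_max = 3, tss_window = 200,
                             flank_size = 200) {
  supported <- exons[exons$tsl <= tsl_max, , drop = FALSE]
  candidates <- exclude_tss_proximal(supported, tss, window = tss_window)
  flanks <- extract_flanks(candidates, flank_size = flank_size)
  list(candidates = candidates, flanks = flanks)
}

#' Build the per-mark flank score table for one pairwise comparison
#'
#' Runs usage-score assignment, peak-leak filtering and flank annotation for
#' every histone mark, and returns the merged flank table used by the caller.
#'
#' @param cf [candidate_flanks()] output.
#' @param deu_records internal usage-event records.
#' @param dhm_by_mark named list of internal peak data.frames (one per mark,
#'   already common/FDR-filtered, e.g. via [prefilter_dhm()] or
#'   [load_dhm_peaks()]).
#' @param exons_all the unfiltered exon universe (TSS-proximal exons
#'   included), for peak-leak detection.
#' @param tss TSS data.frame.
#' @param deu_threshold,fdr_max,min_reads usage-score parameters; see
#'   [assign_deu_scores()] and [min_read_filter()].
#' @return list `tables` (named per mark: flank table with `dhm_score` for
#'   that mark) and `dhm_all` (long data.frame over all marks).
#' @export
comparison_tables <- function(cf, deu_records, dhm_by_mark, exons_all, tss,
                              deu_threshold = 0.2, fdr_max = 0.05,
                              min_reads = 0) {
  recs <- min_read_filter(deu_records, min_reads)
  score_map <- assign_deu_scores(cf$candidates, recs,
                                 deu_threshold = deu_threshold,
                                 fdr_max = fdr_max)
  deu_fl <- annotate_flanks_with_deu(cf$flanks, score_map)
  dhm_long <- list()
  for (mark in names(dhm_by_mark)) {
    pk <- peak_leak_filter(dhm_by_mark[[mark]], exons_all, tss)
    dhm_long[[mark]] <- annotate_flanks_with_dhm(cf$flanks, pk, mark)
  }
  dhm_all <- do.call(rbind, dhm_long)
  rownames(dhm_all) <- NULL
  tables <- lapply(names(dhm_by_mark), function(mark) {
    d <- dhm_long[[mark]]
    m <- merge(deu_fl, d[, c("flank_id", "dhm_score")], by = "flank_id")
    m[order(m$flank_id), , drop = FALSE]
  })
  names(tables) <- names(dhm_by_mark)
  list(tables = tables, dhm_all = dhm_all)
}

#' Run the episplicing caller over every comparison and mark of a scene
#'
#' @param scene [simulate_scene()] output.
#' @param r_min,fdr_max,min_flanks caller thresholds (defaults 0.5, 0.05, 3).
#' @return list with `calls` (comparisons x marks, gene-level data.frames)
#'   and `classes` (comparisons x marks, flank-level class data.frames), and
#'   `cf` (shared candidate flanks).
#' @export
run_scene_calls <- function(scene, r_min = 0.5, fdr_max = 0.05,
                            min_flanks = 3) {
  cf <- candidate_flanks(scene$ann$exons, scene$ann$tss)
  calls <- list(); classes <- list()
  for (ci in seq_along(scene$comparisons)) {
    comp <- scene$comparisons[[ci]]
    dhm <- lapply(comp$dhm, prefilter_dhm)
    ct <- comparison_tables(cf, comp$deu, dhm, scene$ann$exons,
                            scene$ann$tss)
    calls[[ci]] <- lapply(names(ct$tables), function(mark) {
      call_epispliced(ct$tables[[mark]], mark, r_min = r_min,
                      fdr_max = fdr_max, min_flanks = min_flanks,
                      dhm_all = ct$dhm_all)
    })
    names(calls[[ci]]) <- names(ct$tables)
    classes[[ci]] <- lapply(names(ct$tables), function(mark) {
      flank_classes(calls[[ci]][[mark]], ct$tables[[mark]])
    })
    names(classes[[ci]]) <- names(ct$tables)
  }
  list(calls = calls, classes = classes, cf = cf)
}

#' Sensitivity and specificity of the caller against planted truth
#'
#' Pooled over all comparisons: sensitivity is the fraction of planted
#' (epispliced gene, its mark) instances called epispliced; specificity is
#' the fraction of other tested gene-mark instances not called epispliced.
#'
#' @param scene the scene.
#' @param calls `calls` element of [run_scene_calls()].
#' @return list `sensitivity`, `specificity`, `n_planted`, `n_other`.
#' @export
caller_performance <- function(scene, calls) {
  truth <- scene$classes
  epi_key <- paste(truth$gene_id[truth$class == "epispliced"],
                   truth$mark[truth$class == "epispliced"])
  tp <- 0L; fn <- 0L; fp <- 0L; tn <- 0L
  for (comp in calls) {
    for (mark in names(comp)) {
      d <- comp[[mark]]
      key <- paste(d$gene_id, mark)
      planted <- key %in% epi_key
      called <- d$label == "epispliced"
      tp <- tp + sum(planted & called)
      fn <- fn + sum(planted & !called)
      fp <- fp + sum(!planted & called)
      tn <- tn + sum(!planted & !called)
    }
  }
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       n_planted = tp + fn, n_other = fp + tn)
}

#' Consolidated per-mark flank sets of a scene
#'
#' @param classes `classes` element of [run_scene_calls()].
#' @param mark histone mark.
#' @param control_frac control consolidation fraction (default 0.7).
#' @return [consolidate_flank_sets()] output.
#' @export
scene_flank_sets <- function(classes, mark, control_frac = 0.7) {
  consolidate_flank_sets(lapply(classes, `[[`, mark),
                         control_frac = control_frac)
}

#' Flank ids of the planted alternative exons of a gene-class subset
#'
#' @param scene the scene, or its `classes` data.frame (the truth manifest).
#' @param class_name planted class (e.g. `"epispliced"`).
#' @return character vector of flank ids (both sides of each planted exon).
#' @export
truth_class_flanks <- function(scene, class_name) {
  classes <- if (is.data.frame(scene)) scene else scene$classes
  cl <- classes[classes$class == class_name, , drop = FALSE]
  if (!nrow(cl)) return(character())
  ex <- unlist(strsplit(cl$alt_exons, ","))
  gene <- rep(cl$gene_id, lengths(strsplit(cl$alt_exons, ",")))
  c(make_flank_id(gene, ex, "left"), make_flank_id(gene, ex, "right"))
}

#' Binding matrix and class matrices for one mark of a scene
#'
#' Consolidates the mark's epispliced and control flank sets, generates the
#' planted binding events over them (full shift on true epispliced flanks,
#' half shift on constitutive-marked flanks) and assembles the labelled
#' feature matrix plus the three per-class matrices used by the Welch
#' comparisons.
#'
#' @param scene the scene.
#' @param classes `classes` element of [run_scene_calls()].
#' @param mark histone mark to model.
#' @param n_rbps,n_planted,dz_plant,p_event generator knobs (see
#'   [generate_binding()]).
#' @param z_min binding threshold (default 2).
#' @param seed RNG seed for the binding generator.
#' @return list `matrix` (x, y from [build_feature_matrix()]), `events`,
#'   `planted`, `panel`, `class_matrices` (named list `DEU_DHM`,
#'   `DEU_noDHM`, `noDEU_DHM`), `sets` (the consolidated flank sets).
#' @export
scene_feature_matrix <- function(scene, classes, mark, n_rbps = 160,
                                 n_planted = 10, dz_plant = 2.0,
                                 p_event = 0.7, z_min = 2.0, seed = 1) {
  sets <- scene_flank_sets(classes, mark)
  const_fl <- truth_class_flanks(scene, "constitutive_marked")
  all_fl <- unique(c(sets$epispliced, sets$control, const_fl))
  shifted <- intersect(all_fl, truth_class_flanks(scene, "epispliced"))
  gb <- generate_binding(all_fl, shifted_flanks = shifted, n_rbps = n_rbps,
                         n_planted = n_planted, dz_plant = dz_plant,
                         half_shifted_flanks = intersect(all_fl, const_fl),
                         p_event = p_event, seed = seed)
  labels <- rbind(
    data.frame(flank_id = sets$epispliced, label = "epispliced"),
    data.frame(flank_id = sets$control, label = "control"))
  bm <- build_feature_matrix(
    gb$events[gb$events$flank_id %in% labels$flank_id, ], labels,
    rbp_panel = gb$panel, z_min = z_min)
  class_mat <- function(fl) {
    if (!length(fl)) return(NULL)
    lab <- data.frame(flank_id = fl, label = "control")
    build_feature_matrix(gb$events[gb$events$flank_id %in% fl, ], lab,
                         rbp_panel = gb$panel, z_min = z_min)$x
  }
  list(matrix = bm, events = gb$events, planted = gb$planted,
       panel = gb$panel,
       class_matrices = list(
         DEU_DHM = bm$x[bm$y == "epispliced", , drop = FALSE],
         DEU_noDHM = bm$x[bm$y == "control", , drop = FALSE],
         noDEU_DHM = class_mat(const_fl)),
       sets = sets)
}
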