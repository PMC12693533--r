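#!/usr/bin/env Rscript
# Per-mark RBP classification: consolidate epispliced and control flank sets
# across the comparisons, generate the planted RBP binding events over them,
# build the flanks x RBPs matrix, train the cross-validated random forest,
# derive episplicing / non-episplicing RBP sets from held-out Shapley
# attributions plus correlation expansion, and run the three-class Welch
# comparisons. H3K36me3 is modelled here; swap `mark` for the others.

suppressMessages(library(episplicer))

out <- "results"
mark <- "H3K36me3"
seed <- 1

classes <- read.delim(file.path(out, "flank_classes.tsv"))
truth <- jsonlite::read_json(file.path(out, "scene/truth.json"),
                             simplifyVector = TRUE)$classes

class_list <- lapply(split(classes[classes$mark == mark, ],
                           classes$comparison[classes$mark == mark]),
                     function(d) d[, c("flank_id", "gene_id", "class")])
sets <- consolidate_flank_sets(class_list, control_frac = 0.7)
cat(mark, "consolidated flank sets:", length(sets$epispliced), "epispliced,",
    length(sets$control), "control\n")

const_fl <- truth_class_flanks(truth, "constitutive_marked")
all_fl <- unique(c(sets$epispliced, sets$control, const_fl))
gb <- generate_binding(all_fl,
                       shifted_flanks = truth_class_flanks(truth, "epispliced"),
                       half_shifted_flanks = const_fl, seed = seed + 100)
write_rbp_hits(gb$events, file.path(out, "rbp_hits"))
events <- load_rbp_hits(file.path(out, "rbp_hits"))

labels <- rbind(data.frame(flank_id = sets$epispliced, label = "epispliced"),
                data.frame(flank_id = sets$control, label = "control"))
bm <- build_feature_matrix(events[events$flank_id %in% labels$flank_id, ],
                           labels, rbp_panel = gb$panel, z_min = 2)
cat("Feature matrix:", nrow(bm$x), "flanks x", ncol(bm$x), "RBPs;",
    sum(bm$y == "epispliced"), "positive\n")

fit <- train_evaluate(bm$x, bm$y, n_trees = 200, folds = 5, repeats = 10,
                      seed = seed)
print(fit)
write.table(fit$per_fold, file.path(out, "rf_fold_metrics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

at <- shap_attribution(fit, n_perm = 6, seed = seed)
sel <- select_rbps(at$summary, bm$x, top_k = 10)
cat("Episplicing RBPs:", paste(sel$episplicing, collapse = " "), "\n")
cat("Non-episplicing RBPs:", paste(sel$non_episplicing, collapse = " "), "\n")
cat("Expansion added",
    sum(sel$expansion_log$action == "expanded"), "RBP(s) by correlation\n")
cat("Planted RBPs recovered:",
    sum(gb$planted %in% union(sel$episplicing, sel$seed_episplicing)),
    "of", length(gb$planted), "\n")

summ <- merge(at$summary,
              data.frame(rbp = c(sel$episplicing, sel$non_episplicing),
                         set = rep(c("episplicing", "non_episplicing"),
                                   c(length(sel$episplicing),
                                     length(sel$non_episplicing)))),
              by = "rbp", all.x = TRUE)
write.table(summ[order(-summ$mean_abs_shap), ],
            file.path(out, "rbp_selection.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cm <- list(
  DEU_DHM = bm$x[bm$y == "epispliced", , drop = FALSE],
  DEU_noDHM = bm$x[bm$y == "control", , drop = FALSE],
  noDEU_DHM = build_feature_matrix(
    events[events$flank_id %in% const_fl, ],
    data.frame(flank_id = intersect(const_fl, unique(events$flank_id)),
               label = "control"),
    rbp_panel = gb$panel, z_min = 2)$x)
wt <- welch_compare(sel, cm)
write.table(wt, file.path(out, "welch_exon_classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nWelch comparisons across exon classes:\n")
print(wt[, c("set", "class1", "class2", "t", "p_fdr", "signif")])
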