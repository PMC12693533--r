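#!/usr/bin/env Rscript
# Per-comparison, per-mark episplicing calls: annotate candidate flanks with
# usage (delta PSI) and histone-mark (M-value) scores, correlate |DEU| with
# |DHM| gene-wise, and label epispliced / non-epispliced genes. Writes the
# gene-level call tables and the flank-level class tables.

suppressMessages(library(episplicer))

scene_dir <- "results/scene"
out <- "results"
marks <- c("H3K27ac", "H3K27me3", "H3K36me3", "H3K9me3", "H3K4me3")

exons_all <- read.delim(file.path(out, "all_exons.tsv"))
tss <- read.delim(file.path(out, "tss.tsv"))
candidates <- read.delim(file.path(out, "candidate_exons.tsv"))
flanks <- read.delim(file.path(out, "candidate_flanks.tsv"))
cf <- list(candidates = candidates, flanks = flanks)

deu_files <- sort(list.files(scene_dir, pattern = "SE\\.MATS\\.JC\\.txt$",
                             full.names = TRUE))
all_calls <- list(); all_classes <- list()
for (ci in seq_along(deu_files)) {
  deu <- load_deu_table(deu_files[ci])
  dhm <- lapply(marks, function(m) {
    load_dhm_peaks(file.path(scene_dir,
                             sprintf("comp%02d_%s_MAvalues.tsv", ci, m)), m)
  })
  names(dhm) <- marks
  ct <- comparison_tables(cf, deu, dhm, exons_all, tss)
  for (mark in marks) {
    calls <- call_epispliced(ct$tables[[mark]], mark, dhm_all = ct$dhm_all)
    calls$comparison <- ci
    all_calls[[length(all_calls) + 1L]] <- calls
    fc <- flank_classes(calls, ct$tables[[mark]])
    if (nrow(fc)) {
      fc$comparison <- ci; fc$mark <- mark
      all_classes[[length(all_classes) + 1L]] <- fc
    }
  }
  cat(sprintf("comparison %02d: %d genes tested, %d epispliced calls\n", ci,
              length(unique(ct$tables[[1]]$gene_id)),
              sum(vapply(all_calls[(length(all_calls) - 4):length(all_calls)],
                         function(d) sum(d$label == "epispliced"), 0L))))
}
calls <- do.call(rbind, all_calls)
classes <- do.call(rbind, all_classes)
write.table(calls, file.path(out, "episplicing_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(classes, file.path(out, "flank_classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nEpispliced gene calls per mark (all comparisons pooled):\n")
print(table(calls$mark[calls$label == "epispliced"]))

truth <- jsonlite::read_json(file.path(scene_dir, "truth.json"),
                             simplifyVector = TRUE)$classes
epi_key <- paste(truth$gene_id[truth$class == "epispliced"],
                 truth$mark[truth$class == "epispliced"])
key <- paste(calls$gene_id, calls$mark)
tp <- sum(key %in% epi_key & calls$label == "epispliced")
fn <- sum(key %in% epi_key & calls$label != "epispliced")
fp <- sum(!(key %in% epi_key) & calls$label == "epispliced")
tn <- sum(!(key %in% epi_key) & calls$label != "epispliced")
cat(sprintf("\nRecovery of planted epispliced genes: sensitivity %.3f, specificity %.3f\n",
            tp / (tp + fn), tn / (tn + fp)))
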