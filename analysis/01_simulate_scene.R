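#!/usr/bin/env Rscript
# Generate the synthetic study scene: a GFF3 annotation, one rMATS-style
# skipped-exon table and five MAnorm-style peak tables per pairwise
# comparison, and the planted-truth manifest. Everything downstream
# (02-06) reads only the files written here.

suppressMessages(library(episplicer))

seed <- 1
out <- "results/scene"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scene <- simulate_scene(seed = seed)

writeLines(scene$ann$gff_lines, file.path(out, "annotation.gff3"))
for (ci in seq_along(scene$comparisons)) {
  comp <- scene$comparisons[[ci]]
  write_rmats_se(comp$deu, file.path(out, sprintf("comp%02d_SE.MATS.JC.txt", ci)))
  for (mark in names(comp$dhm)) {
    write_manorm(comp$dhm[[mark]],
                 file.path(out, sprintf("comp%02d_%s_MAvalues.tsv", ci, mark)))
  }
}
jsonlite::write_json(
  list(seed = seed, n_comparisons = length(scene$comparisons),
       classes = scene$classes),
  file.path(out, "truth.json"))

cat("Scene written to", out, "\n")
cat("  genes:", nrow(scene$ann$genes),
    " candidate exons:", length(scene$ann$candidate_ids), "\n")
print(table(scene$classes$class))
cat("  epispliced genes per mark:\n")
print(table(scene$classes$mark[scene$classes$class == "epispliced"]))
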