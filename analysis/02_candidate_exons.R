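#!/usr/bin/env Rscript
# Candidate-exon selection: parse the annotation, keep exons of transcripts
# with support level 1-3, drop exons within 200 bp of any TSS (any support
# level), and extract the +/-200 bp flanks.

suppressMessages(library(episplicer))

scene_dir <- "results/scene"
out <- "results"

ann <- load_annotation(file.path(scene_dir, "annotation.gff3"), tsl_max = 3)
cat("TSL 1-3 exon universe:", nrow(ann$exons), "exons;",
    nrow(ann$tss), "TSS (TSL 1-5)\n")

candidates <- exclude_tss_proximal(ann$exons, ann$tss, window = 200)
cat("After TSS-proximity exclusion:", nrow(candidates), "candidate exons (",
    nrow(ann$exons) - nrow(candidates), "removed )\n")

flanks <- extract_flanks(candidates, flank_size = 200)
cat("Flanks:", nrow(flanks), "(clipped flanks dropped)\n")

write.table(candidates, file.path(out, "candidate_exons.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(flanks, file.path(out, "candidate_flanks.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_bed6(flanks, file.path(out, "candidate_flanks.bed"))
# the unfiltered universe is needed later for peak-leak detection
write.table(ann$exons, file.path(out, "all_exons.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ann$tss, file.path(out, "tss.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
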