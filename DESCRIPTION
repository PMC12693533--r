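Package: episplicer
Title: Linking Differential Exon Usage to Local Histone-Mark Changes at Exon Flanks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline connecting alternative splicing to the local
    chromatin state. Candidate exons from well-supported transcripts are scored
    with differential exon usage (delta PSI from rMATS-style tables) and with
    differential histone-modification signal (MAnorm-style M-values) at their
    +/-200 bp flanks; genes whose absolute scores correlate across flanks are
    called epispliced. RNA-binding-protein motif-scan scores over epispliced and
    non-epispliced exon flanks feed per-mark random-forest classifiers, which
    are interpreted with Shapley attributions to nominate episplicing RBPs,
    expanded through binding-score correlation. eCLIP peak overlap and a
    uniform-placement enrichment probability validate nominated RBPs. A
    synthetic-data module generates all upstream file classes with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
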