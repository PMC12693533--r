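flank_tbl <- function(gene, deu, dhm, prefix = gene) {
  n <- length(deu)
  data.frame(flank_id = sprintf("%s|f%02d", prefix, seq_len(n)),
             exon_id = sprintf("%s|e%02d", prefix, ceiling(seq_len(n) / 2)),
             gene_id = rep(gene, n), deu_score = deu,
             is_alternative = abs(deu) >= 0.2, dhm_score = dhm,
             stringsAsFactors = FALSE)
}

test_that("gene-wise correlation handles identity, hand-computed, and excluded cases", {
  expect_equal(gene_correlation(c(0.2, 0.5, 0.9), c(0.2, 0.5, 0.9))$r, 1)
  # frozen from an independent cor.test evaluation of these vectors
  g <- gene_correlation(c(0.3, 0, 0.5, 0), c(1.1, 0, 2.0, 0))
  expect_equal(g$r, 0.998762, tolerance = 1e-6)
  expect_equal(g$p, 0.00123753, tolerance = 1e-5)
  expect_equal(gene_correlation(c(0.3, 0.5), c(1, 2))$reason, "too_few_flanks")
  expect_equal(gene_correlation(c(0.3, 0.3, 0.3), c(1, 2, 3))$reason,
               "constant_vector")
})

test_that("caller labels: correlated alt-only genes epispliced, unmarked alt genes non-epispliced", {
  tab <- rbind(
    flank_tbl("GEPI", c(0.4, 0.4, 0.7, 0.7, 0, 0), c(1.2, 1.2, 2.2, 2.2, 0, 0)),
    flank_tbl("GNON", c(0.5, 0.5, 0, 0), c(0, 0, 0, 0)),
    # passes correlation but has a peak on a zero-usage flank
    flank_tbl("GLEAK", c(0.4, 0.4, 0.7, 0.7, 0, 0), c(1.2, 1.2, 2.2, 2.2, 1.5, 0))
  )
  calls <- call_epispliced(tab, "H3K36me3")
  lab <- setNames(calls$label, calls$gene_id)
  expect_equal(lab[["GEPI"]], "epispliced")
  expect_equal(lab[["GNON"]], "non_epispliced")
  expect_equal(lab[["GLEAK"]], "unclassified")
  expect_match(calls$epispliced_exons[calls$gene_id == "GEPI"], "e01")
})

test_that("the non-epispliced rule consults every mark when a full DHM table is given", {
  tab <- flank_tbl("G1", c(0.5, 0.5, 0, 0), c(0, 0, 0, 0))
  other <- data.frame(flank_id = tab$flank_id[1], mark = "H3K9me3",
                      dhm_score = 2.0)
  calls <- call_epispliced(tab, "H3K36me3", dhm_all = other)
  expect_equal(calls$label, "unclassified")
  calls0 <- call_epispliced(tab, "H3K36me3")
  expect_equal(calls0$label, "non_epispliced")
})

test_that("an unattainable correlation threshold yields zero epispliced genes", {
  tab <- flank_tbl("GEPI", c(0.4, 0.4, 0.7, 0.7, 0, 0),
                   c(1.2, 1.2, 2.2, 2.2, 0, 0))
  calls <- call_epispliced(tab, "H3K36me3", r_min = 1 + 1e-9)
  expect_false(any(calls$label == "epispliced"))
})

test_that("empty batches return empty calls", {
  tab <- flank_tbl("G", numeric(), numeric())
  expect_equal(nrow(call_epispliced(tab, "H3K4me3")), 0L)
})

test_that("batch FDR matches an independent step-up implementation", {
  set.seed(5)
  tabs <- lapply(1:20, function(i) {
    n <- sample(3:6, 1)
    deu <- round(runif(n, 0, 0.8), 2)
    dhm <- 2 * deu + rnorm(n, 0, 1)
    flank_tbl(sprintf("G%02d", i), deu, dhm)
  })
  calls <- call_epispliced(do.call(rbind, tabs), "H3K27ac")
  tested <- !is.na(calls$p_raw)
  expect_equal(calls$p_fdr[tested], bf_bh(calls$p_raw[tested]),
               tolerance = 1e-12)
})

test_that("control consolidation applies the 70% rule over testable comparisons", {
  cls <- function(label, flank = "F1", gene = "G1") {
    data.frame(flank_id = flank, gene_id = gene, class = label,
               stringsAsFactors = FALSE)
  }
  # 7 of 10 comparisons non-epispliced -> control
  in7 <- c(replicate(7, cls("non_epispliced"), simplify = FALSE),
           replicate(3, cls("non_epispliced", flank = "other", gene = "G9"),
                     simplify = FALSE))
  got <- consolidate_flank_sets(in7)
  expect_true("F1" %in% got$control)
  # 6 of 10 -> excluded (gene testable in all 10)
  in6 <- c(replicate(6, cls("non_epispliced"), simplify = FALSE),
           replicate(4, data.frame(flank_id = "F2", gene_id = "G1",
                                   class = "non_epispliced"),
                     simplify = FALSE))
  got6 <- consolidate_flank_sets(in6)
  expect_false("F1" %in% got6$control)
  # epispliced in any comparison wins over control membership
  mix <- list(cls("epispliced"), cls("non_epispliced"), cls("non_epispliced"))
  gotm <- consolidate_flank_sets(mix)
  expect_true("F1" %in% gotm$epispliced)
  expect_false("F1" %in% gotm$control)
})

test_that("flank classes carry only alternative-exon flanks of labelled genes", {
  tab <- rbind(
    flank_tbl("GEPI", c(0.4, 0.4, 0.7, 0.7, 0, 0), c(1.2, 1.2, 2.2, 2.2, 0, 0)),
    flank_tbl("GNON", c(0.5, 0.5, 0, 0), c(0, 0, 0, 0)))
  calls <- call_epispliced(tab, "H3K36me3")
  fc <- flank_classes(calls, tab)
  expect_setequal(fc$class[fc$gene_id == "GEPI"], "epispliced")
  expect_equal(sum(fc$gene_id == "GEPI"), 4L)  # zero-usage flanks excluded
  expect_equal(sum(fc$gene_id == "GNON"), 2L)
})
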