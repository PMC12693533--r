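se_record <- function(start, end, gene = "G1", dpsi = 0.3, p = 0.001,
                      fdr = 0.01, inc = 30L, skip = 30L, chrom = "chr1",
                      strand = "+") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, gene_id = gene, event_type = "SE",
             delta_psi = dpsi, p_value = p, fdr = fdr,
             inc_reads = inc, skip_reads = skip, stringsAsFactors = FALSE)
}

test_that("rMATS skipped-exon rows round-trip through the writer/reader pair", {
  rec <- rbind(se_record(999, 1100), se_record(5000, 5180, dpsi = -0.5))
  path <- tempfile()
  write_rmats_se(rec, path)
  got <- load_deu_table(path)
  expect_equal(got$start, c(999L, 5000L))
  expect_equal(got$end, c(1100L, 5180L))
  expect_equal(got$delta_psi, rec$delta_psi)
  expect_equal(got$inc_reads + got$skip_reads, rec$inc_reads + rec$skip_reads)
})

test_that("MXE rows expand to two exon records with opposite-signed delta PSI", {
  tab <- data.frame(
    ID = 1L, GeneID = '"G1"', geneSymbol = '"G1"', chr = "chr1",
    strand = "+", check.names = FALSE
  )
  tab[["1stExonStart_0base"]] <- 1000L; tab[["1stExonEnd"]] <- 1100L
  tab[["2ndExonStart_0base"]] <- 2000L; tab[["2ndExonEnd"]] <- 2150L
  tab$upstreamES <- 0L; tab$upstreamEE <- 100L
  tab$downstreamES <- 3000L; tab$downstreamEE <- 3100L
  tab$IJC_SAMPLE_1 <- "10,12"; tab$SJC_SAMPLE_1 <- "5,5"
  tab$IJC_SAMPLE_2 <- "8,9"; tab$SJC_SAMPLE_2 <- "6,6"
  tab$PValue <- 1e-4; tab$FDR <- 1e-3; tab$IncLevelDifference <- 0.4
  path <- tempfile()
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- load_deu_table(path)
  expect_equal(nrow(got), 2L)
  expect_setequal(got$event_type, "MXE")
  expect_setequal(got$delta_psi, c(0.4, -0.4))
  expect_equal(got$delta_psi[got$start == 1000L], 0.4)
  expect_equal(unique(got$inc_reads + got$skip_reads), 61L)
})

test_that("events with no junction-read support are dropped with a warning", {
  rec <- rbind(se_record(999, 1100), se_record(2000, 2100, inc = 0L, skip = 0L))
  path <- tempfile()
  write_rmats_se(rec, path)
  expect_warning(got <- load_deu_table(path), "junction-read")
  expect_equal(nrow(got), 1L)
})

test_that("an empty usage table loads as an empty record set", {
  path <- tempfile()
  write_rmats_se(se_record(1, 2)[0, ], path)
  expect_equal(nrow(load_deu_table(path)), 0L)
})

test_that("read-support filter is an inclusive >= threshold", {
  rec <- rbind(se_record(1, 100, inc = 6L, skip = 4L),
               se_record(200, 300, inc = 5L, skip = 4L))
  expect_equal(nrow(min_read_filter(rec, 10)), 1L)
  expect_equal(min_read_filter(rec, 0), rec)
})

test_that("usage scores: qualifying exons get delta PSI, siblings get zero, other genes are absent", {
  cand <- rbind(exon_df(1000, 1100, gene_id = "G1"),
                exon_df(3000, 3150, gene_id = "G1"),
                exon_df(9000, 9100, gene_id = "G2"))
  rec <- rbind(
    se_record(1000, 1100, gene = "G1", dpsi = 0.25, fdr = 0.01),
    se_record(3000, 3150, gene = "G1", dpsi = 0.10, fdr = 0.01),  # below 0.2
    se_record(9000, 9100, gene = "G2", dpsi = 0.50, fdr = 0.20))  # FDR fails
  sm <- assign_deu_scores(cand, rec)
  expect_setequal(sm$gene_id, "G1")
  expect_equal(sm$deu_score[sm$exon_id == cand$exon_id[1]], 0.25)
  expect_true(sm$is_alternative[sm$exon_id == cand$exon_id[1]])
  expect_equal(sm$deu_score[sm$exon_id == cand$exon_id[2]], 0)
  expect_false(cand$exon_id[3] %in% sm$exon_id)
})

test_that("conflicting records on one exon resolve to max |delta PSI|, order-invariantly", {
  cand <- exon_df(1000, 1100)
  rec <- rbind(se_record(1000, 1100, dpsi = 0.3),
               se_record(1000, 1100, dpsi = -0.6))
  expect_message(a <- assign_deu_scores(cand, rec), "conflicting")
  expect_message(b <- assign_deu_scores(cand, rec[2:1, ]), "conflicting")
  expect_equal(a$deu_score, -0.6)
  expect_equal(a, b)
})

test_that("flank annotation extrapolates the exon score to both flanks (2n cardinality)", {
  cand <- rbind(exon_df(1000, 1100, gene_id = "G1"),
                exon_df(3000, 3150, gene_id = "G1"))
  rec <- se_record(1000, 1100, dpsi = 0.25)
  sm <- assign_deu_scores(cand, rec)
  fl <- extract_flanks(cand)
  ann <- annotate_flanks_with_deu(fl, sm)
  expect_equal(nrow(ann), 4L)
  sc <- ann$deu_score[ann$exon_id == cand$exon_id[1]]
  expect_equal(sc, c(0.25, 0.25))
  expect_equal(ann$deu_score[ann$exon_id == cand$exon_id[2]], c(0, 0))
  # alternative flags: exactly twice the alternative exon count
  expect_equal(sum(ann$is_alternative), 2L)
})
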