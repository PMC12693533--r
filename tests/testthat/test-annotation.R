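gff_header <- "##gff-version 3"

mini_gff <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(gff_header, lines), path)
  path
}

tx_line <- function(chrom, start1, end1, strand, tx, gene, tsl) {
  sprintf("%s\ts\ttranscript\t%s\t%s\t.\t%s\t.\tID=%s;Parent=%s;gene_id=%s;transcript_id=%s;transcript_support_level=%s",
          chrom, start1, end1, strand, tx, gene, gene, tx, tsl)
}

exon_line <- function(chrom, start1, end1, strand, tx, gene, tsl, n) {
  sprintf("%s\ts\texon\t%s\t%s\t.\t%s\t.\tID=%s.e%s;Parent=%s;gene_id=%s;transcript_id=%s;transcript_support_level=%s",
          chrom, start1, end1, strand, tx, n, tx, gene, tx, tsl)
}

test_that("TSL filter keeps low-support transcripts out of the candidate set but in the TSS set", {
  path <- mini_gff(c(
    tx_line("chr1", 1001, 3000, "+", "TXA", "G1", "2"),
    exon_line("chr1", 1001, 1200, "+", "TXA", "G1", "2", 1),
    exon_line("chr1", 2001, 2200, "+", "TXA", "G1", "2", 2),
    tx_line("chr1", 5001, 7000, "+", "TXB", "G2", "4"),
    exon_line("chr1", 5001, 5200, "+", "TXB", "G2", "4", 1),
    exon_line("chr1", 6001, 6200, "+", "TXB", "G2", "4", 2)
  ))
  ann <- load_annotation(path)
  expect_setequal(ann$exons$gene_id, "G1")
  expect_equal(nrow(ann$exons), 2L)
  # TSL 4 transcript still contributes its TSS (0-based first base)
  expect_setequal(ann$tss$pos, c(1000L, 5000L))
})

test_that("minus-strand TSS is the rightmost transcribed base and TSL is min over transcripts", {
  path <- mini_gff(c(
    tx_line("chr1", 1001, 3000, "-", "TXA", "G1", "3"),
    exon_line("chr1", 1001, 1200, "-", "TXA", "G1", "3", 1),
    tx_line("chr1", 1001, 3000, "-", "TXB", "G1", "1"),
    exon_line("chr1", 1001, 1200, "-", "TXB", "G1", "1", 1)
  ))
  ann <- load_annotation(path)
  expect_equal(ann$tss$pos, c(2999L, 2999L))
  # same exon in both transcripts: deduplicated, min TSL, both transcripts listed
  expect_equal(nrow(ann$exons), 1L)
  expect_equal(ann$exons$tsl, 1L)
  expect_equal(ann$exons$transcript_ids, "TXA,TXB")
})

test_that("transcripts without a TSL attribute are skipped with a warning", {
  path <- mini_gff(c(
    sprintf("chr1\ts\ttranscript\t1001\t3000\t.\t+\t.\tID=TXA;gene_id=G1;transcript_id=TXA"),
    exon_line("chr1", 1001, 1200, "+", "TXA", "G1", "1", 1)
  ))
  expect_warning(ann <- load_annotation(path), "TSL")
  expect_equal(nrow(ann$exons), 0L)
})

test_that("an empty GFF3 yields empty exon and TSS sets", {
  path <- mini_gff(character())
  ann <- load_annotation(path)
  expect_equal(nrow(ann$exons), 0L)
  expect_equal(nrow(ann$tss), 0L)
})

test_that("generated annotation round-trips to exactly the planted candidate set", {
  ann <- generate_annotation(n_genes = 30, seed = 11)
  loaded <- load_annotation(write_gff3_fixture(ann))
  cand <- exclude_tss_proximal(loaded$exons, loaded$tss, window = 200)
  expect_setequal(cand$exon_id, ann$candidate_ids)
  # the TSL<=3 universe itself matches the construction
  expect_setequal(loaded$exons$exon_id, ann$exons$exon_id[ann$exons$tsl <= 3])
})

test_that("TSS exclusion matches the all-pairs distance oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:4) {
    exons <- random_intervals(50)
    exons$exon_id <- sprintf("E%02d", seq_len(nrow(exons)))
    tss <- data.frame(chrom = sample(c("chr1", "chr2"), 5, replace = TRUE),
                      pos = sample.int(10000, 5))
    got <- exclude_tss_proximal(exons, tss, window = 200)
    want <- bf_tss_retained(exons, tss, window = 200)
    expect_setequal(got$exon_id, want$exon_id)
    expect_equal(exclude_tss_proximal(got, tss, window = 200), got)
  }
})

test_that("TSS exclusion boundary: a TSS on the exon start excludes; empty TSS keeps all", {
  exons <- exon_df(1000, 1100)
  hit <- data.frame(chrom = "chr1", pos = 1000L)
  expect_equal(nrow(exclude_tss_proximal(exons, hit, 200)), 0L)
  # exactly `window` away still excludes (inclusive), window+1 does not
  at200 <- data.frame(chrom = "chr1", pos = 800L)
  at201 <- data.frame(chrom = "chr1", pos = 799L)
  expect_equal(nrow(exclude_tss_proximal(exons, at200, 200)), 0L)
  expect_equal(nrow(exclude_tss_proximal(exons, at201, 200)), 1L)
  none <- data.frame(chrom = character(), pos = integer())
  expect_equal(nrow(exclude_tss_proximal(exons, none, 200)), 1L)
})

test_that("flank extraction follows the half-open convention and strand relabelling", {
  ex <- exon_df(1000, 1100)
  fl <- extract_flanks(ex, 200)
  expect_equal(fl$start, c(800L, 1100L))
  expect_equal(fl$end, c(1000L, 1300L))
  expect_equal(fl$side_tx[fl$side == "left"], "5prime")
  # same exon on '-': identical intervals, swapped transcript-relative sides
  flm <- extract_flanks(exon_df(1000, 1100, strand = "-"), 200)
  expect_equal(flm$start, fl$start)
  expect_equal(flm$side_tx[flm$side == "left"], "3prime")
  # flanks touch but never overlap the exon
  expect_true(all(fl$end <= ex$start | fl$start >= ex$end))
})

test_that("clipped flanks at the contig edge are flagged and dropped by default", {
  ex <- exon_df(150, 400)
  fl <- extract_flanks(ex, 200)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$side, "right")
  kept <- extract_flanks(ex, 200, drop_clipped = FALSE)
  expect_equal(nrow(kept), 2L)
  expect_true(kept$clipped[kept$side == "left"])
  expect_equal(kept$start[kept$side == "left"], 0L)
})

test_that("candidate extraction is invariant to input record order", {
  ann <- generate_annotation(n_genes = 15, seed = 3)
  tss <- ann$tss
  exons <- ann$exons
  perm <- sample(nrow(exons))
  a <- exclude_tss_proximal(exons, tss, 200)
  b <- exclude_tss_proximal(exons[perm, ], tss[sample(nrow(tss)), ], 200)
  expect_setequal(a$exon_id, b$exon_id)
})
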