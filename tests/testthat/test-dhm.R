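peak_df <- function(start, end, m = 1, fdr = 0.01, common = FALSE,
                    chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             m_value = m, p_value = fdr / 2, fdr = fdr, common = common,
             stringsAsFactors = FALSE)
}

test_that("MAnorm-style loading converts coordinates, drops common and non-significant peaks", {
  pk <- rbind(peak_df(1000, 1400, m = -2.5, fdr = 0.01),
              peak_df(2000, 2400, m = 3.0, fdr = 0.01, common = TRUE),
              peak_df(3000, 3400, m = 1.0, fdr = 0.20))
  path <- tempfile()
  write_manorm(pk, path)
  got <- load_dhm_peaks(path, "H3K36me3")
  expect_equal(nrow(got), 1L)
  expect_equal(got$m_value, -2.5)
  expect_equal(got$start, 1000L)  # writer emits 1-based, reader restores
  expect_equal(got$mark, "H3K36me3")
})

test_that("unknown histone-mark labels are a hard error; empty tables load empty", {
  pk <- peak_df(1000, 1400)
  path <- tempfile()
  write_manorm(pk, path)
  expect_error(load_dhm_peaks(path, "H3K79me2"), "unknown histone mark")
  write_manorm(pk[0, ], path)
  expect_equal(nrow(load_dhm_peaks(path, "H3K4me3")), 0L)
})

test_that("peak-leak rule (b): a peak must cover at least half the exon, inclusively", {
  ex <- exon_df(1000, 1200)           # length 200
  tss <- data.frame(chrom = character(), pos = integer())
  p49 <- peak_df(1000, 1098)          # covers 98 bp = 49%
  p50 <- peak_df(1000, 1100)          # covers 100 bp = 50%
  f49 <- peak_leak_filter(p49, ex, tss)
  f50 <- peak_leak_filter(p50, ex, tss)
  expect_equal(f49$exon_ids[[1]], character(0))
  expect_equal(f50$exon_ids[[1]], ex$exon_id)
})

test_that("peak-leak rule (a): touching a TSS-proximal exon removes the peak globally", {
  exons <- rbind(exon_df(1000, 1100, gene_id = "G1"),   # TSS-proximal
                 exon_df(2000, 2150, gene_id = "G1"))   # candidate
  tss <- data.frame(chrom = "chr1", pos = 1000L)
  # one broad peak spans both exons fully
  pk <- peak_df(900, 2300, m = 2)
  out <- peak_leak_filter(pk, exons, tss)
  expect_equal(nrow(out), 0L)
  # a peak on the candidate exon alone survives
  ok <- peak_leak_filter(peak_df(1950, 2200), exons, tss)
  expect_equal(ok$exon_ids[[1]], exons$exon_id[2])
})

test_that("raising the coverage threshold only shrinks the annotatable set", {
  set.seed(9)
  exons <- random_intervals(30)
  exons$gene_id <- "G"; exons$tsl <- 1L
  exons$exon_id <- sprintf("E%02d", seq_len(nrow(exons)))
  peaks <- peak_df(1, 2)[0, ]
  peaks <- do.call(rbind, lapply(1:40, function(i) {
    s <- sample.int(10000, 1)
    peak_df(s, s + sample.int(400, 1), m = rnorm(1),
            chrom = sample(c("chr1", "chr2"), 1))
  }))
  tss <- data.frame(chrom = character(), pos = integer())
  sizes <- vapply(c(0.25, 0.5, 0.75, 1), function(fr) {
    out <- peak_leak_filter(peaks, exons, tss, min_cover_frac = fr)
    sum(lengths(out$exon_ids))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("flank annotation takes the max-|M| overlapping peak and zero-imputes", {
  ex <- exon_df(1000, 1200)
  fl <- extract_flanks(ex)
  peaks <- rbind(peak_df(700, 1250, m = 1.2),    # covers exon, both flanks
                 peak_df(850, 1250, m = -2.5))   # covers exon, both flanks
  tss <- data.frame(chrom = character(), pos = integer())
  pk <- peak_leak_filter(peaks, ex, tss)
  ann <- annotate_flanks_with_dhm(fl, pk, "H3K27ac")
  expect_equal(ann$dhm_score, c(-2.5, -2.5))
  # flank with no overlapping peak: zero imputation
  far <- extract_flanks(exon_df(9000, 9200))
  ann2 <- annotate_flanks_with_dhm(far, pk, "H3K27ac")
  expect_equal(ann2$dhm_score, c(0, 0))
})

test_that("annotation equals a brute-force all-pairs scan on a random fixture", {
  set.seed(21)
  exons <- random_intervals(50, max_pos = 50000)
  exons$gene_id <- sprintf("G%02d", seq_len(nrow(exons)))
  exons$exon_id <- sprintf("E%02d", seq_len(nrow(exons)))
  fl <- extract_flanks(exons)
  peaks <- do.call(rbind, lapply(1:60, function(i) {
    s <- sample.int(50000, 1)
    peak_df(s, s + sample.int(600, 1), m = rnorm(1, 0, 2),
            fdr = runif(1, 1e-4, 0.04), chrom = sample(c("chr1", "chr2"), 1))
  }))
  ann <- annotate_flanks_with_dhm(fl, peaks, "H3K9me3")  # no leak filtering
  want <- vapply(seq_len(nrow(fl)), function(i) {
    best <- 0
    for (j in seq_len(nrow(peaks))) {
      if (fl$chrom[i] != peaks$chrom[j]) next
      if (min(fl$end[i], peaks$end[j]) - max(fl$start[i], peaks$start[j]) <= 0) next
      if (abs(peaks$m_value[j]) > abs(best)) best <- peaks$m_value[j]
    }
    best
  }, numeric(1))
  expect_equal(ann$dhm_score[match(fl$flank_id, ann$flank_id)], want)
})

test_that("equal-|M| ties break by smaller FDR then leftmost start", {
  ex <- exon_df(1000, 1200)
  fl <- extract_flanks(ex)
  peaks <- rbind(peak_df(700, 1250, m = 2, fdr = 0.04),
                 peak_df(800, 1250, m = -2, fdr = 0.001))
  ann <- annotate_flanks_with_dhm(fl, peaks, "H3K27ac")
  expect_equal(unique(ann$dhm_score), -2)
})
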