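# Fixture builders and independent brute-force oracles shared by the suite.
# Oracles are deliberately naive (all-pairs loops, closed forms) so they stay
# independent of the package's vectorized/GenomicRanges code paths.

iv <- function(chrom, start, end, strand = "+", ...) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, ..., stringsAsFactors = FALSE)
}

exon_df <- function(start, end, chrom = "chr1", strand = "+",
                    gene_id = "G1") {
  out <- iv(chrom, start, end, strand, gene_id = gene_id, tsl = 1L)
  out$exon_id <- sprintf("%s:%s:%d-%d:%s", gene_id, chrom, out$start,
                         out$end, strand)
  out
}

random_intervals <- function(n, max_pos = 10000, max_len = 300,
                             chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  iv(sample(chroms, n, replace = TRUE), start,
     start + sample.int(max_len, n, replace = TRUE))
}

# O(n*m) overlap oracle
bf_overlap_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j]) {
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov > 0) out[[length(out) + 1L]] <- c(i, j, ov)
    }
  }
  if (!length(out)) {
    return(data.frame(a = integer(), b = integer(), overlap_bp = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(a = m[, 1], b = m[, 2], overlap_bp = m[, 3])
}

# all-pairs base-to-TSS distance oracle
bf_tss_retained <- function(exons, tss, window) {
  keep <- logical(nrow(exons))
  for (i in seq_len(nrow(exons))) {
    dmin <- Inf
    for (j in seq_len(nrow(tss))) {
      if (exons$chrom[i] != tss$chrom[j]) next
      p <- tss$pos[j]
      d <- if (p >= exons$start[i] && p < exons$end[i]) 0 else
        min(abs(exons$start[i] - p), abs(exons$end[i] - 1L - p))
      dmin <- min(dmin, d)
    }
    keep[i] <- dmin > window
  }
  exons[keep, , drop = FALSE]
}

# textbook Welch with Welch-Satterthwaite df
bf_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# step-up BH oracle
bf_bh <- function(p) {
  n <- length(p); o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in rev(seq_len(n))) {
    prev <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- prev
  }
  adj
}

# threshold-sweep PR-AUC oracle (average precision over distinct thresholds)
bf_pr_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; auc <- 0
  for (t in thr) {
    pred <- scores >= t
    prec <- sum(pred & labels) / sum(pred)
    rec <- sum(pred & labels) / sum(labels)
    auc <- auc + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  auc
}

write_gff3_fixture <- function(ann) {
  path <- tempfile(fileext = ".gff3")
  writeLines(ann$gff_lines, path)
  path
}

# small labelled matrix with planted discriminative columns
planted_matrix <- function(n_pos = 40, n_neg = 120, n_feat = 30,
                           n_planted = 5, dz = 2, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  x <- matrix(pmax(0, rnorm(n * n_feat, 1.5, 0.8)), n, n_feat,
              dimnames = list(sprintf("f%03d", seq_len(n)),
                              sprintf("RBP%03d", seq_len(n_feat))))
  pos <- seq_len(n_pos)
  x[pos, seq_len(n_planted)] <- x[pos, seq_len(n_planted)] + dz
  x[x < 2] <- 0
  y <- factor(rep(c("epispliced", "control"), c(n_pos, n_neg)),
              levels = c("control", "epispliced"))
  list(x = x, y = y, planted = colnames(x)[seq_len(n_planted)])
}
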