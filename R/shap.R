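#' Monte-Carlo Shapley attributions for a probability forest
#'
#' Interventional Shapley values estimated with full permutation chains: per
#' iteration one background row and one feature permutation are drawn, the
#' chain of hybrid rows from background to explained row is predicted in a
#' single batch, and each feature's marginal contribution along the chain is
#' accumulated. Because every chain telescopes, the per-row attributions sum
#' exactly to `f(x) - base` (local accuracy holds to float precision, not
#' just in expectation).
#'
#' @param model a `ranger` probability forest with a positive class named
#'   `epispliced`.
#' @param x numeric matrix of rows to explain (feature columns as trained).
#' @param background numeric matrix of background rows (typically training
#'   rows) the interventional expectation is taken over.
#' @param n_perm number of permutation-chain iterations (default 8; variance
#'   of the estimate shrinks as 1/`n_perm`).
#' @param seed RNG seed.
#' @return list with `shap` (matrix, same shape as `x`), `base` (scalar mean
#'   background prediction over the sampled chains), `fx` (model predictions
#'   for `x`).
#' @export
shap_values <- function(model, x, background, n_perm = 8, seed = 1) {
  stopifnot(is.matrix(x), is.matrix(background),
            identical(colnames(x), colnames(background)))
  n <- nrow(x); p <- ncol(x)
  pos <- "epispliced"
  predict_pos <- function(m) {
    pr <- stats::predict(model, data = m, num.threads = 1)$predictions
    pr[, pos]
  }
  phi <- matrix(0, n, p, dimnames = dimnames(x))
  base_acc <- 0
  set.seed(seed)
  for (iter in seq_len(n_perm)) {
    b <- background[sample.int(nrow(background), 1L), ]
    perm <- sample.int(p)
    blocks <- vector("list", p + 1L)
    cur <- matrix(b, n, p, byrow = TRUE, dimnames = list(NULL, colnames(x)))
    blocks[[1L]] <- cur
    for (k in seq_len(p)) {
      cur[, perm[k]] <- x[, perm[k]]
      blocks[[k + 1L]] <- cur
    }
    preds <- predict_pos(do.call(rbind, blocks))
    pm <- matrix(preds, nrow = n)            # column k = chain step k-1
    base_acc <- base_acc + pm[1L, 1L]
    contrib <- pm[, -1L, drop = FALSE] - pm[, -(p + 1L), drop = FALSE]
    phi[, perm] <- phi[, perm] + contrib
  }
  list(shap = phi / n_perm, base = base_acc / n_perm,
       fx = predict_pos(x))
}

#' Per-RBP summary of Shapley attributions
#'
#' @param shap attribution matrix (rows = flanks, columns = RBPs).
#' @param x the matching binding-score matrix.
#' @return data.frame per RBP: `rbp`, `mean_abs_shap` (over all rows),
#'   `mean_shap_bound` (signed mean over rows where the RBP's score is
#'   non-zero; NA when never bound), `direction_cor` (correlation between
#'   binding score and attribution among bound rows; positive means high
#'   binding pushes toward the epispliced class).
#' @export
shap_summary <- function(shap, x) {
  stopifnot(identical(dim(shap), dim(x)))
  out <- data.frame(rbp = colnames(x), stringsAsFactors = FALSE)
  out$mean_abs_shap <- colMeans(abs(shap))
  out$mean_shap_bound <- vapply(seq_len(ncol(x)), function(j) {
    nz <- x[, j] > 0
    if (!any(nz)) NA_real_ else mean(shap[nz, j])
  }, numeric(1))
  out$direction_cor <- vapply(seq_len(ncol(x)), function(j) {
    nz <- x[, j] > 0
    if (sum(nz) < 3 || stats::sd(x[nz, j]) == 0 || stats::sd(shap[nz, j]) == 0) {
      # too few bound rows for a correlation: fall back to the sign of the
      # mean attribution among bound rows
      s <- out$mean_shap_bound[j]
      return(if (is.na(s)) NA_real_ else sign(s))
    }
    stats::cor(x[nz, j], shap[nz, j])
  }, numeric(1))
  out
}
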