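#' Train and evaluate the per-mark random-forest classifier
#'
#' Stratified K-fold cross-validation, repeated with fresh fold shuffles,
#' of a probability random forest (Gini splits, class weights inversely
#' proportional to training-class frequency) that separates epispliced from
#' control (non-epispliced) exon flanks by RBP binding scores. Each held-out
#' fold contributes PR-AUC plus precision/recall/specificity at a 0.5 vote
#' threshold, alongside a stratified-random baseline whose expected PR-AUC is
#' the positive prevalence.
#'
#' @param x numeric feature matrix (rows = flanks, columns = RBPs).
#' @param y factor with levels `control`, `epispliced` (positive).
#' @param n_trees trees per forest (default 200).
#' @param folds cross-validation folds K (default 5).
#' @param repeats repetitions of the K-fold split (default 10); repeat `r`
#'   uses `seed + r - 1`.
#' @param seed base RNG seed.
#' @param keep_models keep the first repeat's fold models and held-out row
#'   indices for attribution (default TRUE).
#' @return object of class `episplice_rf`: list with `per_fold` (data.frame of
#'   fold-level metrics), `summary` (mean and sd per metric),
#'   `baseline_pr_auc` (positive prevalence), `models` (first-repeat fold
#'   fits + test indices, if kept), and the training data.
#' @export
train_evaluate <- function(x, y, n_trees = 200, folds = 5, repeats = 10,
                           seed = 1, keep_models = TRUE) {
  stopifnot(is.matrix(x), is.factor(y), nrow(x) == length(y))
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  if (nrow(x) < folds) stop("fewer rows than folds")
  pos <- "epispliced"
  rows <- list()
  models <- list()
  for (r in seq_len(repeats)) {
    rs <- seed + r - 1L
    fold <- stratified_folds(y, folds, seed = rs)
    for (k in seq_len(folds)) {
      tr <- fold != k; te <- !tr
      cw <- as.numeric(length(y[tr]) / (2 * table(y[tr])[levels(y)]))
      set.seed(rs * 1000L + k)
      fit <- ranger::ranger(
        x = x[tr, , drop = FALSE], y = droplevels(y[tr]),
        num.trees = n_trees, probability = TRUE, splitrule = "gini",
        class.weights = cw, seed = rs * 1000L + k, num.threads = 1
      )
      prob <- stats::predict(fit, data = x[te, , drop = FALSE],
                             num.threads = 1)$predictions[, pos]
      truth <- y[te] == pos
      set.seed(rs * 1000L + 500L + k)
      base_scores <- stats::runif(sum(te))
      tm <- threshold_metrics(prob, truth)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = k,
        pr_auc = pr_auc(prob, truth),
        precision = tm[["precision"]], recall = tm[["recall"]],
        specificity = tm[["specificity"]],
        baseline_pr_auc = pr_auc(base_scores, truth)
      )
      if (keep_models && r == 1L) {
        models[[k]] <- list(fit = fit, test_idx = which(te),
                            train_idx = which(tr))
      }
    }
  }
  per_fold <- do.call(rbind, rows)
  summarise <- function(v) c(mean = mean(v, na.rm = TRUE),
                             sd = stats::sd(v, na.rm = TRUE))
  metrics <- c("pr_auc", "precision", "recall", "specificity",
               "baseline_pr_auc")
  summary <- t(vapply(metrics, function(m) summarise(per_fold[[m]]),
                      numeric(2)))
  structure(list(per_fold = per_fold, summary = summary,
                 baseline_pr_auc = mean(y == pos),
                 models = models, x = x, y = y,
                 config = list(n_trees = n_trees, folds = folds,
                               repeats = repeats, seed = seed)),
            class = "episplice_rf")
}

#' @export
print.episplice_rf <- function(x, ...) {
  cat("episplice_rf:", nrow(x$x), "flanks x", ncol(x$x), "RBPs;",
      sum(x$y == "epispliced"), "epispliced\n")
  cat(sprintf("PR-AUC %.3f +/- %.3f (baseline prevalence %.3f)\n",
              x$summary["pr_auc", "mean"], x$summary["pr_auc", "sd"],
              x$baseline_pr_auc))
  invisible(x)
}

#' Shapley attribution over held-out folds
#'
#' Computes Monte-Carlo Shapley values for every flank using the first-repeat
#' fold model under which that flank was held out, so attributions are never
#' read off a model that saw the row in training. Backgrounds are sampled
#' from each fold's training rows.
#'
#' @param fit `episplice_rf` object from [train_evaluate()] with kept models.
#' @param n_perm permutation chains per row (default 8).
#' @param n_background background rows sampled per fold (default 50).
#' @param seed RNG seed.
#' @return list with `shap` (matrix aligned to `fit$x` rows), `base`
#'   (per-row base values), `fx` (held-out predictions), and `summary`
#'   (per-RBP data.frame from [shap_summary()]).
#' @export
shap_attribution <- function(fit, n_perm = 8, n_background = 50, seed = 1) {
  stopifnot(inherits(fit, "episplice_rf"), length(fit$models) > 0)
  shap <- matrix(NA_real_, nrow(fit$x), ncol(fit$x),
                 dimnames = dimnames(fit$x))
  base <- numeric(nrow(fit$x)); fx <- numeric(nrow(fit$x))
  for (k in seq_along(fit$models)) {
    m <- fit$models[[k]]
    set.seed(seed + k)
    bg_idx <- sample(m$train_idx, min(n_background, length(m$train_idx)))
    sv <- shap_values(m$fit, fit$x[m$test_idx, , drop = FALSE],
                      fit$x[bg_idx, , drop = FALSE],
                      n_perm = n_perm, seed = seed + 100L + k)
    shap[m$test_idx, ] <- sv$shap
    base[m$test_idx] <- sv$base
    fx[m$test_idx] <- sv$fx
  }
  list(shap = shap, base = base, fx = fx,
       summary = shap_summary(shap, fit$x))
}

#' Select episplicing and non-episplicing RBPs
#'
#' Seed sets are the `top_k` RBPs by mean |SHAP| whose high binding scores
#' push toward (episplicing) or away from (non-episplicing) the epispliced
#' class, judged by the sign of the binding-score/attribution correlation
#' among bound flanks. Each seed set is then expanded with RBPs whose binding
#' scores correlate with a seed member at `r >= r_min` and BH-FDR
#' `< fdr_max`; an expansion candidate pulled toward both sets, or already
#' seeded on the other side, keeps its seed assignment and the conflict is
#' logged.
#'
#' @param shap_sum per-RBP summary from [shap_attribution()].
#' @param x binding-score matrix the model was trained on.
#' @param top_k seed-set size (default 10).
#' @param r_min expansion correlation threshold (default 0.7).
#' @param fdr_max expansion BH-FDR threshold (default 0.05).
#' @return list with `episplicing`, `non_episplicing` (final sets),
#'   `seed_episplicing`, `seed_non_episplicing`, `expansion_log` (data.frame
#'   of added/skipped candidates), `shap_summary`.
#' @export
select_rbps <- function(shap_sum, x, top_k = 10, r_min = 0.7,
                        fdr_max = 0.05) {
  s <- shap_sum[order(-shap_sum$mean_abs_shap), , drop = FALSE]
  eligible <- !is.na(s$direction_cor) & s$mean_abs_shap > 0
  seed_epi <- utils::head(s$rbp[eligible & s$direction_cor > 0], top_k)
  seed_non <- utils::head(s$rbp[eligible & s$direction_cor < 0], top_k)

  cors <- rbp_correlation(x, r_min = r_min, fdr_max = fdr_max)
  sig <- cors[cors$significant, , drop = FALSE]
  expand_set <- function(seed, other_seed) {
    added <- character(); skipped <- character()
    cand <- unique(c(sig$rbp2[sig$rbp1 %in% seed],
                     sig$rbp1[sig$rbp2 %in% seed]))
    cand <- setdiff(cand, seed)
    for (rbp in cand) {
      if (rbp %in% other_seed) skipped <- c(skipped, rbp)
      else added <- c(added, rbp)
    }
    list(added = added, skipped = skipped)
  }
  ee <- expand_set(seed_epi, seed_non)
  en <- expand_set(seed_non, seed_epi)
  # a candidate correlated into both expansions is ambiguous: drop from both
  both <- intersect(ee$added, en$added)
  ee$added <- setdiff(ee$added, both)
  en$added <- setdiff(en$added, both)
  log <- rbind(
    if (length(ee$added)) data.frame(rbp = ee$added, set = "episplicing",
                                     action = "expanded"),
    if (length(en$added)) data.frame(rbp = en$added, set = "non_episplicing",
                                     action = "expanded"),
    if (length(ee$skipped)) data.frame(rbp = ee$skipped, set = "episplicing",
                                       action = "conflict_skipped"),
    if (length(en$skipped)) data.frame(rbp = en$skipped,
                                       set = "non_episplicing",
                                       action = "conflict_skipped"),
    if (length(both)) data.frame(rbp = both, set = "both",
                                 action = "ambiguous_skipped")
  )
  if (is.null(log)) {
    log <- data.frame(rbp = character(), set = character(),
                      action = character(), stringsAsFactors = FALSE)
  }
  list(episplicing = sort(unique(c(seed_epi, ee$added))),
       non_episplicing = sort(unique(c(seed_non, en$added))),
       seed_episplicing = seed_epi, seed_non_episplicing = seed_non,
       expansion_log = log, shap_summary = shap_sum)
}

#' Welch comparisons of RBP-set binding across exon classes
#'
#' For each RBP set (episplicing, non-episplicing), flanks are reduced to
#' their mean binding score over set members, and every pair of exon classes
#' (epispliced `DEU & DHM`, non-epispliced `DEU & !DHM`, constitutive-marked
#' `!DEU & DHM`) is compared with Welch's unequal-variance t-test.
#' Benjamini-Hochberg adjustment runs across the whole table; significance
#' tiers mirror the usual 0.05 / 0.01 / 0.001 asterisks.
#'
#' @param selection RBP selection from [select_rbps()].
#' @param class_matrices named list of binding matrices with identical
#'   columns, one per exon class.
#' @return data.frame: `set`, `class1`, `class2`, `n1`, `n2`, `mean1`,
#'   `mean2`, `t`, `df`, `p`, `p_fdr`, `signif`.
#' @export
welch_compare <- function(selection, class_matrices) {
  stopifnot(length(class_matrices) >= 2, !is.null(names(class_matrices)))
  sets <- list(episplicing = selection$episplicing,
               non_episplicing = selection$non_episplicing)
  pairs <- utils::combn(names(class_matrices), 2, simplify = FALSE)
  rows <- list()
  for (set_name in names(sets)) {
    members <- sets[[set_name]]
    if (length(members) == 0L) next
    means <- lapply(class_matrices, function(m) {
      rowMeans(m[, intersect(colnames(m), members), drop = FALSE])
    })
    for (pr in pairs) {
      a <- means[[pr[1]]]; b <- means[[pr[2]]]
      if (length(a) < 2 || length(b) < 2) {
        message("skipping ", set_name, " ", pr[1], " vs ", pr[2],
                ": class with < 2 flanks")
        next
      }
      wt <- welch_test(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, class1 = pr[1], class2 = pr[2],
        n1 = length(a), n2 = length(b),
        mean1 = wt$mean_x, mean2 = wt$mean_y,
        t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(set = character(), class1 = character(),
                      class2 = character(), n1 = integer(), n2 = integer(),
                      mean1 = numeric(), mean2 = numeric(), t = numeric(),
                      df = numeric(), p = numeric(), p_fdr = numeric(),
                      signif = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$signif <- cut(out$p_fdr, c(-Inf, 0.001, 0.01, 0.05, Inf),
                    labels = c("***", "**", "*", "ns"))
  out$signif <- as.character(out$signif)
  rownames(out) <- NULL
  out
}
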