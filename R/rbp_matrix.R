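#' Build the flanks-by-RBPs binding-score feature matrix
#'
#' For every (RBP, flank) the strongest reported binding event is kept; events
#' below the Z-score threshold become non-binding (0), and flanks with no
#' event for an RBP are zero-imputed. Rows are the labelled flanks, columns
#' the configured RBP panel — fixed even for RBPs without any event, so that
#' matrices built for different marks stay column-compatible.
#'
#' @param events data.frame `rbp`, `flank_id`, `z_score` (one row per
#'   reported binding site).
#' @param flank_labels data.frame `flank_id`, `label`; `label` must be
#'   `"epispliced"` (positive class) or `"control"`.
#' @param rbp_panel character vector of feature column names; defaults to the
#'   sorted set of RBPs seen in `events`.
#' @param z_min minimum Z-score counted as binding (default 2).
#' @return list with `x` (numeric matrix, rownames = flank ids, colnames =
#'   panel) and `y` (factor `control`/`epispliced`, positive class
#'   `epispliced`).
#' @export
build_feature_matrix <- function(events, flank_labels,
                                 rbp_panel = sort(unique(events$rbp)),
                                 z_min = 2.0) {
  stopifnot(all(c("flank_id", "label") %in% names(flank_labels)),
            all(flank_labels$label %in% c("epispliced", "control")),
            !anyDuplicated(flank_labels$flank_id),
            !anyDuplicated(rbp_panel))
  flank_ids <- flank_labels$flank_id
  x <- matrix(0, nrow = length(flank_ids), ncol = length(rbp_panel),
              dimnames = list(flank_ids, rbp_panel))
  if (nrow(events)) {
    unknown <- !(events$flank_id %in% flank_ids)
    if (any(unknown)) {
      warning(sum(unknown), " binding event(s) referencing unlabelled flanks skipped")
      events <- events[!unknown, , drop = FALSE]
    }
    off_panel <- !(events$rbp %in% rbp_panel)
    if (any(off_panel)) {
      warning(sum(off_panel), " binding event(s) for RBPs outside the panel skipped")
      events <- events[!off_panel, , drop = FALSE]
    }
    if (nrow(events)) {
      key <- paste(events$flank_id, events$rbp, sep = "\r")
      best <- tapply(events$z_score, key, max)
      parts <- strsplit(names(best), "\r", fixed = TRUE)
      ri <- match(vapply(parts, `[[`, "", 1L), flank_ids)
      ci <- match(vapply(parts, `[[`, "", 2L), rbp_panel)
      val <- as.numeric(best)
      val[val < z_min] <- 0
      x[cbind(ri, ci)] <- val
    }
  }
  y <- factor(flank_labels$label, levels = c("control", "epispliced"))
  list(x = x, y = y)
}

#' Pairwise RBP binding-score correlation with significance flags
#'
#' Pearson correlation between all pairs of feature columns, with two-sided
#' p-values from the exact t transform and Benjamini-Hochberg adjustment over
#' the upper triangle. Pairs involving a constant column are undefined and
#' flagged non-significant.
#'
#' @param x numeric matrix (rows = flanks, columns = RBPs), >= 3 rows.
#' @param r_min correlation threshold for flagging (default 0.7).
#' @param fdr_max BH-FDR threshold for flagging (default 0.05).
#' @return data.frame `rbp1`, `rbp2`, `r`, `p`, `p_fdr`, `significant`
#'   (one row per unordered pair).
#' @export
rbp_correlation <- function(x, r_min = 0.7, fdr_max = 0.05) {
  stopifnot(is.matrix(x), nrow(x) >= 3, ncol(x) >= 2)
  n <- nrow(x)
  r <- suppressWarnings(stats::cor(x))            # NA for constant columns
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]
  tstat <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rv) >= 1] <- 0
  p_fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- data.frame(
    rbp1 = colnames(x)[ut[, 1L]],
    rbp2 = colnames(x)[ut[, 2L]],
    r = rv, p = p, p_fdr = p_fdr,
    stringsAsFactors = FALSE
  )
  out$significant <- !is.na(out$r) & out$r >= r_min & !is.na(out$p_fdr) &
    out$p_fdr < fdr_max
  out
}

#' AU-richness of a binding motif
#'
#' Mean over motif positions of P(A) + P(U), from a position weight matrix
#' (rows or columns named A/C/G/U; T read as U) or, as fallback, from the
#' letter counts of a consensus string.
#'
#' @param pwm numeric matrix with an A/C/G/U(T) dimension, probabilities
#'   summing to 1 per position; or NULL.
#' @param consensus consensus string, used when `pwm` is NULL.
#' @return AU fraction in \code{[0, 1]}.
#' @export
motif_composition <- function(pwm = NULL, consensus = NULL) {
  if (!is.null(pwm)) {
    stopifnot(is.matrix(pwm))
    dn <- dimnames(pwm)
    norm_names <- function(x) {
      x <- toupper(x); x[x == "T"] <- "U"; x
    }
    if (!is.null(dn[[1]]) && all(norm_names(dn[[1]]) %in% c("A", "C", "G", "U")) &&
        nrow(pwm) == 4L) {
      rownames(pwm) <- norm_names(dn[[1]])
    } else if (!is.null(dn[[2]]) && ncol(pwm) == 4L) {
      pwm <- t(pwm)
      rownames(pwm) <- norm_names(dn[[2]])
    } else {
      stop("PWM must have a 4-letter A/C/G/U dimension with names")
    }
    sums <- colSums(pwm)
    if (any(abs(sums - 1) > 1e-9)) stop("PWM columns must each sum to 1")
    return(mean(pwm["A", ] + pwm["U", ]))
  }
  stopifnot(is.character(consensus), nchar(consensus) > 0)
  letters_ <- strsplit(toupper(consensus), "")[[1]]
  letters_[letters_ == "T"] <- "U"
  mean(letters_ %in% c("A", "U"))
}
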