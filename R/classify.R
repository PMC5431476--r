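#' Confusion counts and the four evaluation metrics
#'
#' NPDR eyes are the positive class and PDR eyes the negative class.
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A zero
#' factor in the MCC denominator yields MCC = 0 with `mcc_flagged = TRUE`.
#'
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers")
  structure(as.list(counts), class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param counts a `confusion_counts`.
#' @return `compute_metrics` returns a `metric_set`: list with `sen`,
#'   `spe`, `acc` (fractions in [0, 1]), `mcc` (in [-1, 1]) and
#'   `mcc_flagged`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  flagged <- denom == 0
  mcc <- if (flagged) {
    warning("MCC denominator has a zero factor; reporting MCC = 0")
    0
  } else {
    (tp * tn - fp * fn) / sqrt(denom)
  }
  structure(list(sen = sen, spe = spe, acc = acc, mcc = mcc,
                 mcc_flagged = flagged), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Sen %.2f%%  Spe %.2f%%  Acc %.2f%%  MCC %.4f\n",
              100 * x$sen, 100 * x$spe, 100 * x$acc, x$mcc))
  invisible(x)
}

#' The eight evaluated feature combinations
#'
#' All combinations built on average area (1) and average amount (2), with
#' average distance (3), average altitude (4) and average reflectivity (5)
#' appended: \{1,2\}, \{1,2,3\}, \{1,2,4\}, \{1,2,5\}, \{1,2,3,4\},
#' \{1,2,3,5\}, \{1,2,4,5\}, \{1,2,3,4,5\}.
#'
#' @return list of 8 integer vectors in that order.
#' @export
enumerate_combos <- function() {
  list(c(1L, 2L), c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 2L, 5L),
       c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 5L), c(1L, 2L, 4L, 5L),
       c(1L, 2L, 3L, 4L, 5L))
}

#' SVM configuration for severity classification
#'
#' @param c_grid,g_grid candidate regularization costs and RBF widths;
#'   defaults are powers of two from 2^-8 to 2^8 in steps of 2^2.
#' @param inner_folds folds of the inner cross-validation used for the
#'   grid search.
#' @export
svm_config <- function(c_grid = 2^seq(-8, 8, by = 2),
                       g_grid = 2^seq(-8, 8, by = 2), inner_folds = 5L) {
  if (length(c_grid) == 0L || length(g_grid) == 0L ||
      any(c_grid <= 0) || any(g_grid <= 0))
    stop("grids must be nonempty and positive")
  list(c_grid = sort(c_grid), g_grid = sort(g_grid),
       inner_folds = as.integer(inner_folds))
}

# Deterministic stratified fold assignment: within each class, members in
# index order get folds 1..k cyclically.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fit_svm <- function(x, y, cost, gamma) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

# Inner-CV grid search; returns the (c, g) with the highest mean fold
# accuracy, ties broken toward smaller c then smaller g.
grid_search_cg <- function(x, y, cfg) {
  if (length(cfg$c_grid) == 1L && length(cfg$g_grid) == 1L)
    return(c(cfg$c_grid, cfg$g_grid))
  k <- min(cfg$inner_folds, min(table(y)))
  folds <- stratified_folds(y, k)
  best <- c(NA, NA); best_acc <- -1
  for (cc in cfg$c_grid) {
    for (gg in cfg$g_grid) {
      correct <- 0L; tried <- 0L
      for (f in seq_len(k)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L) next
        m <- fit_svm(x[tr, , drop = FALSE], y[tr], cc, gg)
        pr <- predict(m, x[!tr, , drop = FALSE])
        correct <- correct + sum(pr == y[!tr])
        tried <- tried + sum(!tr)
      }
      acc <- if (tried > 0) correct / tried else 0
      if (acc > best_acc + 1e-12) { best_acc <- acc; best <- c(cc, gg) }
    }
  }
  best
}

#' Leave-one-out SVM evaluation of one feature combination
#'
#' For each eye, an RBF SVM is trained on the remaining eyes with (c, g)
#' chosen by an inner stratified cross-validated grid search (highest
#' inner accuracy; ties toward smallest c then smallest g), and the
#' held-out eye is predicted. Counts accumulate with NPDR as the positive
#' class. Fully deterministic for fixed inputs and grids.
#'
#' @param features numeric matrix (eyes x 5), normalized to [0, 1].
#' @param labels factor or character vector of "NPDR"/"PDR".
#' @param combo integer vector of feature columns to use (see
#'   [enumerate_combos]).
#' @param cfg an [svm_config].
#' @return list with `counts` ([confusion_counts]), `metrics`
#'   ([compute_metrics] result) and `predictions`.
#' @export
loo_evaluate <- function(features, labels, combo = c(1L, 2L),
                         cfg = svm_config()) {
  x <- as.matrix(features)[, combo, drop = FALSE]
  x[is.na(x)] <- 0  # eyes without lesions contribute zero-valued features
  y <- factor(as.character(labels), levels = c("NPDR", "PDR"))
  if (any(is.na(y))) stop("labels must be 'NPDR' or 'PDR'")
  if (min(table(y)) < 2L) stop("need at least 2 eyes per class")
  n <- nrow(x)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2L)
      stop("training fold for eye ", i, " contains a single class")
    cg <- grid_search_cg(x[tr, , drop = FALSE], y[tr], cfg)
    m <- fit_svm(x[tr, , drop = FALSE], y[tr], cg[1], cg[2])
    pred[i] <- predict(m, x[i, , drop = FALSE])
  }
  counts <- confusion_counts(tp = sum(pred == "NPDR" & y == "NPDR"),
                             fp = sum(pred == "NPDR" & y == "PDR"),
                             tn = sum(pred == "PDR" & y == "PDR"),
                             fn = sum(pred == "PDR" & y == "NPDR"))
  list(counts = counts, metrics = compute_metrics(counts),
       predictions = pred)
}

#' Severity evaluation report over lesion groups and feature combinations
#'
#' Evaluates [loo_evaluate] for all eight feature combinations on each of
#' the supplied per-eye feature tables (typically HE lesions only, HRF
#' excluding HEs, and all HRF), after cohort-wide min-max normalization of
#' the five features.
#'
#' @param feature_tables named list of data.frames with the
#'   [write_feature_table] columns.
#' @param cfg an [svm_config].
#' @return data.frame with columns group, combo, sen, spe, acc (percent)
#'   and mcc (x100, as conventionally tabulated).
#' @export
severity_report <- function(feature_tables, cfg = svm_config()) {
  feat_cols <- c("avg_area_mm2", "amount", "avg_distance_um",
                 "avg_altitude_um", "avg_reflectivity")
  rows <- list()
  for (g in names(feature_tables)) {
    tab <- feature_tables[[g]]
    m <- as.matrix(tab[, feat_cols])
    m[is.na(m)] <- 0
    m <- normalize_features(m)
    for (combo in enumerate_combos()) {
      r <- loo_evaluate(m, tab$label, combo, cfg)
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, combo = paste(combo, collapse = ","),
                   sen = 100 * r$metrics$sen, spe = 100 * r$metrics$spe,
                   acc = 100 * r$metrics$acc, mcc = 100 * r$metrics$mcc,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @rdname severity_report
#' @param report a `severity_report` data.frame.
#' @export
format_severity_report <- function(report) {
  lines <- sprintf("%-12s combo %-10s Sen %6.2f  Spe %6.2f  Acc %6.2f  MCC %6.2f",
                   report$group, report$combo, report$sen, report$spe,
                   report$acc, report$mcc)
  paste(lines, collapse = "\n")
}
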