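#' Confusion counts for binary site prediction
#'
#' Counts are reported in the convention used throughout the package:
#' `n_pos` / `n_neg` are the class totals, `false_neg` the true sites
#' predicted as non-sites, and `false_pos` the non-sites predicted as
#' sites.
#'
#' @param labels 0/1 vector of true labels.
#' @param predictions 0/1 vector of predicted labels.
#' @return Named list `n_pos`, `n_neg`, `false_neg`, `false_pos`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length")
  }
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1))) {
    stop("labels and predictions must be 0/1")
  }
  list(n_pos = sum(labels == 1),
       n_neg = sum(labels == 0),
       false_neg = sum(labels == 1 & predictions == 0),
       false_pos = sum(labels == 0 & predictions == 1))
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Sn = 1 - FN/P, Sp = 1 - FP/N, Acc = 1 - (FN+FP)/(P+N); MCC is the
#' Matthews correlation coefficient, identical to the Pearson correlation
#' of the two binary vectors. A zero MCC denominator (a degenerate row or
#' column of the confusion table) yields 0 with a warning.
#'
#' @param counts List as returned by [confusion_counts()].
#' @return Named list `sn`, `sp`, `acc`, `mcc`.
#' @export
compute_metrics <- function(counts) {
  P <- counts$n_pos; N <- counts$n_neg
  FN <- counts$false_neg; FP <- counts$false_pos
  stopifnot(P > 0, N > 0, FN >= 0, FP >= 0, FN <= P, FP <= N)
  TP <- P - FN; TN <- N - FP
  sn <- 1 - FN / P
  sp <- 1 - FP / N
  acc <- 1 - (FN + FP) / (P + N)
  denom <- sqrt((TP + FP)) * sqrt((TP + FN)) * sqrt((TN + FP)) * sqrt((TN + FN))
  if (denom == 0) {
    warning("MCC denominator is zero; returning 0")
    mcc <- 0
  } else {
    mcc <- (TP * TN - FP * FN) / denom
  }
  list(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Equals the Mann-Whitney statistic: the fraction of (positive, negative)
#' pairs in which the positive scores higher, with ties counted as one
#' half. Computed from average ranks, so it is exact under ties.
#'
#' @param labels 0/1 vector.
#' @param scores Real-valued scores, higher = more likely positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length")
  }
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Sweeps every distinct score threshold and returns the (FPR, TPR) path
#' from (0, 0) to (1, 1). Its trapezoidal area equals [roc_auc()] to
#' numerical precision.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `fpr` and `tpr`, monotone
#'   non-decreasing in both.
#' @export
roc_curve_points <- function(labels, scores) {
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC undefined: both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # collapse tied scores into single thresholds
  last_of_run <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(lab == 1)[last_of_run]
  fp <- cumsum(lab == 0)[last_of_run]
  data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Evaluate a fitted ensemble on labeled data
#'
#' Scores every window with each sub-model and with the fused rule, then
#' reports Sn, Sp, Acc, MCC and AUC per sub-model and for the fused
#' ensemble (the layout of a per-sub-model performance table with one
#' extra fused row). Fused AUC uses the continuous fused score
#' (`min` by default, consistent with the unanimous decision); the fused
#' 0/1 call uses the model's fusion rule.
#'
#' @param model A fitted [promethyl()] object.
#' @param samples Labeled sample data frame.
#' @return Object of class `promethyl_eval`: list with `table` (k+1 row
#'   data frame), `counts` (fused confusion counts) and the fused metrics.
#' @export
evaluate <- function(model, samples) {
  stopifnot(inherits(model, "promethyl"))
  validate_samples(samples, labeled = TRUE)
  labels <- samples$label
  scores <- predict_proba(model, samples)
  thr <- model$threshold
  row_for <- function(name, sc, pred) {
    cc <- confusion_counts(labels, pred)
    m <- compute_metrics(cc)
    data.frame(model = name, sn = m$sn, sp = m$sp, acc = m$acc, mcc = m$mcc,
               auc = roc_auc(labels, sc), stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(model$k), function(i) {
    row_for(paste0("submodel_", i), scores[, i],
            as.integer(scores[, i] > thr))
  })
  fused_sc <- fuse_score(scores, model$score_fusion)
  fused_pred <- fuse_decision(scores, model$fusion, thr)
  rows[[model$k + 1L]] <- row_for("fused", fused_sc, fused_pred)
  tab <- do.call(rbind, rows)
  fused_counts <- confusion_counts(labels, fused_pred)
  structure(list(table = tab,
                 counts = fused_counts,
                 fused = as.list(tab[model$k + 1L, -1]),
                 labels = labels,
                 fused_scores = fused_sc),
            class = "promethyl_eval")
}

#' @export
print.promethyl_eval <- function(x, ...) {
  cat("Evaluation on", x$counts$n_pos, "positives /",
      x$counts$n_neg, "negatives\n\n")
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.promethyl_eval <- function(x, ...) {
  pts <- roc_curve_points(x$labels, x$fused_scores)
  plot(pts$fpr, pts$tpr, type = "l", xlab = "False positive rate (1 - Sp)",
       ylab = "True positive rate (Sn)",
       main = sprintf("Fused ROC (AUC = %.4f)", x$fused$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report A `promethyl_eval` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  jsonlite::write_json(list(counts = report$counts,
                            fused = report$fused,
                            table = report$table),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Repeated stratified k-fold cross-validation of the full ensemble
#'
#' Per repeat, the labeled data are split into stratified folds; for each
#' fold the complete pipeline (negative partitioning, balanced subsets,
#' sub-model training, fusion) is rebuilt on the training folds and
#' evaluated on the held-out fold. Metrics are averaged over folds, then
#' over repeats. All randomness derives from `seed`.
#'
#' @param samples Labeled sample data frame.
#' @param folds Number of folds (>= 2).
#' @param repeats Number of repeats.
#' @param ... Passed to [promethyl()] (encoding, k, config, ...).
#' @param seed Master seed.
#' @return Object of class `promethyl_cv`: `table` with the averaged
#'   per-sub-model and fused metrics, `fused` (the averaged fused row) and
#'   `per_fold` details.
#' @export
cross_validate <- function(samples, folds = 5L, repeats = 1L, ..., seed = 1L) {
  validate_samples(samples, labeled = TRUE)
  stopifnot(folds >= 2L, repeats >= 1L)
  n <- nrow(samples)
  for (cl in c(0L, 1L)) {
    if (sum(samples$label == cl) < folds) {
      stop("class ", cl, " has fewer members than folds; cannot stratify")
    }
  }
  per_fold <- list()
  tables <- list()
  for (r in seq_len(repeats)) {
    fold_of <- integer(n)
    for (cl in c(0L, 1L)) {
      idx <- which(samples$label == cl)
      perm <- with_seed(derive_seed(seed, 23L, r, cl), sample(idx))
      fold_of[perm] <- rep(seq_len(folds), length.out = length(perm))
    }
    for (f in seq_len(folds)) {
      train <- samples[fold_of != f, , drop = FALSE]
      test <- samples[fold_of == f, , drop = FALSE]
      fit <- promethyl(train, ..., seed = derive_seed(seed, 29L, r, f))
      ev <- evaluate(fit, test)
      per_fold[[length(per_fold) + 1L]] <-
        list(repeat_ = r, fold = f, eval = ev)
      tables[[length(tables) + 1L]] <- ev$table
    }
  }
  metric_cols <- c("sn", "sp", "acc", "mcc", "auc")
  avg <- tables[[1]]
  for (col in metric_cols) {
    avg[[col]] <- rowMeans(vapply(tables, `[[`, numeric(nrow(avg)), col))
  }
  fused <- as.list(avg[nrow(avg), metric_cols])
  structure(list(table = avg, fused = fused, per_fold = per_fold,
                 folds = folds, repeats = repeats, seed = seed),
            class = "promethyl_cv")
}

#' @export
print.promethyl_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeat(s), seed %d\n\n",
              x$folds, x$repeats, x$seed))
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
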