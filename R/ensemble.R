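#' Partition negative samples into near-equal groups
#'
#' Randomly (seeded) divides the indices or ids of the negative class into
#' `k` disjoint groups whose sizes differ by at most one. Each group later
#' trains one balanced sub-model.
#'
#' @param negative_ids Vector of ids (or indices).
#' @param k Number of groups.
#' @param seed Integer seed.
#' @return List of `k` disjoint vectors covering `negative_ids`.
#' @export
partition_negatives <- function(negative_ids, k, seed = 1) {
  n <- length(negative_ids)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("cannot partition ", n, " negatives into ", k, " groups")
  perm <- with_seed(derive_seed(seed, 7L), sample(negative_ids))
  grp <- rep(seq_len(k), length.out = n)   # sizes differ by at most 1
  grp <- sort(grp)
  split(perm, grp)
}

#' Build one balanced training subset
#'
#' Combines a negative group with the positive samples. If the two sides
#' differ in size, the larger side is down-sampled (seeded) to the smaller,
#' so the returned subset is exactly balanced.
#'
#' @param group Negative sample data frame.
#' @param positives Positive sample data frame.
#' @param seed Integer seed for the down-sampling draw.
#' @return A labeled sample data frame with equal class counts.
#' @export
build_balanced_subset <- function(group, positives, seed = 1) {
  if (nrow(group) == 0L || nrow(positives) == 0L) {
    stop("both the negative group and the positives must be non-empty")
  }
  m <- min(nrow(group), nrow(positives))
  if (nrow(group) > m) {
    keep <- with_seed(derive_seed(seed, 11L), sample.int(nrow(group), m))
    group <- group[sort(keep), , drop = FALSE]
  }
  if (nrow(positives) > m) {
    keep <- with_seed(derive_seed(seed, 13L), sample.int(nrow(positives), m))
    positives <- positives[sort(keep), , drop = FALSE]
  }
  out <- rbind(group, positives)
  rownames(out) <- NULL
  out
}

#' Fit the down-sampling ensemble predictor
#'
#' Trains the full fusion-decision model on labeled C-centred windows:
#' the negatives are partitioned into `k` near-equal groups
#' ([partition_negatives()]), each group is paired with the positives to
#' form a balanced subset ([build_balanced_subset()]), one sub-network is
#' trained per subset ([train_submodel()]) on the chosen encoding, and
#' predictions are fused across sub-models -- by default a window is called
#' methylated only if every sub-model scores it above the threshold
#' (strict unanimity).
#'
#' Windows containing `N` are dropped from training with a message (they
#' are still scored at prediction time).
#'
#' @param x Labeled sample data frame with columns `window` and `label`
#'   (see [read_samples_tsv()], [generate_dataset()]), or a character
#'   vector of windows accompanied by `y`.
#' @param y Optional 0/1 labels when `x` is a character vector.
#' @param encoding Feature encoding: `"onehot"` (default), `"dpf"` or
#'   `"fused"`.
#' @param k Number of negative groups / sub-models.
#' @param fusion Decision fusion rule: `"unanimous"` (default) or
#'   `"majority"`.
#' @param score_fusion Continuous score fusion for ranking/ROC: `"min"`
#'   (default; thresholding the min score reproduces the unanimous
#'   decision) or `"mean"`.
#' @param threshold Decision threshold on sub-model positive-class
#'   probability.
#' @param config A [submodel_config()]; its seed is re-derived per
#'   sub-model from `seed`.
#' @param seed Master seed; the partitioning, down-sampling and per-sub-model
#'   training seeds are all derived from it deterministically.
#' @param verbose Print one line per trained sub-model.
#' @return An object of class `promethyl`.
#' @seealso [predict.promethyl()], [evaluate()], [cross_validate()],
#'   [save_promethyl()]
#' @examples
#' d <- generate_dataset(n_pos = 40, n_neg = 120, delta = 5, effect = 0.9,
#'                       seed = 1)
#' fit <- promethyl(d, k = 3, config = submodel_config(hidden_layers = 8,
#'                  epochs = 10), seed = 1)
#' fit
#' @export
promethyl <- function(x, y = NULL,
                      encoding = c("onehot", "dpf", "fused"),
                      k = 11L,
                      fusion = c("unanimous", "majority"),
                      score_fusion = c("min", "mean"),
                      threshold = 0.5,
                      config = submodel_config(),
                      seed = 1L,
                      verbose = FALSE) {
  encoding <- match.arg(encoding)
  fusion <- match.arg(fusion)
  score_fusion <- match.arg(score_fusion)
  if (is.character(x)) {
    if (is.null(y)) stop("labels 'y' are required when 'x' is a vector of windows")
    x <- new_samples(x, label = y)
  }
  validate_samples(x, labeled = TRUE)
  if (any(x$has_n)) {
    message("dropping ", sum(x$has_n), " window(s) containing N from training")
    x <- x[!x$has_n, , drop = FALSE]
  }
  delta <- samples_delta(x)
  pos <- x[x$label == 1L, , drop = FALSE]
  neg <- x[x$label == 0L, , drop = FALSE]
  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    stop("training data must contain both classes")
  }
  groups <- partition_negatives(seq_len(nrow(neg)), k = k, seed = seed)
  feats_pos <- encode_batch(pos, encoding)
  submodels <- vector("list", k)
  for (i in seq_len(k)) {
    grp <- neg[groups[[i]], , drop = FALSE]
    m <- min(nrow(grp), nrow(pos))
    # balance by seeded down-sampling of the larger side
    if (nrow(grp) > m) {
      keep <- with_seed(derive_seed(seed, 11L, i), sample.int(nrow(grp), m))
      grp <- grp[sort(keep), , drop = FALSE]
    }
    fp <- feats_pos
    if (nrow(fp) > m) {
      keep <- with_seed(derive_seed(seed, 13L, i), sample.int(nrow(fp), m))
      fp <- fp[sort(keep), , drop = FALSE]
    }
    X <- rbind(encode_batch(grp, encoding), fp)
    lab <- c(rep(0L, m), rep(1L, m))
    cfg <- config
    cfg$seed <- derive_seed(seed, 17L, i)
    submodels[[i]] <- train_submodel(X, lab, cfg)
    if (verbose) {
      message(sprintf("sub-model %2d/%d: n=%d, best epoch %d, val loss %.4f",
                      i, k, 2L * m, submodels[[i]]$best_epoch,
                      submodels[[i]]$val_loss))
    }
  }
  structure(list(submodels = submodels,
                 encoding = encoding,
                 delta = delta,
                 k = as.integer(k),
                 fusion = fusion,
                 score_fusion = score_fusion,
                 threshold = threshold,
                 config = config,
                 seed = as.integer(seed),
                 n_pos = nrow(pos),
                 n_neg = nrow(neg),
                 version = as.character(packageVersion("promethyl"))),
            class = "promethyl")
}

#' Per-sample sub-model scores
#'
#' @param model A fitted [promethyl()] object.
#' @param samples Sample data frame or character vector of windows whose
#'   length matches the model's `2*delta+1`.
#' @return Numeric matrix, one row per sample, one column per sub-model,
#'   entries in `[0, 1]`.
#' @export
predict_proba <- function(model, samples) {
  stopifnot(inherits(model, "promethyl"))
  windows <- if (is.data.frame(samples)) samples$window else samples
  L <- unique(nchar(windows))
  if (length(L) > 1L || (length(L) == 1L && L != 2L * model$delta + 1L)) {
    stop("window length ", paste(L, collapse = "/"),
         " does not match the model's delta = ", model$delta,
         " (expected length ", 2L * model$delta + 1L, ")")
  }
  X <- encode_batch(windows, model$encoding)
  scores <- vapply(model$submodels, function(m) predict(m, X),
                   numeric(length(windows)))
  if (length(windows) == 1L) scores <- matrix(scores, nrow = 1L)
  scores
}

#' Fuse sub-model decisions and scores
#'
#' `fuse_decision` turns a vector of sub-model scores into a 0/1 call:
#' under `"unanimous"` the call is 1 only when every score exceeds the
#' threshold (the strict standard); under `"majority"` when more than half
#' do. `fuse_score` produces a continuous ensemble score: `"min"` is
#' consistent with unanimity (thresholding the min at `t` reproduces the
#' unanimous decision at `t`), `"mean"` averages.
#'
#' @param scores Numeric vector of sub-model scores in `[0, 1]` (one
#'   sample), or a matrix with one row per sample.
#' @param fusion `"unanimous"` or `"majority"`.
#' @param threshold Score threshold.
#' @return `fuse_decision`: integer 0/1 per sample. `fuse_score`: numeric
#'   per sample.
#' @export
fuse_decision <- function(scores, fusion = c("unanimous", "majority"),
                          threshold = 0.5) {
  fusion <- match.arg(fusion)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  if (ncol(scores) == 0L) stop("empty score vector")
  hits <- rowSums(scores > threshold)
  out <- if (fusion == "unanimous") as.integer(hits == ncol(scores))
         else as.integer(hits > ncol(scores) / 2)
  out
}

#' @rdname fuse_decision
#' @param method `"min"` or `"mean"`.
#' @export
fuse_score <- function(scores, method = c("min", "mean")) {
  method <- match.arg(method)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  if (ncol(scores) == 0L) stop("empty score vector")
  if (method == "min") apply(scores, 1, min) else rowMeans(scores)
}

#' Predict methylation of new windows
#'
#' @param object A fitted [promethyl()] model.
#' @param newdata Sample data frame or character vector of windows.
#' @param type `"score"` (fused continuous score, default), `"class"`
#'   (fused 0/1 decision) or `"submodels"` (the n-by-k score matrix).
#' @param ... Unused.
#' @return Numeric vector or matrix, depending on `type`.
#' @export
predict.promethyl <- function(object, newdata,
                              type = c("score", "class", "submodels"), ...) {
  type <- match.arg(type)
  scores <- predict_proba(object, newdata)
  switch(type,
         submodels = scores,
         score = fuse_score(scores, object$score_fusion),
         class = fuse_decision(scores, object$fusion, object$threshold))
}

#' @export
print.promethyl <- function(x, ...) {
  cat("Promoter 5mC fusion-decision ensemble\n")
  cat(sprintf("  %d sub-models, encoding '%s', window %d nt (delta = %d)\n",
              x$k, x$encoding, 2 * x$delta + 1, x$delta))
  cat(sprintf("  fusion: %s vote at threshold %.2f (score fusion: %s)\n",
              x$fusion, x$threshold, x$score_fusion))
  cat(sprintf("  trained on %d positives / %d negatives (seed %d)\n",
              x$n_pos, x$n_neg, x$seed))
  invisible(x)
}

#' @export
summary.promethyl <- function(object, ...) {
  tab <- data.frame(
    submodel = seq_len(object$k),
    best_epoch = vapply(object$submodels, `[[`, integer(1), "best_epoch"),
    val_loss = vapply(object$submodels, `[[`, numeric(1), "val_loss"))
  out <- list(model = object, submodels = tab)
  class(out) <- "summary.promethyl"
  out
}

#' @export
print.summary.promethyl <- function(x, ...) {
  print(x$model)
  cat("\nPer-sub-model training summary:\n")
  print(x$submodels, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.promethyl <- function(object, ...) {
  lapply(object$submodels, function(m) m$par)
}

#' Save / load a fitted ensemble
#'
#' `save_promethyl` writes a model bundle: a directory containing a JSON
#' manifest (encoding, delta, k, fusion rule, threshold, seed, package
#' version, sub-model configuration) and the sub-network weights.
#' `load_promethyl` restores it and verifies compatibility; predictions of
#' the reloaded model are bit-identical.
#'
#' @param model A fitted [promethyl()] object.
#' @param path Bundle directory (created if needed).
#' @return `save_promethyl`: `path`, invisibly. `load_promethyl`: the
#'   restored `promethyl` object.
#' @export
save_promethyl <- function(model, path) {
  stopifnot(inherits(model, "promethyl"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "promethyl-bundle",
                   format_version = 1L,
                   package_version = model$version,
                   encoding = model$encoding,
                   delta = model$delta,
                   k = model$k,
                   fusion = model$fusion,
                   score_fusion = model$score_fusion,
                   threshold = model$threshold,
                   seed = model$seed,
                   n_pos = model$n_pos,
                   n_neg = model$n_neg,
                   config = unclass(model$config))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model$submodels, file.path(path, "submodels.rds"))
  invisible(path)
}

#' @rdname save_promethyl
#' @export
load_promethyl <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  sm_path <- file.path(path, "submodels.rds")
  if (!file.exists(mf_path) || !file.exists(sm_path)) {
    stop("'", path, "' is not a promethyl model bundle ",
         "(manifest.json or submodels.rds missing)")
  }
  manifest <- tryCatch(jsonlite::read_json(mf_path),
                       error = function(e) stop("incompatible bundle: ",
                                                "unreadable manifest: ",
                                                conditionMessage(e)))
  if (!identical(manifest$format, "promethyl-bundle") ||
      !identical(as.integer(manifest$format_version), 1L)) {
    stop("incompatible bundle: unknown format or format version")
  }
  submodels <- tryCatch(readRDS(sm_path),
                        error = function(e) stop("incompatible bundle: ",
                                                 "corrupt or truncated weights: ",
                                                 conditionMessage(e)))
  if (length(submodels) != manifest$k) {
    stop("incompatible bundle: manifest says k = ", manifest$k,
         " but ", length(submodels), " sub-models were found")
  }
  cfg <- manifest$config
  structure(list(submodels = submodels,
                 encoding = manifest$encoding,
                 delta = as.integer(manifest$delta),
                 k = as.integer(manifest$k),
                 fusion = manifest$fusion,
                 score_fusion = manifest$score_fusion,
                 threshold = manifest$threshold,
                 config = submodel_config(
                   hidden_layers = unlist(cfg$hidden_layers),
                   dropout_rate = cfg$dropout_rate,
                   epochs = cfg$epochs,
                   batch_size = cfg$batch_size,
                   learning_rate = cfg$learning_rate,
                   patience = cfg$patience,
                   validation_fraction = cfg$validation_fraction,
                   seed = cfg$seed),
                 seed = as.integer(manifest$seed),
                 n_pos = manifest$n_pos,
                 n_neg = manifest$n_neg,
                 version = manifest$package_version),
            class = "promethyl")
}
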