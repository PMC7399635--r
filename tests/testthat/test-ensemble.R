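test_that("partition_negatives yields disjoint, covering, near-equal groups", {
  g <- partition_negatives(1:22, k = 11, seed = 1)
  expect_length(g, 11L)
  expect_true(all(lengths(g) == 2L))
  expect_setequal(unlist(g), 1:22)

  g <- partition_negatives(1:23, k = 11, seed = 1)
  expect_setequal(unlist(g), 1:23)
  expect_equal(unname(sort(lengths(g), decreasing = TRUE)),
               c(3L, rep(2L, 10)))

  expect_identical(partition_negatives(1:40, 5, seed = 3),
                   partition_negatives(1:40, 5, seed = 3))
  expect_error(partition_negatives(1:5, 11, seed = 1), "cannot partition")
  expect_error(partition_negatives(1:5, 1, seed = 1), "at least 2")
})

test_that("build_balanced_subset balances by down-sampling the larger side", {
  d <- generate_dataset(n_pos = 100, n_neg = 105, delta = 3, seed = 4)
  pos <- d[d$label == 1, ]
  neg <- d[d$label == 0, ]
  sub <- build_balanced_subset(neg[1:100, ], pos)
  expect_equal(nrow(sub), 200L)
  expect_equal(sum(sub$label == 0), sum(sub$label == 1))

  sub <- build_balanced_subset(neg, pos)   # 105 vs 100
  expect_equal(nrow(sub), 200L)
  expect_equal(sum(sub$label == 0), 100L)
  expect_error(build_balanced_subset(neg[0, ], pos), "non-empty")
})

test_that("fuse_decision implements strict unanimity and majority", {
  expect_equal(fuse_decision(rep(0.9, 11), "unanimous"), 1L)
  expect_equal(fuse_decision(c(rep(0.9, 10), 0.4), "unanimous"), 0L)
  expect_equal(fuse_decision(rep(0.1, 11), "unanimous"), 0L)
  expect_equal(fuse_decision(rep(0.1, 11), "majority"), 0L)
  expect_equal(fuse_decision(c(rep(0.9, 6), rep(0.1, 5)), "majority"), 1L)
  expect_equal(fuse_decision(c(rep(0.9, 5), rep(0.1, 6)), "majority"), 0L)
  expect_error(fuse_decision(numeric(0)), "empty")
})

test_that("min-score fusion is threshold-equivalent to the unanimous rule", {
  expect_equal(fuse_score(c(0.9, 0.8, 0.7), "min"), 0.7)
  expect_equal(fuse_score(c(0.9, 0.8, 0.7), "mean"), 0.8)
  expect_error(fuse_score(numeric(0)), "empty")
  set.seed(41)
  for (i in 1:200) {
    sc <- runif(11)
    t <- runif(1)
    expect_equal(as.integer(fuse_score(sc, "min") > t),
                 fuse_decision(sc, "unanimous", t))
  }
})

test_that("the fitted ensemble has the promised structure and methods", {
  d <- generate_dataset(n_pos = 30, n_neg = 120, delta = 4, effect = 0.8,
                        seed = 5)
  fit <- promethyl(d, k = 3, config = tiny_config(), seed = 5)
  expect_s3_class(fit, "promethyl")
  expect_length(fit$submodels, 3L)
  expect_equal(fit$delta, 4L)

  sc <- predict(fit, d, type = "submodels")
  expect_equal(dim(sc), c(nrow(d), 3L))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_identical(sc, predict(fit, d, type = "submodels"))  # deterministic

  fused <- predict(fit, d, type = "score")
  expect_equal(fused, apply(sc, 1, min))
  cls <- predict(fit, d, type = "class")
  expect_true(all(cls %in% 0:1))

  expect_output(print(fit), "3 sub-models")
  expect_output(print(summary(fit)), "val_loss")
  expect_length(coef(fit), 3L)

  expect_error(predict(fit, "ACCCA"), "does not match")
  expect_error(promethyl(d[d$label == 1, ], k = 2, config = tiny_config()),
               "both classes")
})

test_that("refitting with the same master seed reproduces predictions", {
  d <- generate_dataset(n_pos = 25, n_neg = 100, delta = 4, effect = 0.5,
                        seed = 6)
  probe <- generate_dataset(n_pos = 5, n_neg = 20, delta = 4, seed = 7)
  f1 <- promethyl(d, k = 4, config = tiny_config(), seed = 8)
  f2 <- promethyl(d, k = 4, config = tiny_config(), seed = 8)
  expect_identical(predict(f1, probe), predict(f2, probe))
})

test_that("unanimous fusion never flags more negatives than any sub-model", {
  d <- generate_dataset(n_pos = 40, n_neg = 200, delta = 4, effect = 0.6,
                        seed = 9)
  fit <- promethyl(d, k = 4, config = tiny_config(), seed = 9)
  test <- generate_dataset(n_pos = 30, n_neg = 150, delta = 4, effect = 0.6,
                           seed = 10)
  sc <- predict(fit, test, type = "submodels")
  fused_pos <- which(fuse_decision(sc, "unanimous", fit$threshold) == 1)
  for (j in seq_len(ncol(sc))) {
    expect_true(all(fused_pos %in% which(sc[, j] > fit$threshold)))
  }
  ev <- evaluate(fit, test)
  sp <- ev$table$sp
  expect_true(all(sp[length(sp)] >= sp[-length(sp)]))
})

test_that("model bundles round-trip bit-identically and reject corruption", {
  d <- generate_dataset(n_pos = 20, n_neg = 80, delta = 3, effect = 0.7,
                        seed = 11)
  fit <- promethyl(d, k = 3, config = tiny_config(), seed = 11)
  probe <- generate_dataset(n_pos = 5, n_neg = 10, delta = 3, seed = 12)
  bundle <- withr::local_tempdir()
  save_promethyl(fit, bundle)

  manifest <- jsonlite::read_json(file.path(bundle, "manifest.json"))
  expect_equal(manifest$k, 3L)
  expect_equal(manifest$encoding, "onehot")

  back <- load_promethyl(bundle)
  expect_identical(predict(back, probe), predict(fit, probe))

  # truncated weights must be detected
  rds <- file.path(bundle, "submodels.rds")
  raw <- readBin(rds, "raw", file.info(rds)$size)
  writeBin(raw[1:20], rds)
  expect_error(load_promethyl(bundle), "incompatible bundle")
  expect_error(load_promethyl(withr::local_tempdir()), "not a promethyl")
})

test_that("cross-validation partitions correctly and is seeded", {
  d <- generate_dataset(n_pos = 30, n_neg = 150, delta = 3, effect = 0.8,
                        seed = 13)
  cv <- cross_validate(d, folds = 5, k = 3, config = tiny_config(),
                       seed = 13)
  expect_s3_class(cv, "promethyl_cv")
  expect_equal(nrow(cv$table), 4L)             # k sub-models + fused
  tested <- unlist(lapply(cv$per_fold, function(pf) {
    pf$eval$counts$n_pos + pf$eval$counts$n_neg
  }))
  expect_equal(sum(tested), nrow(d))           # each sample in one test fold

  cv2 <- cross_validate(d, folds = 5, k = 3, config = tiny_config(),
                        seed = 13)
  expect_identical(cv$table, cv2$table)
  expect_error(cross_validate(d[c(1:2, 31:60), ], folds = 5, k = 2,
                              config = tiny_config()), "fewer members")
})
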