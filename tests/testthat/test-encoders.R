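test_that("one-hot encoding matches its definition", {
  expect_equal(encode_one_hot("A"), c(1, 0, 0, 0))
  expect_equal(encode_one_hot("ACGT"),
               c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1))
  w41 <- random_window(41)
  expect_length(encode_one_hot(w41), 164)
  expect_error(encode_one_hot("ACB"), "illegal character")
})

test_that("DPF encoding matches its definition", {
  # per-base property triples: A=(1,1,1), C=(0,1,0), G=(1,0,0), T=(0,0,1)
  expect_equal(encode_dpf("ACGT"),
               c(1, 1, 1, 1, 0, 1, 0, 1 / 2, 1, 0, 0, 1 / 3, 0, 0, 1, 1 / 4))
  expect_equal(encode_dpf("AAAA")[c(4, 8, 12, 16)], rep(1, 4))
  expect_length(encode_dpf(random_window(41)), 164)
})

test_that("fused encoding is one-hot followed by DPF", {
  expect_equal(encode_fused("A"), c(1, 0, 0, 0, 1, 1, 1, 1))
  w <- random_window(41)
  v <- encode_fused(w)
  expect_length(v, 328)
  expect_equal(v[1:164], encode_one_hot(w))
  expect_equal(v[165:328], encode_dpf(w))
})

test_that("encoders agree with brute-force oracles on random windows", {
  set.seed(11)
  for (i in 1:30) {
    L <- 2 * sample(2:20, 1) + 1
    w <- random_window(L, alphabet = c("A", "C", "G", "T", "N"))
    expect_identical(encode_one_hot(w), oracle_one_hot(w))
    expect_equal(encode_dpf(w), oracle_dpf(w), tolerance = 1e-15)
  }
})

test_that("encoder invariants hold", {
  set.seed(12)
  for (i in 1:20) {
    L <- 2 * sample(2:15, 1) + 1
    w <- random_window(L, alphabet = c("A", "C", "G", "T", "N"))
    chars <- strsplit(w, "")[[1]]

    oh <- matrix(encode_one_hot(w), ncol = 4, byrow = TRUE)
    block_sums <- rowSums(oh)
    expect_equal(block_sums, as.numeric(chars != "N"))
    # indicator sums recover base counts
    expect_equal(colSums(oh),
                 as.numeric(table(factor(chars, c("A", "C", "G", "T")))))

    dpf <- matrix(encode_dpf(w), ncol = 4, byrow = TRUE)
    lambda <- dpf[, 4]
    expect_equal(lambda[1], 1)
    expect_true(all(lambda > 0 & lambda <= 1))
    # lambda_k * k is the exact cumulative count of the base at k
    counts <- lambda * seq_along(chars)
    expect_equal(counts, round(counts), tolerance = 1e-9)
    for (k in seq_along(chars)) {
      expect_equal(counts[k], sum(chars[1:k] == chars[k]), tolerance = 1e-9)
    }
    expect_true(all(dpf >= 0 & dpf <= 1))

    # purity: same window, same vector
    expect_identical(encode_fused(w), encode_fused(w))
  }
})

test_that("encode_batch matches per-sample encoding and validates input", {
  empty <- encode_batch(character(0), "onehot")
  expect_equal(nrow(empty), 0L)

  w <- random_window(9)
  m <- encode_batch(rep(w, 3), "dpf")
  expect_equal(m[1, ], m[3, ])

  set.seed(13)
  wins <- replicate(8, random_window(11))
  for (enc in c("onehot", "dpf", "fused")) {
    m <- encode_batch(wins, enc)
    fun <- switch(enc, onehot = encode_one_hot, dpf = encode_dpf,
                  fused = encode_fused)
    for (i in seq_along(wins)) expect_equal(m[i, ], fun(wins[i]))
    expect_equal(attr(m, "encoding"), enc)
  }
  expect_error(encode_batch(c(random_window(9), random_window(11))),
               "mixed length")
})
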