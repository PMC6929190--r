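test_that("DCT basis is orthonormal with closed-form atoms", {
  d4 <- dct_domain(4)
  expect_equal(crossprod(d4$atoms), diag(4), tolerance = 1e-12)
  expect_equal(d4$atoms %*% t(d4$atoms), diag(4), tolerance = 1e-12)
  # N = 2: DC atom is (1/sqrt(2), 1/sqrt(2))
  d2 <- dct_domain(2)
  expect_equal(d2$atoms[, 1L], rep(1 / sqrt(2), 2), tolerance = 1e-14)
  # a constant signal loads only the DC atom
  coefs <- analyze(dct_domain(16), rep(2.5, 16))
  expect_equal(sum(abs(coefs) > 1e-10), 1L)
  expect_gt(abs(coefs[1L]), 0)
})

test_that("DCT analysis/synthesis round-trips and returns atoms for unit codes", {
  d <- dct_domain(32)
  set.seed(1)
  for (rep in 1:5) {
    x <- rnorm(32)
    expect_equal(synthesize(d, analyze(d, x)), x, tolerance = 1e-9)
  }
  e5 <- numeric(32); e5[5] <- 1
  expect_equal(synthesize(d, e5), d$atoms[, 5L], tolerance = 1e-12)
})

test_that("segment_corpus cuts non-overlapping windows, dropping the remainder", {
  expect_equal(ncol(segment_corpus(numeric(2048), 1024)$segments), 2L)
  expect_equal(ncol(segment_corpus(numeric(1024000), 1024)$segments), 1000L)
  expect_warning(empty <- segment_corpus(numeric(1023), 1024), "empty")
  expect_equal(ncol(empty$segments), 0L)
  # windows are consecutive samples
  co <- segment_corpus(as.numeric(1:10), 3)
  expect_equal(co$segments, matrix(1:9, 3, 3))
})

test_that("K-SVD on copies of one segment learns that segment as its atom", {
  seg <- sin(seq(0, 4 * pi, length.out = 32))
  corpus <- segment_corpus(rep(seg, 8), 32)
  dict <- ksvd_train(corpus, K = 1, coding_sparsity = 1, iterations = 3,
                     seed = 1)
  target <- seg / sqrt(sum(seg^2))
  err <- min(max(abs(dict$atoms[, 1L] - target)),
             max(abs(dict$atoms[, 1L] + target)))
  expect_lt(err, 1e-10)
})

test_that("K-SVD keeps unit atom norms and a non-increasing objective", {
  setup <- dictionary_recovery_setup(n = 32, K = 12, k = 2, m = 80, seed = 2)
  dict <- ksvd_train(setup$corpus, K = 12, coding_sparsity = 2,
                     iterations = 10, seed = 1)
  expect_equal(sqrt(colSums(dict$atoms^2)), rep(1, 12), tolerance = 1e-9)
  et <- dict$meta$error_trace
  expect_true(all(diff(et) <= 1e-8))
})

test_that("K-SVD analysis recovers the support of a well-separated sparse code", {
  setup <- dictionary_recovery_setup(n = 48, K = 16, k = 2, m = 120, seed = 7)
  dict <- ksvd_train(setup$corpus, K = 16, coding_sparsity = 2,
                     iterations = 15, seed = 1)
  # build an exact 2-sparse synthesis in the learned dictionary
  theta <- numeric(16); theta[c(3, 11)] <- c(1.2, -0.8)
  x <- synthesize(dict, theta)
  rec <- analyze(dict, x, sparsity = 2)
  expect_setequal(which(rec != 0), c(3, 11))
  expect_equal(rec[c(3, 11)], theta[c(3, 11)], tolerance = 1e-6)
})

test_that("dictionaries persist to delimited text and back", {
  setup <- dictionary_recovery_setup(n = 16, K = 8, k = 2, m = 40, seed = 3)
  dict <- ksvd_train(setup$corpus, K = 8, coding_sparsity = 2,
                     iterations = 3, seed = 1)
  path <- tempfile(fileext = ".txt")
  write_domain(dict, path)
  back <- read_domain(path)
  expect_equal(back$atoms, dict$atoms, tolerance = 1e-12)
  expect_equal(back$kind, "ksvd")
  expect_equal(back$meta$K, 8)
  unlink(c(path, paste0(path, ".json")))
})
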