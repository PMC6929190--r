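test_that("clean synthetic ECG peaks at the R centers and is periodic", {
  tpl <- beat_template("ecg")
  ecg <- make_ecg(tpl, duration = 2, fs = 500)
  x <- ecg$signal$samples
  r_idx <- ecg$fiducials$index[ecg$fiducials$name == "R"]
  period_n <- round(tpl$period * 500)
  for (b in seq_along(r_idx)) {
    beat_lo <- (b - 1L) * period_n + 1L
    beat_hi <- b * period_n
    expect_equal(beat_lo + which.max(x[beat_lo:beat_hi]) - 1L, r_idx[b])
  }
  # exactly two beat periods: the two halves coincide
  expect_equal(x[1:period_n], x[(period_n + 1):(2 * period_n)],
               tolerance = 1e-12)
})

test_that("ECG ground-truth fiducials sit on the clean-signal extrema", {
  ecg <- make_ecg(beat_template("ecg"), duration = 4)
  x <- ecg$clean
  fid <- ecg$fiducials
  w <- 10L
  for (b in unique(fid$beat)) {
    fb <- fid[fid$beat == b, ]
    idx <- setNames(fb$index, fb$name)
    for (nm in c("P", "R", "T")) {
      lo <- idx[[nm]] - w; hi <- idx[[nm]] + w
      expect_lte(abs(lo + which.max(x[lo:hi]) - 1L - idx[[nm]]), 1L)
    }
    for (nm in c("Q", "S")) {
      lo <- idx[[nm]] - w; hi <- idx[[nm]] + w
      expect_lte(abs(lo + which.min(x[lo:hi]) - 1L - idx[[nm]]), 1L)
    }
  }
})

test_that("generators are deterministic under a fixed noise seed", {
  ns <- noise_spec(white_sd = 0.02, seed = 42)
  a <- make_ecg(beat_template("ecg"), duration = 2, noise = ns)
  b <- make_ecg(beat_template("ecg"), duration = 2, noise = ns)
  expect_identical(a$signal$samples, b$signal$samples)
  pa <- make_ppg(beat_template("ppg"), duration = 2, noise = ns)
  pb <- make_ppg(beat_template("ppg"), duration = 2, noise = ns)
  expect_identical(pa$signal$samples, pb$signal$samples)
})

test_that("PPG beats peak at the systolic center with the valley between peaks", {
  ppg <- make_ppg(beat_template("ppg"), duration = 4)
  fid <- ppg$fiducials
  p_idx <- fid$index[fid$name == "P"]
  v_idx <- fid$index[fid$name == "V"]
  x <- ppg$clean
  tpl <- beat_template("ppg")
  period_n <- round(tpl$period * 500)
  for (b in seq_along(p_idx)) {
    beat_lo <- (b - 1L) * period_n + 1L
    beat_hi <- min(b * period_n, length(x))
    expect_lte(abs(beat_lo + which.max(x[beat_lo:beat_hi]) - 1L - p_idx[b]), 1L)
  }
  for (i in seq_along(v_idx)) {
    expect_gt(v_idx[i], p_idx[i])
    if (i + 1 <= length(p_idx)) expect_lt(v_idx[i], p_idx[i + 1])
    # valley is the minimum of the clean signal between the peaks
    lo <- p_idx[i]; hi <- min(p_idx[i] + period_n, length(x))
    expect_equal(lo + which.min(x[lo:hi]) - 1L, v_idx[i])
  }
})

test_that("population generator is reproducible and respects jitter", {
  pop0 <- make_population(5, jitter = 0, seed = 1)
  for (i in 2:5) expect_equal(pop0[[i]], pop0[[1L]])
  pop <- make_population(23, jitter = 0.1, seed = 9)
  expect_length(pop, 23)
  pop2 <- make_population(23, jitter = 0.1, seed = 9)
  expect_identical(pop, pop2)
  # subjects differ and stay valid templates (ordering enforced on build)
  amps <- sapply(pop, function(t) t$amplitudes[["R"]])
  expect_gt(sd(amps), 0)
})

test_that("make_ksparse yields exactly k nonzeros and validates k", {
  for (case in list(c(1024, 100), c(64, 1), c(16, 16))) {
    theta <- make_ksparse(case[1], case[2], seed = 3)
    expect_length(theta, case[1])
    expect_equal(sum(theta != 0), case[2])
  }
  theta <- make_ksparse(50, 7, amplitude_range = c(0.5, 1.5), seed = 1)
  mags <- abs(theta[theta != 0])
  expect_true(all(mags >= 0.5 & mags <= 1.5))
  expect_identical(theta, make_ksparse(50, 7, seed = 1))
  expect_error(make_ksparse(10, 11), "sparsity")
})
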