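test_that("ECG feature vectors have 21 named entries and PPG 12", {
  ecg <- make_ecg(beat_template("ecg"), duration = 6)
  feat <- extract_features(detect_ecg_fiducials(ecg$signal), ecg$signal)
  expect_equal(setdiff(names(feat), c("subject", "beat")),
               feature_names("ecg"))
  expect_length(feature_names("ecg"), 21L)
  expect_true(all(is.finite(as.matrix(feat[, feature_names("ecg")]))))

  ppg <- make_ppg(beat_template("ppg"), duration = 6)
  pfeat <- extract_features(detect_ppg_fiducials(ppg$signal), ppg$signal)
  expect_equal(setdiff(names(pfeat), c("subject", "beat")),
               feature_names("ppg"))
  expect_length(feature_names("ppg"), 12L)
})

test_that("amplitude features are signed value differences", {
  # Q amplitude -0.1 and R amplitude 1.0 make the Q-R feature about -1.1
  ecg <- make_ecg(beat_template("ecg"), duration = 6)
  feat <- extract_features(detect_ecg_fiducials(ecg$signal), ecg$signal)
  expect_equal(mean(feat[["a.Q-R"]]), -1.1, tolerance = 0.02)
  expect_equal(mean(feat[["a.S-R"]]), -1.15, tolerance = 0.02)
})

test_that("distances are scale-invariant while amplitudes scale linearly", {
  ecg <- make_ecg(beat_template("ecg"), duration = 6)
  f1 <- extract_features(detect_ecg_fiducials(ecg$signal), ecg$signal)
  scaled <- signal(2 * ecg$signal$samples, 500, kind = "ecg")
  f2 <- extract_features(detect_ecg_fiducials(scaled), scaled)
  dn <- grep("^d\\.", names(f1), value = TRUE)
  an <- grep("^a\\.", names(f1), value = TRUE)
  expect_equal(as.matrix(f2[, dn]), as.matrix(f1[, dn]), tolerance = 1e-12)
  expect_equal(as.matrix(f2[, an]), 2 * as.matrix(f1[, an]),
               tolerance = 1e-12)
})

test_that("RR normalization cancels a uniform time stretch", {
  fast <- make_ecg(beat_template("ecg", heart_rate = 80), duration = 6)
  # the same morphology slowed down: every interval stretches by 80/60
  slow_tpl <- beat_template("ecg", heart_rate = 60,
    centers = beat_template("ecg", heart_rate = 80)$centers * 80 / 60,
    widths = beat_template("ecg", heart_rate = 80)$widths * 80 / 60)
  slow <- make_ecg(slow_tpl, duration = 8)
  ff <- extract_features(detect_ecg_fiducials(fast$signal), fast$signal,
                         aggregate = "mean")
  fsl <- extract_features(detect_ecg_fiducials(slow$signal), slow$signal,
                          aggregate = "mean")
  dn <- grep("^d\\.", names(ff), value = TRUE)
  diffs <- abs(as.numeric(ff[1, dn]) - as.numeric(fsl[1, dn]))
  names(diffs) <- dn
  sample_equiv <- 1 / 500 / 0.75   # one sample at the faster mean RR
  # wave-center landmarks agree to within two sample-equivalents;
  # threshold-crossing onsets/offsets carry extra discretization of the
  # 10% crossing and get a correspondingly looser bound
  onset_based <- grepl("PB|PE|TB|TE", dn)
  expect_true(all(diffs[!onset_based] < 2 * sample_equiv))
  expect_true(all(diffs[onset_based] < 6 * sample_equiv))
})

test_that("feature vectors survive a high-quality reconstruction", {
  # project a clean ECG onto its 100 largest DCT coefficients, compress at
  # CR 0.7, reconstruct with SWAMP, and compare features before/after
  fs <- 500
  n <- 1024
  ecg <- make_ecg(beat_template("ecg", heart_rate = 75), duration = n / fs,
                  fs = fs)
  domain <- dct_domain(n)
  x <- heartcs:::dct_sparsify(ecg$signal$samples, domain, 100)
  sig <- signal(x, fs, kind = "ecg")
  ens <- gaussian_ensemble(n, 0.7, seed = 21)
  rec <- cs_reconstruct(sense(ens, x), domain, "swamp",
                        config = swamp_config(alpha = 0.83))
  expect_gt(matching_rate(x, rec$x_hat), 0.99)
  rsig <- signal(rec$x_hat, fs, kind = "ecg")
  f_before <- extract_features(detect_ecg_fiducials(sig), sig,
                               aggregate = "mean")
  f_after <- extract_features(detect_ecg_fiducials(rsig), rsig,
                              aggregate = "mean")
  fn <- feature_names("ecg")
  rel <- abs(as.numeric(f_after[, fn]) - as.numeric(f_before[, fn])) /
    pmax(abs(as.numeric(f_before[, fn])), 1e-3)
  expect_true(all(rel < 0.05))
})
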